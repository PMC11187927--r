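test_that("the cytosolic tip is the lowest modeled residue on the intracellular arm", {
  s <- fixture_stub()
  tip5 <- cytosolic_tip(select_segment(s, "TM5", "5.36", "5.75"))
  expect_identical(tip5$grn, "5.75")
  tip6 <- cytosolic_tip(select_segment(s, "TM6", "6.29", "6.60"))
  expect_identical(tip6$grn, "6.29")
  # a one-residue segment at the anchor is its own tip (length 0)
  seg1 <- select_segment(s, "TM5", "5.50", "5.50")
  expect_identical(cytosolic_tip(seg1)$grn, "5.50")
  expect_equal(helix_length(seg1), 0L)
  # anchor missing from the segment
  expect_error(cytosolic_tip(select_segment(s, "TM5", "5.36", "5.45")),
               "anchor")
})

test_that("an inverted helix is refused as degenerate", {
  up <- make_ideal_helix(helix_spec(40, tilt_deg = 180, grn_start = "5.36"))
  expect_error(cytosolic_tip(select_segment(up, "TM5", "5.36", "5.75")),
               "degenerate")
})

test_that("helix length counts GRN positions from the tip to x.50", {
  tip_len <- function(tip5) {
    s <- make_ideal_helix(helix_spec(tip5 - 36L + 1L, grn_start = "5.36"))
    helix_length(select_segment(s, "TM5", "5.36", sprintf("5.%02d", tip5)))
  }
  expect_equal(tip_len(75L), 25L)         # Gs-typical tip
  expect_equal(tip_len(69L), 19L)         # just past the extended-TM5 anchor
  expect_gt(tip_len(69L), 18L)
  expect_equal(tip_len(75L) - tip_len(66L), 9L)  # a 5.67..5.75 extension
  # TM6 counts downward from 6.50
  s6 <- make_ideal_helix(helix_spec(32, grn_start = "6.29"))
  expect_equal(helix_length(select_segment(s6, "TM6", "6.29", "6.60")), 21L)
  # length is GRN arithmetic, robust to an unmodeled gap inside the helix
  s <- make_ideal_helix(helix_spec(40, grn_start = "5.36"))
  s$atom <- s$atom[!(s$atom$resno %in% 20:22), ]
  s <- annotated_structure(s$atom, receptor_chain = "A")
  expect_equal(helix_length(select_segment(s, "TM5", "5.36", "5.75")), 25L)
})

test_that("angle_between is the clamped arccos in degrees", {
  expect_equal(angle_between(c(0, 0, 1), c(0, 0, 2)), 0)
  expect_equal(angle_between(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(angle_between(c(0, 0, 1), c(0, sin(pi / 15), cos(pi / 15))), 12,
               tolerance = 1e-9)
  expect_error(angle_between(c(0, 0, 0), c(1, 0, 0)), "zero")
})

test_that("carbonyl averaging recovers ideal helix axes", {
  down <- make_ideal_helix(helix_spec(25, tilt_deg = 0, grn_start = "5.36"))
  ori <- helix_orientation(select_segment(down, "TM5", "5.36", "5.60"), 11L)
  expect_gte(sum(ori$axis * c(0, 0, -1)), 0.999)
  expect_equal(ori$n_residues_used, 11L)
  tilted <- make_ideal_helix(helix_spec(25, tilt_deg = 18, azimuth_deg = 77,
                                        grn_start = "5.36"))
  ori2 <- helix_orientation(select_segment(tilted, "TM5", "5.36", "5.60"), 11L)
  expect_lt(angle_between(ori2$axis, c(0, 0, -1)) - 18, 1)
  frag <- make_ideal_helix(helix_spec(4, grn_start = "5.40"))
  frag$atom <- frag$atom[1:13, ]   # 3 complete residues + a lone N
  frag <- annotated_structure(frag$atom, receptor_chain = "A")
  expect_error(helix_orientation(select_segment(frag, "TM5", "5.40", "5.43")),
               "insufficient")
})

test_that("residues missing C or O are skipped and the window extends deeper", {
  s <- make_ideal_helix(helix_spec(30, grn_start = "5.36"))
  drop <- s$atom$resno %in% c(25L, 27L) & s$atom$elety == "O"
  s$atom <- s$atom[!drop, ]
  s <- annotated_structure(s$atom, receptor_chain = "A")
  ori <- helix_orientation(select_segment(s, "TM5", "5.36", "5.65"), 11L)
  expect_equal(ori$n_residues_used, 11L)
  expect_gte(sum(ori$axis * c(0, 0, -1)), 0.999)
})

test_that("the reference TM5 axis uses a 22-residue window and TM6 reference is -Z", {
  ref <- fixture_reference()
  refs <- build_reference(ref, "5.36", "5.75")
  expect_equal(refs$tm6_reference_axis, c(0, 0, -1))
  expect_lt(angle_between(refs$tm5_reference_axis, c(0, 0, -1)), 1)
  # the reference against itself, at the reference window, is exactly zero
  expect_equal(tm5_tilt(ref, refs, "5.36", "5.75", n_window = 22L), 0,
               tolerance = 1e-9)
  short <- make_ideal_helix(helix_spec(10, grn_start = "5.41"))
  expect_error(build_reference(short, "5.41", "5.50"), "insufficient")
})

test_that("tilt and outward angles recover constructed geometry", {
  ref <- fixture_reference()
  refs <- build_reference(ref, "5.36", "5.75")
  s <- fixture_stub(tilt5 = 18, out6 = 23.8)
  expect_equal(tm5_tilt(s, refs, "5.36", "5.75"), 18, tolerance = 1)
  expect_equal(tm6_outward(s, "6.29", "6.60"), 23.8, tolerance = 1)
  flat <- fixture_stub(tilt5 = 0, out6 = 0, id = "flat")
  expect_lt(tm5_tilt(flat, refs, "5.36", "5.75"), 0.5)
  expect_lt(tm6_outward(flat, "6.29", "6.60"), 0.5)
  wide <- make_ideal_helix(helix_spec(32, tilt_deg = 90, grn_start = "6.29"))
  expect_equal(tm6_outward(wide, "6.29", "6.60"), 90, tolerance = 1)
})

test_that("extract_features populates all four descriptors deterministically", {
  ref <- fixture_reference()
  refs <- build_reference(ref, "5.36", "5.75")
  s <- fixture_stub(tilt5 = 12, out6 = 24, tip5 = 73L, label = "GS")
  cfg <- bounds_of(tip5 = 73L)
  f1 <- extract_features(s, refs, cfg)
  f2 <- extract_features(s, refs, cfg)
  expect_identical(f1, f2)
  expect_equal(f1$tm5_len, 23L)
  expect_equal(f1$tm6_len, 21L)
  expect_equal(f1$tm5_tilt, 12, tolerance = 1)
  expect_equal(f1$tm6_outward, 24, tolerance = 1)
  expect_identical(f1$coupling_label, "GS")
  # a missing TM6 names the failing structure
  no6 <- make_ideal_helix(helix_spec(40, grn_start = "5.36"),
                          structure_id = "no_tm6")
  expect_error(extract_features(no6, refs, cfg), "no_tm6")
})

test_that("features are invariant to translation and Z-rotation of a framed structure", {
  ref <- fixture_reference()
  refs <- build_reference(ref, "5.36", "5.75")
  s <- fixture_stub(tilt5 = 9, out6 = 17)
  cfg <- bounds_of()
  base <- extract_features(s, refs, cfg)
  shifted <- apply_transform(s, list(rotation = diag(3),
                                     translation = c(30, -12, 0)))
  f_shift <- extract_features(shifted, refs, cfg)
  expect_equal(f_shift$tm6_outward, base$tm6_outward, tolerance = 1e-6)
  expect_equal(f_shift$tm5_tilt, base$tm5_tilt, tolerance = 1e-6)
  rotated <- apply_transform(s, list(rotation = rotation_z(65),
                                     translation = c(0, 0, 0)))
  f_rot <- extract_features(rotated, refs, cfg)
  # the outward angle is axially symmetric about the membrane normal
  expect_equal(f_rot$tm6_outward, base$tm6_outward, tolerance = 1e-6)
})

test_that("11- and 22-residue windows agree on ideal helices", {
  for (tl in c(0, 8, 19)) {
    s <- make_ideal_helix(helix_spec(30, tilt_deg = tl, azimuth_deg = 3 * tl,
                                     grn_start = "5.36"))
    seg <- select_segment(s, "TM5", "5.36", "5.65")
    a11 <- helix_orientation(seg, 11L)$axis
    a22 <- helix_orientation(seg, 22L)$axis
    expect_lt(angle_between(a11, a22), 0.5)
  }
})
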