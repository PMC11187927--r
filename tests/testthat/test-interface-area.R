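test_that("SASA matches the analytic sphere and is additive for far atoms", {
  lone <- shrake_rupley(matrix(c(0, 0, 0), 1), "C")
  expect_equal(lone$total, 4 * pi * 3.1^2, tolerance = 0.01)
  expect_equal(lone$total, sum(lone$per_atom_area), tolerance = 1e-6)
  pair <- shrake_rupley(rbind(c(0, 0, 0), c(50, 0, 0)), c("C", "C"))
  expect_equal(pair$total, 2 * lone$total, tolerance = 1e-9)
  expect_warning(shrake_rupley(matrix(0, 1, 3), "XX"), "unknown element")
})

test_that("two overlapping spheres match the spherical-cap closed form", {
  r <- 1.7 + 1.4
  for (d in c(2.0, 3.0, 4.5)) {
    got <- shrake_rupley(rbind(c(0, 0, 0), c(d, 0, 0)), c("C", "C"))$total
    # each sphere loses a cap of height h = r - d/2; area 2*pi*r*h
    analytic <- 2 * (4 * pi * r^2 - 2 * pi * r * (r - d / 2))
    expect_equal(got, analytic, tolerance = 0.02 * analytic)
  }
})

test_that("SASA is converged at the default point count", {
  tc <- make_toy_complex(helix_spec(8, grn_start = "5.40"), slab_gap = 1)
  a <- gcoupler:::chain_atoms(tc, "R")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  s1 <- shrake_rupley(xyz, a$elesy, n_points = 960L)$total
  s2 <- shrake_rupley(xyz, a$elesy, n_points = 1920L)$total
  expect_lt(abs(s1 - s2) / s2, 0.01)
})

test_that("buried area is symmetric, zero when separated, and refuses overlap", {
  tc <- make_toy_complex(helix_spec(10, grn_start = "5.40"), slab_gap = 20)
  r <- gcoupler:::chain_atoms(tc, "R"); g <- gcoupler:::chain_atoms(tc, "G")
  expect_equal(buried_area(r, g), 0, tolerance = 1e-6)
  near <- make_toy_complex(helix_spec(10, grn_start = "5.40"), slab_gap = 0)
  rn <- gcoupler:::chain_atoms(near, "R"); gn <- gcoupler:::chain_atoms(near, "G")
  ab <- buried_area(rn, gn)
  expect_gt(ab, 100)
  expect_equal(buried_area(gn, rn), ab, tolerance = 1e-9)
  expect_equal(buried_area(rn, gn, half = FALSE), 2 * ab, tolerance = 1e-9)
  expect_error(buried_area(rn, rn), "overlap")
})

test_that("buried area decreases monotonically with the helix-slab gap", {
  areas <- vapply(c(0, 2, 4, 8, 20), function(g) {
    tc <- make_toy_complex(helix_spec(10, grn_start = "5.40"), slab_gap = g)
    buried_area(gcoupler:::chain_atoms(tc, "R"),
                gcoupler:::chain_atoms(tc, "G"))
  }, 0)
  expect_true(all(diff(areas) <= 1e-6))
  expect_gt(areas[1], areas[4])
})

test_that("interface residues obey the 4-angstrom any-atom cutoff symmetrically", {
  mk <- function(x) data.frame(chain = "A", resno = 1L, insert = "",
                               resid = "GLY", elety = "CA", x = x, y = 0, z = 0,
                               o = 1, b = 0, elesy = "C")
  near <- interface_residues(mk(0), transform(mk(3.9), chain = "B"))
  expect_equal(nrow(near$a), 1L)
  expect_equal(nrow(near$b), 1L)
  far <- interface_residues(mk(0), transform(mk(4.1), chain = "B"))
  expect_equal(nrow(far$a), 0L)
  expect_equal(nrow(far$b), 0L)
  tc <- make_toy_complex(helix_spec(10, grn_start = "5.40"), slab_gap = 2)
  r <- gcoupler:::chain_atoms(tc, "R"); g <- gcoupler:::chain_atoms(tc, "G")
  ab <- interface_residues(r, g); ba <- interface_residues(g, r)
  expect_identical(ab$a, ba$b)
  expect_identical(ab$b, ba$a)
})

test_that("extended-TM subsets follow the 5.69 / 6.29 anchors", {
  s75 <- make_ideal_helix(helix_spec(40, grn_start = "5.36"))
  seg <- select_segment(s75, "TM5", "5.36", "5.75")
  ext <- extended_tm(seg, "GS")
  expect_equal(length(unique(ext$resno)), 7L)          # 5.69 .. 5.75
  expect_true(all(gcoupler::parse_grn(ext$grn)$position >= 69))
  s66 <- make_ideal_helix(helix_spec(31, grn_start = "5.36"))
  expect_equal(nrow(extended_tm(select_segment(s66, "TM5", "5.36", "5.66"),
                                "GS")), 0L)
  # a 15-residue extension (tip at 5.83)
  s83 <- make_ideal_helix(helix_spec(48, grn_start = "5.36"))
  expect_equal(length(unique(extended_tm(
    select_segment(s83, "TM5", "5.36", "5.83"), "GS")$resno)), 15L)
  s6 <- make_ideal_helix(helix_spec(36, grn_start = "6.25"))
  seg6 <- select_segment(s6, "TM6", "6.25", "6.60")
  expect_equal(length(unique(extended_tm(seg6, "GIO")$resno)), 5L)  # 6.25..6.29
  expect_error(extended_tm(seg, "GIO"), "TM6")
  expect_error(extended_tm(seg6, "GS"), "TM5")
})

test_that("the contact-area regression recovers slopes and flags degeneracy", {
  x <- 3:17
  exact <- data.frame(extended_residues = x, contact_area = 40 * x)
  fit <- fit_area_regression(exact)
  expect_equal(fit$slope, 40, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  withr::local_seed(23)
  noisy <- data.frame(extended_residues = x,
                      contact_area = 40 * x + stats::rnorm(15, sd = 30))
  nf <- fit_area_regression(noisy)
  expect_lt(abs(nf$slope - 40), 3 * nf$slope_se)
  expect_lt(nf$r_squared, 1)
  expect_error(fit_area_regression(exact[1:2, ]), ">= 3")
  flat <- data.frame(extended_residues = rep(5, 4), contact_area = 1:4)
  expect_error(fit_area_regression(flat), "zero variance")
})

test_that("the OLS slope estimator is unbiased on simulated lines", {
  withr::local_seed(77)
  slopes <- replicate(200, {
    x <- 3:17
    fit_area_regression(data.frame(
      extended_residues = x,
      contact_area = 40 * x + stats::rnorm(15, sd = 30)))$slope
  })
  se_mean <- stats::sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 40), 2 * se_mean)
})
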