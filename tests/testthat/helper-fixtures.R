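# shared synthetic fixtures, built once per test run

# a full receptor stub with scaffold helices, TM5 tip 5.75 (length 25),
# tilt 12 deg, TM6 from 6.29 (length 21), outward 20 deg
fixture_stub <- function(tilt5 = 12, out6 = 20, tip5 = 75L, start6 = 29L,
                         azimuth = 40, id = "stub", label = NULL) {
  make_receptor_stub(
    helix_spec(tip5 - 36L + 1L, tilt_deg = tilt5, azimuth_deg = azimuth,
               grn_start = "5.36"),
    helix_spec(60L - start6 + 1L, tilt_deg = out6, azimuth_deg = azimuth + 120,
               grn_start = sprintf("6.%02d", start6)),
    structure_id = id, coupling_label = label)
}

# vertical-helix reference stub whose TM5 axis defines the tilt origin
fixture_reference <- function() {
  fixture_stub(tilt5 = 0, out6 = 0, id = "reference")
}

bounds_of <- function(tip5 = 75L, start6 = 29L) {
  list(tm5_start = "5.36", tm5_end = sprintf("5.%02d", tip5),
       tm6_start = sprintf("6.%02d", start6), tm6_end = "6.60")
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3L, 3L)
}

random_rotation <- function() {
  qr_q <- qr.Q(qr(matrix(stats::rnorm(9), 3L)))
  if (det(qr_q) < 0) qr_q[, 1L] <- -qr_q[, 1L]
  qr_q
}

structure_xyz <- function(s) as.matrix(s$atom[, c("x", "y", "z")])
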