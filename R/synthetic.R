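#' Specification of an ideal transmembrane helix fixture
#'
#' Describes one synthetic alpha helix: residue count, direction of its
#' cytosolic end relative to the membrane normal, and backbone dihedrals.
#' The backbone is grown by internal-coordinate chain extension with ideal
#' bond lengths and angles, so the carbonyl orientations that the axis
#' estimator consumes are chemically realistic; with the default phi/psi of
#' -57/-47 degrees the helix rises ~1.5 angstrom per residue with ~100
#' degrees of twist (3.6 residues per turn).
#'
#' @param n_residues number of residues (>= 4).
#' @param tilt_deg angle of the cytosolic helix direction from (0, 0, -1).
#' @param azimuth_deg in-plane direction of the tilt, degrees from +X.
#' @param grn_start GRN of the first (N-terminal) residue, e.g. `"5.36"`;
#'   GRNs are assigned sequentially along the chain. The helix number fixes
#'   the topology: odd helices (TM1/3/5/7) run extracellular to cytosolic
#'   N- to C-terminus, even helices (TM2/4/6) the reverse.
#' @param phi,psi backbone dihedrals in degrees.
#' @param chain chain id.
#' @param resno_start first author residue number.
#' @param center xyz to which the C-alpha centroid is translated.
#' @return A `helix_spec` list.
#' @export
helix_spec <- function(n_residues, tilt_deg = 0, azimuth_deg = 0,
                       grn_start = "5.36", phi = -57, psi = -47,
                       chain = "A", resno_start = 1L, center = c(0, 0, 0)) {
  if (n_residues < 4L) stop("a helix fixture needs >= 4 residues")
  parse_grn(grn_start)
  structure(list(n_residues = as.integer(n_residues), tilt_deg = tilt_deg,
                 azimuth_deg = azimuth_deg, grn_start = grn_start,
                 phi = phi, psi = psi, chain = chain,
                 resno_start = as.integer(resno_start), center = center),
            class = "helix_spec")
}

# NeRF atom placement: position D bonded to C with |CD| = bond,
# angle(B,C,D) = ang and dihedral(A,B,C,D) = tor (degrees)
place_atom <- function(a, b, c, bond, ang, tor) {
  ang <- ang * pi / 180; tor <- tor * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + cbind(bc, m, n) %*% d2
}

# ideal backbone internal coordinates (angstrom / degrees)
.bb <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
            ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
            ang_ca_c_o = 120.8, omega = 180)

# raw backbone of an n-residue helix with constant phi/psi; rows N,CA,C,O
# per residue, in an arbitrary frame
build_backbone <- function(n, phi, psi) {
  xyz <- matrix(NA_real_, nrow = 4L * n, ncol = 3L)
  row <- function(i, what) (i - 1L) * 4L + match(what, c("N", "CA", "C", "O"))
  xyz[row(1, "N"), ] <- c(0, 0, 0)
  xyz[row(1, "CA"), ] <- c(.bb$n_ca, 0, 0)
  a <- .bb$ang_n_ca_c * pi / 180
  xyz[row(1, "C"), ] <- xyz[row(1, "CA"), ] +
    .bb$ca_c * c(-cos(a), sin(a), 0)
  for (i in seq_len(n)[-1L]) {
    xyz[row(i, "N"), ] <- place_atom(
      xyz[row(i - 1, "N"), ], xyz[row(i - 1, "CA"), ], xyz[row(i - 1, "C"), ],
      .bb$c_n, .bb$ang_ca_c_n, psi)
    xyz[row(i, "CA"), ] <- place_atom(
      xyz[row(i - 1, "CA"), ], xyz[row(i - 1, "C"), ], xyz[row(i, "N"), ],
      .bb$n_ca, .bb$ang_c_n_ca, .bb$omega)
    xyz[row(i, "C"), ] <- place_atom(
      xyz[row(i - 1, "C"), ], xyz[row(i, "N"), ], xyz[row(i, "CA"), ],
      .bb$ca_c, .bb$ang_n_ca_c, phi)
    # carbonyl O of residue i-1: anti to the incoming N across the sp2 carbon
    xyz[row(i - 1, "O"), ] <- place_atom(
      xyz[row(i - 1, "N"), ], xyz[row(i - 1, "CA"), ], xyz[row(i - 1, "C"), ],
      .bb$c_o, .bb$ang_ca_c_o, psi + 180)
  }
  xyz[row(n, "O"), ] <- place_atom(
    xyz[row(n, "N"), ], xyz[row(n, "CA"), ], xyz[row(n, "C"), ],
    .bb$c_o, .bb$ang_ca_c_o, psi + 180)
  xyz
}

# rotation taking unit vector a onto unit vector b (Rodrigues)
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth < -1 + 1e-12) {           # antiparallel: flip about any orthogonal
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a; v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3L, 3L)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

#' Build an ideal helix as an annotated structure
#'
#' Grows a full backbone (N, CA, C, O), orients it so its cytosolic
#' direction points at the requested (tilt, azimuth) from the membrane
#' normal's intracellular direction (0, 0, -1), assigns GRNs sequentially
#' from `grn_start` and returns a framed [annotated_structure()]. The
#' construction is deterministic.
#'
#' @param spec a [helix_spec()].
#' @param structure_id identifier.
#' @return An [annotated_structure()] with a single chain.
#' @export
make_ideal_helix <- function(spec, structure_id = "helix") {
  stopifnot(inherits(spec, "helix_spec"))
  annotated_structure(helix_atoms(spec), structure_id = structure_id,
                      receptor_chain = spec$chain)
}

# atom table of one oriented helix (shared by make_ideal_helix and the stub)
helix_atoms <- function(spec) {
  n <- spec$n_residues
  xyz <- build_backbone(n, spec$phi, spec$psi)
  ca_idx <- seq(2L, 4L * n, by = 4L)
  ca <- xyz[ca_idx, ]
  # exact helix axis: the screw axis of the residue-to-residue rigid motion
  # (the Calpha principal axis is biased by the spiral for short helices)
  tr <- kabsch_fit(xyz[1:4, ], xyz[5:8, ])
  r <- tr$rotation
  axis <- c(r[3, 2] - r[2, 3], r[1, 3] - r[3, 1], r[2, 1] - r[1, 2])
  axis <- axis / sqrt(sum(axis^2))
  if (sum(axis * (ca[n, ] - ca[1L, ])) < 0) axis <- -axis
  g0 <- parse_grn(spec$grn_start)
  t <- spec$tilt_deg * pi / 180; az <- spec$azimuth_deg * pi / 180
  cyt_dir <- c(sin(t) * cos(az), sin(t) * sin(az), -cos(t))
  # odd helices run extracellular->cytosolic N->C; even helices the reverse
  target <- if (g0$helix %% 2L == 1L) cyt_dir else -cyt_dir
  rot <- rotation_between(axis, target)
  xyz <- sweep(xyz %*% t(rot), 2L, colMeans(ca %*% t(rot)) - spec$center, "-")
  atom_names <- rep(c("N", "CA", "C", "O"), n)
  data.frame(
    chain = spec$chain,
    resno = rep(spec$resno_start + seq_len(n) - 1L, each = 4L),
    insert = "", resid = "ALA", elety = atom_names,
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], o = 1, b = 0,
    elesy = substr(atom_names, 1L, 1L),
    grn = rep(sprintf("%d.%d", g0$helix, g0$position + seq_len(n) - 1L),
              each = 4L),
    stringsAsFactors = FALSE)
}

#' Build a two-helix receptor stub with a superposition scaffold
#'
#' Assembles TM5 and TM6 fixtures (and, by default, short vertical TM1-TM4
#' and TM7 scaffold helices whose layout is identical across stubs, so any
#' two stubs can be superposed over the scaffold) into one pre-framed
#' receptor chain. Helices are laterally offset by >= 10 angstrom; the
#' construction is deterministic.
#'
#' @param tm5,tm6 [helix_spec()]s for the two measured helices (their
#'   `chain`, `resno_start` and `center` are overridden by the stub
#'   layout's).
#' @param frame_helices include the TM1-4/TM7 scaffold (default `TRUE`).
#' @param structure_id identifier.
#' @param coupling_label optional `"GS"` / `"GIO"`.
#' @return A single-chain framed [annotated_structure()].
#' @export
make_receptor_stub <- function(tm5, tm6, frame_helices = TRUE,
                               structure_id = "stub", coupling_label = NULL) {
  tm5$chain <- "A"; tm5$resno_start <- 501L; tm5$center <- c(0, 0, 0)
  tm6$chain <- "A"; tm6$resno_start <- 601L; tm6$center <- c(12, 0, 0)
  parts <- list(helix_atoms(tm5), helix_atoms(tm6))
  if (frame_helices) {
    scaffold <- list(c(1L, -12, 8), c(2L, -12, -8), c(3L, 0, -14),
                     c(4L, 12, -14), c(7L, 12, 14))
    for (sc in scaffold) {
      spec <- helix_spec(12L, tilt_deg = 0, grn_start = sprintf("%d.44", sc[1L]),
                         chain = "A", resno_start = 100L * sc[1L] + 1L,
                         center = c(sc[2L], sc[3L], 0))
      parts <- c(parts, list(helix_atoms(spec)))
    }
  }
  atom <- do.call(rbind, parts)
  annotated_structure(atom, structure_id = structure_id, receptor_chain = "A",
                      coupling_label = coupling_label)
}

#' Gaussian group models of the TM5/TM6 geometries
#'
#' Per-class means and standard deviations of the four geometries
#' (`tm5_len`, `tm5_tilt`, `tm6_outward`, `tm6_len`) observed across
#' activated class A receptor structures: Gs-coupled receptors have longer
#' (23.1 +/- 4.6) and more tilted (12.3 +/- 7.1 deg) TM5 and larger TM6
#' outward movement (23.8 +/- 8.4 deg) than Gi/o-coupled ones
#' (18.9 +/- 3.1, 5.90 +/- 2.9 deg, 19.7 +/- 7.6 deg), while TM6 lengths
#' are indistinguishable (medians 20.5 vs 22; spread chosen at 3 residues).
#'
#' @param cor_len_tilt optional correlation between TM5 length and tilt
#'   (Gs-coupled receptors show ~0.5-0.6; default 0, independent draws).
#' @return A `group_model` list: `label`, `mean`, `sd`, `cor_len_tilt`.
#' @export
gs_group_model <- function(cor_len_tilt = 0) {
  structure(list(label = "GS",
                 mean = c(tm5_len = 23.1, tm5_tilt = 12.3,
                          tm6_outward = 23.8, tm6_len = 20.5),
                 sd = c(tm5_len = 4.6, tm5_tilt = 7.1,
                        tm6_outward = 8.4, tm6_len = 3),
                 cor_len_tilt = cor_len_tilt),
            class = "group_model")
}

#' @rdname gs_group_model
#' @export
gio_group_model <- function(cor_len_tilt = 0) {
  structure(list(label = "GIO",
                 mean = c(tm5_len = 18.9, tm5_tilt = 5.90,
                          tm6_outward = 19.7, tm6_len = 22),
                 sd = c(tm5_len = 3.1, tm5_tilt = 2.9,
                        tm6_outward = 7.6, tm6_len = 3),
                 cor_len_tilt = cor_len_tilt),
            class = "group_model")
}

#' Sample a labeled geometry feature table
#'
#' Draws independent Gaussians per feature from each group model (optionally
#' with a TM5 length/tilt correlation), rounds lengths to whole residues
#' (floored at 4) and floors angles at 0. With the default models and
#' 24 Gs : 74 Gi/o counts this emulates the composition of the class A
#' homology-model training set.
#'
#' @param models list of `group_model`s.
#' @param n_per_group integer vector of draws per model (recycled).
#' @param seed RNG seed.
#' @return data.frame `structure_id`, `coupling_label`, `tm5_len`,
#'   `tm6_len`, `tm5_tilt`, `tm6_outward`.
#' @export
sample_feature_table <- function(models = list(gs_group_model(),
                                               gio_group_model()),
                                 n_per_group = c(24L, 74L), seed = 2784L) {
  n_per_group <- rep_len(as.integer(n_per_group), length(models))
  stopifnot(all(n_per_group >= 1L))
  withr::with_seed(seed, {
    rows <- Map(function(gm, n) {
      len <- stats::rnorm(n, gm$mean["tm5_len"], gm$sd["tm5_len"])
      tilt_z <- stats::rnorm(n)
      tilt <- gm$mean["tm5_tilt"] + gm$sd["tm5_tilt"] *
        (gm$cor_len_tilt * (len - gm$mean["tm5_len"]) / gm$sd["tm5_len"] +
           sqrt(1 - gm$cor_len_tilt^2) * tilt_z)
      data.frame(
        coupling_label = gm$label,
        tm5_len = pmax(4L, as.integer(round(len))),
        tm6_len = pmax(4L, as.integer(round(
          stats::rnorm(n, gm$mean["tm6_len"], gm$sd["tm6_len"])))),
        tm5_tilt = pmax(0, tilt),
        tm6_outward = pmax(0, stats::rnorm(n, gm$mean["tm6_outward"],
                                           gm$sd["tm6_outward"])),
        stringsAsFactors = FALSE)
    }, models, n_per_group)
    out <- do.call(rbind, rows)
    out <- cbind(structure_id = sprintf("sim_%s_%03d", tolower(out$coupling_label),
                                        stats::ave(seq_len(nrow(out)),
                                                   out$coupling_label,
                                                   FUN = seq_along)),
                 out)
    rownames(out) <- NULL
    out
  })
}

#' Build a toy helix/G-alpha-slab complex for interface tests
#'
#' Places a helix (chain `R`) above a planar lattice of pseudo-atoms (chain
#' `G`) standing in for the flattened G-alpha surface, with a prescribed
#' vertical gap between the lowest helix atom and the slab plane. Buried
#' interface area decreases monotonically with the gap.
#'
#' @param helix a [helix_spec()].
#' @param slab_gap vertical gap in angstrom (>= 0).
#' @param slab_spacing lattice spacing (default 2 angstrom).
#' @param slab_halfwidth lattice half-extent around the helix footprint.
#' @param structure_id identifier.
#' @return An [annotated_structure()] with `receptor_chain = "R"` and
#'   `galpha_chain = "G"`.
#' @export
make_toy_complex <- function(helix, slab_gap, slab_spacing = 2,
                             slab_halfwidth = 10, structure_id = "toy_complex") {
  if (slab_gap < 0) stop("slab gap must be >= 0")
  helix$chain <- "R"
  h <- helix_atoms(helix)
  z0 <- min(h$z) - slab_gap
  g <- expand.grid(x = seq(-slab_halfwidth, slab_halfwidth, by = slab_spacing),
                   y = seq(-slab_halfwidth, slab_halfwidth, by = slab_spacing))
  slab <- data.frame(chain = "G", resno = seq_len(nrow(g)), insert = "",
                     resid = "UNK", elety = "C",
                     x = g$x + mean(h$x), y = g$y + mean(h$y), z = z0,
                     o = 1, b = 0, elesy = "C", grn = NA_character_,
                     stringsAsFactors = FALSE)
  annotated_structure(rbind(h, slab), structure_id = structure_id,
                      receptor_chain = "R", galpha_chain = "G")
}
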