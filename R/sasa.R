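#' Shrake-Rupley solvent accessible surface area
#'
#' Rolls a probe sphere over each atom: `n_points` test points are placed on
#' the expanded sphere (van der Waals radius + probe) with a deterministic
#' golden-section spiral lattice, and a point counts as accessible when it
#' lies outside every neighbouring expanded sphere. Determinism (no seed)
#' makes interface areas exactly reproducible.
#'
#' @param xyz n x 3 coordinate matrix (angstrom).
#' @param elements character vector of element symbols, one per atom.
#' @param probe probe radius in angstrom (default 1.4, a water molecule).
#' @param n_points sphere test points per atom (default 960).
#' @param radii named vector of van der Waals radii; unknown elements fall
#'   back to 1.8 angstrom with a warning.
#' @return `sasa_result`: `per_atom_area` (angstrom^2 per atom), `total`,
#'   `probe_radius`, `n_sphere_points`.
#' @export
shrake_rupley <- function(xyz, elements, probe = 1.4, n_points = 960L,
                          radii = vdw_radii()) {
  xyz <- rbind(xyz)
  if (nrow(xyz) < 1L) stop("need at least one atom")
  stopifnot(nrow(xyz) == length(elements))
  r <- radii[toupper(elements)]
  if (any(is.na(r))) {
    warning("unknown element(s) ",
            paste(unique(elements[is.na(r)]), collapse = ", "),
            "; using 1.8 angstrom radius")
    r[is.na(r)] <- 1.8
  }
  r <- unname(r) + probe
  sphere <- golden_spiral(n_points)
  n <- nrow(xyz)
  per_atom <- numeric(n)
  # neighbour lists from the pairwise distance bound r_i + r_j
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    pts <- sweep(sphere * r[i], 2L, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- (pts[acc, 1L] - xyz[j, 1L])^2 + (pts[acc, 2L] - xyz[j, 2L])^2 +
            (pts[acc, 3L] - xyz[j, 3L])^2
      acc[acc] <- dj >= r[j]^2
    }
    per_atom[i] <- 4 * pi * r[i]^2 * sum(acc) / n_points
  }
  structure(list(per_atom_area = per_atom, total = sum(per_atom),
                 probe_radius = probe, n_sphere_points = n_points),
            class = "sasa_result")
}

# Bondi-type van der Waals radii (angstrom)
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
}

# deterministic golden-section spiral lattice on the unit sphere
golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  theta <- pi * (1 + sqrt(5)) * i
  cbind(rho * cos(theta), rho * sin(theta), z)
}

#' Atom records of one chain, optionally restricted to residues
#'
#' Convenience accessor for handing chain selections to [buried_area()] and
#' [interface_residues()].
#'
#' @param s an [annotated_structure()].
#' @param chain chain id.
#' @param resno optional author residue numbers to keep.
#' @return Atom data.frame.
#' @export
chain_atoms <- function(s, chain, resno = NULL) {
  a <- s$atom[s$atom$chain == chain, , drop = FALSE]
  if (!is.null(resno)) a <- a[a$resno %in% resno, , drop = FALSE]
  a
}

#' Buried interface area between two atom selections
#'
#' The contact area between two bodies in the same frame, by the standard
#' half-buried-SASA convention:
#' `0.5 * (SASA(A) + SASA(B) - SASA(A+B))`. Used for receptor/G-alpha and
#' extended-TM/G-alpha contact areas.
#'
#' @param atoms_a,atoms_b atom data.frames (columns `x`, `y`, `z`, `elesy`)
#'   of the two disjoint selections, e.g. from an [annotated_structure()]'s
#'   `atom` table.
#' @param half when `FALSE`, report the full SASA loss instead of half.
#' @param ... passed to [shrake_rupley()].
#' @return Buried area in angstrom^2 (clamped at 0 against sampling noise).
#' @export
buried_area <- function(atoms_a, atoms_b, half = TRUE, ...) {
  key_a <- paste(atoms_a$chain, atoms_a$resno, atoms_a$elety)
  key_b <- paste(atoms_b$chain, atoms_b$resno, atoms_b$elety)
  if (length(intersect(key_a, key_b)) > 0L) {
    stop("selections overlap: buried area is defined for disjoint bodies")
  }
  sasa <- function(a) shrake_rupley(as.matrix(a[, c("x", "y", "z")]),
                                    a$elesy, ...)$total
  delta <- sasa(atoms_a) + sasa(atoms_b) - sasa(rbind(atoms_a, atoms_b))
  max(0, if (half) delta / 2 else delta)
}

#' Interface residues within a distance cutoff
#'
#' Residues of either selection having any atom within `cutoff` of the
#' other selection — the convention used to highlight receptor/G-alpha
#' contacts (default 4 angstrom).
#'
#' @param atoms_a,atoms_b atom data.frames in the same frame.
#' @param cutoff distance cutoff in angstrom.
#' @return list `a`, `b`: data.frames of `chain`, `resno`, `insert` of
#'   interface residues on each side.
#' @export
interface_residues <- function(atoms_a, atoms_b, cutoff = 4.0) {
  xa <- as.matrix(atoms_a[, c("x", "y", "z")])
  xb <- as.matrix(atoms_b[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  hit <- d2 <= cutoff^2 + 1e-9
  res <- function(atoms, sel) {
    unique(atoms[sel, c("chain", "resno", "insert")])
  }
  list(a = res(atoms_a, apply(hit, 1L, any)),
       b = res(atoms_b, apply(hit, 2L, any)))
}

#' Extended-TM residue subset
#'
#' The non-canonical receptor/G-alpha interface is formed by helix residues
#' past the canonical cytosolic boundary: for Gs-coupled receptors, TM5
#' residues from 5.69 to the tip (TM5 longer than 18); for Gi/o-coupled
#' receptors, TM6 residues from 6.29 to the tip (TM6 longer than 20.5).
#'
#' @param seg a `helix_segment` (TM5 or TM6).
#' @param coupling `"GS"` (extended TM5) or `"GIO"` (extended TM6).
#' @return Atom data.frame of the extended residues (zero rows when the
#'   helix is short).
#' @export
extended_tm <- function(seg, coupling = c("GS", "GIO")) {
  coupling <- match.arg(coupling)
  if (coupling == "GS" && seg$helix != 5L) {
    stop("extended TM of a Gs-coupled receptor is defined on TM5")
  }
  if (coupling == "GIO" && seg$helix != 6L) {
    stop("extended TM of a Gi/o-coupled receptor is defined on TM6")
  }
  pos <- parse_grn(seg$atom$grn)$position
  keep <- if (coupling == "GS") pos >= 69L else pos <= 29L
  out <- seg$atom[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Contact area per extended residue: OLS regression
#'
#' Regresses the additional contact area of the extended TM against the
#' number of extended residues across receptors (ordinary least squares,
#' via [stats::lm()]). For Gs-coupled receptors this relation is linear at
#' roughly 40 angstrom^2 of extra G-alpha contact per extended TM5 residue.
#'
#' @param points data.frame with columns `extended_residues` and
#'   `contact_area`.
#' @return `area_regression`: `slope`, `slope_se`, `intercept`,
#'   `r_squared`, `n`.
#' @export
fit_area_regression <- function(points) {
  if (nrow(points) < 3L) stop("need >= 3 points for the regression")
  if (stats::var(points$extended_residues) == 0) {
    stop("zero variance in extended residue counts")
  }
  fit <- stats::lm(contact_area ~ extended_residues, data = points)
  sm <- suppressWarnings(summary(fit))   # exact lines trip a perfect-fit warning
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 slope_se = sm$coefficients[2L, 2L],
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = sm$r.squared, n = nrow(points)),
            class = "area_regression")
}
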