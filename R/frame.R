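#' Kabsch superposition onto a membrane-oriented reference
#'
#' All angle measurements in the package are made in a common coordinate
#' frame in which the membrane normal is the Z axis (+Z extracellular). The
#' frame is defined by a reference receptor assumed pre-oriented in the
#' membrane; every other structure is rigidly superposed onto it over
#' C-alpha atoms of GRN-matched residues. By default the match set is
#' restricted to TM1-TM4 and TM7 so that the frame is not biased by the
#' TM5/TM6 helices whose geometry is being measured.
#'
#' @param mobile,reference [annotated_structure()]s with GRNs applied.
#' @param selection list with `helices` (integer vector of TM numbers whose
#'   residues enter the fit; `NULL` = all annotated residues) and `atom`
#'   (atom name, default `"CA"`).
#' @return `kabsch_superpose`: a `frame_result` list with `transform`
#'   (`rotation` 3x3, `translation` length-3: `y = x %*% t(R) + t`), `rmsd`
#'   over the fitted atoms, and `n_atoms_used`.
#' @export
kabsch_superpose <- function(mobile, reference,
                             selection = list(helices = c(1, 2, 3, 4, 7),
                                              atom = "CA")) {
  m <- matched_grn_coords(mobile, reference, selection)
  if (nrow(m$mobile) < 3L) {
    stop("insufficient data: ", nrow(m$mobile),
         " GRN-matched atoms (need >= 3) between ", mobile$structure_id,
         " and ", reference$structure_id)
  }
  tr <- kabsch_fit(m$mobile, m$reference)
  fitted <- sweep(m$mobile %*% t(tr$rotation), 2L, tr$translation, "+")
  rmsd <- sqrt(mean(rowSums((fitted - m$reference)^2)))
  structure(list(transform = tr, rmsd = rmsd, n_atoms_used = nrow(m$mobile)),
            class = "frame_result")
}

# coordinates of GRN-matched atoms, rows aligned between the two structures
matched_grn_coords <- function(mobile, reference, selection) {
  atom_name <- if (is.null(selection$atom)) "CA" else selection$atom
  pick <- function(s) {
    a <- s$atom[s$atom$chain == s$receptor_chain, , drop = FALSE]
    a <- a[!is.na(a$grn) & a$elety == atom_name, , drop = FALSE]
    if (!is.null(selection$helices)) {
      a <- a[parse_grn(a$grn)$helix %in% selection$helices, , drop = FALSE]
    }
    a
  }
  am <- pick(mobile); ar <- pick(reference)
  shared <- intersect(am$grn, ar$grn)
  list(mobile = as.matrix(am[match(shared, am$grn), c("x", "y", "z")]),
       reference = as.matrix(ar[match(shared, ar$grn), c("x", "y", "z")]),
       grn = shared)
}

# least-squares rigid transform mapping x onto y (Kabsch via SVD);
# refuses degenerate (collinear) correspondence sets and never returns a
# reflection
kabsch_fit <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  x0 <- sweep(x, 2L, cx); y0 <- sweep(y, 2L, cy)
  sv <- svd(crossprod(x0, y0))   # H = x0' y0;  R = V diag(1,1,d) U'
  if (sv$d[2L] < 1e-8 * max(sv$d[1L], 1e-12)) {
    stop("degenerate correspondence set (collinear atoms): rotation not determined")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rotation = rot, translation = as.numeric(cy - cx %*% t(rot)))
}

#' @rdname kabsch_superpose
#' @param s structure to transform.
#' @param transform a transform from `kabsch_superpose(...)$transform`.
#' @return `apply_transform`: the structure with transformed coordinates.
#' @export
apply_transform <- function(s, transform) {
  xyz <- as.matrix(s$atom[, c("x", "y", "z")])
  new <- sweep(xyz %*% t(transform$rotation), 2L, transform$translation, "+")
  s$atom$x <- new[, 1L]; s$atom$y <- new[, 2L]; s$atom$z <- new[, 3L]
  s
}

#' @rdname kabsch_superpose
#' @return `to_membrane_frame`: a transformed copy of `s` in the reference
#'   frame (idempotent: re-framing a framed structure is the identity within
#'   numerical precision).
#' @export
to_membrane_frame <- function(s, reference,
                              selection = list(helices = c(1, 2, 3, 4, 7),
                                               atom = "CA")) {
  fit <- kabsch_superpose(s, reference, selection)
  apply_transform(s, fit$transform)
}

#' C-alpha displacement of a residue between two structures
#'
#' Both structures are first placed in the frame of `frame_reference`; the
#' displacement is the Euclidean distance between the C-alpha positions of
#' the GRN-identified residue. This is how helix movements such as the TM6
#' outward shift at residue 6.30 are compared between complexes.
#'
#' @param a,b [annotated_structure()]s.
#' @param grn generic residue number at which to measure.
#' @param frame_reference reference structure defining the common frame.
#' @param selection superposition selection, as in [kabsch_superpose()].
#' @param chain_of function extracting the chain to take the residue from
#'   (default the receptor chain; pass `function(s) s$galpha_chain` for
#'   G-alpha measurements in the receptor-defined frame).
#' @return Distance in angstrom.
#' @export
ca_displacement <- function(a, b, grn, frame_reference,
                            selection = list(helices = c(1, 2, 3, 4, 7),
                                             atom = "CA"),
                            chain_of = function(s) s$receptor_chain) {
  fa <- to_membrane_frame(a, frame_reference, selection)
  fb <- to_membrane_frame(b, frame_reference, selection)
  pa <- grn_xyz(fa, grn, "CA", chain = chain_of(fa))
  pb <- grn_xyz(fb, grn, "CA", chain = chain_of(fb))
  sqrt(sum((pa - pb)^2))
}

#' Serialize / deserialize a rigid transform as JSON
#'
#' Row-major rotation plus translation, so runs can record the exact frame
#' used for every measurement.
#'
#' @param transform list with `rotation` and `translation`.
#' @param path output path for `write_transform_json`.
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(
    list(rotation = as.vector(t(transform$rotation)),
         translation = as.numeric(transform$translation)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(rotation = matrix(obj$rotation, 3L, 3L, byrow = TRUE),
       translation = obj$translation)
}
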