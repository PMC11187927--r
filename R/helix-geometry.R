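#' Cytosolic tip of a transmembrane helix segment
#'
#' The cytosolic tip is the modeled segment residue furthest along the
#' helix's intracellular arm on the generic-number scale (largest GRN
#' position for odd helices such as TM5, smallest for even ones such as
#' TM6). In the membrane frame (+Z extracellular) its C-alpha must lie below
#' the helix anchor (x.50) — a tip above the anchor indicates a mis-framed
#' or inverted segment and is refused. (Selecting the raw minimum-Z residue
#' instead would misidentify the tip by a residue on strongly tilted
#' helices, where the helical spiral outweighs the per-residue rise along
#' Z.)
#'
#' @param seg a `helix_segment` from [select_segment()], in the membrane
#'   frame.
#' @return A list describing the tip residue: `grn`, `position` (GRN
#'   position integer), `chain`, `resno`, `insert`, `resid`, `ca`
#'   (coordinates).
#' @export
cytosolic_tip <- function(seg) {
  stopifnot(inherits(seg, "helix_segment"))
  ca <- segment_atom_xyz(seg, "CA")
  pos <- segment_positions(seg)
  if (!any(pos == 50L)) {
    stop("anchor ", seg$anchor_grn, " not present in ", seg$label,
         " segment of ", seg$structure_id)
  }
  ok <- is.finite(ca[, "z"])
  if (!any(ok)) stop("no C-alpha atoms in ", seg$label, " segment")
  # furthest modeled residue along the intracellular arm: GRN positions
  # > 50 for odd helices (TM5), < 50 for even ones (TM6)
  i <- if (seg$helix %% 2L == 1L) which(ok)[which.max(pos[ok])]
       else which(ok)[which.min(pos[ok])]
  anchor_z <- ca[which(pos == 50L)[1L], "z"]
  inverted <- if (seg$helix %% 2L == 1L) pos[i] < 50L else pos[i] > 50L
  if (inverted || (is.finite(anchor_z) && ca[i, "z"] > anchor_z + 1e-6)) {
    stop("degenerate segment: cytosolic tip of ", seg$label,
         " lies extracellular of the ", seg$anchor_grn, " anchor")
  }
  key <- rownames(ca)[i]
  a <- seg$atom[match(key, residue_key(seg$atom)), ]
  list(grn = a$grn, position = pos[i], chain = a$chain, resno = a$resno,
       insert = a$insert, resid = a$resid, ca = as.numeric(ca[i, ]))
}

#' Helix length in residues, from the cytosolic tip to x.50
#'
#' Length is counted on the generic-residue-number scale: the number of GRN
#' positions strictly intracellular of the anchor through the tip, i.e.
#' `|tip position - 50|`. Counting by GRN position (not by modeled residues)
#' makes the length robust to unmodeled gaps inside the helix. A TM5 tip at
#' 5.75 gives length 25; a TM6 tip at 6.29 gives length 21.
#'
#' @inheritParams cytosolic_tip
#' @return Integer residue count.
#' @export
helix_length <- function(seg) {
  tip <- cytosolic_tip(seg)
  abs(tip$position - 50L)
}

#' Angle between two direction vectors, in degrees
#'
#' @param u,v non-zero 3-vectors (not necessarily normalized).
#' @return Angle in `[0, 180]` degrees.
#' @export
angle_between <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero vector has no direction")
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

#' Helix orientation from averaged backbone carbonyl vectors
#'
#' In an ideal alpha helix the backbone C=O bonds run nearly parallel to the
#' helix axis, and their perpendicular components cancel when averaged over
#' whole turns (3.6 residues per turn). The orientation of the cytosolic end
#' of a helix is therefore estimated as the mean of per-residue unit C->O
#' vectors over a window of `n_window` residues counted from the cytosolic
#' tip. Because the window spans close to whole turns (11 residues is about
#' three), the perpendicular components cancel in the average itself; the
#' normalized mean is the axis estimate, oriented to point toward the
#' cytosolic tip. (An explicit projection onto the principal C-alpha axis
#' of the window is not used: on an 11-residue window that axis is biased
#' by several degrees for non-integral turns, whereas the carbonyl average
#' recovers ideal-helix axes to a few tenths of a degree.)
#'
#' Residues missing a backbone C or O are skipped and the window is extended
#' one residue deeper (toward the extracellular side) until `n_window`
#' usable residues are found or the segment is exhausted; at least 4 usable
#' residues are required.
#'
#' @inheritParams cytosolic_tip
#' @param n_window number of carbonyls to average (11 by default; 22 for the
#'   TM5 reference orientation).
#' @return A `helix_orientation` list: `axis` (unit 3-vector pointing
#'   extracellular to cytosolic), `n_residues_used`, `window` (GRNs used).
#' @export
helix_orientation <- function(seg, n_window = 11L) {
  stopifnot(inherits(seg, "helix_segment"))
  co_c <- segment_atom_xyz(seg, "C")
  co_o <- segment_atom_xyz(seg, "O")
  ca <- segment_atom_xyz(seg, "CA")
  n_res <- nrow(ca)
  usable <- is.finite(co_c[, 1L]) & is.finite(co_o[, 1L])
  # walk from the cytosolic end (last in segment order) toward extracellular
  idx <- rev(seq_len(n_res))
  idx <- idx[usable[idx]]
  if (length(idx) < 4L) {
    stop("insufficient data: ", length(idx), " residues with backbone C and O",
         " in ", seg$label, " window (need >= 4)")
  }
  idx <- idx[seq_len(min(n_window, length(idx)))]
  vec <- co_o[idx, , drop = FALSE] - co_c[idx, , drop = FALSE]
  vec <- vec / sqrt(rowSums(vec^2))
  m <- colMeans(vec)
  nv <- sqrt(sum(m^2))
  if (nv < 1e-12) stop("carbonyl vectors cancel: no orientation")
  v <- m / nv
  ca_w <- ca[idx, , drop = FALSE]
  ca_w <- ca_w[is.finite(ca_w[, 1L]), , drop = FALSE]
  # orient toward the cytosolic tip; idx walks cytosolic -> extracellular,
  # so the window's first row is its cytosolic end
  tip_dir <- ca_w[1L, ] - ca_w[nrow(ca_w), ]
  if (sum(v * tip_dir) < 0) v <- -v
  structure(list(axis = as.numeric(v), n_residues_used = length(idx),
                 window = seg$atom$grn[match(rownames(ca)[sort(idx)],
                                             residue_key(seg$atom))]),
            class = "helix_orientation")
}

#' Reference orientations for the TM5 and TM6 angles
#'
#' The TM5 tilt of every structure is measured against the TM5 orientation
#' of the reference receptor, computed with a 22-residue carbonyl window
#' (twice the standard window, for a more stable reference). The TM6 outward
#' movement is measured against the receptor central axis, which in the
#' membrane frame is the Z axis; its cytosolic direction is (0, 0, -1).
#'
#' @param ref_structure the framed reference [annotated_structure()].
#' @param tm5_start,tm5_end GRN bounds of the reference TM5 segment.
#' @return A `reference_orientations` list: `tm5_reference_axis`,
#'   `tm6_reference_axis` (always `c(0, 0, -1)`).
#' @export
build_reference <- function(ref_structure, tm5_start = "5.36",
                            tm5_end = "5.75") {
  seg <- select_segment(ref_structure, "TM5", tm5_start, tm5_end)
  ori <- helix_orientation(seg, n_window = 22L)
  if (ori$n_residues_used < 22L) {
    stop("insufficient data: reference TM5 has ", ori$n_residues_used,
         " usable residues; 22 needed for the reference window")
  }
  structure(list(tm5_reference_axis = ori$axis,
                 tm6_reference_axis = c(0, 0, -1)),
            class = "reference_orientations")
}

#' TM5 tilt and TM6 outward movement of a framed receptor
#'
#' `tm5_tilt` is the angle between the structure's cytosolic TM5 orientation
#' (11-residue carbonyl window) and the reference receptor's TM5 axis.
#' `tm6_outward` is the angle between the cytosolic TM6 orientation and the
#' membrane normal pointing intracellular, (0, 0, -1) — the hallmark of
#' activation amplitude.
#'
#' @param s a framed [annotated_structure()].
#' @param refs a `reference_orientations` from [build_reference()].
#' @param tm5_start,tm5_end,tm6_start,tm6_end segment GRN bounds.
#' @param n_window carbonyl window size.
#' @return Angle in degrees.
#' @export
tm5_tilt <- function(s, refs, tm5_start = "5.36", tm5_end = "5.75",
                     n_window = 11L) {
  seg <- select_segment(s, "TM5", tm5_start, tm5_end)
  angle_between(helix_orientation(seg, n_window)$axis, refs$tm5_reference_axis)
}

#' @rdname tm5_tilt
#' @export
tm6_outward <- function(s, tm6_start = "6.25", tm6_end = "6.60",
                        n_window = 11L) {
  seg <- select_segment(s, "TM6", tm6_start, tm6_end)
  angle_between(helix_orientation(seg, n_window)$axis, c(0, 0, -1))
}

#' Extract the four TM5/TM6 geometry descriptors of one receptor
#'
#' Computes TM5 length, TM6 length (residue counts from the cytosolic tip to
#' x.50), TM5 tilt and TM6 outward movement for a structure already placed
#' in the membrane frame. The three of these used by the coupling classifier
#' are TM5 length, TM5 tilt and TM6 outward movement; TM6 length is computed
#' for completeness but the two coupling classes are indistinguishable on it.
#'
#' @param s a framed [annotated_structure()].
#' @param refs a `reference_orientations` from [build_reference()].
#' @param config list of segment bounds: `tm5_start`, `tm5_end`,
#'   `tm6_start`, `tm6_end` (GRN strings), and optionally `n_window`.
#' @return One-row data.frame: `structure_id`, `coupling_label`, `tm5_len`,
#'   `tm6_len`, `tm5_tilt`, `tm6_outward`.
#' @export
extract_features <- function(s, refs,
                             config = list(tm5_start = "5.36", tm5_end = "5.75",
                                           tm6_start = "6.25", tm6_end = "6.60")) {
  nw <- if (is.null(config$n_window)) 11L else as.integer(config$n_window)
  withCallingHandlers({
    seg5 <- select_segment(s, "TM5", config$tm5_start, config$tm5_end)
    seg6 <- select_segment(s, "TM6", config$tm6_start, config$tm6_end)
    data.frame(
      structure_id = s$structure_id,
      coupling_label = if (is.null(s$coupling_label)) NA_character_ else s$coupling_label,
      tm5_len = helix_length(seg5),
      tm6_len = helix_length(seg6),
      tm5_tilt = angle_between(helix_orientation(seg5, nw)$axis,
                               refs$tm5_reference_axis),
      tm6_outward = angle_between(helix_orientation(seg6, nw)$axis, c(0, 0, -1)),
      stringsAsFactors = FALSE)
  }, error = function(e) {
    stop("feature extraction failed for ", s$structure_id, ": ",
         conditionMessage(e), call. = FALSE)
  })
}

#' Read / write the geometry feature table
#'
#' CSV interchange format between geometry extraction and the classifier:
#' header `structure_id,coupling_label,tm5_len,tm6_len,tm5_tilt,tm6_outward`
#' with angles in degrees written to 3 decimals.
#'
#' @param features data.frame as returned by [extract_features()] (rows
#'   bound together).
#' @param path CSV path.
#' @export
write_feature_table <- function(features, path) {
  out <- features
  out$tm5_tilt <- round(out$tm5_tilt, 3L)
  out$tm6_outward <- round(out$tm6_outward, 3L)
  cols <- c("structure_id", "coupling_label", "tm5_len", "tm6_len",
            "tm5_tilt", "tm6_outward")
  utils::write.csv(out[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("structure_id", "tm5_len", "tm5_tilt", "tm6_outward")
  if (!all(need %in% names(tab))) {
    stop("feature table needs columns: ", paste(need, collapse = ", "))
  }
  tab
}
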