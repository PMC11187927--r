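#' Atomic structures with generic residue numbers
#'
#' An `annotated_structure` holds the atom records of a receptor (and
#' optionally its G-protein alpha subunit) together with a map from author
#' residue numbering to Ballesteros-Weinstein generic residue numbers (GRNs,
#' `"helix.position"` with helix 1-8 and position 1-99). It is the substrate
#' of every geometric operation in the package.
#'
#' @param atom data.frame of atom records with columns `chain`, `resno`
#'   (author residue number), `insert` (insertion code, `""` if none),
#'   `resid` (3-letter residue name), `elety` (PDB atom name, e.g. `"CA"`),
#'   `x`, `y`, `z` (angstrom), `o` (occupancy), `b` (B-factor), `elesy`
#'   (element symbol) and `grn` (GRN string or `NA`).
#' @param structure_id character identifier.
#' @param receptor_chain chain id of the receptor.
#' @param galpha_chain optional chain id of the G-alpha subunit.
#' @param coupling_label optional `"GS"` or `"GIO"`.
#' @return An object of class `annotated_structure`.
#' @export
annotated_structure <- function(atom, structure_id = "structure",
                                receptor_chain, galpha_chain = NULL,
                                coupling_label = NULL) {
  required <- c("chain", "resno", "insert", "resid", "elety",
                "x", "y", "z", "o", "b", "elesy")
  missing_cols <- setdiff(required, names(atom))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(atom$grn)) atom$grn <- NA_character_
  if (nrow(atom) == 0L) stop("empty structure: no atom records")
  if (!all(is.finite(atom$x) & is.finite(atom$y) & is.finite(atom$z))) {
    stop("non-finite coordinates in atom table")
  }
  if (any(!nzchar(atom$elety))) stop("empty atom names in atom table")
  if (!receptor_chain %in% atom$chain) {
    stop("receptor chain '", receptor_chain, "' not present in structure")
  }
  if (!is.null(coupling_label)) coupling_label <- match.arg(coupling_label, c("GS", "GIO"))
  atom <- atom[order(match(atom$chain, unique(atom$chain)),
                     atom$resno, atom$insert), , drop = FALSE]
  rownames(atom) <- NULL
  check_atom_uniqueness(atom)
  check_grn_invariants(atom)
  structure(
    list(structure_id = structure_id, atom = atom,
         receptor_chain = receptor_chain, galpha_chain = galpha_chain,
         coupling_label = coupling_label),
    class = "annotated_structure"
  )
}

#' @export
print.annotated_structure <- function(x, ...) {
  res <- unique(residue_key(x$atom))
  cat("<annotated_structure> ", x$structure_id, "\n",
      "  chains: ", paste(unique(x$atom$chain), collapse = ", "),
      "  (receptor ", x$receptor_chain,
      if (!is.null(x$galpha_chain)) paste0(", Galpha ", x$galpha_chain) else "",
      ")\n",
      "  residues: ", length(res), "  atoms: ", nrow(x$atom),
      "  GRN-annotated residues: ",
      length(unique(residue_key(x$atom)[!is.na(x$atom$grn)])), "\n",
      if (!is.null(x$coupling_label)) paste0("  coupling: ", x$coupling_label, "\n") else "",
      sep = "")
  invisible(x)
}

# residue identity key: chain|resno|insert
residue_key <- function(atom) {
  paste(atom$chain, atom$resno, atom$insert, sep = "|")
}

check_atom_uniqueness <- function(atom) {
  key <- paste(residue_key(atom), atom$elety)
  if (anyDuplicated(key)) {
    stop("duplicate atom name within a residue: ", key[duplicated(key)][1L])
  }
  invisible(TRUE)
}

check_grn_invariants <- function(atom) {
  has <- !is.na(atom$grn)
  if (!any(has)) return(invisible(TRUE))
  bad <- atom$grn[has][!grepl("^[1-8]\\.[0-9]{1,2}$", atom$grn[has])]
  if (length(bad) > 0L) stop("malformed GRN: '", bad[1L], "'")
  # one GRN maps to one residue per chain
  per_res <- unique(data.frame(chain = atom$chain[has],
                               key = residue_key(atom)[has],
                               grn = atom$grn[has],
                               stringsAsFactors = FALSE))
  dup <- duplicated(paste(per_res$chain, per_res$grn))
  if (any(dup)) {
    stop("duplicate GRN within one chain: ",
         per_res$grn[dup][1L], " (chain ", per_res$chain[dup][1L], ")")
  }
  # and one residue carries at most one GRN
  dup2 <- tapply(per_res$grn, per_res$key, function(g) length(unique(g)))
  if (any(dup2 > 1L)) stop("residue assigned more than one GRN")
  invisible(TRUE)
}

#' Parse a generic residue number
#'
#' @param grn character vector like `"5.50"`.
#' @return data.frame with integer columns `helix` and `position`.
#' @export
parse_grn <- function(grn) {
  ok <- grepl("^[1-8]\\.[0-9]{1,2}$", grn)
  if (any(!ok)) stop("malformed GRN: '", grn[!ok][1L], "'")
  parts <- strsplit(grn, ".", fixed = TRUE)
  data.frame(helix = vapply(parts, function(p) as.integer(p[1L]), 1L),
             position = vapply(parts, function(p) as.integer(p[2L]), 1L))
}

#' Attach a GRN map to a structure
#'
#' Sets the generic residue number of each mapped residue. Every mapped
#' residue must exist and GRNs must stay unique within a chain; unmapped
#' residues keep their GRN absent.
#'
#' @param s an [annotated_structure()].
#' @param map data.frame with columns `chain`, `author_seq_id` and `grn`
#'   (insertion codes may be appended to `author_seq_id` as in `"100A"`).
#' @return The structure with `grn` fields set.
#' @seealso [read_grn_map()]
#' @export
apply_grn_map <- function(s, map) {
  stopifnot(inherits(s, "annotated_structure"))
  if (nrow(map) == 0L) return(s)
  need <- c("chain", "author_seq_id", "grn")
  if (!all(need %in% names(map))) {
    stop("GRN map needs columns: ", paste(need, collapse = ", "))
  }
  seq_chr <- as.character(map$author_seq_id)
  resno <- as.integer(sub("([0-9]+).*", "\\1", seq_chr))
  insert <- sub("^[0-9]+", "", seq_chr)
  map_key <- paste(map$chain, resno, insert, sep = "|")
  if (anyDuplicated(map_key)) stop("GRN map lists a residue twice")
  atom <- s$atom
  akey <- residue_key(atom)
  missing <- !(map_key %in% akey)
  if (any(missing)) {
    stop("GRN map refers to residues absent from the structure: ",
         paste(utils::head(map_key[missing], 3L), collapse = ", "))
  }
  idx <- match(akey, map_key)
  atom$grn <- ifelse(is.na(idx), atom$grn, as.character(map$grn)[idx])
  check_grn_invariants(atom)
  s$atom <- atom
  s
}

#' Select an annotated helix segment
#'
#' Returns the contiguous run of receptor residues between two boundary GRNs
#' (inclusive), ordered extracellular to cytosolic. For odd-numbered helices
#' (TM1/3/5/7) the chain runs extracellular to cytosolic with increasing
#' author numbering; for even helices (TM2/4/6) the order is reversed, so a
#' TM6 segment is returned with residue 6.60 first and the cytosolic tip
#' last.
#'
#' @param s an [annotated_structure()] with GRNs applied.
#' @param label `"TM5"`, `"TM6"`, or another `"TMn"` label.
#' @param grn_start,grn_end boundary GRNs (order-insensitive).
#' @return A `helix_segment`: atoms of the segment residues in
#'   extracellular-to-cytosolic residue order, with `anchor_grn` set to the
#'   x.50 position of the helix.
#' @export
select_segment <- function(s, label, grn_start, grn_end) {
  stopifnot(inherits(s, "annotated_structure"))
  helix <- as.integer(sub("^TM", "", label))
  if (is.na(helix) || helix < 1L || helix > 8L) stop("bad segment label: ", label)
  atom <- s$atom[s$atom$chain == s$receptor_chain, , drop = FALSE]
  for (g in c(grn_start, grn_end)) {
    if (!g %in% atom$grn) stop("GRN '", g, "' not resolved in receptor chain")
  }
  pg <- parse_grn(c(grn_start, grn_end))
  if (any(pg$helix != helix)) stop("boundary GRNs do not belong to ", label)
  lo <- min(pg$position); hi <- max(pg$position)
  has <- !is.na(atom$grn)
  seg_grn <- parse_grn(atom$grn[has])
  keep <- has
  keep[has] <- seg_grn$helix == helix & seg_grn$position >= lo & seg_grn$position <= hi
  seg <- atom[keep, , drop = FALSE]
  pos <- parse_grn(seg$grn)$position
  # extracellular -> cytosolic: ascending GRN for odd helices, descending for even
  ord <- if (helix %% 2L == 1L) order(pos) else order(-pos)
  seg <- seg[ord, , drop = FALSE]
  rownames(seg) <- NULL
  structure(list(label = label, helix = helix, atom = seg,
                 anchor_grn = sprintf("%d.50", helix),
                 structure_id = s$structure_id),
            class = "helix_segment")
}

#' @export
print.helix_segment <- function(x, ...) {
  pos <- parse_grn(x$atom$grn)$position
  cat("<helix_segment> ", x$label, " of ", x$structure_id,
      ": ", length(unique(pos)), " residues (",
      x$helix, ".", min(pos), " .. ", x$helix, ".", max(pos),
      "), anchor ", x$anchor_grn, "\n", sep = "")
  invisible(x)
}

# coordinates of one named atom per segment residue, in segment residue order;
# residues lacking the atom yield NA rows
segment_atom_xyz <- function(seg, elety = "CA") {
  atom <- seg$atom
  keys <- unique(residue_key(atom))
  out <- matrix(NA_real_, nrow = length(keys), ncol = 3L,
                dimnames = list(keys, c("x", "y", "z")))
  sel <- atom$elety == elety
  hit <- residue_key(atom)[sel]
  out[match(hit, keys), ] <- as.matrix(atom[sel, c("x", "y", "z")])
  out
}

# per-residue GRN positions in segment residue order
segment_positions <- function(seg) {
  atom <- seg$atom
  keys <- unique(residue_key(atom))
  first <- match(keys, residue_key(atom))
  parse_grn(atom$grn[first])$position
}

#' Coordinates of one atom of a GRN-identified residue
#'
#' @param s an [annotated_structure()].
#' @param grn generic residue number, e.g. `"6.30"`.
#' @param elety atom name (default `"CA"`).
#' @param chain chain to search (default the receptor chain).
#' @return Numeric length-3 coordinate vector.
#' @export
grn_xyz <- function(s, grn, elety = "CA", chain = s$receptor_chain) {
  atom <- s$atom
  hit <- which(atom$chain == chain & !is.na(atom$grn) & atom$grn == grn &
                 atom$elety == elety)
  if (length(hit) == 0L) {
    stop("no ", elety, " atom at GRN ", grn, " in chain ", chain,
         " of ", s$structure_id)
  }
  as.numeric(atom[hit[1L], c("x", "y", "z")])
}
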