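#' Read a receptor(-G-alpha) structure from PDB or mmCIF
#'
#' Loads the named chains, resolves alternate locations to the highest
#' occupancy conformer (ties broken by file order) and excludes waters.
#' Generic residue numbers are attached afterwards with [apply_grn_map()].
#'
#' @param path file path.
#' @param format `"pdb"` or `"cif"`; guessed from the extension by default.
#' @param receptor_chain chain id of the receptor (required).
#' @param galpha_chain optional chain id of the G-alpha subunit.
#' @param structure_id identifier; defaults to the file base name.
#' @param coupling_label optional `"GS"` or `"GIO"`.
#' @return An [annotated_structure()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           receptor_chain, galpha_chain = NULL,
                           structure_id = sub("\\.[^.]+$", "", basename(path)),
                           coupling_label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("failed to parse ", path, " as ", toupper(format),
                             ": ", conditionMessage(e)))
  atom <- pdb$atom
  chains <- c(receptor_chain, galpha_chain)
  if (!receptor_chain %in% atom$chain) {
    stop("chain '", receptor_chain, "' not found in ", path)
  }
  atom <- atom[atom$chain %in% chains, , drop = FALSE]
  atom <- atom[!(atom$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  atom$insert[is.na(atom$insert)] <- ""
  atom$o[is.na(atom$o)] <- 1
  atom$b[is.na(atom$b)] <- 0
  # alternate locations: keep the highest-occupancy conformer per atom slot
  if (!is.null(atom$alt)) {
    atom$alt[is.na(atom$alt)] <- ""
    slot <- paste(atom$chain, atom$resno, atom$insert, atom$elety)
    keep <- unsplit(lapply(split(seq_len(nrow(atom)), slot), function(i) {
      best <- i[which.max(atom$o[i])]
      seq_along(i) == match(best, i)
    }), slot)
    atom <- atom[keep, , drop = FALSE]
  }
  if (is.null(atom$elesy) || all(is.na(atom$elesy))) {
    atom$elesy <- substr(trimws(atom$elety), 1L, 1L)
  }
  atom <- atom[, c("chain", "resno", "insert", "resid", "elety",
                   "x", "y", "z", "o", "b", "elesy")]
  annotated_structure(atom, structure_id = structure_id,
                      receptor_chain = receptor_chain,
                      galpha_chain = galpha_chain,
                      coupling_label = coupling_label)
}

#' Write a structure as PDB
#'
#' Emits fixed-column PDB v3.3 ATOM records; coordinates round-trip within
#' the 1e-3 angstrom column precision. GRNs are not part of the PDB format
#' and travel in the sidecar table written by [write_grn_map()].
#'
#' @param s an [annotated_structure()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "annotated_structure"))
  a <- s$atom
  if (nrow(a) == 0L) stop("refusing to write an empty structure")
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
                   elety = a$elety, chain = a$chain, insert = a$insert,
                   o = a$o, b = a$b, elesy = a$elesy)
  invisible(path)
}

#' Read / write a GRN sidecar table
#'
#' Tab-separated with header `chain`, `author_seq_id`, `grn` — the
#' interchange format for Ballesteros-Weinstein residue tables exported from
#' GPCRdb-style annotation.
#'
#' @param path file path.
#' @return `read_grn_map`: a data.frame consumable by [apply_grn_map()].
#' @export
read_grn_map <- function(path) {
  if (!file.exists(path)) stop("GRN map not found: ", path)
  map <- utils::read.delim(path, colClasses = "character")
  need <- c("chain", "author_seq_id", "grn")
  if (!all(need %in% names(map))) {
    stop("GRN map ", path, " needs columns: ", paste(need, collapse = ", "))
  }
  map
}

#' @rdname read_grn_map
#' @param s an [annotated_structure()] whose GRN assignments to export.
#' @export
write_grn_map <- function(s, path) {
  a <- s$atom
  has <- !is.na(a$grn)
  per_res <- unique(data.frame(chain = a$chain[has],
                               author_seq_id = paste0(a$resno[has], a$insert[has]),
                               grn = a$grn[has], stringsAsFactors = FALSE))
  utils::write.table(per_res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a dataset manifest
#'
#' CSV with columns `structure_id`, `path`, `receptor_chain`,
#' `galpha_chain`, `coupling_label`, `grn_map` and the per-structure segment
#' bounds `tm5_start`, `tm5_end`, `tm6_start`, `tm6_end`. Relative paths are
#' resolved against the manifest's own directory.
#'
#' @param path manifest CSV path.
#' @return data.frame of manifest rows.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.csv(path, colClasses = "character")
  need <- c("structure_id", "path", "receptor_chain")
  if (!all(need %in% names(man))) {
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  }
  root <- dirname(normalizePath(path))
  rel <- !grepl("^(/|[A-Za-z]:)", man$path)
  man$path[rel] <- file.path(root, man$path[rel])
  if (!is.null(man$grn_map)) {
    rel <- nzchar(man$grn_map) & !grepl("^(/|[A-Za-z]:)", man$grn_map)
    man$grn_map[rel] <- file.path(root, man$grn_map[rel])
  }
  man
}
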