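#' Simulate a synthetic receptor dataset on disk
#'
#' Draws per-structure TM5/TM6 geometries from the Gs and Gi/o group
#' models, builds the corresponding receptor stubs, and writes everything a
#' downstream extraction run needs: one PDB + GRN sidecar per structure, a
#' vertical-TM5 reference stub, a manifest with per-structure segment
#' bounds, the sampled feature table, and a `run_summary.json` recording
#' seed, configuration and package version. Re-running with the same seed
#' reproduces the directory byte for byte.
#'
#' @param out_dir output directory (created if needed).
#' @param n_gs,n_gio number of Gs- / Gi/o-coupled stubs.
#' @param seed RNG seed.
#' @return Invisibly, the manifest data.frame (also written to
#'   `manifest.csv`).
#' @export
run_simulate <- function(out_dir, n_gs = 6L, n_gio = 6L, seed = 2784L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- sample_feature_table(n_per_group = c(n_gs, n_gio), seed = seed)
  az <- withr::with_seed(seed + 1L, stats::runif(nrow(tab), 0, 360))
  rows <- vector("list", nrow(tab) + 1L)
  build_one <- function(id, len5, tilt5, len6, out6, azimuth, label) {
    tip5 <- 50L + len5
    start6 <- 50L - len6
    tm5 <- helix_spec(tip5 - 36L + 1L, tilt_deg = tilt5, azimuth_deg = azimuth,
                      grn_start = "5.36")
    tm6 <- helix_spec(60L - start6 + 1L, tilt_deg = out6,
                      azimuth_deg = azimuth + 120,
                      grn_start = sprintf("6.%02d", start6))
    s <- make_receptor_stub(tm5, tm6, structure_id = id,
                            coupling_label = if (is.na(label)) NULL else label)
    write_structure(s, file.path(out_dir, paste0(id, ".pdb")))
    write_grn_map(s, file.path(out_dir, paste0(id, ".grn.tsv")))
    data.frame(structure_id = id, path = paste0(id, ".pdb"),
               receptor_chain = "A", galpha_chain = "",
               coupling_label = if (is.na(label)) "" else label,
               grn_map = paste0(id, ".grn.tsv"),
               tm5_start = "5.36", tm5_end = sprintf("5.%02d", tip5),
               tm6_start = sprintf("6.%02d", start6), tm6_end = "6.60",
               stringsAsFactors = FALSE)
  }
  # reference: vertical TM5/TM6 stub; its TM5 axis defines the tilt origin
  rows[[1L]] <- build_one("reference", 25L, 0, 21L, 0, 0, NA)
  for (i in seq_len(nrow(tab))) {
    # clamp sampled geometries to buildable GRN ranges
    rows[[i + 1L]] <- build_one(
      tab$structure_id[i],
      min(max(tab$tm5_len[i], 5L), 45L),
      min(tab$tm5_tilt[i], 60),
      min(max(tab$tm6_len[i], 5L), 45L),
      min(tab$tm6_outward[i], 60),
      az[i], tab$coupling_label[i])
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  write_feature_table(tab, file.path(out_dir, "sampled_features.csv"))
  write_run_summary(out_dir, list(command = "simulate", seed = seed,
                                  n_gs = n_gs, n_gio = n_gio))
  invisible(manifest)
}

#' Extract geometry features for every manifest entry
#'
#' Loads each structure with its GRN sidecar, superposes it onto the
#' reference structure (over C-alpha atoms of TM1-4/TM7 by default), and
#' extracts the four TM5/TM6 descriptors. A failure on one structure is
#' recorded and the batch continues.
#'
#' @param manifest_path manifest CSV (see [read_manifest()]).
#' @param reference_id `structure_id` of the pre-oriented reference entry.
#' @param out_csv optional path for the feature table.
#' @param selection superposition selection, as in [kabsch_superpose()].
#' @return list `features` (data.frame), `failures` (named character vector
#'   of error messages), `status` (`"clean"`, `"partial"` or `"failed"`).
#' @export
run_extract <- function(manifest_path, reference_id = "reference",
                        out_csv = NULL,
                        selection = list(helices = c(1, 2, 3, 4, 7),
                                         atom = "CA")) {
  man <- read_manifest(manifest_path)
  if (nrow(man) == 0L) stop("empty manifest")
  load_row <- function(r) {
    s <- read_structure(r$path, receptor_chain = r$receptor_chain,
                        galpha_chain = if (nzchar(r$galpha_chain %||% ""))
                          r$galpha_chain else NULL,
                        structure_id = r$structure_id,
                        coupling_label = if (nzchar(r$coupling_label %||% ""))
                          r$coupling_label else NULL)
    if (!is.null(r$grn_map) && nzchar(r$grn_map)) {
      s <- apply_grn_map(s, read_grn_map(r$grn_map))
    }
    s
  }
  iref <- match(reference_id, man$structure_id)
  if (is.na(iref)) stop("reference '", reference_id, "' not in manifest")
  ref_row <- as.list(man[iref, ])
  reference <- load_row(ref_row)
  refs <- build_reference(reference, ref_row$tm5_start, ref_row$tm5_end)
  feats <- list(); failures <- character(0)
  for (i in setdiff(seq_len(nrow(man)), iref)) {
    r <- as.list(man[i, ])
    res <- tryCatch({
      s <- load_row(r)
      framed <- to_membrane_frame(s, reference, selection)
      extract_features(framed, refs,
                       config = list(tm5_start = r$tm5_start, tm5_end = r$tm5_end,
                                     tm6_start = r$tm6_start, tm6_end = r$tm6_end))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[r$structure_id] <- conditionMessage(res)
      message("extraction failed for ", r$structure_id, ": ",
              conditionMessage(res))
    } else {
      feats[[r$structure_id]] <- res
    }
  }
  features <- if (length(feats) > 0L)
    do.call(rbind, c(feats, list(make.row.names = FALSE))) else NULL
  if (!is.null(out_csv) && length(feats) > 0L) {
    write_feature_table(features, out_csv)
    write_run_summary(dirname(out_csv),
                      list(command = "extract", seed = NA,
                           manifest = manifest_path,
                           reference = reference_id,
                           n_ok = length(feats), n_failed = length(failures)))
  }
  status <- if (length(failures) == 0L) "clean"
            else if (length(feats) > 0L) "partial" else "failed"
  list(features = features, failures = failures, status = status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify a feature table
#'
#' Projects each row onto the principal axes and applies the X > 0.7
#' decision rule.
#'
#' @param features feature data.frame or CSV path.
#' @param model a `projection_model`; the default applies the closed-form
#'   reference constants.
#' @param out_csv optional predictions CSV path.
#' @return data.frame `structure_id`, `X`, `Y`, `predicted`, `label`.
#' @export
run_classify <- function(features, model = reference_projection_model(),
                         out_csv = NULL) {
  if (is.character(features)) features <- read_feature_table(features)
  if (nrow(features) == 0L) stop("empty feature table")
  pred <- classify_features(features, model)
  if (!is.null(out_csv)) {
    out <- pred
    out$X <- round(out$X, 4L); out$Y <- round(out$Y, 4L)
    utils::write.csv(out, out_csv, row.names = FALSE, quote = FALSE)
  }
  pred
}

#' Cross-validate the stump forest on a labeled feature table
#'
#' @param features feature data.frame or CSV path with `coupling_label`.
#' @param k folds (default 10, stratified).
#' @param seed RNG seed.
#' @param out_json optional metrics JSON path.
#' @param ... passed to [fit_stump_forest()].
#' @return As [stratified_kfold_cv()].
#' @export
run_crossval <- function(features, k = 10L, seed = 2784L, out_json = NULL, ...) {
  if (is.character(features)) features <- read_feature_table(features)
  cv <- stratified_kfold_cv(features, features$coupling_label, k = k,
                            seed = seed, ...)
  if (!is.null(out_json)) {
    m <- cv$pooled
    jsonlite::write_json(list(accuracy = m$accuracy, f1 = m$f1, auc = m$auc,
                              mcc = m$mcc,
                              confusion = unclass(m$confusion),
                              k = cv$k, seed = seed,
                              version = package_version_string()),
                         out_json, auto_unbox = TRUE, digits = NA)
  }
  cv
}

#' Measure displacements, RMSD or interface area between two structures
#'
#' @param a,b [annotated_structure()]s (GRNs applied).
#' @param frame_reference reference defining the common frame (default
#'   `b`).
#' @param grn optional GRN at which to measure the C-alpha displacement.
#' @param rmsd report the superposition RMSD of `a` onto `b`.
#' @param interface report the receptor/G-alpha buried area of `a`.
#' @param selection superposition selection.
#' @return Named list of requested measurements plus provenance (selection
#'   and conventions used).
#' @export
run_measure <- function(a, b = NULL, frame_reference = b, grn = NULL,
                        rmsd = FALSE, interface = FALSE,
                        selection = list(helices = c(1, 2, 3, 4, 7),
                                         atom = "CA")) {
  out <- list(provenance = list(
    selection = selection, version = package_version_string(),
    interface_convention = "half buried SASA, probe 1.4 A, Bondi radii"))
  if (!is.null(grn)) {
    if (is.null(b)) stop("displacement needs two structures")
    out[[paste0("displacement_", grn)]] <-
      ca_displacement(a, b, grn, frame_reference, selection)
  }
  if (rmsd) {
    if (is.null(b)) stop("RMSD needs two structures")
    out$rmsd <- kabsch_superpose(a, b, selection)$rmsd
  }
  if (interface) {
    if (is.null(a$galpha_chain)) stop("interface needs a G-alpha chain")
    out$interface_area <- buried_area(
      chain_atoms(a, a$receptor_chain), chain_atoms(a, a$galpha_chain))
  }
  out
}

package_version_string <- function() {
  as.character(utils::packageVersion("gcoupler"))
}

write_run_summary <- function(dir, fields) {
  fields$version <- package_version_string()
  s <- paste(names(fields), unlist(fields), sep = "=", collapse = "|")
  fields$config_hash <- sprintf("%08x",
    sum(utf8ToInt(s) * seq_len(nchar(s))) %% .Machine$integer.max)
  jsonlite::write_json(fields, file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
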