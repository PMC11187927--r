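#' Feature standardization for the coupling classifier
#'
#' The classifier operates on three geometries per receptor — TM5 length,
#' TM5 tilt and TM6 outward movement — centered and scaled feature-wise.
#'
#' @param features data.frame or matrix holding columns/features `tm5_len`,
#'   `tm5_tilt`, `tm6_outward`.
#' @param ddof delta degrees of freedom of the standard deviation: 0
#'   (population, the default) or 1 (sample).
#' @return `standardization_params`: list of `mean` and `scale`, each a
#'   named length-3 vector.
#' @export
fit_standardization <- function(features, ddof = 0L) {
  x <- feature_matrix(features)
  if (nrow(x) < 2L) stop("need >= 2 rows to fit standardization")
  stopifnot(ddof %in% c(0L, 1L))
  mu <- colMeans(x)
  s <- sqrt(colSums(sweep(x, 2L, mu)^2) / (nrow(x) - ddof))
  if (any(s <= 0)) {
    stop("zero-scale feature (constant column): ",
         paste(names(s)[s <= 0], collapse = ", "))
  }
  structure(list(mean = mu, scale = s), class = "standardization_params")
}

feature_matrix <- function(features) {
  cols <- c("tm5_len", "tm5_tilt", "tm6_outward")
  if (is.matrix(features)) {
    if (ncol(features) != 3L) stop("expected 3 feature columns")
    colnames(features) <- cols
    return(features)
  }
  if (!all(cols %in% names(features))) {
    stop("features need columns: ", paste(cols, collapse = ", "))
  }
  as.matrix(features[, cols])
}

#' @rdname fit_standardization
#' @param params a `standardization_params`.
#' @return `standardize`: matrix of z-scores `(x - mean) / scale`.
#' @export
standardize <- function(features, params) {
  x <- feature_matrix(features)
  if (any(params$scale <= 0)) stop("standardization scales must be positive")
  sweep(sweep(x, 2L, params$mean), 2L, params$scale, "/")
}

#' Principal component analysis of the standardized geometries
#'
#' Fits a 2-component PCA (SVD, via [stats::prcomp()]) to the standardized
#' feature rows. The eigenvector sign is fixed so the TM5-length loading of
#' PC1 and the TM6-outward loading of PC2 are positive, pinning the
#' otherwise arbitrary SVD sign to the convention of the published decision
#' formulas.
#'
#' @param z matrix of standardized rows (3 columns).
#' @return `pca_model`: `components` (2x3 matrix, unit rows),
#'   `explained_variance_ratio` (length 2, non-increasing).
#' @export
fit_pca <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) < 3L || ncol(z) != 3L) stop("need >= 3 rows of 3 features")
  pc <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  comp <- t(pc$rotation[, 1:2, drop = FALSE])
  if (comp[1L, 1L] < 0) comp[1L, ] <- -comp[1L, ]
  if (comp[2L, 3L] < 0) comp[2L, ] <- -comp[2L, ]
  var <- pc$sdev^2
  structure(list(components = unname(comp),
                 explained_variance_ratio = var[1:2] / sum(var)),
            class = "pca_model")
}

#' @rdname fit_pca
#' @param pca a `pca_model`.
#' @return `project`: matrix with columns `X` (PC1 score) and `Y` (PC2
#'   score).
#' @export
project <- function(z, pca) {
  z <- rbind(z)
  out <- z %*% t(pca$components)
  colnames(out) <- c("X", "Y")
  out
}

#' The closed-form coupling projection model
#'
#' Bundles standardization parameters, the two principal axes and the Gs
#' decision threshold on PC1. `projection_model()` composes arbitrary
#' fitted parts; `reference_projection_model()` returns the model built
#' from the constants fitted on the 98-receptor class A homology-model
#' training set (24 Gs- and 74 Gi/o-coupled), which defines the closed-form
#' rule: a receptor is predicted Gs-coupled when
#' \deqn{X = 0.156\,\mathrm{tm5\_len} + 0.108\,\mathrm{tm5\_tilt} +
#'   0.055\,\mathrm{tm6\_outward} - 5.110 > 0.7.}
#'
#' @param standardization a `standardization_params`.
#' @param pca a `pca_model`.
#' @param gs_threshold PC1 threshold above which Gs coupling is predicted.
#' @return A `projection_model`.
#' @export
projection_model <- function(standardization, pca, gs_threshold = 0.7) {
  stopifnot(inherits(standardization, "standardization_params"),
            inherits(pca, "pca_model"))
  structure(list(standardization = standardization, pca = pca,
                 gs_threshold = gs_threshold),
            class = "projection_model")
}

#' @rdname projection_model
#' @export
reference_projection_model <- function() {
  std <- structure(list(
    mean = c(tm5_len = 20.276, tm5_tilt = 8.474, tm6_outward = 18.749),
    scale = c(tm5_len = 4.164, tm5_tilt = 5.264, tm6_outward = 9.156)),
    class = "standardization_params")
  pca <- structure(list(
    components = rbind(c(0.649, 0.569, 0.506),
                       c(-0.081, -0.609, 0.789)),
    explained_variance_ratio = c(NA_real_, NA_real_)),
    class = "pca_model")
  projection_model(std, pca)
}

#' Raw-coordinate affine form of the projection
#'
#' Expands standardize-then-project into a single affine map on the raw
#' geometries, `X = a . f + c_x`, `Y = b . f + c_y` — the form in which the
#' decision boundary can be applied by hand. Algebraically identical to
#' `project(standardize(f))` for any constants.
#'
#' @param features data.frame/matrix with `tm5_len`, `tm5_tilt`,
#'   `tm6_outward`, or a length-3 vector.
#' @param model a `projection_model`.
#' @return Matrix with columns `X`, `Y`.
#' @export
raw_projection <- function(features, model) {
  if (is.numeric(features) && is.null(dim(features)) && length(features) == 3L) {
    features <- matrix(features, nrow = 1L)
  }
  x <- feature_matrix(features)
  cf <- raw_coefficients(model)
  out <- cbind(X = x %*% cf$x_coef + cf$x_const,
               Y = x %*% cf$y_coef + cf$y_const)
  colnames(out) <- c("X", "Y")
  out
}

#' @rdname raw_projection
#' @return `raw_coefficients`: list `x_coef`, `x_const`, `y_coef`,
#'   `y_const` (the affine expansion `coef = component / scale`,
#'   `const = -sum(component * mean / scale)`).
#' @export
raw_coefficients <- function(model) {
  s <- model$standardization; p <- model$pca
  cx <- p$components[1L, ] / s$scale
  cy <- p$components[2L, ] / s$scale
  list(x_coef = unname(cx), x_const = -sum(cx * s$mean),
       y_coef = unname(cy), y_const = -sum(cy * s$mean))
}

#' Coupling decision from the PC1 score
#'
#' Predicts Gs coupling when X strictly exceeds the threshold; at or below
#' the threshold the receptor is called Gi/o-coupled (X exactly at the
#' boundary falls to the majority Gi/o class).
#'
#' @param X numeric PC1 score(s).
#' @param threshold decision threshold (default 0.7).
#' @return Character vector of `"GS"` / `"GIO"`.
#' @export
decide <- function(X, threshold = 0.7) {
  if (any(!is.finite(X))) stop("non-finite PC1 score")
  ifelse(X > threshold, "GS", "GIO")
}

#' Classify a feature table with a projection model
#'
#' @param features data.frame with `tm5_len`, `tm5_tilt`, `tm6_outward` and
#'   optionally `structure_id`, `coupling_label`.
#' @param model a `projection_model` (default the reference constants).
#' @return data.frame `structure_id`, `X`, `Y`, `predicted`, `label`.
#' @export
classify_features <- function(features, model = reference_projection_model()) {
  xy <- raw_projection(features, model)
  data.frame(
    structure_id = if (is.null(features$structure_id))
      sprintf("row%d", seq_len(nrow(xy))) else features$structure_id,
    X = xy[, "X"], Y = xy[, "Y"],
    predicted = decide(xy[, "X"], model$gs_threshold),
    label = if (is.null(features$coupling_label)) NA_character_
            else features$coupling_label,
    stringsAsFactors = FALSE)
}

#' Serialize a projection model to JSON
#'
#' @param model a `projection_model`.
#' @param path output path.
#' @export
write_projection_model <- function(model, path) {
  jsonlite::write_json(list(
    mean = as.numeric(model$standardization$mean),
    scale = as.numeric(model$standardization$scale),
    components = apply(model$pca$components, 1L, as.numeric, simplify = FALSE),
    explained_variance_ratio = as.numeric(model$pca$explained_variance_ratio),
    gs_threshold = model$gs_threshold), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_projection_model
#' @export
read_projection_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- c("tm5_len", "tm5_tilt", "tm6_outward")
  std <- structure(list(mean = stats::setNames(obj$mean, nm),
                        scale = stats::setNames(obj$scale, nm)),
                   class = "standardization_params")
  comp <- if (is.list(obj$components)) do.call(rbind, obj$components)
          else rbind(obj$components)
  pca <- structure(list(components = comp,
                        explained_variance_ratio = obj$explained_variance_ratio),
                   class = "pca_model")
  projection_model(std, pca, obj$gs_threshold)
}
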