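# Point-distribution shape model: PCA of Procrustes-aligned shapes,
# projection of new cohorts onto a reference model, score summaries.

SHAPE_MODEL_SCHEMA <- 1L

#' Build a PCA shape model from aligned shapes
#'
#' Principal component analysis of the Procrustes-aligned training shapes
#' in tangent coordinates: each aligned pre-shape is centrally projected
#' onto the tangent hyperplane at the Procrustes mean (scaled by
#' `1 / <shape, mean>`, the Kendall tangent-coordinate scaling), then PCA
#' is applied about the sample average of those coordinates. This makes
#' the mode basis exactly orthogonal to the mean direction, training
#' scores exactly centred, and projection/reconstruction mutually inverse
#' on the model span (see the methods vignette). The top `K` eigenvectors
#' are retained with a fixed sign convention (largest-magnitude
#' coefficient positive) and per-mode SDs taken from the training scores
#' (denominator n - 1), so `mode_sds^2` equals the eigenvalues.
#'
#' @param gpa a `gpa_result`.
#' @param K number of modes to retain (default 10).
#' @param label free-text model label stored in metadata.
#' @return object of class `shape_model`: list with `n_points`, `dim`,
#'   `mean_shape` (unit-size Procrustes mean, the rotation target),
#'   `center` (average tangent-coordinate shape, the reconstruction base),
#'   `modes` (2P x K orthonormal matrix), `mode_sds`, `eigenvalues`
#'   (length K, descending), `total_variance` (trace of the full tangent
#'   covariance), `training_n`, `metadata`.
#' @export
build_shape_model <- function(gpa, K = 10L, label = "ssm") {
  stopifnot(inherits(gpa, "gpa_result"))
  n <- nrow(gpa$aligned)
  if (n < K + 1L)
    stop("need at least K + 1 = ", K + 1L, " shapes, have ", n)
  q <- tangent_coords(gpa$aligned, gpa$mean_shape)
  center <- colMeans(q)
  resid <- sweep(q, 2L, center)
  sv <- svd(resid)
  eig <- sv$d^2 / (n - 1)
  rank <- sum(sv$d > sv$d[1L] * 1e-12)
  if (K > rank)
    stop("K = ", K, " exceeds achievable rank ", rank)
  modes <- sv$v[, seq_len(K), drop = FALSE]
  modes <- apply_sign_convention(modes)
  structure(list(
    n_points = ncol(gpa$aligned) %/% 2L,
    dim = 2L,
    mean_shape = gpa$mean_shape,
    center = center,
    modes = modes,
    mode_sds = sqrt(eig[seq_len(K)]),
    eigenvalues = eig[seq_len(K)],
    total_variance = sum(eig),
    training_n = n,
    metadata = list(label = label, schema = SHAPE_MODEL_SCHEMA,
                    created = "hipmodes")),
    class = "shape_model")
}

# Central projection of rotated pre-shapes onto the tangent hyperplane at
# the (unit-size) mean direction: q_i = p_i / <p_i, mean>, so every row
# satisfies <q_i, mean> = 1. Shapes at 90 degrees or more from the mean
# are refused.
tangent_coords <- function(m, mean_dir) {
  comp <- as.vector(m %*% mean_dir)
  if (any(comp < 0.1))
    stop("configuration(s) too far from the reference mean for tangent ",
         "projection")
  m / comp
}

# sign convention: the largest-|coefficient| entry of each mode is positive
apply_sign_convention <- function(modes) {
  for (k in seq_len(ncol(modes))) {
    i <- which.max(abs(modes[, k]))
    if (modes[i, k] < 0) modes[, k] <- -modes[, k]
  }
  modes
}

#' @export
print.shape_model <- function(x, ...) {
  cat("<shape_model>", x$metadata$label, "-", x$n_points, "points,",
      ncol(x$modes), "modes, trained on n =", x$training_n, "\n")
  cat("  variance explained by retained modes:",
      sprintf("%.1f%%", 100 * sum(x$eigenvalues) / x$total_variance), "\n")
  invisible(x)
}

#' Project a cohort onto a reference shape model
#'
#' Each configuration is reduced to pre-shape, optimally rotated onto the
#' reference mean shape, centrally projected onto the tangent hyperplane
#' at the mean, and its residual from the model center projected on the
#' mode basis. Scores are standardised by the reference (training) SDs —
#' never by the new cohort's — so they read as deviations from the
#' reference mean shape in reference-SD units. A new cohort's scores may
#' therefore have non-zero mean and non-unit SD.
#'
#' @param model a `shape_model`.
#' @param shapes a `landmark_cohort` with matching point count.
#' @param method `"individual"` (default): each shape aligned directly to
#'   the reference mean; `"cohort_gpa"`: the cohort is first superimposed
#'   by its own GPA, then rotated as a block onto the reference mean.
#' @return numeric matrix of class `mode_scores`, n subjects x K, columns
#'   `hsm1..hsmK`, rownames = subject ids.
#' @export
apply_shape_model <- function(model, shapes,
                              method = c("individual", "cohort_gpa")) {
  stopifnot(inherits(model, "shape_model"),
            inherits(shapes, "landmark_cohort"))
  method <- match.arg(method)
  if (attr(shapes, "n_points") != model$n_points)
    stop("point-count mismatch: data have ", attr(shapes, "n_points"),
         ", model expects ", model$n_points)
  if (method == "individual") {
    m <- preshape_matrix(shapes)
    m <- rotate_rows_onto(m, model$mean_shape)
  } else {
    g <- generalized_procrustes(shapes)
    theta <- optimal_rotation(g$mean_shape, model$mean_shape)
    m <- t(apply(g$aligned, 1L, rotate_shape, theta = theta))
    rownames(m) <- rownames(g$aligned)
  }
  score_aligned(model, m)
}

# score rows of an aligned (rotated pre-shape) matrix against the model
score_aligned <- function(model, m) {
  q <- tangent_coords(m, model$mean_shape)
  resid <- sweep(q, 2L, model$center)
  raw <- resid %*% model$modes
  sc <- sweep(raw, 2L, model$mode_sds, "/")
  colnames(sc) <- paste0("hsm", seq_len(ncol(sc)))
  structure(sc, class = c("mode_scores", class(sc)))
}

#' Fraction of shape variance explained by a set of modes
#'
#' Sum of the selected eigenvalues over the total training residual
#' variance (trace of the full covariance, including discarded modes).
#'
#' @param model a `shape_model`.
#' @param modes integer vector of mode indices; empty set gives 0.
#' @return fraction in \[0, 1\].
#' @export
variance_explained <- function(model, modes = seq_along(model$eigenvalues)) {
  if (!length(modes)) return(0)
  modes <- as.integer(modes)
  if (anyDuplicated(modes) || any(modes < 1L) ||
      any(modes > length(model$eigenvalues)))
    stop("invalid mode indices")
  sum(model$eigenvalues[modes]) / model$total_variance
}

#' Pairwise correlation of mode scores
#'
#' Pearson correlations between mode columns; for a model applied to its
#' own training set these are zero (PCA orthogonality), and a mild loss of
#' independence is expected when a reference model is applied to a new
#' cohort. Constant columns yield NA with a warning.
#'
#' @param scores a `mode_scores` matrix (>= 3 subjects).
#' @return K x K correlation matrix.
#' @export
mode_independence <- function(scores) {
  if (nrow(scores) < 3L) stop("need at least 3 subjects")
  sds <- apply(scores, 2L, stats::sd)
  if (any(sds == 0))
    warning("constant mode column(s): ",
            paste(colnames(scores)[sds == 0], collapse = ", "),
            " - correlations reported as NA")
  suppressWarnings(stats::cor(unclass(scores)))
}

#' Per-mode correlation of scores between two timepoints
#'
#' Inner-joins the two score matrices on subject id and reports the
#' per-mode Pearson correlation with the overlap size.
#'
#' @param scores_t1,scores_t2 `mode_scores` matrices with subject rownames.
#' @return data.frame with columns `mode`, `r`, `n`.
#' @export
cross_timepoint_correlation <- function(scores_t1, scores_t2) {
  ids <- intersect(rownames(scores_t1), rownames(scores_t2))
  if (length(ids) < 3L)
    stop("need at least 3 overlapping subjects, found ", length(ids))
  a <- scores_t1[ids, , drop = FALSE]
  b <- scores_t2[ids, , drop = FALSE]
  if (ncol(a) != ncol(b)) stop("mode count mismatch between timepoints")
  data.frame(
    mode = colnames(a),
    r = vapply(seq_len(ncol(a)), function(k)
      stats::cor(a[, k], b[, k]), numeric(1)),
    n = length(ids))
}

#' Rotate a shape model into the frame of a reference mean
#'
#' A Procrustes mean (and hence a model built from it) is only defined up
#' to a global rotation of the coordinate frame. This helper applies the
#' optimal rotation of the model's mean onto `target_mean` to the mean
#' and every mode vector, making two models' bases directly comparable.
#' Scores are invariant under this re-framing.
#'
#' @param model a `shape_model`.
#' @param target_mean interleaved coordinate vector (e.g. another model's
#'   `mean_shape`).
#' @return the re-framed `shape_model`.
#' @export
align_model_frame <- function(model, target_mean) {
  theta <- optimal_rotation(model$mean_shape, target_mean)
  model$mean_shape <- rotate_shape(model$mean_shape, theta)
  model$center <- rotate_shape(model$center, theta)
  model$modes <- apply(model$modes, 2L, rotate_shape, theta = theta)
  model
}

# ---- serialization -----------------------------------------------------

#' Save a shape model as structured JSON
#'
#' Full-precision decimals are written so that `load_shape_model()`
#' reproduces the model bit-identically.
#'
#' @param model a `shape_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_shape_model <- function(model, path) {
  stopifnot(inherits(model, "shape_model"))
  payload <- list(
    schema_version = SHAPE_MODEL_SCHEMA,
    n_points = model$n_points,
    dim = model$dim,
    mean_shape = model$mean_shape,
    center = model$center,
    modes = asplit_cols(model$modes),
    mode_sds = model$mode_sds,
    eigenvalues = model$eigenvalues,
    total_variance = model$total_variance,
    training_n = model$training_n,
    metadata = model$metadata)
  # I(17) = 17 significant digits, enough for exact double round trip
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

asplit_cols <- function(m) lapply(seq_len(ncol(m)), function(k) m[, k])

#' Load a shape model saved by [save_shape_model()]
#'
#' Validates schema version and mode orthonormality (tampered or corrupted
#' bases are refused).
#'
#' @param path model JSON file.
#' @return a `shape_model`.
#' @export
load_shape_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$schema_version) || p$schema_version != SHAPE_MODEL_SCHEMA)
    stop("unsupported shape-model schema version: ",
         if (is.null(p$schema_version)) "missing" else p$schema_version)
  modes <- if (is.matrix(p$modes)) t(p$modes) else do.call(cbind, p$modes)
  gram <- crossprod(modes)
  if (max(abs(gram - diag(ncol(modes)))) > 1e-8)
    stop("model file is corrupt: mode basis is not orthonormal")
  structure(list(
    n_points = as.integer(p$n_points),
    dim = as.integer(p$dim),
    mean_shape = as.numeric(p$mean_shape),
    center = as.numeric(p$center),
    modes = modes,
    mode_sds = as.numeric(p$mode_sds),
    eigenvalues = as.numeric(p$eigenvalues),
    total_variance = as.numeric(p$total_variance),
    training_n = p$training_n,
    metadata = p$metadata), class = "shape_model")
}

#' Write / read mode scores as TSV
#' @param scores a `mode_scores` matrix.
#' @param path file path.
#' @return `path` (write) or a `mode_scores` matrix (read).
#' @export
write_scores <- function(scores, path) {
  df <- data.frame(id = rownames(scores), unclass(scores),
                   check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(list(df$id),
    lapply(df[-1L], num_full), sep = "\t")), con)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[setdiff(names(df), "id")])
  rownames(m) <- df$id
  structure(m, class = c("mode_scores", class(m)))
}
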