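# Generalized Procrustes analysis for 2D landmark configurations.
# Coordinate vectors are interleaved (x1, y1, ..., xP, yP).

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid — the size measure removed by Procrustes scaling.
#'
#' @param x a `landmark_set` or a 2-column coordinate matrix.
#' @return positive scalar.
#' @export
centroid_size <- function(x) {
  pts <- if (inherits(x, "landmark_set")) x$points else as.matrix(x)
  sqrt(sum(scale(pts, scale = FALSE)^2))
}

#' Center and scale a configuration to pre-shape
#'
#' Translates the centroid to the origin and scales to unit centroid size,
#' removing location and size. Rotation is untouched.
#'
#' @param shape a `landmark_set`.
#' @return numeric vector of length 2*P (interleaved x, y) of class
#'   `preshape`, with the subject id in attribute `subject_id`.
#' @export
to_preshape <- function(shape) {
  stopifnot(inherits(shape, "landmark_set"))
  pts <- scale(shape$points, scale = FALSE)
  cs <- sqrt(sum(pts^2))
  if (cs <= 0) stop("degenerate configuration: zero centroid size")
  structure(as.vector(t(pts / cs)), subject_id = shape$subject_id,
            class = "preshape")
}

# vectorised pre-shaping of a whole cohort -> n x 2P matrix
preshape_matrix <- function(cohort) {
  m <- flatten_landmarks(cohort)
  xi <- seq(1L, ncol(m), by = 2L)
  yi <- xi + 1L
  m[, xi] <- m[, xi] - rowMeans(m[, xi, drop = FALSE])
  m[, yi] <- m[, yi] - rowMeans(m[, yi, drop = FALSE])
  cs <- sqrt(rowSums(m^2))
  if (any(cs <= 0)) stop("degenerate configuration: zero centroid size")
  m / cs
}

#' Optimal rotation of one pre-shape onto another
#'
#' Returns the angle theta minimising `||R(theta) shape - target||^2` over
#' proper rotations (no reflection):
#' `theta = atan2(sum(x y' - y x'), sum(x x' + y y'))`.
#'
#' @param shape,target interleaved coordinate vectors of equal length
#'   (pre-shapes or any centred configurations).
#' @return rotation angle in radians, in (-pi, pi].
#' @export
optimal_rotation <- function(shape, target) {
  stopifnot(length(shape) == length(target))
  xi <- seq(1L, length(shape), by = 2L)
  yi <- xi + 1L
  x <- shape[xi]; y <- shape[yi]
  xp <- target[xi]; yp <- target[yi]
  atan2(sum(x * yp - y * xp), sum(x * xp + y * yp))
}

#' Rotate an interleaved coordinate vector
#' @param v interleaved coordinate vector.
#' @param theta angle in radians (counter-clockwise).
#' @return rotated vector.
#' @export
rotate_shape <- function(v, theta) {
  xi <- seq(1L, length(v), by = 2L)
  yi <- xi + 1L
  out <- v
  out[xi] <- cos(theta) * v[xi] - sin(theta) * v[yi]
  out[yi] <- sin(theta) * v[xi] + cos(theta) * v[yi]
  out
}

# rotate every row of m onto target (rows are interleaved vectors)
rotate_rows_onto <- function(m, target) {
  xi <- seq(1L, ncol(m), by = 2L)
  yi <- xi + 1L
  xp <- target[xi]; yp <- target[yi]
  num <- m[, xi, drop = FALSE] %*% yp - m[, yi, drop = FALSE] %*% xp
  den <- m[, xi, drop = FALSE] %*% xp + m[, yi, drop = FALSE] %*% yp
  th <- atan2(num, den)
  ct <- as.vector(cos(th)); st <- as.vector(sin(th))
  out <- m
  out[, xi] <- ct * m[, xi] - st * m[, yi]
  out[, yi] <- st * m[, xi] + ct * m[, yi]
  out
}

#' Generalized Procrustes analysis
#'
#' Iteratively superimposes a set of configurations: each is first reduced
#' to its pre-shape (centred, unit centroid size), then repeatedly rotated
#' onto the current mean while the mean is re-estimated as the
#' coordinate-wise average re-normalised to unit centroid size. Iteration
#' stops when the mean moves less than `tol` (Euclidean norm) or after
#' `max_iter` sweeps.
#'
#' @param shapes a `landmark_cohort` (at least two subjects).
#' @param tol convergence tolerance on the mean-shape displacement.
#' @param max_iter maximum number of sweeps.
#' @return object of class `gpa_result`: list with `mean_shape` (unit-size
#'   interleaved vector), `aligned` (n x 2P matrix of rotated pre-shapes),
#'   `n_iterations`, `converged`, `residual_norms` (per-subject Procrustes
#'   residual norm), `sums_of_squares` (total SS per iteration,
#'   non-increasing).
#' @export
generalized_procrustes <- function(shapes, tol = 1e-10, max_iter = 100L) {
  stopifnot(inherits(shapes, "landmark_cohort"), length(shapes) >= 2L)
  m <- preshape_matrix(shapes)
  mean_shape <- m[1L, ]
  ss_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    m <- rotate_rows_onto(m, mean_shape)
    avg <- colMeans(m)
    new_mean <- avg / sqrt(sum(avg^2))
    ss_trace <- c(ss_trace, sum(sweep(m, 2L, new_mean)^2))
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter, " iterations")
  m <- rotate_rows_onto(m, mean_shape)
  res <- sqrt(rowSums(sweep(m, 2L, mean_shape)^2))
  structure(list(mean_shape = mean_shape, aligned = m,
                 n_iterations = iter, converged = converged,
                 residual_norms = res, sums_of_squares = ss_trace),
            class = "gpa_result")
}

#' @export
print.gpa_result <- function(x, ...) {
  cat("<gpa_result>", nrow(x$aligned), "shapes,", x$n_iterations,
      "iterations,", if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' Pairwise (full) Procrustes distance between two configurations
#'
#' Residual norm after centering, unit-size scaling and optimal rotation of
#' `a` onto `b`.
#'
#' @param a,b `landmark_set` objects or pre-shape vectors.
#' @return non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  va <- if (inherits(a, "landmark_set")) to_preshape(a) else as.numeric(a)
  vb <- if (inherits(b, "landmark_set")) to_preshape(b) else as.numeric(b)
  sqrt(sum((rotate_shape(va, optimal_rotation(va, vb)) - vb)^2))
}
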