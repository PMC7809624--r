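# Independent oracles used across the suite. These deliberately use
# different numerical routes than the package implementation.

# random plausible landmark cohort: template plus smooth-ish jitter
rand_cohort <- function(n, sd = 0.15, seed = NULL,
                        ids = sprintf("s%03d", seq_len(n))) {
  if (!is.null(seed)) set.seed(seed)
  base <- femur_template()$points
  landmark_cohort(lapply(seq_len(n), function(i)
    landmark_set(ids[i], base + matrix(stats::rnorm(106, sd = sd), 53, 2))))
}

# apply a similarity transform to a landmark set
similarity_transform <- function(set, theta = 0, scale = 1, tx = 0, ty = 0) {
  p <- set$points
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  landmark_set(set$subject_id,
               sweep(scale * p %*% t(R), 2, c(tx, ty), "+"))
}

# SVD-based 2D orthogonal Procrustes rotation (proper), independent of
# the closed-form atan2 solution under test
svd_rotation_oracle <- function(shape, target) {
  S <- matrix(shape, ncol = 2, byrow = TRUE)
  Tm <- matrix(target, ncol = 2, byrow = TRUE)
  M <- crossprod(S, Tm)               # maximise tr(R M)
  sv <- svd(M)
  R <- sv$v %*% diag(c(1, det(sv$v %*% t(sv$u)))) %*% t(sv$u)
  atan2(R[2, 1], R[1, 1])
}

# residual of rotating `shape` onto `target` over an explicit angle grid
grid_rotation_oracle <- function(shape, target, n_grid = 1e5) {
  th <- seq(-pi, pi, length.out = n_grid)
  xi <- seq(1, length(shape), 2); yi <- xi + 1
  x <- shape[xi]; y <- shape[yi]; xp <- target[xi]; yp <- target[yi]
  # ||R(th) s - t||^2 expanded; evaluated pointwise on the grid
  a <- sum(x * xp + y * yp); b <- sum(x * yp - y * xp)
  ss <- sum(shape^2) + sum(target^2)
  res2 <- ss - 2 * (a * cos(th) + b * sin(th))
  list(theta = th[which.min(res2)], residual = sqrt(max(min(res2), 0)))
}

# dense-covariance eigendecomposition of the model's tangent coordinates
eigen_oracle <- function(gpa) {
  q <- gpa$aligned / as.vector(gpa$aligned %*% gpa$mean_shape)
  eigen(stats::cov(q), symmetric = TRUE)$values
}

# explicit normal-equations least squares fit of a residual on a basis
normal_equations_oracle <- function(resid, modes) {
  solve(crossprod(modes), crossprod(modes, resid))
}

# HWE exact test by Wigginton-style recurrence over heterozygote counts
# (implementation uses the log-gamma closed form instead)
hwe_recurrence_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  nr <- min(nA, 2 * n - nA)
  if (nr == 0) return(1)
  hets <- seq(nr %% 2, min(nr, 2 * n - nr), by = 2)
  pr <- numeric(length(hets))
  pr[1] <- 1
  for (i in seq_along(hets)[-1]) {
    hm <- hets[i - 1]
    hom_r <- (nr - hm) / 2
    hom_c <- n - hm - hom_r
    pr[i] <- pr[i - 1] * 4 * hom_r * hom_c / ((hm + 2) * (hm + 1))
  }
  pr <- pr / sum(pr)
  obs <- pr[match(nAa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

# explicit OLS + t-distribution oracle (design matrix given with intercept)
ols_oracle <- function(y, X) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- unname(sqrt(diag(solve(XtX)) * s2))
  tval <- as.vector(beta) / se
  list(beta = as.vector(beta), se = se, t = tval,
       p = 2 * stats::pt(-abs(tval), df), df = df)
}

# small complete synthetic cohort shared by several tests
small_sim <- function(n = 120, seed = 5, ...) {
  simulate_cohort(sim_config(n = n, seed = seed, ...))
}
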