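test_that("a planted single mode of variation is recovered", {
  set.seed(41)
  template <- femur_template()
  e <- make_mode_basis(template, K = 1, seed = 77)[, 1]
  m <- as.numeric(to_preshape(template))
  sigma <- 0.02
  z <- stats::rnorm(500)
  shapes <- landmark_cohort(lapply(seq_along(z), function(i)
    landmark_set(sprintf("s%03d", i),
                 matrix(m + z[i] * sigma * e, ncol = 2, byrow = TRUE))))
  g <- generalized_procrustes(shapes)
  model <- build_shape_model(g, K = 1)
  model <- align_model_frame(model, m)
  expect_gte(abs(sum(model$modes[, 1] * e)), 0.999)
  expect_lt(abs(model$mode_sds[1] / (sigma * stats::sd(z)) - 1), 0.05)
})

test_that("training scores are standardised and eigenvalues match the
           dense-covariance oracle", {
  sim <- small_sim(n = 150, seed = 42)
  g <- generalized_procrustes(sim$landmarks)
  model <- build_shape_model(g, K = 10)
  sc <- apply_shape_model(model, sim$landmarks)
  expect_lt(max(abs(colMeans(sc))), 1e-8)
  expect_lt(max(abs(apply(sc, 2, stats::sd) - 1)), 1e-8)
  ev <- eigen_oracle(g)
  expect_equal(model$eigenvalues, ev[1:10], tolerance = 1e-8)
  expect_equal(model$total_variance, sum(ev), tolerance = 1e-10)
  expect_true(all(diff(model$eigenvalues) <= 0))
  # orthonormal modes, positive sign convention
  expect_lt(max(abs(crossprod(model$modes) - diag(10))), 1e-10)
  expect_true(all(apply(model$modes, 2, function(v) v[which.max(abs(v))] > 0)))
  # K beyond achievable rank is refused
  tiny <- generalized_procrustes(sim$landmarks[1:5])
  expect_error(build_shape_model(tiny, K = 10), "rank|at least")
})

test_that("projection maps the mean to zero scores and planted offsets to
           exact scores", {
  model <- synth_reference_model(sim_config(n = 10))
  mean_lm <- landmark_set("m", matrix(model$mean_shape, ncol = 2,
                                      byrow = TRUE))
  # any similarity transform of the mean scores to zero
  tr <- similarity_transform(mean_lm, theta = 0.7, scale = 12, tx = 3,
                             ty = -9)
  sc <- apply_shape_model(model, landmark_cohort(list(tr)))
  expect_lt(max(abs(sc)), 1e-9)
  # mean + 2 sd_1 mode_1 scores exactly (2, 0, ..., 0)
  v <- model$mean_shape + 2 * model$mode_sds[1] * model$modes[, 1]
  s2 <- apply_shape_model(model, landmark_cohort(list(
    landmark_set("p", matrix(v, ncol = 2, byrow = TRUE) * 5))))
  expect_equal(as.numeric(s2), c(2, rep(0, 9)), tolerance = 1e-9)
  # point-count mismatch is a hard error
  bad <- landmark_cohort(list(landmark_set("b", cbind(1:10, (1:10)^2))))
  expect_error(apply_shape_model(model, bad), "mismatch")
})

test_that("projection equals a brute-force normal-equations fit", {
  sim <- small_sim(n = 80, seed = 43)
  model <- sim$model
  sc <- apply_shape_model(model, sim$landmarks)
  ps <- flatten_landmarks(sim$landmarks)
  for (i in c(1, 40, 80)) {
    p <- ps[i, ]
    p <- p - rep(c(mean(p[seq(1, 106, 2)]), mean(p[seq(2, 106, 2)])), 53)
    p <- p / sqrt(sum(p^2))
    p <- rotate_shape(p, optimal_rotation(p, model$mean_shape))
    q <- p / sum(p * model$mean_shape)
    beta <- normal_equations_oracle(q - model$center, model$modes)
    expect_equal(as.numeric(sc[i, ]),
                 as.numeric(beta) / model$mode_sds, tolerance = 1e-9)
  }
})

test_that("scores are invariant to per-subject similarity transforms", {
  sim <- small_sim(n = 25, seed = 44)
  model <- sim$model
  sc1 <- apply_shape_model(model, sim$landmarks)
  set.seed(441)
  moved <- landmark_cohort(lapply(sim$landmarks, function(s)
    similarity_transform(s, theta = stats::runif(1, -pi, pi),
                         scale = stats::runif(1, 0.3, 4),
                         tx = stats::rnorm(1, sd = 20),
                         ty = stats::rnorm(1, sd = 20))))
  sc2 <- apply_shape_model(model, moved)
  expect_equal(unclass(sc1), unclass(sc2), tolerance = 1e-8)
})

test_that("variance explained follows the eigen-spectrum arithmetic", {
  model <- synth_reference_model(sim_config(n = 10))
  # planted spectrum: selected relative variances over the total
  expect_equal(variance_explained(model, c(1, 2, 5)), 0.6001,
               tolerance = 1e-12)
  expect_equal(variance_explained(model, 1:10), 1)
  expect_equal(variance_explained(model, integer(0)), 0)
  expect_error(variance_explained(model, c(1, 99)), "invalid")
  # hand-built spectrum mirroring a (3, 2, 1, 1, 1, 1, 1) decomposition
  toy <- model
  toy$eigenvalues <- c(3, 2, 1, 1, 1, 1, 1)
  toy$total_variance <- 10
  expect_equal(variance_explained(toy, 1:3), 0.6)
  # monotone non-decreasing in the index set
  vs <- vapply(1:10, function(k) variance_explained(model, 1:k), numeric(1))
  expect_true(all(diff(vs) > 0))
})

test_that("mode independence is exact on training data, detected when
           broken", {
  sim <- small_sim(n = 200, seed = 45)
  g <- generalized_procrustes(sim$landmarks)
  model <- build_shape_model(g, K = 6)
  sc <- apply_shape_model(model, sim$landmarks)
  cm <- mode_independence(sc)
  expect_lt(max(abs(cm[upper.tri(cm)])), 1e-8)
  dup <- cbind(unclass(sc), hsm_dup = sc[, 1])
  expect_equal(mode_independence(dup)["hsm1", "hsm_dup"], 1)
  const <- unclass(sc); const[, 2] <- 0
  expect_warning(cm2 <- mode_independence(const), "constant")
  expect_true(is.na(cm2[1, 2]))
  expect_error(mode_independence(sc[1:2, ]), "3 subjects")
})

test_that("large cohorts drawn from the model stay nearly independent", {
  sim <- small_sim(n = 2000, seed = 46)
  sc <- apply_shape_model(sim$model, sim$landmarks)
  cm <- mode_independence(sc)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.1)
})

test_that("cross-timepoint correlation joins on ids and hits the planted
           sharing", {
  sim <- small_sim(n = 50, seed = 47)
  sc <- apply_shape_model(sim$model, sim$landmarks)
  r <- cross_timepoint_correlation(sc, sc)
  expect_equal(r$r, rep(1, 10), tolerance = 1e-12)
  expect_equal(unique(r$n), 50)
  expect_error(cross_timepoint_correlation(sc[1:2, ], sc[1:2, ]),
               "overlapping")
})

test_that("model serialization round-trips bit-identically and rejects
           tampering", {
  sim <- small_sim(n = 60, seed = 48)
  g <- generalized_procrustes(sim$landmarks)
  model <- build_shape_model(g, K = 8)
  f <- withr::local_tempfile(fileext = ".json")
  save_shape_model(model, f)
  back <- load_shape_model(f)
  expect_identical(back$mean_shape, model$mean_shape)
  expect_identical(back$center, model$center)
  expect_identical(unname(back$modes), unname(model$modes))
  expect_identical(back$mode_sds, model$mode_sds)
  sc_a <- apply_shape_model(model, sim$landmarks)
  sc_b <- apply_shape_model(back, sim$landmarks)
  expect_identical(unclass(sc_a), unclass(sc_b))
  # tampered mode vector breaks orthonormality and is refused
  p <- jsonlite::read_json(f, simplifyVector = TRUE)
  p$modes[2, 5] <- p$modes[2, 5] + 0.05
  jsonlite::write_json(p, f, digits = I(17), auto_unbox = TRUE)
  expect_error(load_shape_model(f), "orthonormal")
  # wrong schema version is refused
  p$schema_version <- 99
  jsonlite::write_json(p, f, digits = I(17), auto_unbox = TRUE)
  expect_error(load_shape_model(f), "schema")
})

test_that("score TSV round-trips bit-identically", {
  sim <- small_sim(n = 15, seed = 49)
  sc <- apply_shape_model(sim$model, sim$landmarks)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_scores(sc, f)
  back <- read_scores(f)
  expect_identical(unclass(back), unclass(sc)[, , drop = FALSE])
})
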