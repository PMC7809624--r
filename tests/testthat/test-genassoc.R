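test_that("HWE exact test handles edge cases and allele-label symmetry", {
  expect_equal(hwe_exact_test(0, 0, 25), 1)
  expect_equal(hwe_exact_test(25, 0, 0), 1)
  set.seed(61)
  for (i in 1:50) {
    n <- sample(3:60, 1)
    cnt <- as.vector(stats::rmultinom(1, n, prob = c(0.3, 0.45, 0.25)))
    p <- hwe_exact_test(cnt[1], cnt[2], cnt[3])
    expect_gt(p, 0); expect_lte(p, 1)
    expect_equal(p, hwe_exact_test(cnt[3], cnt[2], cnt[1]))
    expect_equal(p, hwe_recurrence_oracle(cnt[1], cnt[2], cnt[3]),
                 tolerance = 1e-12)
  }
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
})

test_that("QC filter applies MAF, call-rate and HWE rules with reasons", {
  n <- 200
  ids <- sprintf("s%03d", 1:n)
  mk <- function(g) {
    d <- rep(0:2, g)
    length(d) <- n          # pad with NA = missing calls
    d
  }
  # 6 constructed SNPs: pass, MAF fail, call-rate fail (HWE-consistent
  # among called), HWE fail, near-boundary MAF pass, pass
  dos <- rbind(
    ok1 = mk(c(120, 64, 16)),
    rare = c(rep(0, 198), 1, 1),                    # EAF 0.005
    gappy = c(mk(c(106, 70, 12))[1:188], rep(NA, 12)),  # 94% call rate
    hardy = mk(c(100, 0, 100)),                # het deficit, HWE blows up
    edge = mk(c(192, 8, 0)),                   # EAF 0.02 >= 0.01
    ok2 = mk(c(110, 70, 20)))
  colnames(dos) <- ids
  counts <- t(apply(dos, 1, function(d)
    c(sum(d == 0, na.rm = TRUE), sum(d == 1, na.rm = TRUE),
      sum(d == 2, na.rm = TRUE))))
  gt <- dosage_table(
    data.frame(snp_id = rownames(dos),
               effect_allele = "A", other_allele = "G"),
    dos, counts)
  qc <- qc_filter(gt)
  expect_setequal(qc$table$info$snp_id, c("ok1", "edge", "ok2"))
  rep <- qc$report
  expect_equal(rep$reasons[rep$snp_id == "rare"], "MAF")
  expect_equal(rep$reasons[rep$snp_id == "gappy"], "call rate")
  expect_equal(rep$reasons[rep$snp_id == "hardy"], "HWE")
  # hard-call dosages without explicit counts still get the HWE test
  gt_hard <- dosage_table(gt$info[1:3], dos)
  qc_hard <- qc_filter(gt_hard)
  expect_setequal(qc_hard$table$info$snp_id, c("ok1", "edge", "ok2"))
  # fractional (imputed) dosages skip HWE with a warning
  frac <- dos[c("ok1", "hardy"), ] + 0.01
  frac[frac > 2] <- 2
  gt_frac <- dosage_table(gt$info[c(1, 4), ], frac)
  expect_warning(qc_frac <- qc_filter(gt_frac), "HWE test skipped")
  expect_true(all(is.na(qc_frac$report$hwe_p)))
  expect_equal(nrow(qc_frac$table$info), 2)
})

test_that("noiseless additive signal is recovered exactly", {
  set.seed(62)
  n <- 60
  ids <- sprintf("s%02d", 1:n)
  g <- stats::setNames(sample(0:2, n, TRUE), ids)
  cov <- covariate_table(data.frame(
    id = ids, age = stats::runif(n, 13, 15), sex = stats::rbinom(n, 1, 0.5),
    height_cm = stats::rnorm(n, 165, 7), weight_kg = stats::rnorm(n, 55, 9)))
  y <- stats::setNames(0.5 * g + 0.1 * cov$age, ids)
  # perfect fit triggers a harmless summary.lm precision warning
  fit <- suppressWarnings(fit_snp_mode(y, g, cov, spec = "model1"))
  expect_equal(fit$beta, 0.5, tolerance = 1e-10)
  expect_equal(fit$n, n)
})

test_that("an 8-subject fixture matches the explicit OLS + t oracle", {
  ids <- paste0("s", 1:8)
  g <- stats::setNames(c(0, 1, 2, 1, 0, 2, 1, 0), ids)
  cov <- covariate_table(data.frame(
    id = ids, age = c(13.1, 14.2, 13.8, 14.0, 13.5, 14.4, 13.9, 13.2),
    sex = c(0, 1, 0, 1, 0, 1, 0, 1),
    height_cm = c(158, 171, 162, 169, 155, 174, 166, 160),
    weight_kg = c(49, 63, 55, 60, 47, 68, 58, 52)))
  y <- stats::setNames(c(0.21, -0.34, 1.02, 0.13, -0.55, 0.88, 0.07, -0.2),
                       ids)
  fit <- fit_snp_mode(y, g, cov, spec = "model1")
  X <- cbind(1, g, cov$age, cov$sex)
  o <- ols_oracle(as.numeric(y), X)
  expect_equal(fit$beta, o$beta[2], tolerance = 1e-10)
  expect_equal(fit$se, o$se[2], tolerance = 1e-10)
  expect_equal(fit$p, o$p[2], tolerance = 1e-10)
  # degrees of freedom: n - covariates - 2
  expect_equal(o$df, 8 - 2 - 2)
  # model2/model3 use their covariate sets
  fit2 <- fit_snp_mode(y, g, cov, spec = "model2")
  o2 <- ols_oracle(as.numeric(y), cbind(1, g, cov$age, cov$sex,
                                        cov$height_cm))
  expect_equal(fit2$beta, o2$beta[2], tolerance = 1e-10)
  # degenerate designs are refused
  expect_error(fit_snp_mode(y, stats::setNames(rep(1, 8), ids), cov),
               "constant dosage")
  cov2 <- cov; cov2$height_cm <- cov2$age
  expect_error(fit_snp_mode(y, g, cov2, spec = "model2"), "collinear")
})

test_that("planted effects at cohort scale are recovered within
           simulation error", {
  # smaller than the headline cohort to keep the default suite fast;
  # the full n = 3550 run lives in the acceptance suite
  sim <- small_sim(n = 1200, seed = 63)
  sc <- apply_shape_model(sim$model, sim$landmarks)
  res <- fit_snp_mode(sc, sim$dosages$dosage["snp_sox9", ],
                      sim$covariates, spec = "model1", hsm = 1,
                      snp_id = "snp_sox9")
  expect_lt(abs(res$beta - (-0.054)), 3 * res$se)
})

test_that("estimator bias shrinks with sample size", {
  bias <- vapply(c(250, 1000, 4000), function(n) {
    reps <- vapply(1:12, function(r) {
      set.seed(1000 * r + n)
      g <- stats::rbinom(n, 2, 0.35)
      y <- -0.054 * g + stats::rnorm(n)
      ids <- as.character(seq_len(n))
      cov <- covariate_table(data.frame(
        id = ids, age = stats::rnorm(n, 14, 0.2),
        sex = stats::rbinom(n, 1, 0.5),
        height_cm = stats::rnorm(n, 165, 7),
        weight_kg = stats::rnorm(n, 55, 10)))
      fit_snp_mode(stats::setNames(y, ids), stats::setNames(g, ids), cov)$beta
    }, numeric(1))
    abs(mean(reps) + 0.054)
  }, numeric(1))
  expect_lt(bias[3], 0.02)
  expect_lt(bias[3], bias[1] + 0.02)
})

test_that("Bonferroni threshold arithmetic and display match convention", {
  thr <- bonferroni_threshold(0.05, 8)
  expect_equal(as.numeric(thr), 0.00625)
  expect_equal(attr(thr, "display"), "0.006")
  expect_equal(as.numeric(bonferroni_threshold(0.05, 1)), 0.05)
  expect_equal(as.numeric(bonferroni_threshold(0.05, 10)), 0.005)
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
  expect_error(bonferroni_threshold(1.2, 4), "alpha")
})

test_that("the shipped adult look-up panel produces the published flag
           pattern", {
  adult <- adult_snp_table()
  expect_equal(nrow(adult), 9)
  expect_equal(sum(adult$hsm == 1), 5)
  expect_equal(sum(adult$hsm == 2), 3)
  expect_equal(sum(adult$hsm == 5), 1)
  lk <- function(tp) data.frame(snp_id = adult$snp_id, hsm = adult$hsm,
                                beta = adult[[paste0("beta_", tp)]],
                                p = adult[[paste0("p_", tp)]])
  tab <- build_association_table(
    adult, list(age14 = lk("age14"), age18 = lk("age18")),
    bonferroni_threshold(0.05, 8))
  expect_equal(count_significant(tab, "either_timepoint"), 6)
  expect_equal(count_significant(tab, "both_timepoints"), 4)
  both <- tab[rowSums(as.matrix(tab[c("sig_age14", "sig_age18")])) == 2, ]
  expect_setequal(paste(both$snp_id, both$hsm),
                  c("rs2158915 1", "rs10743612 1", "rs6537291 2",
                    "rs2158915 5"))
  expect_true(all(tab$direction_consistent))
  expect_true(all(tab$weak_evidence))
  # monotone threshold bounds
  t1 <- build_association_table(adult, list(age14 = lk("age14"),
                                            age18 = lk("age18")), 1.0)
  expect_equal(count_significant(t1, "either_timepoint"), 9)
  t0 <- build_association_table(adult, list(age14 = lk("age14"),
                                            age18 = lk("age18")), 0)
  expect_equal(count_significant(t0, "either_timepoint"), 0)
  # unmatched pairs are kept and flagged missing, not dropped
  partial <- lk("age14")[1:5, ]
  tp <- build_association_table(adult, list(age14 = partial), 0.006)
  expect_equal(sum(tp$missing), 4)
  expect_equal(nrow(tp), 9)
  # empty table counts zero
  empty <- build_association_table(adult[0, ], list(age14 = lk("age14")[0, ]),
                                   0.006)
  expect_equal(count_significant(empty, "either_timepoint"), 0)
})

test_that("covariate adjustment leaves genotype effects essentially
           unchanged when covariates are independent of genotype", {
  sim <- small_sim(n = 1500, seed = 64)
  sc <- apply_shape_model(sim$model, sim$landmarks)
  fits <- lapply(c("model1", "model2", "model3"), function(m)
    fit_snp_mode(sc, sim$dosages$dosage["snp_hhip", ], sim$covariates,
                 spec = m, hsm = 2))
  b <- vapply(fits, `[[`, numeric(1), "beta")
  se <- vapply(fits, `[[`, numeric(1), "se")
  expect_lt(abs(b[2] - b[1]), 2 * se[1])
  expect_lt(abs(b[3] - b[1]), 2 * se[1])
})
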