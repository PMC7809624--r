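# Candidate-SNP quality control and additive association of allele
# dosages with shape-mode scores.

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the observed allele counts, the p-value is
#' the total probability of all heterozygote counts (same parity as the
#' minor-allele count) whose conditional probability under the HWE null is
#' no greater than that of the observed count. Probabilities are computed
#' from the closed-form expression via log-gamma. A monomorphic SNP has
#' p = 1, and the test is invariant to swapping the two homozygote counts.
#'
#' @param n_AA,n_Aa,n_aa non-negative genotype counts (`aa` = homozygous
#'   effect allele; the labelling does not affect the p-value).
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1L) stop("need at least one genotype")
  n_rare <- min(2L * n_AA + n_Aa, 2L * n_aa + n_Aa)
  if (n_rare == 0L) return(1)
  hets <- seq.int(n_rare %% 2L, min(n_rare, 2L * n - n_rare), by = 2L)
  # log P(h | n, n_rare) for every attainable heterozygote count h
  logp <- lgamma(n + 1) -
    lgamma((n_rare - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma(n - (n_rare + hets) / 2 + 1) +
    hets * log(2) +
    lgamma(n_rare + 1) + lgamma(2 * n - n_rare + 1) - lgamma(2 * n + 1)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

#' SNP quality-control filter
#'
#' Retains SNPs passing all of: minor allele frequency >= `maf_min`, call
#' rate >= `call_rate_min`, and exact Hardy-Weinberg p-value >
#' `hwe_p_min`. HWE requires hard genotype counts; dosage-only SNPs skip
#' the HWE test with a warning (recorded in the report).
#'
#' @param gt a `dosage_table`.
#' @param maf_min minimum minor-allele frequency (default 0.01).
#' @param call_rate_min minimum call rate (default 0.95).
#' @param hwe_p_min exact-HWE exclusion threshold (default 5e-7; a SNP is
#'   kept only if p > this).
#' @return list with `table` (filtered `dosage_table`, possibly zero rows)
#'   and `report` (data.frame: snp_id, maf, call_rate, hwe_p, pass,
#'   reasons).
#' @export
qc_filter <- function(gt, maf_min = 0.01, call_rate_min = 0.95,
                      hwe_p_min = 5e-7) {
  stopifnot(inherits(gt, "dosage_table"))
  n_sub <- ncol(gt$dosage)
  call_rate <- rowSums(!is.na(gt$dosage)) / n_sub
  eaf <- rowMeans(gt$dosage, na.rm = TRUE) / 2
  maf <- pmin(eaf, 1 - eaf)
  counts <- gt$counts
  if (is.null(counts)) {
    # hard-call dosages (all 0/1/2) imply the genotype counts
    hard <- apply(gt$dosage, 1L, function(d)
      all(is.na(d) | d %in% c(0, 1, 2)))
    counts <- t(vapply(seq_len(nrow(gt$dosage)), function(i) {
      if (!hard[i]) return(c(NA_integer_, NA_integer_, NA_integer_))
      d <- gt$dosage[i, ]
      c(sum(d == 0, na.rm = TRUE), sum(d == 1, na.rm = TRUE),
        sum(d == 2, na.rm = TRUE))
    }, integer(3)))
    if (any(!hard))
      warning("no hard genotype counts for ",
              paste(gt$info$snp_id[!hard], collapse = ", "),
              ": HWE test skipped")
  }
  hwe_p <- vapply(seq_len(nrow(counts)), function(i) {
    if (anyNA(counts[i, ])) return(NA_real_)
    hwe_exact_test(counts[i, 1L], counts[i, 2L], counts[i, 3L])
  }, numeric(1))
  reasons <- mapply(function(m, cr, hp) {
    r <- character(0)
    if (m < maf_min) r <- c(r, "MAF")
    if (cr < call_rate_min) r <- c(r, "call rate")
    if (!is.na(hp) && hp <= hwe_p_min) r <- c(r, "HWE")
    paste(r, collapse = ";")
  }, maf, call_rate, hwe_p)
  pass <- !nzchar(reasons)
  report <- data.frame(snp_id = gt$info$snp_id, maf = maf,
                       call_rate = call_rate, hwe_p = hwe_p,
                       pass = pass, reasons = reasons,
                       stringsAsFactors = FALSE)
  keep <- which(pass)
  filtered <- gt
  filtered$info <- gt$info[keep, , drop = FALSE]
  filtered$dosage <- gt$dosage[keep, , drop = FALSE]
  if (!is.null(gt$counts)) filtered$counts <- gt$counts[keep, , drop = FALSE]
  list(table = filtered, report = report)
}

#' Covariate sets for the three adjustment models
#'
#' `model1` adjusts for age and sex; `model2` additionally for height;
#' `model3` additionally for BMI (instead of height).
#'
#' @param spec one of `"model1"`, `"model2"`, `"model3"`.
#' @return character vector of covariate column names.
#' @export
model_covariates <- function(spec = c("model1", "model2", "model3")) {
  switch(match.arg(spec),
         model1 = c("age", "sex"),
         model2 = c("age", "sex", "height_cm"),
         model3 = c("age", "sex", "bmi"))
}

#' Additive association of one SNP with one shape mode
#'
#' Ordinary least squares of the mode score on (intercept, effect-allele
#' dosage, covariates). The reported beta is the dosage coefficient —
#' change in reference-standardised score per effect allele — with its
#' standard error and a two-sided p-value from the t distribution on the
#' residual degrees of freedom.
#'
#' @param scores named numeric vector of one mode's scores (names =
#'   subject ids), or a `mode_scores` matrix together with `hsm`.
#' @param dosage named numeric vector of effect-allele dosages.
#' @param covariates a `covariate_table`.
#' @param spec covariate model, see [model_covariates()].
#' @param hsm mode index, used when `scores` is a matrix and recorded in
#'   the result.
#' @param snp_id,timepoint labels recorded in the result.
#' @return one-row data.frame of class `association_result`: snp_id, hsm,
#'   timepoint, model, n, beta, se, t, p.
#' @export
fit_snp_mode <- function(scores, dosage, covariates,
                         spec = c("model1", "model2", "model3"),
                         hsm = 1L, snp_id = "snp", timepoint = "cohort") {
  spec <- match.arg(spec)
  if (is.matrix(scores)) {
    y <- scores[, hsm]
    names(y) <- rownames(scores)
  } else y <- scores
  cols <- model_covariates(spec)
  ids <- Reduce(intersect, list(names(y), names(dosage), covariates$id))
  cov <- covariates[match(ids, covariates$id), cols, drop = FALSE]
  d <- data.frame(y = y[ids], g = dosage[ids], cov)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  p_cov <- length(cols)
  if (n < p_cov + 3L)
    stop("too few complete cases (n = ", n, ") for ", spec)
  if (stats::var(d$g) == 0) stop("degenerate design: constant dosage")
  fit <- stats::lm(y ~ ., data = d)
  if (fit$rank < p_cov + 2L) stop("degenerate design: collinear covariates")
  cf <- summary(fit)$coefficients
  structure(data.frame(
    snp_id = snp_id, hsm = as.integer(hsm), timepoint = timepoint,
    model = spec, n = n,
    beta = cf["g", "Estimate"], se = cf["g", "Std. Error"],
    t = cf["g", "t value"], p = cf["g", "Pr(>|t|)"],
    stringsAsFactors = FALSE),
    class = c("association_result", "data.frame"))
}

#' Association scan over SNP x mode pairs
#'
#' Convenience wrapper running [fit_snp_mode()] for each requested pair
#' under one or more covariate models.
#'
#' @param scores a `mode_scores` matrix.
#' @param gt a `dosage_table`.
#' @param covariates a `covariate_table`.
#' @param pairs data.frame with columns `snp_id` and `hsm` (mode index);
#'   default: every SNP against every mode.
#' @param models character vector of covariate models.
#' @param timepoint label recorded in results.
#' @return data.frame, one row per SNP x mode x model.
#' @export
association_scan <- function(scores, gt, covariates, pairs = NULL,
                             models = "model1", timepoint = "cohort") {
  if (is.null(pairs))
    pairs <- expand.grid(snp_id = gt$info$snp_id,
                         hsm = seq_len(ncol(scores)),
                         stringsAsFactors = FALSE)
  out <- list()
  for (m in models) {
    for (i in seq_len(nrow(pairs))) {
      dos <- gt$dosage[pairs$snp_id[i], ]
      out[[length(out) + 1L]] <- fit_snp_mode(
        scores, dos, covariates, spec = m, hsm = pairs$hsm[i],
        snp_id = pairs$snp_id[i], timepoint = timepoint)
    }
  }
  do.call(rbind, out)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param n_tests number of tests (>= 1).
#' @return `alpha / n_tests`. The display form (attribute `"display"`)
#'   rounds to 3 decimals, e.g. 0.05/8 = 0.00625 prints as "0.006".
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_tests < 1) stop("n_tests must be >= 1")
  thr <- alpha / n_tests
  structure(thr, display = sprintf("%.3f", round(thr, 3)))
}

#' Published reference SNP-mode association table
#'
#' The adult-discovery look-up panel shipped with the package: nine
#' SNP x HSM pairs (five on HSM1, three on HSM2, one on HSM5) with the
#' adult meta-analysis effect-allele, frequency, beta and p-value, plus
#' the adolescent look-up betas/p-values at the age-14 and age-18 clinics.
#' Betas are in reference-SD units per effect allele, as printed in the
#' source publication.
#'
#' @return data.frame with columns hsm, snp_id, locus, effect_allele, eaf,
#'   beta_adult, p_adult, beta_age14, p_age14, beta_age18, p_age18.
#' @export
adult_snp_table <- function() {
  path <- system.file("extdata", "adult_hip_shape_snps.tsv",
                      package = "hipmodes", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Assemble a look-up association table with significance flags
#'
#' Joins adult-discovery rows to per-timepoint cohort results and flags,
#' per row: `sig_<timepoint>` (p below the threshold at that timepoint),
#' `meets_threshold` (significant at >= 1 timepoint),
#' `direction_consistent` (every available cohort beta has the adult
#' beta's sign) and `weak_evidence` (direction-consistent with p < 0.1 at
#' some timepoint).
#'
#' @param adult data.frame with columns `snp_id`, `hsm`, `beta_adult`,
#'   `p_adult` (e.g. [adult_snp_table()]).
#' @param cohort_results named list of data.frames (one per timepoint,
#'   names = timepoint labels) each with columns `snp_id`, `hsm`, `beta`,
#'   `p` — either [association_scan()] output or transcribed look-up
#'   values.
#' @param threshold significance threshold on p (strict `<`).
#' @return data.frame of class `association_table`; unmatched SNP x HSM
#'   pairs keep their row with NA cohort columns and `missing = TRUE`.
#' @export
build_association_table <- function(adult, cohort_results, threshold) {
  stopifnot(is.data.frame(adult),
            all(c("snp_id", "hsm", "beta_adult", "p_adult") %in% names(adult)))
  threshold <- as.numeric(threshold)
  tps <- names(cohort_results)
  if (is.null(tps) || any(!nzchar(tps)))
    stop("cohort_results must be a named list (names = timepoint labels)")
  tab <- adult
  for (tp in tps) {
    res <- cohort_results[[tp]]
    i <- match(paste(tab$snp_id, tab$hsm),
               paste(res$snp_id, res$hsm))
    tab[[paste0("beta_", tp)]] <- res$beta[i]
    tab[[paste0("p_", tp)]] <- res$p[i]
    tab[[paste0("sig_", tp)]] <- !is.na(res$p[i]) & res$p[i] < threshold
  }
  pcols <- paste0("p_", tps)
  bcols <- paste0("beta_", tps)
  tab$missing <- rowSums(!is.na(as.matrix(tab[pcols]))) == 0L
  tab$meets_threshold <-
    rowSums(as.matrix(tab[paste0("sig_", tps)]), na.rm = TRUE) > 0L
  bmat <- as.matrix(tab[bcols])
  consistent <- sign(bmat) == sign(tab$beta_adult)
  tab$direction_consistent <-
    rowSums(consistent, na.rm = TRUE) == rowSums(!is.na(bmat)) & !tab$missing
  minp <- suppressWarnings(apply(as.matrix(tab[pcols]), 1L, min, na.rm = TRUE))
  tab$weak_evidence <- tab$direction_consistent & is.finite(minp) & minp < 0.1
  attr(tab, "threshold") <- threshold
  attr(tab, "timepoints") <- tps
  class(tab) <- c("association_table", "data.frame")
  tab
}

#' Count significant look-up rows
#'
#' @param table an `association_table`.
#' @param rule `"either_timepoint"` (significant at >= 1 timepoint),
#'   `"both_timepoints"` (at every timepoint present in the table), or
#'   `"per_timepoint"` (named vector of per-timepoint counts).
#' @return integer count (or named integer vector for `per_timepoint`).
#' @export
count_significant <- function(table,
                              rule = c("either_timepoint", "both_timepoints",
                                       "per_timepoint")) {
  rule <- match.arg(rule)
  tps <- attr(table, "timepoints")
  if (!nrow(table))
    return(if (rule == "per_timepoint")
      stats::setNames(integer(length(tps)), tps) else 0L)
  sig <- as.matrix(table[paste0("sig_", tps)])
  switch(rule,
         either_timepoint = sum(rowSums(sig, na.rm = TRUE) > 0L),
         both_timepoints = sum(rowSums(sig, na.rm = TRUE) == length(tps)),
         per_timepoint = stats::setNames(colSums(sig, na.rm = TRUE), tps))
}
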