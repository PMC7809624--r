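# Synthetic-data generator: stylised femur template, smooth orthonormal
# mode basis, cohorts with planted genetic effects, HWE genotypes,
# covariates, nuisance transforms and a truth ledger.

#' Stylised 53-point proximal femur template
#'
#' A fixed, versioned open polyline tracing (in order) the lateral shaft,
#' greater trochanter, trochanteric saddle, superior neck, femoral head
#' (circular arc), inferior neck, lesser trochanter and medial shaft.
#' Deterministic (no randomness) and non-self-intersecting; it stands in
#' for a mean hip outline when no real landmark data are available.
#'
#' @return a `landmark_set` with subject id `"template"`.
#' @export
femur_template <- function() {
  lat_shaft <- cbind(c(0.00, 0.02, 0.05, 0.10, 0.16, 0.25),
                     c(0.0, 0.9, 1.8, 2.7, 3.6, 4.5))
  gtroch   <- cbind(c(0.35, 0.42, 0.55, 0.75, 1.05, 1.35),
                    c(5.2, 5.9, 6.6, 7.1, 7.35, 7.3))
  saddle   <- cbind(c(1.60, 1.80, 2.05, 2.35, 2.70),
                    c(7.05, 6.75, 6.55, 6.50, 6.60))
  sup_neck <- cbind(c(2.90, 3.00, 3.10),
                    c(6.75, 6.90, 7.10))
  ang <- seq(150, -115, length.out = 17) * pi / 180
  head <- cbind(4.9 + 1.85 * cos(ang), 6.6 + 1.85 * sin(ang))
  inf_neck <- cbind(c(3.85, 3.62, 3.45, 3.35),
                    c(4.45, 3.95, 3.45, 3.00))
  ltroch   <- cbind(c(3.42, 3.55, 3.50, 3.30, 3.05),
                    c(2.75, 2.45, 2.10, 1.85, 1.75))
  med_shaft <- cbind(c(2.95, 2.90, 2.87, 2.85, 2.83, 2.82, 2.80),
                     c(1.45, 1.20, 0.95, 0.70, 0.45, 0.22, 0.00))
  landmark_set("template", rbind(lat_shaft, gtroch, saddle, sup_neck,
                                 head, inf_neck, ltroch, med_shaft))
}

#' Check that a polyline has no self-intersections
#'
#' Pairwise segment-intersection sweep over an open polyline (shared
#' endpoints of adjacent segments do not count).
#'
#' @param points P x 2 coordinate matrix.
#' @return TRUE if simple, FALSE otherwise.
#' @export
polyline_is_simple <- function(points) {
  n <- nrow(points)
  for (i in seq_len(n - 3L)) {
    for (j in (i + 2L):(n - 1L)) {
      p1 <- points[i, ]; p2 <- points[i + 1L, ]
      p3 <- points[j, ]; p4 <- points[j + 1L, ]
      d1 <- p2 - p1; d2 <- p4 - p3
      den <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
      if (abs(den) < 1e-14) next
      t <- ((p3[1L] - p1[1L]) * d2[2L] - (p3[2L] - p1[2L]) * d2[1L]) / den
      u <- ((p3[1L] - p1[1L]) * d1[2L] - (p3[2L] - p1[2L]) * d1[1L]) / den
      if (t > 1e-12 && t < 1 - 1e-12 && u > 1e-12 && u < 1 - 1e-12)
        return(FALSE)
    }
  }
  TRUE
}

#' Smooth orthonormal deformation-mode basis
#'
#' Draws `K` smooth random deformation fields (low-order sine/cosine
#' series along the point index, coefficient SD decaying as 1/order) and
#' orthonormalises them against each other and against the
#' four-dimensional similarity subspace at the template (x/y translation,
#' rotation and scaling generators). Planted shape variance along these
#' modes therefore cannot be absorbed by Procrustes alignment. The sign
#' convention (largest-magnitude coefficient positive) matches
#' [build_shape_model()], so planted and re-estimated modes are
#' sign-comparable.
#'
#' @param template a `landmark_set` (deformations are defined at its
#'   pre-shape).
#' @param K number of modes (at most 2P - 4).
#' @param seed integer seed (the basis is fully reproducible from it).
#' @param max_order highest trigonometric order of the fields.
#' @return 2P x K orthonormal matrix (interleaved coordinate layout).
#' @export
make_mode_basis <- function(template, K = 10L, seed = 20L, max_order = 6L) {
  m <- to_preshape(template)
  p2 <- length(m)
  if (K > p2 - 4L) stop("K must be at most 2P - 4 = ", p2 - 4L)
  xi <- seq(1L, p2, by = 2L); yi <- xi + 1L
  gens <- matrix(0, p2, 4L)
  gens[xi, 1L] <- 1                       # x translation
  gens[yi, 2L] <- 1                       # y translation
  gens[xi, 3L] <- -m[yi]; gens[yi, 3L] <- m[xi]   # rotation
  gens[, 4L] <- m                          # scaling
  tt <- (seq_len(p2 %/% 2L) - 1L) / (p2 %/% 2L - 1L)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  for (attempt in 1:5) {
    fields <- vapply(seq_len(K), function(k) {
      f <- numeric(p2)
      for (h in seq_len(max_order)) {
        ax <- stats::rnorm(1, sd = 1 / h); bx <- stats::rnorm(1, sd = 1 / h)
        ay <- stats::rnorm(1, sd = 1 / h); by <- stats::rnorm(1, sd = 1 / h)
        f[xi] <- f[xi] + ax * sin(pi * h * tt) + bx * cos(pi * h * tt)
        f[yi] <- f[yi] + ay * sin(pi * h * tt) + by * cos(pi * h * tt)
      }
      f
    }, numeric(p2))
    qr_all <- qr(cbind(gens, fields))
    if (qr_all$rank >= 4L + K) {
      basis <- qr.Q(qr_all)[, 4L + seq_len(K), drop = FALSE]
      return(apply_sign_convention(basis))
    }
  }
  stop("could not build a full-rank mode basis (rank deficiency)")
}

#' Default per-mode raw SD spectrum
#'
#' Relative variances are chosen so that modes 1, 2 and 5 jointly carry
#' 60% of the total shape variance, with eigenvalues strictly descending
#' and adjacent eigenvalues separated by at least ~12% (so each
#' eigenvector is identifiable from a few thousand training shapes); the
#' total raw shape variance (pre-shape units) defaults to 0.002, i.e.
#' shape displacements are small relative to centroid size, as for real
#' hip outlines.
#'
#' @param total_var total raw shape variance in pre-shape units.
#' @return numeric vector of 10 raw mode SDs.
#' @export
default_mode_sds <- function(total_var = 0.002) {
  relvar <- c(0.315, 0.19, 0.1509, 0.1198, 0.0951,
              0.045, 0.033, 0.024, 0.016, 0.0112)
  sqrt(total_var * relvar)
}

#' Default planted SNP effects
#'
#' Three candidate SNPs mirroring published adult hip-shape loci: a
#' SOX9-region-like variant (EAF 0.35) acting on modes 1 and 5, a
#' PTHLH-region-like variant (EAF 0.24) on mode 1 and an HHIP-region-like
#' variant (EAF 0.38) on mode 2. Betas are per-allele effects on the
#' standardised scores.
#'
#' @return list of per-SNP specs (snp_id, effect_allele, other_allele,
#'   eaf, betas named by mode index).
#' @export
default_snp_specs <- function() {
  list(
    list(snp_id = "snp_sox9", effect_allele = "G", other_allele = "A",
         eaf = 0.35, betas = c("1" = -0.054, "5" = -0.072)),
    list(snp_id = "snp_pthlh", effect_allele = "A", other_allele = "G",
         eaf = 0.24, betas = c("1" = 0.05)),
    list(snp_id = "snp_hhip", effect_allele = "A", other_allele = "C",
         eaf = 0.38, betas = c("2" = -0.063)))
}

# Table-style covariate distributions per timepoint (age in years, height
# in cm, weight in kg; sex-specific where the source table is)
covariate_params <- function(timepoint) {
  switch(timepoint,
    age14 = list(p_female = 0.52, age = c(13.8, 0.20),
                 height_f = c(162.1, 6.2), height_m = c(165.0, 8.7),
                 weight_f = c(54.4, 10.2), weight_m = c(54.8, 11.7)),
    age18 = list(p_female = 0.55, age = c(17.8, 0.38),
                 height_f = c(165.4, 6.2), height_m = c(178.9, 6.6),
                 weight_f = c(62.6, 11.6), weight_m = c(72.7, 13.4)),
    stop("unknown timepoint preset: ", timepoint))
}

default_offsets <- function(timepoint, K = 10L) {
  off <- numeric(K)
  if (timepoint == "age14") {
    off[c(1L, 2L, 5L)] <- c(2.3, 0.6, -1.2)
  } else if (timepoint == "age18") {
    off[c(1L, 2L, 5L)] <- c(2.4, 0.2, -1.5)
  }
  off
}

#' Simulation configuration
#'
#' Bundles every knob of the cohort generator with defaults emulating a
#' mid-adolescence DXA clinic: n = 3550 subjects, 10 modes whose scores
#' (in reference-SD units) have total SD about 1, cohort mean-score
#' offsets on modes 1/2/5, three planted candidate SNPs, sub-pixel
#' landmark noise and random per-subject rigid + scale nuisance
#' transforms.
#'
#' @param n number of subjects.
#' @param seed integer seed controlling every random draw of the cohort.
#' @param timepoint `"age14"` or `"age18"` (selects covariate and offset
#'   presets).
#' @param K number of modes.
#' @param mode_sds raw per-mode SDs (pre-shape units) of the reference
#'   model.
#' @param offsets cohort mean score per mode (reference-SD units).
#' @param snps list of SNP specs as in [default_snp_specs()]; may be
#'   empty.
#' @param noise_sd iid landmark noise SD in pre-shape units (default
#'   5e-4, about 2% of the typical mode-1 displacement).
#' @param rot_deg,scale_frac,trans nuisance ranges: rotation uniform in
#'   +/- `rot_deg` degrees, scale log-uniform in +/- `scale_frac`,
#'   translation uniform in +/- `trans` output units.
#' @param base_size mean centroid size of the written landmarks (output
#'   units, think pixels).
#' @param basis_seed seed of the reference mode basis (kept separate from
#'   the cohort seed so all cohorts share one reference model).
#' @param height_coupling named numeric (snp_id -> cm per allele) adding a
#'   genotype effect on height; default none, so the covariate-adjustment
#'   models agree by construction.
#' @param ids optional explicit subject ids (length n).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n = 3550L, seed = 1L, timepoint = "age14", K = 10L,
                       mode_sds = default_mode_sds(),
                       offsets = default_offsets(timepoint, K),
                       snps = default_snp_specs(),
                       noise_sd = 5e-4, rot_deg = 10, scale_frac = 0.1,
                       trans = 0.5, base_size = 500, basis_seed = 20L,
                       height_coupling = NULL, ids = NULL) {
  stopifnot(n >= 2L, K >= 1L, length(mode_sds) == K,
            all(mode_sds > 0), length(offsets) == K, noise_sd >= 0,
            rot_deg >= 0, scale_frac >= 0, trans >= 0, base_size > 0)
  for (s in snps) {
    if (s$eaf <= 0 || s$eaf >= 1)
      stop("EAF must be in (0, 1) for ", s$snp_id)
    ki <- as.integer(names(s$betas))
    if (anyNA(ki) || any(ki < 1L) || any(ki > K))
      stop("invalid mode index in betas of ", s$snp_id)
  }
  if (!is.null(ids) && length(ids) != n) stop("ids must have length n")
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 timepoint = timepoint, K = as.integer(K),
                 mode_sds = mode_sds, offsets = offsets, snps = snps,
                 noise_sd = noise_sd, rot_deg = rot_deg,
                 scale_frac = scale_frac, trans = trans,
                 base_size = base_size, basis_seed = as.integer(basis_seed),
                 height_coupling = height_coupling, ids = ids),
            class = "sim_config")
}

#' The reference shape model implied by a simulation configuration
#'
#' Built directly from the template pre-shape, the seeded mode basis and
#' the configured raw mode SDs — this is the generator's ground-truth
#' model, playing the role of the adult reference model that new cohorts
#' are projected onto.
#'
#' @param config a `sim_config` (only `K`, `mode_sds` and `basis_seed`
#'   are used).
#' @return a `shape_model`.
#' @export
synth_reference_model <- function(config = sim_config()) {
  template <- femur_template()
  basis <- make_mode_basis(template, K = config$K, seed = config$basis_seed)
  mean_shape <- as.numeric(to_preshape(template))
  structure(list(
    n_points = nrow(template$points),
    dim = 2L,
    mean_shape = mean_shape,
    center = mean_shape,
    modes = basis,
    mode_sds = config$mode_sds,
    eigenvalues = config$mode_sds^2,
    total_variance = sum(config$mode_sds^2),
    training_n = NA_integer_,
    tangent = FALSE,
    metadata = list(label = "synthetic-reference",
                    schema = SHAPE_MODEL_SCHEMA,
                    basis_seed = config$basis_seed)),
    class = "shape_model")
}

#' Draw genotypes in Hardy-Weinberg equilibrium
#'
#' Genotypes are sampled with probabilities ((1-q)^2, 2q(1-q), q^2) for
#' 0, 1, 2 copies of the effect allele (q = `eaf`). Uses the current RNG
#' state unless `seed` is given.
#'
#' @param n number of subjects.
#' @param eaf effect-allele frequency in (0, 1).
#' @param seed optional seed.
#' @return list with `dosage` (integer 0/1/2 vector) and `counts`
#'   (n_AA, n_Aa, n_aa — `aa` homozygous for the effect allele).
#' @export
hwe_genotypes <- function(n, eaf, seed = NULL) {
  if (eaf <= 0 || eaf >= 1) stop("eaf must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  g <- sample(0:2, n, replace = TRUE,
              prob = c((1 - eaf)^2, 2 * eaf * (1 - eaf), eaf^2))
  list(dosage = g,
       counts = c(n_AA = sum(g == 0L), n_Aa = sum(g == 1L),
                  n_aa = sum(g == 2L)))
}

# per-mode residual SD so that the total score SD is ~1 given the planted
# genetic variance
residual_score_sds <- function(config) {
  gvar <- numeric(config$K)
  for (s in config$snps) {
    ki <- as.integer(names(s$betas))
    gvar[ki] <- gvar[ki] + s$betas^2 * 2 * s$eaf * (1 - s$eaf)
  }
  if (any(gvar >= 1))
    stop("planted genetic variance >= 1 on mode(s) ",
         paste(which(gvar >= 1), collapse = ", "))
  sqrt(1 - gvar)
}

#' Simulate a cohort of landmark, covariate and genotype data
#'
#' Per subject, true mode scores are drawn as
#' `z_k = offset_k + sum_j beta_jk g_j + e_k` with the residual SD set so
#' the total score SD is about 1; the landmark configuration is built in
#' the tangent hyperplane at the template as
#' `template + d` with `d = sum_k z_k sd_k mode_k` (so with zero landmark
#' noise the reference-model projection returns the drawn scores
#' exactly), then iid landmark noise and a random rigid + positive-scale
#' nuisance transform are applied. Fully reproducible from
#' `(config, seed)`.
#'
#' @param config a `sim_config`.
#' @param out_dir optional directory; when given, writes `landmarks.csv`
#'   (wide), `covariates.tsv`, `dosages.tsv`, `truth.tsv` and
#'   `reference_model.json`.
#' @return list of class `sim_cohort`: `landmarks` (`landmark_cohort`),
#'   `covariates`, `dosages` (with hard counts), `truth` (per-subject true
#'   scores, dosages and nuisance transform), `model` (the reference
#'   `shape_model`), `config`.
#' @export
simulate_cohort <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  model <- synth_reference_model(config)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(config$seed)
  out <- sim_cohort_draw(config, model)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  if (!is.null(out_dir)) write_sim_cohort(out, out_dir)
  out
}

# Core draw; assumes the RNG is already seeded. `genotypes` (snp x union
# ids) and `latent` (standard-normal, union ids x K) are supplied by the
# longitudinal wrapper; `latent_weight` is the per-mode covariance to be
# carried by the shared latent (must not exceed the residual variance).
sim_cohort_draw <- function(config, model, genotypes = NULL, latent = NULL,
                            latent_weight = 0) {
  n <- config$n; K <- config$K
  ids <- if (is.null(config$ids))
    sprintf("%s_%05d", config$timepoint, seq_len(n)) else config$ids
  # genotypes
  nsnp <- length(config$snps)
  snp_ids <- vapply(config$snps, `[[`, "", "snp_id")
  G <- matrix(0L, nsnp, n, dimnames = list(snp_ids, ids))
  counts <- matrix(0L, nsnp, 3L)
  for (j in seq_len(nsnp)) {
    if (!is.null(genotypes)) {
      G[j, ] <- genotypes[j, ids]
      counts[j, ] <- c(sum(G[j, ] == 0L), sum(G[j, ] == 1L),
                       sum(G[j, ] == 2L))
    } else {
      hw <- hwe_genotypes(n, config$snps[[j]]$eaf)
      G[j, ] <- hw$dosage
      counts[j, ] <- hw$counts
    }
  }
  # covariates
  cp <- covariate_params(config$timepoint)
  sex <- stats::rbinom(n, 1L, 1 - cp$p_female)   # 0 female / 1 male
  age <- stats::rnorm(n, cp$age[1L], cp$age[2L])
  hmu <- ifelse(sex == 0L, cp$height_f[1L], cp$height_m[1L])
  hsd <- ifelse(sex == 0L, cp$height_f[2L], cp$height_m[2L])
  wmu <- ifelse(sex == 0L, cp$weight_f[1L], cp$weight_m[1L])
  wsd <- ifelse(sex == 0L, cp$weight_f[2L], cp$weight_m[2L])
  height <- stats::rnorm(n, hmu, hsd)
  r_hw <- 0.5   # height-weight correlation
  weight <- wmu + r_hw * wsd / hsd * (height - hmu) +
    stats::rnorm(n, 0, sqrt(1 - r_hw^2) * wsd)
  weight <- pmax(weight, 25)
  if (!is.null(config$height_coupling)) {
    for (snp in names(config$height_coupling))
      height <- height + config$height_coupling[[snp]] * G[snp, ]
  }
  cov <- covariate_table(data.frame(
    id = ids, age = age, sex = sex, height_cm = height, weight_kg = weight,
    stringsAsFactors = FALSE))
  # true scores
  rsd <- residual_score_sds(config)
  e <- sweep(matrix(stats::rnorm(n * K), n, K), 2L, rsd, "*")
  if (!is.null(latent) && any(latent_weight > 0)) {
    w <- sqrt(pmin(pmax(latent_weight / rsd^2, 0), 1))
    e <- sweep(latent[ids, , drop = FALSE], 2L, rsd * w, "*") +
      sweep(e, 2L, sqrt(1 - w^2), "*")
  }
  z <- sweep(e, 2L, config$offsets, "+")
  for (j in seq_len(nsnp)) {
    ki <- as.integer(names(config$snps[[j]]$betas))
    z[, ki] <- z[, ki] +
      outer(G[j, ], config$snps[[j]]$betas)
  }
  # landmarks in the tangent hyperplane at the template: template + planted
  # displacement (modes are orthogonal to the similarity subspace, so the
  # tangent-coordinate projection recovers the displacement exactly)
  D <- sweep(z, 2L, config$mode_sds, "*") %*% t(model$modes)
  if (any(rowSums(D^2) >= 1))
    stop("planted displacement exceeds pre-shape scale")
  coords <- rep(1, n) %o% model$mean_shape + D
  if (config$noise_sd > 0)
    coords <- coords + matrix(stats::rnorm(length(coords),
                                           sd = config$noise_sd),
                              nrow(coords))
  theta <- stats::runif(n, -config$rot_deg, config$rot_deg) * pi / 180
  scl <- config$base_size *
    exp(stats::runif(n, -config$scale_frac, config$scale_frac))
  tx <- stats::runif(n, -config$trans, config$trans)
  ty <- stats::runif(n, -config$trans, config$trans)
  xi <- seq(1L, ncol(coords), by = 2L); yi <- xi + 1L
  x0 <- coords[, xi, drop = FALSE]; y0 <- coords[, yi, drop = FALSE]
  coords[, xi] <- scl * (cos(theta) * x0 - sin(theta) * y0) + tx
  coords[, yi] <- scl * (sin(theta) * x0 + cos(theta) * y0) + ty
  rownames(coords) <- ids
  landmarks <- unflatten_landmarks(coords)
  dos <- dosage_table(
    data.frame(snp_id = snp_ids,
               effect_allele = vapply(config$snps, `[[`, "", "effect_allele"),
               other_allele = vapply(config$snps, `[[`, "", "other_allele"),
               eaf = vapply(config$snps, `[[`, 0, "eaf"),
               stringsAsFactors = FALSE),
    `storage.mode<-`(G, "double"), counts)
  truth <- data.frame(id = ids, z, check.names = FALSE)
  names(truth)[1L + seq_len(K)] <- paste0("z", seq_len(K))
  for (j in seq_len(nsnp)) truth[[snp_ids[j]]] <- G[j, ]
  truth$theta <- theta; truth$scale <- scl; truth$tx <- tx; truth$ty <- ty
  structure(list(landmarks = landmarks, covariates = cov, dosages = dos,
                 truth = truth, model = model, config = config),
            class = "sim_cohort")
}

write_sim_cohort <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_landmarks(sim$landmarks, file.path(out_dir, "landmarks.csv"), "wide")
  write_covariates(sim$covariates, file.path(out_dir, "covariates.tsv"))
  write_dosages(sim$dosages, file.path(out_dir, "dosages.tsv"))
  utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  save_shape_model(sim$model, file.path(out_dir, "reference_model.json"))
  invisible(out_dir)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort>", x$config$timepoint, "- n =", x$config$n, "subjects,",
      length(x$config$snps), "planted SNPs, seed", x$config$seed, "\n")
  invisible(x)
}

#' Simulate two cohorts with overlapping subjects
#'
#' Overlapping subjects share their genotypes and a latent score
#' component: the cross-timepoint correlation of each mode's true scores
#' is `rho` (genetic sharing included). Non-overlapping subjects attend
#' only one clinic, emulating partial attendance.
#'
#' @param config_t1,config_t2 `sim_config`s for the two timepoints (their
#'   `n` are the per-timepoint sizes; both must share `K`, `mode_sds`,
#'   `basis_seed` and SNP panel).
#' @param rho shared-score fraction in \[0, 1\].
#' @param n_overlap number of subjects present at both timepoints.
#' @param seed master seed.
#' @return list with `t1`, `t2` (both `sim_cohort`) and `overlap_ids`.
#' @export
simulate_longitudinal <- function(config_t1, config_t2, rho = 0.6,
                                  n_overlap = 2618L, seed = 1L) {
  stopifnot(rho >= 0, rho <= 1,
            n_overlap <= config_t1$n, n_overlap <= config_t2$n,
            config_t1$K == config_t2$K,
            identical(config_t1$mode_sds, config_t2$mode_sds),
            config_t1$basis_seed == config_t2$basis_seed)
  K <- config_t1$K
  n_union <- config_t1$n + config_t2$n - n_overlap
  ids <- sprintf("subj_%05d", seq_len(n_union))
  both <- ids[seq_len(n_overlap)]
  only1 <- ids[n_overlap + seq_len(config_t1$n - n_overlap)]
  only2 <- setdiff(ids, c(both, only1))
  config_t1$ids <- c(both, only1)
  config_t2$ids <- c(both, only2)
  model <- synth_reference_model(config_t1)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  # genotypes for the union, reused by both cohorts
  nsnp <- length(config_t1$snps)
  G <- matrix(0L, nsnp, n_union,
              dimnames = list(vapply(config_t1$snps, `[[`, "", "snp_id"),
                              ids))
  for (j in seq_len(nsnp))
    G[j, ] <- hwe_genotypes(n_union, config_t1$snps[[j]]$eaf)$dosage
  # shared standard-normal latent per mode; its weight in the residual is
  # chosen so cor(z_t1, z_t2) = rho including the shared genetic part
  latent <- matrix(stats::rnorm(n_union * K), n_union, K,
                   dimnames = list(ids, NULL))
  gvar <- 1 - residual_score_sds(config_t1)^2
  lw <- pmax(rho - gvar, 0)   # covariance carried by the latent, per mode
  t1 <- sim_cohort_draw(config_t1, model, genotypes = G, latent = latent,
                        latent_weight = lw)
  t2 <- sim_cohort_draw(config_t2, model, genotypes = G, latent = latent,
                        latent_weight = lw)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  list(t1 = t1, t2 = t2, overlap_ids = both)
}
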