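# ---- landmark sets -----------------------------------------------------

#' Create a landmark configuration for one subject
#'
#' A landmark set is one subject's ordered planar landmark configuration,
#' e.g. the 53 points outlining the proximal femur on a hip DXA image.
#' Coordinates are treated as unitless planar values (pixels or mm);
#' Procrustes scaling later removes the unit.
#'
#' @param subject_id single character id.
#' @param points numeric matrix with one row per landmark and two columns
#'   (x, y). Point order is meaningful and preserved.
#' @return An object of class `landmark_set`: a list with elements
#'   `subject_id` and `points`.
#' @examples
#' s <- landmark_set("s1", cbind(1:53, sin(1:53)))
#' centroid_size(s)
#' @export
landmark_set <- function(subject_id, points) {
  if (length(subject_id) != 1L || is.na(subject_id) || !nzchar(subject_id))
    stop("subject_id must be a single non-empty string")
  points <- as.matrix(points)
  if (ncol(points) != 2L)
    stop("points must have two columns (x, y) [subject ", subject_id, "]")
  storage.mode(points) <- "double"
  if (!all(is.finite(points)))
    stop("non-finite coordinate for subject ", subject_id)
  dimnames(points) <- list(NULL, c("x", "y"))
  obj <- structure(list(subject_id = as.character(subject_id), points = points),
                   class = "landmark_set")
  if (centroid_size(obj) <= 0)
    stop("degenerate (all-coincident) configuration for subject ", subject_id)
  obj
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> subject", x$subject_id, "with", nrow(x$points),
      "points, centroid size", format(centroid_size(x)), "\n")
  invisible(x)
}

#' Bundle landmark sets into a cohort
#'
#' @param sets list of [landmark_set()] objects, all with the same number
#'   of points and distinct subject ids.
#' @return A `landmark_cohort`: a named list of landmark sets with an
#'   `n_points` attribute.
#' @export
landmark_cohort <- function(sets) {
  if (!length(sets)) stop("empty cohort")
  if (!all(vapply(sets, inherits, logical(1), "landmark_set")))
    stop("all elements must be landmark_set objects")
  np <- vapply(sets, function(s) nrow(s$points), integer(1))
  if (length(unique(np)) != 1L)
    stop("inconsistent point counts across subjects: ",
         paste(unique(np), collapse = ", "))
  ids <- vapply(sets, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids))
    stop("duplicate subject ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(sets) <- ids
  structure(sets, n_points = np[[1L]], class = "landmark_cohort")
}

#' @export
print.landmark_cohort <- function(x, ...) {
  cat("<landmark_cohort>", length(x), "subjects x", attr(x, "n_points"),
      "points\n")
  invisible(x)
}

#' @export
`[.landmark_cohort` <- function(x, i) {
  landmark_cohort(unclass(x)[i])
}

#' Subject ids of a landmark cohort
#' @param cohort a `landmark_cohort`.
#' @return character vector of subject ids.
#' @export
cohort_ids <- function(cohort) names(cohort)

#' Flatten a cohort to a coordinate matrix
#'
#' Rows are subjects, columns are interleaved coordinates
#' (x1, y1, x2, y2, ...). This is the layout used throughout the
#' Procrustes and shape-model code.
#'
#' @param cohort a `landmark_cohort`.
#' @return numeric matrix, n subjects x 2*n_points, rownames = subject ids.
#' @export
flatten_landmarks <- function(cohort) {
  stopifnot(inherits(cohort, "landmark_cohort"))
  m <- t(vapply(cohort, function(s) as.vector(t(s$points)),
                numeric(2L * attr(cohort, "n_points"))))
  rownames(m) <- names(cohort)
  m
}

#' Rebuild a cohort from a flat coordinate matrix
#' @param m matrix as produced by [flatten_landmarks()].
#' @return a `landmark_cohort`.
#' @export
unflatten_landmarks <- function(m) {
  stopifnot(is.matrix(m), ncol(m) %% 2L == 0L, !is.null(rownames(m)))
  landmark_cohort(lapply(rownames(m), function(id)
    landmark_set(id, vec_to_points(m[id, ]))))
}

vec_to_points <- function(v) {
  matrix(v, ncol = 2L, byrow = TRUE, dimnames = list(NULL, c("x", "y")))
}

# ---- landmark file formats --------------------------------------------

#' Read landmark configurations from disk
#'
#' Two dialects are supported. `wide`: a CSV with header
#' `id,x1,y1,...,xP,yP`, one row per subject. `long`: a TSV with columns
#' `subject`, `point_index` (1-based), `x`, `y`.
#'
#' @param path file path.
#' @param dialect `"wide"` or `"long"`.
#' @param n_points expected number of points per subject (default 53; any
#'   subject deviating from the per-file count is a hard error).
#' @return a `landmark_cohort`.
#' @export
read_landmarks <- function(path, dialect = c("wide", "long"), n_points = 53L) {
  dialect <- match.arg(dialect)
  if (dialect == "wide") {
    df <- utils::read.csv(path, check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
    if (ncol(df) != 2L * n_points + 1L)
      stop("expected ", 2L * n_points + 1L, " columns (id + ", n_points,
           " xy pairs), found ", ncol(df), " in ", path)
    ids <- as.character(df[[1L]])
    coords <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(coords)) {
      bad <- which(!vapply(df[-1L], is.numeric, logical(1)))[1L]
      stop("non-numeric coordinate in column ", names(df)[bad + 1L],
           " of ", path)
    }
    sets <- lapply(seq_along(ids), function(i) {
      if (anyNA(coords[i, ]))
        stop("non-numeric/missing coordinate in row ", i, " of ", path)
      landmark_set(ids[i], vec_to_points(coords[i, ]))
    })
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("subject", "point_index", "x", "y")
    if (!all(need %in% names(df)))
      stop("long dialect needs columns ", paste(need, collapse = ", "))
    if (!is.numeric(df$x) || !is.numeric(df$y)) {
      bad <- which(is.na(suppressWarnings(as.numeric(df$x))) |
                   is.na(suppressWarnings(as.numeric(df$y))))[1L]
      stop("non-numeric coordinate at row ", bad, " of ", path)
    }
    sets <- lapply(split(df, factor(df$subject, levels = unique(df$subject))),
                   function(d) {
      d <- d[order(d$point_index), , drop = FALSE]
      if (nrow(d) != n_points ||
          !identical(as.integer(d$point_index), seq_len(n_points)))
        stop("subject ", d$subject[1L], " has ", nrow(d),
             " points, expected ", n_points)
      landmark_set(d$subject[1L], cbind(d$x, d$y))
    })
  }
  landmark_cohort(unname(sets))
}

#' Write landmark configurations to disk
#'
#' Full-precision decimal representation is used so that
#' `read_landmarks(write_landmarks(x))` is bit-identical.
#'
#' @param cohort a `landmark_cohort`.
#' @param path output file.
#' @param dialect `"wide"` (CSV) or `"long"` (TSV).
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(cohort, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  np <- attr(cohort, "n_points")
  if (dialect == "wide") {
    m <- flatten_landmarks(cohort)
    hdr <- paste0(c("id", paste0(rep(c("x", "y"), np),
                                 rep(seq_len(np), each = 2L))),
                  collapse = ",")
    rows <- vapply(seq_len(nrow(m)), function(i)
      paste(c(rownames(m)[i], num_full(m[i, ])), collapse = ","),
      character(1))
    writeLines(c(hdr, rows), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("subject\tpoint_index\tx\ty", con)
    for (s in cohort) {
      writeLines(paste(s$subject_id, seq_len(np),
                       num_full(s$points[, 1L]), num_full(s$points[, 2L]),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

# full round-trip decimal representation of doubles
num_full <- function(x) formatC(x, digits = 17, format = "g")

# ---- covariates --------------------------------------------------------

#' Read a covariate table
#'
#' Expected TSV columns: `id`, `age` (years), `sex` (0 = female, 1 = male),
#' `height_cm`, `weight_kg` and optionally `bmi`. If `bmi` is absent it is
#' derived as `weight_kg / (height_cm/100)^2`; if present it must agree
#' with the derived value within 0.1 kg/m^2.
#'
#' @param path TSV file.
#' @return data.frame with the columns above, class `covariate_table`.
#' @export
read_covariates <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  covariate_table(df)
}

#' Validate/construct a covariate table
#' @param df data.frame with columns id, age, sex, height_cm, weight_kg
#'   and optionally bmi.
#' @return validated data.frame of class `covariate_table`.
#' @export
covariate_table <- function(df) {
  need <- c("id", "age", "sex", "height_cm", "weight_kg")
  if (!all(need %in% names(df)))
    stop("covariate table needs columns ", paste(need, collapse = ", "))
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) stop("duplicate subject ids in covariates")
  if (!all(df$sex %in% c(0, 1, NA)))
    stop("sex must be coded 0 (female) / 1 (male)")
  derived <- df$weight_kg / (df$height_cm / 100)^2
  if (is.null(df$bmi)) {
    df$bmi <- derived
  } else {
    ok <- is.na(df$bmi) | is.na(derived) | abs(df$bmi - derived) <= 0.1
    if (!all(ok))
      stop("bmi inconsistent with height/weight for subject(s) ",
           paste(df$id[!ok], collapse = ", "))
  }
  num <- c("age", "height_cm", "weight_kg", "bmi")
  neg <- vapply(df[num], function(v) any(v < 0, na.rm = TRUE), logical(1))
  if (any(neg)) stop("negative values in ", paste(num[neg], collapse = ", "))
  class(df) <- c("covariate_table", "data.frame")
  df
}

#' Write a covariate table
#' @param cov a `covariate_table`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(cov, path) {
  utils::write.table(as.data.frame(cov), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- genotype dosages --------------------------------------------------

#' Construct a genotype dosage table
#'
#' Per-SNP effect-allele dosages in \[0, 2\] (expected count of the effect
#' allele under imputation, or the hard genotype count). Optional hard
#' genotype counts enable the exact Hardy-Weinberg test; dosage-only SNPs
#' skip that test with a warning at QC time.
#'
#' @param info data.frame with columns `snp_id`, `effect_allele`,
#'   `other_allele` and optionally `eaf` (declared effect-allele frequency).
#' @param dosage numeric matrix, SNPs x subjects, values in \[0, 2\] or NA
#'   for missing calls; rownames = snp ids, colnames = subject ids.
#' @param counts optional matrix (SNPs x 3, columns `n_AA`, `n_Aa`, `n_aa`)
#'   of hard genotype counts, `aa` meaning homozygous for the effect allele.
#' @return object of class `dosage_table` with elements `info` (including a
#'   recomputed `eaf_observed = mean(dosage)/2`), `dosage`, `counts`.
#' @export
dosage_table <- function(info, dosage, counts = NULL) {
  stopifnot(is.data.frame(info), is.matrix(dosage))
  need <- c("snp_id", "effect_allele", "other_allele")
  if (!all(need %in% names(info)))
    stop("info needs columns ", paste(need, collapse = ", "))
  if (nrow(info) != nrow(dosage)) stop("info/dosage row mismatch")
  if (is.null(colnames(dosage))) stop("dosage matrix needs subject colnames")
  rownames(dosage) <- info$snp_id
  if (nrow(dosage) && any(!is.na(dosage))) {
    rng <- range(dosage, na.rm = TRUE)
    if (rng[1L] < 0 || rng[2L] > 2)
      stop("dosage outside [0, 2]: range ", rng[1L], " .. ", rng[2L])
  }
  info$eaf_observed <- rowMeans(dosage, na.rm = TRUE) / 2
  if (is.null(info$eaf)) info$eaf <- info$eaf_observed
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    colnames(counts) <- c("n_AA", "n_Aa", "n_aa")
    rownames(counts) <- info$snp_id
    called <- rowSums(!is.na(dosage))
    if (!all(rowSums(counts) == called))
      stop("hard genotype counts do not sum to number of called subjects")
  }
  structure(list(info = info, dosage = dosage, counts = counts),
            class = "dosage_table")
}

#' @export
print.dosage_table <- function(x, ...) {
  cat("<dosage_table>", nrow(x$dosage), "SNPs x", ncol(x$dosage),
      "subjects", if (!is.null(x$counts)) "(hard counts available)", "\n")
  invisible(x)
}

#' Flip the effect allele of SNPs in a dosage table
#'
#' Swaps effect/other allele and replaces every dosage d by 2 - d (an
#' involution: flipping twice restores the original exactly). Hard counts
#' are reversed accordingly.
#'
#' @param gt a `dosage_table`.
#' @param snp_ids SNPs to flip (default: all).
#' @return the modified `dosage_table`.
#' @export
flip_effect_allele <- function(gt, snp_ids = gt$info$snp_id) {
  i <- match(snp_ids, gt$info$snp_id)
  if (anyNA(i)) stop("unknown snp id(s): ",
                     paste(snp_ids[is.na(i)], collapse = ", "))
  ea <- gt$info$effect_allele[i]
  gt$info$effect_allele[i] <- gt$info$other_allele[i]
  gt$info$other_allele[i] <- ea
  gt$dosage[i, ] <- 2 - gt$dosage[i, ]
  gt$info$eaf_observed[i] <- 1 - gt$info$eaf_observed[i]
  gt$info$eaf[i] <- 1 - gt$info$eaf[i]
  if (!is.null(gt$counts)) gt$counts[i, ] <- gt$counts[i, c(3L, 2L, 1L)]
  gt
}

#' Read genotype dosages
#'
#' `tsv`: columns `snp_id`, `effect_allele`, `other_allele`, then one
#' dosage column per subject (NA = missing call). `vcf`: dosages are taken
#' from the `DS` FORMAT field when present, otherwise computed from `GT`
#' as the count of ALT alleles. By default the effect allele is ALT; if
#' `effect_alleles` maps a variant to its REF allele the dosage is flipped
#' to `2 - d`. An effect allele matching neither REF nor ALT is an error.
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @param effect_alleles optional named character vector (names = variant
#'   ids) choosing the effect allele for VCF input.
#' @return a `dosage_table`.
#' @export
read_dosages <- function(path, format = c("tsv", "vcf"),
                         effect_alleles = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    need <- c("snp_id", "effect_allele", "other_allele")
    if (!all(need %in% names(df)))
      stop("dosage TSV needs columns ", paste(need, collapse = ", "))
    meta_cols <- intersect(c(need, "eaf"), names(df))
    info <- df[meta_cols]
    dos <- as.matrix(df[setdiff(names(df), meta_cols)])
    storage.mode(dos) <- "double"
    return(dosage_table(info, dos))
  }
  read_dosages_vcf(path, effect_alleles)
}

read_dosages_vcf <- function(path, effect_alleles = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  ids <- rownames(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- vapply(as.list(VariantAnnotation::alt(vcf)),
                function(a) as.character(a)[1L], character(1))
  g <- VariantAnnotation::geno(vcf)
  # a FORMAT can be declared in the header yet absent from the records
  has_ds <- "DS" %in% names(g) && !all(is.na(g$DS))
  if (has_ds) {
    dos <- g$DS
    storage.mode(dos) <- "double"
  } else if ("GT" %in% names(g)) {
    gt <- g$GT
    dos <- apply(gt, c(1L, 2L), function(s) {
      if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_real_)
      sum(strsplit(s, "[/|]")[[1L]] == "1")
    })
  } else stop("VCF has neither DS nor GT FORMAT fields")
  rng <- range(dos, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 2)
    stop("dosage outside [0, 2] in VCF ", path)
  ea <- alt
  oa <- ref
  flip <- rep(FALSE, length(ids))
  if (!is.null(effect_alleles)) {
    sel <- intersect(names(effect_alleles), ids)
    for (v in sel) {
      i <- match(v, ids)
      want <- effect_alleles[[v]]
      if (want == alt[i]) {
        # already effect = ALT
      } else if (want == ref[i]) {
        flip[i] <- TRUE
        ea[i] <- ref[i]; oa[i] <- alt[i]
      } else stop("effect allele ", want, " for ", v,
                  " matches neither REF (", ref[i], ") nor ALT (",
                  alt[i], ")")
    }
  }
  dos[flip, ] <- 2 - dos[flip, , drop = FALSE]
  info <- data.frame(snp_id = ids, effect_allele = ea, other_allele = oa,
                     stringsAsFactors = FALSE)
  dosage_table(info, dos)
}

#' Write a dosage table as TSV
#' @param gt a `dosage_table`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_dosages <- function(gt, path) {
  df <- cbind(gt$info[c("snp_id", "effect_allele", "other_allele", "eaf")],
              as.data.frame(gt$dosage, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- cohort assembly ---------------------------------------------------

#' Assemble a complete-case cohort dataset
#'
#' Inner-joins landmark, covariate and genotype data on subject id and
#' keeps only subjects present (and complete) in all three; analysis
#' downstream is complete-case only. Never invents subjects: the joined
#' size is at most the smallest component.
#'
#' @param landmarks a `landmark_cohort`.
#' @param covariates a `covariate_table`.
#' @param dosages a `dosage_table`.
#' @param timepoint label, e.g. `"age14"`.
#' @return list of class `cohort_dataset` with aligned components.
#' @export
assemble_cohort <- function(landmarks, covariates, dosages,
                            timepoint = "cohort") {
  ids <- Reduce(intersect, list(cohort_ids(landmarks), covariates$id,
                                colnames(dosages$dosage)))
  cov <- covariates[match(ids, covariates$id), , drop = FALSE]
  complete <- stats::complete.cases(
    cov[c("age", "sex", "height_cm", "weight_kg", "bmi")])
  ids <- ids[complete]
  if (!length(ids)) stop("no complete-case subjects after join")
  structure(list(
    landmarks = landmarks[ids],
    covariates = covariates[match(ids, covariates$id), , drop = FALSE],
    dosages = dosage_table(
      gt_info_strip(dosages$info),
      dosages$dosage[, ids, drop = FALSE]),
    timepoint = timepoint,
    ids = ids), class = "cohort_dataset")
}

# drop derived columns so dosage_table() recomputes them on the subset
gt_info_strip <- function(info) {
  info[setdiff(names(info), "eaf_observed")]
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("<cohort_dataset>", x$timepoint, "-", length(x$ids),
      "complete-case subjects,", nrow(x$dosages$dosage), "SNPs\n")
  invisible(x)
}
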