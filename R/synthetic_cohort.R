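# Synthetic multimodal aging-cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: a
# plasma analyte panel organized into correlated biological blocks driven by
# independent Gaussian latents, a "hallmark" latent (CSF-like amyloid/tau
# analytes plus an ordinal APOE-like allele count), demographics, bilateral
# brain region measures with left/right and measure-type correlation
# structure, diagnosis trajectories on a 6-month visit grid with
# hallmark-driven progression hazard, and hallmark-driven cognitive decline
# and atrophy summaries.

#' Specification of a synthetic cohort
#'
#' @param n_subjects Number of subjects (default 800).
#' @param n_plasma_blocks Number of correlated plasma analyte blocks.
#' @param block_sizes Integer vector of analytes per block.
#' @param block_loading Loading of each block's shared latent, in `[0,1]`
#'   (scalar recycled); within-block pairwise correlation is loading squared.
#' @param n_noise_analytes Independent plasma analytes outside any block.
#' @param n_roi_pairs Bilateral brain region pairs; each yields left/right
#'   thickness, surface area and volume (6 measures per pair).
#' @param hallmark_effect Standardized effect of the hallmark latent on the
#'   progression hazard (log-odds per SD), cognitive decline and atrophy.
#' @param hallmark_loading Loading of the CSF-like hallmark analytes on the
#'   hallmark latent (default 0.8).
#' @param followup_months_mean Mean follow-up duration in months; individual
#'   follow-up lies on a 6-month grid between 6 and 60 months.
#' @param reversion_rate Probability that a stable baseline-MCI subject is
#'   turned into a diagnostic reverter (an interim CN visit).
#' @param missing_rate Optional MCAR missingness rate for the feature panel
#'   (default 0: complete data).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 800L,
                        n_plasma_blocks = 20L,
                        block_sizes = rep(8L, n_plasma_blocks),
                        block_loading = rep(0.7, n_plasma_blocks),
                        n_noise_analytes = 40L,
                        n_roi_pairs = 25L,
                        hallmark_effect = 0.5,
                        hallmark_loading = 0.8,
                        followup_months_mean = 36,
                        reversion_rate = 0.02,
                        missing_rate = 0,
                        seed = 1L) {
  if (length(block_loading) == 1) block_loading <- rep(block_loading, n_plasma_blocks)
  if (length(block_sizes) == 1) block_sizes <- rep(block_sizes, n_plasma_blocks)
  spec <- list(n_subjects = as.integer(n_subjects),
               n_plasma_blocks = as.integer(n_plasma_blocks),
               block_sizes = as.integer(block_sizes),
               block_loading = as.numeric(block_loading),
               n_noise_analytes = as.integer(n_noise_analytes),
               n_roi_pairs = as.integer(n_roi_pairs),
               hallmark_effect = as.numeric(hallmark_effect),
               hallmark_loading = as.numeric(hallmark_loading),
               followup_months_mean = as.numeric(followup_months_mean),
               reversion_rate = as.numeric(reversion_rate),
               missing_rate = as.numeric(missing_rate),
               seed = as.integer(seed))
  with(spec, {
    if (n_subjects < 1 || n_plasma_blocks < 1 || n_roi_pairs < 1) {
      stop("counts must be positive")
    }
    if (n_noise_analytes < 0) stop("n_noise_analytes must be non-negative")
    if (length(block_sizes) != n_plasma_blocks) stop("block_sizes length mismatch")
    if (length(block_loading) != n_plasma_blocks) stop("block_loading length mismatch")
    if (any(block_sizes < 1)) stop("block sizes must be positive")
    if (any(block_loading < 0 | block_loading > 1)) stop("block_loading must lie in [0,1]")
    if (hallmark_loading < 0 || hallmark_loading > 1) stop("hallmark_loading must lie in [0,1]")
    if (reversion_rate < 0 || reversion_rate > 1) stop("reversion_rate must lie in [0,1]")
    if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must lie in [0,1]")
  })
  class(spec) <- "cohort_spec"
  spec
}

#' Generate a synthetic multimodal cohort
#'
#' @param spec A `cohort_spec`.
#' @return An object of class `synthetic_cohort`: `features` (a
#'   `feature_table` of hallmark + plasma + demographic + brain measures),
#'   `diagnoses` (a `diagnostic_ledger` of per-visit diagnoses), `outcomes`
#'   (data.frame of cognitive test totals at baseline/follow-up and the two
#'   signed TBM percent-change summaries), and `truth` (planted hallmark and
#'   block latents, block membership per analyte, progression indicator).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  set.seed(spec$seed)
  n <- spec$n_subjects
  eff <- spec$hallmark_effect
  subjects <- sprintf("S%04d", seq_len(n))

  ## hallmark latent and hallmark block (3 CSF-like analytes + APOE-like count)
  z_hall <- stats::rnorm(n)
  lam <- spec$hallmark_loading
  noise_sd <- sqrt(1 - lam^2)
  csf_abeta42 <- -lam * z_hall + noise_sd * stats::rnorm(n)  # low amyloid = pathology
  csf_tau <- lam * z_hall + noise_sd * stats::rnorm(n)
  csf_ptau <- lam * z_hall + noise_sd * stats::rnorm(n)
  apoe_latent <- lam * z_hall + noise_sd * stats::rnorm(n)
  apoe4 <- (apoe_latent > stats::qnorm(0.70)) + (apoe_latent > stats::qnorm(0.95))
  hallmark <- cbind(csf_abeta42 = csf_abeta42, csf_tau = csf_tau,
                    csf_ptau = csf_ptau, apoe4 = as.numeric(apoe4))

  ## plasma blocks
  B <- spec$n_plasma_blocks
  z_blocks <- matrix(stats::rnorm(n * B), n, B,
                     dimnames = list(subjects, sprintf("block%02d", seq_len(B))))
  plasma_cols <- list()
  membership <- character(0)
  for (b in seq_len(B)) {
    lb <- spec$block_loading[b]
    m <- spec$block_sizes[b]
    block <- lb * z_blocks[, b] + sqrt(1 - lb^2) * matrix(stats::rnorm(n * m), n, m)
    colnames(block) <- sprintf("plasma_b%02d_%02d", b, seq_len(m))
    plasma_cols[[b]] <- block
    membership <- c(membership,
                    stats::setNames(rep(sprintf("block%02d", b), m), colnames(block)))
  }
  plasma <- do.call(cbind, plasma_cols)
  if (spec$n_noise_analytes > 0) {
    noise <- matrix(stats::rnorm(n * spec$n_noise_analytes), n, spec$n_noise_analytes)
    colnames(noise) <- sprintf("plasma_noise_%02d", seq_len(spec$n_noise_analytes))
    plasma <- cbind(plasma, noise)
  }

  ## demographics
  age <- stats::rnorm(n, 75.3, 6.9)
  sex <- stats::rbinom(n, 1, 0.58)                   # 1 = male
  education <- pmin(pmax(round(stats::rnorm(n, 15.5, 3)), 6), 20)
  icv <- stats::rnorm(n, 1500, 110) + 110 * (sex - 0.58)
  weight <- stats::rnorm(n, 75, 12) + 10 * (sex - 0.58)
  demo <- cbind(age = age, sex = sex, education = education, icv = icv,
                weight = weight)
  age_z <- (age - 75.3) / 6.9
  icv_z <- (icv - mean(icv)) / stats::sd(icv)

  ## bilateral brain region measures
  lr_corr <- max(c(0.8, spec$block_loading))
  lam_side <- sqrt(lr_corr)
  brain_cols <- list()
  brain_tags <- character(0)
  n_temporal <- min(5L, spec$n_roi_pairs)
  for (r in seq_len(spec$n_roi_pairs)) {
    w_vol <- stats::rnorm(n)
    w_thk <- 0.4 * w_vol + sqrt(1 - 0.16) * stats::rnorm(n)
    disease <- if (r <= n_temporal) -0.25 * eff * z_hall else 0
    for (side in c("L", "R")) {
      s_vol <- lam_side * w_vol + sqrt(1 - lr_corr) * stats::rnorm(n)
      s_thk <- lam_side * w_thk + sqrt(1 - lr_corr) * stats::rnorm(n)
      thick <- 2.5 + 0.25 * (0.85 * s_thk - 0.30 * age_z + disease +
                               0.45 * stats::rnorm(n))
      area <- 2500 + 400 * (0.80 * s_vol - 0.15 * age_z + 0.40 * icv_z +
                              0.20 * (sex - 0.58) + 0.40 * stats::rnorm(n))
      vol <- 4000 + 600 * (0.80 * s_vol - 0.30 * age_z + 0.40 * icv_z +
                             0.20 * (sex - 0.58) + disease + 0.40 * stats::rnorm(n))
      nm <- sprintf("roi%02d_%s", r, side)
      brain_cols[[length(brain_cols) + 1]] <-
        cbind(stats::setNames(data.frame(thick, area, vol),
                              paste0(nm, c("_thickness", "_area", "_volume"))))
      brain_tags <- c(brain_tags, "brain_thickness", "brain_area", "brain_volume")
    }
  }
  brain <- as.matrix(do.call(cbind, brain_cols))

  ## baseline diagnosis coupled to the hallmark latent
  dx_score <- 1.2 * eff * z_hall + stats::rlogis(n)
  cuts <- stats::quantile(dx_score, c(0.28, 0.76))
  baseline_dx <- cut(dx_score, c(-Inf, cuts, Inf), labels = c("CN", "MCI", "AD"))
  baseline_dx <- as.character(baseline_dx)

  ## follow-up duration on a 6-month grid, and progression
  dur <- stats::rgamma(n, shape = (spec$followup_months_mean / 14)^2,
                       scale = 14^2 / spec$followup_months_mean)
  followup <- pmin(pmax(6 * round(dur / 6), 6), 60)
  base_py <- c(CN = 0.03, MCI = 0.18, AD = 0)[baseline_dx]
  p_year <- ifelse(baseline_dx == "AD", 0,
                   stats::plogis(stats::qlogis(pmax(base_py, 1e-6)) + eff * z_hall))
  p_visit <- 1 - (1 - p_year)^0.5
  visits <- vector("list", n)
  progressed <- logical(n)
  for (i in seq_len(n)) {
    months <- seq(0, followup[i], by = 6)
    dx <- rep(baseline_dx[i], length(months))
    if (baseline_dx[i] != "AD") {
      conv <- stats::runif(length(months) - 1) < p_visit[i]
      if (any(conv)) {
        first <- which(conv)[1] + 1
        dx[first:length(dx)] <- "AD"
        progressed[i] <- TRUE
      }
    }
    visits[[i]] <- data.frame(subject = subjects[i], visit_month = months,
                              diagnosis = dx, stringsAsFactors = FALSE)
  }

  ## inject reverters among stable baseline-MCI subjects
  candidates <- which(baseline_dx == "MCI" & !progressed &
                        vapply(visits, nrow, integer(1)) >= 3)
  if (length(candidates) && spec$reversion_rate > 0) {
    revert <- candidates[stats::runif(length(candidates)) < spec$reversion_rate]
    for (i in revert) {
      mid <- ceiling(nrow(visits[[i]]) / 2)
      visits[[i]]$diagnosis[mid] <- "CN"
    }
  }
  ledger <- diagnostic_ledger(do.call(rbind, visits))

  ## cognition: baseline totals on each test's native scale, decline driven
  ## by the hallmark latent
  means <- list(
    mmse = c(CN = 29.1, MCI = 27.0, AD = 23.3),
    adas13 = c(CN = 9.5, MCI = 18.6, AD = 29.0),
    cdr_sob = c(CN = 0.15, MCI = 1.6, AD = 4.4))
  sds <- list(mmse = c(CN = 1.0, MCI = 1.8, AD = 2.05),
              adas13 = c(CN = 4.1, MCI = 6.3, AD = 7.6),
              cdr_sob = c(CN = 0.25, MCI = 0.9, AD = 1.6))
  draw <- function(test, lo, hi) {
    pmin(pmax(stats::rnorm(n, means[[test]][baseline_dx], sds[[test]][baseline_dx]),
              lo), hi)
  }
  mmse_bl <- round(draw("mmse", 0, 30))
  adas13_bl <- round(draw("adas13", 0, 85), 1)
  cdr_bl <- pmax(round(draw("cdr_sob", 0, 18) * 2) / 2, 0)
  ## decline scales are calibrated so the hallmark association with the
  ## 1-year composite delta is weak but clearly detectable at cohort size
  ## (|r| ~ 0.1-0.15 at a standardized effect of 0.5), as in observational
  ## aging cohorts where baseline biology explains only a small share of
  ## short-term cognitive change
  decline <- eff * z_hall
  mmse_fu <- pmin(pmax(round(mmse_bl - 0.3 * decline - 0.3 * progressed +
                               stats::rnorm(n, 0, 1.5)), 0), 30)
  adas13_fu <- pmin(pmax(round(adas13_bl + 0.7 * decline + 0.8 * progressed +
                                 stats::rnorm(n, 0, 3.5), 1), 0), 85)
  cdr_fu <- pmin(pmax(round((cdr_bl + 0.22 * decline + 0.3 * progressed +
                               stats::rnorm(n, 0, 0.8)) * 2) / 2, 0), 18)

  ## TBM summaries: temporal-lobe loss (negative), ventricular expansion
  ## (positive), both stronger with hallmark pathology and progression
  tbm_temporal <- -1.0 - 0.5 * eff * z_hall - 1.0 * (progressed | baseline_dx == "AD") +
    stats::rnorm(n, 0, 2.0)
  tbm_ventricle <- 1.5 + 0.6 * eff * z_hall + 1.2 * (progressed | baseline_dx == "AD") +
    stats::rnorm(n, 0, 2.2)

  features_mat <- cbind(hallmark, plasma, demo, brain)
  rownames(features_mat) <- subjects
  classes <- c(rep("hallmark", ncol(hallmark)),
               rep("plasma", ncol(plasma)),
               rep("demographic", ncol(demo)),
               brain_tags)
  names(classes) <- colnames(features_mat)
  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(length(features_mat)) < spec$missing_rate,
                   nrow(features_mat))
    features_mat[mask] <- NA
  }
  features <- feature_table(features_mat, classes)

  outcomes <- data.frame(
    subject = subjects,
    mmse_baseline = mmse_bl, mmse_followup = mmse_fu,
    adas13_baseline = adas13_bl, adas13_followup = adas13_fu,
    cdr_sob_baseline = cdr_bl, cdr_sob_followup = cdr_fu,
    tbm_temporal = tbm_temporal, tbm_ventricle = tbm_ventricle,
    stringsAsFactors = FALSE)

  structure(list(
    features = features,
    diagnoses = ledger,
    outcomes = outcomes,
    truth = list(z_hallmark = stats::setNames(z_hall, subjects),
                 z_blocks = z_blocks,
                 block_membership = membership,
                 baseline_dx = stats::setNames(baseline_dx, subjects),
                 progressed = stats::setNames(progressed, subjects)),
    spec = spec
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d features, %d visits\n",
              nrow(ft_data(x$features)), ncol(ft_data(x$features)),
              nrow(x$diagnoses)))
  invisible(x)
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else formatC(v, digits = 17, format = "g")
  }, character(1))
  out
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Writes `features.csv` (subjects x features, first column the subject ID),
#' `diagnoses.csv` (long format subject / visit_month / diagnosis),
#' `outcomes.csv`, and `truth.json` (planted latents, block membership, and
#' the per-feature class tags). Numeric values are written with 17
#' significant digits so the files round-trip bit-identically through
#' [read_cohort()].
#'
#' @param cohort A `synthetic_cohort`.
#' @param directory Output directory (created if absent).
#' @param force Overwrite an existing non-empty directory (default `FALSE`).
#' @return `directory`, invisibly.
#' @export
write_cohort <- function(cohort, directory, force = FALSE) {
  if (dir.exists(directory)) {
    if (length(list.files(directory)) && !force) {
      stop("directory ", directory, " is not empty; use force = TRUE to overwrite")
    }
  } else {
    dir.create(directory, recursive = TRUE)
  }
  fm <- ft_data(cohort$features)
  fdf <- data.frame(subject = rownames(fm),
                    apply(fm, 2, fmt_num),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(fdf, file.path(directory, "features.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$diagnoses, file.path(directory, "diagnoses.csv"),
                   row.names = FALSE, quote = FALSE)
  odf <- cohort$outcomes
  odf[-1] <- lapply(odf[-1], fmt_num)
  utils::write.csv(odf, file.path(directory, "outcomes.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- list(
    feature_classes = as.list(ft_classes(cohort$features)),
    z_hallmark = as.list(cohort$truth$z_hallmark),
    z_blocks = cohort$truth$z_blocks,
    block_membership = as.list(cohort$truth$block_membership),
    baseline_dx = as.list(cohort$truth$baseline_dx),
    progressed = as.list(cohort$truth$progressed),
    spec = unclass(cohort$spec))
  # I(17): 17 significant digits, enough for doubles to round-trip exactly
  jsonlite::write_json(truth, file.path(directory, "truth.json"),
                       digits = I(17), auto_unbox = TRUE)
  invisible(directory)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory Directory containing `features.csv`, `diagnoses.csv`,
#'   `outcomes.csv`, `truth.json`.
#' @return A `synthetic_cohort`.
#' @export
read_cohort <- function(directory) {
  fdf <- utils::read.csv(file.path(directory, "features.csv"),
                         check.names = FALSE, stringsAsFactors = FALSE)
  truth <- jsonlite::read_json(file.path(directory, "truth.json"),
                               simplifyVector = TRUE)
  fm <- as.matrix(fdf[, -1, drop = FALSE])
  storage.mode(fm) <- "double"
  rownames(fm) <- fdf$subject
  classes <- unlist(truth$feature_classes)
  features <- feature_table(fm, classes[colnames(fm)])
  ledger <- diagnostic_ledger(utils::read.csv(file.path(directory, "diagnoses.csv"),
                                              stringsAsFactors = FALSE))
  outcomes <- utils::read.csv(file.path(directory, "outcomes.csv"),
                              stringsAsFactors = FALSE)
  spec <- truth$spec
  spec <- cohort_spec(n_subjects = spec$n_subjects,
                      n_plasma_blocks = spec$n_plasma_blocks,
                      block_sizes = spec$block_sizes,
                      block_loading = spec$block_loading,
                      n_noise_analytes = spec$n_noise_analytes,
                      n_roi_pairs = spec$n_roi_pairs,
                      hallmark_effect = spec$hallmark_effect,
                      hallmark_loading = spec$hallmark_loading,
                      followup_months_mean = spec$followup_months_mean,
                      reversion_rate = spec$reversion_rate,
                      missing_rate = spec$missing_rate,
                      seed = spec$seed)
  structure(list(
    features = features,
    diagnoses = ledger,
    outcomes = outcomes,
    truth = list(z_hallmark = unlist(truth$z_hallmark),
                 z_blocks = truth$z_blocks,
                 block_membership = unlist(truth$block_membership),
                 baseline_dx = unlist(truth$baseline_dx),
                 progressed = unlist(truth$progressed),
                 feature_classes = classes),
    spec = spec
  ), class = "synthetic_cohort")
}
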