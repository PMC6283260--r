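#' Regress nuisance covariates out of brain measures
#'
#' Each brain feature is residualized by ordinary least squares on age, sex
#' and education; surface-area and volume features are additionally adjusted
#' for intra-cranial volume (ICV). Thickness features are never adjusted for
#' ICV. Returns the residuals with the original class tags.
#'
#' @param brain A `feature_table` of `brain_thickness` / `brain_area` /
#'   `brain_volume` features.
#' @param covariates A data.frame (or `feature_table`) with columns `age`,
#'   `sex`, `education`, `icv`, rows aligned to the subjects of `brain`.
#' @param coefficients Optional fit from a previous call (its `$coefficients`)
#'   to apply to new subjects without re-fitting (split-safe mode).
#' @return A `feature_table` of residuals; attribute `coefficients` stores the
#'   fitted OLS coefficients for re-use.
#' @export
residualize <- function(brain, covariates, coefficients = NULL) {
  if (inherits(covariates, "feature_table")) {
    covariates <- as.data.frame(ft_data(covariates))
  }
  needed <- c("age", "sex", "education", "icv")
  missing <- setdiff(needed, colnames(covariates))
  if (length(missing)) stop("missing covariate column(s): ", paste(missing, collapse = ", "))
  if (anyNA(covariates[needed])) stop("covariates must not contain missing values")
  y <- ft_data(brain)
  tags <- ft_classes(brain)
  if (!all(tags %in% c("brain_thickness", "brain_area", "brain_volume"))) {
    stop("residualize expects brain measure features only")
  }
  X_base <- cbind(`(Intercept)` = 1, age = covariates$age, sex = covariates$sex,
                  education = covariates$education)
  X_icv <- cbind(X_base, icv = covariates$icv)
  use_icv <- tags %in% c("brain_area", "brain_volume")
  resid <- y
  coefs <- list()
  fit_block <- function(X, cols) {
    if (!length(cols)) return(NULL)
    if (is.null(coefficients)) {
      b <- qr.coef(qr(X), y[, cols, drop = FALSE])
      b[is.na(b)] <- 0
    } else {
      b <- coefficients[[if (ncol(X) == 5) "with_icv" else "base"]]
      b <- b[, cols, drop = FALSE]
    }
    resid[, cols] <<- y[, cols, drop = FALSE] - X %*% b
    b
  }
  coefs$base <- fit_block(X_base, colnames(y)[!use_icv])
  coefs$with_icv <- fit_block(X_icv, colnames(y)[use_icv])
  out <- feature_table(resid, tags)
  attr(out, "coefficients") <- coefs
  out
}

#' Longitudinal cognitive composite z-score
#'
#' ADAS-Cog-13 and CDR-SOB totals are negated so that lower values mean
#' poorer performance on all three tests, each test is z-scored against the
#' baseline cohort mean/SD of that (signed) test, and the composite is the
#' mean of the three z-scores per timepoint. The longitudinal delta is
#' follow-up minus baseline.
#'
#' @param mmse,adas13,cdr_sob Each a data.frame or matrix with columns
#'   `baseline` and `followup` of per-subject test totals.
#' @return An object of class `cognitive_composite`: list with `baseline_z`,
#'   `followup_z`, `delta` (numeric vectors) and the anchoring means/SDs.
#' @export
cognitive_composite <- function(mmse, adas13, cdr_sob) {
  grab <- function(x, nm) {
    x <- as.data.frame(x)
    if (!all(c("baseline", "followup") %in% colnames(x))) {
      stop(nm, " needs 'baseline' and 'followup' columns")
    }
    x[, c("baseline", "followup")]
  }
  tests <- list(mmse = grab(mmse, "mmse"),
                adas13 = grab(adas13, "adas13"),
                cdr_sob = grab(cdr_sob, "cdr_sob"))
  n <- nrow(tests$mmse)
  if (nrow(tests$adas13) != n || nrow(tests$cdr_sob) != n) {
    stop("all three tests must cover the same subjects")
  }
  signs <- c(mmse = 1, adas13 = -1, cdr_sob = -1)
  anchors <- list()
  z <- list(baseline = matrix(0, n, 3), followup = matrix(0, n, 3))
  for (i in seq_along(tests)) {
    nm <- names(tests)[i]
    signed_bl <- signs[nm] * tests[[nm]]$baseline
    signed_fu <- signs[nm] * tests[[nm]]$followup
    mu <- mean(signed_bl)
    sd_bl <- stats::sd(signed_bl)
    if (!is.finite(sd_bl) || sd_bl == 0) stop("zero baseline SD for test ", nm)
    anchors[[nm]] <- c(mean = mu, sd = sd_bl)
    z$baseline[, i] <- (signed_bl - mu) / sd_bl
    z$followup[, i] <- (signed_fu - mu) / sd_bl
  }
  baseline_z <- rowMeans(z$baseline)
  followup_z <- rowMeans(z$followup)
  # re-anchor the composite so the baseline composite has mean 0, SD 1
  mu_c <- mean(baseline_z)
  sd_c <- stats::sd(baseline_z)
  if (!is.finite(sd_c) || sd_c == 0) stop("degenerate baseline composite")
  baseline_z <- (baseline_z - mu_c) / sd_c
  followup_z <- (followup_z - mu_c) / sd_c
  structure(list(baseline_z = baseline_z,
                 followup_z = followup_z,
                 delta = followup_z - baseline_z,
                 anchors = anchors,
                 composite_anchor = c(mean = mu_c, sd = sd_c)),
            class = "cognitive_composite")
}

#' Construct a diagnostic ledger from long-format visit data
#'
#' @param visits Data.frame with columns `subject`, `visit_month`,
#'   `diagnosis` (values `CN`, `MCI`, `AD`).
#' @return An object of class `diagnostic_ledger` (the validated long
#'   data.frame, sorted by subject and visit).
#' @export
diagnostic_ledger <- function(visits) {
  visits <- as.data.frame(visits)
  needed <- c("subject", "visit_month", "diagnosis")
  if (!all(needed %in% colnames(visits))) {
    stop("visits need columns subject, visit_month, diagnosis")
  }
  bad <- setdiff(unique(visits$diagnosis), c("CN", "MCI", "AD"))
  if (length(bad)) stop("unknown diagnosis code(s): ", paste(bad, collapse = ", "))
  visits$visit_month <- as.numeric(visits$visit_month)
  visits <- visits[order(visits$subject, visits$visit_month), needed]
  rownames(visits) <- NULL
  class(visits) <- c("diagnostic_ledger", "data.frame")
  visits
}

#' Assign diagnostic trajectory groups and progression contrasts
#'
#' Every subject receives exactly one derived group:
#' * `AD-baseline` — AD at the first visit;
#' * `excluded-reverter` — an MCI visit followed by a later CN visit (such
#'   subjects are excluded from the stable-vs-progressor contrasts);
#' * `CN-p` / `MCI-p` — baseline CN/MCI with at least one later AD visit;
#' * `CN-s` / `MCI-s` — constant diagnosis across all visits with at least 12
#'   months of follow-up;
#' * `excluded-short` — constant diagnosis but under 12 months of follow-up.
#'
#' Three binary contrasts are derived: (1) CN-s vs progressors, (2) MCI-s vs
#' progressors, (3) any AD diagnosis ever vs never (all subjects, including
#' short-follow-up and reverters, classified by their observed visits).
#'
#' @param ledger A `diagnostic_ledger`.
#' @return An object of class `diagnostic_groups`: data.frame with columns
#'   `subject`, `baseline_dx`, `group`, `followup_months`, `ad_ever`, and the
#'   three contrast columns `contrast1`..`contrast3` (0/1, `NA` = excluded).
#' @export
assign_groups <- function(ledger) {
  if (!inherits(ledger, "diagnostic_ledger")) ledger <- diagnostic_ledger(ledger)
  per <- split(ledger, ledger$subject)
  rows <- lapply(per, function(d) {
    dx <- d$diagnosis
    months <- d$visit_month
    baseline <- dx[1]
    followup <- max(months) - min(months)
    ad_ever <- any(dx == "AD")
    reverted <- FALSE
    mci_seen <- FALSE
    for (v in dx) {
      if (v == "MCI") mci_seen <- TRUE
      if (v == "CN" && mci_seen) { reverted <- TRUE; break }
    }
    group <- if (baseline == "AD") {
      "AD-baseline"
    } else if (reverted) {
      "excluded-reverter"
    } else if (any(dx == "AD")) {
      paste0(baseline, "-p")
    } else if (length(unique(dx)) == 1 && followup >= 12) {
      paste0(baseline, "-s")
    } else {
      "excluded-short"
    }
    data.frame(subject = d$subject[1], baseline_dx = baseline, group = group,
               followup_months = followup, ad_ever = ad_ever,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  prog <- out$group %in% c("CN-p", "MCI-p")
  out$contrast1 <- ifelse(prog, 1L, ifelse(out$group == "CN-s", 0L, NA_integer_))
  out$contrast2 <- ifelse(prog, 1L, ifelse(out$group == "MCI-s", 0L, NA_integer_))
  out$contrast3 <- as.integer(out$ad_ever)
  class(out) <- c("diagnostic_groups", "data.frame")
  out
}

#' Cohort prevalence and annual conversion rate
#'
#' Prevalence is the percentage of progressors among the four
#' stable/progressor groups, 100 * (CN-p + MCI-p) / (CN-p + MCI-p + CN-s +
#' MCI-s). The annual conversion rate divides the prevalence by the mean
#' follow-up expressed in years. Both are reported rounded to one decimal.
#'
#' @param groups A `diagnostic_groups` object (or a data.frame with `group`
#'   and `followup_months`).
#' @param mean_followup_months Optional override of the mean follow-up used
#'   for annualization; by default the mean over the four groups.
#' @return Named numeric vector `c(prevalence_pct, annual_conversion_pct)`.
#' @export
prevalence_stats <- function(groups, mean_followup_months = NULL) {
  counts <- table(factor(groups$group,
                         levels = c("CN-p", "MCI-p", "CN-s", "MCI-s")))
  denom <- sum(counts)
  if (denom == 0) stop("no stable or progressing subjects")
  n_prog <- counts[["CN-p"]] + counts[["MCI-p"]]
  prevalence <- 100 * n_prog / denom
  if (is.null(mean_followup_months)) {
    keep <- groups$group %in% c("CN-p", "MCI-p", "CN-s", "MCI-s")
    mean_followup_months <- mean(groups$followup_months[keep])
  }
  annual <- if (n_prog == 0) 0 else prevalence / (mean_followup_months / 12)
  c(prevalence_pct = round(prevalence, 1),
    annual_conversion_pct = round(annual, 1))
}

#' Binary outcome vector for one of the three progression contrasts
#'
#' @param groups A `diagnostic_groups` object.
#' @param contrast Integer 1, 2 or 3.
#' @return Named integer vector (0/1) over the subjects entering the
#'   contrast; excluded subjects are dropped.
#' @export
contrast_outcome <- function(groups, contrast) {
  if (!contrast %in% 1:3) stop("contrast must be 1, 2 or 3")
  col <- paste0("contrast", contrast)
  y <- groups[[col]]
  names(y) <- groups$subject
  y[!is.na(y)]
}
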