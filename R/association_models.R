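#' Ordinary least squares with t-based inference
#'
#' Shared OLS core for all covariate-adjusted models in the package. Fits by
#' QR decomposition (via [stats::lm()]), uses listwise deletion of
#' incomplete cases, and reports two-sided t-test p-values and 95%
#' confidence intervals from the t distribution with the residual degrees
#' of freedom. Refuses rank-deficient designs and models with no residual
#' degrees of freedom, rather than silently dropping terms.
#'
#' @param formula Model formula with an intercept.
#' @param data Data frame of outcome and predictors.
#' @param conf_level Confidence level for the intervals.
#' @return List with `table` (term, estimate, se, t, p_value, ci_lower,
#'   ci_upper), `n` (complete cases used), `df_residual`, `sigma` and the
#'   underlying `lm` fit.
#' @export
ols_fit <- function(formula, data, conf_level = 0.95) {
  dat <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  n <- nrow(dat)
  fit <- stats::lm(formula, data = dat)
  p <- length(stats::coef(fit))
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  if (n <= p)
    stop("n (", n, ") must exceed the number of parameters (", p, ")")
  sm <- summary(fit)
  cf <- sm$coefficients
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = fit$df.residual)
  tab <- data.frame(term = rownames(cf),
                    estimate = cf[, 1], se = cf[, 2],
                    t = cf[, 3], p_value = cf[, 4],
                    ci_lower = cf[, 1] - tcrit * cf[, 2],
                    ci_upper = cf[, 1] + tcrit * cf[, 2],
                    row.names = NULL)
  list(table = tab, n = n, df_residual = fit$df.residual,
       sigma = sm$sigma, fit = fit)
}

#' Covariate-adjusted association between a subnetwork strength and a
#' clinical score
#'
#' Fits, in the pooled MS population only, the multiple regression of a
#' clinical score (EDSS or SDMT) on the subnetwork nodal strength of one
#' region within one reference PN, adjusting for age, sex, disease
#' duration, lesion load and deep grey matter volume (the deep-grey-matter
#' covariate because the regions of interest are subcortical). One model
#' per (score, PN rank, region); listwise deletion of incomplete cases.
#'
#' @param cohort A `pnms_cohort`.
#' @param score `"edss"` or `"sdmt"`.
#' @param sub_strengths Long data frame from [subnetwork_nodal_strength()]
#'   for the reference PN of interest.
#' @param region Region label of the predictor strength.
#' @param pn_rank Rank label recorded in the result (defaults to the one in
#'   `sub_strengths`).
#' @param min_n Minimum complete cases; fewer is an error, not a silent fit.
#' @return One-row data frame of class `pnms_association`: `score`,
#'   `pn_rank`, `region`, `coefficient`, `ci_lower`, `ci_upper`, `p_value`,
#'   `n`, `degenerate` (TRUE when the score shows no variance, in which
#'   case the coefficient is 0 and p = 1).
#' @export
clinical_association <- function(cohort, score, sub_strengths, region,
                                 pn_rank = NULL, min_n = 15) {
  score <- match.arg(tolower(score), c("edss", "sdmt"))
  if (is.null(pn_rank)) pn_rank <- sub_strengths$pn_rank[1]
  man <- cohort$manifest
  ms <- man$group != "HC"
  strength <- subnetwork_strength_vector(sub_strengths, region)
  dat <- data.frame(
    y = man[[score]][ms],
    strength = strength[man$subject_id[ms]],
    age = man$age[ms],
    sex_f = as.numeric(man$sex[ms] == "F"),
    disease_duration = man$disease_duration[ms],
    lesion_load = man$lesion_load[ms],
    dgm_volume = man$dgm_volume[ms])
  dat <- dat[stats::complete.cases(dat), ]
  if (nrow(dat) < min_n)
    stop("only ", nrow(dat), " complete cases (< ", min_n,
         ") for ", score, " ~ PN", pn_rank, " ", region)
  if (stats::sd(dat$y) == 0) {
    out <- data.frame(score = score, pn_rank = pn_rank, region = region,
                      coefficient = 0, ci_lower = 0, ci_upper = 0,
                      p_value = 1, n = nrow(dat), degenerate = TRUE)
    class(out) <- c("pnms_association", class(out))
    return(out)
  }
  fit <- ols_fit(y ~ strength + age + sex_f + disease_duration +
                   lesion_load + dgm_volume, data = dat)
  row <- fit$table[fit$table$term == "strength", ]
  out <- data.frame(score = score, pn_rank = pn_rank, region = region,
                    coefficient = row$estimate, ci_lower = row$ci_lower,
                    ci_upper = row$ci_upper, p_value = row$p_value,
                    n = fit$n, degenerate = FALSE)
  class(out) <- c("pnms_association", class(out))
  out
}

#' Association table for the deep-grey regions of interest
#'
#' Runs [clinical_association()] for both clinical scores against the
#' right-thalamus and right-putamen subnetwork strengths in PN1 and PN2
#' (only the combinations whose region is a member of the respective
#' reference PN), reproducing the layout of a score-by-predictor regression
#' summary.
#'
#' @param cohort A `pnms_cohort`.
#' @param strengths_by_pn Named list (`"1"`, `"2"`) of long data frames from
#'   [subnetwork_nodal_strength()].
#' @param regions Predictor regions of interest.
#' @return Data frame, one row per (score, pn, region) actually present.
#' @export
clinical_association_table <- function(cohort, strengths_by_pn,
                                       regions = c("Right thalamus",
                                                   "Right putamen")) {
  rows <- list()
  for (score in c("edss", "sdmt"))
    for (rk in names(strengths_by_pn)) {
      ss <- strengths_by_pn[[rk]]
      for (region in intersect(regions, unique(ss$region_label)))
        rows[[length(rows) + 1]] <-
          clinical_association(cohort, score, ss, region)
    }
  do.call(rbind, rows)
}

#' Pairwise univariate association matrix
#'
#' Exploratory analysis: Pearson correlation between every PN member
#' region's subnetwork strength and each clinical score, over MS subjects,
#' using pairwise-complete observations. Cells with fewer than 3 complete
#' pairs are reported as `NA`.
#'
#' @param cohort A `pnms_cohort`.
#' @param strengths_by_pn Named list of long data frames from
#'   [subnetwork_nodal_strength()], one per PN rank.
#' @return Numeric matrix; rows named `PN<rank> <region>`, columns `edss`
#'   and `sdmt`.
#' @export
association_matrix <- function(cohort, strengths_by_pn) {
  man <- cohort$manifest
  ms_ids <- man$subject_id[man$group != "HC"]
  rows <- list()
  for (rk in names(strengths_by_pn)) {
    ss <- strengths_by_pn[[rk]]
    for (region in unique(ss$region_label)) {
      strength <- subnetwork_strength_vector(ss, region)[ms_ids]
      vals <- vapply(c("edss", "sdmt"), function(score) {
        y <- man[[score]][match(ms_ids, man$subject_id)]
        ok <- stats::complete.cases(strength, y)
        if (sum(ok) < 3) return(NA_real_)
        stats::cor(strength[ok], y[ok])
      }, 0)
      rows[[paste0("PN", rk, " ", region)]] <- vals
    }
  }
  do.call(rbind, rows)
}
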