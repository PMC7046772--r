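#' Nodal strength
#'
#' The strength of a node is the sum of the weights of all edges incident to
#' it (the weighted degree), i.e. the row sum of the connectivity matrix.
#' The strengths always satisfy the conservation identity
#' `sum(strengths) == 2 * total edge weight`.
#'
#' @param weights A validated connectivity matrix.
#' @return Named numeric vector of per-node strengths, in node-table order.
#' @export
nodal_strength <- function(weights) {
  rowSums(weights)
}

#' Group-mean connectivity matrix
#'
#' Entrywise arithmetic mean of the matrices of all subjects in a group.
#' Symmetry and the zero diagonal are preserved by linearity.
#'
#' @param cohort A `pnms_cohort`.
#' @param group Group label (`HC`, `RRMS`, `PPMS`, `SPMS`).
#' @return Connectivity matrix of the same dimension as the inputs.
#' @export
group_mean_matrix <- function(cohort, group) {
  sids <- group_subjects(cohort, group)
  if (length(sids) == 0) stop("no subjects in group '", group, "'")
  Reduce(`+`, cohort$matrices[sids]) / length(sids)
}

#' Detect hubs by the mean + 1 SD strength criterion
#'
#' A region is a hub when its nodal strength on the group-mean matrix is at
#' least the mean plus one standard deviation of the strengths over all
#' nodes (inclusive threshold). The SD uses the sample (n - 1) formula.
#' When the strengths are degenerate (SD = 0) every node meets the
#' threshold; the report is flagged so downstream consumers can refuse to
#' interpret it.
#'
#' @param strengths Named strength vector from a group-mean matrix
#'   ([nodal_strength()]), length >= 2.
#' @param group Optional group label recorded in the report.
#' @return An object of class `pnms_hub_report`: list with `strengths`,
#'   `mu`, `sigma`, `threshold`, `hubs` (region labels, node-table order),
#'   `degenerate` flag and `group`.
#' @export
detect_hubs <- function(strengths, group = NA_character_) {
  if (length(strengths) < 2)
    stop("need at least 2 nodes to define a hub threshold")
  mu <- mean(strengths)
  sigma <- stats::sd(strengths)
  threshold <- mu + sigma
  hubs <- names(strengths)[strengths >= threshold]
  structure(list(strengths = strengths, mu = mu, sigma = sigma,
                 threshold = threshold, hubs = hubs,
                 degenerate = sigma == 0, group = group),
            class = "pnms_hub_report")
}

#' @export
print.pnms_hub_report <- function(x, ...) {
  cat("Hub report", if (!is.na(x$group)) paste0("(", x$group, ")"), "\n")
  cat(sprintf("  mean strength %.4g, SD %.4g, threshold %.4g\n",
              x$mu, x$sigma, x$threshold))
  cat("  ", length(x$hubs), "hubs:", paste(x$hubs, collapse = ", "), "\n")
  if (x$degenerate) cat("  WARNING: degenerate strengths (SD = 0)\n")
  invisible(x)
}

#' Per-subject nodal strengths
#'
#' @param cohort A `pnms_cohort`.
#' @param regions Optional region labels to keep (default all).
#' @return Data frame with one row per subject: `subject_id`, `group`, then
#'   one column per region.
#' @export
subject_strengths <- function(cohort, regions = NULL) {
  s <- t(vapply(cohort$matrices, nodal_strength,
                numeric(nrow(cohort$node_table))))
  if (!is.null(regions)) {
    missing <- setdiff(regions, colnames(s))
    if (length(missing))
      stop("unknown region(s): ", paste(missing, collapse = ", "))
    s <- s[, regions, drop = FALSE]
  }
  data.frame(subject_id = cohort$manifest$subject_id,
             group = cohort$manifest$group,
             s, check.names = FALSE, row.names = NULL)
}

#' Covariate-adjusted group comparison of one hub's strength
#'
#' Pools healthy controls with one MS group and regresses the per-subject
#' full-matrix strength of `hub_region` on a group indicator plus age, sex,
#' lesion load, disease duration and total intracranial volume. Lesion load
#' and disease duration are undefined for healthy controls and are set to
#' zero, with the group indicator absorbing the offset; the group
#' coefficient is therefore the adjusted strength difference at the
#' reference covariate level. A negative coefficient with p < alpha flags a
#' significant strength reduction.
#'
#' @param cohort A `pnms_cohort` containing HC and `ms_group` subjects.
#' @param hub_region Region label whose strength is the outcome.
#' @param ms_group One of `RRMS`, `PPMS`, `SPMS`.
#' @param alpha Significance level for the reduction flag.
#' @return One-row data frame: `region`, `group`, `coefficient`, `ci_lower`,
#'   `ci_upper`, `p_value`, `n`, `significant_reduction`.
#' @export
compare_hub_strength <- function(cohort, hub_region, ms_group,
                                 alpha = 0.05) {
  if (!ms_group %in% c("RRMS", "PPMS", "SPMS"))
    stop("ms_group must be one of RRMS, PPMS, SPMS")
  sids <- c(group_subjects(cohort, "HC"), group_subjects(cohort, ms_group))
  if (length(group_subjects(cohort, ms_group)) == 0)
    stop("no subjects in group '", ms_group, "'")
  if (length(sids) < 10)
    stop("need at least 10 pooled subjects, got ", length(sids))
  man <- cohort$manifest[match(sids, cohort$manifest$subject_id), ]
  strengths <- vapply(cohort$matrices[sids],
                      function(m) nodal_strength(m)[[hub_region]], 0)
  dat <- data.frame(
    strength = strengths,
    is_ms = as.numeric(man$group == ms_group),
    age = man$age,
    sex_f = as.numeric(man$sex == "F"),
    lesion_load = ifelse(man$group == "HC", 0, man$lesion_load),
    disease_duration = ifelse(man$group == "HC", 0, man$disease_duration),
    tiv = man$tiv)
  fit <- ols_fit(strength ~ is_ms + age + sex_f + lesion_load +
                   disease_duration + tiv, data = dat)
  row <- fit$table[fit$table$term == "is_ms", ]
  data.frame(region = hub_region, group = ms_group,
             coefficient = row$estimate, ci_lower = row$ci_lower,
             ci_upper = row$ci_upper, p_value = row$p_value, n = fit$n,
             significant_reduction = row$p_value < alpha & row$estimate < 0,
             row.names = NULL)
}

#' Hub-strength comparison table across MS groups
#'
#' Runs [compare_hub_strength()] for every region of a hub set against every
#' MS group present in the cohort, mirroring a group-comparison summary
#' table layout (per-group mean (SD) strength with significance flags).
#'
#' @param cohort A `pnms_cohort`.
#' @param hub_set Character vector of hub region labels (typically the HC
#'   hub set, the fixed reference).
#' @param ms_groups MS groups to compare against HC.
#' @param alpha Significance level.
#' @return Data frame, one row per (region, group).
#' @export
hub_comparison_table <- function(cohort, hub_set,
                                 ms_groups = c("RRMS", "PPMS", "SPMS"),
                                 alpha = 0.05) {
  present <- ms_groups[vapply(ms_groups, function(g)
    length(group_subjects(cohort, g)) > 0, TRUE)]
  ss <- subject_strengths(cohort, hub_set)
  out <- do.call(rbind, lapply(present, function(g) {
    res <- do.call(rbind, lapply(hub_set, function(r)
      compare_hub_strength(cohort, r, g, alpha = alpha)))
    ms_rows <- ss$group == g
    res$group_mean <- vapply(hub_set, function(r) mean(ss[ms_rows, r]), 0)
    res$group_sd <- vapply(hub_set, function(r) stats::sd(ss[ms_rows, r]), 0)
    res
  }))
  hc_rows <- ss$group == "HC"
  attr(out, "hc_mean") <- vapply(hub_set, function(r) mean(ss[hc_rows, r]), 0)
  attr(out, "hc_sd") <- vapply(hub_set, function(r) stats::sd(ss[hc_rows, r]), 0)
  out
}
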