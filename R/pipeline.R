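#' Run the full connectome analysis pipeline
#'
#' Orchestrates the whole workflow on a cohort: group-mean matrices and hub
#' detection per group, covariate-adjusted hub-strength comparisons against
#' healthy controls, principal-network decomposition per group with
#' membership comparison against the reference group, HC-referenced
#' subnetwork strengths, and the clinical association models. Every stage
#' is a pure function of (cohort, parameters), so the same inputs always
#' produce the same report.
#'
#' @param cohort A `pnms_cohort`, e.g. from [simulate_cohort()] or
#'   [read_cohort()].
#' @param tau Loading threshold for PN membership.
#' @param n_components Number of PNs to extract per group.
#' @param reference Reference group for hub sets, PN membership comparison
#'   and subnetwork bases (default `"HC"`).
#' @param alpha Significance level for comparison flags.
#' @param out_dir Optional directory; when given, writes the artifact tree
#'   (`hubs/`, `pn/`, `subnet/`, `associations/`, `report.json`).
#' @return A report list: per-group hub reports and counts, hub comparison
#'   table, PN decompositions, membership differences, edge compositions,
#'   subnetwork strengths, association tables, and the parameters used.
#' @export
run_pipeline <- function(cohort, tau = 0.1, n_components = 2,
                         reference = "HC", alpha = 0.05, out_dir = NULL) {
  groups <- levels(droplevels(cohort$manifest$group))
  if (!reference %in% groups)
    stop("reference group '", reference, "' absent from the cohort")
  ms_groups <- setdiff(groups, "HC")

  mean_mats <- lapply(stats::setNames(nm = groups),
                      function(g) group_mean_matrix(cohort, g))
  hub_reports <- lapply(stats::setNames(nm = groups), function(g)
    detect_hubs(nodal_strength(mean_mats[[g]]), group = g))
  hub_set <- hub_reports[[reference]]$hubs

  hub_comparison <- if (length(ms_groups) && length(hub_set))
    hub_comparison_table(cohort, hub_set, ms_groups, alpha = alpha)
  else NULL

  pns <- lapply(stats::setNames(nm = groups), function(g)
    pn_decompose(mean_mats[[g]], tau = tau, n_components = n_components))
  empty <- unlist(lapply(groups, function(g)
    vapply(pns[[g]], function(p) length(p$members) == 0, TRUE)))
  membership <- if (length(groups) > 1 && !any(empty))
    pn_membership_comparison(pns, reference = reference)
  else NULL

  composition <- lapply(stats::setNames(nm = groups), function(g)
    lapply(pns[[g]], function(p)
      edge_composition(mean_mats[[g]], p, cohort$node_table)))

  sub_strengths <- lapply(stats::setNames(seq_len(n_components),
                                          as.character(seq_len(n_components))),
                          function(k) {
    if (length(pns[[reference]][[k]]$members) >= 2)
      subnetwork_nodal_strength(cohort, pns[[reference]][[k]])
    else NULL
  })
  sub_strengths <- Filter(Negate(is.null), sub_strengths)

  have_ms <- length(ms_groups) > 0
  assoc_table <- NULL; assoc_matrix <- NULL
  if (have_ms && length(sub_strengths)) {
    assoc_table <- tryCatch(
      clinical_association_table(cohort, sub_strengths),
      error = function(e) {
        warning("clinical associations skipped: ", conditionMessage(e))
        NULL
      })
    assoc_matrix <- association_matrix(cohort, sub_strengths)
  }

  report <- list(
    parameters = list(tau = tau, n_components = n_components,
                      reference = reference, alpha = alpha,
                      n_subjects = nrow(cohort$manifest),
                      n_regions = nrow(cohort$node_table),
                      package_version =
                        as.character(utils::packageVersion("pnms"))),
    hub_counts = vapply(hub_reports, function(h) length(h$hubs), 0L),
    hub_reports = hub_reports,
    hub_set = hub_set,
    hub_comparison = hub_comparison,
    pns = pns,
    pn_sizes = lapply(pns, function(pl)
      vapply(pl, function(p) length(p$members), 0L)),
    empty_pns = any(empty),
    membership = membership,
    composition = composition,
    sub_strengths = sub_strengths,
    associations = assoc_table,
    association_matrix = assoc_matrix)
  if (!is.null(out_dir)) write_pipeline_report(report, cohort, out_dir)
  report
}

write_pipeline_report <- function(report, cohort, out_dir) {
  for (d in c("hubs", "pn", "subnet", "associations"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  for (g in names(report$hub_reports)) {
    h <- report$hub_reports[[g]]
    utils::write.table(
      data.frame(region_label = names(h$strengths),
                 strength = unname(h$strengths),
                 is_hub = names(h$strengths) %in% h$hubs),
      file.path(out_dir, "hubs", paste0(g, "_strengths.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$hub_comparison))
    utils::write.table(report$hub_comparison,
                       file.path(out_dir, "hubs", "comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (g in names(report$pns)) {
    pl <- report$pns[[g]]
    tab <- do.call(rbind, lapply(pl, function(p)
      data.frame(rank = p$rank, eigenvalue = p$eigenvalue,
                 region_label = names(p$loadings),
                 loading = unname(p$loadings),
                 member = names(p$loadings) %in% p$members)))
    utils::write.table(tab,
                       file.path(out_dir, "pn", paste0(g, "_loadings.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$membership))
    utils::write.table(report$membership,
                       file.path(out_dir, "pn", "membership_differences.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (k in names(report$sub_strengths))
    utils::write.table(report$sub_strengths[[k]],
                       file.path(out_dir, "subnet",
                                 paste0("pn", k, "_strengths.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$associations))
    utils::write.table(report$associations,
                       file.path(out_dir, "associations", "models.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$association_matrix))
    utils::write.table(
      data.frame(predictor = rownames(report$association_matrix),
                 report$association_matrix, check.names = FALSE),
      file.path(out_dir, "associations", "association_matrix.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    parameters = report$parameters,
    hub_counts = as.list(report$hub_counts),
    hub_set = report$hub_set,
    pn_sizes = report$pn_sizes,
    empty_pns = report$empty_pns,
    membership_differences = report$membership,
    significant_associations = if (!is.null(report$associations))
      report$associations[report$associations$p_value < report$parameters$alpha, ]
    else NULL,
    significant_hub_reductions = if (!is.null(report$hub_comparison))
      stats::aggregate(significant_reduction ~ group,
                       data = report$hub_comparison, FUN = sum)
    else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  invisible(out_dir)
}
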