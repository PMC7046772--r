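# Shared fixtures, all built in code.

toy_node_table <- function(n = 4, hemis = NULL) {
  labels <- paste0("region", seq_len(n))
  if (is.null(hemis)) hemis <- rep("left", n)
  data.frame(region_label = labels, hemisphere = hemis,
             lobe = "frontal", node_class = "cortical")
}

# symmetric nonnegative zero-diagonal matrix with given labels
toy_matrix <- function(labels, fill = NULL, seed = NULL) {
  n <- length(labels)
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  ut <- upper.tri(m)
  m[ut] <- if (is.null(fill)) stats::runif(sum(ut), 0, 10) else fill
  m + t(m)
}

toy_manifest <- function(groups, ids = NULL) {
  n <- length(groups)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(n))
  data.frame(subject_id = ids, group = groups,
             age = round(seq(30, 60, length.out = n), 1),
             sex = rep(c("M", "F"), length.out = n),
             disease_duration = ifelse(groups == "HC", NA, 10),
             lesion_load = ifelse(groups == "HC", NA, 12),
             tiv = 1450, dgm_volume = 60,
             edss = ifelse(groups == "HC", NA, 4),
             sdmt = 50)
}

# cohort with constant per-group matrices; `deltas` maps group -> named
# vector of per-region row/column attenuations applied to the base matrix
toy_cohort <- function(groups, node_table = toy_node_table(4),
                       base = NULL, deltas = list(), seed = 1) {
  if (is.null(base)) base <- toy_matrix(node_table$region_label, seed = seed)
  man <- toy_manifest(groups)
  mats <- lapply(seq_along(groups), function(i) {
    g <- as.character(groups[i])
    m <- base
    if (!is.null(deltas[[g]])) {
      f <- rep(1, nrow(m)); names(f) <- rownames(m)
      f[names(deltas[[g]])] <- deltas[[g]]
      m <- m * outer(f, f)
    }
    m
  })
  names(mats) <- man$subject_id
  cohort(node_table, man, mats)
}

# The default-condition simulated cohorts are expensive; cache per seed so
# multiple test files can reuse them.
.pnms_cache <- new.env(parent = emptyenv())

cached_cohort <- function(seed = 1L) {
  key <- paste0("cohort", seed)
  if (is.null(.pnms_cache[[key]]))
    .pnms_cache[[key]] <- simulate_cohort(sim_config(seed = seed))
  .pnms_cache[[key]]
}

# Per-seed analysis summary used by the acceptance suite: hub sets, PN
# memberships and sizes, edge composition, adjusted hub-comparison counts,
# and HC right-thalamus strengths.
cohort_summary <- function(seed) {
  key <- paste0("summary", seed)
  if (!is.null(.pnms_cache[[key]])) return(.pnms_cache[[key]])
  coh <- simulate_cohort(sim_config(seed = seed))
  groups <- c("HC", "RRMS", "PPMS", "SPMS")
  out <- list(seed = seed)
  out$hub_sets <- list(); out$pn_members <- list()
  for (g in groups) {
    gm <- group_mean_matrix(coh, g)
    out$hub_sets[[g]] <- detect_hubs(nodal_strength(gm), group = g)$hubs
    pns <- suppressWarnings(pn_decompose(gm, tau = 0.1, n_components = 2))
    out$pn_members[[g]] <- lapply(pns, function(p) p$members)
    if (g == "HC") {
      out$hc_composition <- lapply(pns, function(p)
        edge_composition(gm, p, coh$node_table))
      out$hc_pns <- pns
    }
  }
  hubs <- out$hub_sets$HC
  tab <- hub_comparison_table(coh, hubs)
  out$reduction_counts <- tapply(tab$significant_reduction, tab$group, sum)
  ss <- subject_strengths(coh, "Right thalamus")
  out$hc_right_thal <- ss[ss$group == "HC", "Right thalamus"]
  out$dims_ok <- all(vapply(coh$matrices, function(m)
    nrow(m) == 115 && ncol(m) == 115 &&
      identical(m, t(m)) && all(diag(m) == 0) && all(m >= 0), TRUE))
  .pnms_cache[[key]] <- out
  out
}

expected_pn_members <- function() {
  im <- intended_pn_members()
  list(pn1 = list(HC = im$pn1, RRMS = im$pn1, PPMS = im$pn1,
                  SPMS = setdiff(im$pn1, "Right thalamus")),
       pn2 = list(HC = im$pn2,
                  RRMS = setdiff(im$pn2, "Right putamen"),
                  PPMS = setdiff(im$pn2, "Right putamen"),
                  SPMS = setdiff(im$pn2,
                                 c("Right putamen", "Right thalamus"))))
}

# independent power-iteration oracle for the leading eigenpair
power_iteration <- function(w, tol = 1e-12, max_iter = 10000) {
  v <- rep(1 / sqrt(nrow(w)), nrow(w))
  lambda <- 0
  for (i in seq_len(max_iter)) {
    v_new <- as.vector(w %*% v)
    lambda_new <- sqrt(sum(v_new^2))
    v_new <- v_new / lambda_new
    if (max(abs(v_new - v)) < tol || max(abs(v_new + v)) < tol) {
      v <- v_new; lambda <- lambda_new; break
    }
    v <- v_new; lambda <- lambda_new
  }
  list(value = as.numeric(t(v) %*% w %*% v), vector = v)
}
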