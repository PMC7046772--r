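#' Calibration targets for the 18 high-strength hub regions
#'
#' Group-level mean and standard deviation of full-matrix nodal strength
#' (units of 10^5 summed streamline weights) for the 18 canonical hub
#' regions, per group (healthy controls and the three MS phenotypes).
#' These are the strength targets the synthetic generator is calibrated to:
#' the group templates reproduce the means and the per-subject noise model
#' is solved against the SDs.
#'
#' @return Data frame: `region`, then `<group>_mean` / `<group>_sd` for
#'   `hc`, `rrms`, `ppms`, `spms`.
#' @export
hub_strength_reference <- function() {
  tab <- c(
    "Right precentral gyrus",        3.39, 0.21, 3.34, 0.27, 3.27, 0.24, 3.23, 0.23,
    "Left precentral gyrus",         3.53, 0.23, 3.38, 0.28, 3.36, 0.30, 3.34, 0.32,
    "Right superior frontal gyrus",  3.37, 0.18, 3.22, 0.23, 3.11, 0.26, 3.09, 0.25,
    "Left superior frontal gyrus",   3.28, 0.17, 3.20, 0.26, 3.10, 0.03, 3.13, 0.24,
    "Right middle frontal gyrus",    2.88, 0.20, 2.78, 0.25, 2.75, 0.23, 2.58, 0.22,
    "Left middle frontal gyrus",     3.04, 0.19, 2.92, 0.27, 2.77, 0.23, 2.76, 0.22,
    "Right postcentral gyrus",       2.25, 0.10, 2.28, 0.16, 2.20, 0.16, 2.16, 0.18,
    "Left postcentral gyrus",        2.32, 0.12, 2.27, 0.14, 2.31, 0.19, 2.32, 0.18,
    "Right superior parietal lobule",2.26, 0.10, 2.21, 0.13, 2.09, 0.16, 2.08, 0.15,
    "Left superior parietal lobule", 2.01, 0.10, 1.96, 0.12, 1.93, 0.13, 1.85, 0.11,
    "Right precuneus",               2.20, 0.10, 2.14, 0.13, 2.10, 0.16, 1.98, 0.13,
    "Left precuneus",                2.01, 0.10, 1.95, 0.12, 1.94, 0.13, 1.85, 0.12,
    "Right middle temporal gyrus",   2.06, 0.10, 1.96, 0.13, 1.89, 0.12, 1.88, 0.12,
    "Left middle temporal gyrus",    1.85, 0.09, 1.78, 0.12, 1.73, 0.10, 1.74, 0.11,
    "Right thalamus",                2.67, 0.15, 2.32, 0.02, 2.27, 0.19, 2.08, 0.15,
    "Left thalamus",                 2.53, 0.15, 2.22, 0.13, 2.23, 0.17, 2.06, 0.14,
    "Right putamen",                 2.34, 0.13, 2.13, 0.12, 2.11, 0.02, 2.03, 0.13,
    "Left putamen",                  2.20, 0.09, 2.03, 0.11, 2.04, 0.15, 1.94, 0.13)
  m <- matrix(tab, ncol = 9, byrow = TRUE)
  df <- data.frame(region = m[, 1], stringsAsFactors = FALSE)
  vals <- apply(m[, -1], 2, as.numeric)
  colnames(vals) <- c("hc_mean", "hc_sd", "rrms_mean", "rrms_sd",
                      "ppms_mean", "ppms_sd", "spms_mean", "spms_sd")
  cbind(df, vals)
}

#' Per-group demographic distribution defaults
#'
#' Group-level age (years), proportion female, disease duration (years) and
#' T2 lesion load (ml) used by the synthetic generator. Duration and lesion
#' load do not apply to healthy controls.
#'
#' @return Data frame, one row per group.
#' @export
demographics_reference <- function() {
  data.frame(
    group = c("HC", "RRMS", "PPMS", "SPMS"),
    age_mean = c(41, 42, 52, 53),
    age_sd = c(13, 10, 9, 7),
    prop_female = c(26 / 51, 40 / 58, 18 / 28, 28 / 36),
    duration_mean = c(NA, 11, 14, 22),
    duration_sd = c(NA, 8, 7, 10),
    lesion_load_mean = c(NA, 12.78, 16.56, 15.23),
    lesion_load_sd = c(NA, 15.72, 19.83, 12.73))
}

#' Simulation configuration
#'
#' Builds the configuration object for [simulate_cohort()]. Defaults define
#' the reference study conditions: group sizes 51/58/28/36, hub strength
#' targets from [hub_strength_reference()], demographic distributions from
#' [demographics_reference()], a planted fronto-parietal/thalamic core
#' whose symmetric hybrid mode (PN1, inter-hemispheric dominant) and
#' antisymmetric hybrid mode (PN2, intra-hemispheric dominant) carry the
#' principal networks (see [build_group_template()] for the
#' architecture), group-specific attenuation of the right-putamen (all MS) and
#' right-thalamus (SPMS only) core edges, and clinical scores negatively
#' (EDSS) / positively (SDMT) coupled to the right-thalamus and
#' right-putamen subnetwork strengths with covariate-mediated confounding.
#'
#' Strength units throughout the configuration are 10^5 summed streamline
#' weights; generated matrices are in raw units (`unit` = 1e5).
#'
#' @param seed Integer root seed; per-subject streams are derived from it
#'   by fixed offsets so changing one group's size never reshuffles
#'   another's draws.
#' @param group_sizes Named integer vector (`HC`, `RRMS`, `PPMS`, `SPMS`);
#'   a group may be 0 (absent) but a present group needs >= 2 subjects.
#' @param nonhub_mean,nonhub_sd Strength target (mean, across-subject SD)
#'   shared by the 97 non-hub regions.
#' @param block_share Fraction of a core node's strength routed through the
#'   planted core structure (clique + homotopic + thalamic coupling).
#' @param homotopic_share Named shares of a pair's mean strength placed on
#'   its single homotopic edge, keyed by the pair's base region name;
#'   `background` applies to every pair without its own entry. The frontal
#'   cliques are deliberately concentrated on the precentral/superior
#'   frontal nodes (small homotopic share there, large on middle
#'   frontal/postcentral) so that the intra-hemispheric antisymmetric mode
#'   keeps enough energy to rank second while the symmetric mode's
#'   member-member weight stays inter-hemispheric dominant.
#' @param thal_lat Fraction of the right thalamus' cortical coupling that
#'   stays ipsilateral (the left thalamus couples symmetrically at 0.5);
#'   the lateralisation surplus is what places the right thalamus in the
#'   antisymmetric mode (PN2).
#' @param postc_lat Ipsilateral fraction of the postcentral gyri's coupling
#'   onto the frontal cliques; values below 0.5 make them transcallosally
#'   dominant, which both feeds the first mode's inter-hemispheric
#'   dominance and gives the postcentral pair its antisymmetric-mode
#'   loading.
#' @param put_sat Satellite edge weights (units of 10^5) attaching the
#'   right putamen to the right thalamus and to each right-hemisphere core
#'   cortical region; these couple it into the antisymmetric mode (PN2)
#'   while leaving its symmetric-mode (PN1) loading below threshold.
#' @param fan_share Fraction of each hub's strength not already placed by
#'   the core structure that is routed through a deterministic fan of
#'   edges to non-hub regions of its own hemisphere; fans keep the hubs
#'   strong without concentrating the diffuse background spectrum.
#' @param fan_cap Upper bound (units of 10^5) on any single fan's total
#'   weight, which bounds the fan star modes' eigenvalues well below the
#'   planted principal networks.
#' @param dropout_factor Multiplicative attenuation applied to the core
#'   edges of dropout regions (right putamen in all MS groups, right
#'   thalamus additionally in SPMS); scalar, or named per MS group, graded
#'   by default so deep-grey disconnection deepens with progressive
#'   phenotype.
#' @param age_slope Relative change in every connection weight per year
#'   of age about the subject's group mean age (0 by default: the group
#'   strength targets already embed the groups' age differences).
#' @param tiv_expon Scaling exponent linking connection weights to total
#'   intracranial volume (centred within sex), so that part of each
#'   region's across-subject strength variance is explained by the TIV
#'   covariate, as in real cohorts; the residual noise solver accounts for
#'   it.
#' @param sigma_edge,sigma_global,sigma_node_min Log-normal noise scales:
#'   per-edge, per-subject global, and the floor of the per-node scale that
#'   is otherwise solved from the SD targets.
#' @param severity_w0,severity_wll,severity_wdd Decomposition of a subject's
#'   disease severity multiplier into an unmediated share and shares
#'   proportional to lesion load and disease duration (sum to 1 per
#'   group). Scalars or named vectors over the MS groups; by default the
#'   lesion/duration-mediated share is larger in RRMS (inflammatory,
#'   lesion-driven damage) than in the progressive phenotypes (diffuse
#'   neurodegeneration), and the unspecified shares split the remainder
#'   evenly. The mediated shares create the covariate confounding that
#'   attenuates adjusted group contrasts.
#' @param clinical Named list of clinical-model coefficients; see
#'   `sim_config()$clinical` for the fields.
#' @return Object of class `pnms_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       group_sizes = c(HC = 51L, RRMS = 58L, PPMS = 28L,
                                       SPMS = 36L),
                       nonhub_mean = 0.5, nonhub_sd = 0.1,
                       block_share = 0.6,
                       homotopic_share = c("precentral gyrus" = 0.22,
                                           "superior frontal gyrus" = 0.22,
                                           "middle frontal gyrus" = 0.22,
                                           "postcentral gyrus" = 0.14,
                                           "thalamus" = 0.13,
                                           "putamen" = 0.03,
                                           "background" = 0.06),
                       thal_lat = 0.80, postc_lat = 0.05,
                       put_sat = c(thalamus = 0.5, cortex = 0.06),
                       fan_share = 0.8, fan_cap = 1.3,
                       dropout_factor = c(RRMS = 0.3, PPMS = 0.2,
                                          SPMS = 0.1),
                       age_slope = 0, tiv_expon = 0.60,
                       sigma_edge = 0.10, sigma_global = 0.02,
                       sigma_node_min = 0.005,
                       severity_w0 = c(RRMS = 0.62, PPMS = 0.95,
                                       SPMS = 0.95),
                       severity_wll = NULL, severity_wdd = NULL,
                       clinical = NULL) {
  defaults_clinical <- list(
    edss_base = c(RRMS = 2, PPMS = 6, SPMS = 6.5),
    beta_thal_pn1_edss = -3.2,   # EDSS points per 1e5 strength units
    beta_put_pn2_edss = -4,
    beta_age_edss = 0.015,
    edss_sd = 0.9,
    sdmt_base = c(HC = 65, RRMS = 51, PPMS = 43, SPMS = 39),
    beta_thal_pn2_sdmt = 25,     # SDMT points per 1e5 strength units
    beta_put_pn2_sdmt = 45,
    beta_age_sdmt = -0.25,
    sdmt_sd = 8)
  if (is.null(clinical)) clinical <- list()
  clinical <- utils::modifyList(defaults_clinical, clinical)
  ms <- c("RRMS", "PPMS", "SPMS")
  w0 <- rep_len(severity_w0, 3)
  if (!is.null(names(severity_w0))) w0 <- severity_w0[ms]
  wll <- if (is.null(severity_wll)) (1 - w0) / 2 else {
    x <- rep_len(severity_wll, 3)
    if (!is.null(names(severity_wll))) x <- severity_wll[ms]
    x
  }
  wdd <- if (is.null(severity_wdd)) 1 - w0 - wll else {
    x <- rep_len(severity_wdd, 3)
    if (!is.null(names(severity_wdd))) x <- severity_wdd[ms]
    x
  }
  severity <- data.frame(group = ms, w0 = unname(w0), wll = unname(wll),
                         wdd = unname(wdd))
  cfg <- list(seed = as.integer(seed), group_sizes = group_sizes,
              nonhub_mean = nonhub_mean, nonhub_sd = nonhub_sd,
              block_share = block_share, homotopic_share = homotopic_share,
              thal_lat = thal_lat, postc_lat = postc_lat,
              put_sat = put_sat,
              fan_share = fan_share, fan_cap = fan_cap,
              dropout_factor = dropout_factor,
              age_slope = age_slope, tiv_expon = tiv_expon,
              sigma_edge = sigma_edge, sigma_global = sigma_global,
              sigma_node_min = sigma_node_min,
              severity = severity,
              clinical = clinical,
              hub_targets = hub_strength_reference(),
              demographics = demographics_reference(),
              unit = 1e5)
  class(cfg) <- "pnms_sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  gs <- cfg$group_sizes
  if (!all(names(gs) %in% cohort_groups))
    stop("unknown group in group_sizes: ",
         paste(setdiff(names(gs), cohort_groups), collapse = ", "))
  if (any(gs < 0) || any(gs > 0 & gs < 2))
    stop("each present group needs at least 2 subjects")
  if (sum(gs) == 0) stop("group_sizes are all zero")
  if (cfg$nonhub_sd <= 0 || any(cfg$hub_targets[, -1] <= 0))
    stop("all strength SD/mean targets must be positive")
  w <- cfg$severity$w0 + cfg$severity$wll + cfg$severity$wdd
  if (any(abs(w - 1) > 1e-8) || any(cfg$severity < 0 & FALSE))
    stop("severity shares must sum to 1 within each group")
  if (any(cfg$severity[, -1] < 0))
    stop("severity shares must be nonnegative")
  if (!(cfg$thal_lat >= 0 && cfg$thal_lat <= 1) ||
      !(cfg$postc_lat >= 0 && cfg$postc_lat <= 1))
    stop("lateralisation fractions must lie in [0, 1]")
  if (!(cfg$fan_share >= 0 && cfg$fan_share < 1))
    stop("fan_share must lie in [0, 1)")
  if (any(cfg$dropout_factor < 0) || any(cfg$dropout_factor > 1))
    stop("dropout_factor must lie in [0, 1]")
  if (cfg$block_share <= 0 || cfg$block_share >= 1)
    stop("block_share must lie in (0, 1)")
  cfg
}

core_pairs <- c("precentral gyrus", "superior frontal gyrus",
                "middle frontal gyrus", "postcentral gyrus",
                "thalamus", "putamen")

#' Intended principal-network member sets of the generator
#'
#' The member sets the planted spectral core is designed to express:
#' PN1 = the eight fronto-parietal core regions plus both thalami;
#' PN2 = the same cortex plus the right thalamus and right putamen.
#' The generator uses them to couple the clinical scores to subnetwork
#' strengths; the analysis pipeline never reads them (membership must
#' emerge from the eigendecomposition).
#'
#' @return Named list with components `pn1` and `pn2` (character vectors).
#' @export
intended_pn_members <- function() {
  cortex <- as.vector(outer(c("Left", "Right"),
                            core_pairs[1:4], paste))
  list(pn1 = c(cortex, "Left thalamus", "Right thalamus"),
       pn2 = c(cortex, "Right thalamus", "Right putamen"))
}

group_strength_targets <- function(cfg, node_table, group) {
  ht <- cfg$hub_targets
  col <- paste0(tolower(group), "_mean")
  s <- rep(cfg$nonhub_mean, nrow(node_table))
  names(s) <- node_table$region_label
  s[ht$region] <- ht[[col]]
  s * cfg$unit
}

group_sd_targets <- function(cfg, node_table, group) {
  ht <- cfg$hub_targets
  col <- paste0(tolower(group), "_sd")
  s <- rep(cfg$nonhub_sd, nrow(node_table))
  names(s) <- node_table$region_label
  s[ht$region] <- ht[[col]]
  s * cfg$unit
}

# Symmetric iterative proportional fitting: rescale a symmetric nonnegative
# matrix so its row sums match `target`, by alternating sqrt row/column
# scalings. Stops at relative change < tol or max_iter sweeps.
sinkhorn_rowsums <- function(w, target, tol = 1e-10, max_iter = 500L) {
  for (it in seq_len(max_iter)) {
    rs <- rowSums(w)
    if (any(rs == 0 & target > 0))
      stop("background mask leaves a node with no edges")
    d <- sqrt(ifelse(rs > 0, target / rs, 1))
    w <- w * outer(d, d)
    err <- max(abs(rowSums(w) - target) / pmax(target, 1e-12))
    if (err < tol) break
  }
  if (err >= tol)
    warning("strength calibration stopped at relative error ", format(err))
  w
}

# Solve k >= 0 so the rank-one graph k k' (zero diagonal) has row sums q:
# k_i (S - k_i) = q_i with S = sum(k), via a root-solve on S taking the
# smaller branch per node (the larger branch is not a valid degree split).
solve_rank_one_degrees <- function(q) {
  branch <- function(S) (S - sqrt(pmax(S^2 - 4 * q, 0))) / 2
  gap <- function(S) sum(branch(S)) - S
  lo <- 2 * sqrt(max(q))
  if (gap(lo) < 0)
    stop("rank-one clique budgets are infeasible (one node dominates)")
  hi <- lo + sum(sqrt(q))
  while (gap(hi) > 0) hi <- hi * 2
  S <- stats::uniroot(gap, c(lo, hi), tol = 1e-12 * lo)$root
  branch(S)
}

#' Build a group-level template connectome
#'
#' Constructs the deterministic group template. The planted core covers the
#' ten fronto-parietal/thalamic regions: within each hemisphere the three
#' frontal core regions form a dense (rank-one) clique; the hemispheres
#' are bridged by homotopic edges; the postcentral gyri and thalami couple
#' onto the cliques following their strength profile, the left thalamus
#' symmetrically, the right thalamus with ipsilateral dominance and the
#' postcentral gyri with transcallosal dominance; and the right putamen
#' hangs off the right-lateralised circuit through a thalamo-striatal edge
#' plus weak right-cortical edges. Under homotopic coupling the two
#' cliques hybridise into a symmetric mode -- PN1, inter-hemispheric
#' dominant, containing both thalami -- and an antisymmetric mode -- PN2,
#' intra-hemispheric dominant, in which only the laterally asymmetric
#' subcortical/parietal nodes (right thalamus, right putamen, postcentral
#' pair) join the cortex. Every other left/right pair gets a homotopic
#' edge, the six non-core hub regions route part of their strength through
#' deterministic disjoint fans over their hemisphere's non-hub regions
#' (keeping the diffuse spectrum flat), and a diffuse background is fitted
#' by symmetric iterative proportional scaling so every node's strength
#' equals its group target to numerical tolerance (well inside 0.5%).
#' Dropout regions (right putamen in MS, right thalamus additionally in
#' SPMS) have their core edges attenuated, with the lost strength refilled
#' diffusely, so their PN membership loss must emerge from the
#' eigendecomposition rather than being written into it.
#'
#' @param cfg A `pnms_sim_config`.
#' @param node_table Node table containing the 18 hub labels.
#' @param group Group label.
#' @return Connectivity matrix (raw units) with attribute `core_nodes`.
#' @export
build_group_template <- function(cfg, node_table, group) {
  labels <- node_table$region_label
  n <- length(labels)
  missing <- setdiff(cfg$hub_targets$region, labels)
  if (length(missing))
    stop("node table lacks hub region(s): ", paste(missing, collapse = ", "))
  s <- group_strength_targets(cfg, node_table, group)

  core <- as.vector(t(outer(c("Left", "Right"), core_pairs, paste)))
  hub_regions <- cfg$hub_targets$region
  noncore_hub_pairs <- setdiff(unique(homotopic_base(hub_regions)),
                               core_pairs)

  # homotopic edges for every left/right pair; most of a region's
  # inter-hemispheric weight runs through its homotopic connection
  base <- homotopic_base(labels)
  pair_bases <- unique(base[node_table$hemisphere == "left"])
  pair_bases <- pair_bases[paste("Right", pair_bases) %in% labels]
  h <- numeric(length(pair_bases)); names(h) <- pair_bases
  for (p in pair_bases) {
    share <- if (p %in% names(cfg$homotopic_share))
      cfg$homotopic_share[[p]] else cfg$homotopic_share[["background"]]
    h[p] <- share * mean(s[paste(c("Left", "Right"), p)])
  }
  W <- matrix(0, n, n, dimnames = list(labels, labels))
  for (p in pair_bases)
    W[paste("Left", p), paste("Right", p)] <-
      W[paste("Right", p), paste("Left", p)] <- h[p]

  # dense intra-hemispheric frontal clique (rank-one, zero diag), solved
  # so each member's within-clique strength equals its core budget left
  # after the homotopic edge
  clique_regions <- core_pairs[1:3]
  for (hm in c("Left", "Right")) {
    nodes <- paste(hm, clique_regions)
    q <- pmax(cfg$block_share * s[nodes] - h[clique_regions],
              0.05 * s[nodes])
    k <- solve_rank_one_degrees(q)
    K <- tcrossprod(k); diag(K) <- 0
    W[nodes, nodes] <- K
  }

  # cortico-cortical / thalamo-cortical coupling of the remaining core
  # regions onto the frontal cliques, following each clique's strength
  # profile. The left thalamus splits evenly between hemispheres (so it
  # has no weight in the antisymmetric mode); the right thalamus is
  # ipsilaterally dominant and the postcentral gyri are transcallosally
  # dominant -- the lateralisation surpluses are what give these nodes
  # their antisymmetric-mode (PN2) loadings.
  coupled <- rbind(
    data.frame(node = paste(c("Left", "Right"), "postcentral gyrus"),
               base = "postcentral gyrus", ipsi = cfg$postc_lat),
    data.frame(node = "Left thalamus", base = "thalamus", ipsi = 0.5),
    data.frame(node = "Right thalamus", base = "thalamus",
               ipsi = cfg$thal_lat))
  for (r in seq_len(nrow(coupled))) {
    lab <- coupled$node[r]
    own_hm <- if (startsWith(lab, "Left")) "Left" else "Right"
    budget <- max(cfg$block_share * s[lab] - h[coupled$base[r]],
                  0.05 * s[lab])
    for (target_hm in c("Left", "Right")) {
      nodes <- paste(target_hm, clique_regions)
      side <- if (target_hm == own_hm) coupled$ipsi[r] else
        1 - coupled$ipsi[r]
      kprof <- W[nodes, nodes]
      kw <- rowSums(kprof) / sum(kprof)   # clique strength profile
      W[lab, nodes] <- W[nodes, lab] <- side * budget * kw
    }
  }

  # right putamen as a satellite of the right-lateralised circuit
  uu <- cfg$unit
  W["Right putamen", "Right thalamus"] <-
    W["Right thalamus", "Right putamen"] <- cfg$put_sat[["thalamus"]] * uu
  for (p in core_pairs[1:3]) {
    lab <- paste("Right", p)
    W["Right putamen", lab] <- W[lab, "Right putamen"] <-
      cfg$put_sat[["cortex"]] * uu
  }

  # group-specific attenuation of the dropout regions' core edges; their
  # strength deficit is refilled by the flat fan/background structure
  # below, so membership loss must emerge spectrally
  f <- rep(1, n); names(f) <- labels
  if (group %in% c("RRMS", "PPMS", "SPMS")) {
    gamma <- if (length(cfg$dropout_factor) > 1)
      cfg$dropout_factor[[group]] else cfg$dropout_factor
    f["Right putamen"] <- gamma
    if (group == "SPMS") f["Right thalamus"] <- gamma
  }
  W <- W * outer(f, f)

  # every hub spreads most of its remaining strength over a deterministic
  # fan to non-hub regions of its own hemisphere; disjoint partner sets
  # (round-robin) keep the fans spectrally flat: each fan is a star whose
  # top eigenvalue is only total_weight / sqrt(n_partners), so the diffuse
  # spectrum stays well below the planted modes
  fan_pairs <- c(noncore_hub_pairs, core_pairs)
  nonhub <- setdiff(labels, c(hub_regions, "Brainstem"))
  fan_centres <- as.vector(outer(c("Left", "Right"), fan_pairs, paste))
  n_partners <- 20L
  for (j in seq_along(fan_centres)) {
    lab <- fan_centres[j]
    idx <- ((j - 1L) * n_partners + seq(0, n_partners - 1L)) %%
      length(nonhub) + 1L
    partners <- nonhub[unique(idx)]
    fan_total <- min(cfg$fan_share * (s[lab] - sum(W[lab, ])),
                     cfg$fan_cap * cfg$unit)
    if (fan_total > 0)
      W[lab, partners] <- W[partners, lab] <-
        W[lab, partners] + fan_total / length(partners)
  }

  resid <- s - rowSums(W)
  if (any(resid < 0.02 * s))
    stop("infeasible strength targets for group ", group, ": node(s) ",
         paste(labels[resid < 0.02 * s], collapse = ", "),
         " exceed their budget under the core structure")

  ci <- match(core, labels)
  mask <- matrix(TRUE, n, n)
  mask[ci, ci] <- FALSE       # keep the planted core spectrum clean
  diag(mask) <- FALSE
  bg <- outer(resid, resid) / sum(resid)
  bg[!mask] <- 0
  bg <- sinkhorn_rowsums(bg, resid)
  W <- W + bg
  W <- validate_connectome(W, node_table)
  attr(W, "core_nodes") <- core
  W
}

# match a log-normal to a given mean and sd (both > 0)
lognormal_params <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# mean-one log-normal multiplier(s)
rlnorm1 <- function(n, sdlog) {
  if (sdlog <= 0) return(rep(1, n))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Per-node residual noise scale, solved so the across-subject SD of each
# node's strength matches its group target after accounting for the
# severity-mediated variance, the global scale factor and the edge noise.
# Floored at sigma_node_min when a printed SD target sits below the
# attainable noise floor.
node_noise_sd <- function(cfg, w_group, sd_target, s_target, m_var,
                          age_sd = 0) {
  delta <- attr(w_group, "delta_hc")      # template strength difference
  var_sev <- if (is.null(delta)) 0 else delta^2 * m_var
  v_edge <- exp(cfg$sigma_edge^2) - 1
  var_edge <- v_edge * rowSums(w_group^2)
  cv2 <- (sd_target^2 - var_sev - var_edge) / s_target^2 -
    cfg$sigma_global^2 - (cfg$age_slope * age_sd)^2 -
    (cfg$tiv_expon * 110 / 1465)^2
  sqrt(pmax(cv2, cfg$sigma_node_min^2))
}

#' Simulate one subject
#'
#' Draws a subject's connectivity matrix and record given the group
#' templates. The subject's template interpolates between the HC template
#' and the group template with a severity multiplier `m` (mean 1 within
#' group) composed of an unmediated share and shares proportional to the
#' subject's lesion load and disease duration; multiplicative log-normal
#' noise is then applied per node, per edge and globally. Clinical scores
#' are generated from the subject's true right-thalamus / right-putamen
#' subnetwork strengths (on the intended reference sets) plus covariate
#' effects and Gaussian noise; EDSS is rounded to the 0.5 grid and clipped
#' to [0, 10], SDMT rounded to a nonnegative integer.
#'
#' @param cfg A `pnms_sim_config`.
#' @param templates Named list of group templates from
#'   [build_group_template()], including `HC`.
#' @param group Group of the subject.
#' @param subject_id Identifier.
#' @param sigma_node Per-node noise scales for this group (from the
#'   internal calibration; see [simulate_cohort()]).
#' @param group_ref Named list of the subject group's expected subnetwork
#'   strengths (`st1`, `st2`, `sp2`, raw units, from the group template);
#'   clinical scores couple to the subject's deviation from them, so the
#'   group-level score distributions stay at their configured centres.
#' @return List with `record` (one-row manifest data frame) and `weights`.
#' @export
simulate_subject <- function(cfg, templates, group, subject_id,
                             sigma_node, group_ref) {
  demo <- cfg$demographics[cfg$demographics$group == group, ]
  age <- min(max(stats::rnorm(1, demo$age_mean, demo$age_sd), 18), 85)
  sex <- if (stats::runif(1) < demo$prop_female) "F" else "M"
  is_ms <- group != "HC"
  if (is_ms) {
    llp <- lognormal_params(demo$lesion_load_mean, demo$lesion_load_sd)
    ddp <- lognormal_params(demo$duration_mean, demo$duration_sd)
    lesion_load <- stats::rlnorm(1, llp[1], llp[2])
    duration <- stats::rlnorm(1, ddp[1], ddp[2])
    sev <- cfg$severity[cfg$severity$group == group, ]
    m <- sev$w0 + sev$wll * lesion_load / demo$lesion_load_mean +
      sev$wdd * duration / demo$duration_mean
    m <- min(max(m, 0), 2)
  } else {
    lesion_load <- NA_real_; duration <- NA_real_; m <- 0
  }
  tiv_mean <- if (sex == "M") 1550 else 1380
  tiv <- stats::rnorm(1, tiv_mean, 110)

  tmpl <- templates$HC + m * (templates[[group]] - templates$HC)
  tmpl[tmpl < 0] <- 0
  cov_factor <- max(1 + cfg$age_slope * (age - demo$age_mean), 0.5) *
    (tiv / tiv_mean)^cfg$tiv_expon
  n <- nrow(tmpl)
  fnode <- exp(stats::rnorm(n, -sigma_node^2 / 2, sigma_node))
  g <- cov_factor * rlnorm1(1, cfg$sigma_global)
  e <- matrix(0, n, n)
  ut <- upper.tri(e)
  e[ut] <- rlnorm1(sum(ut), cfg$sigma_edge)
  e <- e + t(e)
  w <- g * tmpl * outer(fnode, fnode) * e
  diag(w) <- 0
  dimnames(w) <- dimnames(tmpl)

  ref <- intended_pn_members()
  st1 <- nodal_strength(extract_subnetwork(w, ref$pn1))[["Right thalamus"]]
  st2 <- nodal_strength(extract_subnetwork(w, ref$pn2))[["Right thalamus"]]
  sp2 <- nodal_strength(extract_subnetwork(w, ref$pn2))[["Right putamen"]]
  cl <- cfg$clinical
  u <- cfg$unit
  if (is_ms) {
    lp <- cl$edss_base[[group]] +
      cl$beta_thal_pn1_edss * (st1 - group_ref$st1) / u +
      cl$beta_put_pn2_edss * (sp2 - group_ref$sp2) / u +
      cl$beta_age_edss * (age - demo$age_mean) +
      stats::rnorm(1, 0, cl$edss_sd)
    edss <- min(max(round(lp * 2) / 2, 0), 10)
  } else edss <- NA_real_
  sd_lp <- cl$sdmt_base[[group]] +
    cl$beta_thal_pn2_sdmt * (st2 - group_ref$st2) / u +
    cl$beta_put_pn2_sdmt * (sp2 - group_ref$sp2) / u +
    cl$beta_age_sdmt * (age - demo$age_mean) +
    stats::rnorm(1, 0, cl$sdmt_sd)
  sdmt <- max(round(sd_lp), 0)
  dgm <- 62 - 2 * (group_ref$st1_hc - st1) / u + stats::rnorm(1, 0, 3)

  record <- data.frame(subject_id = subject_id, group = group,
                       age = round(age, 1), sex = sex,
                       disease_duration = if (is_ms) round(duration, 1) else NA,
                       lesion_load = if (is_ms) round(lesion_load, 2) else NA,
                       tiv = round(tiv), dgm_volume = round(dgm, 1),
                       edss = edss, sdmt = sdmt)
  list(record = record, weights = w)
}

#' Simulate a full cohort
#'
#' Builds the four group templates, calibrates the per-node noise scales
#' against the strength SD targets, and draws every subject with a
#' deterministic per-subject seed: each group gets its own seed stream
#' derived from the root seed and the group index, and subject k uses the
#' k-th value of that stream. The same seed and configuration therefore
#' reproduce the identical cohort bit for bit, and changing one group's
#' size leaves the other groups' draws untouched.
#'
#' @param cfg A `pnms_sim_config`.
#' @param node_table Node table (default the packaged 115-region table).
#' @return A `pnms_cohort` with attributes `templates` (named list of group
#'   templates) and `config`.
#' @export
simulate_cohort <- function(cfg = sim_config(),
                            node_table = default_node_table()) {
  cfg <- validate_sim_config(cfg)
  groups <- names(cfg$group_sizes)[cfg$group_sizes > 0]
  templates <- lapply(stats::setNames(nm = union("HC", groups)),
                      function(g) build_group_template(cfg, node_table, g))
  ref <- intended_pn_members()
  subnet_refs <- function(w) list(
    st1 = nodal_strength(extract_subnetwork(w, ref$pn1))[["Right thalamus"]],
    st2 = nodal_strength(extract_subnetwork(w, ref$pn2))[["Right thalamus"]],
    sp2 = nodal_strength(extract_subnetwork(w, ref$pn2))[["Right putamen"]])
  group_refs <- lapply(templates, subnet_refs)
  st1_hc <- group_refs$HC$st1

  demo <- cfg$demographics
  records <- list(); matrices <- list()
  for (g in groups) {
    gi <- match(g, cohort_groups) - 1L
    w_g <- templates[[g]]
    attr(w_g, "delta_hc") <- nodal_strength(templates$HC) -
      nodal_strength(w_g)
    d <- demo[demo$group == g, ]
    sev <- cfg$severity[cfg$severity$group == g, ]
    m_var <- if (g == "HC") 0 else
      sev$wll^2 * (d$lesion_load_sd / d$lesion_load_mean)^2 +
      sev$wdd^2 * (d$duration_sd / d$duration_mean)^2
    sigma_node <- node_noise_sd(cfg, w_g,
                                group_sd_targets(cfg, node_table, g),
                                group_strength_targets(cfg, node_table, g),
                                m_var, age_sd = d$age_sd)
    set.seed(cfg$seed * 101L + gi)
    subj_seeds <- sample.int(.Machine$integer.max - 1L,
                             cfg$group_sizes[[g]])
    for (k in seq_len(cfg$group_sizes[[g]])) {
      set.seed(subj_seeds[k])
      sid <- sprintf("%s%03d", tolower(g), k)
      gr <- group_refs[[g]]
      gr$st1_hc <- st1_hc
      subj <- simulate_subject(cfg, templates, g, sid, sigma_node, gr)
      records[[sid]] <- subj$record
      matrices[[sid]] <- subj$weights
    }
  }
  manifest <- do.call(rbind, records)
  out <- cohort(node_table, manifest, matrices)
  attr(out, "templates") <- templates
  attr(out, "config") <- cfg
  out
}
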