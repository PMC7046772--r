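test_that("configuration validation rejects inconsistent settings", {
  expect_error(sim_config(group_sizes = c(HC = 1)), "at least 2")
  expect_error(sim_config(group_sizes = c(HC = 0L, RRMS = 0L,
                                          PPMS = 0L, SPMS = 0L)), "zero")
  expect_error(sim_config(severity_w0 = 0.9, severity_wll = 0.3,
                          severity_wdd = 0.3), "sum to 1")
  expect_error(sim_config(dropout_factor = 1.5), "dropout_factor")
  expect_error(sim_config(block_share = 1.2), "block_share")
  expect_error(sim_config(thal_lat = 2), "lateralisation")
})

test_that("group templates hit every strength target within 0.5%", {
  nt <- default_node_table()
  cfg <- sim_config()
  for (g in c("HC", "SPMS")) {
    w <- build_group_template(cfg, nt, g)
    target <- pnms:::group_strength_targets(cfg, nt, g)
    expect_lt(max(abs(nodal_strength(w) - target) / target), 0.005)
    expect_silent(validate_connectome(w, nt))
  }
  # degenerate mixing: all strength on the diffuse background is rejected
  # only when budgets cannot be met; an over-tight block share errors
  cfg_bad <- sim_config(block_share = 0.95)
  expect_error(build_group_template(cfg_bad, nt, "HC"), "infeasible")
})

test_that("same seed reproduces the cohort bit for bit; group streams are independent", {
  cfg <- sim_config(seed = 42, group_sizes = c(HC = 4L, RRMS = 3L))
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$matrices, b$matrices)

  # growing one group leaves the other group's draws untouched
  cfg2 <- sim_config(seed = 42, group_sizes = c(HC = 4L, RRMS = 6L))
  c2 <- simulate_cohort(cfg2)
  for (sid in group_subjects(a, "HC")) {
    expect_identical(c2$matrices[[sid]], a$matrices[[sid]])
  }
  expect_identical(
    a$manifest[a$manifest$group == "HC", ],
    c2$manifest[c2$manifest$group == "HC", ])
})

test_that("with noise scales at zero every subject equals the group template", {
  cfg <- sim_config(seed = 5, group_sizes = c(HC = 3L),
                    sigma_edge = 0, sigma_global = 0,
                    sigma_node_min = 1e-12, tiv_expon = 0)
  cfg$hub_targets[, grep("_sd$", names(cfg$hub_targets))] <- 1e-9
  cfg$nonhub_sd <- 1e-9
  coh <- simulate_cohort(cfg)
  tmpl <- attr(coh, "templates")$HC
  for (m in coh$matrices)
    expect_lt(max(abs(m - tmpl)) / max(tmpl), 1e-5)
})

test_that("small cohorts are valid and MS-only stages refuse an HC-only cohort", {
  coh <- simulate_cohort(sim_config(seed = 3, group_sizes = c(HC = 3L)))
  expect_equal(nrow(coh$manifest), 3)
  for (m in coh$matrices) expect_silent(validate_connectome(m))
  gm <- group_mean_matrix(coh, "HC")
  pn1 <- suppressWarnings(pn_decompose(gm, 0.1, 1))[[1]]
  ss <- subnetwork_nodal_strength(coh, pn1)
  expect_error(clinical_association(coh, "edss", ss, pn1$members[1]),
               "complete cases")
  expect_error(compare_hub_strength(coh, pn1$members[1], "SPMS"),
               "no subjects")
})

test_that("empirical strengths converge to the targets as the group grows", {
  errs <- sapply(c(20L, 100L, 400L), function(n) {
    coh <- simulate_cohort(sim_config(seed = 11, group_sizes = c(HC = n)))
    ss <- subject_strengths(coh)
    emp <- colMeans(ss[, -(1:2)])
    target <- pnms:::group_strength_targets(sim_config(),
                                            coh$node_table, "HC")
    mean(abs(emp - target) / target)
  })
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], errs[2])
})

test_that("default cohort has the study's size, demographics and score ranges", {
  coh <- cached_cohort(1)
  expect_equal(nrow(coh$manifest), 173)
  expect_equal(as.vector(table(coh$manifest$group)), c(51, 58, 28, 36))
  man <- coh$manifest
  expect_true(all(is.na(man$edss[man$group == "HC"])))
  expect_true(all(man$edss >= 0 & man$edss <= 10, na.rm = TRUE))
  expect_true(all(man$edss %% 0.5 == 0, na.rm = TRUE))
  expect_true(all(man$sdmt >= 0 & man$sdmt == round(man$sdmt), na.rm = TRUE))
  expect_true(all(is.na(man$lesion_load[man$group == "HC"])))
  expect_true(all(man$lesion_load > 0, na.rm = TRUE))
  # subject-level noise produces matching across-subject SD scales: the
  # right thalamus SD target is 0.15e5 in HC
  ss <- subject_strengths(coh, "Right thalamus")
  hc_sd <- stats::sd(ss[ss$group == "HC", "Right thalamus"])
  expect_gt(hc_sd, 0.15e5 * 0.6)
  expect_lt(hc_sd, 0.15e5 * 1.4)
})
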