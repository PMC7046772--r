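test_that("nodal strength is the row sum and conserves total edge weight", {
  labs <- paste0("r", 1:3)
  m <- matrix(c(0, 1, 2, 1, 0, 4, 2, 4, 0), 3, dimnames = list(labs, labs))
  expect_equal(unname(nodal_strength(m)), c(3, 5, 6))

  m2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(labs[1:2], labs[1:2]))
  expect_equal(unname(nodal_strength(m2)), c(3, 3))
  expect_equal(nodal_strength(m2 * 0), c(r1 = 0, r2 = 0))

  for (i in 1:5) {
    m3 <- toy_matrix(paste0("r", 1:10), seed = i)
    expect_equal(sum(nodal_strength(m3)), 2 * sum(m3[upper.tri(m3)]),
                 tolerance = 1e-9)
  }
})

test_that("group-mean matrices average entrywise and stay valid", {
  nt <- toy_node_table(4)
  coh <- toy_cohort(c("HC", "HC", "RRMS"), node_table = nt)
  single <- group_mean_matrix(coh, "RRMS")
  expect_identical(single, coh$matrices[["s03"]])

  labs <- nt$region_label
  m1 <- toy_matrix(labs, fill = 2); m2 <- toy_matrix(labs, fill = 4)
  man <- toy_manifest(c("HC", "HC"))
  coh2 <- cohort(nt, man, list(s01 = m1, s02 = m2))
  expect_equal(group_mean_matrix(coh2, "HC"), toy_matrix(labs, fill = 3))

  expect_error(group_mean_matrix(coh, "SPMS"), "no subjects")

  # mean of random valid matrices passes validation
  mats <- lapply(1:6, function(i) toy_matrix(labs, seed = i))
  names(mats) <- sprintf("s%02d", 1:6)
  coh3 <- cohort(nt, toy_manifest(rep("HC", 6)), mats)
  expect_silent(validate_connectome(group_mean_matrix(coh3, "HC"), nt))
})

test_that("hub criterion matches hand computation, flags degeneracy, and agrees with a brute-force oracle", {
  s <- c(n1 = 1, n2 = 1, n3 = 1, n4 = 5)
  rep1 <- detect_hubs(s)
  expect_equal(rep1$threshold, 4)
  expect_equal(rep1$hubs, "n4")
  expect_false(rep1$degenerate)

  s2 <- c(a = 10, b = 10, c = 10, d = 10)
  rep2 <- detect_hubs(s2)
  expect_equal(rep2$threshold, 10)
  expect_equal(rep2$hubs, names(s2))
  expect_true(rep2$degenerate)

  expect_error(detect_hubs(c(a = 1)), "at least 2")

  brute <- function(s) {
    mu <- sum(s) / length(s)
    sigma <- sqrt(sum((s - mu)^2) / (length(s) - 1))
    names(s)[s >= mu + sigma]
  }
  set.seed(7)
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    s <- stats::setNames(stats::rexp(n, rate = 1 / 5), paste0("n", 1:n))
    expect_identical(detect_hubs(s)$hubs, brute(s))
  }
})

test_that("hub detection is permutation-equivariant and scale-covariant", {
  set.seed(11)
  s <- stats::setNames(stats::runif(20, 1, 9), paste0("n", 1:20))
  perm <- sample(20)
  expect_setequal(detect_hubs(s[perm])$hubs, detect_hubs(s)$hubs)
  for (c in c(0.25, 7)) {
    scaled <- detect_hubs(s * c)
    expect_equal(scaled$threshold, detect_hubs(s)$threshold * c)
    expect_identical(scaled$hubs, detect_hubs(s)$hubs)
  }
})

test_that("noiseless planted attenuation is recovered exactly by the adjusted comparison", {
  nt <- toy_node_table(4)
  base <- toy_matrix(nt$region_label, seed = 3)
  coh <- toy_cohort(rep(c("HC", "SPMS"), each = 6), node_table = nt,
                    base = base, deltas = list(SPMS = c(region2 = 0.5)))
  # covariates need within-sample variation for a full-rank design
  set.seed(9)
  coh$manifest$tiv <- stats::rnorm(12, 1450, 90)
  ms <- coh$manifest$group == "SPMS"
  coh$manifest$lesion_load[ms] <- stats::runif(6, 5, 25)
  coh$manifest$disease_duration[ms] <- stats::runif(6, 5, 25)
  res <- suppressWarnings(compare_hub_strength(coh, "region2", "SPMS"))
  planted <- sum(base["region2", ]) -
    sum((base * outer(c(1, 0.5, 1, 1), c(1, 0.5, 1, 1)))["region2", ])
  expect_equal(res$coefficient, -planted, tolerance = 1e-8)
  expect_lt(res$p_value, 1e-12)
  expect_true(res$significant_reduction)
})

test_that("the adjusted comparison keeps its nominal false-positive rate", {
  nt <- toy_node_table(3)
  base <- toy_matrix(nt$region_label, fill = 5)
  groups <- rep(c("HC", "RRMS"), each = 15)
  set.seed(202)
  rejections <- 0; nrep <- 1000
  for (i in seq_len(nrep)) {
    mats <- lapply(seq_along(groups), function(j)
      base * exp(stats::rnorm(1, 0, 0.1)))
    names(mats) <- sprintf("s%02d", seq_along(groups))
    man <- toy_manifest(groups)
    man$age <- stats::rnorm(30, 45, 10)
    man$disease_duration[groups != "HC"] <- stats::rexp(15, 1 / 10)
    man$lesion_load[groups != "HC"] <- stats::rexp(15, 1 / 12)
    man$tiv <- stats::rnorm(30, 1450, 100)
    coh <- cohort(nt, man, mats)
    res <- compare_hub_strength(coh, "region1", "RRMS")
    if (res$p_value < 0.05) rejections <- rejections + 1
  }
  expect_gt(rejections / nrep, 0.03)
  expect_lt(rejections / nrep, 0.07)
})
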