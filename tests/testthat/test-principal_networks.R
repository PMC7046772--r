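test_that("closed-form decompositions match: single edge and two triangles", {
  labs <- c("a", "b")
  m <- matrix(c(0, 1, 1, 0), 2, dimnames = list(labs, labs))
  pns <- pn_decompose(m, tau = 0.1, n_components = 2)
  expect_equal(pns[[1]]$eigenvalue, 1)
  expect_equal(pns[[2]]$eigenvalue, -1)
  expect_equal(unname(pns[[1]]$loadings), c(1, 1) / sqrt(2), tolerance = 1e-6)
  expect_setequal(pns[[1]]$members, labs)
  expect_true(pns[[2]]$negative_eigenvalue)

  # two disconnected triangles, edge weights 4 and 2: triangle adjacency
  # eigenvalues are {2w, -w, -w}
  labs6 <- c("A1", "A2", "A3", "B1", "B2", "B3")
  tri <- matrix(0, 6, 6, dimnames = list(labs6, labs6))
  tri[1:3, 1:3] <- 4; tri[4:6, 4:6] <- 2; diag(tri) <- 0
  pns6 <- pn_decompose(tri, tau = 0.1, n_components = 2)
  expect_equal(pns6[[1]]$eigenvalue, 8)
  expect_setequal(pns6[[1]]$members, c("A1", "A2", "A3"))
  expect_equal(unname(pns6[[1]]$loadings[1:3]), rep(1 / sqrt(3), 3),
               tolerance = 1e-6)
  expect_equal(pns6[[2]]$eigenvalue, 4)
  expect_setequal(pns6[[2]]$members, c("B1", "B2", "B3"))
})

test_that("a weakly attached pendant stays below the loading threshold", {
  labs <- c("c1", "c2", "c3", "pendant")
  m <- matrix(0, 4, 4, dimnames = list(labs, labs))
  m[1:3, 1:3] <- 10; diag(m) <- 0
  m["c1", "pendant"] <- m["pendant", "c1"] <- 0.01
  pn1 <- pn_decompose(m, tau = 0.1, n_components = 1)[[1]]
  expect_setequal(pn1$members, c("c1", "c2", "c3"))
  expect_lt(abs(pn1$loadings["pendant"]), 0.1)
})

test_that("the leading eigenpair matches an independent power-iteration oracle", {
  set.seed(5)
  for (i in 1:5) {
    m <- toy_matrix(paste0("r", 1:20), seed = i)
    pn1 <- pn_decompose(m, n_components = 1)[[1]]
    oracle <- power_iteration(m)
    expect_equal(pn1$eigenvalue, oracle$value,
                 tolerance = 1e-8 * abs(oracle$value))
    expect_lt(min(max(abs(pn1$loadings - oracle$vector)),
                  max(abs(pn1$loadings + oracle$vector))), 1e-6)
  }
})

test_that("eigenvectors are orthonormal and the full set reconstructs the matrix", {
  m <- toy_matrix(paste0("r", 1:12), seed = 9)
  pns <- pn_decompose(m, n_components = 12)
  v <- sapply(pns, function(p) p$loadings)
  expect_lt(max(abs(crossprod(v) - diag(12))), 1e-10)
  rec <- pn_reconstruct(m, pns)
  expect_lt(norm(rec - m, "F") / norm(m, "F"), 1e-8)

  # reconstruction error is non-increasing in retained components
  # (accumulate the raw spectral terms; the spectral theorem gives
  # monotone Frobenius error sqrt(sum of dropped eigenvalues squared))
  acc <- 0 * m
  errs <- sapply(1:12, function(k) {
    p <- pns[[k]]
    acc <<- acc + p$eigenvalue * tcrossprod(p$loadings)
    norm(acc - m, "F")
  })
  expect_true(all(diff(errs) <= 1e-8 * norm(m, "F")))

  # rank-one input: PN1 alone reconstructs the off-diagonal entries
  x <- stats::runif(6, 1, 2)
  r1 <- tcrossprod(x); diag(r1) <- 0
  dimnames(r1) <- list(paste0("q", 1:6), paste0("q", 1:6))
  # restoring the diagonal makes it exactly rank one
  diag(r1) <- x^2
  p1 <- pn_decompose(r1, n_components = 1)
  rec1 <- pn_reconstruct(r1, p1)
  off <- upper.tri(r1)
  expect_equal(rec1[off], r1[off], tolerance = 1e-8)
})

test_that("sign fixing, scaling invariance and relabelling behave as documented", {
  m <- toy_matrix(paste0("r", 1:9), seed = 13)
  pns <- pn_decompose(m, n_components = 3)
  for (p in pns) {
    imax <- which.max(abs(p$loadings))
    expect_gt(p$loadings[imax], 0)
  }
  scaled <- pn_decompose(m * 37.5, n_components = 3)
  for (k in 1:3) {
    expect_equal(scaled[[k]]$loadings, pns[[k]]$loadings, tolerance = 1e-10)
    expect_identical(scaled[[k]]$members, pns[[k]]$members)
  }
  perm <- sample(9)
  pperm <- pn_decompose(m[perm, perm], n_components = 3)
  for (k in 1:3)
    expect_setequal(pperm[[k]]$members, pns[[k]]$members)
})

test_that("PN1 membership recovers a planted dominant block", {
  set.seed(31)
  for (i in 1:20) {
    n <- 30; block <- paste0("r", 1:6)
    labs <- paste0("r", 1:n)
    m <- toy_matrix(labs, seed = 100 + i)        # background in (0, 10)
    ratio <- stats::runif(1, 10, 30)
    m[block, block] <- 10 * ratio
    diag(m) <- 0
    pn1 <- pn_decompose(m, tau = 0.1, n_components = 1)[[1]]
    expect_setequal(pn1$members, block)
  }
})

test_that("input validation and membership comparison work", {
  m <- toy_matrix(paste0("r", 1:4), seed = 2)
  expect_error(pn_decompose(m, tau = 1.5), "tau")
  expect_error(pn_decompose(m, n_components = 9), "n_components")
  asym <- m; asym[1, 2] <- asym[1, 2] * 2
  expect_error(pn_decompose(asym), "symmetric")

  pns_a <- pn_decompose(m, n_components = 2)
  cmp <- pn_membership_comparison(list(HC = pns_a, RRMS = pns_a))
  expect_true(all(cmp$lost == "" & cmp$gained == ""))

  m2 <- m; m2["r1", ] <- m2["r1", ] * 0.01; m2[, "r1"] <- m2[, "r1"] * 0.01
  pns_b <- pn_decompose(m2, n_components = 2)
  cmp2 <- pn_membership_comparison(list(HC = pns_a, SPMS = pns_b))
  expect_true(any(grepl("r1", cmp2$lost)) || any(nchar(cmp2$gained) > 0) ||
                any(nchar(cmp2$lost) > 0))

  pns_c <- pn_decompose(m, tau = 0.2, n_components = 2)
  expect_error(pn_membership_comparison(list(HC = pns_a, X = pns_c)),
               "threshold")
})

test_that("edge composition splits member-member weight by hemisphere", {
  nt <- data.frame(region_label = c("Left X", "Right X", "Left Y", "Brainstem"),
                   hemisphere = c("left", "right", "left", "midline"),
                   lobe = "frontal", node_class = "cortical")
  labs <- nt$region_label
  m <- matrix(0, 4, 4, dimnames = list(labs, labs))
  m["Left X", "Right X"] <- m["Right X", "Left X"] <- 2
  fake_pn <- structure(list(members = c("Left X", "Right X")),
                       class = "pnms_pn")
  ec <- edge_composition(m, fake_pn, nt)
  expect_equal(ec$inter_fraction, 1)
  expect_equal(ec$homotopic_pairs, 1)

  m2 <- m; m2["Left X", "Right X"] <- m2["Right X", "Left X"] <- 0
  m2["Left X", "Left Y"] <- m2["Left Y", "Left X"] <- 3
  fake2 <- structure(list(members = c("Left X", "Left Y")), class = "pnms_pn")
  ec2 <- edge_composition(m2, fake2, nt)
  expect_equal(ec2$intra_fraction, 1)
  expect_equal(ec2$homotopic_pairs, 0)
})
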