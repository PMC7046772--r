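test_that("matrix TSV round-trips bit-exactly and the smallest valid matrix reads", {
  nt <- toy_node_table(2)
  m <- matrix(c(0, 5, 5, 0), 2,
              dimnames = list(nt$region_label, nt$region_label))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_connectome_matrix(m, path)
  got <- read_connectome_matrix(path, nt)
  expect_identical(got[, ], m[, ])

  m2 <- toy_matrix(paste0("region", 1:7), seed = 42) * pi
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_connectome_matrix(m2, path2)
  got2 <- read_connectome_matrix(path2)
  expect_identical(got2[, ], m2[, ])
})

test_that("matrix validation enforces sign, symmetry, labels and diagonal", {
  nt <- toy_node_table(3)
  m <- toy_matrix(nt$region_label, seed = 1)
  neg <- m; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(validate_connectome(neg), "negative")

  asym <- m; asym[1, 2] <- asym[1, 2] + max(m)
  expect_error(validate_connectome(asym), "asymmetry")

  tiny <- m
  tiny[1, 2] <- tiny[1, 2] + 1e-12 * max(m)
  fixed <- validate_connectome(tiny)
  expect_identical(fixed, t(fixed))

  withdiag <- m; diag(withdiag) <- 3
  expect_warning(out <- validate_connectome(withdiag), "diagonal")
  expect_true(all(diag(out) == 0))

  perm <- m[c(2, 1, 3), c(2, 1, 3)]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_connectome_matrix(perm, path)
  expect_error(read_connectome_matrix(path, nt), "region2.*region1")

  expect_error(validate_connectome(m[, 1:2, drop = FALSE]), "square")
  expect_error(validate_connectome(m, toy_node_table(5)), "dimension")
})

test_that("manifest parsing types records and preserves missingness", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,group,age,sex,disease_duration,lesion_load,tiv,dgm_volume,edss,sdmt",
               "s1,HC,41,F,,,1450,190,,",
               "s2,RRMS,50,M,12,8.5,1500,60,4.5,48"), path)
  man <- read_cohort_manifest(path)
  expect_equal(nrow(man), 2)
  expect_true(is.na(man$edss[1]) && is.na(man$disease_duration[1]))
  expect_equal(man$edss[2], 4.5)
  expect_s3_class(man$group, "factor")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,group,age,sex,disease_duration,lesion_load,tiv,dgm_volume,edss,sdmt",
               "s1,HC,41,F,,,1450,190,,",
               "s1,HC,44,M,,,1500,195,,"), dup)
  expect_error(read_cohort_manifest(dup), "duplicate")

  badgrp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,group,age,sex,disease_duration,lesion_load,tiv,dgm_volume,edss,sdmt",
               "s1,CIS,41,F,,,1450,190,,"), badgrp)
  expect_error(read_cohort_manifest(badgrp), "group")

  badedss <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,group,age,sex,disease_duration,lesion_load,tiv,dgm_volume,edss,sdmt",
               "s1,RRMS,41,F,5,3,1450,60,11,40"), badedss)
  expect_error(read_cohort_manifest(badedss), "EDSS")
})

test_that("manifest with the study group sizes yields 173 typed records", {
  groups <- rep(c("HC", "RRMS", "PPMS", "SPMS"), c(51, 58, 28, 36))
  man <- toy_manifest(groups, ids = sprintf("s%03d", seq_along(groups)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_manifest(man, path)
  got <- read_cohort_manifest(path)
  expect_equal(nrow(got), 173)
  expect_equal(as.vector(table(got$group)), c(51, 58, 28, 36))
})

test_that("cohorts validate jointly and survive a write/read round trip", {
  nt <- toy_node_table(5)
  coh <- toy_cohort(c("HC", "HC", "RRMS"), node_table = nt)
  expect_s3_class(coh, "pnms_cohort")
  expect_equal(group_subjects(coh, "HC"), c("s01", "s02"))
  expect_equal(group_subjects(coh, "MS"), "s03")

  # permuting manifest rows yields the same cohort up to subject order
  perm <- coh$manifest[c(3, 1, 2), ]
  coh2 <- cohort(nt, perm, coh$matrices)
  expect_setequal(names(coh2$matrices), names(coh$matrices))
  expect_identical(coh2$matrices[["s02"]], coh$matrices[["s02"]])

  expect_error(cohort(nt, coh$manifest, coh$matrices[1:2]), "match")

  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_identical(back$matrices[["s01"]][, ], coh$matrices[["s01"]][, ])
  expect_equal(back$manifest$age, coh$manifest$age)
})

test_that("the packaged node table has 115 uniquely labelled regions", {
  nt <- default_node_table()
  expect_equal(nrow(nt), 115)
  expect_false(anyDuplicated(nt$region_label) > 0)
  expect_setequal(unique(nt$hemisphere), c("left", "right", "midline"))
  # all 18 hub calibration regions are present
  expect_true(all(hub_strength_reference()$region %in% nt$region_label))
  # homotopic pairing: every left label has a right twin
  left <- nt$region_label[nt$hemisphere == "left"]
  expect_true(all(paste("Right", homotopic_base(left)) %in% nt$region_label))
})
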