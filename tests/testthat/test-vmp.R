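# VMP module: difference matrix, group medians, threshold partition,
# exceedance, feature summaries

test_that("abs_diff_matrix computes orientation-free intrapair differences", {
  d <- make_design(1, 2, 1)
  vals <- matrix(0.5, 2, nrow(d))
  b <- make_beta(vals, d)
  m <- unclass(b)
  m["cg00000001", c("C1_1", "C1_2")] <- c(0.30, 0.42)
  b <- beta_matrix(m)
  adm <- abs_diff_matrix(b, d)
  expect_equal(adm["cg00000001", "C1"], 0.12)
  expect_equal(adm["cg00000002", "C1"], 0)          # identical twins
  expect_equal(attr(adm, "pair_groups"), c("concordant", "discordant", "discordant", "healthy"))

  # swapping twin order in the sheet leaves the matrix unchanged
  df <- as.data.frame(d)
  i <- which(df$pair_id == "C1"); df[i, "sample_id"] <- rev(df[i, "sample_id"])
  expect_equal(unclass(abs_diff_matrix(b, twin_design(df))), unclass(adm))

  b_small <- beta_matrix(m[, -1, drop = FALSE])
  err <- expect_error(abs_diff_matrix(b_small, d), class = "tm_validation_error")
  expect_match(conditionMessage(err), "C1")
})

test_that("group medians follow the order-statistic definition", {
  d <- make_design(4, 3, 1)
  vals <- matrix(0.5, 1, nrow(d), dimnames = list("p", d$sample_id))
  # concordant pair diffs (0.02, 0.08, 0.12, 0.40); discordant (0.1, 0.2, 0.9)
  conc <- c(0.02, 0.08, 0.12, 0.40)
  for (i in 1:4) vals["p", paste0("C", i, "_1")] <- 0.5 + conc[i]
  disc <- c(0.1, 0.2, 0.9)
  for (i in 1:3) vals["p", paste0("D", i, "_1")] <- pmin(0.5 + disc[i], 1)
  vals["p", "D3_1"] <- 1; vals["p", "D3_2"] <- 0.1  # |diff| = 0.9
  vals["p", "H1_1"] <- 0.57                         # single-pair group
  b <- beta_matrix(vals)
  gm <- group_medians(abs_diff_matrix(b, d))
  expect_equal(gm["p", "concordant"], 0.10)  # mean of central pair (even size)
  expect_equal(gm["p", "discordant"], 0.2)   # outlier-insensitive
  expect_equal(gm["p", "healthy"], 0.07)     # single pair passes through
})

test_that("classify_vmps labels exclusivity per the thresholded indicators", {
  gm <- matrix(c(0.12, 0.05, 0.02,
                 0.12, 0.11, 0.03,
                 0.09, 0.09, 0.09,
                 0.02, 0.15, 0.01,
                 0.10, 0.10, 0.10),
               ncol = 3, byrow = TRUE,
               dimnames = list(paste0("p", 1:5), c("concordant", "discordant", "healthy")))
  cls <- classify_vmps(gm)
  expect_equal(cls$classification$exclusivity,
               c("concordant-only", "shared", "none", "discordant-only", "shared"))
  expect_equal(unname(cls$counts[c("concordant-only", "discordant-only",
                                   "healthy-only", "concordant+discordant",
                                   "all-three", "none")]),
               c(1L, 1L, 0L, 1L, 1L, 1L))
  expect_error(classify_vmps(gm, threshold = 0), class = "tm_validation_error")
  expect_error(classify_vmps(gm, threshold = 1), class = "tm_validation_error")
})

test_that("exclusive/shared/none labels always partition the probes", {
  set.seed(31)
  for (i in 1:50) {
    gm <- matrix(runif(60, 0, 0.2), ncol = 3,
                 dimnames = list(paste0("p", 1:20),
                                 c("concordant", "discordant", "healthy")))
    cls <- classify_vmps(gm)
    ind <- gm >= 0.1
    lab <- cls$classification$exclusivity
    expect_equal(lab == "none", rowSums(ind) == 0, ignore_attr = TRUE)
    expect_equal(lab == "shared", rowSums(ind) >= 2, ignore_attr = TRUE)
    for (g in c("concordant", "discordant", "healthy")) {
      expect_equal(lab == paste0(g, "-only"),
                   rowSums(ind) == 1 & ind[, g], ignore_attr = TRUE)
    }
    expect_equal(sum(cls$counts), nrow(gm))
  }
})

test_that("exceedance_fraction counts inclusively and reports the ratio", {
  d <- make_design(1, 2, 1)
  b <- make_beta(matrix(0.5, 10, nrow(d)), d)
  adm <- abs_diff_matrix(b, d)
  expect_equal(exceedance_fraction(adm)$fraction, 0)

  # 1 of 50 cells at exactly the threshold counts (inclusive comparison)
  adm2 <- structure(matrix(c(0.10, rep(0, 49)), nrow = 25),
                    pair_groups = c("a", "b"), class = c("abs_diff_matrix", "matrix", "array"))
  res <- exceedance_fraction(adm2)
  expect_equal(res$fraction, 0.02)
  expect_equal(res$numerator, 1L)
  expect_equal(res$denominator, 50L)

  # permutation invariance of probes and pairs
  set.seed(4)
  d3 <- make_design(2, 2, 2)
  b3 <- random_beta(30, d3)
  a3 <- abs_diff_matrix(b3, d3)
  f1 <- exceedance_fraction(a3)$fraction
  perm <- unclass(a3)[sample(30), sample(6)]
  expect_equal(sum(perm >= 0.1) / length(perm), f1)
})

test_that("group medians resist single-pair corruption (breakdown property)", {
  d <- make_design(1, 4, 1)
  vals <- matrix(0.5, 1, nrow(d), dimnames = list("p", d$sample_id))
  disc <- c(0.02, 0.04, 0.06, 0.08)
  for (i in 1:4) vals["p", paste0("D", i, "_1")] <- 0.5 + disc[i]
  gm0 <- group_medians(abs_diff_matrix(beta_matrix(vals), d))["p", "discordant"]
  expect_equal(gm0, 0.05)
  # corrupt one pair to the maximal difference
  vals["p", "D4_1"] <- 1; vals["p", "D4_2"] <- 0
  gm1 <- group_medians(abs_diff_matrix(beta_matrix(vals), d))["p", "discordant"]
  # median moves only to the next order statistics' midpoint, not to 1
  expect_equal(gm1, 0.05)
})

test_that("feature summary deduplicates categories and sums to 100", {
  d <- make_design(1, 2, 1)
  gm <- matrix(c(0.2, 0, 0,   0.2, 0, 0,   0, 0.2, 0,  0, 0, 0),
               ncol = 3, byrow = TRUE,
               dimnames = list(paste0("p", 1:4), c("concordant", "discordant", "healthy")))
  cls <- classify_vmps(gm)
  ann <- make_annotation(c("p1", "p2", "p3"),
                         feature = c("TSS200", "Body;Body", "Body"))
  fs <- feature_category_summary(cls, ann)
  conc <- fs[fs$exclusivity == "concordant-only", ]
  expect_equal(sort(conc$feature), c("Body", "TSS200"))
  expect_equal(conc$percent, c(50, 50))
  expect_equal(sum(conc$percent), 100)
  disc <- fs[fs$exclusivity == "discordant-only", ]
  expect_equal(disc$feature, "Body")   # "Body;Body" collapsed
  expect_equal(disc$percent, 100)

  # unannotated probes are counted explicitly
  gm2 <- gm; rownames(gm2) <- paste0("q", 1:4)
  fs2 <- feature_category_summary(classify_vmps(gm2), ann)
  expect_true(all(fs2$feature == "unannotated"))
})
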