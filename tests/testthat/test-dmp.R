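# DMP module: paired t, rank scores, rank combination

test_that("paired t matches the df=2 closed form on the worked example", {
  # differences (0.1, 0.2, 0.3): t = 0.2/(0.1/sqrt(3)); the df=2 t-tail has
  # closed form P = 2*(1/2 - t/(2*sqrt(2 + t^2))), evaluated independently:
  t_expect <- 0.2 / (0.1 / sqrt(3))
  p_expect <- 2 * (1 / 2 - t_expect / (2 * sqrt(2 + t_expect^2)))
  res <- paired_t_test(c(0.4, 0.5, 0.6), c(0.3, 0.3, 0.3))
  expect_equal(res$t, 3.4641016, tolerance = 1e-6)
  expect_equal(res$p_value, 0.0741799, tolerance = 1e-5)
  expect_equal(res$t, t_expect)
  expect_equal(res$p_value, p_expect)
  expect_false(res$degenerate)
  expect_equal(res$mean_delta, 0.2)
})

test_that("degenerate difference vectors are flagged with limiting P", {
  res <- paired_t_test(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  res <- paired_t_test(c(0.6, 0.6, 0.6), c(0.5, 0.5, 0.5))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 0)
  expect_error(paired_t_test(0.1, 0.2), class = "tm_validation_error")
})

test_that("rank_scores matches spec cases and the beats-counting oracle", {
  expect_equal(rank_scores(c(0.001, 0.01, 0.1), better = "lower"), c(3, 2, 1))
  expect_equal(rank_scores(c(0.05, 0.20, 0.10), better = "higher"), c(1, 3, 2))
  expect_equal(rank_scores(c(0.5, 0.5), better = "lower"), c(1.5, 1.5))
  expect_error(rank_scores(numeric(0)), class = "tm_validation_error")
  set.seed(21)
  for (i in 1:20) {
    v <- sample(round(runif(30), 2))  # rounding forces ties
    for (dir in c("lower", "higher")) {
      expect_equal(rank_scores(v, dir), oracle_rank_scores(v, dir))
    }
  }
})

test_that("rank_dmps combines scores as hand-computed on a 3-probe instance", {
  # engineer 3 probes over 3 discordant pairs, then score by hand from the
  # package's own per-probe p/mean_delta via independent arithmetic
  d <- make_design(1, 3, 1)
  vals <- matrix(0.5, 3, nrow(d), dimnames = list(c("A", "B", "C"), d$sample_id))
  vals["A", c("D1_1", "D2_1", "D3_1")] <- 0.5 + c(0.049, 0.050, 0.051)
  vals["B", c("D1_1", "D2_1", "D3_1")] <- 0.5 + c(0.15, 0.20, 0.25)
  vals["C", c("D1_1", "D2_1", "D3_1")] <- 0.5 + c(0.05, 0.10, 0.15)
  b <- beta_matrix(vals)
  res <- rank_dmps(b, d, top_k = 1)
  # A: tiny sd => smallest P but smallest |delta|; B: biggest delta;
  # C: middling both. Scores: p:(3,x,y), delta:(1,3,2)
  expect_equal(res$probe_id[res$rank], res$probe_id)
  expect_equal(oracle_rank_dmps(b, d), res$probe_id)
  expect_equal(sort(res$combined_score, decreasing = TRUE), res$combined_score)
  expect_equal(top_dmps(res)$probe_id, res$probe_id[1L])
  expect_error(rank_dmps(b, make_design(2, 1, 2)), class = "tm_validation_error")
})

test_that("all-identical probes rank deterministically with degenerate flags", {
  d <- make_design(1, 3, 1)
  b <- make_beta(matrix(0.4, 5, nrow(d)), d)
  res <- rank_dmps(b, d)
  expect_true(all(res$degenerate))
  expect_true(all(res$p_value == 1))
  expect_equal(res$probe_id, sort(res$probe_id))  # tie-break: probe id
  expect_equal(res$rank, 1:5)
})

test_that("probe input order does not affect the ranking", {
  set.seed(8)
  d <- make_design(1, 4, 1)
  b <- random_beta(40, d)
  res1 <- rank_dmps(b, d)
  perm <- sample(nrow(b))
  b2 <- beta_matrix(unclass(b)[perm, , drop = FALSE])
  res2 <- rank_dmps(b2, d)
  expect_equal(res1$probe_id, res2$probe_id)
  expect_equal(res1$combined_score, res2$combined_score)
})

test_that("planted mean shifts land in the top ranks", {
  cfg <- sim_config(n_probes = 5000, pair_noise_sd = 0.01,
                    dmp_spec = list(n = 10L, delta = -0.08),
                    vmp_spec = list(concordant = 0L, discordant = 0L,
                                    healthy = 0L, magnitude = 0),
                    seed = 42)
  sim <- simulate_twins(cfg)
  res <- rank_dmps(sim$beta, sim$design, top_k = 10)
  expect_setequal(top_dmps(res)$probe_id, sim$truth$dmp$probe_id)
  # by construction no null probe attains a comparable combined score
  null_best <- max(res$combined_score[!res$probe_id %in% sim$truth$dmp$probe_id])
  planted_worst <- min(res$combined_score[res$probe_id %in% sim$truth$dmp$probe_id])
  expect_gt(planted_worst, null_best)
})

test_that("annotate_dmps joins study-style table columns", {
  d <- make_design(1, 2, 1)
  b <- random_beta(3, d)
  ann <- make_annotation(rownames(b)[1:2], gene = c("WDR26", "VCAN"),
                         feature = c("Body", "5'UTR"))
  out <- annotate_dmps(top_dmps(rank_dmps(b, d), k = 3), ann)
  expect_named(out, c("probe_id", "p_value", "mean_delta", "t", "degenerate",
                      "p_score", "delta_score", "combined_score", "rank",
                      "chr", "pos", "gene", "feature"))
  expect_equal(out$gene[out$probe_id == "cg00000001"], "WDR26")
  expect_equal(out$gene[out$probe_id == "cg00000003"], "")
})
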