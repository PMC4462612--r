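# Seeded generator of synthetic MZ-twin beta matrices with the statistical
# structure the analyses assume: bimodal baseline methylation per probe,
# small additive intrapair noise, planted mean shifts in discordant pairs
# (DMPs) and planted group-exclusive large intrapair differences (VMPs).
#
# Noise is additive Gaussian on the beta scale with clipping to [0,1] —
# simple and analytically tractable (the null exceedance fraction has the
# closed form 2*pnorm(-thr/(sd*sqrt(2))) when baselines stay away from the
# boundaries). It does not emulate probe-type chemistry, dye bias or
# cell-composition structure of real arrays.

#' Simulation configuration
#'
#' Defaults mirror the twin study design the package targets: 4 concordant,
#' 6 discordant and 7 healthy pairs (34 samples), bimodal baselines (modes
#' ~0.15 / ~0.85), per-twin additive noise sd 0.02, 10 planted DMPs at
#' delta = -0.08 (affected minus unaffected, discordant pairs only) and
#' (8, 17, 22) group-exclusive VMPs at magnitude 0.3.
#'
#' @param n_pairs named integer vector: pairs per group
#'   (`concordant`, `discordant`, `healthy`).
#' @param n_probes number of probes.
#' @param baseline_modes,baseline_weights,baseline_sd two-component Gaussian
#'   mixture for per-probe baseline methylation.
#' @param baseline_range baselines are clamped to this interval after the
#'   mixture draw (set e.g. `c(0.2, 0.8)` for boundary-free calibration runs).
#' @param pair_noise_sd per-twin additive deviation sd (beta scale).
#' @param dmp_spec list `n` (count of planted DMPs) and `delta` (effect,
#'   affected minus unaffected). Use `n = 0` for none.
#' @param vmp_spec list of per-group planted exclusive VMP counts
#'   (`concordant`, `discordant`, `healthy`) and `magnitude` of the shift
#'   applied to one random twin of each target-group pair.
#' @param seed RNG seed; identical config + seed gives bit-identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = c(concordant = 4L, discordant = 6L, healthy = 7L),
                       n_probes = 10000L,
                       baseline_modes = c(0.15, 0.85),
                       baseline_weights = c(0.5, 0.5),
                       baseline_sd = 0.05,
                       baseline_range = c(0, 1),
                       pair_noise_sd = 0.02,
                       dmp_spec = list(n = 10L, delta = -0.08),
                       vmp_spec = list(concordant = 8L, discordant = 17L,
                                       healthy = 22L, magnitude = 0.3),
                       seed = 1L) {
  n_pairs <- n_pairs[TM_GROUPS]
  if (anyNA(n_pairs) || any(n_pairs < 1L)) {
    tm_error("tm_validation_error",
             "n_pairs needs >= 1 pair per group (concordant, discordant, healthy)")
  }
  structure(list(
    n_pairs = stats::setNames(as.integer(n_pairs), TM_GROUPS),
    n_probes = as.integer(n_probes),
    baseline_modes = baseline_modes, baseline_weights = baseline_weights,
    baseline_sd = baseline_sd, baseline_range = baseline_range,
    pair_noise_sd = pair_noise_sd, dmp_spec = dmp_spec, vmp_spec = vmp_spec,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a twin methylation data set
#'
#' Per twin, beta = clip(baseline_probe + twin_deviation + planted effects,
#' 0, 1). Planted DMPs add `delta` to the affected co-twin of every
#' discordant pair; planted VMPs shift one random co-twin of every pair in
#' the target group by +/- magnitude (sign chosen at random among the
#' directions that stay inside \[0, 1\]). Planted probe sets are pairwise
#' disjoint. Truth tables record planted probes, groups and magnitudes.
#'
#' @param cfg a [sim_config].
#' @return list with `beta` ([beta_matrix]), `design` ([twin_design]),
#'   `annotation` ([probe_annotation]), `truth` (list `dmp`, `vmp`
#'   data.frames) and `config`.
#' @export
simulate_twins <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  n_planted <- cfg$dmp_spec$n + cfg$vmp_spec$concordant + cfg$vmp_spec$discordant +
    cfg$vmp_spec$healthy
  if (n_planted > cfg$n_probes) {
    tm_error("tm_validation_error", sprintf(
      "%d planted probes requested but only %d probes simulated",
      n_planted, cfg$n_probes))
  }
  set.seed(cfg$seed)
  np <- cfg$n_probes
  probe_ids <- sprintf("cg%08d", seq_len(np))

  pair_ids <- c(sprintf("C%d", seq_len(cfg$n_pairs[["concordant"]])),
                sprintf("D%d", seq_len(cfg$n_pairs[["discordant"]])),
                sprintf("H%d", seq_len(cfg$n_pairs[["healthy"]])))
  pair_groups <- rep(TM_GROUPS, cfg$n_pairs)
  design <- twin_design(data.frame(
    sample_id = as.vector(rbind(paste0(pair_ids, "_1"), paste0(pair_ids, "_2"))),
    pair_id = rep(pair_ids, each = 2L),
    group = rep(pair_groups, each = 2L),
    affected = as.vector(rbind(
      pair_groups != "healthy",                 # twin 1 affected unless healthy
      pair_groups == "concordant"               # twin 2 affected only if concordant
    )),
    stringsAsFactors = FALSE
  ))

  comp <- sample.int(2L, np, replace = TRUE, prob = cfg$baseline_weights)
  baseline <- stats::rnorm(np, mean = cfg$baseline_modes[comp], sd = cfg$baseline_sd)
  baseline <- clip01(baseline, cfg$baseline_range[1L], cfg$baseline_range[2L])
  baseline <- clip01(baseline)

  # disjoint planted probe sets
  n_dmp <- cfg$dmp_spec$n
  n_vmp <- c(concordant = cfg$vmp_spec$concordant,
             discordant = cfg$vmp_spec$discordant,
             healthy = cfg$vmp_spec$healthy)
  planted <- sample.int(np, n_dmp + sum(n_vmp))
  dmp_idx <- planted[seq_len(n_dmp)]
  vmp_idx <- split(planted[n_dmp + seq_len(sum(n_vmp))],
                   rep(TM_GROUPS, n_vmp))

  n_samp <- 2L * sum(cfg$n_pairs)
  beta <- baseline + matrix(stats::rnorm(np * n_samp, sd = cfg$pair_noise_sd),
                            nrow = np, ncol = n_samp)
  colnames(beta) <- design$sample_id
  rownames(beta) <- probe_ids

  if (n_dmp > 0L) {
    affected_disc <- design$sample_id[design$group == "discordant" & design$affected]
    beta[dmp_idx, affected_disc] <- beta[dmp_idx, affected_disc] + cfg$dmp_spec$delta
  }

  mag <- cfg$vmp_spec$magnitude
  for (g in TM_GROUPS) {
    idx <- vmp_idx[[g]]
    if (is.null(idx) || !length(idx)) next
    g_pairs <- pair_ids[pair_groups == g]
    for (p in g_pairs) {
      members <- design$sample_id[design$pair_id == p]
      twin <- sample(members, length(idx), replace = TRUE)
      up_ok <- baseline[idx] + mag <= 1
      dn_ok <- baseline[idx] - mag >= 0
      sign <- ifelse(up_ok & dn_ok, sample(c(-1, 1), length(idx), replace = TRUE),
                     ifelse(up_ok, 1, -1))
      for (k in seq_along(idx)) {
        beta[idx[k], twin[k]] <- beta[idx[k], twin[k]] + sign[k] * mag
      }
    }
  }

  beta <- beta_matrix(clip01(beta))

  ann <- probe_annotation(data.frame(
    probe_id = probe_ids,
    chr = paste0("chr", sample.int(22L, np, replace = TRUE)),
    pos = sample.int(2e8L, np, replace = TRUE),
    gene = sprintf("GENE%05d", ceiling(seq_len(np) / 3)),
    feature = sample(TM_FEATURES, np, replace = TRUE),
    stringsAsFactors = FALSE
  ))

  truth_dmp <- data.frame(probe_id = probe_ids[dmp_idx],
                          delta = rep(cfg$dmp_spec$delta, n_dmp),
                          stringsAsFactors = FALSE)
  truth_vmp <- do.call(rbind, lapply(TM_GROUPS, function(g) {
    idx <- vmp_idx[[g]]
    if (is.null(idx) || !length(idx)) return(NULL)
    data.frame(probe_id = probe_ids[idx], group = g, magnitude = mag,
               stringsAsFactors = FALSE)
  }))
  if (is.null(truth_vmp)) {
    truth_vmp <- data.frame(probe_id = character(0), group = character(0),
                            magnitude = numeric(0))
  }

  list(beta = beta, design = design, annotation = ann,
       truth = list(dmp = truth_dmp, vmp = truth_vmp), config = cfg)
}

#' Simulate a null twin data set (no planted effects)
#'
#' Same generative model as [simulate_twins] with the DMP and VMP specs
#' emptied: only baseline + intrapair noise.
#'
#' @param cfg a [sim_config]; its planted-effect specs are ignored.
#' @return as [simulate_twins].
#' @export
simulate_null <- function(cfg = sim_config()) {
  cfg$dmp_spec <- list(n = 0L, delta = 0)
  cfg$vmp_spec <- list(concordant = 0L, discordant = 0L, healthy = 0L,
                       magnitude = 0)
  simulate_twins(cfg)
}
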