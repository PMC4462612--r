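# End-to-end orchestration: (simulate | load) -> dmp -> dmp-validate -> vmp
# [-> enrich], writing per-stage TSVs plus one machine-readable JSON run
# report. Stage outputs are pure functions of (inputs, config, seed), so a
# re-run with the same config is byte-identical.

#' Read a pipeline run configuration
#'
#' YAML (`.yaml`/`.yml`, needs the `yaml` package) or JSON. Recognised keys:
#' `seed`; `input` (either `sim: {n_probes, pair_noise_sd, ...}` or paths
#' `beta`, `design`, `annotation`); `dmp: {top_k}`; `vmp: {threshold}`;
#' `validate: {alpha_level}`; `enrich: {gmt, universe}`; `out_dir`.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    tm_error("tm_io_error", sprintf("config file '%s' not found", path))
  }
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      tm_error("tm_io_error", "YAML config requires the 'yaml' package; use JSON")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Run the full twin-methylation pipeline
#'
#' Stages: acquire data (simulate with the configured seed, or load the
#' configured files), DMP ranking, cross-group validation of the top-k DMPs,
#' VMP classification with exceedance and feature-category summaries, and —
#' when a GMT file is configured — hypergeometric enrichment of each
#' group-exclusive VMP gene list. Writes per-stage TSVs and `report.json`
#' into `out_dir`. Any stage failure aborts with a stage-named condition.
#'
#' @param config named list as produced by [read_run_config], or a path to a
#'   config file.
#' @param out_dir output directory (created if needed); overrides
#'   `config$out_dir`.
#' @return (invisibly) the report as a list.
#' @export
run_all <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- out_dir %||% config$out_dir %||% "twinmeth_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      tm_error("tm_stage_error",
               sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               stage = name)
    })
  }

  # -- data stage ------------------------------------------------------------
  input <- config$input %||% list(sim = list())
  sim_truth <- NULL
  dat <- stage("data", {
    if (!is.null(input$sim) || is.null(input$beta)) {
      args <- input$sim %||% list()
      args$seed <- seed
      cfg <- do.call(sim_config, args)
      sim <- simulate_twins(cfg)
      write_beta_matrix(sim$beta, file.path(out_dir, "B.tsv"))
      write_twin_design(sim$design, file.path(out_dir, "D.csv"))
      write_probe_annotation(sim$annotation, file.path(out_dir, "ann.csv"))
      data.table::fwrite(sim$truth$dmp, file.path(out_dir, "truth_dmp.tsv"), sep = "\t")
      data.table::fwrite(sim$truth$vmp, file.path(out_dir, "truth_vmp.tsv"), sep = "\t")
      sim_truth <- sim$truth  # promise evaluates in run_all's frame
      sim[c("beta", "design", "annotation")]
    } else {
      list(beta = read_beta_matrix(input$beta),
           design = read_twin_design(input$design),
           annotation = if (!is.null(input$annotation))
             read_probe_annotation(input$annotation))
    }
  })

  top_k <- as.integer(config$dmp$top_k %||% 10L)
  threshold <- as.numeric(config$vmp$threshold %||% 0.1)
  alpha_level <- as.numeric(config$validate$alpha_level %||% 0.05)

  # -- dmp stage -------------------------------------------------------------
  dmp <- stage("dmp", rank_dmps(dat$beta, dat$design, top_k = top_k))
  top <- top_dmps(dmp)
  top_out <- if (!is.null(dat$annotation)) annotate_dmps(top, dat$annotation) else as.data.frame(top)
  stage("dmp", {
    data.table::fwrite(as.data.frame(dmp), file.path(out_dir, "dmp.tsv"), sep = "\t")
    data.table::fwrite(top_out, file.path(out_dir, "dmp_top.tsv"), sep = "\t")
  })

  # -- validation stage ------------------------------------------------------
  val <- stage("dmp-validate",
               validate_dmps(dat$beta, dat$design, top$probe_id,
                             alpha_level = alpha_level))
  stage("dmp-validate",
        data.table::fwrite(as.data.frame(val), file.path(out_dir, "dmp_validation.tsv"),
                           sep = "\t"))

  # -- vmp stage -------------------------------------------------------------
  vmp_out <- stage("vmp", {
    adm <- abs_diff_matrix(dat$beta, dat$design)
    gm <- group_medians(adm)
    cls <- classify_vmps(gm, threshold = threshold)
    exc <- exceedance_fraction(adm, threshold = threshold)
    feat <- if (!is.null(dat$annotation))
      feature_category_summary(cls, dat$annotation)
    hits <- cls$classification[cls$classification$exclusivity != "none", , drop = FALSE]
    data.table::fwrite(hits, file.path(out_dir, "vmp.tsv"), sep = "\t")
    if (!is.null(feat)) {
      data.table::fwrite(feat, file.path(out_dir, "vmp_features.tsv"), sep = "\t")
    }
    list(classification = cls, exceedance = exc, features = feat)
  })

  # -- enrich stage ----------------------------------------------------------
  enrich_out <- NULL
  if (!is.null(config$enrich$gmt)) {
    enrich_out <- stage("enrich", {
      sets <- read_gene_sets(config$enrich$gmt)
      universe <- if (!is.null(config$enrich$universe)) {
        readLines(config$enrich$universe, warn = FALSE)
      } else if (!is.null(dat$annotation)) {
        map_probes_to_genes(dat$annotation$probe_id, dat$annotation)
      } else {
        tm_error("tm_validation_error", "no universe available for enrichment")
      }
      cls <- vmp_out$classification$classification
      res <- list()
      for (g in c("concordant-only", "discordant-only", "healthy-only")) {
        probes <- cls$probe_id[cls$exclusivity == g]
        genes <- if (length(probes) && !is.null(dat$annotation))
          map_probes_to_genes(probes, dat$annotation) else character(0)
        if (!length(intersect(genes, universe))) next
        er <- hypergeometric_enrichment(genes, sets, universe = universe)
        data.table::fwrite(as.data.frame(er),
                           file.path(out_dir, paste0("enrich_", sub("-only", "", g), ".tsv")),
                           sep = "\t")
        res[[g]] <- er
      }
      res
    })
  }

  # -- report ----------------------------------------------------------------
  report <- stage("report", {
    cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
    tmp <- tempfile(); writeLines(cfg_json, tmp)
    rep <- list(
      package = "twinmeth",
      version = as.character(utils::packageVersion("twinmeth")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = seed,
      config_hash = unname(tools::md5sum(tmp)),
      n_probes = nrow(dat$beta),
      n_samples = ncol(dat$beta),
      parameters = list(top_k = top_k, vmp_threshold = threshold,
                        alpha_level = alpha_level),
      venn_counts = as.list(vmp_out$classification$counts),
      exceedance = vmp_out$exceedance,
      top_dmps = top_out,
      validation = as.data.frame(val),
      enrichment_method = if (!is.null(enrich_out))
        "hypergeometric ORA (stand-in for network-based pathway analysis)"
    )
    unlink(tmp)
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    rep
  })
  if (!is.null(sim_truth)) report$truth <- sim_truth
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
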