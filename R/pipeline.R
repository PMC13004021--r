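# End-to-end pipeline: configuration, stage composition, and manifest.

#' Default pipeline configuration
#'
#' Returns the demonstration configuration as a named list; any element
#' can be overridden.  A configuration can also be read from a YAML file
#' with [read_pipeline_config()].  `k0` and `M_total` are required
#' measured inputs: the wild-type growth rate cannot be identified from
#' relative abundances, and the message budget sets the transcription
#' scale.
#'
#' @param ... Overrides (named).
#' @return Configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    out_dir = file.path(tempdir(), "kodepletion_demo"),
    demo = TRUE,
    n_genes = 200,
    k0 = 1.2,
    timepoints = seq(0, 12, by = 2),
    depth = 2e5,
    n_replicates = 2,
    seed = 1L,
    partition_cv = 0.05,
    residual_rate = 0.05,
    alpha1 = 1e-4,
    alpha2 = 1e-4,
    min_count0 = 20,
    M_total = 4000,
    rnaseq_reads = 1e6,
    epsilon = 1e-4,
    mu_grid = 10^seq(log10(0.3), 3, length.out = 60),
    n_quantile_bins = 10,
    log_bin_width = 0.25,
    counts_paths = NULL,
    rnaseq_path = NULL,
    annotation_path = NULL)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path Path to a declarative `key: value` YAML file.
#' @return Configuration list (defaults filled in).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

check_config <- function(config) {
  required <- c("k0", "M_total", "alpha1", "alpha2", "seed", "timepoints")
  for (key in required) {
    if (is.null(config[[key]]))
      stop("pipeline configuration is missing required key: ", key,
           call. = FALSE)
  }
  if (!isTRUE(config$demo) &&
      (is.null(config$counts_paths) || is.null(config$rnaseq_path) ||
       is.null(config$annotation_path)))
    stop("non-demo runs need counts_paths, rnaseq_path and ",
         "annotation_path", call. = FALSE)
  invisible(config)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the knockout-depletion pipeline end to end
#'
#' In demo mode, generates a synthetic truth table and all inputs
#' (replicate depletion count matrices, RNA-seq counts, annotation),
#' then runs the full analysis: trajectory classification per replicate,
#' replicate combination, message-number estimation, trend binning by both
#' approaches, subgroup statistics, summary statistics, and the RLTO
#' prediction curve.  All outputs are TSV files under `config$out_dir`
#' plus a JSON manifest recording the package version, every seed,
#' threshold, and tolerance used, and a hash of the configuration; runs
#' are idempotent given an identical configuration.
#'
#' @param config Configuration list from [pipeline_config()] (or a path
#'   to a YAML file).
#' @return Invisibly, a report list: `calls` (per replicate),
#'   `combined`, `records`, `trends`, `group_stats`, `summary`, `rlto`,
#'   and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  check_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  scfg <- sim_config(k0 = config$k0, timepoints = config$timepoints,
                     depth = config$depth, n_genes = config$n_genes,
                     seed = config$seed,
                     partition_cv = config$partition_cv,
                     residual_rate = config$residual_rate)
  if (isTRUE(config$demo)) {
    truth <- run_stage("synth", {
      truth <- demo_truth(n_genes = config$n_genes, seed = config$seed)
      for (k in seq_len(config$n_replicates)) {
        counts <- simulate_tfnseq(truth, scfg, seed = config$seed + k)
        write_counts_tsv(counts, out(sprintf("counts_rep%d.tsv", k)))
      }
      rna <- simulate_rnaseq(truth, config$rnaseq_reads,
                             seed = config$seed + 101L)
      utils::write.table(
        data.frame(gene_id = names(rna), count = rna),
        out("rnaseq.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(gene_id = truth$gene_id, essential = truth$essential,
                   groups = ""),
        out("annotation.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      utils::write.table(truth, out("truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      truth
    })
    counts_paths <- out(sprintf("counts_rep%d.tsv",
                                seq_len(config$n_replicates)))
    rnaseq_path <- out("rnaseq.tsv")
    annotation_path <- out("annotation.tsv")
  } else {
    counts_paths <- config$counts_paths
    rnaseq_path <- config$rnaseq_path
    annotation_path <- config$annotation_path
  }

  annotation <- run_stage("annotation", read_annotation_tsv(annotation_path))

  calls_list <- run_stage("tfnseq", {
    lapply(seq_along(counts_paths), function(k) {
      counts <- read_counts_tsv(counts_paths[k])
      aset <- relative_abundance(counts, min_count0 = config$min_count0)
      calls <- call_mutants(
        aset, k0 = config$k0, alpha1 = config$alpha1,
        alpha2 = config$alpha2, normalization = "reference",
        reference_genes = annotation$gene_id[!annotation$essential])
      write_calls_tsv(calls, out(sprintf("calls_rep%d.tsv", k)))
      calls
    })
  })

  combined <- run_stage("replicates", {
    cmb <- if (length(calls_list) >= 2) replicate_error(calls_list)
    else {
      one <- calls_list[[1]]
      data.frame(gene_id = one$gene_id, n_replicates = 1L,
                 model = one$model, log10_o_mean = one$log10_o,
                 log10_o_sd = NA_real_, discordant = FALSE,
                 missing_in_some = FALSE, stringsAsFactors = FALSE)
    }
    write_calls_tsv(cmb, out("calls_combined.tsv"))
    cmb
  })

  records <- run_stage("compare", {
    rna <- utils::read.table(rnaseq_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    mu_hat <- message_number(stats::setNames(rna$count, rna$gene_id),
                             M_total = config$M_total)
    rec <- merge_gene_records(combined, mu_hat, annotation)
    write_calls_tsv(rec, out("gene_records.tsv"))
    rec
  })

  ess <- records[records$essential & !is.na(records$o) &
                   records$mu_m_hat > 0, ]
  trends <- run_stage("trends", {
    tr <- list(
      quantile = trend_bins(ess$mu_m_hat, ess$o, method = "quantile",
                            n_bins = config$n_quantile_bins,
                            seed = config$seed),
      log_width = trend_bins(ess$mu_m_hat, ess$o, method = "log_width",
                             bin_width = config$log_bin_width,
                             seed = config$seed))
    write_calls_tsv(tr$quantile, out("trend_quantile.tsv"))
    write_calls_tsv(tr$log_width, out("trend_log_width.tsv"))
    tr
  })

  gstats <- run_stage("groups", {
    gs <- group_stats(records)
    write_calls_tsv(gs, out("group_stats.tsv"))
    gs
  })

  summ <- run_stage("summary", {
    s <- summary_stats(records)
    fr <- s$class_fractions_essential
    utils::write.table(
      data.frame(statistic = c("median_o", "weighted_mean_o",
                               paste0("frac_essential_", names(fr))),
                 value = c(s$median_o, s$weighted_mean_o, as.numeric(fr))),
      out("summary.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    s
  })

  run_stage("kde", {
    if (nrow(ess) >= 10) {
      kd <- kde_overlay(ess$mu_m_hat, ess$o)
      grid <- expand.grid(log10_mu_m = kd$x, log10_o = kd$y)
      grid$density <- as.vector(kd$z)
      utils::write.table(grid, out("kde_grid.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    NULL
  })

  rlto <- run_stage("rlto", {
    pred <- optimal_overabundance(config$mu_grid,
                                  epsilon = config$epsilon)
    write_calls_tsv(pred$curve, out("rlto_curve.tsv"))
    pred
  })

  manifest <- list(
    package = "kodepletion",
    version = as.character(utils::packageVersion("kodepletion")),
    config_hash = config_hash(config),
    seeds = list(base = config$seed,
                 replicates = config$seed + seq_len(length(counts_paths)),
                 rnaseq = config$seed + 101L),
    thresholds = list(alpha1 = config$alpha1, alpha2 = config$alpha2,
                      min_count0 = config$min_count0,
                      epsilon = config$epsilon,
                      M_total = config$M_total, k0 = config$k0),
    class_fractions_essential =
      as.list(summ$class_fractions_essential),
    summary = list(median_o = summ$median_o,
                   weighted_mean_o = summ$weighted_mean_o))
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(calls = calls_list, combined = combined,
                 records = records, trends = trends,
                 group_stats = gstats, summary = summ, rlto = rlto,
                 manifest = manifest, out_dir = config$out_dir))
}

# Stable hash of the configuration (md5 of its canonical JSON form).
config_hash <- function(config) {
  config <- config[order(names(config))]
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null"), tf)
  unname(tools::md5sum(tf))
}
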