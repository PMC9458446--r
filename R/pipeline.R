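#' Run the full audit pipeline
#'
#' Chains the package end to end: simulate a bisulfite library (or accept
#' externally supplied reads), call per-read methylation, build the
#' pileup, compute the per-read and aggregate bias diagnostics, classify
#' positions under the threshold model, and juxtapose the threshold-model
#' verdict against the simulation ground truth. Any stage failure aborts
#' with the stage name and cause.
#'
#' @param config A [sim_config()]; all randomness flows from its seed.
#' @param threshold A [threshold_config()].
#' @param trend_bin_width Bin width of the per-read trend (bp of C count).
#' @param x_bins,y_bins Density-tile resolution.
#' @param reads Optional externally supplied read data frame (e.g. from
#'   [read_sam()]); when given, the simulation stage is skipped and no
#'   truth comparison is made.
#' @param outdir Optional directory; when given, all tables are written as
#'   TSV and the report as JSON (deterministic for a fixed config).
#' @return An `audit_bundle` list: `config`, `sim` (or `NULL`),
#'   `summaries`, `per_read`, `pileup`, `strand_bias`, `c_coverage_bias`,
#'   `observed`, `expected`, `tv_distance`, `trend`, `tiles`,
#'   `classification`, `model_summary`, `truth_mean_methylation`.
#' @export
run_pipeline <- function(config, threshold = threshold_config(),
                         trend_bin_width = 15L, x_bins = 40L, y_bins = 20L,
                         reads = NULL, outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  genome <- config$genome
  sim <- NULL
  if (is.null(reads)) {
    sim <- stage("simulate", simulate_reads(config))
    reads <- sim$reads
  }
  summaries <- stage("extract", call_reads(reads, genome))
  pileup <- stage("extract", build_pileup(reads, genome))
  tab <- stage("diagnose", per_read_table(summaries))
  sb <- stage("diagnose", strand_bias_from_reads(reads, genome))
  ccb <- stage("diagnose", c_coverage_bias(pileup, genome))
  obs <- stage("diagnose", observed_c_distribution(tab))
  expd <- stage("diagnose",
                expected_c_distribution(genome, reads$length))
  tv <- stage("diagnose", distribution_divergence(obs, expd))
  trend <- stage("diagnose", binned_trend(tab, trend_bin_width))
  tiles <- stage("diagnose", density_tiles(tab, x_bins, y_bins))
  classes <- stage("classify", classify_positions(pileup, threshold))
  ms <- stage("classify", methylome_fraction(classes))
  truth_mean <- if (!is.null(sim)) {
    mean(sim$truth$true_meth_fraction, na.rm = TRUE)
  } else {
    NA_real_
  }
  bundle <- structure(
    list(config = config, sim = sim, summaries = summaries,
         per_read = tab, pileup = pileup, strand_bias = sb,
         c_coverage_bias = ccb, observed = obs, expected = expd,
         tv_distance = tv, trend = trend, tiles = tiles,
         classification = classes, model_summary = ms,
         truth_mean_methylation = truth_mean),
    class = "audit_bundle")
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# write all bundle tables (1-based positions in outputs) plus the JSON report
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  f <- function(name) file.path(outdir, name)
  write_tsv(bundle$per_read, f("per_read.tsv"))
  write_pileup_tsv(bundle$pileup, f("pileup.tsv"))
  write_tsv(bundle$trend, f("trend.tsv"))
  write_tsv(bundle$tiles, f("tiles.tsv"))
  write_tsv(data.frame(support = bundle$observed$support,
                       observed = bundle$observed$mass),
            f("observed_distribution.tsv"))
  write_tsv(data.frame(support = bundle$expected$support,
                       expected = bundle$expected$mass),
            f("expected_distribution.tsv"))
  cls <- bundle$classification
  cls$position <- cls$position + 1L
  write_tsv(cls, f("classification.tsv"))
  if (!is.null(bundle$sim)) {
    tr <- bundle$sim$truth
    tr$position <- tr$position + 1L
    write_tsv(tr, f("truth.tsv"))
  }
  rep <- render_report(bundle)
  jsonlite::write_json(rep$json, f("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  writeLines(rep$text, f("report.txt"))
  invisible(outdir)
}

#' Render an audit report
#'
#' Produces a short human-readable summary and a machine-readable list
#' (serializable as JSON) juxtaposing the bias diagnostics, the
#' threshold-model verdict and, for simulated data, the ground truth.
#'
#' @param bundle An `audit_bundle` from [run_pipeline()].
#' @return List with `text` (character lines) and `json` (named list).
#' @export
render_report <- function(bundle) {
  need <- c("strand_bias", "c_coverage_bias", "tv_distance",
            "model_summary", "classification")
  missing <- need[vapply(need, function(n) is.null(bundle[[n]]),
                         logical(1))]
  if (length(missing) > 0L) {
    stop("incomplete bundle; missing artifacts: ",
         paste(missing, collapse = ", "))
  }
  sb <- bundle$strand_bias
  ms <- bundle$model_summary
  json <- list(
    genome = bundle$config$genome$name,
    genome_length = bundle$config$genome$length,
    seed = bundle$config$seed,
    prep_mode = bundle$config$prep_mode,
    degradation_rate = bundle$config$degradation_rate,
    n_reads = nrow(bundle$summaries),
    strand_bias = list(n_H = sb$n_H, n_L = sb$n_L, ratio = sb$ratio,
                       ratio_display = sb$ratio_display),
    c_coverage_bias = unclass(bundle$c_coverage_bias),
    tv_distance = bundle$tv_distance,
    model_summary = unclass(ms),
    truth_mean_methylation = bundle$truth_mean_methylation
  )
  text <- c(
    sprintf("Audit of %s (%d bp), seed %d, %s, delta = %g",
            json$genome, json$genome_length, json$seed, json$prep_mode,
            json$degradation_rate),
    sprintf("  reads:                    %d", json$n_reads),
    sprintf("  H/L strand bias:          %s",
            if (is.na(sb$ratio)) sb$note else sprintf("%.2f", sb$ratio)),
    sprintf("  C coverage bias:          %.2f",
            bundle$c_coverage_bias$bias),
    sprintf("  TV(observed, expected):   %.4f", bundle$tv_distance),
    sprintf("  threshold-model calls:    %.4f methylated (%.4f by proportion, %.4f by coverage unmethylated)",
            ms$fraction_methylated, ms$unmethylated_by_proportion,
            ms$unmethylated_by_coverage),
    if (!is.na(bundle$truth_mean_methylation)) {
      sprintf("  true mean methylation:    %.4f",
              bundle$truth_mean_methylation)
    } else {
      "  true mean methylation:    (external reads; unknown)"
    }
  )
  list(text = text, json = json)
}

#' @export
print.audit_bundle <- function(x, ...) {
  cat(paste(render_report(x)$text, collapse = "\n"), "\n")
  invisible(x)
}
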