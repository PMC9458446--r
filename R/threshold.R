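#' Threshold-model configuration
#'
#' Parameters of the position-level methylation-calling model audited by
#' this package: a reference cytosine is called methylated when its
#' methylation proportion reaches `cutoff` (9% by default, inclusive) and
#' its call coverage is at least `min_coverage` (10 by default); positions
#' below the coverage floor are called unmethylated rather than discarded.
#' This model is implemented to demonstrate its behaviour, not endorsed:
#' the knife-edge at the cutoff (9.0% coverage-adequate proportion is
#' "fully methylated", 8.9% "fully unmethylated") and the treatment of
#' low-coverage positions are exactly the pathologies the package's
#' diagnostics expose.
#'
#' @param cutoff Methylation-proportion threshold in `[0, 1]`; default
#'   0.09.
#' @param min_coverage Minimum call coverage; default 10.
#' @param inclusive Whether the cutoff comparison is `>=` (default) or
#'   strict `>`.
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(cutoff = 0.09, min_coverage = 10L,
                             inclusive = TRUE) {
  if (cutoff < 0 || cutoff > 1) stop("cutoff must lie in [0, 1]")
  min_coverage <- as.integer(min_coverage)
  if (is.na(min_coverage) || min_coverage < 1L) {
    stop("min_coverage must be >= 1")
  }
  structure(list(cutoff = cutoff, min_coverage = min_coverage,
                 inclusive = isTRUE(inclusive)),
            class = "threshold_config")
}

#' Classify reference cytosines under the threshold model
#'
#' Every position of the pileup receives exactly one class:
#' `methylated` (coverage adequate and proportion reaching the cutoff),
#' `unmethylated_by_proportion` (coverage adequate, proportion below), or
#' `unmethylated_by_coverage` (coverage below the floor, including
#' uncovered positions). Proportions are compared at full precision; no
#' rounding happens before thresholding.
#'
#' @param pileup A `pileup` (see [build_pileup()] / [as_pileup()]).
#' @param config A [threshold_config()].
#' @return A `position_classification`: data frame `position`, `strand`,
#'   `context`, `coverage`, `meth_count`, `proportion` (`NA` at zero
#'   coverage), `class`.
#' @export
classify_positions <- function(pileup, config = threshold_config()) {
  stopifnot(inherits(pileup, "pileup"), inherits(config, "threshold_config"))
  prop <- ifelse(pileup$coverage > 0,
                 pileup$meth_count / pileup$coverage, NA_real_)
  covered <- pileup$coverage >= config$min_coverage
  reaches <- !is.na(prop) &
    (if (config$inclusive) prop >= config$cutoff else prop > config$cutoff)
  cls <- ifelse(!covered, "unmethylated_by_coverage",
                ifelse(reaches, "methylated", "unmethylated_by_proportion"))
  out <- data.frame(position = pileup$position, strand = pileup$strand,
                    context = pileup$context, coverage = pileup$coverage,
                    meth_count = pileup$meth_count, proportion = prop,
                    class = cls)
  structure(out, config = config,
            class = c("position_classification", "data.frame"))
}

#' Position-level false positive rate
#'
#' The audited definition: the number of positions called methylated over
#' the total number of reference cytosines, applied to a control asserted
#' to be truly unmethylated. Note what this omits -- it is computed on
#' genomic positions, not base calls, and contemplates neither true
#' positives nor false negatives.
#'
#' @param classes A `position_classification`.
#' @return FPR in `[0, 1]`.
#' @export
false_positive_rate <- function(classes) {
  stopifnot(inherits(classes, "position_classification"))
  if (nrow(classes) == 0L) stop("empty classification")
  sum(classes$class == "methylated") / nrow(classes)
}

#' Accuracy as the complement of the false positive rate
#'
#' `ACC = 1 - FPR`, the audited accuracy measure (controls type I error
#' only).
#'
#' @param fpr A false positive rate in `[0, 1]`.
#' @return `1 - fpr`.
#' @export
accuracy <- function(fpr) {
  if (is.na(fpr) || fpr < 0 || fpr > 1) stop("fpr must lie in [0, 1]")
  1 - fpr
}

#' Methylated/unmethylated genome fractions under the threshold model
#'
#' Summarizes a classification into the fraction of reference cytosines
#' called methylated and unmethylated, decomposing the latter into its
#' below-cutoff and below-coverage components -- the decomposition that
#' shows a reported "unmethylated genome" fraction conflates low
#' methylation with missing data. `fpr`/`acc` are meaningful when the
#' underlying sample is a truly unmethylated control.
#'
#' @param classes A `position_classification`.
#' @return A `model_summary` list: `fraction_methylated`,
#'   `fraction_unmethylated`, `unmethylated_by_proportion`,
#'   `unmethylated_by_coverage`, `n_positions`, `fpr`, `acc`.
#' @export
methylome_fraction <- function(classes) {
  stopifnot(inherits(classes, "position_classification"))
  n <- nrow(classes)
  if (n == 0L) stop("empty classification")
  f_m <- sum(classes$class == "methylated") / n
  f_up <- sum(classes$class == "unmethylated_by_proportion") / n
  f_uc <- sum(classes$class == "unmethylated_by_coverage") / n
  structure(
    list(fraction_methylated = f_m, fraction_unmethylated = f_up + f_uc,
         unmethylated_by_proportion = f_up,
         unmethylated_by_coverage = f_uc,
         n_positions = n, fpr = f_m, acc = 1 - f_m),
    class = "model_summary")
}

#' @export
print.model_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Threshold-model summary over %d reference cytosines:\n",
           "  methylated:                 %.4f\n",
           "  unmethylated (proportion):  %.4f\n",
           "  unmethylated (coverage):    %.4f\n"),
    x$n_positions, x$fraction_methylated, x$unmethylated_by_proportion,
    x$unmethylated_by_coverage))
  invisible(x)
}
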