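#' Heavy/light strand coverage bias
#'
#' The ratio of reads assigned to the heavy (G-rich) strand over the light
#' (C-rich) strand. Ratios above 1 indicate depletion of the C-rich strand,
#' the hallmark of bisulfite-induced selective degradation. The full
#' precision ratio is stored; display rounds to 2 decimals.
#'
#' @param n_H,n_L Read counts assigned to the H and L strands.
#' @return A `strand_bias_report`: list with `n_H`, `n_L`, `ratio` (full
#'   precision; `NA` with an explanatory `note` when `n_L` is 0) and
#'   `ratio_display` (2 dp).
#' @examples
#' strand_bias(77064281, 32301489)$ratio_display # 2.39
#' @export
strand_bias <- function(n_H, n_L) {
  stopifnot(n_H >= 0, n_L >= 0)
  if (n_L == 0) {
    out <- list(n_H = n_H, n_L = n_L, ratio = NA_real_,
                ratio_display = NA_real_,
                note = "undefined (no L-strand reads)")
  } else {
    r <- n_H / n_L
    out <- list(n_H = n_H, n_L = n_L, ratio = r,
                ratio_display = round(r, 2), note = NULL)
  }
  structure(out, class = "strand_bias_report")
}

#' @export
print.strand_bias_report <- function(x, ...) {
  if (is.na(x$ratio)) {
    cat(sprintf("H/L strand bias: %s (H = %s, L = %s)\n", x$note,
                format(x$n_H, big.mark = ","),
                format(x$n_L, big.mark = ",")))
  } else {
    cat(sprintf("H/L strand bias: %.2f (H = %s, L = %s)\n",
                x$ratio_display, format(x$n_H, big.mark = ","),
                format(x$n_L, big.mark = ",")))
  }
  invisible(x)
}

#' Strand bias of a read set under composition-derived H/L labels
#'
#' @param reads Data frame with a `strand` column
#'   (`"forward"`/`"reverse"`).
#' @param genome A [circular_genome()]; labels come from
#'   [assign_strand_labels()].
#' @return A `strand_bias_report` (see [strand_bias()]).
#' @export
strand_bias_from_reads <- function(reads, genome) {
  lab <- assign_strand_labels(genome)
  n_fwd <- sum(reads$strand == "forward")
  n_rev <- sum(reads$strand == "reverse")
  if (lab$forward_label == "H") strand_bias(n_fwd, n_rev)
  else strand_bias(n_rev, n_fwd)
}

#' Cytosine coverage bias
#'
#' The fraction of aligned base calls landing on forward-reference cytosine
#' positions, divided by the genome's C fraction. Values below 1 mean
#' C-rich regions are underrepresented in the library relative to uniform
#' coverage -- the selective-degradation signature at the aggregate level.
#'
#' @param pileup A `pileup` from [build_pileup()] (its `base_coverage`
#'   attribute supplies the aligned-base counts).
#' @param genome A [circular_genome()].
#' @return A `c_coverage_bias` list: `observed_c_fraction`,
#'   `expected_c_fraction`, `bias`.
#' @export
c_coverage_bias <- function(pileup, genome) {
  base_cov <- attr(pileup, "base_coverage")
  if (is.null(base_cov)) {
    stop("pileup carries no base_coverage; build it with build_pileup()")
  }
  total <- sum(as.numeric(base_cov))
  if (total == 0) stop("empty pileup: no aligned bases")
  fchars <- strand_chars(genome, "forward")
  obs <- sum(as.numeric(base_cov[fchars == "C"])) / total
  expd <- sum(fchars == "C") / genome$length
  structure(list(observed_c_fraction = obs, expected_c_fraction = expd,
                 bias = obs / expd),
            class = "c_coverage_bias")
}

#' @export
print.c_coverage_bias <- function(x, ...) {
  cat(sprintf(
    "C coverage bias (observed/expected): %.2f (%.4f / %.4f)\n",
    x$bias, x$observed_c_fraction, x$expected_c_fraction))
  invisible(x)
}

#' Per-read (C count, methylated fraction) table
#'
#' One row per read with at least one reference cytosine; reads covering no
#' cytosine have an undefined methylated fraction and are excluded but
#' counted in the `n_excluded` attribute.
#'
#' @param summaries Per-read summaries from [call_reads()].
#' @return Data frame with columns `n_ref_c`, `frac_meth`; attribute
#'   `n_excluded`.
#' @export
per_read_table <- function(summaries) {
  keep <- summaries$n_ref_c > 0L
  out <- data.frame(n_ref_c = summaries$n_ref_c[keep],
                    frac_meth = summaries$frac_meth[keep])
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' 2-D read-density histogram
#'
#' Summarizes the per-read scatter (C count vs methylated fraction) into
#' density tiles.
#'
#' @param table A [per_read_table()].
#' @param x_bins,y_bins Number of bins along `n_ref_c` and `frac_meth`.
#' @return Data frame `x_mid`, `y_mid`, `count` over nonempty tiles; tile
#'   counts sum to `nrow(table)`.
#' @export
density_tiles <- function(table, x_bins = 40L, y_bins = 20L) {
  if (nrow(table) == 0L) stop("empty per-read table")
  xb <- seq(min(table$n_ref_c) - 0.5, max(table$n_ref_c) + 0.5,
            length.out = x_bins + 1L)
  yb <- seq(0, 1, length.out = y_bins + 1L)
  xi <- cut(table$n_ref_c, xb, include.lowest = TRUE, labels = FALSE)
  yi <- cut(table$frac_meth, yb, include.lowest = TRUE, labels = FALSE)
  tab <- as.data.frame(table(xi, yi), stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  xi <- as.integer(tab$xi); yi <- as.integer(tab$yi)
  data.frame(x_mid = (xb[xi] + xb[xi + 1L]) / 2,
             y_mid = (yb[yi] + yb[yi + 1L]) / 2,
             count = as.integer(tab$Freq))
}

#' Binned trend of methylated fraction against per-read C count
#'
#' The smoothed estimate of the per-read scatter's main trend, implemented
#' as binned means so it is exactly testable. Bins partition `n_ref_c` into
#' intervals of `bin_width`; empty bins are omitted.
#'
#' @param table A [per_read_table()].
#' @param bin_width Width of the `n_ref_c` bins (>= 1).
#' @return Data frame `bin_lo`, `bin_hi` (half-open), `n_ref_c_mid`,
#'   `mean_frac_meth`, `n`.
#' @export
binned_trend <- function(table, bin_width = 1L) {
  bin_width <- as.integer(bin_width)
  if (is.na(bin_width) || bin_width < 1L) stop("bin_width must be >= 1")
  bin <- table$n_ref_c %/% bin_width
  agg <- stats::aggregate(table$frac_meth, list(bin = bin),
                          function(v) c(mean(v), length(v)))
  m <- agg$x
  data.frame(bin_lo = agg$bin * bin_width,
             bin_hi = (agg$bin + 1L) * bin_width,
             n_ref_c_mid = (agg$bin + 0.5) * bin_width,
             mean_frac_meth = m[, 1L], n = as.integer(m[, 2L]))
}

new_c_count_distribution <- function(support, mass, kind) {
  if (any(mass < 0) || abs(sum(mass) - 1) > 1e-9) {
    stop("distribution mass must be nonnegative and sum to 1")
  }
  structure(list(support = as.integer(support), mass = as.numeric(mass),
                 kind = kind),
            class = "c_count_distribution")
}

#' Expected per-read C-count distribution under uniform circular coverage
#'
#' The null against which the observed per-read C-count marginal is judged:
#' if coverage were uniform over the circle, a read of length `w` would
#' start at every position with equal probability, so its reference-C count
#' would follow the enumeration of [circular_window_c_counts()]. The null
#' mixes over the empirical read-length multiset and over strands
#' (default 50/50).
#'
#' @param genome A [circular_genome()].
#' @param read_lengths Integer vector of observed read lengths (the
#'   empirical multiset; duplicated values weight the mixture).
#' @param strand_weights Numeric pair (forward, reverse) summing to 1.
#' @return A `c_count_distribution` with `kind = "expected"`.
#' @export
expected_c_distribution <- function(genome, read_lengths,
                                    strand_weights = c(0.5, 0.5)) {
  if (length(strand_weights) != 2L || any(strand_weights < 0) ||
      abs(sum(strand_weights) - 1) > 1e-9) {
    stop("strand_weights must be two nonnegative numbers summing to 1")
  }
  read_lengths <- as.integer(read_lengths)
  if (any(read_lengths < 1L | read_lengths > genome$length)) {
    stop("read lengths must lie in [1, genome length]")
  }
  len_tab <- table(read_lengths)
  len_w <- as.numeric(len_tab) / sum(len_tab)
  max_c <- max(read_lengths)
  mass <- numeric(max_c + 1L)
  for (k in seq_along(len_tab)) {
    w <- as.integer(names(len_tab))[k]
    for (s in 1:2) {
      if (strand_weights[s] == 0) next
      counts <- circular_window_c_counts(
        genome, c("forward", "reverse")[s], w)
      p <- tabulate(counts + 1L, nbins = max_c + 1L) / length(counts)
      mass <- mass + len_w[k] * strand_weights[s] * p
    }
  }
  new_c_count_distribution(0:max_c, mass, "expected")
}

#' Observed per-read C-count distribution
#'
#' Empirical distribution of `n_ref_c` over reads (reads with no covered
#' cytosine were already excluded by [per_read_table()]; each read counts
#' once, unweighted by length).
#'
#' @param table A [per_read_table()] (or per-read summaries with an
#'   `n_ref_c` column).
#' @return A `c_count_distribution` with `kind = "observed"`.
#' @export
observed_c_distribution <- function(table) {
  n <- table$n_ref_c
  if (length(n) == 0L) stop("no reads")
  max_c <- max(n)
  mass <- tabulate(n + 1L, nbins = max_c + 1L) / length(n)
  new_c_count_distribution(0:max_c, mass, "observed")
}

#' Total variation distance between two C-count distributions
#'
#' Distributions are aligned on the union of their supports;
#' `TV = 0.5 * sum(|p - q|)`, in `[0, 1]`.
#'
#' @param obs,expected Two `c_count_distribution` objects.
#' @return A single number in `[0, 1]`.
#' @export
distribution_divergence <- function(obs, expected) {
  stopifnot(inherits(obs, "c_count_distribution"),
            inherits(expected, "c_count_distribution"))
  hi <- max(max(obs$support), max(expected$support))
  p <- q <- numeric(hi + 1L)
  p[obs$support + 1L] <- obs$mass
  q[expected$support + 1L] <- expected$mass
  0.5 * sum(abs(p - q))
}

#' Mass in the C-rich tail of a C-count distribution
#'
#' Helper for the degradation signature: the probability of C counts
#' strictly above a threshold, typically the upper quartile of the expected
#' distribution.
#'
#' @param dist A `c_count_distribution`.
#' @param threshold Count value; mass strictly above it is returned.
#' @return A probability.
#' @export
upper_tail_mass <- function(dist, threshold) {
  sum(dist$mass[dist$support > threshold])
}

#' Quantile of a C-count distribution
#'
#' Smallest support value at which the cumulative mass reaches `p`.
#'
#' @param dist A `c_count_distribution`.
#' @param p Probability in `[0, 1]`.
#' @return An integer support value.
#' @export
c_count_quantile <- function(dist, p) {
  stopifnot(p >= 0, p <= 1)
  dist$support[which(cumsum(dist$mass) >= p - 1e-12)[1L]]
}

#' Figure-style per-read diagnostic panel
#'
#' Density tiles of the per-read scatter with the binned-trend curve
#' (dashed) and, below, the observed versus expected per-read C-count
#' marginals. Requires ggplot2.
#'
#' @param table A [per_read_table()].
#' @param trend A [binned_trend()].
#' @param obs,expected `c_count_distribution` objects.
#' @param x_bins,y_bins Tile resolution.
#' @return A ggplot object (patchable list of two when both marginals are
#'   supplied: `$scatter` and `$marginal`).
#' @export
plot_read_diagnostics <- function(table, trend = binned_trend(table, 5L),
                                  obs = observed_c_distribution(table),
                                  expected = NULL,
                                  x_bins = 40L, y_bins = 20L) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_read_diagnostics requires ggplot2")
  }
  tiles <- density_tiles(table, x_bins, y_bins)
  p1 <- ggplot2::ggplot(tiles, ggplot2::aes(.data$x_mid, .data$y_mid)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$count)) +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::geom_line(
      data = trend,
      ggplot2::aes(.data$n_ref_c_mid, .data$mean_frac_meth),
      linetype = "dashed", linewidth = 0.8, color = "white") +
    ggplot2::labs(x = "reference cytosines in read",
                  y = "proportion methylated", fill = "reads") +
    ggplot2::theme_minimal()
  md <- data.frame(support = obs$support, mass = obs$mass,
                   kind = "observed")
  if (!is.null(expected)) {
    md <- rbind(md, data.frame(support = expected$support,
                               mass = expected$mass, kind = "expected"))
  }
  p2 <- ggplot2::ggplot(
    md, ggplot2::aes(.data$support, .data$mass, fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "reference cytosines in read", y = "mass") +
    ggplot2::theme_minimal()
  list(scatter = p1, marginal = p2)
}
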