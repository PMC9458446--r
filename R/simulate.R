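#' Simulator configuration
#'
#' Parameters of the generative model of bisulfite (BS) library preparation
#' on a circular genome. The model emulates the mechanism by which BS-seq
#' overestimates mtDNA methylation: per-molecule methylation states,
#' fragmentation (sonication of the circle, or enzymatic linearization at a
#' fixed cut site followed by shearing), incomplete C->T conversion with a
#' fragment-level incomplete-denaturation component, selective degradation
#' of fragments in proportion to how many of their cytosines were actually
#' deaminated (methylated and otherwise unconverted cytosines are spared),
#' and single-end read emission from fragment 5' ends with full ground
#' truth.
#'
#' @param genome A [circular_genome()].
#' @param n_molecules Number of full-length template molecules (each
#'   randomly assigned a strand of origin).
#' @param meth_prob Probability that a given cytosine is methylated on a
#'   given molecule. Either a single value or a named vector with entries
#'   `CpG`, `CHG`, `CHH` for context-specific rates.
#' @param conversion_efficiency Probability that an unmethylated C on a
#'   fully denatured fragment is deaminated (reads as T).
#' @param overconversion_rate Probability that a methylated C is wrongly
#'   deaminated. Default 0.
#' @param incomplete_fraction Fraction of fragments that escape full
#'   denaturation and convert at `incomplete_efficiency` instead; these are
#'   the wholly-unconverted-read artifact of real BS libraries. Set to 0
#'   together with `conversion_efficiency = 1` for a perfectly converted
#'   control.
#' @param incomplete_efficiency Conversion efficiency on
#'   incompletely denatured fragments.
#' @param prep_mode `"sonication"` (random breakpoints on the circle) or
#'   `"linearization"` (single cut at `cut_site`, then shearing).
#' @param frag_len_mean,frag_len_sd,frag_len_min Fragment length model, bp:
#'   lengths are Normal(mean, sd) truncated below at `frag_len_min`.
#' @param degradation_rate Per-deaminated-cytosine survival penalty
#'   (delta) in `[0, 1)` applied in sonication mode: a fragment in which
#'   `u` cytosines were deaminated survives with probability
#'   `(1 - delta)^u`.
#' @param degradation_rate_linearization Corresponding (smaller) penalty in
#'   linearization mode; defaults to half `degradation_rate`.
#' @param read_length Emitted read length, bp (reads are truncated to the
#'   fragment length when shorter).
#' @param cut_site 0-based forward-strand coordinate of the linearization
#'   cut. Default 0.
#' @param seed Integer seed; all randomness in [simulate_reads()] flows
#'   from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome,
                       n_molecules = 2000L,
                       meth_prob = 0,
                       conversion_efficiency = 0.95,
                       overconversion_rate = 0,
                       incomplete_fraction = 0.08,
                       incomplete_efficiency = 0.05,
                       prep_mode = c("sonication", "linearization"),
                       frag_len_mean = 167,
                       frag_len_sd = 50,
                       frag_len_min = 30,
                       degradation_rate = 0.02,
                       degradation_rate_linearization = degradation_rate / 2,
                       read_length = 75L,
                       cut_site = 0L,
                       seed = 1L) {
  stopifnot(inherits(genome, "circular_genome"))
  prep_mode <- match.arg(prep_mode)
  probs <- c(conversion_efficiency, overconversion_rate,
             incomplete_fraction, incomplete_efficiency, meth_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (is.null(names(meth_prob))) {
    if (length(meth_prob) != 1L) stop("scalar meth_prob must have length 1")
  } else if (!all(c("CpG", "CHG", "CHH") %in% names(meth_prob))) {
    stop("context-specific meth_prob needs entries CpG, CHG and CHH")
  }
  if (degradation_rate < 0 || degradation_rate >= 1 ||
      degradation_rate_linearization < 0 ||
      degradation_rate_linearization >= 1) {
    stop("degradation rates must lie in [0, 1)")
  }
  if (n_molecules < 1L) stop("n_molecules must be positive")
  if (frag_len_min < 1 || frag_len_mean < frag_len_min) {
    stop("need frag_len_mean >= frag_len_min >= 1")
  }
  if (read_length < 1L) stop("read_length must be positive")
  structure(
    list(genome = genome, n_molecules = as.integer(n_molecules),
         meth_prob = meth_prob,
         conversion_efficiency = conversion_efficiency,
         overconversion_rate = overconversion_rate,
         incomplete_fraction = incomplete_fraction,
         incomplete_efficiency = incomplete_efficiency,
         prep_mode = prep_mode,
         frag_len_mean = frag_len_mean, frag_len_sd = frag_len_sd,
         frag_len_min = as.integer(frag_len_min),
         degradation_rate = degradation_rate,
         degradation_rate_linearization = degradation_rate_linearization,
         read_length = as.integer(read_length),
         cut_site = as.integer(cut_site) %% genome$length,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Deterministic mtDNA-like demonstration genome (synthetic)
#'
#' A fixed synthetic circular genome with rCRS-like average base
#' composition (A 0.31, C 0.31, G 0.13, T 0.25 on the forward strand), so
#' the forward strand is C-rich and is labelled L by
#' [assign_strand_labels()], as for human mtDNA. Cytosine density varies
#' regionally (sinusoidally between about 17% and 45% over two periods of
#' the circle) because real mtDNA is compositionally heterogeneous --
#' C-rich and C-poor domains are what give the per-read C-count axis its
#' spread and make selective degradation visible as a positional coverage
#' bias. The sequence is generated from an internal fixed seed and is
#' identical across calls and sessions; it stands in for the rCRS in
#' simulations so no external data are needed.
#'
#' @param length Genome length in bp, default 2000.
#' @return A [circular_genome()] named `"synthetic_mtdna"`.
#' @export
demo_genome <- function(length = 2000L) {
  length <- as.integer(length)
  i <- seq_len(length) - 1L
  p_c <- 0.31 + 0.14 * sin(2 * pi * 2 * i / length)
  p_g <- 0.13
  p_a <- (1 - p_c - p_g) * 0.55
  p_t <- (1 - p_c - p_g) * 0.45
  chars <- with_local_seed(42L, {
    u <- stats::runif(length)
    ifelse(u < p_a, "A",
           ifelse(u < p_a + p_c, "C",
                  ifelse(u < p_a + p_c + p_g, "G", "T")))
  })
  circular_genome(paste(chars, collapse = ""), name = "synthetic_mtdna")
}

# run code under a temporary seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

# per-strand cytosine positions (0-based strand coords) and trinucleotide
# contexts, cached per call site
strand_c_info <- function(genome, strand) {
  chars <- strand_chars(genome, strand)
  cpos <- which(chars == "C") - 1L
  list(chars = chars, cpos = cpos,
       context = context_from_chars(chars, cpos, genome$circular))
}

# trinucleotide context of cytosines at 0-based positions `cpos` within a
# strand's own character vector, with circular neighbors
context_from_chars <- function(chars, cpos, circular = TRUE) {
  L <- length(chars)
  nxt1 <- chars[(cpos + 1L) %% L + 1L]
  nxt2 <- chars[(cpos + 2L) %% L + 1L]
  ifelse(nxt1 == "G", "CpG", ifelse(nxt2 == "G", "CHG", "CHH"))
}

#' Simulate full-length template molecules with methylation states
#'
#' Draws `n_molecules` circular template molecules, each assigned a strand
#' of origin with equal probability, and methylates each cytosine of that
#' strand independently with `meth_prob` (context-specific when a named
#' vector is supplied). Draws come from the session RNG; [simulate_reads()]
#' seeds it from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `molecule_set`: list with `strand` (character vector) and
#'   `meth` (list of logical vectors over the strand's cytosine positions,
#'   ascending strand coordinates).
#' @export
simulate_molecules <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$genome
  info <- list(forward = strand_c_info(g, "forward"),
               reverse = strand_c_info(g, "reverse"))
  pr <- lapply(info, function(si) {
    if (is.null(names(config$meth_prob))) {
      rep(as.numeric(config$meth_prob), length(si$cpos))
    } else {
      unname(config$meth_prob[si$context])
    }
  })
  n <- config$n_molecules
  strand <- sample(c("forward", "reverse"), n, replace = TRUE)
  meth <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pr[[strand[i]]]
    meth[[i]] <- stats::runif(length(p)) < p
  }
  structure(list(strand = strand, meth = meth,
                 genome_name = g$name, genome_length = g$length),
            class = "molecule_set")
}

#' True per-position methylation proportions of a molecule set
#'
#' @param molecules A `molecule_set` from [simulate_molecules()].
#' @param genome The [circular_genome()] the molecules were simulated on.
#' @return Data frame with columns `position` (0-based forward coordinate
#'   of the cytosine; for reverse-strand cytosines this is the position of
#'   the complementary G), `strand`, `context`, `true_meth_fraction` and
#'   `n_molecules` (molecules of that strand).
#' @export
truth_table <- function(molecules, genome) {
  L <- genome$length
  out <- lapply(c("forward", "reverse"), function(s) {
    si <- strand_c_info(genome, s)
    idx <- which(molecules$strand == s)
    frac <- if (length(idx) == 0L) {
      rep(NA_real_, length(si$cpos))
    } else {
      rowMeans(do.call(cbind, molecules$meth[idx]))
    }
    fwd_pos <- if (s == "forward") si$cpos else (L - 1L - si$cpos)
    data.frame(position = fwd_pos, strand = s, context = si$context,
               true_meth_fraction = frac, n_molecules = length(idx))
  })
  res <- do.call(rbind, out)
  res[order(res$strand, res$position), , drop = FALSE]
}

# draw fragment lengths tiling a circle of length L
draw_fragment_lengths <- function(L, mean_len, sd_len, min_len) {
  lens <- integer(0)
  while (sum(lens) < L) {
    k <- max(8L, ceiling((L - sum(lens)) / max(min_len, mean_len / 2)))
    draw <- pmax(min_len, as.integer(round(stats::rnorm(k, mean_len, sd_len))))
    lens <- c(lens, draw)
  }
  cut <- which(cumsum(lens) >= L)[1L]
  lens <- lens[seq_len(cut)]
  lens[cut] <- L - sum(lens[-cut])
  if (lens[cut] < min_len && cut > 1L) {
    lens[cut - 1L] <- lens[cut - 1L] + lens[cut]
    lens <- lens[-cut]
  }
  if (lens[length(lens)] == 0L) lens <- lens[-length(lens)]
  lens
}

#' Fragment molecules into a fragment set
#'
#' Sonication places a uniformly random breakpoint phase on the circle and
#' tiles it with lengths drawn Normal(`frag_len_mean`, `frag_len_sd`)
#' truncated at `frag_len_min`; linearization cuts every molecule at the
#' configured `cut_site` and shears the resulting linear molecule the same
#' way. Fragment lengths of each molecule sum exactly to the genome length.
#'
#' @param molecules A `molecule_set`, or a single-molecule subset of one.
#' @param config A [sim_config()].
#' @return A `fragment_set`: data frame with columns `molecule`, `strand`,
#'   `start` (0-based, strand coordinates), `length`, and an attached
#'   `cytosines` attribute (data frame `fragment` (row index), `offset`
#'   (0-based within the fragment), `meth`).
#' @export
fragmentize <- function(molecules, config) {
  stopifnot(inherits(molecules, "molecule_set"),
            inherits(config, "sim_config"))
  g <- config$genome
  L <- g$length
  info <- list(forward = strand_c_info(g, "forward"),
               reverse = strand_c_info(g, "reverse"))
  n_mol <- length(molecules$strand)

  f_mol <- f_strand <- f_start <- f_len <- vector("list", n_mol)
  c_frag <- c_off <- c_meth <- vector("list", n_mol)
  frag_base <- 0L
  for (i in seq_len(n_mol)) {
    s <- molecules$strand[i]
    cpos <- info[[s]]$cpos
    off <- if (config$prep_mode == "sonication") {
      sample.int(L, 1L) - 1L
    } else if (s == "forward") {
      config$cut_site
    } else {
      (L - config$cut_site) %% L
    }
    lens <- draw_fragment_lengths(L, config$frag_len_mean,
                                  config$frag_len_sd, config$frag_len_min)
    bounds <- c(0L, cumsum(lens))
    nf <- length(lens)
    f_mol[[i]] <- rep.int(i, nf)
    f_strand[[i]] <- rep.int(s, nf)
    f_start[[i]] <- (off + bounds[-(nf + 1L)]) %% L
    f_len[[i]] <- lens
    rel <- (cpos - off) %% L
    fi <- findInterval(rel, bounds, rightmost.closed = FALSE,
                       left.open = FALSE)
    c_frag[[i]] <- frag_base + fi
    c_off[[i]] <- rel - bounds[fi]
    c_meth[[i]] <- molecules$meth[[i]]
    frag_base <- frag_base + nf
  }
  frags <- data.frame(molecule = unlist(f_mol), strand = unlist(f_strand),
                      start = unlist(f_start), length = unlist(f_len))
  cyt <- data.frame(fragment = unlist(c_frag), offset = unlist(c_off),
                    meth = unlist(c_meth))
  cyt <- cyt[order(cyt$fragment, cyt$offset), , drop = FALSE]
  rownames(cyt) <- NULL
  attr(frags, "cytosines") <- cyt
  class(frags) <- c("fragment_set", "data.frame")
  frags
}

#' Apply bisulfite conversion to a fragment set
#'
#' Each fragment is either fully denatured (probability
#' `1 - incomplete_fraction`), converting unmethylated cytosines with
#' `conversion_efficiency`, or incompletely denatured, converting with
#' `incomplete_efficiency`. Methylated cytosines convert only at
#' `overconversion_rate`. The per-cytosine outcome (deaminated or not) and
#' the per-fragment deaminated count are recorded; [fragment_sequence()]
#' materializes the converted sequence of a fragment.
#'
#' @param fragments A `fragment_set` from [fragmentize()].
#' @param config A [sim_config()].
#' @return The fragment set with added columns `incomplete` (logical) and
#'   `n_deaminated`, and a `converted` logical column on the `cytosines`
#'   attribute.
#' @export
bisulfite_convert <- function(fragments, config) {
  stopifnot(inherits(fragments, "fragment_set"))
  cyt <- attr(fragments, "cytosines")
  nf <- nrow(fragments)
  incomplete <- stats::runif(nf) < config$incomplete_fraction
  eff <- ifelse(incomplete, config$incomplete_efficiency,
                config$conversion_efficiency)
  p_conv <- ifelse(cyt$meth, config$overconversion_rate, eff[cyt$fragment])
  cyt$converted <- stats::runif(nrow(cyt)) < p_conv
  fragments$incomplete <- incomplete
  fragments$n_deaminated <- tabulate(cyt$fragment[cyt$converted], nbins = nf)
  attr(fragments, "cytosines") <- cyt
  fragments
}

#' Selectively degrade a fragment set
#'
#' Each fragment survives independently with probability
#' `(1 - rate)^u`. When conversion has been applied, `u` is the fragment's
#' count of deaminated cytosines: the deamination reaction is the damaging
#' event, so 5-methylcytosines (which resist deamination) protect a
#' fragment, and C-rich unmethylated fragments are preferentially lost --
#' the selective-degradation artifact that inflates apparent mtDNA
#' methylation. On an unconverted fragment set `u` falls back to the count
#' of unmethylated cytosines (identical in expectation when conversion is
#' perfect).
#'
#' @param fragments A `fragment_set`.
#' @param rate Survival penalty delta in `[0, 1)`; when `NULL`, taken from
#'   `config` according to its `prep_mode`.
#' @param config Optional [sim_config()] supplying `rate`.
#' @return The surviving subset, a `fragment_set` with its `cytosines`
#'   attribute re-indexed. The number of input fragments is recorded in the
#'   `n_before` attribute.
#' @export
degrade <- function(fragments, rate = NULL, config = NULL) {
  stopifnot(inherits(fragments, "fragment_set"))
  if (is.null(rate)) {
    if (is.null(config)) stop("supply `rate` or `config`")
    rate <- if (config$prep_mode == "linearization") {
      config$degradation_rate_linearization
    } else {
      config$degradation_rate
    }
  }
  if (rate < 0 || rate >= 1) stop("degradation rate must lie in [0, 1)")
  cyt <- attr(fragments, "cytosines")
  nf <- nrow(fragments)
  u <- if (!is.null(fragments$n_deaminated)) {
    fragments$n_deaminated
  } else {
    tabulate(cyt$fragment[!cyt$meth], nbins = nf)
  }
  keep <- stats::runif(nf) <= (1 - rate)^u
  out <- fragments[keep, , drop = FALSE]
  new_id <- cumsum(keep)
  ckeep <- keep[cyt$fragment]
  cyt <- cyt[ckeep, , drop = FALSE]
  cyt$fragment <- new_id[cyt$fragment]
  rownames(out) <- rownames(cyt) <- NULL
  attr(out, "cytosines") <- cyt
  class(out) <- c("fragment_set", "data.frame")
  attr(out, "n_before") <- nf
  out
}

#' Materialize the (optionally converted) sequence of one fragment
#'
#' @param fragments A `fragment_set`.
#' @param i Row index of the fragment.
#' @param genome The [circular_genome()] the fragments derive from.
#' @param converted Apply recorded conversion outcomes (requires
#'   [bisulfite_convert()] to have run) so deaminated cytosines read as T.
#' @return A single string, the fragment's own-strand 5'->3' sequence.
#' @export
fragment_sequence <- function(fragments, i, genome, converted = TRUE) {
  stopifnot(inherits(fragments, "fragment_set"), i >= 1, i <= nrow(fragments))
  chars <- strand_chars(genome, fragments$strand[i])
  L <- genome$length
  idx <- (fragments$start[i] + seq_len(fragments$length[i]) - 1L) %% L + 1L
  out <- chars[idx]
  if (converted) {
    cyt <- attr(fragments, "cytosines")
    if (is.null(cyt$converted)) stop("fragments have not been converted")
    cc <- cyt[cyt$fragment == i & cyt$converted, , drop = FALSE]
    out[cc$offset + 1L] <- "T"
  }
  paste(out, collapse = "")
}

#' Emit single-end reads from surviving fragments
#'
#' One read per fragment from its 5' end, of length
#' `min(read_length, fragment length)`. Reads are reported the way an
#' aligner would: `start` is the 0-based leftmost forward-strand reference
#' coordinate and `sequence` is forward-projected (reverse-origin reads are
#' reverse-complemented), so downstream extraction needs no external
#' aligner. The true strand and per-read methylation truth travel with each
#' read.
#'
#' @param fragments A converted `fragment_set` (see [bisulfite_convert()]).
#' @param config A [sim_config()].
#' @return Data frame of class `read_set`: `read_id`, `strand` (strand of
#'   origin), `start`, `length`, `sequence`, plus ground truth columns
#'   `true_c` (strand cytosines covered), `true_meth` (methylated among
#'   them) and `molecule`.
#' @export
emit_reads <- function(fragments, config) {
  stopifnot(inherits(fragments, "fragment_set"))
  g <- config$genome
  L <- g$length
  cyt <- attr(fragments, "cytosines")
  if (is.null(cyt$converted)) stop("fragments have not been converted")
  nf <- nrow(fragments)
  if (nf == 0L) {
    out <- data.frame(read_id = character(), strand = character(),
                      start = integer(), length = integer(),
                      sequence = character(), true_c = integer(),
                      true_meth = integer(), molecule = integer())
    class(out) <- c("read_set", "data.frame")
    return(out)
  }
  rl <- pmin(config$read_length, fragments$length)
  fchars <- strand_chars(g, "forward")
  rchars <- strand_chars(g, "reverse")

  idx <- rep.int(seq_len(nf), rl)
  off <- sequence(rl) - 1L
  spos <- (fragments$start[idx] + off) %% L
  is_fwd <- fragments$strand[idx] == "forward"
  chars <- ifelse(is_fwd, fchars[spos + 1L], rchars[spos + 1L])
  # apply conversion outcomes at read-covered cytosines
  inread <- cyt$offset < rl[cyt$fragment]
  conv <- cyt[inread & cyt$converted, , drop = FALSE]
  base_at <- c(0L, cumsum(rl))[seq_len(nf)]
  chars[base_at[conv$fragment] + conv$offset + 1L] <- "T"
  # forward projection: reverse-origin reads are reverse-complemented
  rev_rows <- !is_fwd
  chars[rev_rows] <- COMPLEMENT[chars[rev_rows]]
  ord_off <- ifelse(rev_rows, rl[idx] - 1L - off, off)
  o <- order(idx, ord_off)
  seqs <- vapply(split(chars[o], idx[o]), paste, character(1), collapse = "")
  start_fwd <- ifelse(fragments$strand == "forward", fragments$start,
                      (L - fragments$start - rl) %% L)
  covered <- cyt[inread, , drop = FALSE]
  out <- data.frame(
    read_id = sprintf("read_%d", seq_len(nf)),
    strand = fragments$strand,
    start = as.integer(start_fwd),
    length = as.integer(rl),
    sequence = unname(seqs),
    true_c = tabulate(covered$fragment, nbins = nf),
    true_meth = tabulate(covered$fragment[covered$meth], nbins = nf),
    molecule = fragments$molecule
  )
  class(out) <- c("read_set", "data.frame")
  out
}

#' Run the full library-preparation simulation
#'
#' Seeds the RNG from `config$seed` and chains
#' [simulate_molecules()] -> [fragmentize()] -> [bisulfite_convert()] ->
#' [degrade()] -> [emit_reads()]. Because the degradation stage consumes
#' exactly one uniform per fragment after all other draws, runs at matched
#' seeds but different degradation rates share molecules, fragments and
#' conversion outcomes, and the survivor sets are nested (higher delta
#' keeps a subset) -- the cleanest way to compare degradation severities.
#'
#' @param config A [sim_config()].
#' @return List of class `bs_simulation`: `reads` (a `read_set`), `truth`
#'   (see [truth_table()]), `n_molecules`, `n_fragments`, `n_surviving`,
#'   and `config`.
#' @export
simulate_reads <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  molecules <- simulate_molecules(config)
  fragments <- fragmentize(molecules, config)
  fragments <- bisulfite_convert(fragments, config)
  n_fragments <- nrow(fragments)
  survivors <- degrade(fragments, config = config)
  reads <- emit_reads(survivors, config)
  structure(
    list(reads = reads, truth = truth_table(molecules, config$genome),
         n_molecules = config$n_molecules, n_fragments = n_fragments,
         n_surviving = nrow(survivors), config = config),
    class = "bs_simulation"
  )
}

#' @export
print.bs_simulation <- function(x, ...) {
  cat(sprintf(
    "<bs_simulation> %d molecules -> %d fragments -> %d surviving reads (%s, delta = %g)\n",
    x$n_molecules, x$n_fragments, x$n_surviving,
    x$config$prep_mode,
    if (x$config$prep_mode == "linearization")
      x$config$degradation_rate_linearization else x$config$degradation_rate))
  invisible(x)
}

#' Write reads as FASTQ
#'
#' Standard four-line records with uniform maximum quality (the simulator
#' does not model base quality).
#'
#' @param reads A `read_set` from [emit_reads()].
#' @param path Output path (`.gz` accepted).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$read_id
  Biostrings::writeXStringSet(seqs, path, format = "fastq")
  invisible(path)
}
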