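# independent brute-force oracles and small fixture builders

random_genome <- function(n, seed, name = "rand",
                          prob = c(0.3, 0.3, 0.15, 0.25)) {
  set.seed(seed)
  circular_genome(paste(sample(c("A", "C", "G", "T"), n, TRUE, prob),
                        collapse = ""), name = name)
}

write_temp_fasta <- function(records, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".fa.gz" else ".fa")
  con <- if (gz) gzfile(path, "w") else file(path, "w")
  for (nm in names(records)) {
    writeLines(c(paste0(">", nm), records[[nm]]), con)
  }
  close(con)
  path
}

# naive per-start recount of circular window C counts
brute_window_c <- function(genome, strand, w) {
  chars <- strand_chars(genome, strand)
  L <- genome$length
  vapply(seq_len(L) - 1L, function(a) {
    sum(chars[(a + seq_len(w) - 1L) %% L + 1L] == "C")
  }, integer(1))
}

# nested-loop tally of methylation calls and base coverage over reads
brute_pileup_tally <- function(reads, genome) {
  L <- genome$length
  ref <- strand_chars(genome, "forward")
  meth <- unmeth <- matrix(0L, nrow = L, ncol = 2,
                           dimnames = list(NULL, c("forward", "reverse")))
  base_cov <- integer(L)
  for (i in seq_len(nrow(reads))) {
    chars <- strsplit(reads$sequence[i], "")[[1]]
    for (k in seq_along(chars)) {
      p <- (reads$start[i] + k - 1L) %% L
      base_cov[p + 1L] <- base_cov[p + 1L] + 1L
      s <- reads$strand[i]
      if (s == "forward" && ref[p + 1L] == "C") {
        if (chars[k] == "C") meth[p + 1L, s] <- meth[p + 1L, s] + 1L
        if (chars[k] == "T") unmeth[p + 1L, s] <- unmeth[p + 1L, s] + 1L
      }
      if (s == "reverse" && ref[p + 1L] == "G") {
        if (chars[k] == "G") meth[p + 1L, s] <- meth[p + 1L, s] + 1L
        if (chars[k] == "A") unmeth[p + 1L, s] <- unmeth[p + 1L, s] + 1L
      }
    }
  }
  list(meth = meth, unmeth = unmeth, base_cov = base_cov)
}

# exhaustive enumeration of the uniform-coverage C-count null
brute_expected_dist <- function(genome, read_lengths, strand_weights) {
  counts <- numeric(max(read_lengths) + 1L)
  lens <- table(read_lengths)
  for (k in seq_along(lens)) {
    w <- as.integer(names(lens))[k]
    lw <- as.numeric(lens[k]) / length(read_lengths)
    for (s in 1:2) {
      cc <- brute_window_c(genome, c("forward", "reverse")[s], w)
      for (v in cc) {
        counts[v + 1L] <- counts[v + 1L] +
          lw * strand_weights[s] / length(cc)
      }
    }
  }
  counts
}

# a small synthetic pileup with given per-position counts
uniform_pileup <- function(n_pos, coverage, meth_count) {
  as_pileup(data.frame(
    position = seq_len(n_pos) - 1L, strand = "forward", context = "CHH",
    coverage = coverage, meth_count = meth_count))
}
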