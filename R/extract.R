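#' Strand-aware per-read methylation calling
#'
#' Calls methylation for one ungapped read against a circular reference.
#' For forward-origin reads, every forward-strand reference cytosine under
#' the read yields a call: read base `C` is methylated (the cytosine
#' resisted conversion), `T` unmethylated, anything else no call. For
#' reverse-origin reads the same logic runs on the opposite strand in
#' forward coordinates: at reference `G` positions, read base `G` is
#' methylated and `A` unmethylated. Positions without a call contribute
#' neither to `n_ref_c` nor to coverage.
#'
#' @param read One-row data frame (or list) with `read_id`, `strand`
#'   (`"forward"`/`"reverse"`), `start` (0-based forward coordinate),
#'   `sequence` (forward-projected, as an aligner reports it) and `length`.
#' @param genome A [circular_genome()].
#' @return List with `summary` (data frame `read_id`, `n_ref_c`, `n_meth`,
#'   `frac_meth`; `frac_meth` is `NA` when no cytosine is covered) and
#'   `calls` (data frame `position`, `strand`, `context`, `methylated`).
#' @export
call_read <- function(read, genome) {
  L <- genome$length
  start <- as.integer(read$start)
  if (is.na(start) || start < 0L || start >= L) {
    stop("read start must lie in [0, genome length)")
  }
  chars <- strsplit(read$sequence[[1]], "", fixed = TRUE)[[1L]]
  pos <- (start + seq_along(chars) - 1L) %% L
  ref <- strand_chars(genome, "forward")[pos + 1L]
  if (identical(read$strand[[1]], "forward")) {
    at <- ref == "C"
    meth_base <- "C"; unmeth_base <- "T"; strand <- "forward"
  } else {
    at <- ref == "G"
    meth_base <- "G"; unmeth_base <- "A"; strand <- "reverse"
  }
  called <- at & chars %in% c(meth_base, unmeth_base)
  calls <- data.frame(
    position = pos[called], strand = strand,
    context = if (any(called)) {
      annotate_context(genome, pos[called], strand)
    } else {
      character(0)
    },
    methylated = chars[called] == meth_base
  )
  n_ref_c <- nrow(calls)
  n_meth <- sum(calls$methylated)
  list(
    summary = data.frame(
      read_id = as.character(read$read_id[[1]]),
      n_ref_c = n_ref_c, n_meth = n_meth,
      frac_meth = if (n_ref_c > 0L) n_meth / n_ref_c else NA_real_),
    calls = calls
  )
}

# vectorized flat decomposition of a read set: one row per aligned base
flat_read_bases <- function(reads, genome) {
  L <- genome$length
  lens <- as.integer(reads$length)
  idx <- rep.int(seq_len(nrow(reads)), lens)
  off <- sequence(lens) - 1L
  pos <- (rep.int(as.integer(reads$start), lens) + off) %% L
  chars <- unlist(strsplit(reads$sequence, "", fixed = TRUE),
                  use.names = FALSE)
  list(idx = idx, pos = pos, chars = chars,
       is_fwd = rep.int(reads$strand == "forward", lens))
}

#' Per-read methylation summaries for a read set
#'
#' Vectorized equivalent of applying [call_read()] to every read.
#'
#' @param reads A data frame of reads (see [call_read()] for required
#'   columns), e.g. from [emit_reads()] or [read_sam()].
#' @param genome A [circular_genome()].
#' @return Data frame with one row per read: `read_id`, `strand`,
#'   `n_ref_c`, `n_meth`, `frac_meth` (`NA` where `n_ref_c` is 0).
#' @export
call_reads <- function(reads, genome) {
  n <- nrow(reads)
  fl <- flat_read_bases(reads, genome)
  ref <- strand_chars(genome, "forward")[fl$pos + 1L]
  called_f <- fl$is_fwd & ref == "C" & fl$chars %in% c("C", "T")
  called_r <- !fl$is_fwd & ref == "G" & fl$chars %in% c("G", "A")
  called <- called_f | called_r
  meth <- (called_f & fl$chars == "C") | (called_r & fl$chars == "G")
  n_ref_c <- tabulate(fl$idx[called], nbins = n)
  n_meth <- tabulate(fl$idx[meth], nbins = n)
  data.frame(read_id = reads$read_id, strand = reads$strand,
             n_ref_c = n_ref_c, n_meth = n_meth,
             frac_meth = ifelse(n_ref_c > 0L, n_meth / n_ref_c, NA_real_))
}

#' Trinucleotide context of reference cytosines
#'
#' Standard bisulfite contexts with circular neighbors: `CpG` when the next
#' base on the cytosine's strand is G, `CHG` when the base after next is G,
#' otherwise `CHH` (N neighbors count as H). Positions are given in forward
#' coordinates; for the reverse strand, `position` is the forward
#' coordinate of the complementary G and neighbors are read 5'->3' on the
#' reverse strand.
#'
#' @param genome A [circular_genome()].
#' @param position Integer vector of 0-based forward coordinates.
#' @param strand `"forward"` or `"reverse"` (scalar).
#' @return Character vector of contexts.
#' @export
annotate_context <- function(genome, position,
                             strand = c("forward", "reverse")) {
  strand <- match.arg(strand)
  L <- genome$length
  position <- as.integer(position)
  fchars <- strand_chars(genome, "forward")
  if (strand == "forward") {
    if (any(fchars[position + 1L] != "C")) {
      stop("position is not a C on the forward strand")
    }
    nxt1 <- fchars[(position + 1L) %% L + 1L]
    nxt2 <- fchars[(position + 2L) %% L + 1L]
    ifelse(nxt1 == "G", "CpG", ifelse(nxt2 == "G", "CHG", "CHH"))
  } else {
    if (any(fchars[position + 1L] != "G")) {
      stop("position is not a C on the reverse strand")
    }
    nxt1 <- fchars[(position - 1L) %% L + 1L]
    nxt2 <- fchars[(position - 2L) %% L + 1L]
    ifelse(nxt1 == "C", "CpG", ifelse(nxt2 == "C", "CHG", "CHH"))
  }
}

#' Aggregate per-read calls into a per-position pileup
#'
#' Every reference cytosine of both strands appears in the pileup, covered
#' or not, so downstream position classification sees uncovered positions
#' too. Alongside the methylation-call counts, total aligned base coverage
#' per forward position (every aligned base, callable or not) is recorded
#' in the `base_coverage` attribute; [c_coverage_bias()] uses it.
#'
#' @param reads A data frame of reads (see [call_reads()]).
#' @param genome A [circular_genome()].
#' @return A `pileup`: data frame with columns `position` (0-based forward
#'   coordinate), `strand`, `context`, `coverage`, `meth_count`,
#'   `unmeth_count`, where `coverage = meth_count + unmeth_count` counts
#'   methylation calls only. Attributes: `base_coverage` (integer vector,
#'   one entry per genome position), `genome_name`, `genome_length`.
#' @export
build_pileup <- function(reads, genome) {
  L <- genome$length
  fchars <- strand_chars(genome, "forward")
  if (nrow(reads) > 0L) {
    fl <- flat_read_bases(reads, genome)
    ref <- fchars[fl$pos + 1L]
    called_f <- fl$is_fwd & ref == "C" & fl$chars %in% c("C", "T")
    called_r <- !fl$is_fwd & ref == "G" & fl$chars %in% c("G", "A")
    meth <- (called_f & fl$chars == "C") | (called_r & fl$chars == "G")
    cov_f <- tabulate(fl$pos[called_f] + 1L, nbins = L)
    meth_f <- tabulate(fl$pos[called_f & meth] + 1L, nbins = L)
    cov_r <- tabulate(fl$pos[called_r] + 1L, nbins = L)
    meth_r <- tabulate(fl$pos[called_r & meth] + 1L, nbins = L)
    base_cov <- tabulate(fl$pos + 1L, nbins = L)
  } else {
    cov_f <- meth_f <- cov_r <- meth_r <- base_cov <- integer(L)
  }
  cpos_f <- which(fchars == "C") - 1L
  cpos_r <- which(fchars == "G") - 1L
  out <- rbind(
    data.frame(position = cpos_f, strand = "forward",
               context = annotate_context(genome, cpos_f, "forward"),
               coverage = cov_f[cpos_f + 1L],
               meth_count = meth_f[cpos_f + 1L]),
    data.frame(position = cpos_r, strand = "reverse",
               context = annotate_context(genome, cpos_r, "reverse"),
               coverage = cov_r[cpos_r + 1L],
               meth_count = meth_r[cpos_r + 1L])
  )
  out$unmeth_count <- out$coverage - out$meth_count
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  as_pileup(out, base_coverage = base_cov, genome_name = genome$name,
            genome_length = L)
}

#' Validate and mark a data frame as a pileup
#'
#' For pileups assembled outside [build_pileup()] (for instance synthetic
#' worked examples). Requires columns `position`, `strand`, `coverage`,
#' `meth_count`; `unmeth_count` defaults to `coverage - meth_count` and
#' `context` to `"CHH"` when absent.
#'
#' @param x Data frame of per-position counts.
#' @param base_coverage Optional integer vector of total aligned-base
#'   coverage per genome position.
#' @param genome_name,genome_length Optional provenance fields.
#' @return `x` with class `pileup`.
#' @export
as_pileup <- function(x, base_coverage = NULL, genome_name = NA_character_,
                      genome_length = NA_integer_) {
  need <- c("position", "strand", "coverage", "meth_count")
  if (!all(need %in% names(x))) {
    stop("pileup needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(x$unmeth_count)) x$unmeth_count <- x$coverage - x$meth_count
  if (is.null(x$context)) x$context <- "CHH"
  if (any(x$meth_count + x$unmeth_count != x$coverage)) {
    stop("meth_count + unmeth_count must equal coverage at every position")
  }
  if (any(x$meth_count < 0 | x$unmeth_count < 0)) {
    stop("negative counts in pileup")
  }
  structure(x, base_coverage = base_coverage, genome_name = genome_name,
            genome_length = genome_length,
            class = c("pileup", "data.frame"))
}

#' Write a pileup as TSV
#'
#' Output positions are 1-based (bioinformatics convention); internal
#' arithmetic is 0-based half-open.
#'
#' @param pileup A `pileup`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup_tsv <- function(pileup, path) {
  out <- data.frame(position = pileup$position + 1L, strand = pileup$strand,
                    context = pileup$context, coverage = pileup$coverage,
                    meth_count = pileup$meth_count,
                    meth_fraction = ifelse(pileup$coverage > 0,
                                           pileup$meth_count / pileup$coverage,
                                           NA_real_))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read aligned bisulfite reads from SAM
#'
#' Expects a SAM file with a single-reference header and ungapped
#' alignments (the package's documented limitation for external input;
#' indel-containing reads are dropped with a warning). Strand of origin is
#' taken from the Bismark-style `XG` tag when present (`CT` = forward
#' genome, `GA` = reverse), otherwise from the reverse-complement FLAG bit.
#' When the per-read methylation-call `XM` tag is present
#' (`z/Z` CpG, `x/X` CHG, `h/H` CHH, `u/U` unknown; uppercase =
#' methylated), per-read summaries are derived from it directly via
#' [xm_summaries()]; otherwise call against the reference with
#' [call_reads()].
#'
#' @param path Path to a SAM file.
#' @param genome Optional [circular_genome()] for length validation.
#' @return A data frame of reads (`read_id`, `strand`, `start`, `length`,
#'   `sequence`) with an `xm` attribute holding the XM strings (or `NULL`).
#' @export
read_sam <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ".bam"),
                          overwrite = TRUE, indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "seq", "cigar"),
    tag = c("XM", "XR", "XG"))
  res <- Rsamtools::scanBam(bam, param = p)[[1L]]
  mapped <- !is.na(res$pos)
  gapped <- grepl("[IDNSHP]", res$cigar) & mapped
  if (any(gapped)) {
    warning(sum(gapped), " read(s) with non-matching CIGAR dropped")
  }
  keep <- mapped & !gapped
  xg <- res$tag$XG
  strand <- if (!is.null(xg) && !all(is.na(xg))) {
    ifelse(xg == "GA", "reverse", "forward")
  } else {
    ifelse(bitwAnd(res$flag, 16L) > 0L, "reverse", "forward")
  }
  seqs <- as.character(res$seq)
  out <- data.frame(read_id = res$qname[keep], strand = strand[keep],
                    start = res$pos[keep] - 1L,
                    length = nchar(seqs[keep]), sequence = seqs[keep])
  if (!is.null(genome) && nrow(out) > 0L &&
      any(out$start < 0L | out$start >= genome$length)) {
    stop("read start outside genome")
  }
  xm <- res$tag$XM
  attr(out, "xm") <- if (!is.null(xm)) xm[keep] else NULL
  out
}

#' Per-read summaries from Bismark-style XM methylation strings
#'
#' @param xm Character vector of XM strings (one per read); `z/Z` CpG,
#'   `x/X` CHG, `h/H` CHH, `u/U` unknown context, uppercase = methylated.
#' @param read_id Optional read identifiers.
#' @return Data frame `read_id`, `n_ref_c`, `n_meth`, `frac_meth`.
#' @export
xm_summaries <- function(xm, read_id = NULL) {
  n_ref_c <- nchar(gsub("[^zZxXhHuU]", "", xm))
  n_meth <- nchar(gsub("[^ZXHU]", "", xm))
  data.frame(
    read_id = if (is.null(read_id)) sprintf("read_%d", seq_along(xm))
              else read_id,
    n_ref_c = n_ref_c, n_meth = n_meth,
    frac_meth = ifelse(n_ref_c > 0L, n_meth / n_ref_c, NA_real_))
}
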