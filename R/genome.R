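#' Circular genome objects
#'
#' A `circular_genome` models a single circular nucleotide sequence such as
#' the 16,569 bp human mitochondrial genome. Coordinates are 0-based,
#' half-open throughout the package; circular wraparound is index modulo
#' length. The two strands are referred to as `"forward"` (the sequence as
#' stored) and `"reverse"` (its reverse complement, in its own 5'->3'
#' coordinates); biological heavy/light (H/L) labels are assigned from base
#' composition by [assign_strand_labels()].
#'
#' @param sequence Nucleotide string over `A`, `C`, `G`, `T`, `N`
#'   (lowercase accepted, stored uppercase).
#' @param name Identifier for the sequence.
#' @param circular Logical; the package's analyses assume `TRUE`.
#' @return An object of class `circular_genome` with fields `name`,
#'   `sequence`, `length` and `circular`.
#' @examples
#' g <- circular_genome("ACGTACGT", name = "toy")
#' g$length
#' @export
circular_genome <- function(sequence, name = "genome", circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) {
    stop("genome sequence must be non-empty")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L) {
    stop("non-nucleotide characters in sequence: ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(name = as.character(name), sequence = sequence,
         length = length(chars), circular = isTRUE(circular)),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %d bp%s\n", x$name, x$length,
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Per-strand character vector of a genome
#'
#' Returns the bases of the requested strand in that strand's own 5'->3'
#' order (the reverse strand is the reverse complement of the stored
#' sequence). Position `i` (0-based) of the reverse strand corresponds to
#' forward-coordinate `length - 1 - i`.
#'
#' @param genome A [circular_genome()].
#' @param strand `"forward"` or `"reverse"`.
#' @return Character vector of single bases, length `genome$length`.
#' @export
strand_chars <- function(genome, strand = c("forward", "reverse")) {
  strand <- match.arg(strand)
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1L]]
  if (strand == "forward") chars else unname(rev(COMPLEMENT[chars]))
}

#' Base composition of one strand
#'
#' Counts of `A`, `C`, `G`, `T`, `N` on the requested strand. Reverse-strand
#' counts are the complement of the forward counts, so forward C equals
#' reverse G and vice versa; totals equal the genome length.
#'
#' @inheritParams strand_chars
#' @return Named integer vector over `A`, `C`, `G`, `T`, `N`.
#' @export
base_composition <- function(genome, strand = c("forward", "reverse")) {
  strand <- match.arg(strand)
  chars <- strand_chars(genome, strand)
  counts <- table(factor(chars, levels = c("A", "C", "G", "T", "N")))
  stats::setNames(as.integer(counts), names(counts))
}

#' Assign heavy/light strand labels from base composition
#'
#' Mitochondrial strands are named heavy (H) and light (L) for their
#' buoyant-density difference, which tracks purine/pyrimidine content: the
#' G-rich strand is H and the C-rich strand is L. Labels here are derived
#' from the composition of the supplied genome rather than assumed from any
#' reference convention. An exact C = G tie cannot be resolved from
#' composition and is an error; set labels explicitly in your run
#' configuration in that case.
#'
#' @param genome A [circular_genome()].
#' @return A `strand_labeling` list with `forward_label` and
#'   `reverse_label`, each `"H"` or `"L"`.
#' @examples
#' assign_strand_labels(circular_genome("GGGAC"))$forward_label # "H"
#' @export
assign_strand_labels <- function(genome) {
  comp <- base_composition(genome, "forward")
  if (comp[["C"]] == comp[["G"]]) {
    stop("forward-strand C and G counts are equal; H/L labels cannot be ",
         "derived from composition -- set strand labels explicitly in the ",
         "run configuration")
  }
  fwd <- if (comp[["G"]] > comp[["C"]]) "H" else "L"
  structure(
    list(forward_label = fwd, reverse_label = if (fwd == "H") "L" else "H"),
    class = "strand_labeling"
  )
}

#' Cytosine counts in every circular window
#'
#' For each of the `length` start positions on the given strand (that
#' strand's own coordinates), counts the strand's cytosines in the window of
#' `window_len` bases beginning there, wrapping around the circle. This
#' enumeration over all start positions is the uniform-coverage null used by
#' [expected_c_distribution()]: under uniform circular coverage every window
#' is equally likely to be sequenced.
#'
#' @inheritParams strand_chars
#' @param window_len Window length in bp, between 1 and the genome length.
#' @return Integer vector of length `genome$length`; entry `i` (1-based in
#'   R) is the C count of the window starting at 0-based position `i - 1`.
#' @examples
#' circular_window_c_counts(circular_genome("CCAA"), "forward", 2) # 2 1 0 1
#' @export
circular_window_c_counts <- function(genome,
                                     strand = c("forward", "reverse"),
                                     window_len) {
  strand <- match.arg(strand)
  L <- genome$length
  window_len <- as.integer(window_len)
  if (is.na(window_len) || window_len < 1L || window_len > L) {
    stop("window_len must be in [1, genome length]")
  }
  is_c <- as.integer(strand_chars(genome, strand) == "C")
  if (window_len == 1L) return(is_c)
  # sliding circular sum via cumulative sums over the wrapped vector
  ext <- c(is_c, is_c[seq_len(window_len - 1L)])
  cs <- cumsum(ext)
  counts <- cs[window_len:length(ext)] - c(0L, cs[seq_len(L - 1L)])
  as.integer(counts)
}

#' Load a single-record FASTA file as a circular genome
#'
#' Accepts plain or gzip-compressed FASTA with one sequence record
#' (multi-line sequences fine). The record is uppercased and returned as a
#' [circular_genome()] with `circular = TRUE`.
#'
#' @param path Path to the FASTA file.
#' @param circular Logical, default `TRUE`.
#' @return A [circular_genome()].
#' @export
load_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(set) != 1L) {
    stop("expected exactly one FASTA record, found ", length(set))
  }
  circular_genome(as.character(set[[1L]]), name = names(set)[1L],
                  circular = circular)
}
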