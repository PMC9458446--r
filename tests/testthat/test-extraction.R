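test_that("per-read calling handles both strands in forward coordinates", {
  g <- circular_genome("ACCGTA")
  # forward read identical to the reference: every C resisted conversion
  r <- list(read_id = "f1", strand = "forward", start = 0L,
            sequence = "ACCGTA", length = 6L)
  res <- call_read(r, g)
  expect_equal(res$summary$n_ref_c, 2L)
  expect_equal(res$summary$frac_meth, 1)
  expect_equal(res$calls$position, c(1L, 2L))

  # every reference C read as T: fully converted
  rt <- list(read_id = "f2", strand = "forward", start = 0L,
             sequence = "ATTGTA", length = 6L)
  expect_equal(call_read(rt, g)$summary$frac_meth, 0)

  # reverse-origin read: calls at reference G positions, G = methylated
  rr <- list(read_id = "r1", strand = "reverse", start = 0L,
             sequence = "ACCGTA", length = 6L)
  resr <- call_read(rr, g)
  expect_equal(resr$summary$n_ref_c, 1L)
  expect_equal(resr$calls$position, 3L)
  expect_equal(resr$summary$frac_meth, 1)
  ra <- list(read_id = "r2", strand = "reverse", start = 0L,
             sequence = "ACCATA", length = 6L)
  expect_equal(call_read(ra, g)$summary$frac_meth, 0)

  # ambiguous bases at callable positions are no-calls
  rn <- list(read_id = "f3", strand = "forward", start = 0L,
             sequence = "ACNGTA", length = 6L)
  expect_equal(call_read(rn, g)$summary$n_ref_c, 1L)

  # circular overhang wraps around the origin: covers 4,5,0,1
  rw <- list(read_id = "w", strand = "forward", start = 4L,
             sequence = "TAAC", length = 4L)
  resw <- call_read(rw, g)
  expect_equal(resw$calls$position, 1L)
  expect_equal(resw$summary$n_meth, 1L)
  expect_equal(resw$summary$n_ref_c, 1L)
  expect_error(call_read(list(read_id = "b", strand = "forward",
                              start = 9L, sequence = "A", length = 1L), g),
               "start")
})

test_that("bulk calling equals per-read calling and the simulator's truth", {
  g <- demo_genome(800)
  cfg <- sim_config(g, n_molecules = 40, meth_prob = 0.5,
                    conversion_efficiency = 1, incomplete_fraction = 0,
                    overconversion_rate = 0, degradation_rate = 0, seed = 31)
  sim <- simulate_reads(cfg)
  s <- call_reads(sim$reads, g)
  # with perfect conversion the calls recover the per-molecule truth exactly
  expect_equal(s$n_ref_c, sim$reads$true_c)
  expect_equal(s$n_meth, sim$reads$true_meth)
  # and the vectorized path agrees with the scalar one
  for (i in c(1L, 7L, nrow(sim$reads))) {
    one <- call_read(sim$reads[i, ], g)$summary
    expect_equal(s$n_ref_c[i], one$n_ref_c)
    expect_equal(s$n_meth[i], one$n_meth)
  }
})

test_that("context annotation follows the trinucleotide rule with wraparound", {
  g <- circular_genome("ACGACAGACATA")
  expect_equal(annotate_context(g, 1L, "forward"), "CpG")
  expect_equal(annotate_context(g, 4L, "forward"), "CHG")
  expect_equal(annotate_context(g, 8L, "forward"), "CHH")
  # C at the last position of "GAAC" wraps to the leading G
  expect_equal(annotate_context(circular_genome("GAAC"), 3L, "forward"),
               "CpG")
  # reverse strand: C at forward G, neighbors 5'->3' on the reverse strand
  g2 <- circular_genome("CGTTTT")
  expect_equal(annotate_context(g2, 1L, "reverse"), "CpG")
  expect_error(annotate_context(g, 0L, "forward"), "not a C")
})

test_that("pileup aggregation is conservative and matches a brute-force tally", {
  g <- demo_genome(600)
  cfg <- sim_config(g, n_molecules = 250, meth_prob = 0.3,
                    conversion_efficiency = 0.9, seed = 32)
  sim <- simulate_reads(cfg)
  reads <- sim$reads
  expect_gt(nrow(reads), 500)
  p <- build_pileup(reads, g)
  expect_true(all(p$meth_count + p$unmeth_count == p$coverage))

  # conservation against per-read summaries
  s <- call_reads(reads, g)
  expect_equal(sum(p$coverage), sum(s$n_ref_c))
  expect_equal(sum(p$meth_count), sum(s$n_meth))

  # nested-loop oracle equivalence, entry by entry
  oracle <- brute_pileup_tally(reads, g)
  for (strand in c("forward", "reverse")) {
    sub <- p[p$strand == strand, ]
    expect_equal(sub$meth_count, oracle$meth[sub$position + 1L, strand])
    expect_equal(sub$coverage - sub$meth_count,
                 oracle$unmeth[sub$position + 1L, strand])
  }
  expect_equal(attr(p, "base_coverage"), oracle$base_cov)

  # a duplicated read doubles its own counts
  one <- reads[1, ]
  p1 <- build_pileup(one, g)
  p2 <- build_pileup(rbind(one, one), g)
  expect_equal(p2$meth_count, 2L * p1$meth_count)
  expect_equal(p2$coverage, 2L * p1$coverage)
})

test_that("calling is invariant under reverse-complementing the world", {
  g <- random_genome(400, seed = 41)
  cfg <- sim_config(g, n_molecules = 30, meth_prob = 0.4, seed = 42)
  reads <- simulate_reads(cfg)$reads
  s1 <- call_reads(reads, g)

  chars <- strsplit(g$sequence, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  g_rc <- circular_genome(paste(rev(comp[chars]), collapse = ""))
  flipped <- reads
  flipped$strand <- ifelse(reads$strand == "forward", "reverse", "forward")
  flipped$start <- (g$length - reads$start - reads$length) %% g$length
  flipped$sequence <- vapply(strsplit(reads$sequence, ""), function(ch) {
    paste(rev(comp[ch]), collapse = "")
  }, character(1))
  s2 <- call_reads(flipped, g_rc)
  expect_equal(s1$n_ref_c, s2$n_ref_c)
  expect_equal(s1$n_meth, s2$n_meth)
})

test_that("SAM input recovers coordinates, strand and XM summaries", {
  g <- circular_genome("ACCGTAAC", name = "chrM")
  sam <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chrM\tLN:8",
    paste("r1", 0, "chrM", 1, 42, "6M", "*", 0, 0, "ACCGTA", "IIIIII",
          "XM:Z:.ZX...", "XR:Z:CT", "XG:Z:CT", sep = "\t"),
    paste("r2", 16, "chrM", 1, 42, "6M", "*", 0, 0, "ACCATA", "IIIIII",
          "XM:Z:...h..", "XR:Z:CT", "XG:Z:GA", sep = "\t"),
    paste("r3", 0, "chrM", 2, 42, "4M1I1M", "*", 0, 0, "CTGAAC", "IIIIII",
          sep = "\t")
  )
  path <- tempfile(fileext = ".sam")
  writeLines(sam, path)
  expect_warning(reads <- read_sam(path, g), "CIGAR")
  expect_equal(nrow(reads), 2L)
  expect_equal(reads$start, c(0L, 0L))
  expect_equal(reads$strand, c("forward", "reverse"))
  expect_equal(reads$sequence, c("ACCGTA", "ACCATA"))

  xm <- attr(reads, "xm")
  xs <- xm_summaries(xm, reads$read_id)
  expect_equal(xs$n_ref_c, c(2L, 1L))
  expect_equal(xs$n_meth, c(2L, 0L))

  # sequence-based re-calling agrees with the XM strings here
  s <- call_reads(reads, g)
  expect_equal(s$n_ref_c, xs$n_ref_c)
  expect_equal(s$n_meth, xs$n_meth)
})
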