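test_that("sim_config validates probabilities, rates and sizes", {
  g <- demo_genome(200)
  expect_s3_class(sim_config(g), "sim_config")
  expect_error(sim_config(g, meth_prob = 1.2), "probabilities")
  expect_error(sim_config(g, conversion_efficiency = -0.1), "probabilities")
  expect_error(sim_config(g, degradation_rate = 1), "degradation")
  expect_error(sim_config(g, n_molecules = 0), "n_molecules")
  expect_error(sim_config(g, meth_prob = c(CpG = 0.5)), "CHG")
})

test_that("molecule methylation states follow the configured probability", {
  g <- demo_genome(500)
  set.seed(1)
  mol0 <- simulate_molecules(sim_config(g, n_molecules = 50, meth_prob = 0))
  expect_false(any(unlist(mol0$meth)))
  mol1 <- simulate_molecules(sim_config(g, n_molecules = 50, meth_prob = 1))
  expect_true(all(unlist(mol1$meth)))

  # empirical rate within 3 binomial SDs of 0.3
  cfg <- sim_config(g, n_molecules = 2000, meth_prob = 0.3)
  set.seed(2)
  mol <- simulate_molecules(cfg)
  states <- unlist(mol$meth)
  n <- length(states)
  expect_lt(abs(mean(states) - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  expect_setequal(unique(mol$strand), c("forward", "reverse"))
})

test_that("context-specific methylation hits only the requested context", {
  g <- demo_genome(500)
  cfg <- sim_config(g, n_molecules = 20,
                    meth_prob = c(CpG = 1, CHG = 0, CHH = 0))
  set.seed(3)
  mol <- simulate_molecules(cfg)
  frags <- fragmentize(mol, cfg)
  tt <- truth_table(mol, g)
  expect_true(all(tt$true_meth_fraction[tt$context == "CpG"] == 1))
  expect_true(all(tt$true_meth_fraction[tt$context != "CpG"] == 0))
})

test_that("fragment lengths tile the circle exactly", {
  g <- demo_genome(2000)
  cfg <- sim_config(g, n_molecules = 30)
  set.seed(4)
  mol <- simulate_molecules(cfg)
  frags <- fragmentize(mol, cfg)
  sums <- tapply(frags$length, frags$molecule, sum)
  expect_true(all(sums == g$length))

  # degenerate shearing: sd = 0 with mean dividing the genome length
  cfg0 <- sim_config(g, n_molecules = 5, frag_len_mean = 100,
                     frag_len_sd = 0, frag_len_min = 50)
  set.seed(5)
  frags0 <- fragmentize(simulate_molecules(cfg0), cfg0)
  expect_true(all(frags0$length == 100L))

  # mean length close to the configured mean over many fragments
  cfg1 <- sim_config(g, n_molecules = 1000)
  set.seed(6)
  frags1 <- fragmentize(simulate_molecules(cfg1), cfg1)
  expect_gt(nrow(frags1), 10000)
  expect_lt(abs(mean(frags1$length) - cfg1$frag_len_mean),
            0.05 * cfg1$frag_len_mean)
})

test_that("linearization cuts every molecule at the configured site", {
  g <- demo_genome(1000)
  cfg <- sim_config(g, n_molecules = 40, prep_mode = "linearization",
                    cut_site = 250)
  set.seed(7)
  mol <- simulate_molecules(cfg)
  frags <- fragmentize(mol, cfg)
  first <- frags[!duplicated(frags$molecule), ]
  expect_true(all(first$start[first$strand == "forward"] == 250L))
  expect_true(all(first$start[first$strand == "reverse"] ==
                    (1000L - 250L) %% 1000L))
})

test_that("bisulfite conversion behaves at the efficiency extremes", {
  g <- demo_genome(1000)
  set.seed(8)
  # perfect conversion on an unmethylated sample leaves no cytosine
  cfg1 <- sim_config(g, n_molecules = 3, meth_prob = 0,
                     conversion_efficiency = 1, incomplete_fraction = 0)
  fr1 <- bisulfite_convert(fragmentize(simulate_molecules(cfg1), cfg1), cfg1)
  for (i in c(1L, nrow(fr1))) {
    expect_false(grepl("C", fragment_sequence(fr1, i, g)))
  }
  # zero efficiency leaves the sequence untouched
  cfg0 <- sim_config(g, n_molecules = 3, meth_prob = 0,
                     conversion_efficiency = 0, incomplete_fraction = 0)
  set.seed(9)
  fr0 <- bisulfite_convert(fragmentize(simulate_molecules(cfg0), cfg0), cfg0)
  expect_identical(fragment_sequence(fr0, 1, g, converted = TRUE),
                   fragment_sequence(fr0, 1, g, converted = FALSE))

  # residual-C rate near 1 - efficiency
  cfge <- sim_config(g, n_molecules = 60, meth_prob = 0,
                     conversion_efficiency = 0.98, incomplete_fraction = 0)
  set.seed(10)
  fre <- bisulfite_convert(fragmentize(simulate_molecules(cfge), cfge), cfge)
  cyt <- attr(fre, "cytosines")
  expect_gt(nrow(cyt), 10000)
  resid <- mean(!cyt$converted)
  expect_lt(abs(resid - 0.02), 3 * sqrt(0.02 * 0.98 / nrow(cyt)))
})

test_that("degradation spares protected fragments and obeys its closed form", {
  g <- demo_genome(1000)
  cfg <- sim_config(g, n_molecules = 100, meth_prob = 0)
  set.seed(11)
  frags <- bisulfite_convert(fragmentize(simulate_molecules(cfg), cfg), cfg)
  expect_equal(nrow(degrade(frags, rate = 0)), nrow(frags))

  # fully methylated molecules have no deamination events: all survive
  cfgm <- sim_config(g, n_molecules = 20, meth_prob = 1,
                     overconversion_rate = 0)
  set.seed(12)
  frm <- bisulfite_convert(fragmentize(simulate_molecules(cfgm), cfgm), cfgm)
  expect_true(all(frm$n_deaminated == 0L))
  expect_equal(nrow(degrade(frm, rate = 0.5)), nrow(frm))

  # Monte-Carlo survival matches mean (1 - delta)^u within 3 SEs
  set.seed(13)
  surv <- degrade(frags, rate = 0.02)
  p <- (1 - 0.02)^frags$n_deaminated
  se <- sqrt(sum(p * (1 - p))) / nrow(frags)
  expect_lt(abs(nrow(surv) / nrow(frags) - mean(p)), 3 * se)
  expect_equal(attr(surv, "n_before"), nrow(frags))
})

test_that("read emission conserves fragments and truncates at read length", {
  g <- demo_genome(1000)
  cfg <- sim_config(g, n_molecules = 30, read_length = 75)
  set.seed(14)
  frags <- bisulfite_convert(fragmentize(simulate_molecules(cfg), cfg), cfg)
  reads <- emit_reads(frags, cfg)
  expect_equal(nrow(reads), nrow(frags))
  expect_equal(reads$length, pmin(75L, frags$length))
  expect_true(all(nchar(reads$sequence) == reads$length))
  expect_true(all(reads$start >= 0 & reads$start < g$length))

  # FASTQ round trip
  fq <- tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  back <- Biostrings::readDNAStringSet(fq, format = "fastq")
  expect_equal(as.character(back), reads$sequence, ignore_attr = TRUE)
  expect_equal(names(back), reads$read_id)
})

test_that("seeded simulations are reproducible and seeds matter", {
  cfg <- sim_config(demo_genome(500), n_molecules = 50, seed = 99)
  s1 <- simulate_reads(cfg)
  s2 <- simulate_reads(cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  cfg2 <- sim_config(demo_genome(500), n_molecules = 50, seed = 100)
  expect_false(identical(simulate_reads(cfg2)$reads, s1$reads))
})

test_that("the H/L read ratio grows with the degradation rate", {
  g <- demo_genome(2000)
  ratios <- vapply(c(0, 0.02, 0.05), function(d) {
    cfg <- sim_config(g, n_molecules = 1500, meth_prob = 0,
                      degradation_rate = d, seed = 21)
    strand_bias_from_reads(simulate_reads(cfg)$reads, g)$ratio
  }, numeric(1))
  expect_gt(ratios[2], 1)
  expect_true(all(diff(ratios) > 0))
})
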