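# mtbsaudit

Audit tools for bisulfite-sequencing (BS-seq) evidence of mitochondrial DNA
methylation.

Whole-genome bisulfite sequencing converts unmethylated cytosine to uracil
(read as T) while 5-methylcytosine (5mC) resists conversion, so methylation
is inferred by comparing reads to the unconverted reference. On mtDNA this
inference is fragile in two specific, well-documented ways:

1. **Selective degradation.** The harsh bisulfite treatment preferentially
   destroys unmethylated, cytosine-rich fragments; 5mC is protective. The
   C-rich light (L) strand of mtDNA is hit hardest, producing heavy/light
   (H/L) strand coverage ratios far above 1, depleted coverage of C-rich
   regions, and — because the surviving C-rich fragments are the
   unconverted ones — an inflated apparent methylation level.
2. **Threshold calling.** A position-level model that calls a reference
   cytosine *methylated* when its methylation proportion is ≥ 9% at ≥ 10×
   coverage (and *unmethylated* otherwise, including every position below
   the coverage floor) turns these modest artifacts into categorical
   claims: a sample at a uniform 9.0% apparent methylation is reported as
   100% methylated, at 8.9% as 100% unmethylated.

`mtbsaudit` is for bioinformaticians and reviewers who want to test whether
a claimed mtDNA methylome could be an artifact of this pipeline. It
provides:

- a **generative simulator** of BS library preparation on a circular
  genome: per-molecule methylation states, sonication or
  enzymatic-linearization fragmentation, incomplete conversion (including
  the fragment-level incomplete-denaturation artifact), selective
  degradation with survival `(1 − δ)^u` for `u` deaminated cytosines, and
  read emission with full ground truth — no external data needed;
- **strand-aware methylation extraction**: per-read calling against the
  circular reference, pileups with CpG/CHG/CHH context, SAM input with
  Bismark-style `XM`/`XG` tags;
- **per-read diagnostics**: each read is placed by its number of reference
  cytosines *n* (how C-rich its region is) and the fraction of those
  cytosines called methylated. Against the uniform-coverage null — the
  enumeration of C counts over every circular window — degradation shows up
  as (a) H/L read ratio > 1, (b) apparent methylation rising with *n*,
  (c) a depleted C-rich tail, and (d) a large total-variation distance
  between observed and expected C-count distributions;
- the **threshold model itself** (`cutoff = 0.09`, `min_coverage = 10`),
  with its position-level false positive rate `FPR = #methylated Cs /
  total Cs` on an unmethylated control and `ACC = 1 − FPR`, implemented
  faithfully so its behaviour can be demonstrated against known truth.

## Worked example

A truly unmethylated sample, 95% conversion efficiency, mild selective
degradation (δ = 0.02), on the bundled 2 kb synthetic mtDNA-like genome:

```r
library(mtbsaudit)
genome <- demo_genome()
cfg <- sim_config(genome, n_molecules = 2000, meth_prob = 0,
                  conversion_efficiency = 0.95, degradation_rate = 0.02,
                  seed = 7)
bundle <- run_pipeline(cfg)
bundle
#> Audit of synthetic_mtdna (2000 bp), seed 7, sonication, delta = 0.02
#>   reads:                    14609
#>   H/L strand bias:          1.63
#>   C coverage bias:          0.97
#>   TV(observed, expected):   0.1138
#>   threshold-model calls:    1.0000 methylated (0.0000 by proportion, 0.0000 by coverage unmethylated)
#>   true mean methylation:    0.0000
```

Reading the numbers: the sample contains **no methylation at all**
(`true mean methylation: 0`), yet the H-strand is 1.63× overrepresented,
C-rich regions are undercovered (C coverage bias 0.97 < 1), the observed
per-read C-count distribution has drifted from the uniform-coverage null
(TV 0.114), and the 9%/10× threshold model declares **every** reference
cytosine methylated — residual unconverted cytosines plus survivor bias
push every position past the 9% cutoff. The per-read trend makes the
mechanism visible:

```r
binned_trend(bundle$per_read, 15)
#>   bin_lo bin_hi n_ref_c_mid mean_frac_meth     n
#> 1      0     15         7.5      0.1557608 10294
#> 2     15     30        22.5      0.1844069  3218
#> 3     30     45        37.5      0.2421118  1090
```

Reads from C-rich regions (right bins) look *more* methylated and are
*rarer* — the signature of unmethylated C-rich fragments being destroyed
before amplification, not of biology. `plot_read_diagnostics()` draws the
corresponding density-tile panel with the dashed trend and the
observed/expected marginals.

A thin CLI over the same functions lives at `inst/cli/mtbsaudit.R`
(subcommands `simulate`, `audit`, `classify`).

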