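---
title: "Auditing bisulfite evidence of mtDNA methylation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing bisulfite evidence of mtDNA methylation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(mtbsaudit)
```

# The problem

Mitochondrial DNA is a circular molecule of 16,569 bp in humans, present in
many copies per cell, with strands of markedly different base composition:
the light (L) strand is cytosine-rich, the heavy (H) strand guanine-rich.
Whether mtDNA carries appreciable cytosine methylation is contested, and
the disagreement is largely methodological. Bisulfite (BS) sequencing
infers methylation from failure to convert C to T, so *any* process that
spares cytosines from conversion, or that preferentially removes
highly converted molecules from the library, inflates apparent
methylation. Two such processes are well documented for mtDNA:

- **incomplete conversion** — conversion efficiency is never 100%, and a
  fraction of fragments escape denaturation almost entirely, yielding
  wholly unconverted reads;
- **selective degradation** — the bisulfite reaction degrades DNA, and the
  damage tracks the deamination events themselves, so unmethylated C-rich
  fragments are preferentially destroyed while 5mC-bearing (or otherwise
  unconverted) fragments survive.

On top of this sits a position-level calling model used in the disputed
literature: call a reference cytosine *methylated* if its methylation
proportion is at least 9% with coverage at least 10×, otherwise call it
*unmethylated* — including every position that merely lacks coverage. This
package implements the generative artifact model, the per-read diagnostics
that expose it, and the threshold model itself, so that the chain
"unmethylated sample → biased library → categorical methylome claim" can
be reproduced and dissected under known ground truth.

# The generative model

A simulation run (`simulate_reads()`) draws, in order:

1. **Molecules.** `n_molecules` full-length circular templates, each
   assigned a strand of origin with probability 1/2. Each cytosine of the
   molecule's strand is methylated independently with `meth_prob`
   (optionally per CpG/CHG/CHH context). This represents the heterogeneous
   population of mtDNA copies in a sample: every position can have any
   methylation proportion between 0 and 100% across molecules.
2. **Fragmentation.** Sonication places a uniform random breakpoint phase
   on the circle and tiles it with lengths drawn from
   Normal(`frag_len_mean`, `frag_len_sd`) truncated at `frag_len_min`;
   lengths per molecule sum exactly to the genome length. Linearization
   instead cuts every molecule at a fixed `cut_site` (a single-cutter
   enzyme) and shears the linear molecule the same way.
3. **Conversion.** A fragment is *incompletely denatured* with probability
   `incomplete_fraction`; its cytosines then deaminate with probability
   `incomplete_efficiency`, versus `conversion_efficiency` on fully
   denatured fragments. Methylated cytosines deaminate only at
   `overconversion_rate` (default 0).
4. **Degradation.** A fragment in which `u` cytosines were actually
   deaminated survives with probability `(1 − δ)^u`. Linearization uses a
   separately configurable, by default smaller, δ (gentler handling;
   single-cut protocols avoid the extra sonication damage).
5. **Read emission.** One single-end read per surviving fragment from its
   5′ end, length `min(read_length, fragment length)`, reported the way an
   aligner would (forward-projected sequence, 0-based forward start), with
   per-read ground truth attached.

## Why degradation is coupled to deamination

The degradation step is the package's central modeling decision. Survival
is `(1 − δ)^u` with `u` the number of *deaminated* cytosines, not simply
the number of unmethylated cytosines. The chemical rationale: degradation
during bisulfite treatment is driven by the deamination reaction itself,
so a cytosine that escapes deamination — whether because it is methylated
or because its fragment never fully denatured — contributes no damage.
This preserves the two facts the audit rests on (5mC protects; C-rich
unmethylated fragments die) and adds a third that a purely
methylation-state-based penalty cannot produce: among surviving C-rich
fragments, *unconverted* fragments are overrepresented.

That last point matters mathematically. If every cytosine behaved
independently (independent conversion, survival factorizing over
cytosines), then conditioning on survival would shift the residual-C
probability by the same factor at every position, and the mean per-read
methylated fraction would be exactly flat in per-read C count — no trend,
however strong the degradation. The observed artifact (C-rich reads
looking *fully* methylated) requires a fragment-level coupling, which the
incomplete-denaturation mixture provides: incompletely denatured fragments
convert almost nowhere, so they carry near-zero `u` and survive
degradation essentially untouched, while their fully denatured C-rich
siblings are destroyed. The survivors of C-rich regions are therefore
increasingly the unconverted ones, and apparent methylation rises with
per-read C content — the per-read signature the diagnostics test for.

## Defaults and what they emulate

| parameter | default | rationale |
|---|---|---|
| genome | `demo_genome()`, 2 kb | fixed synthetic circle, rCRS-like composition (A .31, C .31, G .13, T .25), C-density varying regionally (~17–45% over two periods) because real mtDNA is compositionally heterogeneous — regional C-rich domains are what make degradation visible positionally |
| `frag_len_mean`, `sd`, `min` | 167, 50, 30 bp | typical sonicated BS library insert scale |
| `read_length` | 75 bp | matches the hard-trim length common in reanalyses of these libraries |
| `conversion_efficiency` | 0.95 | deliberately imperfect conversion of a problematic library |
| `incomplete_fraction` | 0.08 | wholly-unconverted-read fractions of a few percent are routinely reported for difficult preps; 8% represents a badly affected, high-temperature-denaturation library |
| `incomplete_efficiency` | 0.05 | an undenatured duplex is nearly inert to bisulfite |
| `degradation_rate` δ | 0.02 | per-deamination survival penalty; at 167 bp and ~30% C this yields H/L ratios of ~1.5 and C coverage bias ~0.96, the qualitative regime of real mtDNA BS libraries (published ratios run from ~1.3 to >40) |
| `meth_prob` | 0 | the null sample the audit is about: truly unmethylated mtDNA |

The defaults therefore describe a *pathological but realistic* library of
an unmethylated sample. For a clean control, set
`conversion_efficiency = 1`, `incomplete_fraction = 0`,
`degradation_rate = 0` — all three are part of "perfect conversion, no
degradation"; with those settings apparent methylation equals the
simulated truth exactly in expectation, and exactly 0 everywhere for an
unmethylated sample.

What the generator does **not** model: sequencing errors and base
qualities, adapters, paired-end geometry, PCR duplicates and
amplification bias, alignment ambiguity (reads carry their true origin),
and M-bias along read cycles. Consequences for interpretation: passing
diagnostics here show that the statistical machinery detects the
degradation artifact when present and stays quiet when absent; they do not
show robustness to alignment or sequencing noise, which real data add on
top.

# The diagnostics

For each read with at least one reference cytosine of its origin strand,
the extraction records `n_ref_c` (cytosines covered) and `frac_meth`
(fraction called methylated: read C at a reference C for forward-origin
reads, read G at a reference G for reverse-origin). Reads covering no
cytosine are excluded from the per-read analyses but counted.

- **Uniform-coverage null.** Under uniform circular coverage, a read of
  length `w` starts anywhere with equal probability, so its C count
  follows the exact enumeration of C counts over all `L` circular windows
  (`circular_window_c_counts()`). `expected_c_distribution()` mixes this
  over the empirical read-length multiset and over strands (50/50 by
  default; the null is agnostic about strand imbalance, which is tested
  separately — a coverage-proportional weighting is available).
- **Strand bias** `n_H / n_L`, with H/L assigned from composition
  (G-rich = H). An exact C = G tie is an error directing the user to set
  labels explicitly; `n_L = 0` yields an explicit "undefined" report, not
  an exception.
- **C coverage bias**: aligned-base coverage fraction on forward-reference
  C positions over the genome's C fraction.
- **Trend**: binned means of `frac_meth` against `n_ref_c`. Binned means
  (not a kernel or spline smoother) because they are exactly testable;
  the default audit bin width is 15 cytosines, wide enough that every
  populated bin holds hundreds of reads at the audit's sample sizes, so
  bin means are resolvable above sampling noise.
- **Divergence**: total variation distance between observed and expected
  C-count distributions, aligned on the union support.

# The threshold model

`classify_positions()` assigns every reference cytosine of both strands
exactly one class: `methylated` (coverage ≥ `min_coverage` and proportion
≥ `cutoff`), `unmethylated_by_proportion`, or `unmethylated_by_coverage`
(including uncovered positions). Design choices:

- the cutoff is **inclusive** ("9% or more"); a strict-inequality flag
  exists because the source descriptions are inconsistent on this point;
- proportions are compared at **full precision** — the 8.9%-vs-9.0%
  dichotomy is only reproducible without intermediate rounding;
- classification is **per strand**; no CpG-pair merging is offered, since
  the audited claims concern non-CpG contexts where merging has no basis;
- `FPR = #methylated / #total cytosines` and `ACC = 1 − FPR` are provided
  as defined in the audited model, with their limitation on display: they
  are position-level quantities on an assumed-unmethylated control and
  contemplate neither true positives nor false negatives.

# Numerical and interface conventions

- Coordinates are 0-based half-open internally; all wraparound is index
  modulo length. TSV outputs are 1-based.
- All randomness in a run flows from `sim_config(seed = )`; the
  degradation stage consumes exactly one uniform per fragment *after* all
  other draws, so runs at matched seeds but different δ share molecules,
  fragments and conversion outcomes and have nested survivor sets —
  δ-sweeps are coupled comparisons by construction.
- `N` bases are never cytosines, generate no calls, and count as H in
  context annotation.
- Distribution masses must sum to 1 within 1e-9; divergence refuses
  unnormalized input.
- The H/L label of the reference's forward strand is derived from
  composition, not assumed from any reference convention (conventions in
  the literature are inconsistent); an explicit override belongs in the
  run configuration when composition is uninformative.

# Problem sizes

The audit runs used in the package's tests were fixed as follows: the
per-read degradation signature uses 8,000 molecules (~60,000 surviving
reads) on the 2 kb demonstration genome, which puts ≥ ~1,000 reads in the
C-richest trend bin; the perfectly converted control uses 850 molecules
(~10,000 reads); the δ-sweep of threshold-model overestimation uses 2,000
molecules per δ ∈ {0, 0.01, 0.02, 0.05} with conversion efficiency 0.97
and incomplete fraction 0.03, chosen so the baseline per-call residual
rate (~5.8%) sits below the 9% cutoff and the model has dynamic range to
overestimate into. Oracle-equivalence checks (window enumeration, pileup
tallies) run exactly on genomes of 0.4–2 kb and ~10³ reads.

# Known limitations

- External SAM input must be ungapped against a single reference; indels
  are dropped with a warning. This is adequate for mtDNA BS diagnostics
  and for the simulator's own output, not for general re-extraction.
- The simulator's degradation severity δ is a free parameter: the real
  severity of any given kit/protocol is not identifiable from published
  summaries, only its signature direction.
- The package deliberately does not provide a "correct" methylation
  caller; the threshold model is implemented to be studied, not used.
- Real-data panels of published reanalyses cannot be regenerated here:
  the underlying libraries have no public accession. The simulator
  reproduces the artifact's signature, not any specific sample.
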