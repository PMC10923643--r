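---
title: "Methods: windowed WGBS methylome analysis and its simulator"
author: "fruitMethyl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed WGBS methylome analysis and its simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical model, the
choices made where the methodology was genuinely open, and what the
simulator does and does not emulate. It states no empirical result that
the test suite and `scripts/acceptance.R` do not themselves compute.

## Data model and coordinate conventions

The unit record is one strand-specific cytosine with its sequence context
(CG, CHG or CHH, H = A/T/C, read 5'→3' on the cytosine's own strand) and
two counts: methylated reads `#C` and total covering reads `#C + #T`.
Symmetric-context cytosines on opposite strands are *not* merged: the
upstream methylation extractors this dialect comes from report per strand,
and keeping records per strand leaves the weighted level well defined.

Everything lives on `GenomicRanges` containers, so the package uses the
1-based closed coordinate convention of the Bioconductor stack throughout;
dialect conversion for GFF3 (1-based inclusive) and BED (0-based
half-open) happens in `rtracklayer` at the file boundary. A single
convention internally eliminates off-by-one classes; it is simply the
GRanges convention rather than a 0-based one.

Cytosine contexts are re-derived from the reference rather than trusted
from upstream output: a plus-strand C at position *i* is classified from
bases *i+1, i+2*; a minus-strand cytosine (a G at *i* on the plus strand)
from the reverse complement of bases *i−1, i−2*. A cytosine whose two-base
window contains an N or runs off the chromosome end has an undefined
context and is omitted rather than imputed — this also means the last one
or two cytosines of a chromosome never appear, a deliberate edge rule.

## Conversion rate and methylcytosine calling

Bisulfite converts unmethylated C to T; the failure ("non-conversion")
rate is estimated from an unmethylated spike-in sequence, carried in the
same FASTA under the reserved name `lambda_control`. The estimate is
pooled, `1 − Σ#C/Σ(#C+#T)` over all control cytosines — the maximum
likelihood estimate under a common rate, preferred to averaging per-site
ratios which would weight shallow sites equally with deep ones.

A cytosine is called a methylcytosine by a one-sided upper-tail exact
binomial test with null `p₀ = 1 − conversion`: only methylation *above*
non-conversion noise is of interest, hence one-sided. Following the
analysis this package operationalizes, raw `p < α` (default α = 0.05) is
used with **no multiple-testing correction** across sites; α is an
explicit argument so a user who wants a stricter threshold can set one.
Zero-coverage records are untestable and are skipped with a count, never
silently treated as unmethylated.

## Weighted levels

The level of any cytosine set is `Σ#C / (Σ#C + Σ#T)` — the weighted
method. It pools reads instead of averaging per-site ratios, so the pooled
level over a region equals the count-weighted mean over any partition of
it (a property the tests verify). An empty or zero-coverage subset has no
level; the function raises an error rather than returning 0, because a 0
would be indistinguishable from a genuinely unmethylated region.

## DMR calling

The genome (control excluded) is tiled in non-overlapping 200-bp windows;
the final window of each chromosome is truncated and flagged, not
dropped. Per window and context, counts are pooled over all
strand-specific cytosines; two samples are compared by a two-sided
Fisher's exact test on `[[c_A, n_A−c_A], [c_B, n_B−c_B]]`. A testable
window is a DMR when all three hold:

* |level difference| strictly above the context threshold — CG 0.4,
  CHG 0.2, CHH 0.1;
* Fisher `p < 0.05` (strict);
* Benjamini–Hochberg `q < 0.05`, with BH computed **per context** over all
  testable windows of that context, since the thresholds and the biology
  are context-specific.

Choices behind that definition:

* **Sidedness.** Two-sided by the conventional point-probability
  definition (sum of all tables with hypergeometric probability ≤ the
  observed one, with the same `1 + 1e−7` relative tie tolerance that
  `stats::fisher.test` uses). The implementation is a vectorized
  `dhyper` summation; the tests verify it against an independent
  binomial-coefficient enumeration oracle for every table with margins
  ≤ 12 and against `stats::fisher.test` on random larger tables.
* **Testability floors.** The source methodology states no minimum
  coverage; Fisher's test on a near-empty 2×2 table is meaningless, so a
  window must have ≥ 10 pooled reads and ≥ 3 covered context cytosines in
  *each* sample (both exposed in `dmrParams()`). Windows failing the
  floors are reported untestable and excluded from the BH family.
* **Replicates.** Counts are pooled across replicates before windowing
  (the two-replicate designs this targets were pooled likewise); no
  dispersion model is fit. Beta-binomial or regression-based DMR models
  are out of scope by design.
* **Strictness.** All inequalities are strict, exactly as the thresholds
  are conventionally printed; a boundary value does not qualify.

`sharedDmrs()` defines a shared DMR as a *coordinate-identical* window of
the same context present in both comparisons — well-defined because both
comparisons use the same fixed tiling; overlap-based sharing is
deliberately not used. Direction concordance is the fraction of shared
windows with equal hyper/hypo direction. `genomeDmrCoverage()` divides
the union of DMR windows by the **total assembly length** (control
excluded); covered-sequence length is a defensible alternative
denominator, and a caller can obtain it by passing adjusted `seqlengths`.

## Metagene profiles and DMR density

Profiles span a 2-kb upstream flank (20 bins of 100 bp), the body scaled
to 40 proportional bins regardless of feature length, and a 2-kb
downstream flank. Minus-strand features are reversed so bin 0 is always
5'-most. Each bin's value is the weighted level pooled over all (feature,
cytosine) incidences in that bin, so the profile inherits the partition
invariance of the weighted level. Features shorter than the body bin
count cannot be subdivided and are skipped with a count; flank bins
beyond chromosome ends are clipped. Bins never touched by a covered
cytosine are `NA`, not 0. No smoothing is applied.

DMR positional density around TSS and TES is computed from DMR
*midpoints* (avoiding double counting across bins), per feature per kb,
in strand-oriented 200-bp bins over ±2 kb. The randomization scheme for
the background is declared, not inherited: each permutation places an
equal number of length-matched regions uniformly on the genome (chromosome
chosen proportional to length, start uniform; control excluded), with no
masking. The one-sided empirical enrichment p-value uses the standard
add-one correction `(1 + #{perm ≥ obs})/(1 + n_perm)`, so it is never 0
and equals `1/(1+n_perm)` at maximal enrichment.

## Expression association

DEG labels are *thresholded from supplied statistics* (`|log2FC| > 2`,
adjusted `p < 0.05`, strict); fitting the differential-expression model
itself is out of scope. A gene is a DMG when its body ± 2 kb intersects at
least one DMR by any base-pair overlap ("intersecting" is otherwise
undefined, and any-overlap is the most inclusive reading); regions are
reported strand-aware, with the promoter flank being the 2 kb 5' of the
TSS. DEG∩DMG enrichment uses the one-sided upper-tail hypergeometric test
(enrichment is the stated direction of interest), with the universe
defaulting to all annotated genes — exposed as a parameter since the
published analyses do not always print theirs; for the same reason a
published enrichment p-value whose universe and DMG total are not printed
cannot be reproduced and is not attempted. Reported overlap percentages
are rounded half-up (one decimal for overlap-in-DEG, two for shared-DEG
fractions) as such numbers are conventionally printed.

## The simulator

The generator emulates the statistical structure the analysis assumes,
not sequencing itself:

* **Genome**: i.i.d. bases at a configurable GC content (default 0.36,
  plant-like) over a configurable number of chromosomes, plus the
  unmethylated control sequence at 50% GC in the same FASTA. Genes are
  packed into equal per-chromosome slots (guaranteeing non-overlap, with
  an explicit error when packing is infeasible); TEs are placed uniformly
  and may overlap genes, as in real genomes.
* **Methylation**: `contextLevelMeans` is the target *observed*
  genome-wide weighted level per stage and context — the quantity a
  methylome report prints. The generator back-solves the latent mean
  `(m − r)/(1 − r)` for non-conversion rate `r`, draws per-site true
  levels from a Beta with that mean and concentration κ = 20 (a
  two-parameter stand-in reproducing the overdispersion of real
  methylomes; the source methodology states no parametric form), then
  draws coverage `max(1, Poisson(40))` and methylated counts
  `Binomial(n, t + (1−t)r)`. Control cytosines have true level exactly 0,
  so the pooled control fraction estimates `r` — the calibration the
  tests check.
* **Differential plan**: a fraction (default 10%) of 200-bp windows per
  context is selected once and receives an additive level shift (defaults
  CG −0.45, CHG −0.25, CHH +0.15) in *every stage after the first*, so
  the later-versus-first comparisons share one plan and shared-DMR
  direction concordance is near-total by construction, emulating the
  near-complete concordance real developmental series show.
* **Expression**: genes whose ±2 kb neighbourhood contains a true
  differential window are true DMGs; with probability `couplingProb`
  (default 0.9) a true DMG receives a strong expression shift
  (|log2FC| = 4, adjusted p = 10⁻⁶). A background rate (default 5%) of
  non-DMG genes receives the same shift — expression changes unrelated to
  methylation exist in real data, and without them a decoupled
  configuration would produce no DEGs at all and the enrichment test
  could never be exercised under its null. All other genes draw null
  statistics (log2FC ~ N(0, 1), adjusted p ~ U(0,1)).

Default stage targets mirror the motivating system: CHH 0.066 → 0.153 →
0.145 across young, expanding and mature fruit, with CG and CHG declining
gently (0.65/0.60/0.58 and 0.45/0.40/0.38 — the decline is the documented
pattern; the CG/CHG magnitudes are typical citrus-scale values chosen
once). Note an interaction that matters for validation: because the
differential-window effect is *additive on top of* the stage means, a
configuration with both moving backgrounds and implanted windows has more
genuinely differential windows than the implanted plan alone. The
package therefore uses three calibration regimes, all built from the same
generator:

* *null*: stage-constant means, no implanted windows — for false-positive
  calibration of the DMR caller;
* *recovery*: stage-constant means, 10% implanted windows with the CHH
  +0.15 shift at 40× coverage — for recall/false-discovery scoring
  against ground truth, where the plan is the complete truth;
* *level recovery*: stage-varying means, no implanted windows — for
  verifying that genome-wide weighted levels reproduce the configured
  targets (to within sampling error; an implanted fraction would shift
  the realized mean by fraction × effect, by construction).

Determinism: one top-level seed feeds fixed substreams per stage (genome,
methylomes, expression, backgrounds), so identical spec + seed reproduces
every output byte-for-byte and each pipeline stage is independently
reproducible.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: read-level artifacts (mapping bias, M-bias,
PCR duplicates), spatial autocorrelation of methylation along the genome
beyond the window plan, sequence-composition effects on methylation
(levels are independent of local GC), realistic TE families and their
methylation excess, chromosome-scale features (centromeric gradients),
and biological replicate variance (counts are drawn for one pooled sample
per stage). Results on real data additionally depend on alignment quality,
which is entirely out of scope.

## Problem sizes

Desk-scale validation uses 150–200 kb genomes over two chromosomes with a
10–20 kb control, ~40× coverage and 1% non-conversion: large enough that
genome-wide weighted levels estimate their targets to well under the
±0.01 validation band, that ~750–1000 CHH windows per comparison are
testable, and that ~100 implanted CHH windows give a stable recall
estimate, while the full suite runs in about a minute. The exactness
checks are not simulations at all: the Fisher p is verified against full
enumeration for every 2×2 table with margins ≤ 12, and the binomial
caller against explicit tail summation for all n ≤ 50, both at
tolerances far below any decision threshold.

## Known limitations

* The mC caller inherits the no-FDR convention of the methodology it
  implements; at genome scale, raw p < 0.05 admits a predictable
  false-call proportion (bounded by the realized test size, which the
  validation script measures).
* Fixed non-overlapping windows cannot resolve DMR boundaries below 200
  bp and can split a true region across a window edge; sliding windows
  and HMM-based callers are deliberate non-goals.
* The hypergeometric association treats genes as exchangeable; no
  correction for gene length or cytosine density is attempted, so on real
  data the enrichment p-value is an association statement, not a causal
  one.
* Per-strand records mean symmetric-context (CG/CHG) evidence is not
  combined across strands; a strand-merged analysis would roughly double
  per-site coverage for those contexts.
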