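---
title: "Methods: desk-scale WGBS methylome analysis with ground truth"
author: "mossmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale WGBS methylome analysis with ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them: what each stage assumes, which parameters matter, what
the simulator does and does not emulate, and therefore what a passing test
suite does and does not demonstrate about real data.

# The measurement model

Bisulfite treatment converts unmethylated cytosine to uracil (sequenced as
T) while methylated cytosine is protected. A directional single-end library
therefore reports, at every cytosine of the read's origin strand, either
retention (C) or conversion (T). Two error channels blur this signal:

* incomplete conversion — an unmethylated C is read as C with probability
  $1 - c$, where $c$ is the conversion rate (default 0.995);
* conversion of methylated cytosines ("methylation failure") — a methylated
  C is read as T with probability $f$ (default 0.005).

The measured level of a cytosine with true methylation probability $p$ has
expectation $p(1-f) + (1-p)(1-c)$. The additive background $1-c$ is tiny in
absolute terms but matters for *ratios*: a knockout retaining 5% of a
context whose absolute level is ~0.1 appears to retain ~10% if raw levels
are compared, because the background inflates numerator and denominator
equally. This is why `genome_average()` and `feature_average()` accept a
`nonconversion` argument. The background is estimated the way plant WGBS
practice does — from a compartment known to be unmethylated (the
organelle-like chromosome the simulator emits; `estimate_nonconversion()`)
— and levels are corrected as $(\ell - b)/(1 - b)$. The corrected values
are deliberately *not* clipped at zero: clipping would bias the mean of
near-zero cytosines upward, and it is the mean that downstream ratios use.
Under this correction the expected mutant/wild-type ratio of context means
equals the constructed retention factor exactly.

# Alignment

Reads are aligned in two reduced-alphabet spaces sharing the forward
coordinate frame: reference and read converted C→T (forward-strand
origins), and reference G→A versus the G→A conversion of the reverse
complement of the read (reverse-strand origins; for a C→T-converted read
this query is simply its reverse complement). The aligner seeds with the
exact first $k$-mer of the converted read ($k = 20$ by default) and extends
without gaps, counting mismatches in converted space.

Decisions, with reasons:

* **Unique best hit only.** A read is usable only if its lowest-mismatch
  alignment (cap: `max_mismatches`, default 2) is unique across both
  spaces; ties at different loci are discarded as multi-mapped. Random
  assignment of multi-mappers would bleed methylation between repeat
  copies.
* **No gaps, no quality weighting, single-end.** This matches the
  short-read, ungapped era of bisulfite alignment the analysis chain
  models, and it keeps the exhaustive reference implementation
  (`align_reads_scan()`, which scores every position of both spaces)
  simple enough to serve as an oracle. On simulated error-free reads the
  two algorithms agree exactly; with a first-seed-only policy a read whose
  leading $k$-mer contains a sequencing error can go unaligned, a known
  and accepted sensitivity limitation.
* **Duplicates are not collapsed.** The simulator makes exact duplicates
  rare; deduplication is a library-artifact treatment out of scope here.
* External alignments (SAM/BAM) can be imported with
  `read_sam_alignments()`, bypassing the internal aligner but feeding the
  same pileup.

The pileup counts a read only at cytosines of its own origin strand
(forward C positions for "+" origins, forward G positions for "−"), so
retention + conversion at a cytosine can never exceed the usable reads
overlapping it.

# Contexts and calling

Context is determined solely by the reference sequence of the cytosine's
strand: CG (next base G), CHG (H then G), CHH (H twice), H = {A, C, T}.
Subcontext tokens refine these: the NCG triplet and the derived DCG class
(N ≠ C) for CG sites; CWG versus CCG (W = {A, T}) partitioning CHG; CWH,
plus CWA when the third base is A, within CHH. Cytosines whose context
window runs off the chromosome or contains N are `undefined` and excluded
everywhere. Genome averages are unweighted per-cytosine means — every
covered cytosine counts once, with no coverage floor by default
(`min_coverage = 1`); window-level thresholds handle noise instead.

# Windows and differential methylation

Windows are non-overlapping 50-bp tiles by default. The window fraction is
computed from pooled counts (count-weighted), not as a mean of per-cytosine
levels, so deeply covered cytosines carry proportional weight;
`n_informative` is the pooled C+T observation count, the "informative
sequenced cytosines" of the filters. A `step` parameter smaller than the
window produces overlapping tilings when a sliding summary is wanted, but
the tiled default avoids dependence between adjacent tests.

A window is tested for differential methylation when its fraction reaches
0.1 in either sample and it has at least 10 informative observations in
both samples ("both" rather than "either" is this package's reading where
the rule could be read either way). The test is two-sided Fisher's exact on
the pooled 2×2 count table; windows with p < 0.05 are reported with the
percent-change statistic

$$\mathrm{pc}(w, m) = \begin{cases}
 100\,(w - m)/w & w > m\\
 -100\,(m - w)/m & w < m\\
 0 & w = m
\end{cases}$$

— the difference normalised by the *higher* of the two levels, so it is
bounded in $[-100, 100]$, antisymmetric, and positive when the second
sample (the mutant) has lost methylation. No multiple-testing correction is
applied by default, matching the raw-p analysis style this reproduces; a
Benjamini–Hochberg option exists. The box-plot style analyses share the
0.1-in-either rule but use 20 informative observations, their own
convention.

# Meta-analyses

* **TE metaplots** align all TEs at the 5′ end (strand-aware) and pool
  per-cytosine levels in 100-bp intervals; contributing-TE counts per
  interval are reported because distal intervals are populated by long
  elements only.
* **TE edges near TSS**: for genes on "+", TE *end* coordinates are tested;
  for genes on "−", TE *starts* — i.e. the edge facing the gene — in 25-bp
  windows up to 500 bp upstream, and only the closest edge per gene counts,
  so a gene contributes to at most one window. Percentages are over all
  genes supplied.
* **Centile stratification**: empirical quantile groups (5 for GC and TE
  size, 10 for siRNA, 4 for histone marks), ties resolved to the lower
  centile. Histone features are $\log_2((\mathrm{mark}+\varepsilon)/
  (\mathrm{H3}+\varepsilon))$ with $\varepsilon = 0.01$ to avoid division
  by zero; windows lacking signal in any of H3K9me2, H3K4me3 or H3 form
  the ND class and are excluded from the quantile computation.
* **Chromosome profiles**: per-100-kb-bin unweighted means smoothed with
  LOWESS; the span (default 0.1 of the bins) is a parameter with no
  canonical value, and a single-bin chromosome is returned unsmoothed.
* **Overlap summaries** (TEs × methylation × siRNA) require the
  "methylated TE" and "siRNA-positive" thresholds explicitly — there is no
  defensible silent default for either, so none is supplied.

# The simulator: what it emulates, and what it does not

The generator's defaults are the package's study conditions: two 100-kb
nuclear chromosomes plus a 20-kb unmethylated organelle control; 70 TEs
(log-uniform 100–5000 bp) and 30 genes packed without overlap, with an 80%
occupancy feasibility cap; GC 0.34 baseline with TE neighbourhoods shifted
up with TE size; 30× single-end 75-bp coverage (20× in the knockout
recovery runs); conversion 0.995 and failure 0.005 — depth and conversion
are simulator choices where no study value exists.

Chromatin is generated at 50-bp resolution: H3K9me2 increases and H3K4me3
decreases with TE size; total H3 is roughly uniform; 24-nt siRNA counts are
Poisson, concentrated quadratically on long TEs with a small background;
2% of windows lose each mark independently, feeding the ND class. The
methylome is TE-restricted ($p_\mathrm{true} = 0$ outside TEs, per
cytosine) and inside TEs follows a logistic landscape in the standardized
local H3K9me2 and GC signals, with the per-context intercept calibrated by
root-finding so the TE-cytosine mean equals the target exactly (defaults
CG 0.8, CHG 0.7, CHH 0.2). Knockout genotypes multiply $p_\mathrm{true}$
by per-context retention factors — presets: met 0.07 at CG; cmt 0.03 at
CHG; dnmt3b 0.05 at CHH with a secondary 0.87 at CG — with optional
subcontext overrides, and the cmt preset additionally rescales CHH by
$\exp(-d\,z)$ ($d = 0.7$, $z$ = standardized H3K9me2, capped at
probability 1): heterochromatic CHH down, euchromatic CHH up.

Not emulated: real genome composition and repeat families (every simulated
locus is unique sequence, so multi-mapping is exercised only by dedicated
tests), coverage biases, PCR duplicates, adapters, paired ends, and
sequencing error beyond an optional uniform substitution rate (off by
default, to isolate the chain's statistical behaviour). Consequently,
passing recovery tests demonstrate the *pipeline's* correctness under its
own measurement model — unbiased calling, correctly calibrated tests,
faithful geometry — not robustness to the artifacts of real libraries.

# Numerical and degenerate-case choices

* Fisher p-values come from `stats::fisher.test`; the test suite verifies
  them against exhaustive hypergeometric enumeration for margins ≤ 200.
* The paired t statistic is computed in closed form so the degenerate
  cases have defined behaviour: all differences zero → t = 0, p = 1;
  constant nonzero differences → infinite t, p = 0, flagged.
* Percent change of two zero fractions falls in the equality branch (0).
* Correlation entries with fewer than 3 pairwise-complete windows or zero
  variance are NA and flagged rather than fabricated.
* Amplicon clones with > 10% non-C/T bases at cytosine sites are rejected;
  the paired t over clone matrices pairs *sites* (per-site fractions), the
  finer-grained of the two possible pairing units.
* All internal coordinates are 0-based half-open; single-c output is
  1-based to match the deposited-file style, and GFF3/bedGraph converters
  round-trip exactly.

# Problem sizes

The validation suite runs entirely on generated data: unit fixtures of
5–60 kb, a 100-kb genome with 10,000 reads for the aligner-versus-scan
comparison, and a 200-kb genome at 20× (four genotypes plus a replicate
wild-type draw) for knockout recovery, null calibration (≈ 4,000 tested
windows) and the chromatin-redistribution check. These sizes were chosen so
that every stochastic check has enough data for its tolerance (binomial
standard errors well under the asserted margins) while the whole suite
remains quick to run at a desk.
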