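---
title: "An exon-array screen for splicing-factor targets: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An exon-array screen for splicing-factor targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psiscreen)
```

# The problem

Exon arrays measure every exon of a transcript with its own probeset, so
in principle a two-group comparison can detect changes in *exon
inclusion* — alternative splicing — separately from changes in *transcript
abundance*. In practice the two are badly confounded: a transcript that is
down-regulated as a whole drags all of its exon signals down, and the
naive exon-level contrast then reports every one of its exons as
"differentially spliced". A screen for targets of a splicing factor such
as Tra2b therefore needs a cascade of guards: an inclusion statistic
normalized by the parent gene, an effect-size window, a significance
filter, explicit exclusion of differentially expressed transcripts, and a
biological prior — Tra2b binds (A)GAA elements, so true targets should be
AGAA-rich. A final translation step asks what skipping the candidate exon
would do to the reading frame, since frame-shifting skips create premature
termination codons (PTCs) and route the transcript into nonsense-mediated
decay (NMD).

A further, study-specific complication is mosaicism: in a conditional
(Cre-driven) knockout tissue only a fraction of cells actually lose the
factor. RNA from unedited cells dilutes every molecular effect toward the
control state, and a screen that looks significant in a clean system can
lose most of its sensitivity in mosaic tissue. The synthetic-data
generator models this explicitly so the cost can be quantified.

# The screened statistic

Per sample, the splicing index of exon $e$ on transcript $g$ is

$$\mathrm{SI}_{e,s} = 2^{\,x_{e,s} - x_{g,s}}$$

where $x_{e,s}$ and $x_{g,s}$ are the summarized log2 exon and gene
signals. The group-level inclusion proxy (PSI) is the mean SI over a
group's samples, and the screened quantity is the ratio
$\mathrm{PSI}_{KO}/\mathrm{PSI}_{CTRL}$. The platform does not measure
inclusion on an absolute 0–1 scale, so the per-group PSI is only defined
up to a probe-affinity constant; that constant is shared between groups
and cancels exactly in the ratio. This is why the screen filters on the
*ratio*, never on PSI itself.

Two design choices here were genuinely open:

* **How PSI is computed from probe data.** The exon/gene splicing index is
  the standard proxy on this platform and is what the ratio-of-group-means
  definition implies; richer alternatives (probe-level interaction models)
  exist but estimate the same contrast with more machinery. The package
  uses the splicing index.
* **The exon-level test.** The per-exon p-value comes from a two-sided
  pooled two-sample Student's t on the per-sample log2 splicing indices —
  the convention used for the validation experiments as well. A moderated
  variant is available (`compute_psi_ratio(..., test = "moderated")`) but
  is not the default, keeping the exon and validation layers on the same
  test.

The exclusion window defaults to $(2/3,\ 1.5)$: the lower cut is exactly
the reciprocal of the upper cut, so the window is symmetric on the log
scale and a halving is treated exactly like a doubling. A published
rounding of the lower bound (0.66) is reproducible by setting
`psi_low_cut = 0.66`.

# Transcript-level differential expression

The DE layer exists to *remove* exons, not to find biology: any exon on a
transcript whose overall abundance shifted is uninterpretable as a
splicing change. Each transcript gets an empirical-Bayes moderated t: with
per-feature pooled variance $s_g^2$ on $d_g = n-2$ df, the prior
$(d_0, s_0^2)$ is estimated by closed-form moment matching of
$\log s_g^2$ (digamma/trigamma inversion), the posterior variance is
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0+d_g)$, and the statistic is
referred to $t_{d_0+d_g}$. When the log-variances are no more dispersed
than chi-square sampling alone the prior df is infinite and the fit
degenerates to a common variance; forcing $d_0 = 0$ recovers the ordinary
pooled t exactly (this is an oracle check in the test suite, and the fit
agrees with the reference empirical-Bayes implementation to numerical
precision when both estimate the prior).

Calls use |linear fold| ≥ 1.5 **and** p ≤ 0.05, both inclusive, sorted by
p. No multiple-testing correction enters the call — the screen is a
ranked candidate generator feeding wet-lab validation, not an inference
procedure — but a Benjamini–Hochberg column is emitted for information.
Signed folds follow the field's convention: the KO/CTRL ratio $r$ is
reported as $+r$ when $r \ge 1$ and $-1/r$ otherwise, so magnitudes are
always ≥ 1.

# The AGAA filter

The binding-site frequency is calibrated against the chance occurrence
rate of the motif — about once per 256 bp — so that

$$F = 256 \cdot \frac{\text{count}}{\text{exon length}}$$

equals 1 for one site in a 256-bp exon at any exon length. An alternative
literal reading of the defining phrase (count·length/256) agrees only at
length 256 and contradicts the calibration elsewhere; it is available as
`motif_frequency(..., convention = "literal")` for fidelity experiments
but is not the default. Overlapping occurrences are counted
(`AGAAGAA` contains two sites): clustered GAA-rich stretches are the
recognized biological signal, and overlap-counting credits them fully.
Matching is sense-strand only, on the exon's mRNA sequence. Candidates
need count ≥ 1 and F ≥ 1.5.

# PTC and NMD prediction

`predict_ptcs()` removes one exon from a transcript model, maps the
original start and stop codons into the shortened transcript, translates
from the start codon and counts in-frame stops strictly upstream of the
remapped original stop. NMD is called by the classical last-junction
rule: the first premature stop must lie more than `junction_rule_nt`
(default 50) nucleotides upstream of the last exon–exon junction. The
50-nt boundary is a parameter because the rule is an empirical
approximation, not a law; skipping an exon whose removal leaves no
downstream junction can never be NMD-positive. Transcript coordinates are
1-based and inclusive throughout the package — the R convention — with
`cds_start`/`cds_stop` pointing at the first nucleotide of the start and
stop codons.

# What the synthetic data emulates

`simulation_design()` encodes the study conditions: 4 CTRL vs 4 KO
arrays, probe-level Gaussian noise on the log2 scale (sd 0.25 by
default), probesets of 4 probes whose affinities are drawn once from
N(0, 0.3) and fixed across samples (as probe sequence effects are), an
additive exponential background (mean 20, linear scale), a fraction of
transcripts with planted expression folds, a fraction of internal exons
with planted inclusion ratios, and a mosaic fraction $m$ that mixes the
KO expectation with the CTRL expectation on the linear scale:

$$\mu_{KO}^{obs} = (1-m)\,\mu_{KO} + m\,\mu_{CTRL}$$

which contracts every observed PSI ratio to $(1-m)\,r + m$ — the
two-cell-population picture of incomplete Cre recombination, applied to
expected signals rather than to whole samples because both populations
contribute RNA to every homogenized tissue sample.

Generator choices worth knowing:

* **Planted ratios never fall inside the exclusion window** (draws are
  log-uniform over the design range with the window cut out, or a
  discrete set such as `c(0.5, 2)`), so ground truth is detectable by
  design and recovery measures the pipeline, not the draw.
* **Planted exons are disjoint from planted DE transcripts**, keeping the
  truth orthogonal to the DE-exclusion rule.
* **Inclusion anchoring.** A planted ratio $r \ge 1$ is realized as
  CTRL inclusion $0.95/r$ vs KO $0.95$ (and mirrored for $r < 1$), so the
  planted KO/CTRL inclusion ratio is exactly $r$ and inclusions stay in
  $(0, 1]$.
* **Baseline brightness.** Log2 transcript abundances are drawn from
  N(8, 1.2): after expression filtering, transcripts screened on real
  arrays sit one to two orders of magnitude above background, and the
  generator reproduces that regime rather than populating the
  background-dominated tail the floors exist to remove.
* **Motif content is controlled.** Raw sequence is first scrubbed of AGAA
  (by a G→C rewrite that can create neither a stop codon nor a new
  motif), then occurrences are re-planted at a Poisson rate calibrated
  per 256 bp; `motif_rate = 0` yields strictly motif-free exons, and
  `motif_rate = 1` reproduces the chance rate. Exons carrying planted
  splicing effects are additionally enriched to F ≈ 2.5 by default
  (`enrich_planted_motifs()`), reflecting that genuine Tra2b targets are
  motif-rich; planting refuses positions that would break the open
  reading frame.
* **Every transcript has a clean ORF** — ATG start, no internal in-frame
  stop, stop codon in the last exon, CDS spanning ≥ 2 exons — so the
  unskipped transcript is always PTC-free and skipping consequences are
  attributable to the skip.

What the generator does **not** model: probe-sequence (GC) bias on
intensities, cross-hybridization, correlated probe noise, partial
inclusion baselines per constitutive exon, CEL-level artifacts. Passing
recovery tests on this generator therefore demonstrates that the cascade
is implemented correctly and behaves sanely under realistic noise and
mosaicism — not that it would achieve the same sensitivity on real
hybridization data, whose artifact structure is richer.

# Numerical choices

* **Background correction** uses the closed-form posterior mean of the
  exponential-signal/normal-background convolution; it is strictly
  positive and monotone. Where the normal-tail denominator underflows
  (observations deep in the background), the exponential-tail limit is
  substituted. Parameters default to per-array mode-based estimates; the
  simulated pipeline passes the generative background parameters instead,
  because on synthetic data every probe carries signal and the intensity
  mode sits in the signal bulk, not the background.
* **Quantile normalization** maps each sample onto the across-sample mean
  of rank-ordered values; tied ranks receive the mean of the target
  quantiles they span. The operation is idempotent and rank-preserving
  within samples.
* **Zero-variance features** are testable whenever the variance prior is
  positive ($\tilde s^2 > 0$), which moderation guarantees.
* **Summarization** is the arithmetic mean of log2 probe values (the
  platform's mean/log2 convention), not median polish.
* **Expression floors** read "across arrays" as the mean over arrays —
  the most permissive common reading; the aggregation is not exposed
  because the floors themselves (25 linear for genes, 3 log2 for exons)
  are parameters and any stricter reading is expressible by raising them.
* **Determinism.** All randomness flows from one integer seed through
  per-stage child seeds; the global RNG state is saved and restored, so
  package calls never perturb a user's session RNG.

# Problem sizes in the test suite

The statistical acceptance tests run ten null studies of 2,000 exons
(250 transcripts × 8 exons, 4 vs 4) for the type-I check and a 300-
transcript study with planted ratios {0.5, 2} for the recovery and
mosaicism checks — sizes at which the binomial error of a rejection rate
(±0.5% at n = 20,000) and of a sensitivity estimate (±3% at ~90 planted
exons) is small relative to the asserted margins, while the whole suite
stays interactive (under a minute).

# Known limitations

* PSI here is a relative inclusion proxy; absolute percent inclusion is
  only available from the two-isoform quantification layer
  (`percent_inclusion()`), not from array signals.
* The DE-exclusion rule keys on transcript identity. Exons shared between
  overlapping transcripts of different genes are not disambiguated.
* The moderated-t layer fits a single prior across all transcripts; no
  intensity-dependent variance trend is modeled.
* The NMD rule is the 50-nt heuristic; it knows nothing of
  translation-reinitiation, uORFs or long 3'UTR effects.
* Headline counts from the original full-platform analysis (tens of
  thousands of retained transcripts, ~1,000 initial exons) depend on the
  commercial preprocessing stack and full-size arrays and are not
  reproducible at package-test scale; the suite asserts distributional
  behaviour (error control, recovery, monotonicity) instead.
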