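---
title: "Methods: models, parameters and numerical choices in psiquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices in psiquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the quantitative model behind each `psiquant` stage,
the default parameters and why they were chosen, the scope and limits of the
synthetic-data generator, and the numerical decisions that affect results.
Code chunks are shown for reference and not evaluated at build time.

## 1. The BID-seq quantification chain

BID-seq converts pseudouridine (Ψ) into a reverse-transcription deletion. At
each transcript position the data are a pair (deletion reads, total reads) and
the raw signal is the gap ratio

$$g = \frac{\text{deletion reads}}{\text{total reads}}.$$

Stoichiometry (the Ψ *fraction*, i.e. the proportion of transcript copies
modified) is read off a monotone calibration curve $f = C(g)$ estimated from
spike-ins with known fractions. `calibration_curve(gap_ratio, fraction)`
stores the control points and `calibrate_fraction()` evaluates them by
piecewise-linear interpolation (`stats::approx`, `rule = 2`, so values outside
the fitted range clamp to the boundary fractions). Curves must be strictly
increasing and anchored at $(0, 0)$; `identity_curve()` is the neutral choice
used throughout the synthetic work so planted and recovered fractions live on
the same scale.

A site is *called* when, after merging replicates by summation
(`combine_replicates()`), it passes all of:

* `min_depth = 20` total reads (inclusive),
* `min_deletion_reads = 5` (inclusive),
* `min_gap_ratio = 0.02` (inclusive),
* reference base U (T in the DNA alphabet, on the annotated strand),
* Benjamini–Hochberg $q \le 0.05$ over the candidate set, where the per-site
  P-value is the one-sided binomial upper tail
  $P(X \ge k),\ X \sim \mathrm{Bin}(n, b)$ against the background deletion
  rate $b$.

If no background rate is supplied, `call_sites()` estimates it as the median
gap ratio over covered non-U positions — a robust estimator because true Ψ
signal cannot contaminate non-U positions. The binomial tail is computed as
`pbinom(k - 1, n, b, lower.tail = FALSE)`, which is exact and avoids summing
many tiny terms.

## 2. Synthetic data with planted truth

`sim_config()` freezes every generator parameter together with a single master
seed. All randomness flows through named streams: a stream seed is a hash of
`(master seed, stream name, indices)` reduced modulo a large prime below
$2^{31}$, and `.with_stream()` saves and restores the global RNG state. The
practical consequence is that adding a tissue, a replicate or a new stage
never perturbs draws made by existing streams.

### Transcriptome

Each of `n_genes = 50` genes gets a mature transcript
`5UTR + ATG + sense codons + stop + 3UTR` with lengths drawn uniformly from
`utr5_len_range = (20, 100)`, `cds_len_range = (120, 600)` (rounded to whole
codons) and `utr3_len_range = (30, 150)`. Internal methionine codons are
allowed; internal stops are not. Between 0 and 2 introns of 50–150 nt with
canonical `GT…AG` ends are inserted at uniform positions, and the exon
intervals that map pre-mRNA to mature coordinates are recorded
(`premrna_to_mature()`). The ranges are small enough for second-scale tests
yet long enough that every sense codon appears many times, which matters for
codon-level statistics.

### Planted Ψ sites

Sites are drawn uniformly from U positions, either a fixed `n_psi_sites` or
binomially at `psi_site_rate = 0.02` per U. The base fraction comes from the
two-component Beta mixture

$$f \sim 0.75\,\mathrm{Beta}(1.2, 15) + 0.25\,\mathrm{Beta}(5, 2.5),$$

which puts roughly 71% of its mass below 0.2 — a majority of low-stoichiometry
sites with a substantial high-stoichiometry tail, the structure reported for
mRNA Ψ landscapes. A site is shared across all tissues with probability
`share_all_tissues = 0.5`, otherwise it is unique to one home tissue;
per-tissue fractions jitter around the base on the logit scale with
`tissue_fraction_sd = 0.3`.

### Sequencing

Per tissue and replicate, depth at every position is negative binomial
(`depth_mean = 1000`, dispersion `size = 10`) and deletions are binomial with
success probability `C^{-1}(f) + b` clamped to $[0, 1]$, where
$b$ = `background_deletion_rate = 0.01`. The additive background means
recovered fractions carry a small upward bias of order $b$; the acceptance
RMSE budget (0.03) accounts for this deliberately rather than subtracting the
background, because the subtraction would presume the background is known
exactly.

### Footprints, lifetimes

`simulate_footprints()` plants per-codon dwell times $2^{U(-1,1)} \in
[0.5, 2]$ and a per-transcript translation efficiency whose log responds to
the transcript's summed Ψ fraction with slope `te_effect`. Expected P-site
counts per codon are proportional to dwell × TE × RNA abundance with lognormal
noise (`dwell_noise_sd = 0.1`); reads are emitted with lengths 29–35 nt so
that the P-site (start + `psite_offset = 12`) falls on the codon, plus a 5%
out-of-range junk share (20–28 / 36–45 nt) to exercise the length filter.
`simulate_lifetimes()` plants
$\log(\text{lifetime}) = \log(6\,\mathrm{h}) + \beta \cdot \text{summed
fraction} + \varepsilon$ with `lifetime_effect` $\beta$ and Gaussian noise.

### Scope and limits

The generator is deliberately simple where simplicity does not affect what is
being tested: uniform base composition, independent positions (no alignment
artefacts, no sequence-dependent deletion bias), one strand, no alternative
isoforms, and tissue effects that are exchangeable across tissues. It is
*not* a read simulator — pileups are generated directly — so mapping error is
out of scope by construction.

## 3. Annotation and conservation

`assign_region()` works in pre-mRNA coordinates, first splitting intron from
exon via the recorded exon intervals and then splitting exonic positions into
5′UTR/CDS/3′UTR by the mature-coordinate boundaries. `metagene_profile()`
maps each exonic site to $(p - 0.5)/L$ within its region and bins the three
regions onto a common axis of 30 bins each; densities sum to one.
`region_density()` normalises site counts by the total length of each region
class, with introns measured as pre-mRNA minus mature length.

`smith_waterman()` is a hand-authored local-alignment dynamic programme
(linear gap penalty; default scores match +2, mismatch −1, gap −2). Ties in
the cell recurrence break deterministically diagonal > up > left, and
traceback starts from the first maximal cell in row-major order, so results
are reproducible. The independent test oracle scores all start cells with a
no-floor prefix recursion; `Biostrings::pairwiseAlignment` provides an
external cross-check.

Conservation classes follow the four-way scheme: class 1 — no homologous
site (outside the aligned window or opposite a gap); class 2 — homologous
position that is not U; class 3 — one-to-one homologous U; class 4 —
homologous U in a one-to-many context. Classes 3 + 4 are "conserved".
`conservation_score()` scores an MSA column as the mean pairwise identity of
non-gap pairs, smooths with a truncated moving average and min–max scales to
$[0, 1]$; a constant track scales to all zeros with a warning rather than
dividing by zero.

## 4. Translation efficiency

`compute_tpm()` is the standard length-normalised rate scaled to sum to
$10^6$. `transcript_te()` is the TPM ratio ribo/RNA with an abundance floor
`min_tpm = 1` (inclusive) applied to the denominator sample. `codon_dwell()`
computes, per gene, per-codon P-site counts relative to the gene's mean over
a trimmed CDS window — the first `2 + trim` and last `1 + trim` codons are
excluded (`trim = 5`), dropping initiation/termination artefacts — and then
averages codons across genes weighted by RNA abundance. Only sense codons are
reported. `codon_te()` is the elementwise reciprocal. The estimator is
invariant to global count rescaling by construction, which the tests verify.

## 5. Statistics

* `site_te_correlation()` correlates each site's per-tissue fraction vector
  with each transcript's per-tissue TE vector (pairwise-complete Pearson,
  minimum 3 tissues), records the median r per site, and tallies
  positive/negative/zero/skipped medians.
* `sign_odds_ratio()` reports $\mathrm{OR} = n_+ / n_-$ (exactly-zero r
  excluded but counted) with the one-tailed binomial P-value of $n_+$
  successes in $n_+ + n_-$ trials at $p = 0.5$; $n_- = 0$ yields the `Inf`
  sentinel.
* `wilcoxon_one_tailed()` uses the exact `pwilcox` distribution when the
  pooled sample is tie-free and $\le$ `exact_limit = 12`, otherwise the
  tie-corrected normal approximation with $\pm 0.5$ continuity correction —
  matching `stats::wilcox.test` in both regimes, with full rank-split
  enumeration as the test oracle.
* `.quantile_groups()` makes equal-sized groups (sizes differ by at most one,
  extras to the earliest groups) with ties broken stably by identifier, so
  group membership is reproducible.
* `group_by_feature()` implements the relative 5′UTR length as
  `utr5_len / cds_len`, excluding zero-CDS rows.
* tRNA analysis decodes anticodons with standard wobble rules (G34 pairs
  C/U, U34 pairs A/G, A34 pairs U, C34 pairs G; stop codons removed) and
  correlates each Ψ site's tissue fractions with the TE of every decoded
  codon, one record per (site, codon).

## 6. Problem sizes and runtime

Default sizes are chosen so the full test suite runs in under a minute of
compute per module and the complete acceptance script finishes in seconds:
50–400 genes, 1–9 tissues, depth ~1000×, 200 planted sites for calling
recovery, 500 alignment oracle trials at length ≤ 8, and 200 null replicates
for P-value calibration. These are the package's own choices for fast,
well-powered verification; all of them scale linearly through the same code
paths for larger inputs.

## 7. Open modelling questions and the choices made

* **Background handling.** The observed deletion probability is modelled as
  signal plus background; calling tests against the background but fraction
  estimates are not background-subtracted (see §2). Users fitting real
  calibration curves absorb this into the curve itself.
* **Per-site median correlation.** "The median correlation of each site" is
  computed as the median over transcripts of per-(site, transcript) r. The
  alternative (pooling tissues across transcripts first) is not implemented.
* **Group-wise correlation.** Grouped TE analyses compute statistics per
  transcript and then compare groups; computing one statistic per group
  directly is available through the stratified path of `te_group_analysis()`.
* **tRNA regions.** Cloverleaf region labels come from the canonical
  76-position numbering table (`trna_region_map()`), not from folding the
  sequence.
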