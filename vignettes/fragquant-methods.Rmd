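---
title: "Calibrating long-read counts with restriction-fragment length standards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating long-read counts with restriction-fragment length standards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Single-molecule long-read sequencing (PacBio SMRTbell ligation libraries,
Oxford Nanopore ligation and transposase libraries) recovers DNA molecules
with an efficiency that depends strongly — and non-linearly — on molecule
length, on the bases at the ligated 3′ termini, and on how the molecules
were handled. When the question is *how much* of each DNA species is present
(the motivating case is quality control of rAAV gene-therapy vector
preparations, whose genome and plausible contaminants span roughly 200 bp to
10 kb), raw read counts misstate molar composition by up to an order of
magnitude.

A complete restriction digest of a genome is a natural length standard:
every fragment occurs exactly once per genome copy, so the digest is
equimolar by construction (up to repeat-induced duplicate fragments and
replication-driven copy-number gradients, both of which this package models
explicitly). Digesting a genome *in silico*, sequencing the same digest, and
comparing per-fragment read frequency with the known equimolar truth yields
the relative sequencing efficiency as a function of length — and a cubic
smoothing spline fitted to a small spike-in digest (phage lambda) transfers
that calibration to unknown samples.

`fragquant` implements the full path:

1. **`digest()` / `find_cut_sites()`** — IUPAC-degenerate site scanning on
   circular or linear genomes, fragment inventory with 3′ terminal-base
   classes, duplicate collapsing (`collapse_unique()`).
2. **`load_alignments()` / `filter_reads()` / `count_and_normalize()`** —
   per-fragment counting from SAM/BAM against a per-fragment reference,
   with whole-read removal of supplementary-alignment (chimeric,
   incomplete-digest) reads, percent / RPM / RPKM normalizations, observed
   length statistics and coverage profiles.
3. **`cv_by_length()` / `end_bias_table()` / `end_bias_summary()`** —
   variability by length bin and ligation bias by unordered 3′
   terminal-base pair (10 classes) or terminal-dinucleotide pair.
4. **`per_fragment_ratio()` / `rolling_bin_average()` /
   `extremum_report()` / `region_significance()`** — replication-gradient
   detection between growth conditions across a circular chromosome.
5. **`fit_calibration()` / `calibrate()`** — the spike-in smoothing-spline
   calibration and its application to correct frequencies into molar
   abundance estimates.
6. **`simulate_genome()` / `bias_model()` / `simulate_library()`** — a
   truth-annotated generator of biased synthetic libraries so the entire
   pipeline is testable without any sequencing data.

## In-silico digestion conventions

Coordinates are 0-based half-open on the top strand. A cut coordinate is
the genome position immediately before which the blunt cut falls: a site
matched at position $s$ with cut offset $o$ cuts at $s + o$. Both strands
are scanned (for the palindromic-degenerate patterns of the four built-in
enzymes — AleI `CACNN^NNGTG`, PshAI `GACNN^NNGTC`, XmnI `GAANN^NNTTC`,
PvuII `CAG^CTG` — the reverse-complement scan is redundant and is skipped).
Distinct coordinates are counted once even when several overlapping windows
imply the same cut; overlapping windows implying *different* coordinates
count separately. Circular genomes are scanned across the origin by
extending the sequence with its first `patlen - 1` bases; a circular genome
with $n \ge 1$ cuts yields exactly $n$ fragments, a linear genome $n + 1$.
`N` bases in the genome never match any pattern position, so ambiguous
reference regions cannot create phantom sites.

Duplicate fragments (e.g. from ribosomal repeats) are collapsed by
canonical sequence — the lexicographic minimum of a fragment's sequence and
its reverse complement — because reads from such fragments cannot be
assigned to a single locus; the representative keeps `copy_count`, and all
per-molecule quantities downstream divide by it.

For a blunt fragment the two 3′ termini are the complement of the first
base (bottom strand, left end) and the last base (top strand, right end).
Since left/right is not biologically meaningful, classes are unordered
pairs: 10 single-base classes, and analogous dinucleotide-pair classes for
the stronger composite bias.

## Counting rules

Reads are assigned to fragments by the aligner's reference name (the
reference is the per-fragment FASTA emitted by `write_fragment_fasta()`);
there is no positional re-assignment. A read with *any* supplementary
alignment spans more than one predicted fragment — the signature of an
incompletely digested, chimeric molecule — and is removed entirely.
Secondary and unmapped records are never counted; each surviving read
contributes exactly one primary record. Zero-count fragments stay in every
table so the full inventory is always the denominator of the three
normalizations (`freq_pct` summing to 100, `rpm` to $10^6$, and
`rpkm = rpm / (L/1000)`, which is length-flat for an unbiased
transposase library).

"Observed length" is the query length of the read (full molecule for
ligation-style protocols); the aligned span is kept separately. The
shear-suspect flag in `length_concordance()` (median observed length below
0.9 of expected) is a reporting convention, configurable. Coverage
profiles normalize depth to the maximum over all fragments of the same DNA
source by default; per-fragment normalization is available where the
per-source convention would hide low-frequency fragments.

## The calibration model

The response fitted is the **per-molecule frequency**
$y_i = f_i / c_i$ (library percent divided by duplicate copy count) against
expected fragment length $L_i$, in linear space. The default curve is a
natural cubic smoothing spline in the `csaps` parametrization: minimize

$$ p \sum_i (y_i - g(L_i))^2 + (1 - p) \int g''(t)^2 \, dt $$

over natural cubic splines with knots at the data lengths. $p = 1$
interpolates the points; $p = 0$ degenerates exactly to the least-squares
line (implemented as the analytic limit, and verified against `lm()`).
Duplicate lengths are averaged before fitting, since the abscissae must be
distinct. The solver is the Green–Silverman band formulation
($f = (pI + (1-p)K)^{-1} p\,y$ with $K = Q R^{-1} Q^\top$), dense — spike
digests have at most a few hundred fragments, so no sparse machinery is
warranted. Tests verify the fit variationally (random perturbations of the
fitted values increase the penalized objective) and check the $p = 1$ limit
against `stats::spline(method = "natural")`.

When no smoothing level is supplied, $p$ is chosen by leave-one-out
cross-validation over a $\lambda = (1-p)/p$ grid centered on the classical
$\bar h^3/6$ scale. The LOO loss is **relative** squared error
$((\hat y_{-i} - y_i)/y_i)^2$: count frequencies carry roughly
multiplicative noise, and an absolute loss lets the peak of the curve
dominate, oversmoothing the low-efficiency tails where relative accuracy
matters most.

Predictions are clamped, not extrapolated: below the training minimum the
curve value at the minimum is returned (flagged out of range), and beyond
10 kb the plateau value $e(10\,\mathrm{kb})$ is used, because counts are
approximately length-independent there and a spline extrapolates
polynomially and unsafely. Corrected abundances are
$a_i \propto f_i / e(L_i)$, renormalized to sum to 100. Because each
library is normalized within itself, only the *shape* of $e(L)$ transfers
between libraries; `evaluate_fit()` therefore rescales predictions by a
single total-matching factor before computing RMSE and median absolute
relative error. Straight-line baselines (linear, and linear in
$\log L$) are provided for comparison and fail clearly on the unimodal
efficiency profiles real libraries show.

Models serialize to JSON with all numerics encoded as `%.17g` strings, so
a round-trip through `write_calibration()` / `read_calibration()` is
bit-exact.

## Bias quantification choices

Length-bin CV uses the sample standard deviation over the mean of
`freq_pct` in 500 bp bins (bins with fewer than two members are omitted).
End-bias cells report the **raw** mean count per class — matching the
average-read-count convention of ligation-bias analyses — with frequency
available by flag; cells supported by five or fewer fragments are
suppressed. Default length-bin edges are 401–1000 and then 1000-wide bins
to 10,000 bp. Class-level summaries weight bin cells by fragment support.

For replication gradients, per-fragment ratios use within-sample
normalized frequencies (depth cancels); fragments with zero frequency in
either condition are excluded and counted. Tracks average ratios in
100,000 bp bins by fragment midpoint (midpoint assignment also decides
bin-boundary-spanning fragments), with circular wrap. The alternative
smoother is a sliding window of $k$ adjacent fragments (default 50)
weighted by fragment length — ratios of long fragments rest on more reads.
Regional significance uses a two-sided permutation test on region labels
(default 10,000 permutations, $p = (1 + \#\{|T^\ast| \ge |T|\})/(n+1)$)
because per-fragment ratios are neither normal nor independent of length;
a Mann–Whitney U alternative is available. Regions are selected around two
centers either by fixed genomic distance or by fixed fragment count, and
must not overlap.

## What the simulator emulates — and what it does not

`bias_model()` declares the generative mechanisms; `simulate_library()`
draws molecules by fragment abundance (`copy_count` × copy-number profile ×
3′ end-efficiency product, × length in transposase mode) and then applies:

* **Random shearing** — per-molecule break count Poisson(`shear_rate` × L)
  at uniform positions; the default preset 1e-4/bp reproduces a mean
  observed-length plateau near 10 kb while medians track expected length
  much further.
* **Length selection** — the unimodal length-efficiency curve (presets:
  `short_prep`, log-normal-shaped peak at 4 kb with a 0.05 floor and
  width σ = 0.6 in log length; `long_prep`, peak 10 kb; `flat`) is applied
  as a retention probability `le(len)/max(le)` to each molecule, or to each
  *piece* of a sheared ligation molecule independently. This single
  placement makes the expected counted frequency of an unsheared library
  exactly the composite weight recorded in the truth table, and it is what
  produces the mid-fragment coverage dip of long sheared fragments: the
  piece containing a fragment's middle is necessarily the longest and, past
  the efficiency peak, the most likely to be lost. Under a flat curve every
  piece is retained and the pieces of each molecule tile its interval
  exactly.
* **End-base ligation bias** — multiplicative per-3′-base efficiencies
  applied once per end; the default A = 0.41, T = 0.8, G = 0.9, C = 1.0
  ordering yields both-A fragments lowest, no-A highest, and a roughly
  six-fold AA:CC deficit at the terminal-dinucleotide level.
* **Incomplete digestion** — with probability `incomplete_digest_rate`
  (0.01 is typical for a complete digest; 0.07 mimics a
  methylation-blocked enzyme) a molecule is an uncut chimera of two
  genomically adjacent fragments, emitted as a primary plus a supplementary
  SAM record — precisely what `filter_reads()` removes.
* **Transposase mode** — reads start at a uniform internal insertion point
  and end at a uniform downstream position, so original length information
  is lost and sampling gains a factor of L.
* **Replication gradient** — `copy_number_gradient()` interpolates copy
  number linearly in circular distance between an origin and the
  diametrically opposite terminus.

Everything is seed-deterministic (bit-identical reads, truth tables and SAM
files under the same seed, with the caller's RNG stream restored).

The simulator does **not** model base-call errors or quality strings
(SAM qualities are `*`), mappability or alignment ambiguity, enzyme star
activity, sticky-end chemistry, or sequence-specific (beyond terminal-base)
library effects. Passing tests therefore demonstrate that the *estimators*
are correct under the declared generative model and recover injected
parameters; they do not certify accuracy on real data, where alignment and
chemistry add error modes the generator omits.

## Problem sizes and statistical design of the test fixtures

The validation suite simulates genomes of 0.2–12 Mb and libraries of
2×10^4–8×10^5 molecules; the full suite runs in a few minutes on one CPU.
Two fixture choices deserve explanation:

* **Equimolar recovery window.** The end-to-end check (equimolar XmnI
  digest under the short-prep bias, calibrated with a spline fitted on a
  disjoint spike genome) asserts a corrected max/min ratio ≤ 1.25 at
  10^5 reads, over fragments of 1–10 kb. The window follows from counting
  power, decided before the fixture was frozen: at 10^5 reads a fragment
  needs roughly ≥ 700 expected counts for its 3-SD binomial band to fit
  inside ±12%, which fragments below ~1 kb (efficiency ≤ 10% of peak under
  the short-prep curve) cannot reach at this depth. XmnI is used because
  its ~4 kb mean fragment length concentrates fragments near the
  efficiency peak.
* **Dinucleotide-class support.** Both-AA and both-CC terminal
  dinucleotide pairs each occur on ~1/256 of fragments, so the
  supplementary-style AA:CC comparison simulates a large (≥ 12 Mb) genome
  and, in the acceptance script, grows it until both classes clear the
  more-than-five-fragments cell rule.

The digestion scanner is validated against an independent brute-force
oracle (IUPAC → regex character classes, overlapping matches by lookahead,
both strands scanned explicitly) on hundreds of random genomes up to 50 kb,
and the known cut inventory of the *E. coli* MG1655 chromosome
(`NC_000913.3`) is asserted exactly by an acceptance test that reads the
genome FASTA from `tests/testthat/local/` — the 4.6 Mb reference is not
bundled with the package; drop it (and `J02459.1.fasta` for lambda) in that
directory to run those checks.

## Known limitations

* Only blunt, palindromic-degenerate cutters are modelled; overhang
  chemistry is an explicit extension point.
* Methylation sensitivity is not predicted; incomplete digestion enters
  only as a rate in the simulator.
* The calibration corrects length bias only; end-base bias is quantified
  but not corrected, and applying a length-only correction to a sample
  with strong end-base composition skew will leave residual error.
* Below-range lengths are clamped, so abundance estimates for fragments
  shorter than the spike-in's shortest fragment inherit its efficiency and
  are flagged rather than extrapolated.
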