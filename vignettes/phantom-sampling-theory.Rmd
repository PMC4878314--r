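---
title: "Sampling theory for paired rRNA/rDNA community surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling theory for paired rRNA/rDNA community surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantomtaxa)
```

## The problem

Comparative 16S surveys sequence the same community twice: rDNA (gene)
amplicons profile the *total* community — active, dormant and dead cells
alike — while rRNA (transcript, sequenced as cDNA) amplicons profile its
*potentially active* fraction, because ribosome content scales with
metabolic activity. Active taxa are by definition a subset of total taxa,
yet real paired datasets routinely contain **phantom taxa**: OTUs observed
in the rRNA libraries and never in the rDNA libraries. `phantomtaxa`
implements a sampling model that explains phantoms as a pure
finite-sampling artifact, quantifies how fast they disappear with
sequencing depth, and provides the comparative analysis pipeline (OTU
partitions, rRNA:rDNA activity ratios, diversity and Canberra distances)
that such studies run on their paired OTU tables.

## The community model

A community of $S$ taxa is specified by three ingredients:

* a **species abundance distribution** (SAD) for the rDNA pool: taxon $i$
  holds $k_i \ge 1$ rDNA copies. All SADs here are zero-truncated
  (a present taxon has at least one copy). The default working SAD is a
  zero-truncated negative binomial with shape 1, a conventional
  heavy-tailed choice for microbial SADs; its mean is user-set.
* an **activity profile** $\alpha(k) \in [0,1]$: the fraction of taxa at
  abundance $k$ that are metabolically active.
* an **activity intensity** $m(k) > 0$: the rRNA:rDNA copy ratio of an
  active taxon at abundance $k$.

$\alpha$ and $m$ are step functions over abundance classes
(`activity_profile()`, `intensity_function()`): classes are half-open
intervals $[b_j, b_{j+1})$ with an open-ended last class, so every $k \ge 1$
belongs to exactly one class. A three-class parameterization is the
canonical use; per-$k$ resolution is available by supplying one breakpoint
per abundance value. When breakpoints are not given, `realize_model()` uses
the empirical tertiles of the realized abundances, so that the three
classes are populated roughly equally regardless of the SAD's scale.

A realized community assigns each taxon an activity state and an rRNA copy
count

$$r_i = \begin{cases} \max\{1,\ \mathrm{round}(m(k_i)\,k_i)\} & \text{taxon } i \text{ active} \\ 0 & \text{otherwise,} \end{cases}$$

with rounding half away from zero. Two modelling commitments are built in:

* **Inactive taxa carry zero rRNA.** Dormant-but-ribosome-bearing cells
  exist in nature but are outside this model's scope; "active" here means
  "rRNA producing".
* **Active taxa carry at least one rRNA copy.** Without the floor, an
  active taxon with $m(k)k < 0.5$ would be invisible to the rRNA pool even
  at exhaustive sampling, and the rRNA rarefaction curve would no longer
  converge to the active fraction $S_\mathrm{active}/S$ — a convergence the
  theory relies on.

Activity assignment has two modes. `bernoulli` (default) marks each taxon
independently active with probability $\alpha(k_i)$ — the natural
statistical reading. `expected` activates exactly
$\mathrm{round}(\alpha \cdot n_c)$ taxa in each class $c$, chosen by a
seeded shuffle; it exists because deterministic class-wise activation makes
paired comparisons (same abundance draw, different profiles) exact, which
the contrast between the two preset regimes exploits.

## Sampling theory

Sequencing is modelled as random sampling from the two pools, drawn
**independently** — the rDNA and rRNA libraries are prepared and sequenced
separately, and the phantom mechanism ("its rRNA is caught, its rDNA avoids
collection") factorizes only under independence. Within-cell coupling
between the two pools is out of scope.

For a taxon holding $c$ of the $T$ copies in a pool sampled $n$ times, the
detection (occupancy) probability is

$$p_\mathrm{wo}(c, T, n) = 1 - \binom{T-c}{n}\Big/\binom{T}{n}
\qquad\text{(without replacement)},$$
$$p_\mathrm{wr}(c, T, n) = 1 - (1 - c/T)^n
\qquad\text{(with replacement)},$$

with $\binom{a}{b} = 0$ for $b > a$. Binomial coefficients are evaluated in
log-gamma space (`lchoose`) so pools of millions of copies do not overflow.
Expected richness is the sum of detection probabilities over taxa
(inactive taxa contribute zero to the rRNA pool), and the expected phantom
count is

$$E[\text{phantoms}] = \sum_{i\,\mathrm{active}}
  p(r_i, R, n_\mathrm{rRNA}) \,\bigl(1 - p(k_i, N, n_\mathrm{rDNA})\bigr).$$

`rarefaction_curves()` maps a single effort fraction $f$ to both pools
proportionally ($n_\mathrm{rDNA} = \mathrm{round}(fN)$,
$n_\mathrm{rRNA} = \mathrm{round}(fR)$) — the faithful reading of a single
"sampling effort" axis; independent per-pool depths remain available
through `sampling_design()`. Without replacement, three exact limits hold
at $f = 1$ and are asserted in the test suite: the rDNA richness fraction
reaches 1, the rRNA fraction reaches $S_\mathrm{active}/S$, and the phantom
count reaches 0. They are exact only without replacement, which is why that
is the default scheme for the theory; `with_replacement` is provided for
relative-abundance-only inputs.

Phantom curves report expected **counts**; a normalized variant
(divided by $S_\mathrm{active}$) sits behind `normalize_phantom = TRUE`.

Three independent routes compute the same quantities and are held to each
other in the tests: the analytic forms above; `monte_carlo_expectations()`
(multivariate-hypergeometric or multinomial simulation, replicate draws
vectorized across a chain of `rhyper` calls); and
`brute_force_expectations()`, an exhaustive enumeration over all equally
likely subset pairs, feasible for pools of at most a few copies and guarded
at $10^6$ enumerated pairs. Analytic and brute-force values agree to
$10^{-12}$ on all small communities tested; Monte-Carlo means agree with
the analytic values within three standard errors.

One boundary note: the with/without-replacement detection probabilities
agree closely only while both $n/T$ and $c/T$ are small. At pool size
$10^4$ the gap stays below $10^{-3}$ across $c, n \le 100$ except at the
joint corner $c = n = 100$, where it is $1.8\times 10^{-3}$; the finite
pool correction is of relative order $cn/T^2$ and both factors are maximal
there.

## The two preset regimes

`preset_figure4()` encodes the two contrasting three-class regimes used
throughout:

* **Regime a** — activity and intensity increase with abundance:
  $\alpha = (0.10, 0.60, 1.00)$, $m = (1, 10, 2000)$ across ascending
  abundance classes. Active taxa are mostly abundant, their rDNA is easy to
  catch, and phantoms vanish quickly with effort.
* **Regime b** — both reversed: $\alpha = (1.00, 0.60, 0.10)$,
  $m = (2000, 10, 1)$. Activity concentrates in rare taxa with very high
  rRNA output: their rRNA is caught almost immediately while their single
  rDNA copies escape sampling, so phantoms persist to much higher effort.

With a shared abundance draw and `expected`-mode activation, the regime-b
phantom curve dominates regime a's at every interior effort — an ordering
the acceptance tests check directly rather than assume.

## The synthetic-data generator

`generate_paired_tables()` is the observation layer: for each of
`n_sample_pairs` days (default 4, matching a four-day paired-library
layout) it draws one rDNA and one rRNA library from the community's pools.
Defaults and their reasons:

* **Multinomial reads by default**, even though the community is finite:
  library preparation resamples template molecules, so reads are draws
  *with* replacement from copy proportions. `without_replacement`
  generation is retained because it corresponds exactly to the analytic
  theory, which the end-to-end consistency tests exploit.
* **Equal depths per pair by default**; no split between rDNA and rRNA
  depth is imposed. A depth of 19,136 reads per library — a typical
  filtered-library yield for this kind of survey — is the CLI default.
* **Day-to-day variation** is a single optional lognormal perturbation of
  the pool proportions (default off). Anything richer (autocorrelation,
  compositional drift) would be invention, and the perturbation is only
  defined for multinomial reads — there are no "proportions" to perturb in
  a finite-pool subset draw, so combining noise with `without_replacement`
  is an error rather than a silent approximation.
* **All-zero rows are retained** in generated tables so the row universe
  equals the community's taxa; the pipeline strips them after rarefaction.

What the generator does **not** emulate — and therefore what passing tests
do not demonstrate about real data: PCR and primer bias, chimeras,
sequencing error and the cDNA base-call-error route to phantom OTUs
(a laboratory mechanism distinct from the sampling artifact modelled
here), OTU-clustering artifacts, 16S copy-number variation (1–15 copies
per genome), contaminant filtering, and any taxonomic structure. Phantom
fractions in real studies are the sum of the sampling effect modelled here
plus those mechanisms.

## The analysis pipeline

`run_report()` chains the stages a paired-table study runs; each stage is
available separately.

* **Rarefaction** (`rarefy`): every column subsampled without replacement
  to one even depth (via `vegan::rrarefy`), short columns either an error
  or dropped, all-zero rows dropped afterwards. Empirical rarefaction is a
  single seeded draw — matching common practice and a single
  "OTUs after rarefaction" accounting — while theory-side curves use
  analytic expectations; the two should not be conflated.
* **Partition** (`partition_otus`): detection is pooled across all samples
  of a nucleic-acid class (count > 0 in any column), because library-wide
  shared/phantom totals are the standard summary; `per_sample` gives
  day-wise partitions. Percentages are rounded half away from zero to one
  decimal.
* **Ratios** (`rrna_rdna_ratios`): per-OTU class means of per-column
  relative abundances, ratio = rRNA mean / rDNA mean, defined only for
  shared OTUs (both means positive). Class means of relative abundances —
  rather than pooled counts — keep unequal library depths from biasing
  ratios; this convention is a package decision, recorded here because
  either reading is defensible.
* **Correlation** (`ratio_abundance_correlation`): ratio against mean rDNA
  relative abundance, both log10-transformed by default (both are strictly
  positive for shared OTUs; the relationship is multiplicative). Pearson
  and tie-corrected Kendall tau-b are exposed; p-values are asymptotic.
* **Diversity** (`alpha_diversity`): richness, Shannon entropy in nats,
  Pielou evenness $J = H/\ln(\text{richness})$ with an `NA` marker when
  richness < 2.
* **Distances** (`canberra_matrix`): classic Canberra
  $\sum_{x_i+y_i>0} |x_i-y_i|/(x_i+y_i)$ and the nonzero-normalized
  variant (divided by the number of contributing coordinates, the
  `vegan::vegdist` convention). Classic Canberra is a semimetric; only
  symmetry, nonnegativity and zero self-distance are guaranteed or tested.
* **Shared-OTU percentage** (`shared_otu_percentage`): the core set is the
  OTUs present in *every* sample of a class; per-sample percentage is
  relative to that sample's richness. The alternative reading — mean
  pairwise overlap — is not implemented.

Detection is count ≥ 1 after rarefaction; read-level filters (singleton
removal, contaminant and organelle screening) belong to upstream sequence
processing, not to this pipeline. Differential-abundance testing is
likewise out of scope — established tools exist for it and the partition,
ratio and phantom machinery is the analytical core here.

## Numerical conventions and degenerate inputs

* All rounding of counts and percentages is **half away from zero**
  (`round_half_away()`), stated so outputs are bit-comparable across
  platforms and languages.
* Hypergeometric terms are computed in log space; probabilities are
  clamped to $[0,1]$ against floating-point underflow.
* Zero-truncated negative binomial sampling is by rejection (redraw
  zeros); the zero-truncated geometric uses the exact shift
  `rgeom(p) + 1`; log-series sampling inverts a pmf table truncated where
  the tail mass falls below $10^{-12}$.
* Every random operation takes a `seed` argument evaluated under a local
  RNG (`withr::with_seed`), leaving the caller's RNG stream untouched;
  identical seeds give field-identical communities, byte-identical written
  tables and reports.
* Degenerate inputs fail loudly: an empty rRNA pool cannot be sampled
  without replacement (but yields all-zero rRNA columns under multinomial
  generation, mirroring a fully dormant community); a table whose rRNA
  side detects nothing aborts the partition stage; correlations with fewer
  than 3 records or zero variance are errors, not `NA`s.

## Problem sizes used in the test suite

The suite realizes communities of 40–500 taxa, enumerates exhaustive
oracles on pools of at most 8 copies, runs Monte-Carlo checks at 2,000
replicates over 20 randomized community/design pairs of 200 taxa, and
averages end-to-end phantom fractions over 200 generation seeds along a
500/2,000/8,000-read depth ladder. These sizes were chosen to make the
statistical assertions (3-standard-error brackets) sharp while keeping the
default test run fast on a laptop; all scale linearly if enlarged.

## Known limitations

* The phantom expectation assumes pool independence; any within-cell
  coupling between rDNA and rRNA capture would change the product form.
* rRNA copy counts are deterministic given $(k, m(k))$ — there is no
  taxon-level dispersion of intensity within a class.
* No inference: $\alpha(k)$ and $m(k)$ are inputs, not estimated from
  data, and no richness extrapolation (Chao-type) is attempted beyond
  observed effort.
* The empirical-tertile default for breakpoints depends on the realized
  draw; supply explicit breakpoints when exact cross-run comparability of
  class boundaries matters.
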