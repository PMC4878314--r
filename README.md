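# phantomtaxa

Sampling theory and comparative analysis for paired rRNA/rDNA microbial
community surveys.

## The problem

Comparative 16S surveys profile a community twice: rDNA (gene) libraries
capture the **total** community, while rRNA (transcript, sequenced as cDNA)
libraries capture its **metabolically active** fraction, since active cells
carry hundreds to thousands of ribosomes but only a handful of rRNA gene
copies. Active taxa are by definition a subset of total taxa — yet paired
datasets routinely contain **phantom taxa**: OTUs detected in the rRNA
libraries but never in the rDNA libraries.

`phantomtaxa` is for microbial ecologists running or interpreting such
paired surveys. It shows quantitatively that phantoms arise from random
sampling alone — an active taxon's abundant rRNA is caught while its few
rDNA copies escape collection — and lets you compute, for any assumed
community structure, how deeply you must sequence to push the expected
phantom count below a chosen threshold.

## The model

A community of `S` taxa is specified by:

* a zero-truncated **species abundance distribution** for rDNA copies
  (taxon `i` holds `k_i >= 1` copies; negative binomial with shape 1 is the
  working default);
* an **activity profile** `alpha(k)`: the fraction of taxa at abundance `k`
  that are active;
* an **activity intensity** `m(k)`: the rRNA:rDNA copy ratio of active
  taxa at abundance `k`,

with `alpha` and `m` step functions over abundance classes. An active taxon
carries `max(1, round(m(k) * k))` rRNA copies; an inactive taxon carries
none. Sequencing draws the two pools independently. The detection
probability of a taxon with `c` of `T` pool copies in a sample of `n` is
hypergeometric, `1 - C(T-c, n) / C(T, n)` (or `1 - (1 - c/T)^n` with
replacement), giving expected richness as a sum over taxa, and the expected
phantom count as

```
E[phantoms] = sum over active taxa of
              P(detected in rRNA sample) * (1 - P(detected in rDNA sample)).
```

The rDNA rarefaction curve converges to 1 at full without-replacement
sampling, the rRNA curve to the active fraction `S_active / S`, and the
phantom curve to 0 — how *fast* it decays depends on whether activity
concentrates in abundant taxa (regime "a": `alpha` = 10%, 60%, 100% and
`m` = 1, 10, 2000 across ascending abundance classes) or in rare taxa
(regime "b": both reversed), both available via `preset_figure4()`.

## Worked example

```r
library(phantomtaxa)

# Rare-active regime: activity and intensity fall with abundance
cfg <- preset_figure4("b", n_taxa = 500)
com <- realize_model(cfg, seed = 42)
com
#> Joint rDNA/rRNA community: S = 500 taxa (268 active), N = 5433 rDNA copies, R = 744489 rRNA copies

rarefaction_curves(com, efforts = c(0, 0.05, 0.25, 0.5, 1))
#>   effort n_rdna n_rrna rdna_fraction rrna_fraction phantom_count
#> 1   0.00      0      0         0.000         0.000           0.0
#> 2   0.05    272  37224         0.371         0.520         200.9
#> 3   0.25   1358 186122         0.796         0.536          91.0
#> 4   0.50   2717 372245         0.922         0.536          38.3
#> 5   1.00   5433 744489         1.000         0.536           0.0
```

At 5% effort the rRNA pool already reveals 52% of all taxa (nearly every
active one — the active fraction is 53.6%) while the rDNA pool has found
only 37%, leaving ~201 active taxa expected as phantoms; by full effort the
rDNA curve reaches 1 and phantoms vanish.

Simulate four days of paired libraries at 1,000 reads each and run the
comparative pipeline:

```r
tab <- generate_paired_tables(com, n_sample_pairs = 4,
                              depth_rdna = 1000, depth_rrna = 1000, seed = 43)
rep <- run_report(tab, quiet = TRUE)
rep$partition
#> OTU partition (n = 498):
#>   shared rDNA+rRNA :   159 (31.9%)
#>   rDNA only        :   306 (61.4%)
#>   rRNA only        :    33 (6.6%)  <- phantom taxa
```

33 OTUs (6.6%) are phantoms — truly active taxa whose rDNA escaped all four
1,000-read libraries. The per-OTU rRNA:rDNA activity ratios span 0.0213–57
(mean 12.2), and the ratio falls with rDNA abundance
(`rep$correlation$estimate` = −0.781, Pearson on log10 scales): the rare
members of the total community are the disproportionately active ones, as
this regime encodes.

A thin command-line wrapper over the same functions ships in
`inst/cli/phantomtaxa.R` with `curves`, `simulate` and `analyze`
subcommands.

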