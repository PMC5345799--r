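# chromarch

Two-state chromatin domain segmentation and genome-architecture
statistics for *Drosophila*-scale genomes.

## The problem

Repressive chromatin marked by H3K27me3 is organised in domains. Given
a tiling-array ChIP profile of H3K27me3, `chromarch` partitions each
chromosome into **D** (depleted) and **E** (enriched) domains and then
quantifies how that binary partition relates to the physical
architecture of the genome measured by Hi-C:

* correspondence of D/E borders with TAD boundaries and with polytene
  band borders (nearest-distance statistics, e.g. the fraction of TAD
  boundaries within one 10-kb bin of a D/E border);
* composition of D and E domains — TSSs, binding summits, chromatin
  states, gene-expression breadth;
* scaled-domain and accumulation profiles of binding summits;
* the contrast between short-range (5–50 kb) and long-range
  (50–500 kb) interactions inside D versus E domains;
* detection of **D-D corner hotspots**: elevated contact between the
  two D domains flanking an E-domain TAD.

It is aimed at computational epigenomicists who want each stage of this
kind of analysis as a tested, scriptable R function, together with a
synthetic-data generator that provides ground truth for all of them.

## Models at the core

**Segmentation.** Per chromosome the binned signal
$x_t$ follows a two-state hidden Markov model with Gaussian emissions
$x_t \mid s_t = k \sim \mathcal N(\mu_k, \sigma_k^2)$, fitted by
expectation-maximisation (deterministic median-split initialisation,
missing bins contribute no emission term) and decoded by the
most-probable path. The state with lower $\mu$ is D; runs of equal
labels become regions; probe gaps flanked by one state are absorbed.

**Hi-C normalisation.** Binned counts $o_{ij}$ are divided by the
binomial coverage-product expectation $e_{ij} = 2 r_i r_j N$
($r_i^2 N$ on the diagonal), where $r_i$ is bin $i$'s share of read
ends and $N$ the intra-chromosomal pair total.

**TAD calling.** Exact dynamic programming under a block likelihood on
$\log(1+x)$ values — block-constant means on diagonal blocks over a
shared background mean, likelihood restricted to cells within 500 kb of
the diagonal — followed by a border filter that removes the lowest 10%
of the "linear portion" of the sorted per-border log-likelihood gains
(chord-distance elbow rule).

**Hotspots.** An eligible E domain (≥ 60 kb, D on both sides) is a
hotspot when the corner rectangle of flanking-D bins has aggregate
observed/expected density more than 1.1-fold above same-shape D-D
neighbour rectangles, after a joint fit of per-bin visibility and
distance decay over cross-domain cells.

## Worked example

Simulate a two-arm genome under the default study conditions, segment
it, and check the recovery against the generator's truth:

```r
library(chromarch)

gen <- genome(c("c2L", "c2R"), c(2e7, 2e7))
cfg <- sim_config(gen)

sim <- simulate_chip_track(cfg, seed = 1)
map <- segment_track(sim$track)
attr(map, "params")$c2L
#> hmm_params: means -0.2972/0.5978, sds 0.2507/0.3486, stay 0.9789/0.9812

d <- nearest_border_distances(domain_borders(sim$truth),
                              domain_borders(map))
fraction_within(d, 1000)
#> [1] 0.9148387

feats <- simulate_features(cfg, sim$truth, seed = 2)
assign_points(feats, map)$table
#>          class  n_D  n_E n_gap frac_D frac_E
#> 1 housekeeping 1869  131     0 0.9345 0.0655
#> 2    regulated  480 1520     0 0.2400 0.7600
```

The fitted emission means and stay probabilities reproduce the
generating values (−0.3/+0.6, 0.98); 91.5% of true domain borders are
recovered within one 1-kb bin; and the called map assigns 93.5% of
housekeeping-like TSSs to D domains against a configured placement
probability of 0.95 (the shortfall is features in the few domains the
decoder cannot resolve).

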