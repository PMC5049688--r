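---
title: "Simulating bacterial genomes under the coalescent with gene conversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating bacterial genomes under the coalescent with gene conversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bacsim)
```

## The model

`bacsim` simulates a sample of `n` bacterial genomes backward in time
under the coalescent with gene conversion. The state is a set of
lineages, each carrying *ancestral material*: the set of genomic sites
at which the lineage is ancestral to the sample, represented as sorted
disjoint half-open intervals (`interval_set`). Three processes compete
as independent exponentials:

* **Coalescence** at rate $k(k-1)/2$ for $k$ active lineages; the pair
  is uniform, materials union.
* **Within-species gene conversion**: each site of each lineage
  initiates a tract at scaled rate $R/2$ per coalescent time unit;
  tract lengths are geometric with mean $\delta$,
  $P(\ell) = \tfrac1\delta(1 - \tfrac1\delta)^{\ell-1}$. The recipient
  lineage splits: a donor lineage carries the tract backward (never on
  the clonal frame), the recipient keeps the complement.
* **Between-species imports**: initiation at rate $R_e/2$ per site,
  geometric lengths with mean $\delta_e$. The donor is *not* tracked:
  the tract's ancestry resolves outside the population, the tract is
  removed from backward-time material, and a divergence
  $d \sim \mathrm{Uniform}(D_1, D_2)$ is stored for sequence
  simulation.

Time is in units of $N_e$ generations; all rates are population-scaled.
The per-lineage factor of $1/2$ follows the $\rho/2$ convention of
standard coalescent simulators, and is pinned down operationally by a
test: in the rejection-sampling reference implementation, raw initiation
counts divided by $(R/2)\,G\,\times$ (total material-bearing lineage
time) must equal one.

### Effective events only

Most candidate conversions do not change the ancestry of the sample: a
tract that misses a lineage's material entirely, or that swallows it
whole, shifts nothing observable. An event is *effective* when the
tract bipartitions the material into two non-empty parts (for external
imports: when it touches material at all, since the donor is external).
`bacsim` samples only effective events. For a fixed start site $s$ the
effective tract lengths form one contiguous range $[a(s), L(s)]$, so

$$P(\text{effective} \mid s) \;=\; q^{\,a(s)-1} - q^{\,L(s)},
  \qquad q = 1 - 1/\delta ,$$

and the start sites fall into $O(k)$ categories over which these
weights have closed-form geometric sums: material-interior sites,
material-interval start sites, and runs of non-material sites at
distance $d$ before the next interval (on a linear genome the leading
gap, the first material site, and sites after the first material site
behave differently because tracts truncate at the right end and
material to the left of $s$ can never be captured). The total weight is
the effective rate (`effective_within_rate`), and sampling picks a
category by weight, a site within the category (uniform or truncated
geometric in $d$), and a length from the geometric law truncated to
$[a, L]$ (`sample_within_event`). Rate and sampler share one
decomposition, so they agree by construction; both are tested for exact
equality (rates) and distributional equality ($\chi^2$) against a
brute-force enumeration over all $(s, \ell)$, and the whole simulator
against an independently coded rejection sampler.

Tracts may start on gap or non-ancestral sites and reach material:
only the induced bipartition matters. This preserves the long-range
correlation structure along the replicon that per-locus approximations
lose.

### Pruning at local MRCAs

A site carried by a single lineage has found the most recent common
ancestor of all its sampled copies; any later event at that site would
shift every sample identically and be unobservable. `bacsim` maintains
a per-site carrier count (as a step function over the genome) and, when
a region's count reaches one, records the resolution node and removes
the region from all material. Without this pruning the effective-event
machinery alone cannot deliver the efficiency needed at high $R$ —
lineage material would never shrink and effective rates would stay
near $R G / 2$ for the whole history.

Clonal-frame lineages are exempt from removal: they persist with empty
material (zero recombination rates, still coalescing), so the complete
clonal genealogy is always produced and is distributed exactly as an
$n$-sample coalescent tree regardless of $R$ — a property the test
suite checks by comparing clonal TMRCA distributions at $R = 0$ and
$R = 0.05$.

## Sequence simulation

Substitutions follow Jukes–Cantor at rate $\theta/2$ per site per unit
time: per edge, per site, a Poisson number of substitutions, each to one
of the other three bases uniformly. Content is propagated tip-ward
through the graph: resolved regions take the root sequence at their
resolution node, recombination splits splice donor- and recipient-side
content, and import tracts receive the root homolog with each site
flipped to another base with probability $d$.

Design choices here, made where the behaviour was genuinely open:

* **One root sequence for all segments.** Every locally resolved region
  receives the same i.i.d.-uniform root sequence. Under JC stationarity
  this is marginally exact for every segment; only the correlation
  between root states of different segments (unobservable at
  stationarity) is not modelled.
* **$d$ is an observed-divergence probability, not a branch length.**
  "Adding an amount of divergence" is implemented as per-site mismatch
  probability $d$, keeping $D_1, D_2$ directly interpretable; the test
  suite verifies the realized mismatch fraction equals $d$. One $d$ is
  drawn per event (not per site).
* **Import edges in Newick.** The local-tree export grafts an
  import-terminated clade onto the root with branch length $2d/\theta$
  coalescent units — the length whose expected substitution load at
  rate $\theta/2$ is $d$ — tagged `[&import d=...]`. Internally the
  object keeps $d$ itself, and sequence simulation always uses $d$,
  never the converted length.
* **Imports leave backward-time material.** The tract's ancestry is
  resolved outside the population, so it is dropped from tracking; this
  is what attaches the clade to the root via a divergence edge and
  generates homoplasy. Retaining it would contradict the premise that
  the external donor is not tracked.

## Genome geometry

Coordinates are 0-based half-open; a circular tract wrapping the origin
is canonicalized into two intervals at construction, so no downstream
operation sees wrapped raw pairs. Fragmented assemblies are described
as `len:gap` pairs; gap sites are real coordinates that carry
initiation probability and may be spanned by tracts (keeping long-range
correlations intact across assembly gaps), but they are excluded from
material bookkeeping and produce no alignment columns. Whether real
conversion tracts span assembly gaps is not observable from a finished
assembly; spanning is the default here as the biologically conservative
choice for a single circular replicon split only by sequencing gaps.

## Numerical and implementation notes

* Geometric tails $q^k$ and $1 - q^k$ are computed through
  `log1p`/`expm1`, so means as large as $\delta = 10^9$ remain accurate
  (the $\delta \to \infty$ limit on a linear genome degenerates to
  crossover-like splits `[s, G)`, which the tests check structurally).
* The event loop keeps one RNG stream (R's, so `set.seed` gives
  byte-identical reruns), breaks floating-point time ties by generation
  order, and caps the event count (`max_events`, default $5\times10^6$)
  with an error naming the parameter set rather than hanging on
  runaway inputs.
* Per-lineage rates are recomputed only for lineages whose material
  changed; running totals are maintained incrementally and refreshed
  exactly every 2048 events to stop floating-point drift. The carrier
  count map is compacted after every decrement so it stays small.
* The hot loop and sequence propagation are C++ (Rcpp); the rejection
  oracle is deliberately plain R with a per-site carrier vector, sharing
  no code with the analytical path beyond the public interval algebra.

## What the simulator does and does not emulate

Simulated data reproduce: coalescent genealogies and their
gene-conversion distortions, clonal frames, geometric tract lengths,
external imports with tunable divergence (hence homoplasy), JC
substitution at stationarity, circular/linear topology and fragmented
assemblies. They do **not** include demography (growth, bottlenecks),
population structure or migration, selection, rate variation along the
genome, non-JC substitution models, indels, or distributive conjugal
transfer; a single replicon is assumed. Tests passing on these
simulations therefore validate the recombination and coalescent
machinery, not robustness of downstream methods to demographic or
mutational complications — for non-JC models, feed the exported local
genealogies to an external sequence simulator.

## Validation oracles and problem sizes

The test suite validates against three independent routes: brute-force
enumeration of $(s, \ell)$ laws on genomes up to a few hundred sites;
closed-form coalescent/Watterson expectations
($E[T_{\mathrm{MRCA}}] = 2(1 - 1/n)$,
$E[S] = \theta G \sum_{i<n} 1/i$) at $n = 10$, $G = 10^5$, 500
replicates; and the rejection sampler at $n = 5$, $G = 200$,
$R = 0.02$, $\delta = 10$, 5000 replicates (Kolmogorov–Smirnov,
$\alpha = 0.001$). Statistical tests use fixed seeds and stated
replicate counts throughout.

The clonal-frame recovery experiment measures Robinson–Foulds branch
accuracy of NJ/UPGMA/ML trees against the true clonal frame, overall
and stratified by the distance from the root to the branch midpoint
(old < 1.32, middle 1.32–2.09, young > 2.09 $N_e$ generations). The
in-package experiment runs at $G = 50$ kb, $n = 15$, $\theta = 0.01$,
$\delta = 500$, $R \in \{0, 0.1\}$ with 50 seed-paired replicates —
sizes chosen so the whole suite stays a routine desk run while the
qualitative contrasts (accuracy drops with $R$; old branches suffer
most) are decisively resolved. The full-scale version (1 Mbp, ML
inference, hours of runtime) ships as `inst/scripts/recovery_full.R`;
no external constraint fixes the experiment's sample size, so the
script exposes it as a `--samples` flag (default 15).

## Known limitations

Alignment memory is $O(nG)$ characters plus transient per-node buffers;
a 1 Mbp, $n = 1000$ run fits comfortably, but the per-segment local
*tree* extraction is R-level and intended for inspection and moderate
event counts, not for megabase genomes at $R = 0.1$ (the event list and
alignment remain fast there). The rejection oracle is for validation
regimes only. Divergence is capped at $D_2 \le 0.75$, the JC saturation
point, and distance-based inference refuses saturated alignments.
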