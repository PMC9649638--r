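---
title: "Methods: plasmid-encoded proteins in PPI network topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plasmid-encoded proteins in PPI network topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidPPI)
```

## The problem

Plasmids move genes between bacterial hosts, and the proteins those
genes encode must function inside the host's protein–protein
interaction (PPI) network. Two quantitative questions follow. First, do
plasmid-encoded and chromosomal proteins interact with each other at
the rate random mixing would predict, or does the network show
structure between the two groups? Second, how much of the network's
*indirect* connectivity — loops of interactions joining proteins that
do not interact directly — depends on the plasmid-encoded proteins, so
that losing a plasmid would reorganize the network rather than merely
trim its periphery?

`plasmidPPI` answers both for cohorts of per-sample networks in the
STRING combined-score dialect (undirected weighted edges, integer
scores 0–999).

## Classification model

A protein is **plasmid-encoded** when its cleaned gene name has been
observed on a plasmid originating in the *same species*; everything
else is chromosomal. Cleaning case-folds the name and rejects
locus-tag-like names ending in an underscore, dash or dot followed by
digits (`group_1`, `ybt.2`); rejected names are excluded both from the
short/long name-length profile and from catalog matching, since
numbered tags would otherwise create spurious cross-sample matches.
Matching is case-insensitive *exact* matching on cleaned names: fuzzy
name similarity is deliberately out of scope because it is not
reproducible without the original resolution choices. Proteins with no
usable name are chromosomal — plasmid assignment requires positive
evidence. "Short" names in the length profile are exactly four
characters (the canonical bacterial gene symbol shape, e.g. `sfmC`) and
"long" names five or more; one- to three-character names fall in
neither class.

Each edge is then `chromosomal_only`, `plasmid_chromosome` (exactly one
plasmid endpoint) or `plasmid_plasmid`; the three counts partition the
edge set, and an edge with at least one plasmid endpoint is
*plasmid-related*.

## Mixing statistic

With plasmid-protein frequency $p$ treated like an allele frequency,
random mixing predicts a fraction $\mathrm{exp} = 2p(1-p)$ of mixed
(plasmid–chromosome) edges. For the observed mixed fraction
$\mathrm{obs}$,

$$F = 1 - \mathrm{obs}/\mathrm{exp}$$

is 0 under random mixing, positive when the groups keep to themselves,
1 at complete separation, and negative under excess mixing. $F$ is
undefined (flagged, not an error) when either group is empty or the
network has no edges. Note the small-sample property: with $N$ proteins
the pairwise-exact null expectation is $2 n_p n_c / (N(N-1))$, slightly
above $2p(1-p) = 2 n_p n_c / N^2$, so the null distribution of $F$ sits
about $-1/(N-1)$ below zero. The null-centring simulation in the test
suite therefore uses $N = 200$ proteins and ~800 edges per replicate,
where this bias (~0.005) is well inside three standard errors of the
200-replicate mean (~0.011).

Per-group PPI rates count each qualifying edge once per group: the
plasmid rate is (plasmid–plasmid + plasmid–chromosome edges) / plasmid
proteins, and the chromosomal rate uses chromosomal-only edges. This
convention is forced by the published Serratia arithmetic the package
reproduces ((92 + 2214)/69 = 33.4, not the endpoint-doubled
alternative). Group rates are compared with Welch's two-sided t-test on
per-protein degree lists (the groups' variances differ strongly, so the
pooled test would be wrong more often than not), corrected across a
cohort with Benjamini–Hochberg. Samples qualify for testing with at
least 3 plasmid proteins and 10 plasmid-related PPIs by default; both
thresholds are configuration, not claims.

## Topology model

The **Vietoris–Rips 2-skeleton** of a PPI network is the graph plus a
filled triangle ("trio") for every three mutually interacting proteins.
Its Betti numbers are computed over GF(2):

* $b_0$: connected components (isolated proteins count one each);
* $b_1 = (E - V + b_0) - \operatorname{rank}_{GF(2)} \partial_2$, where
  $\partial_2$ is the edge-by-trio boundary matrix — the number of
  independent loops *not* filled by trios, i.e. indirect connections.

GF(2) is the natural field for loop counting; a rational-arithmetic
route (QR rank of the signed boundary matrix) is provided as a
cross-check and agrees on all fixtures and random graphs exercised —
the two can differ only through 2-torsion, which the clique complexes
seen here do not produce. The GF(2) elimination packs matrix rows into
31-bit words so whole rows XOR at once; the test suite checks it
against an independent, deliberately naive dense implementation. Trio
enumeration intersects endpoint neighbour sets per edge, counting each
trio once via vertex ordering.

Two degenerate-input conventions keep sweeps total: the loops-per-edge
ratio $b_1/E$ is defined as 0 when $E = 0$, and a network with no
proteins has $b_0 = 0$. When edges are filtered at a threshold,
proteins that lose all edges drop out of the filtered network (unless a
node manifest pins them), so sweep-level $b_0$ counts only components
with at least one surviving interaction.

## PMNLE and the threshold sweep

The loops-per-edge ratio varies with the score threshold, so a
single-threshold value is arbitrary. The **PMNLE** (persistent maximum
of non-trivial loops per edge) is the largest ratio *reached or
exceeded* across a contiguous threshold interval spanning at least 100
score units: over every window of consecutive thresholds whose span is
≥ 100, take the window's minimum ratio, then the maximum over windows.
A spike at one threshold never persists. "Interval of at least 100
score thresholds" is read as a span of 100 score units (the full-score
grid is every integer, so 100 thresholds = 100 units); on the
approximation grid of 400–900 step 20 (the **aPMNLE**, 26 thresholds)
this means at least 6 consecutive grid points. Window comparison uses ≥
throughout. Filtering is strict (`score > t`), matching the STRING
convention of "> 400".

## Robustness to plasmid loss

Each sample is swept twice: the full network, and the chromosomal-only
induced subnetwork (plasmid proteins and their edges removed). The
aPMNLE difference (full − chromosomal) measures how much indirect
connectivity the plasmid proteins carry. At cohort level, a sample is
flagged non-robust when its difference exceeds the cohort mean by more
than two cohort standard deviations; the exceedance is measured from
the mean so that a cohort of identical differences flags nobody, and
the comparison is strict. The SD is taken over unscaled differences by
default with the scaled variant (`(full − chrom)/full`) as a
configuration switch, since either reading of a cohort-SD rule is
defensible; the scaled delta is reported alongside regardless, defined
as 0 when the two aPMNLEs are equal and undefined when the full aPMNLE
is 0.

## Synthetic data: what it emulates, what it does not

The generator produces two-block random graphs with ground-truth
labels, the sample's plasmid-gene catalog derived from those labels
(genes chunked twelve per plasmid, the typical plasmid gene content),
and protein identifiers that double as gene names, so catalog-driven
classification recovers the truth exactly even after a file round
trip. Default scores are uniform on 401–999 (every edge survives the
default threshold); a decreasing-score alternative makes sweeps
informative. Attachment modes encode the two topological hypotheses:

* **peripheral** — each plasmid protein pendant on one chromosomal
  protein. Pendant vertices change neither the cycle space nor the
  component count, so this attachment is topology-neutral by
  construction: the robust condition.
* **disconnected** — plasmid proteins wired into their own components,
  chunked into 4-cycles (with a trailing triangle or edge), carrying
  scores 901–999 so the planted loops persist across the whole default
  sweep: the fragile condition.
* **mixed** — plain two-block model governed by the three block
  probabilities, used for the F-statistic simulations.

The default parameters emulate the cohort make-up the analysis assumes:
plasmid genes ~0.65% of proteins (10 of 1540 at defaults) and
plasmid-related PPIs a small minority. The simulation studies in the
tests and acceptance script run on deliberately smaller networks
(40–200 chromosomal proteins, sparse mean degree ≈ 1.4–8) so hundreds
of replicates stay cheap; at those sizes the plasmid-protein *fraction*
is necessarily far above 0.65%, which affects none of the recovery
properties being checked. What the generator does **not** emulate:
degree heterogeneity and hubs of real PPI networks, score dependence
between edges, annotation errors in gene names, or hub-attached plasmid
proteins with elevated PPI rates (per-sample rate tests on peripheral
cohorts legitimately find *lower* plasmid rates, since pendants have
degree 1). Passing recovery tests therefore show the estimators and
flags behave correctly under their own assumptions, not that real
cohorts satisfy those assumptions.

The fragile-recovery study (200 samples, 5% fragile, chromosomal blocks
of ~50 proteins at mean degree 1.4) was sized so the planted aPMNLE
displacement (~0.03–0.07) clearly exceeds the peripheral samples'
near-zero differences while the whole cohort sweeps in under a minute;
the binomial 3-SD acceptance band on the flagged fraction comes from
the planting rate itself.

## Numerical and degenerate-input choices

* Directed duplicate records in an edge list collapse keeping the
  **maximum** score (conservative inclusion; the count of dropped
  self-loops is logged).
* Unordered pairs canonicalize lexicographically; all outputs are
  sorted, so results are invariant to edge input order.
* Zero-edge samples report fractions of 0 with a `zero_edges` flag
  rather than dividing by zero; empty rate groups and undefined F
  values are flags, not errors.
* GF(2) pivoting always takes the first eligible row — fully
  deterministic.
* BH adjustment and component finding are delegated to `stats::p.adjust`
  and `igraph::components`; the boundary-matrix homology, PMNLE window
  statistic and F analog are implemented here.

## Known limitations

* Gene-name matching inherits annotation quality; the name-length
  profile quantifies, but cannot fix, uninformative naming.
* b2 and higher homology, full persistence barcodes, and 3-simplices
  are out of scope: the complex is two-dimensional by design.
* The dense boundary-matrix representation suits networks up to a few
  thousand edges per threshold; cohort-scale STRING networks with
  hundreds of thousands of edges per sample would need a sparse
  reduction backend.
* The cohort robustness rule is relative: it flags outliers within the
  analysed cohort, so the flagged fraction is only meaningful for
  cohorts of broadly comparable samples.
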