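---
title: "Methods: scoring, filtering and validating an RTK interactome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, filtering and validating an RTK interactome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(rtkscape)
```

## The problem

Receptor tyrosine kinases (RTKs) signal through physical interactions and
through tyrosine phosphorylation of substrates. A systematic study of the
family tags each receptor as a *bait*, purifies or proximity-labels its
partners (*preys*) in replicate mass-spectrometry runs, and must then answer
a chain of statistical questions:

1. Which bait–prey pairs are real, given noisy replicate spectral counts and
   GFP control runs? (scoring)
2. Which survivors are frequent contaminants rather than interactors?
   (filtering)
3. Is the resulting network enriched for independently known interactions
   beyond what its degree sequence forces? (validation)
4. Which preys co-purify across baits, indicating shared complexes?
   (co-association)
5. What functions, domains and complexes are over-represented among the
   interactors? (enrichment)
6. Which tyrosine sites does each kinase phosphorylate in vitro, and do the
   substrate repertoires mirror the receptor families? (phosphorylome)

`rtkscape` implements this chain as composable tidyverse-style functions
plus a one-call pipeline, and ships a synthetic-data module that generates
every input from a planted ground truth so each stage's error rates can be
measured without access to any external dataset.

## Interaction scoring

Spectral counts for a candidate pair are modelled with two Poisson
hypotheses. Under the background hypothesis, a prey's counts in a bait run
follow the rate estimated from the GFP control runs of the same method,
floored at a pseudo-rate (default 0.1) so preys absent from controls do not
produce a zero rate:

$$\lambda_0 = \max(\bar{x}_{\text{control}},\; \lambda_{\text{pseudo}}),
\qquad
\lambda_1 = \max(\bar{x}_{\text{bait}},\; \lambda_0).$$

The $\max$ in $\lambda_1$ makes the test one-sided: preys *depleted*
relative to controls are never evidence of interaction. The replicate log
likelihood ratio has the closed form
$\mathrm{llr} = \sum_i x_i \cdot \log(\lambda_1/\lambda_0) -
n(\lambda_1 - \lambda_0)$, and combines with a prior probability of
interaction (default 0.05: most identified pairs are not interactions) into
a posterior. Within each (bait, method, condition) group, pairs are ranked
by descending posterior and the Bayesian false discovery rate of the top
$k$ pairs is the cumulative mean of $1 - \text{posterior}$ — the convention
of spectral-count interaction scorers:

```{r}
bfdr_from_posterior(c(0.99, 0.90, 0.50))
```

A deliberately small worked example (two preys, one of which tracks the
control rate exactly, so its posterior equals the prior):

```{r}
counts <- tibble::tibble(
  bait = c(rep("RTK001", 4), rep(control_tag(), 2)),
  method = "APMS", condition = "WT",
  replicate = c(1L, 2L, 1L, 2L, 1L, 2L),
  prey = c("P1", "P1", "P2", "P2", "P2", "P2"),
  spectral_count = c(20, 30, 2, 0, 8, 12))
score_interactions(counts)
```

## The compound high-confidence filter

A scored pair is retained if and only if

* its BFDR is strictly below 0.05, **and**
* its prey is detected in strictly less than 20% of
  contaminant-repository experiments, **or** its average spectral count
  exceeds 3 times the repository average for that prey.

The second clause is the contaminant-frequency exception: genuinely
interacting chaperones and cytoskeletal proteins are frequent in negative
controls yet strongly over-recovered by their true baits. Boundary
semantics are strict and tested: BFDR exactly 0.05 is dropped, frequency
exactly 20% needs the rescue, fold change exactly 3 does not rescue.
Preys absent from the repository get frequency 0 and a pseudo-rate
denominator (0.1) for the fold change.

AP-MS and BioID are scored and filtered separately, then merged;
`detection` labels each pair `APMS_ONLY`, `BIOID_ONLY` or `BOTH`, which
partitions the interactome. The two methods are complementary by design —
stable complexes versus a ~10 nm labeling radius — so single-method pairs
dominate.

## The random-topology null

The observed count of interactions also present in a merged
known-interaction database is compared against random networks that keep
every bait's degree and redraw its preys uniformly without replacement from
the *pre-filter* identification universe (using the post-filter set would
smuggle the filter's enrichment into the null). For one bait with degree
$d_b$ drawn from a universe of $N$ proteins containing $K_b$ known partners
of that bait, the number of known pairs hit is exactly hypergeometric, so
iterations are drawn with `stats::rhyper()` per bait — distributionally
identical to permuting prey identities and fast enough for the default
100,000 iterations. The analytic mean $\sum_b d_b K_b / N$ is reported next
to the Monte-Carlo mean as a built-in self-check, and the empirical p-value
uses the add-one estimator $(r + 1)/(n + 1)$, which never returns an exact
zero.

## Prey–prey co-association

Preys that are subunits of one complex are pulled down together, so their
average-count profiles across the bait panel correlate. Profiles include
zeros (absence is informative), require at least 3 non-zero baits, and are
compared with the Pearson product-moment correlation; p-values use the
t-transform with $n - 2$ degrees of freedom and q-values are
Benjamini–Hochberg across all computed pairs. Edges need signed $r > 0.7$
at $q < 0.01$ — anti-correlation is never evidence of co-association.
Connected components with at least 3 members become clusters, and cluster
members are matched against curated complex definitions: a complex is
called at $\ge 60\%$ subunit coverage, with greedy overlap resolution so
the more complete of two overlapping candidates wins.

## Enrichment

One shared engine serves every annotation analysis: right-tail Fisher exact
(hypergeometric tail) p-values, fold change $(k/n)/(K/N)$, and
Benjamini–Hochberg within one collection. The background set is the
pre-filter identification universe, not the proteome, so enrichment
reflects the filter's selectivity rather than detectability. The BH routine
is implemented once, directly from the step-up definition, and is verified
in the test suite against `stats::p.adjust` on a thousand random vectors
(the hand-rolled version exists so the same routine provably serves both
the correlation and enrichment modules).

## Phosphorylome

In-vitro kinase assay sites are filtered on localization probability
(exactly 0.75 is kept; anything below is dropped) and against no-kinase
control runs, which remove heat-stable background phosphorylation
regardless of probability. Windows of ±7 residues are cut with `_` padding
at the termini:

```{r}
extract_window("MYSA", 2)
```

Motifs use a small grammar — `E-x-y-x-[LIV]` means glutamate at −2, any
residue at ±1, the acceptor tyrosine at 0 and an aliphatic residue at +2 —
and the matcher reports the fraction of *constrained* positions satisfied,
so motifs of different complexity are comparable; padding never satisfies a
constraint. Kinases are clustered by their binary site-incidence profiles
with Ward (D2) linkage on Jaccard distances (`dist(method = "binary")`),
and dendrograms can be exported as Newick and compared by cophenetic
correlation.

## The synthetic study generator

Every input is generated from a planted truth, with parameters defaulting
to the scale of a family-wide RTK study: 50 baits across 20 subfamilies,
a 2,000-protein prey universe, 30 true preys per bait, two replicates,
GFP controls, and both AP-MS and BioID strata with BioID-heavy stratum
probabilities.

Design choices that matter for realism:

* **Contaminants** draw a Bernoulli detection indicator times a
  zero-truncated Poisson count, and the simulated repository reports the
  detection fraction plus the mean count *where detected*
  ($\lambda/(1 - e^{-\lambda})$) — the quantity real contaminant
  repositories tabulate. This keeps the count model and the filter's
  fold-change denominator mutually consistent.
* **Subfamily sharing** attaches each subfamily's shared prey set in full
  to every member bait — a shared effector binds all family members — which
  is what makes bait profiles correlate and subfamily pool terms enrich.
  Cross-subfamily preys are drawn with Zipf (1/rank) popularity weights, so
  a few hub adaptors recur across many families.
* **One-hit wonders**: each bait run receives a handful of run-specific
  single-count identifications, giving the pre-filter universe the breadth
  (thousands of identified proteins per study) that makes the enrichment
  background meaningful.
* **Planted bait–bait edges** (receptor heterodimers, biased 3:1 toward
  same-subfamily partners) give the RTK–RTK subnetwork genuine signal.

Known limits: counts are Poisson (no overdispersion), contaminant rates are
shared rather than per-protein, substrate sequences are i.i.d. uniform
amino acids, and planted motifs have exactly two constrained positions.
These simplifications are intentional — they keep every stage's expected
behavior analytically checkable — but absolute simulated counts should not
be read as biology.

## A full run

```{r, eval = FALSE}
res <- run_rtk_pipeline(config = pipeline_config(rng_seed = 42))
res
#> <rtk_report> seed 42; stages: interactome, network, coassociation,
#>   enrichment, phospho
#>   scored pairs: 18998; HCIs: 1609 (APMS_ONLY 294, BIOID_ONLY 1213, BOTH 102)
#>   known HCI pairs: 781 observed vs null mean 13.71 (p = 1e-05);
#>   RTK-RTK edges: 74
#>   association edges: 122; clusters: 10; complex calls: 7
#>   enriched terms (q < 0.05): 21
#>   phospho: 1197 unique sites, 1106 kinase-substrate pairs,
#>   1197 site relations
```

The observed count of known interactions (781) sits about fifty-fold above
the null mean (13.7), which itself matches the analytic expectation to
Monte-Carlo precision — the planted biology is recovered, and the null
model is wired correctly. With `out_dir` set, each stage is exported as a
pipeline-dialect TSV plus a JSON run report that is byte-identical across
runs at the same seed.

## Numerical conventions

* All tabular I/O is TSV with `.` for missing values; list columns collapse
  with `;`. Protein identifiers are opaque, case-sensitive accessions.
* Undirected pairs are stored canonically (`a < b` lexicographically) so a
  pair is one row regardless of direction.
* Hypergeometric tails come from `stats::phyper(k - 1, ...,
  lower.tail = FALSE)`; the test suite compares this exhaustively against
  exact `lchoose` sums for every table with $N \le 60$.
* Every stochastic function takes an explicit integer seed, and
  `simulate_study()` derives sub-seeds below $2^{31}$ from one master seed,
  so whole studies are reproducible from a single integer.
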