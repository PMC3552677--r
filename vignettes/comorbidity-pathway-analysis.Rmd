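---
title: "Methods: dual-disease pathway crosstalk and candidate inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-disease pathway crosstalk and candidate inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comopath)
```

# The problem

When two complex diseases co-occur more often than chance — the motivating
pair is schizophrenia and type 2 diabetes — one standing hypothesis is
shared etiology: pleiotropic genes whose products act in biological
pathways relevant to both conditions. `comopath` operationalises that
hypothesis as three linked computations over two disease susceptibility
gene lists, a pathway annotation, and a protein–protein interaction (PPI)
network. This vignette documents the statistical model of each stage, the
tunable parameters, the synthetic benchmark, and the numerical and design
choices a maintainer should know about.

# Stage 1: two-cluster over-representation

## Model

Let $U$ be the background universe of annotated genes, $Q \subseteq U$
the *combined* query (the union of both disease lists intersected with
$U$), and $P \subseteq U$ a pathway. Under the null of no association,
the overlap $k = |P \cap Q|$ follows a hypergeometric distribution, and
the reported p-value is the inclusive upper tail

$$p = \Pr(X \ge k), \qquad X \sim \mathrm{Hypergeom}(N = |U|,\; K = |P|,\; n = |Q|).$$

Pathways with $k = 0$ are excluded *before* the testing family is
formed: they are untestable and would only dilute the
Benjamini–Hochberg (BH) step-up adjustment, which is applied across all
tested pathways of the merged (multi-database) collection in a single
family, because the analysis reports one adjusted p-value per pathway
regardless of which database contributed it. Significance means adjusted
$p < \alpha$.

One deliberate design choice: the test is run once per pathway on the
*combined* query, and the per-cluster counts are used only for the
specificity call below. The alternative — one test per cluster per
pathway — doubles the family and produces two adjusted p-values per
pathway, which does not match a single merged result table with one
adjusted p-value each.

## Specificity classification

For each significant pathway the mapped genes are partitioned into
$u_1$ (exclusive to cluster 1), $u_2$ (exclusive to cluster 2) and $c$
(on both lists), with total $t = u_1 + u_2 + c$ — an identity asserted
throughout the test suite. With cluster fractions
$f_i = (u_i + c) / t$, the pathway is labelled `CLUSTER1` iff
$f_1 > \tau$ and $f_2 \le \tau$ (symmetrically `CLUSTER2`), and `BOTH`
otherwise, i.e. when both or neither fraction clears the threshold.
Conventions fixed here:

* "over $\tau$" is implemented as *strictly greater*;
* genes common to both lists count toward *both* fractions — discarding
  them from either side would throw away exactly the genes most relevant
  to comorbidity.

No single counting convention reproduces every published label we are
aware of for this kind of merged table (tools that produce such tables
apply their own internal gene-to-term remapping before counting; a row
with counts (3, 2, 1) sits at $f_1 = 4/6 \approx 0.667$, a knife-edge
case). Rather than fitting a convention to any particular printed table,
$\tau$ and the common-gene rule are explicit parameters with the
documented defaults.

## Parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `alpha` | significance level on adjusted p | 0.05 | conventional FDR level |
| `tau` | specificity fraction threshold | 0.66 | the customary two-thirds rule for term-specificity in two-cluster enrichment tools |
| background | universe $U$ | union of all pathway members | the annotation's own gene space, the default of term-enrichment tools; a user-supplied background file overrides it |

# Stage 2: pathway crosstalk network

Crosstalk between two significant pathways is scored as Cohen's kappa of
their binary membership indicators over a gene domain $D$: with
$a = |A \cap B|$, $b = |A \setminus B|$, $c = |B \setminus A|$,
$d = |D| - a - b - c$ and $T = |D|$,

$$P_o = \frac{a + d}{T}, \qquad
  P_e = \frac{(a+b)(a+c) + (c+d)(b+d)}{T^2}, \qquad
  \kappa = \frac{P_o - P_e}{1 - P_e}.$$

An edge is drawn when $\kappa \ge \theta$ (default $\theta = 0.4$, the
customary connectivity default of kappa-based term networks). Choices:

* **Membership domain.** $D$ defaults to the mapped query genes (those
  appearing in at least one of the supplied pathways) rather than the
  full annotation universe. The overlay layer displays exactly those
  genes, and a term–term kappa computed on the query's membership matrix
  is the established practice; the full-universe alternative can be
  selected by passing `domain = collection$universe`. Note the
  full-universe domain inflates $d$ (joint absences) and with it
  $P_o$, so the two choices are *not* interchangeable.
* **Degenerate agreement.** When $P_e = 1$ both indicators are constant;
  $\kappa$ is then defined as 1 if the two sets are identical and 0
  otherwise (a continuity convention, covered by a dedicated test).
* **Overlay.** Every mapped query gene becomes a small node tagged by
  cluster origin (`1`, `2`, `both`) and linked to each of its
  significant pathways; `shared_gene_report()` tabulates the resulting
  membership degrees. Per-pathway cluster fractions are exported as
  numeric node attributes (`frac1`, `frac2`) for downstream rendering;
  the package draws nothing.

# Stage 3: interactome candidate inference

The PPI table is cleaned on ingestion — self-interactions removed,
duplicate unordered pairs collapsed (first occurrence wins, warned),
isolated nodes dropped — and the susceptibility proteins of both
diseases are mapped onto it; proteins absent from the interactome are
dropped with a logged count. The working network is the induced subgraph
over the mapped susceptibility proteins and their first neighbours, with
node classes `SUS1`, `SUS2`, `SUS_BOTH` (on both lists) and `NEIGHBOR`.

Guilt-by-association candidates are `NEIGHBOR` proteins with at least
`min_each` *distinct* susceptibility partners of each disease, where
`SUS_BOTH` partners count toward both diseases (any other convention
discards the shared proteins' information). Hubs are candidates with at
least $h$ partners per disease, boundary inclusive ($h = 5$ by default).
The candidate sub-network contains the candidates and their
susceptibility partners under induced-subgraph semantics — all parent
edges among retained nodes survive, including
susceptibility–susceptibility and candidate–candidate adjacencies —
because the neighbourhood structure among partners is part of what such
sub-networks are extracted to show.

`min_each` defaults to 1, the plain reading of "simultaneously
interacting with both diseases' proteins"; the stricter "more than one
of each" reading is `min_each = 2`. Both are exposed because the
published phrasing of this rule is genuinely ambiguous; the partner
census (`partner_census()`) reports the $\ge 1$ and $\ge 2$ strata for
each disease so either convention can be audited.

Determinism: candidate tables are sorted by $\min(d_1, d_2)$ descending,
then $d_1 + d_2$ descending, then symbol; enrichment tables by adjusted
p ascending with ties broken by pathway id. Both orders are asserted
invariant under permutation of input rows.

# The synthetic benchmark

`generate_synthetic()` emits the exact file formats the readers consume
(gene lists, GMT, PPI TSV) with planted truth, as a pure function of its
seed (same seed, byte-identical files). Its defaults *are* the study
conditions the package is tested under:

* two lists of 196 and 200 genes sharing 14 (382 unique), drawn from a
  2,000-gene universe of neutral zero-padded tokens (no real symbols, so
  fixtures can never be mistaken for biological claims);
* 10 cluster-1-specific, 11 cluster-2-specific and 7 shared enriched
  pathways plus 30 nulls, each of size 20; planted pathways draw
  `round(20 × 0.75) = 15` members from their target cluster and the
  rest uniformly from the remaining universe; null pathways draw
  uniformly. Shared pathways draw their planted block *balanced* across
  the two exclusive lists plus one common gene rather than uniformly
  from the union: a uniform draw of 15 from ~382 genes crosses the
  $\tau = 0.66$ line by chance in roughly one run in seven, which would
  turn exact planted-truth tests into statistical ones. One common
  "marker" gene is additionally planted into 12 enriched pathways to
  exercise the overlay layer's high-membership tail;
* a PPI with 20 planted candidates wired to *exact* (deg1, deg2) partner
  counts — 9 of them hubs with both degrees ≥ 5, up to (7, 13) — partners
  sampled without replacement from the exclusive lists only; decoy
  proteins (200) may touch susceptibility proteins of at most one
  disease (and never a shared protein, a single edge to which would
  satisfy the dual rule), plus Erdős–Rényi decoy–decoy edges
  ($p = 0.01$) and 100 random susceptibility–susceptibility edges.
  Exact wiring makes recovery tests exact rather than statistical; the
  background topology is nuisance structure and an Erdős–Rényi layer
  suffices for it.

`recount_truth()` re-reads the emitted files through the package's own
readers and recounts every planted quantity against the stored truth.

What the generator does **not** emulate: realistic interactome topology
(degree distributions, clustering), annotation redundancy between
databases, symbol aliasing, or noise in the gene lists themselves. A
passing suite therefore demonstrates algorithmic correctness on planted
structure, not robustness to the false-positive-prone gene lists and
incomplete annotations of real studies — both of which propagate
directly into any real analysis run with this (or any equivalent)
pipeline.

# Test design and problem sizes

The statistical primitives are checked against independent oracles: the
hypergeometric tail against exhaustive enumeration of all
$(k, K, n, N)$ with $N \le 12$ at tolerance $10^{-12}$; BH against a
hand-written sort-and-cummin step-up on 1,000 random vectors of lengths
1–50; kappa against an independent chance-corrected-agreement
implementation on all $16 \times 16$ subset pairs of a 4-element domain.
Planted recovery is measured over 200 seeded generator runs at the
default conditions (with a 50-seed cohort in the acceptance script):
cluster-specific pathways must be significant and correctly labelled in
at least 95% of cases, null pathways significant in at most 10%, and
candidate/hub recovery exact in every run. These sizes keep the full
suite around half a minute while the enumeration spaces stay exhaustive
where exhaustiveness is the point.

# Known limitations

* Symbol normalisation is uppercase-and-trim only; no alias mapping.
  Lists and annotations using different symbol vocabularies will
  silently under-overlap — inspect the logged unmapped counts.
* The universe default (union of pathway members) makes significance
  depend on the loaded annotation; supply an explicit background for
  cross-annotation comparability.
* Kappa is computed pairwise; no seeding/agglomeration heuristics of
  term-clustering tools are applied.
* The PPI is treated as a static, unweighted, undirected graph;
  interaction confidence, direction and context-specificity are out of
  scope.
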