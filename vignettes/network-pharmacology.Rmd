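---
title: "Methods: network-pharmacology screening with netpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-pharmacology screening with netpharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The screening model

Network pharmacology triages the constituents of a complex natural product
before any wet-lab work: it asks which isolated compounds are plausible oral
drugs, which of their predicted protein targets are also implicated in the
disease, which of those sit at topologically central positions of the
interactome, and which biological pathways tie the whole set together.
`netpharm` implements that cascade as five pure functions of tabular inputs,
so that every stage is reproducible from files on disk and auditable through a
manifest.

### Drug-likeness: QED

The quantitative estimate of drug-likeness maps eight physicochemical
descriptors — molecular weight (Da), Crippen logP, hydrogen-bond acceptor and
donor counts, topological polar surface area (Å²), rotatable bonds, aromatic
rings and structural alerts — through desirability functions and aggregates
them as a weighted geometric mean:

$$\mathrm{QED} = \exp\!\left(\frac{\sum_i w_i \ln d_i(x_i)}{\sum_i w_i}\right),
\qquad
d(x) = \frac{1}{d_{\max}}\left[a + \frac{b}{1 + e^{-(x - c + d/2)/e}}
\left(1 - \frac{1}{1 + e^{-(x - c - d/2)/f}}\right)\right].$$

Each desirability is a normalised asymmetric double sigmoid: it rises to 1 in
the descriptor's drug-like range and decays to plateaus on both sides, so a
single extreme descriptor drags the geometric mean down without zeroing it.
The published coefficient tables (including each curve's normalisation maximum
and the three published weighting schemes) ship in the package source;
`qed_score()` defaults to the mean-weight scheme, with `"unweighted"` (plain
geometric mean) and `"max"` selectable. Which weighting variant a given
upstream descriptor service used is generally not recoverable, which is why
both are first-class modes rather than a guess; the weighted/unweighted choice
shifts scores by a few hundredths and rarely flips a verdict at the 0.3
cutoff. The implementation is checked against an independent reference
implementation (RDKit's) on ten standard drugs to 1e-6.

Oral bioavailability uses Veber's rule: rotatable bonds ≤ 10 **and**
TPSA ≤ 140 Å². Compounds with QED ≥ 0.3 and a Veber pass are flagged as
expected active compounds (EAC). All cutoffs are inclusive — a compound at
exactly QED 0.3, ROTB 10 or TPSA 140 passes — and `select_eac()` is idempotent
and monotone in the cutoff.

Descriptors are taken from the input table as supplied; the package does not
compute them from structures. That keeps the stage deterministic and
independent of any cheminformatics engine, at the cost of trusting the
upstream descriptor source.

### Target sets

Gene identity is the uppercase, whitespace-trimmed symbol string; no alias or
identifier mapping is attempted, and case variants of one symbol collapse on
ingest. This is deliberate: alias resolution requires a versioned mapping
resource and silently changes set sizes; a documented string identity is
reproducible. The optional `score` column of the compound–target map can be
thresholded (`score_min`, default 0 = keep all) as a configurable stand-in for
upstream "false-positive" filtering, whose exact upstream definition is not
recoverable. An empty intersection warns rather than errors — it is a valid
scientific outcome.

### PPI topology

The interaction graph is undirected and simple: self-loops are dropped and
reversed duplicates collapsed. When restricted to a query set, members without
any surviving interaction are retained as isolated nodes, as database
subnetwork exports do. Centralities follow the conventions of Cytoscape's
NetworkAnalyzer, since screening thresholds of 0.01 (betweenness) and 0.5
(closeness) are only meaningful on those normalised scales:

* degree — neighbour count;
* betweenness — Brandes' algorithm, divided by $(n-1)(n-2)/2$ with $n$ the
  **full** graph's node count, isolated nodes included;
* closeness — component-local: $(s-1)/\sum_u d(v,u)$ over the $s$ members of
  the node's connected component; isolated nodes get 0. A
  `"wasserman-faust"` option rescales by component coverage $(s-1)/(n-1)$ for
  users who want the global convention.

Key targets are the nodes meeting all three inclusive thresholds
(defaults 4 / 0.01 / 0.5). Induced subgraphs always recompute centralities:
betweenness and closeness are not restriction-invariant. Degree, betweenness
and closeness are validated against an exhaustive shortest-path enumeration
oracle on every non-isomorphic graph with up to 7 nodes plus random 8-node
graphs.

### Over-representation

For a query of effective size $n$ (query genes present in the universe)
against a term with $K$ members in a universe of $N$, the raw p-value is the
hypergeometric upper tail $P(X \ge k)$, or DAVID's conservative EASE variant
$P(X \ge \max(k-1, 0))$, under which single-gene overlaps can never be
significant. EASE is the default because the screening convention this
package follows used DAVID. The universe defaults to all genes appearing in
the annotation collection (an annotation-based background), overridable.
Benjamini–Hochberg adjustment is applied over all overlapping terms before
truncation. Ranking is fully specified — ascending p, then descending overlap,
then term id — so the top-20 table is byte-stable. Gene ratio is $k/n$.

### The integrated C-T-P network

The tripartite network joins EAC to key targets via the compound–target map
and key targets to pathways via the enrichment rows' overlap genes (not full
pathway membership — the network stays consistent with what the enrichment
stage actually found). Compounds and pathways never connect directly, and
isolated compounds/pathways are kept and flagged so the EAC roster is
preserved in reports. Whether compound–target edges should include non-key
targets is genuinely open; the default restricts to key targets (that is what
"merging EAC, key targets and pathways" means), and `restrict_to_key = FALSE`
widens. Node degree is incident-edge count; the handshake identity
$\sum \deg = 2|E|$ is asserted after every build.

## The synthetic-data generator

Real inputs to this kind of screen come from live web databases and are not
reproducible offline, so `simulate_study()` generates all five inputs with
*planted, provable* structure:

* **Compounds** (default 43, of which `round(frac_druglike * n) = 28`
  drug-like): descriptors are sampled stratified by the intended verdict —
  drug-like draws from MW 250–450 Da, ALOGP 1–3.5, HBA 2–6, HBD 0–3,
  TPSA 40–120 Å², ROTB 0–8, AROM 1–3, ALERTS 0; non-drug-like draws violate
  Veber (ROTB 11–20 or TPSA 141–200) or carry a bulky high-alert profile with
  QED < 0.3. Each compound's computed verdict is verified and resampled
  (bounded) on mismatch, so the planted EAC set is recovered exactly for every
  seed. Stratification, rather than rejection sampling from marginals, makes
  the pass fraction exactly controllable and exercises the decision boundary
  from both sides.
* **Target layers**: a 447-gene predicted pool inside a 3000-gene universe;
  per-compound targets drawn at rate 0.05 with coverage topped up through the
  drug-like compounds so the EAC target union equals the pool; the 265-gene
  disease set takes exactly 24 genes from the pool and the rest from outside
  it. The intersection stage therefore provably returns the planted 24 genes
  and Venn counts (423, 241, 24).
* **Interactome**: 9 of the 24 potential targets form a clique-like core
  (pairwise edge probability 0.95); each non-hub is pinned to one home hub,
  and further background edges appear at probability 0.02. Because the three
  centrality thresholds are global properties no local rule can guarantee,
  the generator verifies post hoc that exactly the hubs pass the key-target
  filter and resamples up to 50 times, erroring with the achieved margins if
  separation fails.
* **Annotations**: 66 terms over a pool of 600 background genes plus the key
  genes; one planted term contains ⌈0.8 × |key|⌉ key genes, the rest sample
  members at rate 0.05, so chance overlaps occur at a realistic rate and the
  planted term ranks first with high probability.

Randomness is one master seed split into fixed-order sub-streams (compounds,
target layers, interactome, annotations), so adding a downstream generator
never perturbs an earlier stream, and identical configs give byte-identical
files.

Default sizes mirror a single-herb screen (43 isolates, 447 predicted
targets, 265 disease genes, 24-node interactome, 66 pathways). What the
generator does **not** emulate: real chemical structures, correlated
descriptors (real MW and TPSA co-vary), scale-free interactome degree
distributions, hierarchical GO-style annotation redundancy, and gene-symbol
aliasing. Passing the recovery tests therefore demonstrates the pipeline's
correctness and determinism on data with known truth — not that any particular
real herb screen would reproduce, which depends on database snapshots.

## Numerical and design choices

* **Adduct m/z.** Monoisotopic atomic masses (C, H, N, O, S, P, halogens) are
  hard-coded at ≥ 6 decimals; ion m/z is the adduct-adjusted monoisotopic
  mass divided by |charge| with **no electron-mass correction** — the
  convention under which standard published "calcd" values at 4 decimals are
  reproduced; `electron_mass = TRUE` applies the ≈ 0.00055 Da/charge
  correction for the other convention. The composite formate-adduct-minus-
  water ion is one adduct with net delta +C −H +O at charge −1, because the
  two steps are always reported jointly for a single observed ion; whether
  such an observed ion is truly formate-minus-water or another species is an
  upstream ambiguity the calculator does not resolve. Presentation rounding is
  R's round-half-even at 4 decimals, matching standard MS reporting.
* **Desirability normalisation** uses the published curve maxima; for custom
  coefficient sets without a supplied maximum it is found numerically
  (`optimize`, tolerance 1e-10, wide bracket around the curve centre).
  Degenerate sigmoids (e or f = 0) are rejected.
* **Hypergeometric tails** go through `stats::phyper` (log-space stable);
  BH through `stats::p.adjust`. Both are verified against exhaustive subset
  enumeration for all parameter tuples with N ≤ 12 at 1e-12.
* **Ties and determinism.** Every ranked output has a total order (enrichment:
  p, overlap, term id; degree tables: layer, degree, name), GraphML exports
  are byte-stable, and the pipeline manifest records MD5 checksums of inputs
  and outputs so reruns are provably identical.
* **Degenerate inputs.** Empty compound tables, empty intersections, empty key
  sets and edgeless graphs flow through with empty (not error) results, except
  where a stage cannot be meaningfully computed (query disjoint from the
  annotation universe), which errors with advice.

## Problem sizes in the test suite

The suite validates centralities on all 1252 atlas graphs (≤ 7 nodes) plus
300 random connected 8-node graphs; hypergeometric/EASE on every tuple with
N ≤ 12; QED on ten reference drugs; and end-to-end planted-structure recovery
on 100 generator seeds at the default study scale, requiring precision =
recall = 1 in at least 95 of them. These sizes keep each property exhaustively
or statistically convincing while the whole suite runs in about two minutes.

## Limitations

* Descriptor values are trusted as supplied; no structure-based computation
  or sanity cross-check against SMILES is performed.
* Symbol-string gene identity will treat aliases as distinct genes.
* The enrichment universe default (all annotated genes) matters: counts of
  significant terms are not comparable across annotation collections of
  different coverage.
* Centrality conventions other than the two implemented (component-local,
  Wasserman–Faust) are out of scope, as are weighted or directed networks.
* The generator's planted structures are much cleaner than live-database
  outputs; absolute counts from real screens (numbers of enriched terms,
  edges in a STRING export) depend on database versions and confidence
  thresholds and cannot be reproduced offline.
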