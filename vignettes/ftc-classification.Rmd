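---
title: "Building a functional therapeutic chemical classification"
author: "ftcbuild"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a functional therapeutic chemical classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftcbuild)
```

## The problem

Curated drug classifications such as the ATC record the sanctioned,
well-known actions of approved compounds. For drug repositioning one wants
the opposite emphasis: a systematic, over-complete catalogue of everything a
compound *can* do, derived automatically from molecular evidence. `ftcbuild`
constructs such a catalogue — a Functional Therapeutic Chemical (FTC)
classification — from three public-style inputs: a GO-style ontology (OBO),
protein-to-term annotations (GAF 2.x) and a drug-target table with
pharmacological action terms.

## The model and its assumptions

**Categories.** Every non-obsolete biological-process or molecular-function
term that does not itself carry a `regulates`-family edge anchors exactly two
mode-of-action categories, "Pro-*X* agent" and "Anti-*X* agent". Regulation
terms ("positive regulation of *X*") are *folded*, not reified: no
"Anti-positive-regulation-of-X agent" class exists. Their content reaches the
base term through the sign algebra below. This matches the intended reading
of the worked coagulation example, where an inhibitor of a positive
coagulation regulator lands in "Anti-blood coagulation agent" itself.

**The regulator pattern.** A perturbation link carries a sign
*p* ∈ {+1, −1} obtained from a versioned action vocabulary
(`default_action_signs()`): inhibitor-like actions are −1, agonist-like +1,
everything else "unknown". An annotated term resolves to regulation forms
(*B*, *r*) by `classify_regulation()`: *r* = +1/−1 for signed regulation,
*r* = 0 for neutral `regulates`, or a direct form when the term has no
regulation edges. Membership polarity is the product *p* · *r* (or *p* for
direct forms). The polarity set {+1, −1} is closed under this product — an
inhibitor of a negative regulator is a *pro* agent.

Three simplifying assumptions are inherited deliberately from the underlying
modelling idea and are worth keeping in mind:

* membership is boolean — no binding-affinity or dosage weighting;
* a drug that perturbs a protein is assumed to perturb *all* of the
  protein's annotated functions;
* unknown actions ("binder") and neutral regulation contribute nothing
  rather than erroring, because source action vocabularies are open.

**Taxonomy.** Categories inherit the term hierarchy per polarity:
Pro-*X* ⊂ Pro-*Y* exactly when *X* reaches *Y* through the configured
propagation relations (default `is_a` + `part_of`; `regulates` edges never
produce subclass edges), with the edge set reduced transitively. Four
synthetic roots (pro/anti × process/function) close the DAG at the top; a
subclass edge never mixes polarities. Indirect memberships are the ancestor
closure of direct ones.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `regulation_chain_depth` | 2 | maximum length of composed regulation chains; "positive regulation of negative regulation of X" resolves at depth 2, deeper chains are inert |
| `propagation_relations` | `is_a`, `part_of` | hierarchy relations lifted into the taxonomy |
| `include_namespaces` | BP, MF | ontology namespaces eligible for categories (no cellular-component categories) |
| `exclude_evidence` | none | GAF evidence codes to drop at parse time (e.g. `IEA`); all evidence is kept by default |
| `include_roots` (similarity) | `FALSE` | roots are shared by almost every drug and only compress the similarity range |
| `n_perm` | 20000 | permutations for the within-class test |

The depth-2 default reflects that one level of regulation is the common case
in practice and two levels close the obvious "regulation of regulation"
compositions; arbitrarily deep composition would mostly manufacture
low-confidence memberships.

## Reasoning implementation and its oracle

The category definitions instantiate one fixed axiom pattern, so a general
OWL reasoner is unnecessary: `classify()` enumerates link × annotation ×
regulation-form combinations directly. Because a bespoke engine is easy to
get subtly wrong, the package ships `brute_force_oracle()`, a deliberately
naive re-implementation (per-pair path search, hand-rolled reachability, no
shared traversal code) that the test suite keeps set-identical to
`classify()` over a hundred seeded random knowledge bases.

## Similarity and significance

A drug's MoA profile is its direct-plus-indirect category set (roots
excluded by default). Drug-drug similarity is the plain Jaccard index of
profiles: 1 exactly for identical profiles, 0 for disjoint ones. Note one
sharpening: two drugs sharing *a* category have similarity 1 only when their
*whole* profiles coincide; plain Jaccard is the simplest formula consistent
with the required range and identity case, and is fixed here as the
package's definition.

The within-ATC-class test asks whether drugs sharing a therapeutic class
(ATC code prefix at a chosen level) have a higher mean pairwise MoA
similarity than random drug groupings. The null is generated by shuffling
the drug-to-label assignment, which preserves the similarity-matrix
structure and the class sizes and rests on a standard exchangeability
argument — "permuting the similarity values" themselves would destroy the
matrix's internal consistency. The one-sided p-value uses the add-one
estimator (1 + #{null ≥ observed}) / (1 + n_perm), so a finite permutation
count never reports p = 0. Drugs labelled `multiple` or `NoCategory` are
excluded from testing, classes with fewer than two drugs are skipped, and
drugs are sorted into canonical order before permuting so results are
independent of input ordering.

## Evaluation against ATC

Curated evaluation points (one FTC category ↔ one or more ATC prefixes) are
scored over the universe of drugs present in both classifications; drugs
without any ATC code are repositioning hypotheses, not false positives, and
are excluded. Matching is by code prefix, since ATC levels are prefixes by
construction. Per-point TP/FP/FN counts are summed across points (a drug in
two overlapping points is counted once per point; the distinct-drug coverage
is reported separately), and precision/recall follow with zero-denominator
cases defined as 0.

## What the synthetic generator emulates — and what it does not

`generate_random_kb()` builds a rank-layered DAG (terms only point to
earlier terms of the same namespace, so acyclicity and namespace coherence
hold by construction), attaches regulation terms with signed edges (chains
at most two deep, matching the default composition depth), annotates
proteins, links drugs with signed actions, and emits the exact file formats
the parsers read. Ground truth is derived *constructively* from the planted
chains by generator-local code, so the classifier is falsifiable rather than
self-confirming. With planted clusters, drugs in a cluster share their whole
signed link set (plus an inert binder link) and an ATC letter, giving
within-cluster similarity exactly 1 — the "strong overlap" regime — and one
matching evaluation point per cluster.

The generator does **not** emulate real GO topology statistics (fan-out,
depth distribution, term reuse), realistic DrugBank action-term frequencies,
or annotation sparsity. Passing tests therefore demonstrate correctness of
the algebra, closure and statistics on structurally faithful toy inputs, not
performance characteristics on a full GO/DrugBank-scale build. Full-scale
headline counts from historical data releases (tens of thousands of
categories, four-digit drug counts) require those releases as inputs and are
out of scope; the suite replaces them with fixture-level recounts of the
same metrics.

## Numerical and degenerate-input choices

* Parsing is canonicalising: terms, edges, annotations and links are
  deduplicated and sorted, so shuffled input rows give identical structures
  and identical downstream output.
* A cycle in the `is_a`/`part_of` subgraph is a hard validation error
  naming a cycle member; `regulates` edges may close cycles freely (they are
  not hierarchy).
* Obsolete terms are recorded but edge-less and category-less; annotations
  to them are dropped with a count.
* Two empty MoA profiles have undefined similarity: `NA` with a warning,
  excluded from matrices (which only cover drugs with ≥ 1 membership).
* The permutation test runs per-class means over one shared shuffle per
  iteration; ties count as "≥ observed", making p conservative under heavy
  discreteness.
* Problem sizes used in the shipped test-suite simulations — knowledge
  bases of ≤ 40 terms and ≤ 12 drugs, 100 seeds for oracle equivalence, 200
  replicates × 1000 permutations for calibration — were chosen as the
  smallest sizes at which every structural regime (multi-parent DAGs,
  two-step chains, clusters, inert links) occurs routinely.

## Known limitations

* The id scheme keeps only the numeric part of a term id, so anchors from
  ontologies with colliding numeric ids would collide; `generate_categories()`
  detects and rejects this.
* Membership inference treats every annotation as positive involvement;
  qualifier semantics beyond `NOT`-exclusion (e.g. `contributes_to`) are not
  modelled.
* The evaluation depends entirely on the curated points supplied; the
  package scores them but cannot validate their curation.
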