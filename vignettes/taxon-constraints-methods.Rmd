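---
title: "Deriving and applying taxon-based GO constraints"
author: "gotaxcon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and applying taxon-based GO constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gotaxcon)
```

## The problem

Gene Ontology (GO) annotations are species-agnostic, but many functions
are not: a trypanosome has no chloroplast, a bacterium no nucleus.
When automatic function-prediction tools transfer annotations across
species purely by sequence similarity, terms leak into organisms that
cannot perform them, and such errors percolate through databases. A
*taxon constraint* makes the biology explicit: `never_in(taxon, term)`
forbids a GO term (and all of its GO descendants) for every species in
a taxonomic clade, while `only_in(taxon, term)` restricts a term to one
clade. The Gene Ontology Consortium curates such constraints by hand,
but coverage of ~40&nbsp;000 terms across hundreds of thousands of
species is necessarily sparse. This package derives constraints
automatically from the annotation corpus itself, merges them with the
consortium's axioms and with user-curated overrides, audits annotation
databases against them, and measures their effect on predictions with
the CAFA species-centric metrics.

## The derivation rule

The automatic derivation works per *reference taxonomic node* — a
taxonomy node chosen to pool the annotations of all organisms beneath
it:

1. **Corpus cleaning.** GAF records are dropped when they carry the
   `ND` (no data) evidence code, a `NOT` qualifier, a namespace-root
   term (GO:0008150, GO:0003674, GO:0005575), an `RNAcentral` source,
   an "environmental samples" lineage, an obsolete/unknown term, or an
   unresolvable taxon. Each record is counted once, under the first
   matching rule, and the report reconciles exactly
   (`total_in = total_out + sum of reasons`). All other evidence codes,
   IEA included, are kept deliberately — electronic annotations are the
   bulk of the corpus and the only route to broad taxonomic coverage.
2. **Cumulative frequencies.** For a scope (the whole corpus, or one
   reference node's subtree) the *cumulative frequency* of a term is
   the number of annotations to the term or any of its GO descendants,
   counted once per annotation even through diamond-shaped regions of
   the DAG. Propagation runs over `is_a` and `part_of` (the standard
   annotation-propagation pair; the relation set is a configuration
   switch, and regulates-family edges are parsed but never propagated).
3. **The never_in rule.** A term is marked `never_in` for a reference
   node when its corpus-wide cumulative frequency is at least the
   threshold (default **500**) *and* its cumulative frequency inside
   the reference node is exactly **zero**. The threshold keeps the
   derivation away from rare, model-organism-specific terms for which
   absence elsewhere is no evidence; the zero rule means a single
   annotation anywhere in the clade vetoes the constraint. The
   threshold is checked before the zero test, so reporting reflects
   corpus-wide eligibility first.
4. **Compact storage, closed expansion.** Output is pruned to the
   GO-topmost qualifying terms; `expand_constraints()` restores the
   full prohibited set on demand by closing over GO descendants and
   inheriting records down the taxonomy.

### Reference nodes

Reference nodes can be supplied as a published list
(`load_reference_nodes()`) or selected automatically
(`select_reference_nodes()`): a node qualifies when its subtree
accumulates at least `min_annotations_unreliable` annotations
(default 1000) from at least `min_species` distinct taxa (default 5),
and is labelled *reliable* above `min_annotations_reliable`
(default 50000), *unreliable* otherwise. The labels are provenance
only — both classes generate constraints with the same rules. Nothing
below species rank is eligible. These thresholds are declared package
defaults for a selection heuristic whose published counterpart is not
specified to this level of detail; on real corpora they should be
tuned, or a curated list supplied instead.

When reference nodes nest, the frequency table of a node is computed
over its **whole subtree**, so annotations of organisms claimed by a
deeper reference node still count for every ancestor reference node.
This guarantees the central soundness property — a term annotated to
any species inside a clade is never emitted `never_in` for that clade —
which a strict closest-node partition would violate (the deeper node
would starve its ancestor's counts, and an ancestor with an empty bin
would prohibit entire namespaces for organisms that are demonstrably
annotated). The closest-node partition (`group_by_reference()`)
remains the unit of per-organism bookkeeping and discard reporting.

A corollary of the zero rule worth knowing: a reference clade with *no*
cleaned annotations at all in one namespace receives `never_in` on that
namespace's root (the root's corpus-wide count always clears the
threshold). The compact output then carries a single root record. This
is the rule's honest verdict under total absence of evidence; supplying
a better reference-node list, or a manual `allow`, overrides it.

## Priority merging

Three sources are merged under strict priority
**manual &gt; consortium &gt; automatic**:

* consortium `only_in(g, T)` converts to `never_in` everywhere outside
  `subtree(T)` — compactly, one subtree record per off-path sibling
  branch along the root-to-`T` path plus a node-scoped record on each
  strict ancestor (ancestors of `T` are themselves outside the clade).
  `only_in` on the taxonomy root therefore prohibits nothing.
  Several `only_in` records on the same term pool their clades: the
  allowed region is the union of subtrees.
* the manual tier adds an `allow` directive beyond `never_in`/`only_in`
  so users can cancel a bad lower-tier constraint for a clade; this is
  the minimal mechanism for the manual tier's purpose of fixing
  observed annotation issues.
* resolution is evaluated per (taxon, term) after closure, tier by
  tier: within a tier, permissions are applied before prohibitions, so
  a `never_in` beats an `only_in` of the same tier (consortium-internal
  collisions resolve `never_in`-wins, with a warning), while any higher
  tier overrides everything below. Contradictory manual directives on
  an identical (taxon, term) pair are a hard error. The merge attaches
  a conflict report listing every overridden record.

The test suite pins these semantics to an independent sequential
overwrite oracle: apply the automatic tier on the fully expanded
(taxon × term) verdict matrix, overwrite with the consortium tier,
overwrite with the manual tier.

## Evaluation metrics

The species-centric benchmark pools all predicted terms of one species
into a single non-redundant set; a term's score is the **maximum**
score any protein of that species obtained for it. Predictions and
ground truth are ancestor-closed before scoring (the usual CAFA
consistency convention, exposed as a flag), and namespace roots are
excluded. Per subontology, a descending threshold sweep over the
distinct predicted scores (thinned to at most 101 points; ties are
evaluated at the score value itself) yields:

* precision `|P∩T|/|P|` (thresholds with empty `P` are skipped, not
  scored as zero), recall `|P∩T|/|T|`, and
  `F_max = max 2·pr·rc/(pr+rc)`;
* weighted variants with set sizes replaced by information-content
  sums, giving `wF_max`;
* remaining uncertainty `ru = Σ ic(T\P)`, misinformation
  `mi = Σ ic(P\T)`, and `S_min = min √(ru² + mi²)`.

Information content is computed from the same cleaned corpus used for
the constraints: `ic(g) = −log2((c(g)+1)/(c(root)+1))` with cumulative
counts `c`, +1 smoothing so unannotated terms stay finite, and base-2
logarithm (bits). Base-2 versus natural log only rescales `wF_max`
inputs uniformly and `S_min` monotonically; it is a configuration-level
choice, not a result-level one.

## The synthetic-data generators

`fixture_spec()` / `make_fixture_bundle()` generate, from one seed, a
three-namespace ontology (random DAG with a controllable diamond
fraction, obsolete terms, alt_ids, embedded consortium axiom lines), a
taxdump-dialect taxonomy (with designated reference nodes, an
"environmental samples" clade and merged-id redirects), and a GAF 2.2
corpus spiked with every category of dirty line the cleaning step must
remove. Defaults — 22 taxonomy nodes, 42 terms, 700 annotation lines, a
derivation threshold of 50, two planted exclusion patterns — are sized
so that a handful of terms clear the threshold and planted absences
become constraints; they emulate the *structure* of a real corpus
(skewed term usage, nested clades, noise categories), not its
statistics (no realistic annotation-depth or species-abundance
distributions). Passing tests therefore demonstrate the correctness of
the rules, not calibrated performance on a production corpus; the
corpus-scale threshold of 500 remains the pipeline default.

The generator writes real files so parser paths are exercised, and
computes its manifest — which (reference node, term) pairs must and
must not be emitted — with its own naive recursive traversals, nested
loops, and rule mirror, independent of the pipeline's memoised
machinery. The headline acceptance property re-derives constraints on
100 seeded bundles and requires exact agreement with these manifests.

## Numerical and degenerate-input choices

* All traversals are iterative BFS with memoised closures; results are
  sorted so outputs are deterministic regardless of input order.
* Merged taxon ids are redirected at every entry point; deleted ids are
  unknown. Multi-organism GAF taxon fields keep the first taxon (the
  annotated gene product's organism). alt_ids resolve at load time.
* Annotations to obsolete or unknown terms are removed during cleaning
  (they would corrupt frequency counts); the frequency engine treats
  their reappearance as a defensive error.
* Empty scopes yield all-zero tables; an empty ground truth is an error
  (the metrics are undefined); prediction scores outside [0, 1] are an
  input error.
* `derive_never_in` rejects thresholds below 1.

## Problem sizes

The shipped tests and the acceptance script run at desk scale: bundles
of ≤ 24 taxonomy nodes, ≤ 46 terms and ≤ 721 GAF lines; 100 bundles
for the manifest-equivalence property; 1000 random instances for the
metric-curve oracle; exhaustive (all taxa × all axioms) checks for the
only_in conversion. These sizes are the package's own choice of a
thorough-but-quick regression envelope; every operation streams or
memoises, so corpus-scale inputs differ in time, not in code path.

## Known limitations

* The automatic selection heuristic for reference nodes is a declared
  stand-in; published reference-node lists should be preferred when
  available (`load_reference_nodes()`).
* OWL input support is a minimal RDF/XML reader for GO-shaped content
  (classes, subclass links, part_of restrictions, taxon axioms); full
  OWL reasoning and cross-ontology imports are out of scope. OBO is the
  primary dialect.
* The audit reports violations; it does not repair GAF files.
* Constraint derivation counts annotation lines by default; distinct
  proteins can be counted instead (`count_unit = "proteins"`), which
  matters when a few heavily re-annotated proteins dominate a clade.
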