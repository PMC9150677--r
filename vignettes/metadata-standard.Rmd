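---
title: "A queryable metadata standard for connectomics annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A queryable metadata standard for connectomics annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurometa)
```

## Motivation and scope

Volumetric electron-microscopy reconstructions annotate millions of
neuroanatomical objects, but each lab stores those annotations — and
especially the *metadata* attached to them — in its own shapes. This package
implements a metadata layer that is deliberately independent of raw
annotation formats: entities are typed documents with an open key-value
property map, community-defined classes carry a minimum required property
set, and a fixed query surface answers common neuroanatomy questions against
any conforming dataset. Raw annotation processing (segmentation,
skeletonization, mesh handling) is explicitly out of scope: all counts and
assignments arrive *as metadata*.

## The document model

An entity document has six reserved keys (`entity_id`, `entity_class`,
`uri`, `representation`, `links`, `dataset_id`); everything else is a
property. Properties are typed (`integer`, `long`, `double`, `string`,
`boolean`, nested `object`, integer 3-vector, bounding `box`), and
categorical values are symbolic in memory while integer-coded on disk,
translated through configurable code tables. The community registry
pre-defines three classes:

```{r}
reg <- schema_registry()
reg
```

Validation distinguishes three severities of finding: a missing or
ill-typed required property is an **error**; an unknown extra key is a
**warning** (it is treated as a user-defined extension — the standard is
extensible by design); and class-specific consistency findings are errors or
warnings depending on whether they can be legitimate. Two rules deserve
explanation:

* `n_incoming_synapses >= n_incoming_excitatory + n_incoming_inhibitory` is
  an *inequality*: polarity classifiers abstain on ambiguous synapses, so
  unclassified incoming synapses are legal.
* A stored `ei_balance` that differs from `E/(E+I)` recomputed from the
  stored counts by more than `1e-9` is a **warning**, not an error: stored
  values from the source dataset are treated as authoritative, but the drift
  is worth surfacing.

Two presence rules are strict "iff"s: `spinyness` (spine nodes / dendrite
nodes) must be present exactly when dendrite skeleton nodes exist, and
`ei_balance` exactly when classified incoming synapses exist. Undefined is
encoded as an *absent key*, never a sentinel value, to avoid collision with
legitimate zeros.

The neuron schema carries the 16 attributes its source material lists
explicitly; any further attributes a dataset wants to attach travel in the
extension property map rather than being invented as schema slots.

A note on the synapse `location`: it is typed here as an integer 3-vector of
voxel coordinates (a point in a volume needs three coordinates), with the
bounding box half-open (`[min, max)`) and 0-based indexing, the convention of
most volumetric tooling. The dataset header records the voxel resolution in
nanometers so physical positions are recoverable.

## Store and endpoints

The reference store is in-memory with JSON Lines persistence — one file per
collection plus a dataset header — so tests and pipelines are hermetic; the
collection contract (insert-with-validation, id uniqueness, indexed lookup)
is what a hosted document database would implement behind the same surface.
The retrieval surface is fixed at eight endpoints: get/list for each of the
three community collections, a partner-indexed `neuron_synapses` listing,
and a summary endpoint with exact scan tallies. List results are
stable-ordered by entity id (numeric where ids are numeric), and a missing
id is a distinct `nm_not_found` condition, never an empty list — an empty
list always means "the filter matched nothing".

Filter predicates are conjunctions of `(key, comparator, value)` clauses
with dotted access into nested documents. When an equality clause touches an
indexed field (layer, polarity, pre/post partner id) the index supplies the
candidate set; the remaining clauses run as a scan. The test suite
property-checks that indexed evaluation and an exhaustive scan agree on
randomized predicates.

## The question catalog

Seven templates cover counting, extrema, layer geometry, neuron length, and
excitatory/inhibitory balance. Their parameter domains are:

* synapse-type selectors: `all`, `excitatory`, `inhibitory`,
  `onto_axon_initial_segment` (4 members);
* locations: the whole volume or one of the seven layers (8 members);
* binary slots: most/fewest, average/total, greater/less;
* a free numeric balance slot for Q6/Q7.

```{r}
length(enumerate_question_catalog())
```

The expansion is `4·8 + 2·4 + 7 + 2·8 + 4·8 + 8 + 2·8 = 119`. The selector
domain is fixed at four members: treating "onto axon initial segments or
dendrites" as two separate selectors would give a 137-question catalog, and
119 is only reproduced with four. The dendrite-targeting filter remains
available off-catalog through
`filter_predicate(where("postsynaptic_partner.compartment", "eq", "dendrite_shaft"))`.
The Q6/Q7 balance value is bound at ask time; each discrete parameter
combination contributes one catalog instance.

Semantics chosen where the template wording is open:

* **Membership**: a synapse or neuron belongs to a layer through its `layer`
  attribute (the layer that contains a synapse's location in generated
  data), not through bounding-box intersection. Entities without a layer
  belong to the whole volume but to no single layer, which yields the
  additivity identity *per-layer counts + unassigned = whole-volume count*,
  property-tested for every selector.
* **Q4 neuron length**: no path-length is stored, so length is proxied by
  the sum of the six skeleton-node counts times a configurable node spacing
  (default 1.0, i.e. lengths are reported in node units). The average over
  zero neurons is undefined, not zero; the total is zero.
* **Q5** counts *incoming* synapses (matching the neuron document's
  incoming-tally fields); an outgoing variant stays off-catalog.
* **Ties** always break to the lowest id (layers in Q2, neurons in Q5/Q6);
  Q7 uses strict inequality and excludes undefined balances.

## The synthetic generator

`generator_config()` fixes the study conditions for all testing: seven layer
widths (150–400 µm, summing to a 2 mm cortical depth), neurons placed in
layers with probability proportional to layer thickness, a 65/25/10
pyramidal/interneuron/glia type mixture, an excitatory synapse fraction of
0.8 (cortical excitatory synapses dominate by roughly this margin),
compartment targets weighted toward spines and shafts with 5% onto axon
initial segments and, by default, 5% of synapses left without a layer
assignment so the additivity identity is genuinely exercised. Partner
assignment is uniform with self-synapses excluded; layers stack along the
y axis. Drawn spine-node counts are clamped to the dendrite-node count —
spines are part of the dendritic arbor — which keeps generated spinyness in
`[0, 1]` for any configured ranges. These are one-time choices of plausible magnitudes, not estimates of
any real dataset.

The generator computes its ground truth *from the same draws* that produce
the documents — per-(selector, location) tallies, per-neuron connectivity
and balance — so `ground_truth_answer()` is an oracle that never touches the
store, its indexes, or derived document fields. What passing the
engine-vs-oracle sweep shows is that the query engine, the store and the
document plumbing are mutually consistent and deterministic; it does **not**
show biological realism. Real data differ in ways the generator deliberately
ignores: spatial clustering of synapses, distance-dependent connectivity,
morphology, non-uniform annotation error. Conclusions about real volumes
need real metadata imported through `import_table()`.

Determinism: one integer seed drives all draws through R's RNG
(restored afterwards), so identical configs give byte-identical documents
within this implementation; reproducibility across RNG implementations is
not promised.

## Numerical and format choices

* Doubles serialize to JSON with 17 significant digits, so JSON Lines
  round-trips are bit-identical (`read(write(x))` is `identical()` to `x`).
* All numeric property values are held as doubles (counts are
  whole-number-checked at validation); this keeps round-trips type-stable
  across R's integer/double split.
* CSV export renders doubles decimally; re-import is compared at `1e-12`
  relative tolerance.
* Degenerate inputs: `E + I = 0` and zero dendrite nodes give undefined
  (`NA`/absent) ratios; empty stores answer count questions with 0 and list
  questions with empty results; averages over empty sets are `NA`.
* An infeasible generator configuration (layer widths not tiling the
  volume, synapses with fewer than two neurons, probabilities not summing
  to 1) fails fast with a configuration error.

## Problem sizes used in verification

The shipped tests run the full 119-question engine-vs-oracle sweep on
datasets of 60 neurons / 600 synapses across several seeds, and the
end-to-end acceptance checks use 500 neurons / 5,000 synapses on three
seeds — ample to exercise every selector-location cell while keeping the
suite quick on a laptop. Import/export round-trips use 300–1,000 generated
records. These sizes are the package's own verification choices; the
formats and algorithms have no built-in scale assumptions beyond memory.

## Known limitations

* The store is single-process and in-memory; persistence is whole-collection
  JSON Lines, not incremental.
* No HTTP façade ships here; the eight endpoints are library calls and CLI
  subcommands (an HTTP layer would map 1:1 onto them).
* No natural-language question parsing; questions are template id +
  parameters.
* Only conjunctive filters; no disjunction or negation.
* The neuron schema stores three derived quantities (spinyness, balance,
  tallies) rather than recomputing them lazily; consistency is audited at
  validation time instead.
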