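# neurometa

Standardized annotation **metadata** for connectomics datasets: typed,
validated documents for neurons, synapses and cortical layers, a
document-oriented metadata store with eight retrieval endpoints, and a
seven-template question catalog for interrogating a reconstructed volume
without touching raw annotations (segmentations, meshes, skeletons).

## Who this is for

Nanoscale electron-microscopy and X-ray-microtomography reconstructions ship
their annotations in lab-specific formats, so even basic questions — *how
many inhibitory synapses are there in layer 4? which neuron receives the most
input onto its axon initial segment?* — require dataset-specific plumbing.
`neurometa` is for connectomics researchers and data engineers who want to

* publish entity **metadata** (counts, types, layer assignments, connectivity
  tallies) in a standard, validated document format,
* import lab-style tabular dumps into that format, and
* query any conforming dataset through one fixed engine.

## The data model

Every annotated object is an **entity document**: an id, an entity class, a
URI locating the source data, a data representation (`skeleton`, `mesh`,
`pixels`, `table`, `none`), links to related entities (parent/child/sibling,
pre/postsynaptic partner, layer membership), and an open key-value property
map. Three **community-defined** classes carry a minimum required property
set, enforced by `validate_entity()`:

* **neuron** — 16 attribute slots: id, volume, outgoing/incoming synapse
  tallies, incoming tallies split by polarity, six per-compartment skeleton
  node counts, spinyness, layer, neuron type, and the
  excitatory/inhibitory balance
  `E/(E+I)` (E, I = classified incoming excitatory/inhibitory synapses;
  undefined when `E + I = 0`);
* **synapse** — exactly 7 slots: id, polarity, presynaptic site,
  postsynaptic partner (with target compartment), voxel location, half-open
  bounding box `[min, max)`, layer;
* **layer** — one required attribute: its width in nanometers.

User-defined classes (`register_entity_class()`) extend the registry without
shadowing the community trio; unknown extra keys on any record are warnings,
never errors.

A `metadata_store()` holds one collection per class with secondary indexes,
and exposes **eight retrieval endpoints** (`endpoint_get_neuron`,
`endpoint_list_neurons`, `endpoint_get_synapse`, `endpoint_list_synapses`,
`endpoint_get_layer`, `endpoint_list_layers`, `endpoint_neuron_synapses`,
`endpoint_summary`). The query engine answers **seven question templates**
parameterized over four synapse-type selectors (all / excitatory /
inhibitory / onto axon initial segments) and eight locations (whole volume
or any of the seven cortical layers), for a catalog of **119** concrete
questions (`enumerate_question_catalog()`).

A seeded synthetic generator (`generate()`) emits a desk-scale dataset with
this exact structure plus ground-truth tallies, so every query can be
audited against an independent oracle.

## Worked example

```r
library(neurometa)

gen   <- generate(generator_config(seed = 11, n_neurons = 200, n_synapses = 2000))
store <- store_from_generated(gen)

q1_count_synapses(store, "excitatory", "layer_3")
#> [1] 227
q2_layer_extremum(store, "most", "all")
#> $layer_id  [1] 7
#> $count     [1] 410
q4_neuron_length(store, "average", "whole_volume")
#> [1] 3027.055
q6_find_neuron_by_balance(store, 0.9, "layer_2")
#> $neuron_id   [1] 172
#> $ei_balance  [1] 0.9166667
endpoint_summary(store)
#> <dataset_summary> synthetic
#>   layer      7
#>   neuron     200
#>   synapse    2000
#>   synapses/layer: 133 185 277 261 283 356 410 | unassigned: 95
```

Layer 7 is the widest layer in the default configuration, so it accrues the
most synapses (410 of 2000 here). The 95 "unassigned" synapses have no layer
attribute: they count toward whole-volume questions but toward no single
layer, and the per-layer tallies plus the unassigned count always reproduce
the total. Neuron 172's balance 0.917 is the closest defined `E/(E+I)` value
to the requested 0.9 among layer-2 neurons. Every generated document
validates cleanly:

```r
validate_entity(endpoint_get_neuron(store, 42), schema_registry())
#> <validation_report> valid (0 error(s), 0 warning(s))
```

The same operations are available from a shell via the thin CLI wrapper
(`inst/scripts/neurometa`): `generate`, `import`, `validate`, `query`,
`endpoints`, `summary`, with JSON on stdout and exit codes 0 (success),
1 (validation failure), 2 (usage error).

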