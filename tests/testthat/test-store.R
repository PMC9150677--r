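test_that("insert/get round-trips documents and rejects duplicates", {
  store <- metadata_store("t")
  recs <- lapply(c(3, 1, 2), function(i) {
    neuron_record(neuron_id = i, dataset_id = "t")
  })
  insert_records(store, recs)
  for (rec in recs) {
    expect_identical(endpoint_get_neuron(store, rec$entity_id), rec)
  }
  expect_error(insert(store, recs[[1]]), class = "nm_validation_error")
  expect_length(endpoint_list_neurons(store), 3)

  invalid <- neuron_record(neuron_id = 99, n_incoming_synapses = 0,
                           n_incoming_excitatory = 5, dataset_id = "t")
  expect_error(insert(store, invalid), class = "nm_validation_error")
  expect_length(endpoint_list_neurons(store), 3)
})

test_that("the retrieval surface has exactly eight endpoints", {
  eps <- list_endpoints()
  expect_length(eps, 8)
  expect_equal(anyDuplicated(eps), 0)
  # each endpoint is exported as a library call
  fns <- paste0("endpoint_", setdiff(eps, "summary"))
  for (fn in c(fns, "endpoint_summary")) {
    expect_true(is.function(getExportedValue("neurometa", fn)), info = fn)
  }
})

test_that("unknown ids raise not-found, distinct from empty filter results", {
  store <- toy_store()
  expect_error(endpoint_get_neuron(store, 12345), class = "nm_not_found")
  expect_error(endpoint_get_layer(store, 8), class = "nm_not_found")
  empty <- endpoint_list_synapses(store, filter_predicate(where("layer", "eq", 99)))
  expect_identical(empty, list())

  empty_store <- metadata_store("e")
  expect_error(endpoint_neuron_synapses(empty_store, 1, "both"),
               class = "nm_not_found")
})

test_that("neuron_synapses follows the pre/post partner indexes", {
  store <- toy_store()
  out_ids <- record_ids(endpoint_neuron_synapses(store, 42, "outgoing"))
  in_ids <- record_ids(endpoint_neuron_synapses(store, 42, "incoming"))
  both_ids <- record_ids(endpoint_neuron_synapses(store, 42, "both"))
  expect_setequal(out_ids, c("d", "e", "f"))
  expect_setequal(in_ids, c("a", "b", "c"))
  expect_setequal(both_ids, union(out_ids, in_ids))
})

test_that("list endpoints are stable-ordered by entity id", {
  store <- toy_store()
  ids <- record_ids(endpoint_list_synapses(store))
  expect_identical(ids, sort(ids))
  nids <- as.numeric(record_ids(endpoint_list_neurons(store)))
  expect_identical(nids, sort(nids))
  expect_length(endpoint_list_layers(store), 7)
})

test_that("indexed filter evaluation equals an exhaustive scan", {
  fx <- generated_fixture(seed = 4L)
  store <- fx$store
  raw <- endpoint_list_synapses(store)
  set.seed(99)
  candidates <- list(
    function() filter_predicate(where("synapse_type", "eq",
                                      sample(c("excitatory", "inhibitory"), 1))),
    function() filter_predicate(where("layer", "eq", sample(1:7, 1))),
    function() filter_predicate(where("synapse_type", "eq", "excitatory"),
                                where("layer", "eq", sample(1:7, 1))),
    function() filter_predicate(where("postsynaptic_partner.neuron_id", "eq",
                                      sample(1:60, 1))),
    function() filter_predicate(where("postsynaptic_partner.compartment", "eq",
                                      "axon_initial_segment"),
                                where("layer", "le", sample(1:7, 1))),
    function() filter_predicate(where("layer", "in", sample(1:7, 3)))
  )
  for (i in 1:20) {
    pred <- candidates[[sample(length(candidates), 1)]]()
    expect_identical(record_ids(endpoint_list_synapses(store, pred)),
                     record_ids(brute_filter(raw, pred)))
  }
  expect_error(where("layer", "matches", 3), class = "nm_argument_error")
})

test_that("per-layer index tallies equal full-scan tallies after bulk insert", {
  fx <- generated_fixture(seed = 5L, n_neurons = 40L, n_synapses = 1000L)
  store <- fx$store
  raw <- endpoint_list_synapses(store)
  for (k in 1:7) {
    indexed <- endpoint_list_synapses(store, filter_predicate(where("layer", "eq", k)))
    expect_length(indexed, brute_q1(raw, "all", paste0("layer_", k)))
  }
})

test_that("summary tallies are conserved", {
  fx <- generated_fixture(seed = 1L)
  s <- endpoint_summary(fx$store)
  expect_equal(sum(s$synapses_per_layer) + s$synapses_unassigned_layer,
               s$collection_counts$synapse)
  expect_equal(sum(s$neurons_per_layer) + s$neurons_unassigned_layer,
               s$collection_counts$neuron)
  expect_equal(s$collection_counts$layer, 7)
})
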