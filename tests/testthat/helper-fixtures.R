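# Shared fixtures and the independent brute-force oracle used to audit the
# engine. The oracle only walks raw record lists: it never touches store
# indexes, cached frames, or derived document fields.

toy_registry <- function() schema_registry()

# a hand-countable store: 7 layers, 3 neurons, 6 synapses
#   incoming of neuron 42: syn a (exc), syn b (exc), syn c (inh)  -> E=2 I=1
#   outgoing of neuron 42: syn d, e, f
toy_store <- function() {
  store <- metadata_store("toy")
  widths <- c(150000, 200000, 300000, 250000, 300000, 400000, 400000)
  for (k in 1:7) insert(store, layer_record(k, widths[[k]], dataset_id = "toy"))
  mk_neuron <- function(id, E, I, n_in, n_out, layer, dn = 10, sp = 5) {
    insert(store, neuron_record(
      neuron_id = id, volume = 1000, n_outgoing_synapses = n_out,
      n_incoming_synapses = n_in, n_incoming_excitatory = E,
      n_incoming_inhibitory = I,
      n_dendrite_skeleton_nodes = dn, n_axon_skeleton_nodes = 5,
      n_dendritic_spine_skeleton_nodes = sp,
      neuron_type = "pyramidal",
      spinyness = if (dn > 0) sp / dn,
      layer = layer,
      ei_balance = if (E + I > 0) E / (E + I),
      dataset_id = "toy"))
  }
  mk_neuron(42, E = 2, I = 1, n_in = 3, n_out = 3, layer = 2)
  mk_neuron(7, E = 2, I = 0, n_in = 2, n_out = 2, layer = 3)
  mk_neuron(9, E = 0, I = 1, n_in = 1, n_out = 1, layer = 3)
  syn <- function(id, type, pre, post, layer, cmp = "dendrite_shaft") {
    insert(store, synapse_record(id, type, pre, post, c(5, 10, 15),
                                 compartment = cmp, layer = layer,
                                 dataset_id = "toy"))
  }
  syn("a", "excitatory", 7, 42, 2)
  syn("b", "excitatory", 9, 42, 2, cmp = "dendritic_spine")
  syn("c", "inhibitory", 7, 42, 3)
  syn("d", "excitatory", 42, 7, 3, cmp = "axon_initial_segment")
  syn("e", "excitatory", 42, 7, NULL)
  syn("f", "inhibitory", 42, 9, 1)
  store
}

generated_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1L, n_neurons = 60L, n_synapses = 600L) {
    key <- paste(seed, n_neurons, n_synapses, sep = "_")
    if (is.null(cache[[key]])) {
      gen <- generate(generator_config(seed = seed, n_neurons = n_neurons,
                                       n_synapses = n_synapses))
      cache[[key]] <- list(gen = gen, store = store_from_generated(gen))
    }
    cache[[key]]
  }
})

# ---- brute-force oracle over raw record lists --------------------------------

syn_prop <- function(recs, f) vapply(recs, function(r) f(r$properties), numeric(1))

brute_selector <- function(recs, type_sel) {
  switch(type_sel,
    all = rep(TRUE, length(recs)),
    excitatory = vapply(recs, function(r) r$properties$synapse_type == "excitatory", logical(1)),
    inhibitory = vapply(recs, function(r) r$properties$synapse_type == "inhibitory", logical(1)),
    onto_axon_initial_segment = vapply(recs, function(r) {
      r$properties$postsynaptic_partner$compartment == "axon_initial_segment"
    }, logical(1)))
}

brute_location <- function(recs, location) {
  if (location == "whole_volume") return(rep(TRUE, length(recs)))
  k <- as.numeric(sub("layer_", "", location))
  vapply(recs, function(r) {
    !is.null(r$properties$layer) && r$properties$layer == k
  }, logical(1))
}

brute_q1 <- function(synapses, type_sel, location) {
  sum(brute_selector(synapses, type_sel) & brute_location(synapses, location))
}

brute_incoming_count <- function(synapses, neuron_id, type_sel) {
  sel <- brute_selector(synapses, type_sel)
  post <- syn_prop(synapses, function(p) p$postsynaptic_partner$neuron_id)
  sum(sel & post == neuron_id)
}

# exhaustive-scan evaluation of a filter predicate (no indexes)
brute_filter <- function(records, predicate) {
  keep <- vapply(records, function(r) {
    all(vapply(predicate, function(cl) {
      val <- record_field(r, cl$key)
      if (is.null(val)) return(FALSE)
      switch(cl$op,
        eq = isTRUE(val == cl$value), lt = isTRUE(val < cl$value),
        gt = isTRUE(val > cl$value), le = isTRUE(val <= cl$value),
        ge = isTRUE(val >= cl$value), `in` = isTRUE(val %in% cl$value))
    }, logical(1)))
  }, logical(1))
  matched <- records[keep]
  ids <- vapply(matched, function(r) r$entity_id, character(1))
  num <- suppressWarnings(as.numeric(ids))
  ord <- if (length(ids) && !anyNA(num)) order(num) else order(ids, method = "radix")
  matched[ord]
}

record_ids <- function(records) vapply(records, function(r) r$entity_id, character(1))
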