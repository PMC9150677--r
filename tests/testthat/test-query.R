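test_that("Q1 counts synapses under type and location filters", {
  empty <- metadata_store("e")
  expect_equal(q1_count_synapses(empty, "all", "whole_volume"), 0L)

  store <- toy_store()
  expect_equal(q1_count_synapses(store, "all", "whole_volume"), 6)
  expect_equal(q1_count_synapses(store, "excitatory", "whole_volume"), 4)
  expect_equal(q1_count_synapses(store, "inhibitory", "layer_3"), 1)
  expect_equal(q1_count_synapses(store, "onto_axon_initial_segment", "whole_volume"), 1)
  # the unassigned-layer synapse counts in the whole volume but in no layer
  per_layer <- vapply(1:7, function(k) {
    q1_count_synapses(store, "all", paste0("layer_", k))
  }, integer(1))
  expect_equal(sum(per_layer), 5)
  expect_error(q1_count_synapses(store, "dendrites", "whole_volume"),
               class = "nm_argument_error")
})

test_that("Q2 finds the extremal layer with ties to the lowest id", {
  store <- metadata_store("t")
  widths <- rep(100000, 7)
  for (k in 1:7) insert(store, layer_record(k, widths[[k]], dataset_id = "t"))
  insert(store, neuron_record(1, dataset_id = "t"))
  insert(store, neuron_record(2, dataset_id = "t"))
  add_syn <- function(id, layer) {
    insert(store, synapse_record(id, "excitatory", 1, 2, c(1, 1, 1),
                                 layer = layer, dataset_id = "t"))
  }
  # counts {L1: 2, L2: 2, L3: 3}
  add_syn("a", 1); add_syn("b", 1)
  add_syn("c", 2); add_syn("d", 2)
  add_syn("e", 3); add_syn("f", 3); add_syn("g", 3)
  expect_equal(q2_layer_extremum(store, "most", "all"),
               list(layer_id = 3, count = 3))
  # fewest ties between empty layers 4..7 resolve to layer 4
  expect_equal(q2_layer_extremum(store, "fewest", "all"),
               list(layer_id = 4, count = 0))

  bare <- metadata_store("b")
  expect_error(q2_layer_extremum(bare, "most", "all"), class = "nm_config_error")
})

test_that("Q3 returns the stored layer width verbatim", {
  store <- toy_store()
  expect_equal(q3_layer_width(store, 4), 250000)
  expect_error(q3_layer_width(store, 8), class = "nm_not_found")
})

test_that("Q4 aggregates skeleton-node lengths with undefined empty averages", {
  store <- metadata_store("t")
  for (k in 1:7) insert(store, layer_record(k, 1000, dataset_id = "t"))
  mk <- function(id, layer) {
    insert(store, neuron_record(id, n_dendrite_skeleton_nodes = 10,
                                n_axon_skeleton_nodes = 5,
                                spinyness = 0, layer = layer, dataset_id = "t"))
  }
  mk(1, 2); mk(2, 2)
  expect_equal(q4_neuron_length(store, "total", "whole_volume"), 30)
  expect_equal(q4_neuron_length(store, "average", "whole_volume"), 15)
  expect_equal(q4_neuron_length(store, "total", "layer_5"), 0)
  expect_true(is.na(q4_neuron_length(store, "average", "layer_5")))
})

test_that("Q5 picks the neuron with most incoming synapses of the kind", {
  store <- toy_store()
  top <- q5_top_neuron(store, "excitatory", "whole_volume")
  expect_equal(top$neuron_id, 7) # 2 incoming excitatory, lowest id on tie with 42
  expect_equal(top$count, 2)
  expect_equal(q5_top_neuron(store, "all", "layer_2"),
               list(neuron_id = 42, count = 3))
  expect_null(q5_top_neuron(store, "all", "layer_6"))
})

test_that("Q6 returns the nearest-balance neuron and Q7 the strict threshold list", {
  store <- toy_store() # balances: 42 -> 2/3, 7 -> 1, 9 -> 0
  expect_equal(q6_find_neuron_by_balance(store, 0.75, "whole_volume")$neuron_id, 42)
  expect_equal(q6_find_neuron_by_balance(store, 0.0, "whole_volume")$neuron_id, 9)
  expect_error(q6_find_neuron_by_balance(store, 1.5), class = "nm_argument_error")

  expect_equal(q7_list_neurons_by_balance(store, "greater", 0.5, "whole_volume"),
               c(7, 42))
  expect_equal(q7_list_neurons_by_balance(store, "less", 0.5, "whole_volume"), 9)
  expect_error(q7_list_neurons_by_balance(store, "greater", -0.1),
               class = "nm_argument_error")

  # greater(v), less(v) and {balance == v} partition the defined-balance neurons
  for (v in c(0, 0.3, 2 / 3, 1)) {
    g <- q7_list_neurons_by_balance(store, "greater", v)
    l <- q7_list_neurons_by_balance(store, "less", v)
    all_defined <- c(7, 9, 42)
    eq <- setdiff(all_defined, c(g, l))
    expect_setequal(c(g, l, eq), all_defined)
    expect_equal(length(g) + length(l) + length(eq), 3)
  }
})

test_that("the catalog enumerates 119 unique instances over 7 templates", {
  cat119 <- enumerate_question_catalog()
  expect_length(cat119, 119)
  templates <- vapply(cat119, function(q) q$template_id, character(1))
  expect_setequal(unique(templates), paste0("Q", 1:7))
  keys <- vapply(cat119, function(q) {
    paste(q$template_id, paste(names(q$params), unlist(lapply(q$params, function(p) {
      if (is.null(p)) "<free>" else as.character(p)
    })), sep = "=", collapse = ","))
  }, character(1))
  expect_equal(anyDuplicated(keys), 0)
  # template-wise closed form: |T|*|L| + 2|T| + 7 + 2|L| + |T|*|L| + |L| + 2|L|
  expect_equal(as.vector(table(factor(templates, levels = paste0("Q", 1:7)))),
               c(32, 8, 7, 16, 32, 8, 16))
  # deterministic enumeration
  expect_identical(enumerate_question_catalog(), cat119)
})

test_that("restricted one-selector one-location domains give 16 instances", {
  small <- enumerate_question_catalog(selectors = "all",
                                      locations = "whole_volume")
  expect_length(small, 1 + 2 + 7 + 2 + 1 + 1 + 2)
})

test_that("answer() dispatches to the template implementations", {
  store <- toy_store()
  q <- question_instance("Q1", list(type_sel = "excitatory",
                                    location = "whole_volume"))
  res <- answer(store, q)
  expect_s3_class(res, "query_result")
  expect_equal(res$result, q1_count_synapses(store, "excitatory", "whole_volume"))

  expect_error(answer(store, question_instance("Q9", list())),
               class = "nm_argument_error")
  expect_error(answer(store, question_instance("Q6", list(location = "whole_volume"))),
               class = "nm_argument_error") # unbound value slot
})

test_that("layer additivity holds for every selector on seeded data", {
  fx <- generated_fixture(seed = 9L)
  store <- fx$store
  for (sel in synapse_selectors()) {
    per_layer <- vapply(1:7, function(k) {
      as.numeric(q1_count_synapses(store, sel, paste0("layer_", k)))
    }, numeric(1))
    raw <- endpoint_list_synapses(store)
    unassigned <- sum(brute_selector(raw, sel) &
                        vapply(raw, function(r) is.null(r$properties$layer), logical(1)))
    expect_equal(sum(per_layer) + unassigned,
                 as.numeric(q1_count_synapses(store, sel, "whole_volume")))
    # Q2 consistency with the per-layer vector
    expect_equal(q2_layer_extremum(store, "most", sel)$count, max(per_layer))
    expect_equal(q2_layer_extremum(store, "fewest", sel)$count, min(per_layer))
  }
})

test_that("engine answers equal a brute-force scan that ignores indexes", {
  fx <- generated_fixture(seed = 10L)
  store <- fx$store
  raw_syn <- endpoint_list_synapses(store)
  for (sel in synapse_selectors()) {
    for (loc in c("whole_volume", "layer_2", "layer_6")) {
      expect_equal(as.numeric(q1_count_synapses(store, sel, loc)),
                   brute_q1(raw_syn, sel, loc))
    }
    top <- q5_top_neuron(store, sel, "whole_volume")
    counts <- vapply(1:60, function(id) brute_incoming_count(raw_syn, id, sel),
                     numeric(1))
    expect_equal(top$count, max(counts))
    expect_equal(top$neuron_id, which.max(counts))
  }
})
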