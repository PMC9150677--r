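test_that("generation is deterministic: same config, identical output", {
  cfg <- generator_config(seed = 21L, n_neurons = 15L, n_synapses = 120L)
  a <- generate(cfg)
  b <- generate(cfg)
  expect_identical(a$neurons, b$neurons)
  expect_identical(a$synapses, b$synapses)
  expect_identical(a$layers, b$layers)
  expect_identical(a$ground_truth, b$ground_truth)

  c2 <- generate(generator_config(seed = 22L, n_neurons = 15L, n_synapses = 120L))
  expect_false(identical(a$synapses, c2$synapses))
})

test_that("the generator honors its count contract and layer geometry", {
  gen <- generate(generator_config(seed = 7L, n_neurons = 12L, n_synapses = 200L))
  expect_length(gen$synapses, 200)
  expect_length(gen$neurons, 12)
  expect_length(gen$layers, 7)

  gt <- gen$ground_truth
  for (sel in synapse_selectors()) {
    per_layer <- gt$synapse_tally[sel, paste0("layer_", 1:7)]
    expect_equal(sum(per_layer) + gt$synapse_tally_unassigned[[sel]],
                 gt$synapse_tally[sel, "whole_volume"])
  }
  expect_equal(unname(gt$synapse_tally["all", "whole_volume"]), 200)

  # each assigned synapse's layer is the layer containing its y coordinate
  widths <- generator_config()$layer_widths
  bounds <- cumsum(widths)
  res_y <- 8
  for (s in gen$synapses) {
    p <- s$properties
    if (!is.null(p$layer)) {
      y_nm <- p$location[[2]] * res_y
      expect_equal(p$layer, findInterval(y_nm, bounds) + 1)
    }
    expect_true(all(p$location >= p$bounding_box$min &
                    p$location < p$bounding_box$max))
    # no self-synapses
    expect_false(p$presynaptic_site$neuron_id == p$postsynaptic_partner$neuron_id)
  }
})

test_that("an empty config yields only the seven layer documents", {
  gen <- generate(generator_config(seed = 1L, n_neurons = 0L, n_synapses = 0L))
  expect_length(gen$neurons, 0)
  expect_length(gen$synapses, 0)
  expect_length(gen$layers, 7)
  expect_equal(unname(gen$ground_truth$synapse_tally["all", "whole_volume"]), 0)
  expect_equal(nrow(gen$ground_truth$neurons), 0)
})

test_that("infeasible configs are rejected", {
  expect_error(generator_config(n_neurons = 1L, n_synapses = 10L),
               class = "nm_config_error")
  expect_error(generator_config(layer_widths = rep(1e5, 7),
                                volume_dim = c(100, 100, 100)),
               class = "nm_config_error")
  expect_error(generator_config(excitatory_fraction = 1.2),
               class = "nm_config_error")
  expect_error(generator_config(neuron_type_probs = c(a = 0.5, b = 0.6)),
               class = "nm_config_error")
})

test_that("the empirical excitatory share matches the configured fraction", {
  gen <- generate(generator_config(seed = 13L, n_neurons = 50L,
                                   n_synapses = 10000L,
                                   excitatory_fraction = 0.8))
  share <- gen$ground_truth$synapse_tally["excitatory", "whole_volume"] / 10000
  sd3 <- 3 * sqrt(0.8 * 0.2 / 10000)
  expect_lt(abs(share - 0.8), sd3)
})

test_that("ground-truth answers equal engine answers across the catalog and seeds", {
  cat119 <- enumerate_question_catalog()
  for (seed in c(1L, 2L, 3L)) {
    fx <- generated_fixture(seed = seed)
    for (q in cat119) {
      for (v in if (q$template_id %in% c("Q6", "Q7")) c(0.25, 0.8) else NA) {
        eng <- answer(fx$store, q, value = v)
        gt <- ground_truth_answer(fx$gen$ground_truth, q, value = v)
        expect_true(query_results_equal(eng, gt),
                    info = paste(seed, q$template_id,
                                 paste(unlist(q$params), collapse = ","), v))
      }
    }
  }
})
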