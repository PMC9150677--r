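test_that("community schemas expose the expected attribute slots", {
  reg <- schema_registry()
  expect_equal(schema_slots(reg, "synapse"), 7)
  expect_equal(schema_slots(reg, "neuron"), 16)
  expect_equal(schema_required(reg, "layer"), "width")
  expect_length(schema_required(reg, "layer"), 1)
})

test_that("a complete synapse record validates and a gutted one does not", {
  reg <- schema_registry()
  rec <- synapse_record("s1", "excitatory", pre_neuron = 1, post_neuron = 2,
                        location = c(10, 20, 30), compartment = "dendritic_spine",
                        layer = 3)
  rep <- validate_entity(rec, reg)
  expect_true(rep$valid)
  expect_equal(sum(rep$issues$severity == "error"), 0)

  broken <- rec
  broken$properties$synapse_type <- NULL
  rep2 <- validate_entity(broken, reg)
  expect_false(rep2$valid)
  err <- rep2$issues[rep2$issues$severity == "error", ]
  expect_equal(nrow(err), 1)
  expect_equal(err$property_key, "synapse_type")
})

test_that("validation is idempotent and flags geometry violations", {
  reg <- schema_registry()
  rec <- synapse_record("s1", "inhibitory", 1, 2, c(5, 5, 5),
                        bounding_box = list(min = c(0, 0, 0), max = c(10, 10, 10)))
  expect_identical(validate_entity(rec, reg), validate_entity(rec, reg))

  outside <- synapse_record("s2", "inhibitory", 1, 2, c(50, 5, 5),
                            bounding_box = list(min = c(0, 0, 0), max = c(10, 10, 10)))
  rep <- validate_entity(outside, reg)
  expect_false(rep$valid)
  expect_true(any(grepl("bounding box", rep$issues$message)))

  degenerate <- synapse_record("s3", "inhibitory", 1, 2, c(0, 0, 0),
                               bounding_box = list(min = c(0, 0, 0), max = c(0, 1, 1)))
  expect_false(validate_entity(degenerate, reg)$valid)
})

test_that("user-defined classes are registerable but community classes are protected", {
  reg <- schema_registry()
  register_entity_class(reg, "blood_vessel", required = c(radius = "double"))
  good <- entity_record("bv1", "blood_vessel",
                        properties = list(blood_vessel_id = "bv1", radius = 5))
  expect_true(validate_entity(good, reg)$valid)

  bad <- entity_record("bv2", "blood_vessel",
                       properties = list(blood_vessel_id = "bv2"))
  rep <- validate_entity(bad, reg)
  expect_false(rep$valid)
  expect_true(any(rep$issues$property_key == "radius"))

  expect_error(register_entity_class(reg, "neuron", required = c(x = "integer")),
               class = "nm_argument_error")

  unknown <- entity_record("m1", "mitochondrion",
                           properties = list(mitochondrion_id = "m1"))
  repu <- validate_entity(unknown, reg)
  expect_false(repu$valid)
  expect_true(any(grepl("unknown entity class", repu$issues$message)))
})

test_that("unknown extra keys warn instead of failing validation", {
  reg <- schema_registry()
  rec <- synapse_record("s1", "excitatory", 1, 2, c(1, 2, 3))
  rec$properties$my_confidence <- 0.9
  rep <- validate_entity(rec, reg)
  expect_true(rep$valid)
  expect_true(any(rep$issues$severity == "warning" &
                  rep$issues$property_key == "my_confidence"))
})

test_that("neuron consistency rules: counts, balance presence, stored-vs-derived", {
  reg <- schema_registry()
  base <- function(...) {
    neuron_record(neuron_id = 1, n_incoming_synapses = 4,
                  n_incoming_excitatory = 3, n_incoming_inhibitory = 1,
                  n_dendrite_skeleton_nodes = 10,
                  n_dendritic_spine_skeleton_nodes = 5,
                  spinyness = 0.5, ei_balance = 0.75, ...)
  }
  expect_true(validate_entity(base(), reg)$valid)

  # classified tally exceeding the incoming total is inconsistent
  bad <- base()
  bad$properties$n_incoming_synapses <- 2
  expect_false(validate_entity(bad, reg)$valid)

  # stored balance drifting from E/(E+I) is a warning, not an error
  drift <- base()
  drift$properties$ei_balance <- 0.60
  rep <- validate_entity(drift, reg)
  expect_true(rep$valid)
  expect_true(any(rep$issues$severity == "warning" &
                  rep$issues$property_key == "ei_balance"))

  # balance present without classified synapses violates the iff rule
  nosyn <- base()
  nosyn$properties$n_incoming_excitatory <- 0
  nosyn$properties$n_incoming_inhibitory <- 0
  expect_false(validate_entity(nosyn, reg)$valid)

  # spinyness defined iff dendrite nodes exist
  spineless <- base()
  spineless$properties$n_dendrite_skeleton_nodes <- 0
  spineless$properties$n_dendritic_spine_skeleton_nodes <- 0
  expect_false(validate_entity(spineless, reg)$valid)
  spineless$properties$spinyness <- NULL
  expect_true(validate_entity(spineless, reg)$valid)
})

test_that("every generated document validates with zero errors", {
  fx <- generated_fixture(seed = 3L)
  reg <- schema_registry()
  for (recs in list(fx$gen$neurons, fx$gen$synapses, fx$gen$layers)) {
    reports <- lapply(recs, validate_entity, registry = reg)
    expect_true(all(vapply(reports, `[[`, logical(1), "valid")))
    n_err <- vapply(reports, function(r) sum(r$issues$severity == "error"), numeric(1))
    expect_equal(sum(n_err), 0)
  }
})
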