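#' Generator configuration for synthetic connectome metadata
#'
#' Describes a desk-scale synthetic dataset emulating the annotation
#' structure of a petascale cortical EM volume: seven cortical layers
#' stacked along the y axis, neurons with per-compartment skeleton-node
#' counts and a layer assignment, and synapses with polarity, pre/post
#' partners, voxel location, bounding box and layer. The layer widths must
#' exactly tile the volume's y extent (in nanometers); by default the y
#' dimension is derived from the widths.
#'
#' @param seed Integer RNG seed; the same config (seed included) always
#'   yields identical documents and ground truth.
#' @param n_neurons,n_synapses Document counts.
#' @param layer_widths Seven layer widths in nanometers.
#' @param neuron_type_probs Named mixture over neuron-type symbols.
#' @param excitatory_fraction Probability a synapse is excitatory.
#' @param compartment_probs Named mixture over postsynaptic compartments.
#' @param unassigned_layer_fraction Fraction of synapses left without a
#'   layer assignment (they still have a location).
#' @param node_count_ranges Named list of `c(min, max)` uniform integer
#'   ranges for the six skeleton-node-count fields.
#' @param resolution Voxel resolution in nm, 3-vector.
#' @param volume_dim Volume dimensions in voxels; `NULL` derives the y
#'   extent from the layer widths.
#' @param dataset_id Dataset identifier stamped on every document.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(seed = 1L, n_neurons = 50L, n_synapses = 500L,
                             layer_widths = c(150000, 200000, 300000, 250000,
                                              300000, 400000, 400000),
                             neuron_type_probs = c(pyramidal = 0.65,
                                                   interneuron = 0.25,
                                                   glia = 0.10),
                             excitatory_fraction = 0.8,
                             compartment_probs = c(dendrite_shaft = 0.30,
                                                   dendritic_spine = 0.55,
                                                   soma = 0.10,
                                                   axon_initial_segment = 0.05),
                             unassigned_layer_fraction = 0.05,
                             node_count_ranges = list(
                               dendrite = c(50, 2000), axon = c(50, 3000),
                               dendritic_spine = c(0, 500), cilia = c(0, 20),
                               ais = c(0, 60), myelinated_axon = c(0, 400)),
                             resolution = c(8, 8, 33),
                             volume_dim = NULL,
                             dataset_id = "synthetic") {
  cfg <- list(seed = as.integer(seed), n_neurons = as.integer(n_neurons),
              n_synapses = as.integer(n_synapses),
              layer_widths = as.numeric(layer_widths),
              neuron_type_probs = neuron_type_probs,
              excitatory_fraction = excitatory_fraction,
              compartment_probs = compartment_probs,
              unassigned_layer_fraction = unassigned_layer_fraction,
              node_count_ranges = node_count_ranges,
              resolution = as.numeric(resolution),
              volume_dim = volume_dim, dataset_id = dataset_id)
  if (is.null(cfg$volume_dim)) {
    cfg$volume_dim <- c(2000, sum(cfg$layer_widths) / cfg$resolution[[2L]], 1000)
  }
  cfg$volume_dim <- as.numeric(cfg$volume_dim)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_neurons < 0 || cfg$n_synapses < 0) {
    nm_config_error("document counts must be >= 0")
  }
  if (length(cfg$layer_widths) != 7L || any(cfg$layer_widths <= 0)) {
    nm_config_error("layer_widths must be seven positive widths in nm")
  }
  for (pr in list(cfg$neuron_type_probs, cfg$compartment_probs)) {
    if (abs(sum(pr) - 1) > 1e-9 || any(pr < 0)) {
      nm_config_error("mixture probabilities must be non-negative and sum to 1")
    }
  }
  if (cfg$excitatory_fraction < 0 || cfg$excitatory_fraction > 1 ||
      cfg$unassigned_layer_fraction < 0 || cfg$unassigned_layer_fraction > 1) {
    nm_config_error("fractions must lie in [0, 1]")
  }
  y_nm <- cfg$volume_dim[[2L]] * cfg$resolution[[2L]]
  if (abs(sum(cfg$layer_widths) - y_nm) > 1e-6) {
    nm_config_error("layer widths must exactly tile the volume's y extent")
  }
  if (cfg$n_synapses > 0 && cfg$n_neurons < 2L) {
    nm_config_error("synapses need at least two neurons (self-synapses are excluded)")
  }
  invisible(cfg)
}

sample_int_range <- function(n, range) {
  if (range[[2L]] <= range[[1L]]) rep(range[[1L]], n)
  else floor(stats::runif(n, range[[1L]], range[[2L]] + 1))
}

#' Generate a synthetic connectome dataset with exact ground truth
#'
#' Draws neurons, synapses and the seven layer documents under the study
#' conditions of `config`, together with a [ground_truth] object holding the
#' exact per-(selector, location) synapse tallies, per-neuron connectivity
#' tallies and layer widths computed from the same draws. Every emitted
#' document validates against the community registry; each synapse's layer
#' attribute is the layer containing its location except for the configured
#' unassigned fraction; neuron documents store aggregates equal to the
#' ground-truth tallies.
#'
#' @param config A [generator_config()].
#' @return List with `neurons`, `synapses`, `layers` (lists of
#'   [entity_record()]s), `ground_truth`, and `header` (dataset id,
#'   resolution, node spacing, code tables).
#' @export
#' @examples
#' gen <- generate(generator_config(seed = 7, n_neurons = 10, n_synapses = 40))
#' length(gen$synapses)
generate <- function(config) {
  if (!inherits(config, "generator_config")) {
    config <- do.call(generator_config, unclass(config))
  }
  validate_generator_config(config)
  with_seed(config$seed, generate_impl(config))
}

generate_impl <- function(cfg) {
  nn <- cfg$n_neurons
  ns <- cfg$n_synapses
  res_y <- cfg$resolution[[2L]]
  bounds_nm <- cumsum(cfg$layer_widths)
  ds <- cfg$dataset_id

  layers <- lapply(1:7, function(k) {
    layer_record(k, cfg$layer_widths[[k]], dataset_id = ds)
  })

  # neuron-level draws; layer occupancy proportional to layer thickness
  if (nn > 0) {
    n_layer <- sample(1:7, nn, replace = TRUE,
                      prob = cfg$layer_widths / sum(cfg$layer_widths))
    n_type <- sample(names(cfg$neuron_type_probs), nn, replace = TRUE,
                     prob = cfg$neuron_type_probs)
    n_volume <- sample_int_range(nn, c(1e5, 1e8))
    nodes <- lapply(cfg$node_count_ranges, function(r) sample_int_range(nn, r))
    # spines are part of the dendritic arbor: spinyness stays in [0, 1]
    nodes$dendritic_spine <- pmin(nodes$dendritic_spine, nodes$dendrite)
  } else {
    n_layer <- numeric(0); n_type <- character(0); n_volume <- numeric(0)
    nodes <- lapply(cfg$node_count_ranges, function(r) numeric(0))
  }

  # synapse-level draws
  if (ns > 0) {
    s_type <- ifelse(stats::runif(ns) < cfg$excitatory_fraction,
                     "excitatory", "inhibitory")
    s_pre <- sample.int(nn, ns, replace = TRUE)
    # postsynaptic partner uniform over the other neurons (no self-synapses)
    s_post <- sample.int(nn - 1L, ns, replace = TRUE)
    s_post <- ifelse(s_post >= s_pre, s_post + 1L, s_post)
    s_cmp <- sample(names(cfg$compartment_probs), ns, replace = TRUE,
                    prob = cfg$compartment_probs)
    s_x <- sample_int_range(ns, c(0, cfg$volume_dim[[1L]] - 1))
    s_y <- sample_int_range(ns, c(0, cfg$volume_dim[[2L]] - 1))
    s_z <- sample_int_range(ns, c(0, cfg$volume_dim[[3L]] - 1))
    s_layer <- findInterval(s_y * res_y, bounds_nm, left.open = FALSE) + 1
    s_layer <- pmin(s_layer, 7)
    unassigned <- stats::runif(ns) < cfg$unassigned_layer_fraction
    s_layer[unassigned] <- NA_real_
  } else {
    s_type <- character(0); s_pre <- integer(0); s_post <- integer(0)
    s_cmp <- character(0); s_x <- s_y <- s_z <- numeric(0)
    s_layer <- numeric(0); unassigned <- logical(0)
  }

  # exact per-neuron connectivity tallies from the same draws
  tab <- function(ids) if (nn > 0) tabulate(ids, nbins = nn) else numeric(0)
  n_out <- tab(s_pre)
  n_in <- tab(s_post)
  n_exc <- tab(s_post[s_type == "excitatory"])
  n_inh <- tab(s_post[s_type == "inhibitory"])
  n_ais_in <- tab(s_post[s_cmp == "axon_initial_segment"])
  balance <- ifelse(n_exc + n_inh > 0, n_exc / (n_exc + n_inh), NA_real_)

  neurons <- lapply(seq_len(nn), function(i) {
    neuron_record(
      neuron_id = i, volume = n_volume[[i]],
      n_outgoing_synapses = n_out[[i]], n_incoming_synapses = n_in[[i]],
      n_incoming_excitatory = n_exc[[i]], n_incoming_inhibitory = n_inh[[i]],
      n_dendrite_skeleton_nodes = nodes$dendrite[[i]],
      n_axon_skeleton_nodes = nodes$axon[[i]],
      n_dendritic_spine_skeleton_nodes = nodes$dendritic_spine[[i]],
      n_cilia_skeleton_nodes = nodes$cilia[[i]],
      n_ais_skeleton_nodes = nodes$ais[[i]],
      n_myelinated_axon_skeleton_nodes = nodes$myelinated_axon[[i]],
      neuron_type = n_type[[i]],
      spinyness = if (nodes$dendrite[[i]] > 0) {
        nodes$dendritic_spine[[i]] / nodes$dendrite[[i]]
      },
      layer = n_layer[[i]],
      ei_balance = if (!is.na(balance[[i]])) balance[[i]],
      dataset_id = ds
    )
  })

  synapses <- lapply(seq_len(ns), function(j) {
    loc <- c(s_x[[j]], s_y[[j]], s_z[[j]])
    synapse_record(
      synapse_id = sprintf("syn%06d", j),
      synapse_type = s_type[[j]],
      pre_neuron = s_pre[[j]], post_neuron = s_post[[j]],
      location = loc, compartment = s_cmp[[j]],
      bounding_box = list(min = pmax(loc - 2, 0), max = loc + 3),
      layer = if (!is.na(s_layer[[j]])) s_layer[[j]],
      dataset_id = ds
    )
  })

  # exact per-(selector, location) synapse tallies
  sel_masks <- list(
    all = rep(TRUE, ns),
    excitatory = s_type == "excitatory",
    inhibitory = s_type == "inhibitory",
    onto_axon_initial_segment = s_cmp == "axon_initial_segment"
  )
  tally <- matrix(0, nrow = 4L, ncol = 8L,
                  dimnames = list(synapse_selectors(), location_domain()))
  unassigned_tally <- stats::setNames(numeric(4), synapse_selectors())
  for (sel in synapse_selectors()) {
    m <- sel_masks[[sel]]
    tally[sel, "whole_volume"] <- sum(m)
    for (k in 1:7) {
      tally[sel, paste0("layer_", k)] <- sum(m & !is.na(s_layer) & s_layer == k)
    }
    unassigned_tally[[sel]] <- sum(m & is.na(s_layer))
  }

  node_mat <- if (nn > 0) do.call(cbind, nodes) else matrix(0, 0, 6)
  gt <- structure(list(
    layer_widths = cfg$layer_widths,
    synapse_tally = tally,
    synapse_tally_unassigned = unassigned_tally,
    neurons = data.frame(
      id = seq_len(nn), layer = n_layer,
      n_incoming = n_in, n_outgoing = n_out,
      n_incoming_excitatory = n_exc, n_incoming_inhibitory = n_inh,
      n_incoming_ais = n_ais_in, ei_balance = balance,
      skeleton_nodes = if (nn > 0) rowSums(node_mat) else numeric(0)
    ),
    n_synapses = ns
  ), class = "ground_truth")

  header <- list(dataset_id = ds, resolution = cfg$resolution,
                 node_spacing = 1.0, code_tables = default_code_tables())

  list(neurons = neurons, synapses = synapses, layers = layers,
       ground_truth = gt, header = header)
}

#' Build a metadata store from a generated dataset
#'
#' @param gen The list returned by [generate()].
#' @param registry Optional [schema_registry()].
#' @return A loaded [metadata_store()].
#' @export
store_from_generated <- function(gen, registry = schema_registry()) {
  store <- metadata_store(gen$header$dataset_id, registry = registry,
                          resolution = gen$header$resolution,
                          node_spacing = gen$header$node_spacing)
  insert_records(store, gen$layers)
  insert_records(store, gen$neurons)
  insert_records(store, gen$synapses)
  store
}

#' Answer a catalog question from ground truth alone
#'
#' The oracle twin of [answer()]: computes the same typed result using only
#' the generator's exact tallies — never the store, its indexes, or derived
#' document fields — so that engine answers can be cross-checked against an
#' independent bookkeeping path.
#'
#' @param gt A `ground_truth` object from [generate()].
#' @param question A [question_instance()].
#' @param value Balance value for free-slot Q6/Q7 instances.
#' @param node_spacing Skeleton node spacing used for neuron lengths.
#' @return A `query_result` matching [answer()]'s shape.
#' @export
ground_truth_answer <- function(gt, question, value = NULL, node_spacing = 1.0) {
  if (!inherits(question, "question_instance") ||
      !is_scalar_string(question$template_id %||% "")) {
    nm_argument_error("malformed question instance")
  }
  p <- question$params
  nfr <- gt$neurons
  in_loc <- function(location) {
    k <- location_layer(location)
    if (is.na(k)) rep(TRUE, nrow(nfr)) else !is.na(nfr$layer) & nfr$layer == k
  }
  res <- switch(question$template_id,
    Q1 = unname(gt$synapse_tally[check_selector(p$type_sel), p$location]),
    Q2 = {
      counts <- gt$synapse_tally[check_selector(p$type_sel), paste0("layer_", 1:7)]
      k <- if (p$extremum == "most") which.max(counts) else which.min(counts)
      list(layer_id = as.numeric(k), count = unname(counts[[k]]))
    },
    Q3 = {
      if (!p$layer_id %in% 1:7) nm_not_found("unknown layer")
      gt$layer_widths[[p$layer_id]]
    },
    Q4 = {
      lens <- nfr$skeleton_nodes[in_loc(p$location)] * node_spacing
      if (p$aggregate == "total") sum(lens)
      else if (length(lens) == 0L) NA_real_ else mean(lens)
    },
    Q5 = {
      sub <- nfr[in_loc(p$location), , drop = FALSE]
      if (nrow(sub) == 0L) NULL
      else {
        cnt <- switch(check_selector(p$type_sel),
          all = sub$n_incoming,
          excitatory = sub$n_incoming_excitatory,
          inhibitory = sub$n_incoming_inhibitory,
          onto_axon_initial_segment = sub$n_incoming_ais)
        ord <- order(sub$id)
        sub <- sub[ord, , drop = FALSE]; cnt <- cnt[ord]
        best <- which.max(cnt)
        list(neuron_id = sub$id[[best]], count = cnt[[best]])
      }
    },
    Q6 = {
      v <- p$value %||% value %||% nm_argument_error("Q6 requires a balance value")
      if (v < 0 || v > 1) nm_argument_error("balance value must lie in [0, 1]")
      sub <- nfr[in_loc(p$location) & !is.na(nfr$ei_balance), , drop = FALSE]
      if (nrow(sub) == 0L) NULL
      else {
        sub <- sub[order(abs(sub$ei_balance - v), sub$id), , drop = FALSE]
        list(neuron_id = sub$id[[1L]], ei_balance = sub$ei_balance[[1L]])
      }
    },
    Q7 = {
      v <- p$value %||% value %||% nm_argument_error("Q7 requires a balance value")
      if (v < 0 || v > 1) nm_argument_error("balance value must lie in [0, 1]")
      keep <- in_loc(p$location) & !is.na(nfr$ei_balance) &
        (if (p$direction == "greater") nfr$ei_balance > v else nfr$ei_balance < v)
      sort(nfr$id[keep])
    },
    nm_argument_error(paste0("unknown template '", question$template_id, "'"))
  )
  bound <- p
  if (question$template_id %in% c("Q6", "Q7") && is.null(bound$value)) {
    bound$value <- value
  }
  structure(list(question = question_instance(question$template_id, bound),
                 result = res),
            class = "query_result")
}
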