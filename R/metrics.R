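#' Excitatory/inhibitory synapse balance
#'
#' The balance is E/(E+I), where E and I are the numbers of classified
#' incoming excitatory and inhibitory synapses of a neuron. It lies in
#' \[0, 1\]: 1 means all classified input is excitatory, 0 all inhibitory.
#' With no classified incoming synapses the balance is undefined (`NA`).
#'
#' @param n_excitatory,n_inhibitory Non-negative counts.
#' @return E/(E+I) as a double, or `NA_real_` when E + I = 0.
#' @export
#' @examples
#' compute_ei_balance(3, 1)  # 0.75
#' compute_ei_balance(0, 0)  # NA: undefined
compute_ei_balance <- function(n_excitatory, n_inhibitory) {
  if (!is_scalar_count(n_excitatory) || !is_scalar_count(n_inhibitory)) {
    nm_argument_error("synapse counts must be non-negative integers")
  }
  tot <- n_excitatory + n_inhibitory
  if (tot == 0) NA_real_ else n_excitatory / tot
}

#' Dendritic spinyness
#'
#' Ratio of dendritic-spine skeleton nodes to dendrite skeleton nodes;
#' undefined (`NA`) for neurons without dendrite skeleton nodes.
#'
#' @param n_spine_nodes,n_dendrite_nodes Non-negative node counts.
#' @return The ratio as a double, or `NA_real_` when the denominator is 0.
#' @export
#' @examples
#' compute_spinyness(5, 10)  # 0.5
compute_spinyness <- function(n_spine_nodes, n_dendrite_nodes) {
  if (!is_scalar_count(n_spine_nodes) || !is_scalar_count(n_dendrite_nodes)) {
    nm_argument_error("skeleton node counts must be non-negative integers")
  }
  if (n_dendrite_nodes == 0) NA_real_ else n_spine_nodes / n_dendrite_nodes
}

#' Recompute a neuron's synapse aggregates from a synapse collection
#'
#' Tallies a neuron's connectivity directly from synapse documents: outgoing
#' synapses are those whose presynaptic site references the neuron, incoming
#' those whose postsynaptic partner does; incoming synapses are further split
#' by polarity, and the E/(E+I) balance is derived via
#' [compute_ei_balance()]. Used both to populate neuron documents and to
#' audit stored tallies for consistency.
#'
#' @param neuron_id Integer neuron identifier.
#' @param synapses A list of synapse [entity_record()]s.
#' @return List with `n_outgoing`, `n_incoming`, `n_incoming_excitatory`,
#'   `n_incoming_inhibitory` and `ei_balance` (`NA` when undefined).
#' @export
derive_neuron_aggregates <- function(neuron_id, synapses) {
  neuron_id <- as.numeric(neuron_id)
  pre <- vapply(synapses, function(s) s$properties$presynaptic_site$neuron_id, numeric(1))
  post <- vapply(synapses, function(s) s$properties$postsynaptic_partner$neuron_id, numeric(1))
  type <- vapply(synapses, function(s) s$properties$synapse_type, character(1))
  incoming <- post == neuron_id
  n_exc <- sum(incoming & type == "excitatory")
  n_inh <- sum(incoming & type == "inhibitory")
  list(
    n_outgoing = sum(pre == neuron_id),
    n_incoming = sum(incoming),
    n_incoming_excitatory = n_exc,
    n_incoming_inhibitory = n_inh,
    ei_balance = compute_ei_balance(n_exc, n_inh)
  )
}
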