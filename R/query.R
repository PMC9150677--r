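#' Synapse-type selector domain
#'
#' The four selectors a question can range over: every synapse, the two
#' polarities, and synapses made onto axon initial segments (a distinguished
#' postsynaptic compartment). Selectors filter on synapse polarity or on the
#' postsynaptic target compartment.
#'
#' @return Character vector of length 4.
#' @export
synapse_selectors <- function() {
  c("all", "excitatory", "inhibitory", "onto_axon_initial_segment")
}

#' Location selector domain
#'
#' The entire volume plus each of the seven cortical layers.
#'
#' @return Character vector of length 8.
#' @export
location_domain <- function() c("whole_volume", paste0("layer_", 1:7))

location_layer <- function(location) {
  if (identical(location, "whole_volume")) return(NA_real_)
  m <- regmatches(location, regexec("^layer_([1-7])$", location))[[1L]]
  if (length(m) != 2L) nm_argument_error(paste0("unknown location '", location, "'"))
  as.numeric(m[[2L]])
}

check_selector <- function(type_sel) {
  if (!type_sel %in% synapse_selectors()) {
    nm_argument_error(paste0("unknown synapse selector '", type_sel, "'"))
  }
  type_sel
}

# logical mask over the synapse frame for a selector
selector_mask <- function(sf, type_sel) {
  switch(check_selector(type_sel),
    all = rep(TRUE, nrow(sf)),
    excitatory = sf$type == "excitatory",
    inhibitory = sf$type == "inhibitory",
    onto_axon_initial_segment = sf$compartment == "axon_initial_segment")
}

# logical mask over a frame with a `layer` column for a location; synapses or
# neurons without a layer belong to the whole volume but to no single layer
location_mask <- function(fr, location) {
  k <- location_layer(location)
  if (is.na(k)) rep(TRUE, nrow(fr)) else !is.na(fr$layer) & fr$layer == k
}

require_layers <- function(store) {
  ids <- store_frame(store, "layer")$id
  if (!all(1:7 %in% ids)) {
    nm_config_error("store must contain all seven layer entities")
  }
}

#' Q1: count synapses of a type in a location
#'
#' Synapses without a layer assignment count toward the whole volume but are
#' excluded from every single-layer location.
#'
#' @param store A [metadata_store()].
#' @param type_sel One of [synapse_selectors()].
#' @param location One of [location_domain()].
#' @return Integer count.
#' @export
q1_count_synapses <- function(store, type_sel = "all", location = "whole_volume") {
  if (is.null(store$collections[["synapse"]])) {
    check_selector(type_sel); location_layer(location)
    return(0L)
  }
  sf <- store_frame(store, "synapse")
  sum(selector_mask(sf, type_sel) & location_mask(sf, location))
}

#' Q2: the layer with the most (or fewest) synapses of a type
#'
#' @inheritParams q1_count_synapses
#' @param extremum `"most"` or `"fewest"`.
#' @return List with `layer_id` and `count`; ties resolve to the lowest
#'   layer id. All seven layer entities must exist.
#' @export
q2_layer_extremum <- function(store, extremum = c("most", "fewest"), type_sel = "all") {
  extremum <- match.arg(extremum)
  require_layers(store)
  counts <- vapply(1:7, function(k) {
    as.numeric(q1_count_synapses(store, type_sel, paste0("layer_", k)))
  }, numeric(1))
  k <- if (extremum == "most") which.max(counts) else which.min(counts)
  list(layer_id = as.numeric(k), count = counts[[k]])
}

#' Q3: the width of a layer
#'
#' @inheritParams q1_count_synapses
#' @param layer_id Layer number 1..7.
#' @return The stored width in nanometers; unknown layers raise
#'   `nm_not_found`.
#' @export
q3_layer_width <- function(store, layer_id) {
  rec <- endpoint_get_layer(store, layer_id)
  rec$properties$width
}

#' Q4: average or total neuron length in a location
#'
#' Neuron length is proxied by the sum of the six per-compartment skeleton
#' node counts multiplied by the store's node spacing. Neurons without a
#' layer assignment belong to the whole volume only. The average over zero
#' neurons is undefined (`NA`); the total over zero neurons is 0.
#'
#' @inheritParams q1_count_synapses
#' @param aggregate `"average"` or `"total"`.
#' @return A double, possibly `NA`.
#' @export
q4_neuron_length <- function(store, aggregate = c("average", "total"),
                             location = "whole_volume") {
  aggregate <- match.arg(aggregate)
  if (is.null(store$collections[["neuron"]])) {
    location_layer(location)
    return(if (aggregate == "total") 0 else NA_real_)
  }
  nf <- store_frame(store, "neuron")
  lens <- nf$skeleton_nodes[location_mask(nf, location)] * store$node_spacing
  if (aggregate == "total") sum(lens)
  else if (length(lens) == 0L) NA_real_
  else mean(lens)
}

# incoming synapse counts per neuron under a selector, as a named vector
incoming_counts <- function(store, type_sel, neuron_ids) {
  counts <- stats::setNames(rep(0, length(neuron_ids)), as.character(neuron_ids))
  if (!is.null(store$collections[["synapse"]])) {
    sf <- store_frame(store, "synapse")
    sel <- selector_mask(sf, type_sel)
    tab <- table(as.character(sf$post[sel]))
    hit <- intersect(names(tab), names(counts))
    counts[hit] <- as.numeric(tab[hit])
  } else {
    check_selector(type_sel)
  }
  counts
}

#' Q5: the neuron with the greatest number of incoming synapses of a type
#'
#' Counts are tallied from the synapse collection (incoming means the neuron
#' is the postsynaptic partner); the neuron must belong to the location.
#'
#' @inheritParams q2_layer_extremum
#' @return List with `neuron_id` and `count` (ties to the lowest neuron id),
#'   or `NULL` when the location contains no neurons.
#' @export
q5_top_neuron <- function(store, type_sel = "all", location = "whole_volume") {
  check_selector(type_sel)
  if (is.null(store$collections[["neuron"]])) {
    location_layer(location)
    return(NULL)
  }
  nf <- store_frame(store, "neuron")
  ids <- sort(nf$id[location_mask(nf, location)])
  if (length(ids) == 0L) return(NULL)
  counts <- incoming_counts(store, type_sel, ids)
  best <- which.max(counts) # first maximum; ids sorted ascending
  list(neuron_id = ids[[best]], count = unname(counts[[best]]))
}

#' Q6: a neuron with E/(E+I) balance nearest a target value
#'
#' Among neurons in the location whose balance is defined, returns the one
#' minimizing the absolute difference to `value` (ties to the lowest id).
#'
#' @inheritParams q1_count_synapses
#' @param value Target balance in \[0, 1\].
#' @return List with `neuron_id` and `ei_balance`, or `NULL` when no neuron
#'   in the location has a defined balance.
#' @export
q6_find_neuron_by_balance <- function(store, value, location = "whole_volume") {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value > 1) {
    nm_argument_error("balance value must lie in [0, 1]")
  }
  if (is.null(store$collections[["neuron"]])) {
    location_layer(location)
    return(NULL)
  }
  nf <- store_frame(store, "neuron")
  nf <- nf[location_mask(nf, location) & !is.na(nf$ei_balance), , drop = FALSE]
  if (nrow(nf) == 0L) return(NULL)
  nf <- nf[order(abs(nf$ei_balance - value), nf$id), , drop = FALSE]
  list(neuron_id = nf$id[[1L]], ei_balance = nf$ei_balance[[1L]])
}

#' Q7: all neurons with E/(E+I) balance above (or below) a value
#'
#' Strict inequality; neurons with undefined balance are excluded.
#'
#' @inheritParams q6_find_neuron_by_balance
#' @param direction `"greater"` or `"less"`.
#' @return Numeric vector of neuron ids, sorted ascending.
#' @export
q7_list_neurons_by_balance <- function(store, direction = c("greater", "less"),
                                       value, location = "whole_volume") {
  direction <- match.arg(direction)
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value > 1) {
    nm_argument_error("balance value must lie in [0, 1]")
  }
  if (is.null(store$collections[["neuron"]])) {
    location_layer(location)
    return(numeric(0))
  }
  nf <- store_frame(store, "neuron")
  keep <- location_mask(nf, location) & !is.na(nf$ei_balance) &
    (if (direction == "greater") nf$ei_balance > value else nf$ei_balance < value)
  sort(nf$id[keep])
}

# ---- question catalog --------------------------------------------------------

#' Construct one parameterization of a question template
#'
#' @param template_id `"Q1"` .. `"Q7"`.
#' @param params Named list of template parameters (see the `qN` functions);
#'   Q6/Q7 may leave `value` as `NULL` to be bound at ask time.
#' @return A `question_instance`.
#' @export
question_instance <- function(template_id, params) {
  structure(list(template_id = template_id, params = params),
            class = "question_instance")
}

#' @export
print.question_instance <- function(x, ...) {
  ps <- vapply(names(x$params), function(k) {
    paste0(k, "=", x$params[[k]] %||% "<free>")
  }, character(1))
  cat(sprintf("<question %s> %s\n", x$template_id, paste(ps, collapse = " ")))
  invisible(x)
}

#' Enumerate the full question catalog
#'
#' Expands the seven question templates over their default parameter domains
#' (four synapse-type selectors, eight locations, the seven layers, the
#' most/fewest, average/total and greater/less binary slots). The free
#' numeric balance slot of Q6/Q7 contributes one catalog instance per
#' discrete parameter combination; the value is supplied when the question
#' is asked. The expansion yields
#' 4·8 + 2·4 + 7 + 2·8 + 4·8 + 8 + 2·8 = 119 unique instances.
#'
#' @param selectors Synapse-type selector domain (default the full
#'   four-member domain).
#' @param locations Location domain (default whole volume + seven layers).
#' @return List of `question_instance` objects — 119 under the default
#'   domains — in template order; enumeration is deterministic and
#'   duplicate-free.
#' @export
#' @examples
#' length(enumerate_question_catalog())
enumerate_question_catalog <- function(selectors = synapse_selectors(),
                                       locations = location_domain()) {
  out <- list()
  add <- function(template_id, params) {
    out[[length(out) + 1L]] <<- question_instance(template_id, params)
  }
  for (t in selectors) for (l in locations) {
    add("Q1", list(type_sel = t, location = l))
  }
  for (e in c("most", "fewest")) for (t in selectors) {
    add("Q2", list(extremum = e, type_sel = t))
  }
  for (k in 1:7) add("Q3", list(layer_id = k))
  for (a in c("average", "total")) for (l in locations) {
    add("Q4", list(aggregate = a, location = l))
  }
  for (t in selectors) for (l in locations) {
    add("Q5", list(type_sel = t, location = l))
  }
  for (l in locations) add("Q6", list(value = NULL, location = l))
  for (d in c("greater", "less")) for (l in locations) {
    add("Q7", list(direction = d, value = NULL, location = l))
  }
  out
}

#' Answer a catalog question against a store
#'
#' Dispatches a [question_instance()] to the matching template
#' implementation. Questions with a free numeric slot (Q6, Q7) take the
#' balance through `value` unless already bound in the instance.
#'
#' @param store A [metadata_store()].
#' @param question A `question_instance`.
#' @param value Balance in \[0, 1\] for Q6/Q7 instances whose slot is free.
#' @return A `query_result`: list with the echoed `question` and the typed
#'   `result` (`NA`/`NULL` encode an undefined or empty answer).
#' @export
answer <- function(store, question, value = NULL) {
  if (!inherits(question, "question_instance") ||
      !is_scalar_string(question$template_id %||% "")) {
    nm_argument_error("malformed question instance")
  }
  p <- question$params
  res <- switch(question$template_id,
    Q1 = q1_count_synapses(store, p$type_sel, p$location),
    Q2 = q2_layer_extremum(store, p$extremum, p$type_sel),
    Q3 = q3_layer_width(store, p$layer_id),
    Q4 = q4_neuron_length(store, p$aggregate, p$location),
    Q5 = q5_top_neuron(store, p$type_sel, p$location),
    Q6 = q6_find_neuron_by_balance(store, p$value %||% value %||%
      nm_argument_error("Q6 requires a balance value"), p$location),
    Q7 = q7_list_neurons_by_balance(store, p$direction, p$value %||% value %||%
      nm_argument_error("Q7 requires a balance value"), p$location),
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

#' @export
print.query_result <- function(x, ...) {
  print(x$question)
  cat("  result: ")
  utils::str(x$result, give.attr = FALSE)
  invisible(x)
}

#' Compare two query results for semantic equality
#'
#' Results are equal when they answer the same template and their typed
#' payloads match: numeric scalars to within `tol`, `NA`/`NULL` (undefined /
#' empty) only to themselves, lists field-for-field, id vectors elementwise.
#'
#' @param a,b `query_result` objects.
#' @param tol Numeric tolerance.
#' @return TRUE or FALSE.
#' @export
query_results_equal <- function(a, b, tol = 1e-9) {
  if (!identical(a$question$template_id, b$question$template_id)) return(FALSE)
  payload_equal(a$result, b$result, tol)
}

payload_equal <- function(x, y, tol) {
  if (is.null(x) || is.null(y)) return(is.null(x) && is.null(y))
  if (is.list(x) || is.list(y)) {
    if (!is.list(x) || !is.list(y)) return(FALSE)
    if (!setequal(names(x), names(y))) return(FALSE)
    for (k in names(x)) if (!payload_equal(x[[k]], y[[k]], tol)) return(FALSE)
    return(TRUE)
  }
  if (length(x) != length(y)) return(FALSE)
  if (length(x) == 0L) return(TRUE)
  if (is.numeric(x) && is.numeric(y)) {
    na_x <- is.na(x); na_y <- is.na(y)
    if (!identical(na_x, na_y)) return(FALSE)
    return(all(abs(x[!na_x] - y[!na_y]) <= tol))
  }
  isTRUE(all(x == y))
}
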