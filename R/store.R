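indexed_fields <- function(class) {
  switch(class,
    neuron = "layer",
    synapse = c("layer", "synapse_type",
                "presynaptic_site.neuron_id", "postsynaptic_partner.neuron_id"),
    character(0))
}

#' Create an in-memory metadata store
#'
#' A document-oriented store holding one collection per entity class: the
#' three community collections (`neuron`, `synapse`, `layer`) plus any
#' user-defined collections. Every inserted record is validated against the
#' registry; secondary indexes are maintained on entity id, layer, synapse
#' polarity and pre/postsynaptic partner ids, and always agree with a full
#' scan. The store persists to one JSON Lines file per collection plus a
#' dataset header (see [save_store()] / [load_store()]).
#'
#' @param dataset_id Dataset identifier written into the header and records.
#' @param registry A [schema_registry()]; defaults to a fresh one.
#' @param resolution Voxel resolution in nanometers, 3-vector (x, y, z).
#' @param node_spacing Physical spacing represented by one skeleton node, in
#'   the unit neuron lengths should be reported in (default 1.0).
#' @return A `metadata_store` object (an environment, modified in place by
#'   [insert()]).
#' @export
#' @examples
#' store <- metadata_store("demo")
#' insert(store, layer_record(1, 150000, dataset_id = "demo"))
#' endpoint_get_layer(store, 1)
metadata_store <- function(dataset_id = "local", registry = schema_registry(),
                           resolution = c(8, 8, 33), node_spacing = 1.0) {
  store <- new.env(parent = emptyenv())
  store$dataset_id <- dataset_id
  store$registry <- registry
  store$resolution <- as.numeric(resolution)
  store$node_spacing <- as.numeric(node_spacing)
  store$collections <- list()
  store$indexes <- list()
  store$frames <- list()
  class(store) <- "metadata_store"
  store
}

#' @export
print.metadata_store <- function(x, ...) {
  cat(sprintf("<metadata_store> dataset=%s\n", x$dataset_id))
  for (cl in names(x$collections)) {
    cat(sprintf("  %-10s %d document(s)\n", cl, length(x$collections[[cl]])))
  }
  invisible(x)
}

#' Insert a record into the store
#'
#' The record must validate against the store's registry (warnings are
#' tolerated, errors reject the insert) and its entity id must be unique
#' within its collection. On rejection the store is left unchanged.
#'
#' @param store A [metadata_store()].
#' @param record An [entity_record()].
#' @return The store, invisibly.
#' @export
insert <- function(store, record) {
  stopifnot(inherits(store, "metadata_store"))
  rep <- validate_entity(record, store$registry)
  if (!rep$valid) {
    nm_validation_error(paste0(
      "record '", record$entity_id %||% "?", "' failed validation: ",
      paste(rep$issues$message[rep$issues$severity == "error"], collapse = "; ")))
  }
  cl <- record$entity_class
  if (is.null(store$collections[[cl]])) {
    store$collections[[cl]] <- list()
    idx <- new.env(parent = emptyenv())
    for (f in indexed_fields(cl)) assign(f, new.env(parent = emptyenv()), envir = idx)
    store$indexes[[cl]] <- idx
  }
  id <- record$entity_id
  if (!is.null(store$collections[[cl]][[id]])) {
    nm_validation_error(paste0("duplicate entity_id '", id, "' in collection '", cl, "'"))
  }
  store$collections[[cl]][[id]] <- record
  idx <- store$indexes[[cl]]
  for (f in indexed_fields(cl)) {
    val <- record_field(record, f)
    if (!is.null(val)) {
      key <- as.character(val)
      fe <- get(f, envir = idx)
      fe[[key]] <- c(fe[[key]], id)
    }
  }
  store$frames[[cl]] <- NULL
  invisible(store)
}

#' Insert several records
#' @inheritParams insert
#' @param records List of entity records.
#' @return The store, invisibly.
#' @export
insert_records <- function(store, records) {
  for (rec in records) insert(store, rec)
  invisible(store)
}

collection_ids <- function(store, class) {
  names(store$collections[[class]]) %||% character(0)
}

get_record <- function(store, class, id) {
  store$collections[[class]][[as.character(id)]]
}

# Flattened per-collection data-frame view of the query-relevant columns,
# cached until the next insert; queries and tallies run off this frame.
store_frame <- function(store, class) {
  fr <- store$frames[[class]]
  if (!is.null(fr)) return(fr)
  recs <- store$collections[[class]] %||% list()
  fr <- switch(class,
    synapse = {
      grab <- function(f) vapply(recs, f, numeric(1))
      data.frame(
        id = vapply(recs, function(r) r$entity_id, character(1)),
        type = vapply(recs, function(r) r$properties$synapse_type, character(1)),
        layer = vapply(recs, function(r) r$properties$layer %||% NA_real_, numeric(1)),
        pre = grab(function(r) r$properties$presynaptic_site$neuron_id),
        post = grab(function(r) r$properties$postsynaptic_partner$neuron_id),
        compartment = vapply(recs, function(r) r$properties$postsynaptic_partner$compartment,
                             character(1)),
        stringsAsFactors = FALSE
      )
    },
    neuron = {
      nodes <- function(r) {
        p <- r$properties
        p$n_dendrite_skeleton_nodes + p$n_axon_skeleton_nodes +
          p$n_dendritic_spine_skeleton_nodes + p$n_cilia_skeleton_nodes +
          p$n_ais_skeleton_nodes + p$n_myelinated_axon_skeleton_nodes
      }
      data.frame(
        id = vapply(recs, function(r) r$properties$neuron_id, numeric(1)),
        layer = vapply(recs, function(r) r$properties$layer %||% NA_real_, numeric(1)),
        ei_balance = vapply(recs, function(r) r$properties$ei_balance %||% NA_real_, numeric(1)),
        skeleton_nodes = vapply(recs, nodes, numeric(1)),
        n_incoming = vapply(recs, function(r) r$properties$n_incoming_synapses, numeric(1)),
        n_outgoing = vapply(recs, function(r) r$properties$n_outgoing_synapses, numeric(1)),
        stringsAsFactors = FALSE
      )
    },
    layer = data.frame(
      id = vapply(recs, function(r) r$properties$layer_id, numeric(1)),
      width = vapply(recs, function(r) r$properties$width, numeric(1)),
      stringsAsFactors = FALSE
    ),
    nm_argument_error(paste0("no frame view for class ", class))
  )
  store$frames[[class]] <- fr
  fr
}

# ---- filter predicates -------------------------------------------------------

filter_comparators <- function() c("eq", "lt", "gt", "le", "ge", "in")

#' Build a filter clause
#'
#' @param key Dotted document key (e.g. `"postsynaptic_partner.compartment"`).
#' @param op Comparator: one of `eq`, `lt`, `gt`, `le`, `ge`, `in`.
#' @param value Comparison value (a vector for `in`).
#' @return A filter clause for [filter_predicate()].
#' @export
where <- function(key, op, value) {
  if (!op %in% filter_comparators()) {
    nm_argument_error(paste0("unknown comparator '", op, "'"))
  }
  if (!is_scalar_string(key)) nm_argument_error("filter key must be a non-empty string")
  structure(list(key = key, op = op, value = value), class = "nm_clause")
}

#' Conjunction of filter clauses
#'
#' A record matches when every clause matches; an empty predicate matches
#' everything. Clauses address top-level document keys or descend into nested
#' documents along dots.
#'
#' @param ... Clauses built with [where()].
#' @return A `filter_predicate`.
#' @export
#' @examples
#' filter_predicate(where("synapse_type", "eq", "excitatory"),
#'                  where("layer", "eq", 2))
filter_predicate <- function(...) {
  clauses <- list(...)
  if (length(clauses) == 1L && is.list(clauses[[1L]]) &&
      !inherits(clauses[[1L]], "nm_clause")) {
    clauses <- clauses[[1L]]
  }
  for (cl in clauses) {
    if (!inherits(cl, "nm_clause")) nm_argument_error("clauses must be built with where()")
  }
  structure(clauses, class = "filter_predicate")
}

clause_matches <- function(record, clause) {
  val <- record_field(record, clause$key)
  if (is.null(val)) return(FALSE)
  if (length(val) != 1L && clause$op != "in") return(FALSE)
  switch(clause$op,
    eq = isTRUE(val == clause$value),
    lt = isTRUE(val < clause$value),
    gt = isTRUE(val > clause$value),
    le = isTRUE(val <= clause$value),
    ge = isTRUE(val >= clause$value),
    `in` = isTRUE(val %in% clause$value))
}

predicate_matches <- function(record, predicate) {
  if (is.null(predicate) || length(predicate) == 0L) return(TRUE)
  for (cl in predicate) if (!clause_matches(record, cl)) return(FALSE)
  TRUE
}

# Candidate ids via the first equality clause on an indexed field, narrowed
# by scanning the remaining clauses; falls back to a full scan.
filter_collection <- function(store, class, predicate) {
  recs <- store$collections[[class]] %||% list()
  ids <- names(recs)
  if (!is.null(predicate) && length(predicate) > 0L) {
    idx <- store$indexes[[class]]
    if (!is.null(idx)) {
      for (cl in predicate) {
        if (cl$op == "eq" && cl$key %in% indexed_fields(class)) {
          fe <- get(cl$key, envir = idx)
          ids <- fe[[as.character(cl$value)]] %||% character(0)
          break
        }
      }
    }
  }
  keep <- vapply(ids, function(id) predicate_matches(recs[[id]], predicate), logical(1))
  out_ids <- order_ids(ids[keep])
  unname(recs[out_ids])
}

# ---- the eight retrieval endpoints ------------------------------------------

#' The retrieval endpoint surface
#'
#' Names of the eight retrieval operations through which stored neuron,
#' synapse and layer metadata is accessed; each is exported as a library
#' function and mirrored by the CLI.
#'
#' @return Character vector of length 8.
#' @export
list_endpoints <- function() {
  c("get_neuron", "list_neurons", "get_synapse", "list_synapses",
    "get_layer", "list_layers", "neuron_synapses", "summary")
}

endpoint_get <- function(store, class, id) {
  rec <- get_record(store, class, id)
  if (is.null(rec)) {
    nm_not_found(paste0(class, " '", id, "' not found in dataset ", store$dataset_id))
  }
  rec
}

#' Retrieve one neuron document by id
#' @param store A [metadata_store()].
#' @param neuron_id Neuron identifier.
#' @return The [entity_record()]; unknown ids raise an `nm_not_found` error
#'   (distinct from an empty filter result).
#' @export
endpoint_get_neuron <- function(store, neuron_id) endpoint_get(store, "neuron", neuron_id)

#' List neuron documents matching a filter
#' @inheritParams endpoint_get_neuron
#' @param filter A [filter_predicate()] or `NULL` for all.
#' @return List of records, stable-ordered by entity id.
#' @export
endpoint_list_neurons <- function(store, filter = NULL) {
  filter_collection(store, "neuron", filter)
}

#' Retrieve one synapse document by id
#' @inheritParams endpoint_get_neuron
#' @param synapse_id Synapse identifier.
#' @export
endpoint_get_synapse <- function(store, synapse_id) endpoint_get(store, "synapse", synapse_id)

#' List synapse documents matching a filter
#' @inheritParams endpoint_list_neurons
#' @export
endpoint_list_synapses <- function(store, filter = NULL) {
  filter_collection(store, "synapse", filter)
}

#' Retrieve one cortical layer document
#' @inheritParams endpoint_get_neuron
#' @param layer_id Layer number 1..7.
#' @export
endpoint_get_layer <- function(store, layer_id) endpoint_get(store, "layer", layer_id)

#' List all cortical layer documents
#' @inheritParams endpoint_get_neuron
#' @export
endpoint_list_layers <- function(store) filter_collection(store, "layer", NULL)

#' List the synapses of one neuron
#'
#' Uses the presynaptic/postsynaptic partner indexes: `outgoing` synapses
#' have the neuron as presynaptic site, `incoming` as postsynaptic partner,
#' `both` is their union.
#'
#' @inheritParams endpoint_get_neuron
#' @param direction `"incoming"`, `"outgoing"` or `"both"`.
#' @return List of synapse records, stable-ordered by entity id. The neuron
#'   must exist (`nm_not_found` otherwise); a neuron without synapses yields
#'   an empty list.
#' @export
endpoint_neuron_synapses <- function(store, neuron_id,
                                     direction = c("both", "incoming", "outgoing")) {
  direction <- match.arg(direction)
  endpoint_get(store, "neuron", neuron_id) # not-found check
  idx <- store$indexes[["synapse"]]
  key <- as.character(as.numeric(neuron_id))
  ids <- character(0)
  if (!is.null(idx)) {
    if (direction %in% c("outgoing", "both")) {
      ids <- c(ids, get("presynaptic_site.neuron_id", envir = idx)[[key]] %||% character(0))
    }
    if (direction %in% c("incoming", "both")) {
      ids <- c(ids, get("postsynaptic_partner.neuron_id", envir = idx)[[key]] %||% character(0))
    }
  }
  ids <- order_ids(unique(ids))
  unname(store$collections[["synapse"]][ids])
}

#' Summarize a dataset
#'
#' Exact scan tallies: per-collection document counts, per-layer neuron and
#' synapse tallies, and the number of synapses without a layer assignment
#' (so that per-layer synapse tallies plus the unassigned count reproduce the
#' total).
#'
#' @inheritParams endpoint_get_neuron
#' @return A `dataset_summary` list.
#' @export
endpoint_summary <- function(store) {
  counts <- vapply(store$collections, length, integer(1))
  sf <- if (!is.null(store$collections[["synapse"]])) store_frame(store, "synapse") else NULL
  nf <- if (!is.null(store$collections[["neuron"]])) store_frame(store, "neuron") else NULL
  per_layer <- function(fr) {
    if (is.null(fr)) return(stats::setNames(rep(0L, 7L), paste0("layer_", 1:7)))
    stats::setNames(vapply(1:7, function(k) sum(!is.na(fr$layer) & fr$layer == k),
                           integer(1)), paste0("layer_", 1:7))
  }
  structure(list(
    dataset_id = store$dataset_id,
    collection_counts = as.list(counts),
    synapses_per_layer = per_layer(sf),
    neurons_per_layer = per_layer(nf),
    synapses_unassigned_layer = if (is.null(sf)) 0L else sum(is.na(sf$layer)),
    neurons_unassigned_layer = if (is.null(nf)) 0L else sum(is.na(nf$layer))
  ), class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat(sprintf("<dataset_summary> %s\n", x$dataset_id))
  for (cl in names(x$collection_counts)) {
    cat(sprintf("  %-10s %d\n", cl, x$collection_counts[[cl]]))
  }
  cat("  synapses/layer:", paste(x$synapses_per_layer, collapse = " "),
      "| unassigned:", x$synapses_unassigned_layer, "\n")
  invisible(x)
}
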