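#' Default integer code tables
#'
#' Disk formats in connectomics dumps encode categorical attributes as small
#' integers; the package keeps symbolic values internally and translates at the
#' import/export boundary. The defaults can be overridden by a code-table
#' config (YAML/JSON) naming the same three tables.
#'
#' @return A named list of named character vectors mapping integer codes
#'   (as names) to symbols, for `synapse_type`, `neuron_type` and
#'   `compartment`.
#' @export
#' @examples
#' default_code_tables()$synapse_type
default_code_tables <- function() {
  list(
    synapse_type = c(`0` = "unknown", `1` = "excitatory", `2` = "inhibitory"),
    neuron_type = c(`0` = "unclassified", `1` = "pyramidal",
                    `2` = "interneuron", `3` = "glia"),
    compartment = c(`0` = "unknown", `1` = "dendrite_shaft",
                    `2` = "dendritic_spine", `3` = "soma",
                    `4` = "axon_initial_segment")
  )
}

community_classes <- function() c("neuron", "synapse", "layer")

link_relations <- function() {
  c("parent", "child", "sibling", "presynaptic_neuron",
    "postsynaptic_neuron", "member_of_layer")
}

data_representations <- function() c("skeleton", "mesh", "pixels", "table", "none")

compartment_levels <- function() {
  c("dendrite_shaft", "dendritic_spine", "soma", "axon_initial_segment", "unknown")
}

# ---- property-type conformance -----------------------------------------------

check_type <- function(value, type) {
  switch(type,
    integer = ,
    long = is.numeric(value) && length(value) == 1L && !is.na(value) &&
      value == trunc(value),
    double = is.numeric(value) && length(value) == 1L && !is.na(value),
    string = is.character(value) && length(value) == 1L && !is.na(value),
    boolean = is.logical(value) && length(value) == 1L && !is.na(value),
    object = is.list(value),
    int3 = is.numeric(value) && length(value) == 3L && !anyNA(value) &&
      all(value == trunc(value)),
    box = is.list(value) && all(c("min", "max") %in% names(value)) &&
      check_type(value$min, "int3") && check_type(value$max, "int3"),
    nm_argument_error(paste0("unknown property type: ", type))
  )
}

# ---- registry ----------------------------------------------------------------

#' Community schema registry
#'
#' Builds the registry of entity-class schemas. The three community-defined
#' classes (`neuron`, `synapse`, `layer`) are pre-registered with their
#' minimum required properties; additional user-defined classes can be added
#' with [register_entity_class()] but can never shadow a community class.
#'
#' Each schema consists of an identifier property (mirroring the document's
#' `entity_id`), required properties, optional properties (attributes that a
#' record may legitimately leave undefined, such as a neuron's layer), and a
#' class-specific consistency check.
#'
#' @param code_tables Integer code tables, see [default_code_tables()].
#' @return An object of class `schema_registry`.
#' @export
#' @examples
#' reg <- schema_registry()
#' schema_slots(reg, "synapse")   # the seven synapse attribute slots
schema_registry <- function(code_tables = default_code_tables()) {
  reg <- new.env(parent = emptyenv())
  reg$classes <- list()
  reg$code_tables <- code_tables
  class(reg) <- "schema_registry"

  register_class_impl(
    reg, "neuron",
    id_property = c(neuron_id = "integer"),
    required = c(
      volume = "long",
      n_outgoing_synapses = "integer",
      n_incoming_synapses = "integer",
      n_incoming_excitatory = "integer",
      n_incoming_inhibitory = "integer",
      n_dendrite_skeleton_nodes = "integer",
      n_axon_skeleton_nodes = "integer",
      n_dendritic_spine_skeleton_nodes = "integer",
      n_cilia_skeleton_nodes = "integer",
      n_ais_skeleton_nodes = "integer",
      n_myelinated_axon_skeleton_nodes = "integer",
      neuron_type = "string"
    ),
    optional = c(spinyness = "double", layer = "integer", ei_balance = "double"),
    community = TRUE, check = check_neuron
  )
  register_class_impl(
    reg, "synapse",
    id_property = c(synapse_id = "string"),
    required = c(
      synapse_type = "string",
      presynaptic_site = "object",
      postsynaptic_partner = "object",
      location = "int3",
      bounding_box = "box"
    ),
    optional = c(layer = "integer"),
    community = TRUE, check = check_synapse
  )
  register_class_impl(
    reg, "layer",
    id_property = c(layer_id = "integer"),
    required = c(width = "long"),
    optional = character(0),
    community = TRUE, check = check_layer
  )
  reg
}

register_class_impl <- function(reg, name, id_property, required, optional,
                                community, check = NULL) {
  reg$classes[[name]] <- list(
    name = name,
    id_property = id_property,
    required = required,
    optional = optional,
    community = community,
    check = check
  )
  invisible(reg)
}

#' Register a user-defined entity class
#'
#' Data owners can declare entity classes beyond the community-defined trio
#' (e.g. `blood_vessel`, `mitochondrion`). Subsequent validation honours the
#' new schema. Community classes are protected and cannot be redefined.
#'
#' @param registry A [schema_registry()].
#' @param name Class name; must not be `neuron`, `synapse` or `layer`.
#' @param required Named character vector `key = type` of required properties.
#'   Types: `integer`, `long`, `double`, `string`, `boolean`, `object`,
#'   `int3`, `box`.
#' @param optional Named character vector of optional properties.
#' @param id_property Optional named character vector (length 1) naming the
#'   identifier property and its type; defaults to `<name>_id` of type string.
#' @return The registry, invisibly (it is modified in place).
#' @export
#' @examples
#' reg <- schema_registry()
#' register_entity_class(reg, "mitochondrion", required = c(parent_neuron = "integer"))
register_entity_class <- function(registry, name, required = character(0),
                                  optional = character(0), id_property = NULL) {
  stopifnot(inherits(registry, "schema_registry"))
  if (!is_scalar_string(name)) nm_argument_error("class name must be a non-empty string")
  if (name %in% community_classes()) {
    nm_argument_error(paste0("'", name, "' is a community-defined class and cannot be redefined"))
  }
  if (is.null(id_property)) {
    id_property <- stats::setNames("string", paste0(name, "_id"))
  }
  required <- as_schema_vec(required)
  optional <- as_schema_vec(optional)
  register_class_impl(registry, name, id_property, required, optional,
                      community = FALSE, check = NULL)
  invisible(registry)
}

as_schema_vec <- function(x) {
  if (length(x) == 0L) return(character(0))
  if (is.list(x)) x <- unlist(x)
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    nm_argument_error("schema properties must be a named vector of key = type")
  }
  x
}

#' Count the attribute slots of a registered schema
#'
#' The slot count is the identifier property plus every required and optional
#' property: the synapse schema exposes seven slots, the neuron schema sixteen.
#'
#' @param registry A [schema_registry()].
#' @param class Entity class name.
#' @return Integer number of attribute slots.
#' @export
schema_slots <- function(registry, class) {
  sch <- registry$classes[[class]]
  if (is.null(sch)) nm_not_found(paste0("unknown entity class: ", class))
  length(sch$id_property) + length(sch$required) + length(sch$optional)
}

#' Required non-identifier attributes of a schema
#' @inheritParams schema_slots
#' @return Character vector of required property keys (identifier excluded).
#' @export
schema_required <- function(registry, class) {
  sch <- registry$classes[[class]]
  if (is.null(sch)) nm_not_found(paste0("unknown entity class: ", class))
  names(sch$required)
}

#' @export
print.schema_registry <- function(x, ...) {
  cat("<schema_registry> classes:\n")
  for (cl in names(x$classes)) {
    sch <- x$classes[[cl]]
    cat(sprintf("  %-14s %s  slots=%d (required=%d, optional=%d)\n",
                cl, if (sch$community) "[community]" else "[user]",
                length(sch$id_property) + length(sch$required) + length(sch$optional),
                length(sch$required), length(sch$optional)))
  }
  invisible(x)
}

# ---- entity records ----------------------------------------------------------

#' Construct a standardized entity record
#'
#' An entity record is the generic standardized annotation document: an
#' identifier, an entity class, a URI locating the source data, a data
#' representation, links to related entities, and an open key-value property
#' map. Community-classed records must satisfy their registered minimum
#' property set (checked by [validate_entity()], and enforced on insertion
#' into a [metadata_store()]).
#'
#' @param entity_id Identifier, unique within `(dataset_id, entity_class)`.
#' @param entity_class `"neuron"`, `"synapse"`, `"layer"`, or a user class.
#' @param properties Named list of property values.
#' @param uri Locator; defaults to the dataset-local
#'   `<dataset>/<class>/<id>` form.
#' @param representation One of `skeleton`, `mesh`, `pixels`, `table`, `none`.
#' @param links List of `list(relation =, target =)` entries; relations are
#'   drawn from the closed set `parent`, `child`, `sibling`,
#'   `presynaptic_neuron`, `postsynaptic_neuron`, `member_of_layer`.
#' @param dataset_id Dataset the record belongs to.
#' @return An object of class `entity_record` (a named list).
#' @export
entity_record <- function(entity_id, entity_class, properties = list(),
                          uri = NULL, representation = "table",
                          links = list(), dataset_id = "local") {
  entity_id <- as.character(entity_id)
  if (!is_scalar_string(entity_id)) nm_argument_error("entity_id must be non-empty")
  if (!is_scalar_string(entity_class)) nm_argument_error("entity_class must be non-empty")
  uri <- uri %||% paste(dataset_id, entity_class, entity_id, sep = "/")
  properties <- properties[!vapply(properties, is.null, logical(1))]
  rec <- list(
    entity_id = entity_id,
    entity_class = entity_class,
    uri = uri,
    representation = representation,
    links = links,
    dataset_id = dataset_id,
    properties = properties
  )
  class(rec) <- "entity_record"
  rec
}

#' @export
print.entity_record <- function(x, ...) {
  cat(sprintf("<entity_record> %s/%s id=%s (%d properties, %d links)\n",
              x$dataset_id, x$entity_class, x$entity_id,
              length(x$properties), length(x$links)))
  invisible(x)
}

#' Look up a field of a record by dotted key
#'
#' Reserved document keys (`entity_id`, `entity_class`, `uri`,
#' `representation`, `links`, `dataset_id`) are addressed directly; any other
#' key resolves into the property map, descending nested documents along dots
#' (e.g. `"postsynaptic_partner.compartment"`).
#'
#' @param record An [entity_record()].
#' @param key Dotted key.
#' @return The value, or `NULL` when undefined.
#' @export
record_field <- function(record, key) {
  head <- strsplit(key, ".", fixed = TRUE)[[1L]][1L]
  if (head %in% reserved_keys()) {
    extract_path(record, key)
  } else {
    extract_path(record$properties, key)
  }
}

reserved_keys <- function() {
  c("entity_id", "entity_class", "uri", "representation", "links", "dataset_id")
}

# Convenience constructors for the three community classes -------------------

#' Construct a neuron metadata record
#'
#' Carries the community-defined neuron attributes: per-compartment skeleton
#' node counts, incoming/outgoing synapse tallies split by polarity, volume,
#' spinyness (spine nodes / dendrite nodes), cortical layer, a coded neuron
#' type, and the excitatory/inhibitory balance E/(E+I) of classified incoming
#' synapses. `spinyness` must be left `NULL` when the neuron has no dendrite
#' skeleton nodes, and `ei_balance` when it has no classified incoming
#' synapses.
#'
#' @param neuron_id Integer identifier.
#' @param volume Segmentation volume in voxels.
#' @param n_outgoing_synapses,n_incoming_synapses Total synapse tallies.
#' @param n_incoming_excitatory,n_incoming_inhibitory Classified incoming
#'   tallies; their sum may be below `n_incoming_synapses` (unclassified
#'   synapses are permitted).
#' @param n_dendrite_skeleton_nodes,n_axon_skeleton_nodes,n_dendritic_spine_skeleton_nodes,n_cilia_skeleton_nodes,n_ais_skeleton_nodes,n_myelinated_axon_skeleton_nodes
#'   Per-compartment skeleton node counts.
#' @param neuron_type Symbolic cell type (see [default_code_tables()]).
#' @param spinyness,layer,ei_balance Optional derived/assigned attributes;
#'   `NULL` means undefined.
#' @param ... Extra user-defined properties.
#' @inheritParams entity_record
#' @return An `entity_record` of class `neuron`.
#' @export
neuron_record <- function(neuron_id, volume = 0,
                          n_outgoing_synapses = 0, n_incoming_synapses = 0,
                          n_incoming_excitatory = 0, n_incoming_inhibitory = 0,
                          n_dendrite_skeleton_nodes = 0, n_axon_skeleton_nodes = 0,
                          n_dendritic_spine_skeleton_nodes = 0,
                          n_cilia_skeleton_nodes = 0, n_ais_skeleton_nodes = 0,
                          n_myelinated_axon_skeleton_nodes = 0,
                          neuron_type = "unclassified",
                          spinyness = NULL, layer = NULL, ei_balance = NULL,
                          dataset_id = "local", ...) {
  props <- list(
    neuron_id = as.numeric(neuron_id), volume = as.numeric(volume),
    n_outgoing_synapses = as.numeric(n_outgoing_synapses),
    n_incoming_synapses = as.numeric(n_incoming_synapses),
    n_incoming_excitatory = as.numeric(n_incoming_excitatory),
    n_incoming_inhibitory = as.numeric(n_incoming_inhibitory),
    n_dendrite_skeleton_nodes = as.numeric(n_dendrite_skeleton_nodes),
    n_axon_skeleton_nodes = as.numeric(n_axon_skeleton_nodes),
    n_dendritic_spine_skeleton_nodes = as.numeric(n_dendritic_spine_skeleton_nodes),
    n_cilia_skeleton_nodes = as.numeric(n_cilia_skeleton_nodes),
    n_ais_skeleton_nodes = as.numeric(n_ais_skeleton_nodes),
    n_myelinated_axon_skeleton_nodes = as.numeric(n_myelinated_axon_skeleton_nodes),
    neuron_type = neuron_type,
    spinyness = if (!is.null(spinyness)) as.numeric(spinyness),
    layer = if (!is.null(layer)) as.numeric(layer),
    ei_balance = if (!is.null(ei_balance)) as.numeric(ei_balance)
  )
  extra <- list(...)
  props[names(extra)] <- extra
  entity_record(neuron_id, "neuron", properties = props,
                representation = "skeleton", dataset_id = dataset_id)
}

#' Construct a synapse metadata record
#'
#' A synapse document has exactly seven attribute slots: identifier, polarity
#' (`excitatory`/`inhibitory`, or `unknown` for unclassified), the
#' presynaptic site (neuron id + class type), the postsynaptic partner
#' (neuron id, class type, target compartment), a voxel location, a half-open
#' bounding box `[min, max)`, and an optional cortical layer.
#'
#' @param synapse_id Identifier string.
#' @param synapse_type `"excitatory"`, `"inhibitory"` or `"unknown"`.
#' @param pre_neuron,post_neuron Partner neuron ids.
#' @param pre_class,post_class Integer class-type codes of the partners.
#' @param compartment Postsynaptic target compartment.
#' @param location Integer 3-vector of voxel coordinates.
#' @param bounding_box `list(min =, max =)` of integer 3-vectors, min corner
#'   inclusive, max corner exclusive; defaults to a unit box at `location`.
#' @param layer Cortical layer 1..7, or `NULL` when unassigned.
#' @inheritParams entity_record
#' @return An `entity_record` of class `synapse`.
#' @export
synapse_record <- function(synapse_id, synapse_type, pre_neuron, post_neuron,
                           location, compartment = "unknown",
                           pre_class = 0, post_class = 0,
                           bounding_box = NULL, layer = NULL,
                           dataset_id = "local") {
  location <- as.numeric(location)
  bounding_box <- bounding_box %||% list(min = location, max = location + 1)
  props <- list(
    synapse_id = as.character(synapse_id),
    synapse_type = synapse_type,
    presynaptic_site = list(neuron_id = as.numeric(pre_neuron),
                            class_type = as.numeric(pre_class)),
    postsynaptic_partner = list(neuron_id = as.numeric(post_neuron),
                                class_type = as.numeric(post_class),
                                compartment = compartment),
    location = location,
    bounding_box = list(min = as.numeric(bounding_box$min),
                        max = as.numeric(bounding_box$max)),
    layer = if (!is.null(layer)) as.numeric(layer)
  )
  entity_record(synapse_id, "synapse", properties = props,
                representation = "pixels", dataset_id = dataset_id)
}

#' Construct a cortical layer record
#'
#' @param layer_id Layer number 1..7.
#' @param width Layer width in nanometers.
#' @inheritParams entity_record
#' @return An `entity_record` of class `layer`.
#' @export
layer_record <- function(layer_id, width, dataset_id = "local") {
  entity_record(layer_id, "layer",
                properties = list(layer_id = as.numeric(layer_id),
                                  width = as.numeric(width)),
                representation = "pixels", dataset_id = dataset_id)
}

# ---- validation --------------------------------------------------------------

issue_row <- function(severity, key, message) {
  data.frame(severity = severity, property_key = key %||% NA_character_,
             message = message, stringsAsFactors = FALSE)
}

#' Validate an entity record against the registry
#'
#' Checks the record's document structure (identifier, URI, representation,
#' link relations) and its property map against the registered schema of its
#' class: every required property must be present with a conforming type;
#' optional properties are type-checked when present; unknown extra keys are
#' reported as warnings (they are user-defined extensions), never as errors.
#' Community classes additionally run class-specific consistency checks, e.g.
#' a synapse's location must lie inside its bounding box, and a stored
#' E/(E+I) balance that disagrees with the one recomputed from the stored
#' counts by more than 1e-9 yields a warning (the stored value stays
#' authoritative).
#'
#' Validation is pure: it never mutates the record or the registry, and two
#' calls on the same inputs return identical reports.
#'
#' @param record An [entity_record()].
#' @param registry A [schema_registry()].
#' @return A `validation_report`: list with `valid` (TRUE iff no
#'   error-severity issues) and `issues` (data frame of severity,
#'   property_key, message).
#' @export
#' @examples
#' reg <- schema_registry()
#' rec <- synapse_record("s1", "excitatory", 1, 2, c(10, 20, 30), layer = 3)
#' validate_entity(rec, reg)$valid
validate_entity <- function(record, registry) {
  stopifnot(inherits(registry, "schema_registry"))
  issues <- issue_row(character(0), character(0), character(0))

  if (!inherits(record, "entity_record")) {
    return(validation_report(issue_row("error", NA, "not an entity record")))
  }
  sch <- registry$classes[[record$entity_class]]
  if (is.null(sch)) {
    return(validation_report(issue_row(
      "error", NA, paste0("unknown entity class: ", record$entity_class))))
  }

  if (!is_scalar_string(record$entity_id))
    issues <- rbind(issues, issue_row("error", "entity_id", "entity_id must be non-empty"))
  if (!valid_uri(record$uri))
    issues <- rbind(issues, issue_row("error", "uri",
      "uri must be scheme:rest or <dataset>/<collection>/<id>"))
  if (!is_scalar_string(record$representation) ||
      !record$representation %in% data_representations())
    issues <- rbind(issues, issue_row("error", "representation",
      paste0("representation must be one of ",
             paste(data_representations(), collapse = ", "))))
  for (lk in record$links) {
    if (!is.list(lk) || is.null(lk$relation) || is.null(lk$target) ||
        !lk$relation %in% link_relations() || !is_scalar_string(as.character(lk$target))) {
      issues <- rbind(issues, issue_row("error", "links", "malformed link"))
    }
  }

  props <- record$properties
  id_key <- names(sch$id_property)

  if (is.null(props[[id_key]])) {
    issues <- rbind(issues, issue_row("error", id_key,
      paste0("missing identifier property '", id_key, "'")))
  } else if (as.character(props[[id_key]]) != record$entity_id) {
    issues <- rbind(issues, issue_row("error", id_key,
      "identifier property must match entity_id"))
  }

  for (key in names(sch$required)) {
    val <- props[[key]]
    if (is.null(val)) {
      issues <- rbind(issues, issue_row("error", key,
        paste0("missing required property '", key, "'")))
    } else if (!check_type(val, sch$required[[key]])) {
      issues <- rbind(issues, issue_row("error", key,
        paste0("property '", key, "' does not conform to type ",
               sch$required[[key]])))
    }
  }
  for (key in names(sch$optional)) {
    val <- props[[key]]
    if (!is.null(val) && !check_type(val, sch$optional[[key]])) {
      issues <- rbind(issues, issue_row("error", key,
        paste0("property '", key, "' does not conform to type ",
               sch$optional[[key]])))
    }
  }

  known <- c(id_key, names(sch$required), names(sch$optional))
  for (key in setdiff(names(props), known)) {
    issues <- rbind(issues, issue_row("warning", key,
      paste0("unknown property '", key, "' treated as user-defined extension")))
  }

  if (!is.null(sch$check) && !any(issues$severity == "error")) {
    issues <- rbind(issues, sch$check(props))
  }
  validation_report(issues)
}

validation_report <- function(issues) {
  structure(list(valid = !any(issues$severity == "error"), issues = issues),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s (%d error(s), %d warning(s))\n",
              if (x$valid) "valid" else "INVALID",
              sum(x$issues$severity == "error"),
              sum(x$issues$severity == "warning")))
  if (nrow(x$issues)) print(x$issues, row.names = FALSE)
  invisible(x)
}

valid_uri <- function(uri) {
  if (!is_scalar_string(uri)) return(FALSE)
  grepl("^[A-Za-z][A-Za-z0-9+.-]*:\\S+$", uri) ||
    grepl("^[^/[:space:]]+/[^/[:space:]]+/[^/[:space:]]+$", uri)
}

# Class-specific consistency checks; run only after the typed-slot checks pass.

check_neuron <- function(p) {
  issues <- issue_row(character(0), character(0), character(0))
  counts <- c("volume", "n_outgoing_synapses", "n_incoming_synapses",
              "n_incoming_excitatory", "n_incoming_inhibitory",
              "n_dendrite_skeleton_nodes", "n_axon_skeleton_nodes",
              "n_dendritic_spine_skeleton_nodes", "n_cilia_skeleton_nodes",
              "n_ais_skeleton_nodes", "n_myelinated_axon_skeleton_nodes")
  for (key in counts) {
    if (p[[key]] < 0) issues <- rbind(issues, issue_row("error", key, "count must be >= 0"))
  }
  ei <- p$n_incoming_excitatory + p$n_incoming_inhibitory
  if (p$n_incoming_synapses < ei) {
    issues <- rbind(issues, issue_row("error", "n_incoming_synapses",
      "incoming synapse count below classified excitatory + inhibitory tally"))
  }
  if (is.null(p$ei_balance) != (ei == 0)) {
    issues <- rbind(issues, issue_row("error", "ei_balance",
      "ei_balance must be defined exactly when classified incoming synapses exist"))
  }
  if (!is.null(p$ei_balance)) {
    if (p$ei_balance < 0 || p$ei_balance > 1) {
      issues <- rbind(issues, issue_row("error", "ei_balance", "ei_balance must lie in [0, 1]"))
    } else if (ei > 0 && abs(p$ei_balance - p$n_incoming_excitatory / ei) > 1e-9) {
      issues <- rbind(issues, issue_row("warning", "ei_balance",
        "stored ei_balance differs from E/(E+I) recomputed from counts"))
    }
  }
  if (is.null(p$spinyness) != (p$n_dendrite_skeleton_nodes == 0)) {
    issues <- rbind(issues, issue_row("error", "spinyness",
      "spinyness must be defined exactly when dendrite skeleton nodes exist"))
  }
  if (!is.null(p$spinyness) && (p$spinyness < 0 || p$spinyness > 1)) {
    issues <- rbind(issues, issue_row("error", "spinyness", "spinyness must lie in [0, 1]"))
  }
  if (!is.null(p$layer) && !(p$layer %in% 1:7)) {
    issues <- rbind(issues, issue_row("error", "layer", "layer must be in 1..7"))
  }
  issues
}

check_synapse <- function(p) {
  issues <- issue_row(character(0), character(0), character(0))
  if (!p$synapse_type %in% c("excitatory", "inhibitory", "unknown")) {
    issues <- rbind(issues, issue_row("error", "synapse_type",
      "synapse_type must be excitatory, inhibitory or unknown"))
  }
  for (side in c("presynaptic_site", "postsynaptic_partner")) {
    site <- p[[side]]
    if (!check_type(site$neuron_id %||% NA, "integer") ||
        !check_type(site$class_type %||% NA, "integer")) {
      issues <- rbind(issues, issue_row("error", side,
        paste0(side, " must carry integer neuron_id and class_type")))
    }
  }
  cmp <- p$postsynaptic_partner$compartment
  if (is.null(cmp) || !cmp %in% compartment_levels()) {
    issues <- rbind(issues, issue_row("error", "postsynaptic_partner.compartment",
      paste0("compartment must be one of ", paste(compartment_levels(), collapse = ", "))))
  }
  bb <- p$bounding_box
  if (!all(bb$min < bb$max)) {
    issues <- rbind(issues, issue_row("error", "bounding_box",
      "bounding box min must be componentwise below max"))
  } else if (!all(p$location >= bb$min & p$location < bb$max)) {
    issues <- rbind(issues, issue_row("error", "location",
      "location must lie inside the half-open bounding box [min, max)"))
  }
  if (!is.null(p$layer) && !(p$layer %in% 1:7)) {
    issues <- rbind(issues, issue_row("error", "layer", "layer must be in 1..7"))
  }
  issues
}

check_layer <- function(p) {
  issues <- issue_row(character(0), character(0), character(0))
  if (!(p$layer_id %in% 1:7)) {
    issues <- rbind(issues, issue_row("error", "layer_id", "layer_id must be in 1..7"))
  }
  if (p$width < 0) {
    issues <- rbind(issues, issue_row("error", "width", "width must be >= 0 nanometers"))
  }
  issues
}
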