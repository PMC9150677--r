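# Canonical on-disk document: reserved keys + properties flattened to the
# top level; undefined values are absent keys, never sentinel numbers.
record_to_doc <- function(record) {
  doc <- list(
    entity_id = record$entity_id,
    entity_class = record$entity_class,
    uri = record$uri,
    representation = record$representation,
    links = record$links,
    dataset_id = record$dataset_id
  )
  for (k in names(record$properties)) doc[[k]] <- record$properties[[k]]
  doc
}

doc_to_record <- function(doc) {
  res <- names(doc) %in% reserved_keys()
  props <- doc[!res]
  props <- lapply(props, normalize_value)
  entity_record(
    entity_id = doc$entity_id,
    entity_class = doc$entity_class,
    properties = props,
    uri = doc$uri,
    representation = doc$representation,
    links = lapply(doc$links %||% list(), function(lk) {
      list(relation = lk$relation, target = lk$target)
    }),
    dataset_id = doc$dataset_id %||% "local"
  )
}

# JSON parsing yields integers where the writer held doubles; normalize all
# numeric leaves to double so round-trips are field-for-field identical.
normalize_value <- function(x) {
  if (is.numeric(x)) as.numeric(x)
  else if (is.list(x)) lapply(x, normalize_value)
  else x
}

#' Write entity records as JSON Lines
#'
#' One JSON object per line, UTF-8, snake_case keys; undefined-valued
#' properties are omitted keys.
#'
#' @param records List of [entity_record()]s.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_jsonl <- function(records, path) {
  lines <- vapply(records, function(rec) {
    # 17 significant digits: doubles survive the decimal rendering exactly
    as.character(jsonlite::toJSON(record_to_doc(rec), auto_unbox = TRUE,
                                  digits = I(17), null = "null"))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read entity records from JSON Lines
#'
#' @param path Input file path.
#' @param registry Optional [schema_registry()]; when given, every record is
#'   validated and the first invalid record aborts the read.
#' @return List of [entity_record()]s.
#' @export
read_jsonl <- function(path, registry = NULL) {
  if (!file.exists(path)) nm_not_found(paste0("no such file: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  records <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    doc <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE,
                         simplifyDataFrame = FALSE, simplifyMatrix = FALSE),
      error = function(e) {
        nm_validation_error(paste0("malformed JSON at line ", i, ": ",
                                   conditionMessage(e)))
      })
    rec <- doc_to_record(doc)
    if (!is.null(registry)) {
      rep <- validate_entity(rec, registry)
      if (!rep$valid) {
        nm_validation_error(paste0(
          "invalid record at line ", i, " (id ", rec$entity_id, "): ",
          paste(rep$issues$message[rep$issues$severity == "error"], collapse = "; ")))
      }
    }
    records[[i]] <- rec
  }
  records
}

#' Persist a store as a JSON Lines directory
#'
#' Writes one `<class>.jsonl` file per collection plus a `header.json`
#' carrying the dataset id, voxel resolution, node spacing and code tables.
#'
#' @param store A [metadata_store()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_store <- function(store, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  header <- list(dataset_id = store$dataset_id, resolution = store$resolution,
                 node_spacing = store$node_spacing,
                 code_tables = lapply(store$registry$code_tables, as.list))
  jsonlite::write_json(header, file.path(dir, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  for (cl in names(store$collections)) {
    recs <- store$collections[[cl]][order_ids(names(store$collections[[cl]]))]
    write_jsonl(unname(recs), file.path(dir, paste0(cl, ".jsonl")))
  }
  invisible(dir)
}

#' Load a store from a JSON Lines directory
#'
#' @param dir Directory written by [save_store()] (or by the CLI `generate`
#'   subcommand).
#' @param registry Optional registry; defaults to one built from the
#'   header's code tables.
#' @return A [metadata_store()].
#' @export
load_store <- function(dir, registry = NULL) {
  hpath <- file.path(dir, "header.json")
  if (!file.exists(hpath)) nm_not_found(paste0("no dataset header in ", dir))
  header <- jsonlite::read_json(hpath, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  tables <- lapply(header$code_tables, function(tb) unlist(tb))
  if (is.null(registry)) {
    registry <- schema_registry(
      code_tables = if (length(tables)) tables else default_code_tables())
  }
  store <- metadata_store(header$dataset_id %||% "local", registry = registry,
                          resolution = unlist(header$resolution) %||% c(8, 8, 33),
                          node_spacing = header$node_spacing %||% 1.0)
  for (f in list.files(dir, pattern = "\\.jsonl$", full.names = TRUE)) {
    insert_records(store, read_jsonl(f, registry))
  }
  store
}

# ---- tabular import/export ---------------------------------------------------

#' Define a column mapping for tabular imports
#'
#' Maps the columns of a lab-style CSV/TSV dump onto standardized entity
#' properties. Each column spec gives the target property key (dotted keys
#' descend into nested documents, a trailing `[i]` addresses a 3-vector
#' slot), the property type, and optionally the name of an integer code
#' table used to translate disk codes into symbols.
#'
#' @param entity_class Target entity class.
#' @param id_column Source column holding the entity id.
#' @param columns Named list: source column -> `list(target =, type =,
#'   codes = NULL)`.
#' @param constants Named list of constant properties injected into every
#'   record.
#' @return A `column_mapping` object.
#' @export
column_mapping <- function(entity_class, id_column, columns, constants = list()) {
  targets <- vapply(columns, function(cs) cs$target, character(1))
  if (anyDuplicated(targets)) nm_argument_error("target property keys must be unique")
  if (!is_scalar_string(id_column)) nm_argument_error("id_column is required")
  structure(list(entity_class = entity_class, id_column = id_column,
                 columns = columns, constants = constants),
            class = "column_mapping")
}

#' Read a column mapping from a YAML or JSON config file
#' @param path Config path (`.yaml`/`.yml` or `.json`).
#' @return A [column_mapping()].
#' @export
read_column_mapping <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  column_mapping(cfg$entity_class, cfg$id_column,
                 lapply(cfg$columns, function(cs) {
                   list(target = cs$target, type = cs$type,
                        codes = cs$codes %||% NULL)
                 }),
                 cfg$constants %||% list())
}

read_delim_table <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path)) {
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
}

convert_cell <- function(raw, type, codes, code_tables) {
  if (is.na(raw) || (is.character(raw) && !nzchar(raw))) return(NULL)
  if (!is.null(codes)) {
    table <- code_tables[[codes]]
    if (is.null(table)) nm_config_error(paste0("unknown code table '", codes, "'"))
    sym <- unname(table[as.character(raw)])
    if (is.na(sym)) nm_validation_error(paste0("unknown code ", raw,
                                               " for table '", codes, "'"))
    return(sym)
  }
  switch(type,
    integer = , long = , double = as.numeric(raw),
    string = as.character(raw),
    boolean = as.logical(raw),
    as.character(raw))
}

#' Import a delimited annotation table as entity records
#'
#' Builds one standardized record per row via a [column_mapping()]: integer
#' codes are translated through the registry's code tables, dotted targets
#' assemble nested documents, empty cells become undefined properties. Every
#' created record validates against the registry; rows that fail (unknown
#' codes, schema violations) are rejected and enumerated with reasons —
#' import never partially converts a row.
#'
#' @param path CSV (comma, header row) or TSV file; the dialect is chosen by
#'   extension.
#' @param mapping A [column_mapping()].
#' @param registry A [schema_registry()].
#' @param dataset_id Dataset id stamped on the records.
#' @return List with `records` (valid [entity_record()]s, input order) and
#'   `report` (rows read, created, rejected with row numbers and reasons).
#' @export
import_table <- function(path, mapping, registry, dataset_id = "local") {
  stopifnot(inherits(mapping, "column_mapping"))
  df <- read_delim_table(path)
  needed <- c(mapping$id_column, names(mapping$columns))
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    nm_argument_error(paste0("mapped column(s) absent from table: ",
                             paste(missing, collapse = ", ")))
  }
  records <- list()
  rejected <- data.frame(row = integer(0), reason = character(0),
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    rec <- tryCatch({
      props <- list()
      for (src in names(mapping$columns)) {
        cs <- mapping$columns[[src]]
        val <- convert_cell(df[[src]][[i]], cs$type, cs$codes,
                            registry$code_tables)
        if (!is.null(val)) props <- assign_path(props, cs$target, val)
      }
      for (k in names(mapping$constants)) {
        props <- assign_path(props, k, mapping$constants[[k]])
      }
      # the identifier property mirrors the id column unless mapped explicitly
      sch <- registry$classes[[mapping$entity_class]]
      if (!is.null(sch)) {
        id_key <- names(sch$id_property)
        if (is.null(props[[id_key]])) {
          raw_id <- df[[mapping$id_column]][[i]]
          id_val <- if (sch$id_property[[1L]] %in% c("integer", "long", "double")) {
            as.numeric(raw_id)
          } else {
            as.character(raw_id)
          }
          props <- c(stats::setNames(list(id_val), id_key), props)
        }
      }
      props <- lapply(props, normalize_value)
      rec <- entity_record(df[[mapping$id_column]][[i]], mapping$entity_class,
                           properties = props, dataset_id = dataset_id)
      rep <- validate_entity(rec, registry)
      if (!rep$valid) {
        nm_validation_error(paste(
          rep$issues$message[rep$issues$severity == "error"], collapse = "; "))
      }
      rec
    }, nm_error = function(e) e)
    if (inherits(rec, "entity_record")) {
      records[[length(records) + 1L]] <- rec
    } else {
      rejected <- rbind(rejected, data.frame(row = i,
                                             reason = conditionMessage(rec),
                                             stringsAsFactors = FALSE))
    }
  }
  report <- structure(list(rows_read = nrow(df),
                           records_created = length(records),
                           records_rejected = nrow(rejected),
                           rejected = rejected),
                      class = "import_report")
  list(records = records, report = report)
}

#' @export
print.import_report <- function(x, ...) {
  cat(sprintf("<import_report> read %d, created %d, rejected %d\n",
              x$rows_read, x$records_created, x$records_rejected))
  if (nrow(x$rejected)) print(x$rejected, row.names = FALSE)
  invisible(x)
}

#' Export entity records to a delimited table
#'
#' Inverse of [import_table()] under the same mapping: symbols are
#' translated back to integer codes, undefined properties become empty
#' cells.
#'
#' @inheritParams import_table
#' @param records List of [entity_record()]s of the mapping's class.
#' @return `path`, invisibly.
#' @export
export_table <- function(records, path, mapping, registry) {
  stopifnot(inherits(mapping, "column_mapping"))
  cols <- c(mapping$id_column, names(mapping$columns))
  rows <- lapply(records, function(rec) {
    out <- stats::setNames(vector("list", length(cols)), cols)
    out[[mapping$id_column]] <- rec$entity_id
    for (src in names(mapping$columns)) {
      cs <- mapping$columns[[src]]
      target <- sub("\\[([0-9]+)\\]$", ".\\1", cs$target)
      val <- record_field(rec, target)
      if (!is.null(val) && !is.null(cs$codes)) {
        table <- registry$code_tables[[cs$codes]]
        code <- names(table)[match(val, table)]
        val <- if (length(code)) as.numeric(code) else NA
      }
      out[[src]] <- val %||% NA
    }
    as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
  })
  df <- do.call(rbind, rows) %||%
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, na = "",
                     qmethod = "double")
  invisible(path)
}

#' Built-in column mapping for synapse tables
#'
#' Flat tabular layout of the seven synapse attributes: polarity and
#' compartment as integer codes, partner sites and 3-vector coordinates
#' spread over columns.
#'
#' @return A [column_mapping()].
#' @export
synapse_table_mapping <- function() {
  column_mapping(
    "synapse", "synapse_id",
    list(
      synapse_type = list(target = "synapse_type", type = "string",
                          codes = "synapse_type"),
      pre_neuron_id = list(target = "presynaptic_site.neuron_id", type = "integer"),
      pre_class_type = list(target = "presynaptic_site.class_type", type = "integer"),
      post_neuron_id = list(target = "postsynaptic_partner.neuron_id", type = "integer"),
      post_class_type = list(target = "postsynaptic_partner.class_type", type = "integer"),
      post_compartment = list(target = "postsynaptic_partner.compartment",
                              type = "string", codes = "compartment"),
      x = list(target = "location[1]", type = "integer"),
      y = list(target = "location[2]", type = "integer"),
      z = list(target = "location[3]", type = "integer"),
      bbox_min_x = list(target = "bounding_box.min[1]", type = "integer"),
      bbox_min_y = list(target = "bounding_box.min[2]", type = "integer"),
      bbox_min_z = list(target = "bounding_box.min[3]", type = "integer"),
      bbox_max_x = list(target = "bounding_box.max[1]", type = "integer"),
      bbox_max_y = list(target = "bounding_box.max[2]", type = "integer"),
      bbox_max_z = list(target = "bounding_box.max[3]", type = "integer"),
      layer = list(target = "layer", type = "integer")
    ))
}

#' Built-in column mapping for neuron tables
#' @return A [column_mapping()].
#' @export
neuron_table_mapping <- function() {
  simple <- function(key, type = "integer") list(target = key, type = type)
  column_mapping(
    "neuron", "neuron_id",
    list(
      volume = simple("volume", "long"),
      n_outgoing_synapses = simple("n_outgoing_synapses"),
      n_incoming_synapses = simple("n_incoming_synapses"),
      n_incoming_excitatory = simple("n_incoming_excitatory"),
      n_incoming_inhibitory = simple("n_incoming_inhibitory"),
      n_dendrite_skeleton_nodes = simple("n_dendrite_skeleton_nodes"),
      n_axon_skeleton_nodes = simple("n_axon_skeleton_nodes"),
      n_dendritic_spine_skeleton_nodes = simple("n_dendritic_spine_skeleton_nodes"),
      n_cilia_skeleton_nodes = simple("n_cilia_skeleton_nodes"),
      n_ais_skeleton_nodes = simple("n_ais_skeleton_nodes"),
      n_myelinated_axon_skeleton_nodes = simple("n_myelinated_axon_skeleton_nodes"),
      neuron_type = list(target = "neuron_type", type = "string",
                         codes = "neuron_type"),
      spinyness = simple("spinyness", "double"),
      layer = simple("layer"),
      ei_balance = simple("ei_balance", "double")
    ))
}
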