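#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == trunc(x)
}

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)

#' Stop with a typed condition
#'
#' Internal error constructors so callers can distinguish a missing document
#' (`nm_not_found`) from an invalid argument (`nm_argument_error`), an invalid
#' record (`nm_validation_error`) or an infeasible configuration
#' (`nm_config_error`).
#' @noRd
nm_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "nm_error", "error", "condition")))
}

nm_not_found <- function(msg) nm_stop(msg, "nm_not_found")
nm_argument_error <- function(msg) nm_stop(msg, "nm_argument_error")
nm_validation_error <- function(msg) nm_stop(msg, "nm_validation_error")
nm_config_error <- function(msg) nm_stop(msg, "nm_config_error")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Order entity ids numerically when every id parses as a number, otherwise
# lexicographically; list endpoints promise a stable order by entity_id.
order_ids <- function(ids) {
  if (length(ids) == 0L) return(character(0))
  num <- suppressWarnings(as.numeric(ids))
  if (!anyNA(num)) ids[order(num)] else ids[order(ids, method = "radix")]
}

# Resolve a dotted path ("postsynaptic_partner.compartment") inside a record's
# merged top-level + property view; returns NULL when absent.
extract_path <- function(doc, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1L]]
  cur <- doc
  for (p in parts) {
    idx <- suppressWarnings(as.integer(p))
    if (!is.na(idx) && is.null(names(cur))) {
      if (idx > length(cur)) return(NULL)
      cur <- cur[[idx]]
    } else {
      if (!is.list(cur) && !is.environment(cur)) {
        # vector leaf addressed by numeric slot, e.g. location.2
        if (!is.na(idx) && idx <= length(cur)) return(cur[[idx]])
        return(NULL)
      }
      if (is.null(cur[[p]])) return(NULL)
      cur <- cur[[p]]
    }
  }
  cur
}

# Assign `value` at a dotted path, creating nested lists on the way.
# A trailing "[i]" on a component addresses slot i of a numeric vector
# (used for 3-vector coordinates in tabular mappings).
assign_path <- function(doc, path, value) {
  m <- regmatches(path, regexec("^(.*)\\[([0-9]+)\\]$", path))[[1L]]
  slot <- NA_integer_
  if (length(m) == 3L) {
    path <- m[[2L]]
    slot <- as.integer(m[[3L]])
  }
  parts <- strsplit(path, ".", fixed = TRUE)[[1L]]
  rec_assign <- function(node, parts) {
    if (is.null(node)) node <- list()
    key <- parts[[1L]]
    if (length(parts) == 1L) {
      if (is.na(slot)) {
        node[[key]] <- value
      } else {
        vec <- node[[key]] %||% numeric(0)
        if (length(vec) < slot) vec <- c(vec, rep(NA_real_, slot - length(vec)))
        vec[[slot]] <- value
        node[[key]] <- vec
      }
    } else {
      node[[key]] <- rec_assign(node[[key]], parts[-1L])
    }
    node
  }
  rec_assign(doc, parts)
}
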