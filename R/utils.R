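#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble new_tibble
NULL

# Condition helpers. Every user-visible failure carries one of these classes so
# the command-line wrapper can map it onto a stable exit code.
abort_validation <- function(message, ...) {
  abort(message, class = c("astax_validation_error", "astax_error"), ...)
}

abort_capacity <- function(message, ...) {
  abort(message,
    class = c("astax_capacity_error", "astax_validation_error", "astax_error"),
    ...
  )
}

abort_structure <- function(message, ...) {
  abort(message,
    class = c("astax_structure_error", "astax_validation_error", "astax_error"),
    ...
  )
}

abort_lookup <- function(message, ...) {
  abort(message,
    class = c("astax_lookup_error", "astax_validation_error", "astax_error"),
    ...
  )
}

abort_parse <- function(message, ...) {
  abort(message, class = c("astax_parse_error", "astax_error"), ...)
}

abort_io <- function(message, ...) {
  abort(message, class = c("astax_io_error", "astax_error"), ...)
}

# Canonical, locale-independent ordering of identifiers: numeric when every id
# is a plain integer string (NCBI taxids), byte-wise (radix) otherwise. All
# tie-breaking in the package goes through this so runs are reproducible.
order_ids <- function(x) {
  if (length(x) == 0L) return(integer(0))
  if (all(grepl("^[0-9]+$", x))) {
    order(as.numeric(x), method = "radix")
  } else {
    order(x, method = "radix")
  }
}

sort_ids <- function(x) x[order_ids(x)]

# order by (-score, seq_id ascending): the package-wide similarity tie rule
order_by_score <- function(score, seq_id) {
  ord_id <- order_ids(seq_id)
  ord_id[order(-score[ord_id], method = "radix")]
}

`%||%` <- function(x, y) if (is.null(x)) y else x
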