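#' @importFrom stats setNames
#' @importFrom utils adist head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Condition helpers.  Three error families are used throughout:
##  - osql_parse_error    : malformed ontology documents / O-SQL expressions
##  - osql_semantic_error : query text that resolves to no concept, unknown ids
##  - osql_db_error       : missing tables/columns/keys, SQL engine failures
osql_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "osql_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

osql_parse_error <- function(message, ...) {
  osql_abort(message, "osql_parse_error", ...)
}

osql_semantic_error <- function(message, ...) {
  osql_abort(message, "osql_semantic_error", ...)
}

osql_db_error <- function(message, ...) {
  osql_abort(message, "osql_db_error", ...)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

trimws2 <- function(x) gsub("\\s+", " ", trimws(x))
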