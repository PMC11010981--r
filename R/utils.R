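clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

#' Hash a configuration-like object
#'
#' Serializes the object to canonical JSON and returns its MD5 digest. Used
#' to stamp every session log so outputs can be traced back to the exact
#' parameter set that produced them.
#'
#' @param x any JSON-serializable list.
#' @return a length-1 character MD5 digest.
#' @export
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"), tf)
  unname(tools::md5sum(tf))
}
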