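`%||%` <- function(x, y) if (is.null(x)) y else x

# stop() with sprintf-style formatting and no call in the message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= min && x == as.integer(x)
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x)

# collapse a few ids for an error message
id_preview <- function(ids, n = 5L) {
  shown <- paste(head(ids, n), collapse = ", ")
  if (length(ids) > n) shown <- paste0(shown, ", ... (", length(ids), " total)")
  shown
}
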