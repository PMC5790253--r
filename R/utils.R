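# Internal helpers shared across modules.

# Reserved species code marking a transect that was surveyed but held no
# organisms of a taxon group. It keeps legitimate zero densities in the data
# without pretending a species was seen.
NONE_CODE <- "NONE"

ZONE_LEVELS <- c("control", "reserve")
GROUP_LEVELS <- c("fish", "invertebrate")

abort_format <- function(msg) {
  stop(structure(
    class = c("mpaeval_format_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

abort_validation <- function(msg) {
  stop(structure(
    class = c("mpaeval_validation_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

abort_design <- function(msg) {
  stop(structure(
    class = c("mpaeval_design_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_format(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# scales a seed derived from a user seed into 32-bit integer range
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i)) %% .Machine$integer.max)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x)
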