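abort_ims <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "imsvoc_error")))
}

#' Derive a stage seed from a global seed
#'
#' One global seed fans out to per-stage seeds through a fixed affine rule,
#' kept inside the 32-bit integer range, so that each pipeline stage draws
#' from an independent, reproducible stream.
#'
#' @param seed integer global seed.
#' @param offset non-negative integer stage offset.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %%
    2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
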