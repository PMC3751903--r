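# Shared helpers. Internal coordinates are 0-based half-open throughout;
# conversion to the 1-based inclusive browser convention happens only at
# report boundaries.

#' Convert internal 0-based half-open coordinates to 1-based inclusive
#'
#' @param start,end numeric vectors of 0-based half-open interval bounds.
#' @return data.frame with columns `start`, `end` in 1-based inclusive
#'   coordinates.
#' @export
to_one_based <- function(start, end) {
  stopifnot(all(end > start))
  data.frame(start = start + 1L, end = end)
}

#' Convert 1-based inclusive coordinates to internal 0-based half-open
#'
#' @param start,end numeric vectors of 1-based inclusive interval bounds.
#' @return data.frame with columns `start`, `end`, 0-based half-open.
#' @export
to_zero_based <- function(start, end) {
  stopifnot(all(end >= start))
  data.frame(start = start - 1L, end = end)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# 0-based positions covered by a set of (start, length) runs
runs_positions <- function(starts, lengths) {
  if (length(starts) == 0L) return(integer(0))
  unlist(mapply(function(s, l) seq.int(s, length.out = l), starts, lengths,
                SIMPLIFY = FALSE), use.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_id_counter <- function() {
  i <- 0L
  function() {
    i <<- i + 1L
    i
  }
}
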