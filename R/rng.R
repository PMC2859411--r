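# Reproducible worker substreams.
#
# The transport engine partitions randomness across workers by jump-ahead:
# worker k draws from a xoshiro256++ generator seeded with the master seed and
# advanced k * 2^128 states.  Substreams are therefore pairwise
# non-overlapping by construction, and (master_seed, n_workers, worker_index)
# always reproduces the identical substream, so merged tallies are
# bit-identical across repeat runs regardless of hardware.

#' Create non-overlapping worker substreams
#'
#' @param master_seed Integer master seed.
#' @param n_workers Number of substreams (>= 1).
#' @return A list of `photon_stream` objects, one per worker (0-based index
#'   `worker_index` in the attribute).
#' @examples
#' s <- substreams(42, 4)
#' stream_uniform(s[[1]], 5)
#' @export
substreams <- function(master_seed, n_workers) {
  if (n_workers < 1) abort("n_workers must be >= 1")
  lapply(seq_len(n_workers) - 1L, function(w) {
    structure(list(ptr = rcpp_make_stream(as.double(master_seed), w),
                   master_seed = master_seed, worker_index = w,
                   n_workers = n_workers),
              class = "photon_stream")
  })
}

#' Draw uniform unit random numbers from a substream
#'
#' Values lie in the half-open interval `[0, 1)`; wherever the engine takes
#' `log(xi)` an exact zero is remapped to the next draw.  The stream is
#' stateful: successive calls continue the sequence.
#'
#' @param stream A `photon_stream` from [substreams()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
stream_uniform <- function(stream, n = 1) {
  stopifnot(inherits(stream, "photon_stream"))
  rcpp_stream_unif(stream$ptr, as.integer(n))
}

#' @export
print.photon_stream <- function(x, ...) {
  cat(sprintf("<photon_stream> master_seed=%s worker %d/%d\n",
              format(x$master_seed), x$worker_index, x$n_workers))
  invisible(x)
}
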