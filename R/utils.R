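# shared small helpers: argument checking, seed derivation, config errors

stop_config <- function(msg) {
  rlang::abort(msg, class = "microexperts_config_error")
}

stop_data <- function(msg) {
  rlang::abort(msg, class = "microexperts_data_error")
}

#' Derive a child seed from a master seed
#'
#' All stochastic stages (phantom generation, augmentation, weight
#' initialization, batch shuffling, one per expert) draw their own seed from
#' the single master seed so that runs are reproducible end to end while the
#' streams stay decoupled. Values stay below 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param k integer stream index (>= 0).
#' @return integer seed for stream `k`.
#' @export
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), is.numeric(k))
  as.integer((as.numeric(seed) * 48271 + 7919 * (as.numeric(k) + 1)) %% 2147483647)
}

# largest-remainder apportionment of `total` among quotas proportional to w
largest_remainder <- function(w, total) {
  if (total < 0) stop_config("total must be nonnegative")
  q <- w / sum(w) * total
  base <- floor(q)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(q - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
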