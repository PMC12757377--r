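# Parameter / FLOP / size accounting.
#
# Parameters = sum over layers of weights + biases (batch-norm affine
# parameters included, running statistics excluded). FLOPs count one
# multiply-accumulate of the convolutional and fully connected layers as
# one operation (GFLOPs here are GMACs; elementwise normalization,
# activation and pooling work is excluded). Size assumes 4 bytes (32-bit)
# per parameter.

#' Complexity report for a set of expert networks
#'
#' @param nets a list of `mx_expert` objects (or a single one).
#' @param input_size input side length at which FLOPs are evaluated
#'   (default 224).
#' @return an object of class `mx_complexity`: a list with `per_expert`
#'   (tibble: name, params, macs, gflops, size_mb) and `totals` (one-row
#'   tibble), plus the counting convention in `convention`.
#' @export
complexity_report <- function(nets, input_size = 224L) {
  if (inherits(nets, "mx_expert")) nets <- list(nets)
  rows <- purrr::map_dfr(nets, function(net) {
    pl <- net$plan(as.integer(input_size))
    realized <- net_n_params(net)
    planned <- sum(pl$params)
    if (realized != planned) {
      rlang::warn(sprintf("plan/realized parameter mismatch for '%s': %d vs %d",
                          net$name, planned, realized))
    }
    tibble::tibble(
      name = net$name,
      params = realized,
      macs = sum(pl$macs),
      gflops = sum(pl$macs) / 1e9,
      size_mb = realized * 4 / 1e6
    )
  })
  totals <- tibble::tibble(
    name = "ensemble",
    params = sum(rows$params),
    macs = sum(rows$macs),
    gflops = sum(rows$macs) / 1e9,
    size_mb = sum(rows$size_mb)
  )
  structure(list(per_expert = rows, totals = totals,
                 input_size = as.integer(input_size),
                 convention = "1 FLOP = 1 multiply-accumulate (conv + fully connected layers)"),
            class = "mx_complexity")
}

#' @export
print.mx_complexity <- function(x, ...) {
  cat(sprintf("Complexity at %dx%d input (%s):\n", x$input_size, x$input_size,
              x$convention))
  print(as.data.frame(x$per_expert), row.names = FALSE)
  cat(sprintf("ensemble: %s parameters, %.4f GFLOPs, %.4f MB\n",
              format(x$totals$params, big.mark = ","),
              x$totals$gflops, x$totals$size_mb))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mx_complexity <- function(x, ...) {
  dplyr::bind_rows(x$per_expert, x$totals)
}

#' @exportS3Method generics::glance
glance.mx_complexity <- function(x, ...) {
  tibble::tibble(
    n_experts = nrow(x$per_expert),
    params = x$totals$params,
    params_m = x$totals$params / 1e6,
    gflops = x$totals$gflops,
    size_mb = x$totals$size_mb
  )
}

complexity_json <- function(x) {
  list(
    convention = x$convention,
    input_size = x$input_size,
    per_expert = purrr::map(seq_len(nrow(x$per_expert)), function(i) {
      r <- x$per_expert[i, ]
      list(name = r$name, params = r$params, gflops = r$gflops,
           size_mb = r$size_mb)
    }),
    totals = list(params = x$totals$params, params_m = x$totals$params / 1e6,
                  gflops = x$totals$gflops, size_mb = x$totals$size_mb)
  )
}
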