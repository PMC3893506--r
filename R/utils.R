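#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor dhyper hclust dist as.dist p.adjust runif rnorm setNames
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_input <- function(...) stop(..., call. = FALSE)

stopifnot_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_input(sprintf("'%s' must be a single finite number", name))
  if (strict_min && x <= min)
    abort_input(sprintf("'%s' must be > %s", name, format(min)))
  if (!strict_min && x < min)
    abort_input(sprintf("'%s' must be >= %s", name, format(min)))
  invisible(x)
}

#' Derive a reproducible sub-seed for a named stage
#'
#' All randomized stages draw their seed from one user-supplied seed plus the
#' stage name, so any stage can be re-run in isolation with identical results.
#' The hash stays below 2^31 so it is always a valid R integer seed.
#'
#' @param seed Integer master seed.
#' @param label Character stage label.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot_scalar_number(seed, "seed")
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483629
  as.integer((abs(seed) %% 2147483629 * 48271 + h) %% 2147483629 + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# rows standardized to zero mean / unit sd; zero-variance rows -> NA
standardize_rows <- function(m) {
  mu <- rowMeans(m)
  ct <- m - mu
  sd <- sqrt(rowSums(ct^2) / (ncol(m) - 1L))
  sw <- ct / sd
  sw[sd == 0, ] <- NA_real_
  sw
}
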