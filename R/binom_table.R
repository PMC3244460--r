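#' Cumulative binomial lookup table
#'
#' Precomputes the cumulative distribution \eqn{F(k; n, p)} for every
#' \eqn{n = 0, \ldots, N_{max}} and \eqn{k = 0, \ldots, n}, so a binomial
#' variate can later be drawn from a single uniform variate by binary search
#' in \eqn{O(\log n)} comparisons.  Row \eqn{n} of the table has exactly
#' \eqn{n + 1} entries, is non-decreasing, and ends at 1.
#'
#' @param N_max largest supported count \eqn{n} (positive integer).
#' @param p success probability, strictly between 0 and 1.
#' @return An object of class `cum_binom_table` with fields `p`, `N_max`,
#'   `cdf` (all rows concatenated) and `offsets` (0-based start of row `n`
#'   at position `n + 1`).
#' @examples
#' tab <- build_cumulative_binomial_table(10, 0.5)
#' table_row(tab, 1)   # c(0.5, 1)
#' @export
build_cumulative_binomial_table <- function(N_max, p) {
  if (!is.numeric(N_max) || length(N_max) != 1L || N_max < 1 ||
      N_max != floor(N_max))
    stop("`N_max` must be a positive integer", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
    stop("`p` must lie strictly between 0 and 1", call. = FALSE)
  N_max <- as.integer(N_max)
  lens <- seq_len(N_max + 1L)                       # row n has n + 1 entries
  ns <- rep.int(0:N_max, lens)
  ks <- sequence(lens) - 1L
  structure(
    list(p = p, N_max = N_max,
         cdf = pbinom(ks, ns, p),
         offsets = as.integer((0:N_max) * (1:(N_max + 1L)) / 2)),
    class = "cum_binom_table")
}

#' @rdname build_cumulative_binomial_table
#' @param table a `cum_binom_table`.
#' @param n the row (count) to extract, `0 <= n <= N_max`.
#' @export
table_row <- function(table, n) {
  stopifnot(inherits(table, "cum_binom_table"))
  if (n < 0 || n > table$N_max) stop("`n` out of table range", call. = FALSE)
  table$cdf[(table$offsets[n + 1L] + 1L):(table$offsets[n + 1L] + n + 1L)]
}

#' @export
print.cum_binom_table <- function(x, ...) {
  cat(sprintf("<cum_binom_table> p = %g, N_max = %d (%d entries)\n",
              x$p, x$N_max, length(x$cdf)))
  invisible(x)
}

#' Draw binomial variates from a lookup table by binary search
#'
#' Returns the smallest `k` with \eqn{F(k; n, p) > u}, i.e. the inverse-CDF
#' transform of the uniform variate `u` through the tabulated cumulative
#' binomial distribution.  `u` is expected in `[0, 1)` so the final table
#' entry (exactly 1) is always reachable.  Vectorized over `n` and `u`.
#'
#' @param n count(s), each between 0 and `table$N_max` (counts above `N_max`
#'   raise a capacity error directing the caller to
#'   [sample_binomial_normal_approx()]).
#' @param table a [build_cumulative_binomial_table()] result.
#' @param u uniform variate(s) in `[0, 1)`, same length as `n`.
#' @return integer-valued vector of draws, each in `[0, n]`.
#' @examples
#' tab <- build_cumulative_binomial_table(10, 0.5)
#' sample_binomial(10, tab, 0.5)   # 5
#' @export
sample_binomial <- function(n, table, u) {
  stopifnot(inherits(table, "cum_binom_table"))
  if (length(n) != length(u)) stop("`n` and `u` must have equal length", call. = FALSE)
  if (any(n < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(n > table$N_max))
    stop(sprintf(paste0("count %d exceeds table capacity N_max = %d; ",
                        "use sample_binomial_normal_approx() for large counts"),
                 max(n), table$N_max), call. = FALSE)
  if (any(u < 0 | u >= 1)) stop("`u` must lie in [0, 1)", call. = FALSE)
  as.numeric(cpp_sample_binomial(as.numeric(n), table$cdf, table$offsets,
                                 table$N_max, table$p, as.numeric(u), FALSE))
}

#' Normal-approximation binomial sampling for large counts
#'
#' For counts beyond the lookup-table capacity, Binomial(n, p) is
#' approximated by a normal distribution with mean \eqn{np} and variance
#' \eqn{np(1-p)}: the draw is `round(n p + z sqrt(n p (1 - p)))` clamped to
#' `[0, n]`.
#'
#' @param n count(s); intended for `n` above the lookup-table capacity.
#' @param p success probability.
#' @param z standard-normal variate(s).
#' @return integer-valued vector of draws in `[0, n]`.
#' @examples
#' sample_binomial_normal_approx(1e6, 0.5, 2)   # 501000
#' @export
sample_binomial_normal_approx <- function(n, p, z) {
  if (any(n < 0)) stop("counts must be non-negative", call. = FALSE)
  k <- round(n * p + z * sqrt(n * p * (1 - p)))
  pmin(pmax(k, 0), n)
}
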