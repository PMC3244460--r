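#' Periodic lattice of molecule counts
#'
#' A `molecule_grid` stores the number of diffusing molecules in each square
#' (2D) or voxel (3D) of a periodic lattice, together with the physical side
#' length of a square.  Counts must be non-negative whole numbers; diffusion
#' steps conserve their total exactly, since the lattice has no sources or
#' sinks of its own.
#'
#' @param counts numeric matrix (2D) or 3-dimensional array (3D) of
#'   non-negative whole-number molecule counts.
#' @param square_side side length \eqn{\delta} of a lattice square, in µm.
#' @return An object of class `molecule_grid` with fields `counts`, `dims`,
#'   `shape`, `square_side` and `boundary` (always `"periodic"`).
#' @examples
#' g <- molecule_grid(matrix(0, 5, 5))
#' total_count(g)
#' @export
molecule_grid <- function(counts, square_side = 1) {
  if (is.matrix(counts)) {
    dims <- 2L
  } else if (is.array(counts) && length(dim(counts)) == 3L) {
    dims <- 3L
  } else {
    stop("`counts` must be a matrix (2D) or a 3-dimensional array (3D)",
         call. = FALSE)
  }
  storage.mode(counts) <- "double"
  if (anyNA(counts) || any(counts < 0))
    stop("molecule counts must be non-negative", call. = FALSE)
  if (any(counts != floor(counts)))
    stop("molecule counts must be whole numbers", call. = FALSE)
  if (!is.numeric(square_side) || length(square_side) != 1L || square_side <= 0)
    stop("`square_side` must be a positive scalar", call. = FALSE)
  structure(
    list(counts = counts, dims = dims, shape = dim(counts),
         square_side = as.numeric(square_side), boundary = "periodic"),
    class = "molecule_grid")
}

#' @rdname molecule_grid
#' @param grid a `molecule_grid`.
#' @export
total_count <- function(grid) {
  stopifnot(inherits(grid, "molecule_grid"))
  sum(grid$counts)
}

#' @export
print.molecule_grid <- function(x, ...) {
  cat(sprintf("<molecule_grid> %s lattice (delta = %g um, periodic), total count %s\n",
              paste(x$shape, collapse = " x "), x$square_side,
              format(total_count(x), big.mark = ",")))
  invisible(x)
}

#' Physical and algorithmic diffusion parameters
#'
#' Couples the diffusion coefficient `D`, lattice spacing `delta`, time step
#' `dt`, per-step emigration probability `p_move` and the dimensionless
#' constant `c` of the relation \eqn{\Delta t = \delta^2 / (c D)}.  Exactly
#' one of `dt` and `c` may be omitted, in which case it is derived from the
#' other; when both are given they must agree to a relative tolerance of
#' 1e-9.
#'
#' @param D diffusion coefficient (µm²/s).
#' @param delta lattice square side \eqn{\delta} (µm).
#' @param dt time step \eqn{\Delta t} (s), or `NULL` to derive from `c`.
#' @param p_move per-step emigration probability, in (0, 1).
#' @param c dimensionless time-step constant, or `NULL` to derive from `dt`.
#' @param dims spatial dimensionality, 2 or 3.
#' @param N_max largest per-square count supported by the lookup table.
#' @param normal_fallback if `TRUE` (default), counts above `N_max` are
#'   sampled with the normal approximation instead of erroring.
#' @return An object of class `diffusion_spec`.
#' @examples
#' diffusion_spec(D = 50, delta = 20, c = 8)      # dt = 1 s
#' @export
diffusion_spec <- function(D, delta, dt = NULL, p_move = 0.5, c = NULL,
                           dims = 2, N_max = 1024L, normal_fallback = TRUE) {
  if (!is.numeric(D) || D <= 0) stop("`D` must be positive", call. = FALSE)
  if (!is.numeric(delta) || delta <= 0) stop("`delta` must be positive", call. = FALSE)
  if (!is.numeric(p_move) || p_move <= 0 || p_move >= 1)
    stop("`p_move` must lie strictly between 0 and 1", call. = FALSE)
  if (!dims %in% c(2, 3)) stop("`dims` must be 2 or 3", call. = FALSE)
  if (!is.numeric(N_max) || N_max < 1) stop("`N_max` must be >= 1", call. = FALSE)
  if (is.null(dt) && is.null(c))
    stop("supply at least one of `dt` and `c`", call. = FALSE)
  if (is.null(dt)) dt <- delta^2 / (c * D)
  if (is.null(c)) c <- delta^2 / (dt * D)
  if (dt <= 0 || c <= 0) stop("`dt` and `c` must be positive", call. = FALSE)
  rel <- abs(dt - delta^2 / (c * D)) / dt
  if (rel > 1e-9)
    stop(sprintf(paste0("inconsistent parameters: dt = %g but delta^2/(c*D) = %g ",
                        "(relative error %.3g > 1e-9)"),
                 dt, delta^2 / (c * D), rel), call. = FALSE)
  structure(
    list(D = D, delta = delta, dt = dt, p_move = p_move, c = c,
         dims = as.integer(dims), N_max = as.integer(N_max),
         normal_fallback = isTRUE(normal_fallback)),
    class = "diffusion_spec")
}

#' @export
print.diffusion_spec <- function(x, ...) {
  cat(sprintf(paste0("<diffusion_spec> %dD: D = %g um^2/s, delta = %g um, ",
                     "dt = %g s (c = %g), p_move = %g, N_max = %d\n"),
              x$dims, x$D, x$delta, x$dt, x$c, x$p_move, x$N_max))
  invisible(x)
}
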