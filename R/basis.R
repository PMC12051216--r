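#' B-spline basis specification
#'
#' Describes the cubic (by default) B-spline basis used for class mean
#' trajectories: degree, number of interior knots, knot-placement strategy
#' and the boundary interval on the weeks-since-diagnosis axis. Boundary
#' knots are clamped (repeated `degree + 1` times), so the basis dimension
#' is `n_interior + degree + 1`.
#'
#' @param times numeric vector of pooled observation times (weeks); used by
#'   the `"equipotent"` strategy, which places knots at empirical quantiles.
#' @param n_interior number of interior knots (>= 1).
#' @param strategy `"equidistant"` (equal-width inter-knot intervals) or
#'   `"equipotent"` (equal numbers of data points per interval, i.e. knots
#'   at the j/(n_interior+1) empirical quantiles of the pooled times).
#' @param boundary length-2 numeric, the basis support `(t_min, t_max)`.
#'   Defaults to `c(0, max(times))`.
#' @param degree spline degree; 3 (cubic) by default.
#' @return An object of class `basis_spec`: a list with `degree`,
#'   `n_interior` (effective, after collapsing tied quantiles), `strategy`,
#'   `boundary`, `interior_knots` and the basis dimension `m`.
#' @examples
#' sp <- basis_spec(times = runif(200, 0, 100), n_interior = 4,
#'                  strategy = "equidistant", boundary = c(0, 100))
#' sp$interior_knots  # 20 40 60 80
#' @export
basis_spec <- function(times, n_interior, strategy = c("equipotent", "equidistant"),
                       boundary = NULL, degree = 3L) {
  strategy <- match.arg(strategy)
  if (degree < 1L) stop("degree must be >= 1")
  if (n_interior < 1L) stop("n_interior must be >= 1")
  if (is.null(boundary)) {
    if (length(times) == 0L) stop("times must be non-empty when boundary is not given")
    boundary <- c(0, max(times))
  }
  if (boundary[2] <= boundary[1]) stop("boundary must satisfy t_min < t_max")
  knots <- place_knots(times, n_interior, strategy, boundary)
  structure(list(degree = as.integer(degree),
                 n_interior = length(knots),
                 strategy = strategy,
                 boundary = as.numeric(boundary),
                 interior_knots = knots,
                 m = length(knots) + degree + 1L),
            class = "basis_spec")
}

#' @export
print.basis_spec <- function(x, ...) {
  cat(sprintf("B-spline basis: degree %d, %d interior knots (%s), boundary [%g, %g], dim %d\n",
              x$degree, x$n_interior, x$strategy, x$boundary[1], x$boundary[2], x$m))
  invisible(x)
}

#' Place interior knots
#'
#' Equidistant knots subdivide the boundary interval into `n_interior + 1`
#' equal pieces; equipotent knots sit at the `j/(n_interior + 1)` empirical
#' quantiles of the pooled observation times, so each inter-knot interval
#' holds (approximately) the same number of data points. Tied equipotent
#' quantiles are collapsed to unique values with a warning, reducing the
#' effective number of interior knots.
#'
#' @inheritParams basis_spec
#' @return numeric vector of strictly increasing interior knots, all
#'   strictly inside the boundary interval.
#' @export
place_knots <- function(times, n_interior, strategy = c("equipotent", "equidistant"),
                        boundary) {
  strategy <- match.arg(strategy)
  if (n_interior < 1L) stop("n_interior must be >= 1")
  if (strategy == "equidistant") {
    knots <- boundary[1] + (seq_len(n_interior) / (n_interior + 1)) * diff(boundary)
  } else {
    if (length(times) == 0L) stop("equipotent placement needs observation times")
    probs <- seq_len(n_interior) / (n_interior + 1)
    knots <- as.numeric(stats::quantile(times, probs = probs, names = FALSE, type = 7))
    # keep knots strictly interior, collapse ties
    knots <- knots[knots > boundary[1] & knots < boundary[2]]
    uk <- unique(knots)
    if (length(uk) < n_interior) {
      warning(sprintf("equipotent quantiles tied or on the boundary: %d interior knots reduced to %d",
                      n_interior, length(uk)))
    }
    knots <- uk
    if (length(knots) == 0L)
      stop("degenerate knots: all equipotent quantiles coincide or fall on the boundary")
  }
  knots
}

#' Evaluate the B-spline basis matrix
#'
#' Rows are basis evaluations at each time; by the clamped construction
#' every row sums to 1 (partition of unity) and all entries are
#' non-negative. Times outside the boundary are clamped to it — beyond the
#' data support spline extrapolation is unstable, so predictions are held
#' at the boundary value.
#'
#' @param times numeric vector of evaluation times (weeks); may be empty.
#' @param spec a [basis_spec()].
#' @return numeric matrix of dimension `length(times) x spec$m`.
#' @export
basis_matrix <- function(times, spec) {
  stopifnot(inherits(spec, "basis_spec"))
  if (length(times) == 0L) return(matrix(0, 0L, spec$m))
  t_cl <- pmin(pmax(times, spec$boundary[1]), spec$boundary[2])
  knots <- c(rep(spec$boundary[1], spec$degree + 1L),
             spec$interior_knots,
             rep(spec$boundary[2], spec$degree + 1L))
  splines::splineDesign(knots, t_cl, ord = spec$degree + 1L)
}
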