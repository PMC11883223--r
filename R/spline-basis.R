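# Natural cubic spline basis for the post-transplant month effect.
#
# Four interior knots at quantiles 0.05/0.35/0.65/0.95 of the person-period
# month column yield a five-column restricted cubic spline basis: piecewise
# cubic between knots, twice continuously differentiable, and constrained to
# be linear beyond the boundary knots, so evaluation (and prediction) past
# the observed follow-up is a linear extrapolation.

#' Spline specification for the time basis
#'
#' @param interior_knots increasing vector of interior knot positions
#'   (months).
#' @param boundary_knots length-2 vector bracketing the interior knots.
#' @return a `spline_spec` with `n_basis = length(interior_knots) + 1`.
#' @export
spline_spec <- function(interior_knots, boundary_knots) {
  interior_knots <- as.numeric(interior_knots)
  boundary_knots <- as.numeric(boundary_knots)
  if (length(boundary_knots) != 2L) stop("boundary_knots must have length 2")
  knots <- c(boundary_knots[1L], interior_knots, boundary_knots[2L])
  if (any(diff(knots) <= 0)) {
    stop("knots must be strictly increasing with boundary knots bracketing ",
         "the interior knots; got: ", paste(signif(knots, 6), collapse = ", "))
  }
  structure(list(interior_knots = interior_knots,
                 boundary_knots = boundary_knots,
                 n_basis = length(interior_knots) + 1L),
            class = "spline_spec")
}

#' Place knots at quantiles of observed at-risk months
#'
#' Interior knots sit at the stated empirical quantiles (linear-interpolation
#' definition, [stats::quantile()] type 7) of the person-period month column;
#' boundary knots at the observed minimum and maximum month.
#'
#' @param times vector of at-risk months (the person-period month column).
#' @param quantiles interior-knot quantiles; the default four give a
#'   five-column basis.
#' @return a `spline_spec`.
#' @export
#' @examples
#' place_knots(rep(1:100, each = 2))
place_knots <- function(times, quantiles = c(0.05, 0.35, 0.65, 0.95)) {
  times <- as.numeric(times)
  if (length(unique(times)) < 10L) {
    stop("need at least 10 distinct time values to place knots")
  }
  interior <- unname(quantile(times, probs = quantiles, type = 7))
  boundary <- range(times)
  all_knots <- c(boundary[1L], interior, boundary[2L])
  if (anyDuplicated(all_knots) || any(diff(all_knots) <= 0)) {
    stop("degenerate time distribution: coincident knots at ",
         paste(signif(all_knots, 6), collapse = ", "))
  }
  spline_spec(interior, boundary)
}

#' Evaluate the natural-spline time basis
#'
#' @param t months (any positive values; values beyond the boundary knots are
#'   linearly extrapolated).
#' @param spec a `spline_spec`.
#' @return numeric matrix, one row per element of `t`, `spec$n_basis`
#'   columns named `time_ns1`, `time_ns2`, ...
#' @export
spline_design <- function(t, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  b <- splines::ns(as.numeric(t), knots = spec$interior_knots,
                   Boundary.knots = spec$boundary_knots, intercept = FALSE)
  b <- unclass(b)
  attributes(b) <- attributes(b)["dim"]
  colnames(b) <- paste0("time_ns", seq_len(ncol(b)))
  b
}

spline_colnames <- function(spec) paste0("time_ns", seq_len(spec$n_basis))

#' @export
print.spline_spec <- function(x, ...) {
  cat("natural-spline time basis:", x$n_basis, "columns\n")
  cat("  interior knots:", paste(signif(x$interior_knots, 5), collapse = ", "),
      "\n  boundary knots:", paste(signif(x$boundary_knots, 5), collapse = ", "),
      "\n")
  invisible(x)
}
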