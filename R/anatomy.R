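#' Columns along one lobula axis of a circular eye
#'
#' Models the eye as a circle of `n_columns` equal-area visual columns
#' distributed uniformly across the lobula; the number of columns along one
#' axis is the diameter of that circle in column units,
#' `round(2 * sqrt(n_columns / pi))`. With the ~750 ommatidia of the fly eye
#' this gives ~31 columns per axis.
#'
#' @param n_columns Number of visual columns (default 750).
#' @return Integer count of columns along one axis.
#' @export
columns_per_axis <- function(n_columns = 750) {
  if (!(n_columns >= 1)) stop("n_columns must be >= 1")
  as.integer(round(2 * sqrt(n_columns / pi)))
}

#' Estimated visual-column coverage of an LC arbor
#'
#' Treats an LC neuron's arbor within a lobula layer as planar and
#' ellipse-shaped, with semi-axes given by the measured fractional spreads
#' along the anterior-posterior and dorsal-ventral lobula axes. The covered
#' column count is the ellipse area in column units,
#' pi/4 * (frac_ap * D) * (frac_dv * D) with D = 2 * sqrt(n_columns / pi),
#' which simplifies algebraically to `frac_ap * frac_dv * n_columns`. Large
#' arbors are overestimated by this idealization; no correction is applied.
#'
#' @param frac_ap Fraction of the anterior-posterior axis covered, in (0, 1].
#' @param frac_dv Fraction of the dorsal-ventral axis covered, in (0, 1].
#' @param n_columns Number of visual columns in the eye model (default 750).
#' @return Estimated number of covered columns (real; round for display).
#' @export
arbor_column_coverage <- function(frac_ap, frac_dv, n_columns = 750) {
  if (any(frac_ap <= 0 | frac_ap > 1) || any(frac_dv <= 0 | frac_dv > 1))
    stop("spread fractions must lie in (0, 1]")
  if (!(n_columns >= 1)) stop("n_columns must be >= 1")
  D <- 2 * sqrt(n_columns / pi)
  pi / 4 * (frac_ap * D) * (frac_dv * D)
}
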