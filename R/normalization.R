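#' Normalization specification
#'
#' The two-step per-chip normalization used for single-channel arrays:
#' a detection floor (signals below \code{floor_value} are raised to it)
#' followed by a percentile shift (each chip's log2 values are shifted so
#' that the chip's Pth percentile is zero). Conventionally P = 75 for
#' mRNA chips and P = 99 for miRNA chips. Exosomal miRNA chips may in
#' addition carry per-sample multiplicative mass-correction factors that
#' rescale signals to a common loaded RNA mass (1 ng).
#'
#' @param floor_value detection floor in linear fluorescence units
#'   (default 1).
#' @param percentile P in (0, 100]; the chip percentile shifted to zero.
#' @param mass_correction_factors optional numeric vector, one linear
#'   multiplicative factor per sample (factor = 1 ng / loaded mass in ng),
#'   or NULL.
#' @param shift_scale \code{"log2"} (default: subtract the chip's Pth
#'   percentile of the log2 values) or \code{"linear"} (divide by the
#'   chip's Pth percentile of the linear values, then log2).
#' @param mass_correct_first logical; apply mass correction to the raw
#'   signals before flooring (default TRUE, treating the correction as a
#'   property of the raw signal), or after flooring and before the shift.
#' @return a \code{NormalizationSpec} list.
#' @export
normalization_spec <- function(floor_value = 1, percentile = 75,
                               mass_correction_factors = NULL,
                               shift_scale = c("log2", "linear"),
                               mass_correct_first = TRUE) {
  shift_scale <- match.arg(shift_scale)
  if (!is.numeric(floor_value) || floor_value <= 0)
    stop("floor_value must be > 0")
  if (!is.numeric(percentile) || percentile <= 0 || percentile > 100)
    stop("percentile must lie in (0, 100]")
  if (!is.null(mass_correction_factors) &&
      any(mass_correction_factors <= 0))
    stop("mass correction factors must be > 0")
  structure(list(floor_value = floor_value, percentile = percentile,
                 mass_correction_factors = mass_correction_factors,
                 shift_scale = shift_scale,
                 mass_correct_first = mass_correct_first),
            class = "NormalizationSpec")
}

#' Apply the detection floor
#'
#' Every linear-scale signal below \code{floor_value} is replaced by
#' \code{floor_value}; all other signals are untouched.
#'
#' @param x an \code{ExpressionMatrix} on the linear scale.
#' @param floor_value detection floor (linear units, default 1).
#' @return the floored \code{ExpressionMatrix}.
#' @export
floor_signals <- function(x, floor_value = 1) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$is_log2)
    stop("floor_signals operates on linear-scale signals; ",
         "this matrix is already log2")
  if (floor_value <= 0)
    stop("floor_value must be > 0")
  x$signals[x$signals < floor_value] <- floor_value
  x
}

#' Percentile-shift normalization
#'
#' Log2-transforms each chip (sample column) and subtracts the chip's Pth
#' percentile of the log2 values, so that after normalization every
#' chip's Pth percentile equals zero and chips become comparable.
#' Percentiles use linear interpolation between closest ranks. The
#' alternative \code{shift_scale = "linear"} divides each chip by its Pth
#' percentile on the linear scale before log2; the two coincide whenever
#' the percentile falls on an exact data rank and differ only in the
#' interpolation scale between ranks.
#'
#' @param x a floored, linear-scale \code{ExpressionMatrix}.
#' @param percentile P in (0, 100].
#' @param shift_scale see \code{\link{normalization_spec}}.
#' @return an \code{ExpressionMatrix} with \code{is_log2 = TRUE} and
#'   \code{normalized = TRUE}.
#' @export
percentile_shift <- function(x, percentile,
                             shift_scale = c("log2", "linear")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  shift_scale <- match.arg(shift_scale)
  if (x$is_log2)
    stop("percentile_shift expects linear-scale input; ",
         "this matrix is already log2 (double normalization?)")
  if (percentile <= 0 || percentile > 100)
    stop("percentile must lie in (0, 100]")
  if (any(x$signals <= 0))
    stop("non-positive signals; apply floor_signals first")
  p <- percentile / 100
  if (shift_scale == "log2") {
    l <- log2(x$signals)
    q <- apply(l, 2L, stats::quantile, probs = p, type = 7, names = FALSE)
    x$signals <- sweep(l, 2L, q, `-`)
  } else {
    q <- apply(x$signals, 2L, stats::quantile, probs = p, type = 7,
               names = FALSE)
    x$signals <- log2(sweep(x$signals, 2L, q, `/`))
  }
  x$is_log2 <- TRUE
  x$normalized <- TRUE
  x
}

#' Exosome mass correction
#'
#' Multiplies each sample's linear signals by a per-sample factor that
#' rescales the chip to a common loaded RNA mass (factor = 1 ng / loaded
#' mass in ng), so exosomal chips loaded with different amounts of RNA
#' become comparable.
#'
#' @param x a linear-scale \code{ExpressionMatrix}.
#' @param factors numeric vector, one factor per sample.
#' @return the corrected \code{ExpressionMatrix}.
#' @export
mass_correct <- function(x, factors) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$is_log2)
    stop("mass_correct operates on linear-scale signals")
  if (length(factors) != ncol(x$signals))
    stop("need one factor per sample: got ", length(factors),
         " factors for ", ncol(x$signals), " samples")
  if (any(factors <= 0))
    stop("mass correction factors must be > 0")
  x$signals <- sweep(x$signals, 2L, factors, `*`)
  x
}

#' Run the full chip normalization
#'
#' Applies, in order: mass correction (if factors are supplied), the
#' detection floor, and the percentile shift, as configured in the
#' \code{\link{normalization_spec}}. No per-feature baseline
#' transformation is performed.
#'
#' @param x a raw linear-scale \code{ExpressionMatrix}.
#' @param spec a \code{NormalizationSpec}.
#' @return a normalized log2 \code{ExpressionMatrix}.
#' @export
normalize_chips <- function(x, spec = normalization_spec()) {
  stopifnot(inherits(x, "ExpressionMatrix"),
            inherits(spec, "NormalizationSpec"))
  if (x$normalized)
    stop("matrix is already normalized; refusing to double-normalize")
  f <- spec$mass_correction_factors
  if (!is.null(f) && spec$mass_correct_first)
    x <- mass_correct(x, f)
  x <- floor_signals(x, spec$floor_value)
  if (!is.null(f) && !spec$mass_correct_first)
    x <- mass_correct(x, f)
  percentile_shift(x, spec$percentile, spec$shift_scale)
}
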