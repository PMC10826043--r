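#' Construct a median-effect fit object
#'
#' Container for the parameters of the mass-action median-effect model
#' \deqn{f_a / f_u = (D / D_m)^m,} where `Dm` is the median-effect dose (the
#' dose producing 50% effect, i.e. the IC50 in an inhibition assay) and `m`
#' the sigmoidicity coefficient of the dose-effect curve (`m = 1` hyperbolic,
#' `m > 1` sigmoidal). Usually produced by [fit_median_effect()]; construct
#' one directly to work from published parameters.
#'
#' @param dm median-effect dose, `> 0`, in the same unit as the input doses.
#' @param m sigmoidicity coefficient; finite and nonzero. `m <= 0` is accepted
#'   with a warning (it implies effect decreasing with dose, unexpected for an
#'   inhibitor).
#' @param r Pearson correlation coefficient of the linearized median-effect
#'   plot, in \[-1, 1\]; `NA` when unknown (e.g. parameters taken from a
#'   publication without the underlying data).
#' @param n_points number of points used in the fit (`NA` if not fitted here).
#' @param dose_unit optional unit label carried through the analysis (e.g.
#'   `"mM"`, `"mg/mL"`); opaque, never interpreted.
#' @param agent optional agent name.
#' @return object of class `medfit`.
#' @examples
#' acarbose <- median_effect_fit(dm = 0.061, m = 1.32, dose_unit = "mM",
#'                               agent = "acarbose")
#' dose_for_effect(acarbose, 0.5)  # the median dose itself
#' @export
median_effect_fit <- function(dm, m, r = NA_real_, n_points = NA_integer_,
                              dose_unit = NA_character_, agent = NA_character_) {
  stopifnot(is.numeric(dm), length(dm) == 1L, is.numeric(m), length(m) == 1L)
  if (!is.finite(dm) || dm <= 0) {
    stop("`dm` (median-effect dose) must be finite and > 0", call. = FALSE)
  }
  if (!is.finite(m) || m == 0) {
    stop("`m` (sigmoidicity) must be finite and nonzero", call. = FALSE)
  }
  if (m < 0) {
    warning("m < 0: effect decreases with dose; check the data orientation",
            call. = FALSE)
  }
  if (!is.na(r) && abs(r) > 1 + 1e-12) {
    stop("`r` must lie in [-1, 1]", call. = FALSE)
  }
  structure(
    list(dm = as.numeric(dm), m = as.numeric(m), r = as.numeric(r),
         n_points = as.integer(n_points), dose_unit = as.character(dose_unit),
         agent = as.character(agent)),
    class = "medfit")
}

#' @export
print.medfit <- function(x, digits = 3, ...) {
  agent <- if (is.na(x$agent)) "median-effect fit" else x$agent
  unit <- if (is.na(x$dose_unit)) "" else paste0(" ", x$dose_unit)
  cat(sprintf("<medfit> %s: Dm = %s%s, m = %s", agent,
              signif(x$dm, digits), unit, signif(x$m, digits)))
  if (!is.na(x$r)) cat(sprintf(", r = %s", signif(x$r, digits)))
  if (!is.na(x$n_points)) cat(sprintf(" (n = %d)", x$n_points))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.medfit <- function(x, ...) {
  data.frame(agent = x$agent, dm = x$dm, m = x$m, r = x$r,
             n_points = x$n_points, dose_unit = x$dose_unit,
             stringsAsFactors = FALSE)
}

is_medfit <- function(x) inherits(x, "medfit")

assert_medfit <- function(x, arg) {
  if (!is_medfit(x)) {
    stop(sprintf("`%s` must be a `medfit` object (see median_effect_fit())", arg),
         call. = FALSE)
  }
  invisible(x)
}

#' Fit the median-effect model to dose-effect data
#'
#' Linearizes the median-effect equation to
#' \deqn{\log_{10}(f_a / f_u) = m \log_{10}(D) - m \log_{10}(D_m)}
#' and fits it by unweighted ordinary least squares of
#' `y = log10(fa / (1 - fa))` on `x = log10(dose)`. The slope is `m`; the
#' x-intercept gives `Dm = 10^(-intercept/slope)`. Conformity of the data to
#' the mass-action model is summarized by the signed Pearson correlation `r`
#' of the `(x, y)` pairs.
#'
#' Points unusable on the log-logit scale — `dose <= 0`, `fa <= 0`, or
#' `fa >= 1` — are excluded from the fit and reported in a warning listing
#' their positions; they are never silently nudged by an epsilon (nudging
#' biases `m`). At least 2 usable points are required; fewer than 4 triggers a
#' warning.
#'
#' @param points data frame with numeric columns `dose` and `fa` (one row per
#'   observation; aggregate replicates first with [aggregate_replicates()] if
#'   desired, or fit all replicates jointly).
#' @param dose_unit,agent optional labels stored on the fit.
#' @return a [median_effect_fit()] object with `r` and `n_points` filled in.
#' @examples
#' d <- data.frame(dose = c(0.5, 1, 2, 4, 8),
#'                 fa = effect_at_dose(median_effect_fit(2, 1.5), c(0.5, 1, 2, 4, 8)))
#' fit_median_effect(d)  # recovers Dm = 2, m = 1.5, r = 1
#' @export
fit_median_effect <- function(points, dose_unit = NA_character_,
                              agent = NA_character_) {
  points <- as.data.frame(points)
  if (!all(c("dose", "fa") %in% names(points))) {
    stop("`points` must have columns `dose` and `fa`", call. = FALSE)
  }
  dose <- as.numeric(points$dose)
  fa <- as.numeric(points$fa)
  usable <- is.finite(dose) & is.finite(fa) & dose > 0 & fa > 0 & fa < 1
  if (any(!usable)) {
    warn_flag("points excluded from the median-effect fit", which(!usable),
              "dose <= 0 or fa outside (0, 1) cannot enter the log-logit transform")
  }
  n <- sum(usable)
  if (n < 2L) {
    stop(sprintf(paste0(
      "need at least 2 usable points (dose > 0, 0 < fa < 1) to fit; got %d ",
      "(excluded positions: %s)"), n,
      if (any(!usable)) paste(which(!usable), collapse = ", ") else "none"),
      call. = FALSE)
  }
  if (n < 4L) {
    warning(sprintf("only %d usable points: the fit is poorly constrained", n),
            call. = FALSE)
  }
  x <- log10(dose[usable])
  y <- log10(fa[usable] / (1 - fa[usable]))
  if (diff(range(x)) == 0) {
    stop("all usable points share one dose: zero variance in log10(dose), slope undefined",
         call. = FALSE)
  }
  ols <- stats::lm(y ~ x)
  m <- unname(stats::coef(ols)[2L])
  intercept <- unname(stats::coef(ols)[1L])
  r <- stats::cor(x, y)
  median_effect_fit(dm = 10^(-intercept / m), m = m, r = r, n_points = n,
                    dose_unit = dose_unit, agent = agent)
}

#' Effect produced by a dose
#'
#' Inverts the fitted median-effect relation to the effect scale:
#' `fa = 1 / (1 + (Dm / D)^m)`. Strictly increasing in `D` when `m > 0`;
#' `effect_at_dose(fit, Dm)` is exactly 0.5.
#'
#' @param fit a [median_effect_fit()] object.
#' @param dose numeric vector of doses, all `> 0`.
#' @return numeric vector of fractions affected in (0, 1).
#' @seealso [dose_for_effect()] for the inverse.
#' @export
effect_at_dose <- function(fit, dose) {
  assert_medfit(fit, "fit")
  if (!is.numeric(dose) || any(!is.finite(dose)) || any(dose <= 0)) {
    stop("`dose` must be finite and > 0", call. = FALSE)
  }
  1 / (1 + (fit$dm / dose)^fit$m)
}

#' Dose required for an effect level
#'
#' Closed-form inverse of [effect_at_dose()]:
#' `D = Dm * (fa / (1 - fa))^(1/m)`. At `fa = 0.5` this is the median dose
#' `Dm` by definition. Round-trips with [effect_at_dose()] to numerical
#' tolerance.
#'
#' @param fit a [median_effect_fit()] object.
#' @param fa numeric vector of effect levels, each strictly inside (0, 1).
#' @return numeric vector of doses (same unit as `fit$dose_unit`).
#' @examples
#' acarbose <- median_effect_fit(0.061, 1.32, dose_unit = "mM")
#' dose_for_effect(acarbose, c(0.10, 0.50, 0.90))
#' @export
dose_for_effect <- function(fit, fa) {
  assert_medfit(fit, "fit")
  if (!is.numeric(fa) || any(!is.finite(fa)) || any(fa <= 0 | fa >= 1)) {
    stop("`fa` must lie strictly inside (0, 1); the model dose diverges at the endpoints",
         call. = FALSE)
  }
  fit$dm * (fa / (1 - fa))^(1 / fit$m)
}
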