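#' Design effect-matched binary mixtures
#'
#' Builds the mixture series in which, at each effect level `x`, the two
#' components are combined at the doses that would each produce `x` percent
#' inhibition when used independently: component doses
#' `(dose_for_effect(fit_a, x), dose_for_effect(fit_b, x))`. The component
#' ratio therefore drifts across levels whenever the two agents' curve shapes
#' differ — this is an effect-matched design, not a fixed-ratio one.
#'
#' @param fit_a,fit_b [median_effect_fit()] objects for the two components.
#' @param effect_levels effect levels in (0, 1); default the classic
#'   IC10/IC30/IC50/IC70/IC90 series.
#' @return tibble with columns `level`, `c_a`, `c_b`, `level_label` and an
#'   `fa` column of `NA` to be filled with the observed mixture effect.
#' @examples
#' acar <- median_effect_fit(0.061, 1.32, dose_unit = "mM", agent = "acarbose")
#' prop <- median_effect_fit(1.07, 0.512, dose_unit = "mg/mL", agent = "propolis")
#' design_effect_matched_mixtures(acar, prop)
#' @export
design_effect_matched_mixtures <- function(fit_a, fit_b,
                                           effect_levels = c(0.10, 0.30, 0.50, 0.70, 0.90)) {
  assert_medfit(fit_a, "fit_a")
  assert_medfit(fit_b, "fit_b")
  if (any(!is.finite(effect_levels)) || any(effect_levels <= 0 | effect_levels >= 1)) {
    stop("effect levels must lie strictly inside (0, 1)", call. = FALSE)
  }
  tibble::tibble(
    level = effect_levels,
    c_a = dose_for_effect(fit_a, effect_levels),
    c_b = dose_for_effect(fit_b, effect_levels),
    fa = NA_real_,
    level_label = sprintf("IC%g-matched", 100 * effect_levels)
  )
}

validate_mixtures <- function(observations) {
  observations <- as.data.frame(observations)
  if (!all(c("c_a", "c_b", "fa") %in% names(observations))) {
    stop("mixture observations need columns `c_a`, `c_b`, `fa`", call. = FALSE)
  }
  with(observations, {
    if (any(c_a < 0 | c_b < 0)) {
      stop("component doses must be >= 0", call. = FALSE)
    }
    if (any(c_a + c_b <= 0)) {
      stop("each mixture needs a positive total dose (c_a + c_b > 0)", call. = FALSE)
    }
    if (any(!is.finite(fa) | fa <= 0 | fa >= 1)) {
      stop("observed `fa` must lie strictly inside (0, 1) for analysis", call. = FALSE)
    }
  })
  observations
}

#' Combination index of binary mixtures
#'
#' For each observed mixture `(c_a, c_b, fa)`, computes the equi-effective
#' single-agent doses `IC_fa,A = dose_for_effect(fit_a, fa)` and `IC_fa,B`,
#' and the combination index
#' \deqn{CI = \frac{C_A}{IC_{fa,A}} + \frac{C_B}{IC_{fa,B}}.}
#' CI below, at, or above 1 indicates synergism, additivity (the Loewe null),
#' or antagonism. The dose-reduction indices `DRI = IC_fa / C` for each
#' component are returned alongside; the identity `CI = 1/DRI_A + 1/DRI_B`
#' holds exactly.
#'
#' @param observations data frame with columns `c_a`, `c_b`, `fa` (and any
#'   others, carried through), one row per mixture.
#' @param fit_a,fit_b single-agent [median_effect_fit()] objects.
#' @param tolerance classification band around CI = 1 passed to
#'   [classify_interaction()]; default 0 (strict).
#' @return tibble with one row per observation: `fa`, `c_a`, `c_b`, `ic_a`,
#'   `ic_b`, `ci`, `dri_a`, `dri_b`, `interaction_class`. A component dose of
#'   0 gives an infinite DRI for that component (its CI term is 0).
#' @examples
#' acar <- median_effect_fit(0.061, 1.32, dose_unit = "mM")
#' prop <- median_effect_fit(1.07, 0.512, dose_unit = "mg/mL")
#' obs <- data.frame(c_a = 0.0115, c_b = 0.0146, fa = 0.235)
#' combination_index(obs, acar, prop)
#' @export
combination_index <- function(observations, fit_a, fit_b, tolerance = 0) {
  assert_medfit(fit_a, "fit_a")
  assert_medfit(fit_b, "fit_b")
  obs <- validate_mixtures(observations)
  ic_a <- dose_for_effect(fit_a, obs$fa)
  ic_b <- dose_for_effect(fit_b, obs$fa)
  ci <- obs$c_a / ic_a + obs$c_b / ic_b
  tibble::tibble(
    fa = obs$fa, c_a = obs$c_a, c_b = obs$c_b,
    ic_a = ic_a, ic_b = ic_b, ci = ci,
    dri_a = ic_a / obs$c_a, dri_b = ic_b / obs$c_b,
    interaction_class = classify_interaction(ci, tolerance)
  )
}

#' Dose-reduction index of one mixture component
#'
#' Fold reduction in an agent's dose achieved by the combination at equal
#' effect: the dose of the agent alone producing the observed mixture effect,
#' divided by its dose inside the mixture,
#' `DRI = dose_for_effect(fit, fa) / dose`. A DRI above 1 is favorable. The
#' classic definition is written at the 50% level; here it is evaluated at
#' whatever effect level the mixture actually produced, which is the form
#' tabulated per effect level in practice.
#'
#' @param dose the component's dose inside the mixture (`> 0`).
#' @param fa observed fractional effect of the mixture, in (0, 1).
#' @param fit the component's single-agent [median_effect_fit()].
#' @param allow_infinite return `Inf` for a zero component dose instead of
#'   erroring (a component absent from the mixture has unbounded dose
#'   reduction). Default `FALSE`.
#' @return numeric vector of DRIs.
#' @export
dose_reduction_index <- function(dose, fa, fit, allow_infinite = FALSE) {
  assert_medfit(fit, "fit")
  if (any(!is.finite(dose) | dose < 0) || (!allow_infinite && any(dose == 0))) {
    stop("component `dose` must be > 0 (set allow_infinite = TRUE to report Inf for absent components)",
         call. = FALSE)
  }
  dose_for_effect(fit, fa) / dose
}

#' Classify a combination index
#'
#' Maps CI to the interaction class: synergism when `ci < 1 - tolerance`,
#' antagonism when `ci > 1 + tolerance`, additivity otherwise. The default
#' `tolerance = 0` is the strict textbook rule; a small band is useful for
#' noisy data where CI hovers around 1.
#'
#' @param ci numeric vector of combination indices, all `> 0`.
#' @param tolerance half-width of the additivity band, `>= 0`.
#' @return character vector: `"synergism"`, `"additivity"` or `"antagonism"`.
#' @export
classify_interaction <- function(ci, tolerance = 0) {
  if (any(!is.finite(ci) | ci <= 0)) {
    stop("`ci` must be finite and > 0", call. = FALSE)
  }
  stopifnot(tolerance >= 0)
  dplyr::case_when(
    ci < 1 - tolerance ~ "synergism",
    ci > 1 + tolerance ~ "antagonism",
    .default = "additivity"
  )
}

#' fa-CI curve
#'
#' Combination index as a function of effect level, the standard diagnostic
#' for how an interaction changes along the dose-effect curve. Two modes:
#'
#' * **Observation mode** (`observations` given): CI at each observed mixture
#'   exactly as in [combination_index()].
#' * **Constant-ratio mode** (`combo_fit` and `ratio` given): the mixture is
#'   treated as a single diluted drug with median-effect fit `combo_fit`; at
#'   each `fa` in `fa_grid` the total dose is `dose_for_effect(combo_fit, fa)`
#'   and is split `(ratio, 1 - ratio)` between A and B.
#'
#' @param fit_a,fit_b single-agent [median_effect_fit()] objects.
#' @param combo_fit [median_effect_fit()] of the mixture on total dose
#'   (constant-ratio mode), e.g. from [combination_median_effect()].
#' @param ratio fraction of the total dose contributed by component A, in
#'   \[0, 1\] (constant-ratio mode).
#' @param observations mixture data frame (`c_a`, `c_b`, `fa`) for
#'   observation mode.
#' @param fa_grid effect levels at which to evaluate CI in constant-ratio
#'   mode.
#' @return tibble with columns `fa`, `ci` (plus the dose columns).
#' @export
fa_ci_curve <- function(fit_a, fit_b, combo_fit = NULL, ratio = NULL,
                        observations = NULL,
                        fa_grid = seq(0.05, 0.95, by = 0.05)) {
  assert_medfit(fit_a, "fit_a")
  assert_medfit(fit_b, "fit_b")
  if (!is.null(observations)) {
    res <- combination_index(observations, fit_a, fit_b)
    return(res[, c("fa", "c_a", "c_b", "ci")])
  }
  if (is.null(combo_fit) || is.null(ratio)) {
    stop(paste0("provide either `observations` (observation mode) or both ",
                "`combo_fit` and `ratio` (constant-ratio mode)"), call. = FALSE)
  }
  assert_medfit(combo_fit, "combo_fit")
  stopifnot(is.numeric(ratio), length(ratio) == 1L, ratio >= 0, ratio <= 1)
  total <- dose_for_effect(combo_fit, fa_grid)
  obs <- tibble::tibble(c_a = total * ratio, c_b = total * (1 - ratio),
                        fa = fa_grid)
  res <- combination_index(obs, fit_a, fit_b)
  res[, c("fa", "c_a", "c_b", "ci")]
}

#' Isobologram data
#'
#' Equal-effect diagram of the two components' doses. Two representations are
#' returned:
#'
#' * `classical`: per effect level, the additive line joins the single-agent
#'   equi-effective doses `(IC_x,A, 0)` and `(0, IC_x,B)` in raw dose space;
#'   each observation at that (approximate) level is placed at its component
#'   doses.
#' * `normalized`: every observation is mapped to
#'   `(c_a / IC_fa,A, c_b / IC_fa,B)` where the equi-effective doses are taken
#'   at the observation's own `fa`; the additive line is `x + y = 1` for all
#'   levels at once, and the coordinate sum of a point is exactly its CI.
#'
#' Points below, on, or above the additive line indicate synergism,
#' additivity, or antagonism.
#'
#' @param fit_a,fit_b single-agent [median_effect_fit()] objects.
#' @param observations mixture data frame (`c_a`, `c_b`, `fa`).
#' @param effect_levels levels for the classical additive lines.
#' @param tolerance on-line band for the position label (in CI units).
#' @return object of class `isobologram`: a list with tibbles `classical`
#'   (`level`, `ic_a`, `ic_b`) and `points` (`fa`, `c_a`, `c_b`, `x`, `y`,
#'   `ci`, `position`). Plot with [plot_isobologram()] or export with
#'   [render_report()].
#' @export
isobologram <- function(fit_a, fit_b, observations,
                        effect_levels = c(0.10, 0.30, 0.50, 0.70, 0.90),
                        tolerance = 0) {
  assert_medfit(fit_a, "fit_a")
  assert_medfit(fit_b, "fit_b")
  metrics <- combination_index(observations, fit_a, fit_b)
  pts <- tibble::tibble(
    fa = metrics$fa, c_a = metrics$c_a, c_b = metrics$c_b,
    x = metrics$c_a / metrics$ic_a, y = metrics$c_b / metrics$ic_b,
    ci = metrics$ci,
    position = dplyr::case_when(
      metrics$ci < 1 - tolerance ~ "below",
      metrics$ci > 1 + tolerance ~ "above",
      .default = "on"
    )
  )
  lines <- tibble::tibble(
    level = effect_levels,
    ic_a = dose_for_effect(fit_a, effect_levels),
    ic_b = dose_for_effect(fit_b, effect_levels)
  )
  structure(list(classical = lines, points = pts,
                 agent_a = fit_a$agent, agent_b = fit_b$agent,
                 unit_a = fit_a$dose_unit, unit_b = fit_b$dose_unit),
            class = "isobologram")
}

#' @export
print.isobologram <- function(x, ...) {
  cat(sprintf("<isobologram> %d observation(s), %d additive line level(s)\n",
              nrow(x$points), nrow(x$classical)))
  print(x$points)
  invisible(x)
}

#' Median-effect fit of a binary mixture
#'
#' Fits the median-effect model to mixture observations, taking the total
#' dose `c_a + c_b` as the dose variable. When the two components carry
#' different dose units the sum is a formal quantity; the resulting fit is
#' tagged with a composite unit label and a warning is emitted. This is the
#' standard treatment of a combination as a third "drug" whose CI behaviour
#' is then read off the fa-CI curve.
#'
#' @param observations mixture data frame (`c_a`, `c_b`, `fa`).
#' @param unit_a,unit_b component dose units (used for the composite label).
#' @param agent label for the fitted mixture (e.g. `"A + B"`).
#' @return a [median_effect_fit()] object on the total-dose scale.
#' @export
combination_median_effect <- function(observations, unit_a = NA_character_,
                                      unit_b = NA_character_,
                                      agent = NA_character_) {
  obs <- validate_mixtures(observations)
  unit <- if (!is.na(unit_a) && !is.na(unit_b) && identical(unit_a, unit_b)) {
    unit_a
  } else if (!is.na(unit_a) || !is.na(unit_b)) {
    warning(sprintf(paste0(
      "summing component doses with heterogeneous units (%s + %s); ",
      "the combination's Dm is on this composite scale"),
      unit_a, unit_b), call. = FALSE)
    paste0(unit_a, "+", unit_b)
  } else {
    NA_character_
  }
  fit_median_effect(data.frame(dose = obs$c_a + obs$c_b, fa = obs$fa),
                    dose_unit = unit, agent = agent)
}

#' Plot a normalized isobologram
#'
#' Normalized dose-space view: each observation at
#' `(c_a / IC_fa,A, c_b / IC_fa,B)` against the additive line `x + y = 1`.
#'
#' @param iso an [isobologram()] object.
#' @return a ggplot object.
#' @export
plot_isobologram <- function(iso) {
  stopifnot(inherits(iso, "isobologram"))
  lab_a <- if (is.na(iso$agent_a)) "A" else iso$agent_a
  lab_b <- if (is.na(iso$agent_b)) "B" else iso$agent_b
  ggplot2::ggplot(iso$points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = -1, intercept = 1, linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$position), size = 2.5) +
    ggplot2::labs(x = sprintf("%s dose / equi-effective dose", lab_a),
                  y = sprintf("%s dose / equi-effective dose", lab_b),
                  colour = "vs additive line") +
    ggplot2::coord_cartesian(xlim = c(0, NA), ylim = c(0, NA)) +
    ggplot2::theme_classic()
}

#' Plot the fa-CI curve
#'
#' @param curve tibble from [fa_ci_curve()].
#' @return a ggplot object.
#' @export
plot_fa_ci <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$fa, y = .data$ci)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "fraction affected (fa)", y = "combination index (CI)") +
    ggplot2::theme_classic()
}
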