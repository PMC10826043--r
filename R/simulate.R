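#' Simulate dose-effect data from known median-effect parameters
#'
#' Generates `fa` observations from the median-effect model with Gaussian
#' noise added on the linearized (log-logit) scale:
#' `y = m * log10(D / Dm) + e`, `e ~ N(0, noise_sd^2)`, then
#' `fa = 10^y / (1 + 10^y)`. Noise on this scale keeps every simulated `fa`
#' strictly inside (0, 1) and makes the OLS fit of [fit_median_effect()] the
#' exact maximum-likelihood estimator under the simulation, so parameter
#' recovery is sharp. With `noise_sd = 0` the output equals
#' [effect_at_dose()] exactly and the simulate-fit round trip returns
#' `(dm, m)` with `r = 1`.
#'
#' For realism at the raw-signal level use `absorbance = TRUE`, which also
#' returns control-anchored 540 nm absorbances via
#' [inhibition_to_absorbance()] with Gaussian noise of `abs_noise_sd` AU
#' added to the extract reading.
#'
#' @param dm,m true median-effect parameters (`dm > 0`, `m > 0`).
#' @param doses dose grid (`> 0`), e.g. a log-spaced series around `dm`.
#' @param noise_sd standard deviation of the noise on the `log10(fa/fu)`
#'   scale; `>= 0`.
#' @param replicates replicate measurements per dose, `>= 1`.
#' @param seed optional integer; when given, generation is deterministic and
#'   the caller's RNG state is untouched.
#' @param absorbance also simulate raw absorbance triples.
#' @param abs_positive,abs_negative,abs_noise_sd absorbance-mode controls
#'   (AU): fully-inhibited and uninhibited control levels, and extract-reading
#'   noise.
#' @return tibble with columns `dose`, `replicate`, `fa` (plus `abs_extract`,
#'   `abs_positive`, `abs_negative` in absorbance mode).
#' @examples
#' simulate_dose_effect(dm = 2, m = 1.5, doses = c(0.5, 1, 2, 4, 8))
#' @export
simulate_dose_effect <- function(dm, m, doses, noise_sd = 0, replicates = 1L,
                                 seed = NULL, absorbance = FALSE,
                                 abs_positive = 0.10, abs_negative = 0.80,
                                 abs_noise_sd = 0) {
  stopifnot(is.finite(dm), dm > 0, is.finite(m), m > 0,
            is.finite(noise_sd), noise_sd >= 0, replicates >= 1L)
  if (any(!is.finite(doses) | doses <= 0)) {
    stop("`doses` must be finite and > 0", call. = FALSE)
  }
  gen <- function() {
    d <- rep(doses, each = replicates)
    y <- m * log10(d / dm) + stats::rnorm(length(d), 0, noise_sd)
    out <- tibble::tibble(dose = d,
                          replicate = rep(seq_len(replicates), length(doses)),
                          fa = 10^y / (1 + 10^y))
    if (absorbance) {
      tr <- inhibition_to_absorbance(out$fa, abs_positive, abs_negative)
      tr$abs_extract <- tr$abs_extract + stats::rnorm(nrow(tr), 0, abs_noise_sd)
      out <- dplyr::bind_cols(out, tr)
    }
    out
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Effect of a binary mixture under a prescribed interaction strength
#'
#' Solves for the unique effect level `fa` at which the mixture's combination
#' index equals `ci_true`:
#' \deqn{\frac{c_A}{IC_{fa,A}} + \frac{c_B}{IC_{fa,B}} = CI_{true}.}
#' With `ci_true = 1` this is the Loewe-additivity null — the effect the
#' mixture would produce if the two agents behaved as dilutions of one
#' another; `ci_true < 1` generates synergistic data, `> 1` antagonistic.
#' Because both equi-effective doses increase strictly with `fa` (for
#' `m > 0`), the left side is strictly decreasing in `fa` and the root is
#' unique; it is found numerically to `|delta fa| < 1e-10`.
#'
#' Re-analyzing mixtures generated this way with [combination_index()] (using
#' the same fits) returns `ci_true` at every level, which makes the
#' generator-analyzer pair a closed loop for validation.
#'
#' @param fit_a,fit_b single-agent [median_effect_fit()] objects.
#' @param c_a,c_b component doses (vectors recycled to a common length;
#'   `c_a + c_b > 0` per mixture).
#' @param ci_true target combination index, `> 0`; default 1 (Loewe null).
#' @return numeric vector of `fa` values in (0, 1).
#' @examples
#' acar <- median_effect_fit(0.061, 1.32)
#' prop <- median_effect_fit(1.07, 0.512)
#' simulate_mixture_fa(acar, prop, c_a = 0.0305, c_b = 0.535)  # additive fa
#' @export
simulate_mixture_fa <- function(fit_a, fit_b, c_a, c_b, ci_true = 1) {
  assert_medfit(fit_a, "fit_a")
  assert_medfit(fit_b, "fit_b")
  stopifnot(is.finite(ci_true), ci_true > 0)
  n <- max(length(c_a), length(c_b))
  c_a <- rep_len(c_a, n)
  c_b <- rep_len(c_b, n)
  if (any(c_a < 0 | c_b < 0) || any(c_a + c_b <= 0)) {
    stop("component doses must be >= 0 with c_a + c_b > 0", call. = FALSE)
  }
  lo <- 1e-12
  hi <- 1 - 1e-12
  vapply(seq_len(n), function(i) {
    f <- function(fa) {
      c_a[i] / dose_for_effect(fit_a, fa) + c_b[i] / dose_for_effect(fit_b, fa) - ci_true
    }
    flo <- f(lo)
    fhi <- f(hi)
    if (!is.finite(flo) || !is.finite(fhi) || flo < 0 || fhi > 0) {
      stop(sprintf(paste0(
        "no root in (0, 1) for mixture %d (c_a = %g, c_b = %g, ci_true = %g): ",
        "CI - ci_true spans [%g, %g] over fa in [%g, %g]"),
        i, c_a[i], c_b[i], ci_true, fhi, flo, lo, hi), call. = FALSE)
    }
    stats::uniroot(f, lower = lo, upper = hi, tol = 1e-12)$root
  }, numeric(1))
}

#' Absorbance triple producing a given fractional inhibition
#'
#' Inverse of [percent_inhibition()]: constructs the extract absorbance that,
#' with the given controls, yields exactly `100 * fa` percent inhibition —
#' `abs_extract = abs_positive + (1 - fa) * (abs_negative - abs_positive)`.
#' Used to build end-to-end pipeline tests and absorbance-level simulations.
#'
#' @param fa fractional inhibition (vector).
#' @param abs_positive,abs_negative control absorbances (AU), distinct.
#' @return tibble with columns `abs_extract`, `abs_positive`, `abs_negative`.
#' @export
inhibition_to_absorbance <- function(fa, abs_positive, abs_negative) {
  stopifnot(is.numeric(fa), all(is.finite(fa)))
  if (any(abs_negative == abs_positive)) {
    stop("control absorbances must differ (degenerate controls)", call. = FALSE)
  }
  tibble::tibble(
    abs_extract = abs_positive + (1 - fa) * (abs_negative - abs_positive),
    abs_positive = rep_len(abs_positive, length(fa)),
    abs_negative = rep_len(abs_negative, length(fa))
  )
}
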