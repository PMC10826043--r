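#' Percent inhibition from DNS-assay absorbances
#'
#' Converts one or more absorbance triples (extract, positive control,
#' negative control, all read at 540 nm) into percent inhibition of the
#' enzyme:
#'
#' \deqn{\%Inh = 100 \times \left[1 - \frac{A_{extract} - A_{pos}}{A_{neg} - A_{pos}}\right]}
#'
#' The positive control is the fully inhibited reaction (reference drug), the
#' negative control the uninhibited one. The equation is affine in
#' `abs_extract`, so an extract reading equal to the negative control gives 0%
#' and one equal to the positive control gives 100%.
#'
#' Values outside \[0, 100\] can arise from measurement noise; they are
#' returned unchanged with a warning rather than clamped, so that raw data are
#' preserved. Clamping happens only at [to_fraction_affected()].
#'
#' @param abs_extract numeric, absorbance of the test reaction (AU).
#' @param abs_positive numeric, absorbance of the positive (fully inhibited)
#'   control (AU).
#' @param abs_negative numeric, absorbance of the negative (uninhibited)
#'   control (AU).
#' @return numeric vector of percent inhibition values.
#' @examples
#' percent_inhibition(0.45, abs_positive = 0.10, abs_negative = 0.80)  # 50
#' @seealso [to_fraction_affected()], [inhibition_to_absorbance()]
#' @export
percent_inhibition <- function(abs_extract, abs_positive, abs_negative) {
  n <- max(length(abs_extract), length(abs_positive), length(abs_negative))
  abs_extract <- rep_len(abs_extract, n)
  abs_positive <- rep_len(abs_positive, n)
  abs_negative <- rep_len(abs_negative, n)
  vals <- c(abs_extract, abs_positive, abs_negative)
  if (!all(is.finite(vals))) {
    stop("all absorbances must be finite", call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("absorbances must be >= 0", call. = FALSE)
  }
  bad <- abs_negative == abs_positive
  if (any(bad)) {
    stop(sprintf(paste0(
      "degenerate controls: negative-control absorbance equals ",
      "positive-control absorbance (%s) at position(s) %s; ",
      "the inhibition equation denominator is zero"),
      format(abs_positive[which(bad)[1L]]),
      paste(utils::head(which(bad), 5L), collapse = ", ")), call. = FALSE)
  }
  pct <- 100 * (1 - (abs_extract - abs_positive) / (abs_negative - abs_positive))
  out_of_range <- which(pct < 0 | pct > 100)
  if (length(out_of_range)) {
    warn_flag("percent inhibition outside [0, 100]", out_of_range,
              "returned unchanged; will be clamped at the fa conversion")
  }
  pct
}

#' Convert percent inhibition to fraction affected
#'
#' Divides by 100 and clamps to \[0, 1\], with a warning whenever clamping
#' occurs (noise can push percent inhibition slightly outside \[0, 100\]).
#' The fraction affected `fa` is the model-domain quantity used by
#' [fit_median_effect()]; its complement `fu = 1 - fa` is computed on demand,
#' never stored.
#'
#' @param percent numeric vector of percent inhibition values.
#' @return numeric vector of `fa` values in \[0, 1\].
#' @examples
#' to_fraction_affected(c(50, 23.5))
#' @export
to_fraction_affected <- function(percent) {
  if (!is.numeric(percent) || !all(is.finite(percent))) {
    stop("percent inhibition must be finite numeric", call. = FALSE)
  }
  fa <- percent / 100
  clamped <- which(fa < 0 | fa > 1)
  if (length(clamped)) {
    warn_flag("fraction affected clamped to [0, 1]", clamped,
              "input percent inhibition was outside [0, 100]")
    fa <- pmin(pmax(fa, 0), 1)
  }
  fa
}

#' Average replicate dose-effect measurements
#'
#' Collapses replicate observations to one point per unique dose (per agent,
#' if an `agent` column is present), with `fa` the arithmetic mean across
#' replicates. The replicate count and the standard deviation of `fa` are
#' retained as `n_replicates` and `fa_sd` columns.
#'
#' Aggregation is on the `fa` scale, not the absorbance scale; convert raw
#' absorbances with [percent_inhibition()] and [to_fraction_affected()] first.
#'
#' @param points data frame with columns `dose` and `fa`, optionally `agent`.
#' @return tibble with one row per (agent,) dose: `dose`, `fa` (mean),
#'   `n_replicates`, `fa_sd` (`NA` for singletons).
#' @examples
#' aggregate_replicates(data.frame(dose = c(1, 1, 2), fa = c(0.4, 0.6, 0.7)))
#' @export
aggregate_replicates <- function(points) {
  points <- as.data.frame(points)
  if (nrow(points) == 0L) {
    stop("no dose-effect points to aggregate", call. = FALSE)
  }
  if (!all(c("dose", "fa") %in% names(points))) {
    stop("`points` must have columns `dose` and `fa`", call. = FALSE)
  }
  keys <- intersect(c("agent", "dose"), names(points))
  out <- dplyr::summarise(
    dplyr::group_by(points, dplyr::across(dplyr::all_of(keys))),
    n_replicates = dplyr::n(),
    fa_sd = if (dplyr::n() > 1L) stats::sd(.data$fa) else NA_real_,
    fa = mean(.data$fa),
    .groups = "drop"
  )
  tibble::as_tibble(out[, c(keys, "fa", "n_replicates", "fa_sd")])
}

#' Read and write dose-effect tables
#'
#' Plain-CSV I/O for dose-effect data. The file must have a header; columns
#' are either already-reduced (`agent, dose, dose_unit, fa[, replicate]`) or
#' raw absorbances (`agent, dose, dose_unit, abs_extract, abs_positive,
#' abs_negative[, replicate]`), in which case the reader reduces them via
#' [percent_inhibition()] and [to_fraction_affected()]. Columns and units are
#' taken from the header as declared, never inferred from magnitudes.
#'
#' @param path file path.
#' @return `read_dose_effect()`: tibble with columns `agent`, `dose`,
#'   `dose_unit`, `fa` and, when present in the file, `replicate`.
#' @export
read_dose_effect <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  raw_cols <- c("abs_extract", "abs_positive", "abs_negative")
  if (all(raw_cols %in% names(df))) {
    df$fa <- to_fraction_affected(
      percent_inhibition(df$abs_extract, df$abs_positive, df$abs_negative))
    df <- df[, setdiff(names(df), raw_cols)]
  }
  need <- c("agent", "dose", "dose_unit", "fa")
  if (!all(need %in% names(df))) {
    stop(sprintf("dose-effect CSV must declare columns %s (or raw absorbance columns); found: %s",
                 paste(need, collapse = ", "), paste(names(df), collapse = ", ")),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' @param x data frame of dose-effect points.
#' @rdname read_dose_effect
#' @export
write_dose_effect <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}
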