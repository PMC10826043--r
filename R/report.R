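#' Worked alpha-amylase inhibition example
#'
#' Published median-effect parameters for pancreatic alpha-amylase inhibition
#' by acarbose, kaempferol and an Egyptian propolis extract (DNS assay,
#' 540 nm), together with the observed fractional inhibition of the
#' effect-matched binary combinations acarbose + propolis and acarbose +
#' kaempferol at the IC10/IC30/IC50/IC70/IC90-matched levels, and the
#' published per-level CI, dose and DRI columns for cross-checking.
#'
#' The mixture component doses are the nominal design doses of the
#' effect-matched protocol (each agent's IC10...IC90 from its own fit); the
#' published per-level dose columns are the *single-agent* equi-effective
#' doses at the observed effect, from which the in-combination doses follow
#' as `IC_x / DRI`.
#'
#' @return list with elements:
#'   * `fits`: named list of single-agent [median_effect_fit()] objects
#'     (`acarbose`, `kaempferol`, `propolis`).
#'   * `combo_fits`: named list of the published combination fits on the
#'     total-dose scale.
#'   * `mixtures`: named list of tibbles (`level`, `c_a`, `c_b`, `fa`,
#'     `level_label`), one per pair, with nominal design doses and observed
#'     `fa`.
#'   * `reference`: tibble of the published per-level CI, equi-effective dose
#'     and DRI values (columns suffixed `_printed`).
#' @examples
#' ex <- amylase_example()
#' combination_index(ex$mixtures$`acarbose+propolis`, ex$fits$acarbose,
#'                   ex$fits$propolis)
#' @export
amylase_example <- function() {
  pars <- readr::read_csv(
    system.file("extdata", "amylase_median_effect.csv", package = "medsyn",
                mustWork = TRUE), show_col_types = FALSE)
  ref <- readr::read_csv(
    system.file("extdata", "amylase_combination_reference.csv",
                package = "medsyn", mustWork = TRUE), show_col_types = FALSE)
  mk <- function(row) {
    median_effect_fit(dm = row$dm, m = row$m, r = row$r,
                      dose_unit = row$dose_unit, agent = row$agent)
  }
  singles <- pars[!pars$is_combination, ]
  combos <- pars[pars$is_combination, ]
  fits <- setNames(lapply(seq_len(nrow(singles)),
                          function(i) mk(singles[i, ])), singles$agent)
  combo_fits <- setNames(lapply(seq_len(nrow(combos)),
                                function(i) mk(combos[i, ])), combos$agent)
  mixtures <- lapply(split(ref, ref$pair), function(tab) {
    des <- design_effect_matched_mixtures(fits[[tab$agent_a[1L]]],
                                          fits[[tab$agent_b[1L]]],
                                          effect_levels = tab$level)
    des$fa <- tab$fa_obs
    des
  })
  list(fits = fits, combo_fits = combo_fits, mixtures = mixtures,
       reference = ref)
}

#' Run the full combination analysis
#'
#' Orchestrates the pipeline: reduce dose-effect data (if given as raw
#' points), fit each single agent, then for each combination pair compute the
#' per-level combination metrics ([combination_index()]), the mixture's own
#' median-effect fit on total dose ([combination_median_effect()]) and the
#' isobologram representations. Deterministic for fixed inputs.
#'
#' @param config a list with elements:
#'   * `dose_effect`: data frame (`agent`, `dose`, `fa`\[, `dose_unit`,
#'     `replicate`\]) of single-agent data, and/or `fits`: named list of
#'     ready-made [median_effect_fit()] objects (fits win on name clashes).
#'   * `pairs`: list of lists, each with `a`, `b` (agent names) and
#'     `mixtures` (data frame `c_a`, `c_b`, `fa`). Optional; empty gives a
#'     fits-only report.
#'   * `effect_levels`: levels for isobologram additive lines (default
#'     IC10...IC90 series).
#'   * `tolerance`: CI classification band (default 0).
#' @return object of class `analysis_report`: list with `fits` (tibble, one
#'   row per agent), `combinations` (named list with `metrics`, `combo_fit`,
#'   `isobologram`) and `provenance`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(is.list(config))
  levels <- config$effect_levels %||% c(0.10, 0.30, 0.50, 0.70, 0.90)
  tol <- config$tolerance %||% 0
  fits <- list()
  if (!is.null(config$dose_effect)) {
    de <- as.data.frame(config$dose_effect)
    stopifnot(all(c("agent", "dose", "fa") %in% names(de)))
    for (ag in unique(de$agent)) {
      sub <- de[de$agent == ag, , drop = FALSE]
      unit <- if ("dose_unit" %in% names(sub)) as.character(sub$dose_unit[1L]) else NA_character_
      fits[[ag]] <- fit_median_effect(sub, dose_unit = unit, agent = ag)
    }
  }
  for (nm in names(config$fits)) fits[[nm]] <- config$fits[[nm]]
  if (!length(fits)) {
    stop("config must provide `dose_effect` data and/or `fits`", call. = FALSE)
  }
  fit_tab <- dplyr::bind_rows(lapply(fits, as.data.frame))
  combinations <- list()
  for (pair in config$pairs %||% list()) {
    if (!all(c("a", "b", "mixtures") %in% names(pair))) {
      stop("each pair needs elements `a`, `b`, `mixtures`", call. = FALSE)
    }
    for (side in c("a", "b")) {
      if (!pair[[side]] %in% names(fits)) {
        stop(sprintf("pair component '%s' has no fitted agent", pair[[side]]),
             call. = FALSE)
      }
    }
    fa_fit <- fits[[pair$a]]
    fb_fit <- fits[[pair$b]]
    key <- paste(pair$a, pair$b, sep = "+")
    metrics <- combination_index(pair$mixtures, fa_fit, fb_fit, tolerance = tol)
    combo_fit <- combination_median_effect(pair$mixtures,
                                           unit_a = fa_fit$dose_unit,
                                           unit_b = fb_fit$dose_unit,
                                           agent = key)
    combinations[[key]] <- list(
      metrics = metrics,
      combo_fit = combo_fit,
      isobologram = isobologram(fa_fit, fb_fit, pair$mixtures,
                                effect_levels = levels, tolerance = tol)
    )
  }
  structure(list(
    fits = tibble::as_tibble(fit_tab),
    combinations = combinations,
    provenance = list(
      package = "medsyn",
      version = as.character(utils::packageVersion("medsyn")),
      effect_levels = levels,
      tolerance = tol,
      agents = sort(names(fits)),
      pairs = names(combinations),
      inputs = config$input_files %||% character(0)
    )
  ), class = "analysis_report")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d agent fit(s), %d combination(s)\n",
              nrow(x$fits), length(x$combinations)))
  print(x$fits)
  for (nm in names(x$combinations)) {
    cat("\n--", nm, "--\n")
    print(x$combinations[[nm]]$metrics)
  }
  invisible(x)
}

# per-level combination table in the published layout:
# fa x 100, CI (+class), single-agent equi-effective doses, DRIs
combination_table <- function(metrics) {
  tibble::tibble(
    fa_pct = 100 * metrics$fa,
    ci = metrics$ci,
    interaction_class = metrics$interaction_class,
    dose_a = metrics$ic_a,
    dose_b = metrics$ic_b,
    dri_a = metrics$dri_a,
    dri_b = metrics$dri_b
  )
}

#' Serialize an analysis report
#'
#' Renders an [run_full_analysis()] report deterministically (identical
#' report, identical bytes):
#'
#' * `"json"`: full machine precision, fixed key order; round-trips
#'   losslessly.
#' * `"csv"`: two CSV blocks (fits table; per-level combination tables) at 3
#'   significant figures.
#' * `"markdown"`: human-readable tables at 3 significant figures, the
#'   combination columns ordered as in the classic per-effect-level table
#'   (fa x 100, CI, doses, DRIs).
#'
#' @param report an `analysis_report`.
#' @param format one of `"json"`, `"csv"`, `"markdown"`.
#' @return a single character string.
#' @export
render_report <- function(report, format = c("json", "csv", "markdown")) {
  stopifnot(inherits(report, "analysis_report"))
  format <- match.arg(format)
  tabs <- lapply(report$combinations, function(cb) combination_table(cb$metrics))
  if (format == "json") {
    payload <- list(
      fits = report$fits,
      combinations = lapply(names(report$combinations), function(nm) {
        cb <- report$combinations[[nm]]
        list(pair = nm,
             table = tabs[[nm]],
             combo_fit = as.data.frame(cb$combo_fit),
             isobologram_points = cb$isobologram$points,
             additive_lines = cb$isobologram$classical)
      }),
      provenance = report$provenance
    )
    return(as.character(jsonlite::toJSON(payload, dataframe = "columns",
                                         digits = NA, auto_unbox = TRUE,
                                         na = "null")))
  }
  sig3 <- function(df) {
    df[] <- lapply(df, function(col) if (is.numeric(col)) signif(col, 3) else col)
    df
  }
  if (format == "csv") {
    lines <- c("# fits", readr::format_csv(sig3(report$fits)))
    for (nm in names(tabs)) {
      lines <- c(lines, sprintf("# combination: %s", nm),
                 readr::format_csv(sig3(tabs[[nm]])))
    }
    return(paste(lines, collapse = "\n"))
  }
  md_table <- function(df) {
    df <- sig3(df)
    cells <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
    cells <- matrix(cells, nrow = nrow(df))
    paste(c(paste0("| ", paste(names(df), collapse = " | "), " |"),
            paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
            apply(cells, 1L, function(rw) paste0("| ", paste(rw, collapse = " | "), " |"))),
          collapse = "\n")
  }
  out <- c("## Single-agent median-effect fits", "", md_table(report$fits), "")
  for (nm in names(tabs)) {
    out <- c(out, sprintf("## Combination: %s", nm), "", md_table(tabs[[nm]]), "")
  }
  paste(out, collapse = "\n")
}

#' Parse a JSON report back into tables
#'
#' Inverse of `render_report(report, "json")` at the level of the tables:
#' returns the fits table, the per-pair combination tables and the provenance
#' block with full numeric precision.
#'
#' @param json character scalar as produced by [render_report()].
#' @return list with `fits`, `combinations` (named list of tibbles),
#'   `provenance`.
#' @export
parse_report_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  combos <- obj$combinations
  tables <- setNames(
    lapply(seq_along(combos$pair), function(i) {
      tibble::as_tibble(as.data.frame(lapply(combos$table[i, ], unlist)))
    }),
    combos$pair)
  list(fits = tibble::as_tibble(obj$fits), combinations = tables,
       provenance = obj$provenance)
}
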