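# Per-cell, per-parameter change scores: log-transformed, baseline-relative,
# and centered on the control group, the substrate of the per-condition radar
# summaries.

#' Log change score of one parameter
#'
#' Natural-log difference between a post-treatment value and the baseline
#' value of the same cell. The base is a pure rescaling of all scores and
#' cancels in group contrasts.
#'
#' @param value_bl,value_t positive cell-level parameter values at baseline
#'   and at the later timepoint.
#' @return `log(value_t) - log(value_bl)`.
#' @export
change_score <- function(value_bl, value_t) {
  if (any(!is.finite(value_bl)) || any(!is.finite(value_t)) ||
      any(value_bl <= 0) || any(value_t <= 0)) {
    stop("change_score requires positive, finite values")
  }
  log(value_t) - log(value_bl)
}

#' Center raw change scores on the control group
#'
#' Subtracts, within every (parameter, timepoint) stratum, the mean raw score
#' of the control condition, so that the control group's mean normalized
#' score is exactly 0 in every stratum.
#'
#' @param scores tibble with columns `cell_id`, `condition`, `timepoint`,
#'   `parameter`, `raw_score`.
#' @param control_label the condition to center on.
#' @return the input with a `normalized_score` column appended.
#' @export
normalize_to_control <- function(scores, control_label = "control") {
  needed <- c("cell_id", "condition", "timepoint", "parameter", "raw_score")
  stopifnot(all(needed %in% names(scores)))
  strata <- unique(scores[, c("parameter", "timepoint")])
  missing_ctrl <- character()
  for (i in seq_len(nrow(strata))) {
    sel <- scores$parameter == strata$parameter[i] &
      scores$timepoint == strata$timepoint[i] &
      scores$condition == control_label
    if (!any(sel & is.finite(scores$raw_score))) {
      missing_ctrl <- c(missing_ctrl,
                        sprintf("%s @ %s", strata$parameter[i],
                                strata$timepoint[i]))
    }
  }
  if (length(missing_ctrl)) {
    stop("no control cells in stratum(s): ",
         paste(missing_ctrl, collapse = "; "))
  }
  ctrl_means <- scores |>
    dplyr::filter(.data$condition == control_label) |>
    dplyr::group_by(.data$parameter, .data$timepoint) |>
    dplyr::summarise(.ctrl_mean = mean(.data$raw_score, na.rm = TRUE),
                     .groups = "drop")
  out <- dplyr::left_join(scores, ctrl_means,
                          by = c("parameter", "timepoint"))
  out$normalized_score <- out$raw_score - out$.ctrl_mean
  out$.ctrl_mean <- NULL
  out
}

#' Build the change-score and summary tables for an experiment
#'
#' Takes long-format per-cell parameter values (one row per cell, timepoint
#' and parameter, baseline included), computes the per-cell raw change score
#' of each post-baseline timepoint against the cell's own baseline, centers
#' on the control group, and aggregates to a per-condition mean +/- sem
#' table.
#'
#' Cells lacking a baseline value for a parameter, or with a non-positive
#' value at either end, are excluded for that parameter and listed in the
#' `excluded` element.
#'
#' @param cell_values tibble with columns `cell_id`, `condition`,
#'   `timepoint` (`"BL"`, `"6h"`, `"24h"`), `parameter`, `value`.
#' @param control_label condition used for centering.
#' @return list: `change_scores` (long tibble with `raw_score`,
#'   `normalized_score`), `summary` (per condition x parameter x timepoint:
#'   `mean`, `sem`, `n`), `excluded` (tibble of dropped cell/parameter
#'   pairs with a reason).
#' @export
build_summary_table <- function(cell_values, control_label = "control") {
  needed <- c("cell_id", "condition", "timepoint", "parameter", "value")
  stopifnot(all(needed %in% names(cell_values)))
  post <- cell_values[cell_values$timepoint != "BL", , drop = FALSE]
  bl <- cell_values[cell_values$timepoint == "BL",
                    c("cell_id", "parameter", "value"), drop = FALSE]
  names(bl)[names(bl) == "value"] <- "value_bl"
  merged <- dplyr::left_join(post, bl, by = c("cell_id", "parameter"))
  bad_bl <- is.na(merged$value_bl)
  bad_pos <- !bad_bl & (merged$value_bl <= 0 | merged$value <= 0 |
                          !is.finite(merged$value_bl) |
                          !is.finite(merged$value))
  excluded <- tibble::tibble(
    cell_id = merged$cell_id[bad_bl | bad_pos],
    parameter = merged$parameter[bad_bl | bad_pos],
    timepoint = merged$timepoint[bad_bl | bad_pos],
    reason = ifelse(bad_bl[bad_bl | bad_pos], "missing baseline",
                    "non-positive value")
  )
  ok <- merged[!(bad_bl | bad_pos), , drop = FALSE]
  ok$raw_score <- log(ok$value) - log(ok$value_bl)
  scores <- normalize_to_control(
    ok[, c("cell_id", "condition", "timepoint", "parameter", "raw_score")],
    control_label)
  summary <- scores |>
    dplyr::group_by(.data$condition, .data$parameter, .data$timepoint) |>
    dplyr::summarise(
      mean = mean(.data$normalized_score),
      sem = stats::sd(.data$normalized_score) /
        sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop")
  summary$sem[summary$n == 1L] <- 0
  list(change_scores = scores, summary = summary, excluded = excluded)
}
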