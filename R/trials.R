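# Trial-table parsing, questionnaire scoring and descriptive statistics.

#' Parse and validate a Go/NoGo trial table
#'
#' Validates the trial schema: NoGo trials may occur only in Mixed blocks,
#' a reaction time must be present if and only if the trial was responded
#' to, and reaction times must lie in (0, 1000] ms (the response window).
#' Rows violating an invariant are dropped with a warning naming their line
#' numbers; they are also attached as attribute `rejected`.
#'
#' @param x path to a CSV file or a data frame with columns
#'   `participant_id`, `group` (`Control`/`Synchronized`), `block_index`,
#'   `block_type` (`AllGo`/`Mixed`), `trial_type` (`Go`/`NoGo`),
#'   `responded` (logical), `rt` (ms, `NA` when no response).
#' @return A validated tibble of trials.
#' @export
parse_trials <- function(x) {
  df <- if (is.character(x)) {
    readr::read_csv(x, show_col_types = FALSE)
  } else tibble::as_tibble(x)
  required <- c("participant_id", "group", "block_index", "block_type",
                "trial_type", "responded", "rt")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("parse_trials(): missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$responded <- as.logical(df$responded)
  df$rt <- as.numeric(df$rt)
  bad <- !(df$group %in% c("Control", "Synchronized")) |
    !(df$block_type %in% c("AllGo", "Mixed")) |
    !(df$trial_type %in% c("Go", "NoGo")) |
    (df$trial_type == "NoGo" & df$block_type == "AllGo") |
    (df$responded & (is.na(df$rt) | df$rt <= 0 | df$rt > 1000)) |
    (!df$responded & !is.na(df$rt)) |
    is.na(df$responded)
  if (any(bad)) {
    warning(sprintf("parse_trials(): rejected %d invalid row(s): lines %s",
                    sum(bad),
                    paste(utils::head(which(bad), 20), collapse = ", ")))
  }
  out <- df[!bad, , drop = FALSE]
  attr(out, "rejected") <- df[bad, , drop = FALSE]
  out
}

#' Score the extraversion + self-esteem questionnaire
#'
#' Sums a 10-item extraversion scale (Likert 1-5) and a 10-item self-esteem
#' scale (Likert 0-3), reversing negatively worded items
#' (extraversion: v -> 6 - v; self-esteem: v -> 3 - v). The participant's
#' score is the sum of both scales (maximum 80).
#'
#' @param responses data frame with columns `scale`
#'   (`"extraversion"`/`"self_esteem"`), `item`, `value`, `reversed`
#'   (logical). One participant's responses.
#' @return Integer total score.
#' @export
score_extraversion <- function(responses) {
  responses <- tibble::as_tibble(responses)
  stopifnot(all(c("scale", "item", "value", "reversed") %in% names(responses)))
  if (any(is.na(responses$value))) {
    stop("score_extraversion(): missing item value(s)")
  }
  ext <- responses[responses$scale == "extraversion", ]
  se <- responses[responses$scale == "self_esteem", ]
  if (any(ext$value < 1 | ext$value > 5)) {
    stop("extraversion items must lie in 1..5")
  }
  if (any(se$value < 0 | se$value > 3)) {
    stop("self-esteem items must lie in 0..3")
  }
  ext_v <- ifelse(ext$reversed, 6 - ext$value, ext$value)
  se_v <- ifelse(se$reversed, 3 - se$value, se$value)
  as.integer(sum(ext_v) + sum(se_v))
}

#' Descriptive statistics for Go/NoGo performance
#'
#' Mean and SD of responded Go-trial reaction times per (group, block type),
#' and of per-participant Mixed-block commission-error totals (count of
#' responded NoGo trials) per group.
#'
#' @param trials a validated trial tibble (see [parse_trials()]).
#' @return A tibble with `measure` (`"reaction_time_ms"` /
#'   `"commission_errors"`), `group`, `block_type`, `mean`, `sd`, `n`.
#' @export
descriptive_stats <- function(trials) {
  rt <- trials |>
    dplyr::filter(.data$trial_type == "Go", .data$responded) |>
    dplyr::group_by(.data$group, .data$block_type) |>
    dplyr::summarise(
      measure = "reaction_time_ms",
      mean = mean(.data$rt), sd = stats::sd(.data$rt), n = dplyr::n(),
      .groups = "drop"
    )
  ce <- trials |>
    dplyr::filter(.data$block_type == "Mixed", .data$trial_type == "NoGo") |>
    dplyr::group_by(.data$group, .data$participant_id) |>
    dplyr::summarise(errors = sum(.data$responded), .groups = "drop") |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      measure = "commission_errors", block_type = "Mixed",
      mean = mean(.data$errors), sd = stats::sd(.data$errors),
      n = dplyr::n(), .groups = "drop"
    )
  dplyr::bind_rows(ce, rt) |>
    dplyr::select("measure", "group", "block_type", "mean", "sd", "n")
}

# Per-participant summary used by several models: mean responded-Go RT and
# Mixed-block commission totals with NoGo exposure.
participant_summary <- function(trials) {
  rt <- trials |>
    dplyr::filter(.data$trial_type == "Go", .data$responded) |>
    dplyr::group_by(.data$participant_id, .data$group) |>
    dplyr::summarise(mean_rt = mean(.data$rt), .groups = "drop")
  ce <- trials |>
    dplyr::filter(.data$block_type == "Mixed", .data$trial_type == "NoGo") |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      commission_errors = sum(.data$responded),
      n_nogo = dplyr::n(), .groups = "drop"
    )
  dplyr::left_join(rt, ce, by = "participant_id")
}
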