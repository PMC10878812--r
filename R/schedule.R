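# Go/NoGo task schedule generator.

#' Simulate the Go/NoGo task schedule
#'
#' Builds the trial-by-trial schedule of the response-inhibition task:
#' 40 blocks of 12 trials, 20 AllGo blocks (Go trials only) and 20 Mixed
#' blocks (8 Go + 4 NoGo trials in random positions). Each block opens with a
#' 2-s cue; every trial is preceded by a fixation interval jittered uniformly
#' over 500-1500 ms and allows 1000 ms for a response (letter up to 500 ms
#' plus blank up to 500 ms); blocks are separated by a blank interval
#' jittered uniformly over 16-22 s. Block order and NoGo positions are
#' randomized by `seed`.
#'
#' @param seed integer seed controlling block order, NoGo positions and
#'   jitters.
#' @param n_blocks total number of blocks (even; half AllGo, half Mixed).
#'   Default 40, the full protocol.
#' @return A tibble with one row per trial: `block_index`, `block_type`
#'   (`"AllGo"`/`"Mixed"`), `trial_index` (within block), `trial_type`
#'   (`"Go"`/`"NoGo"`), `onset_s` (trial onset), `block_onset_s` (onset of
#'   the block's first trial, the event time used for haemodynamic
#'   modelling).
#' @examples
#' sched <- simulate_task_schedule(seed = 1)
#' table(sched$block_type, sched$trial_type)
#' @export
simulate_task_schedule <- function(seed = 1L, n_blocks = 40L) {
  stopifnot(n_blocks >= 2, n_blocks %% 2 == 0)
  with_seed(seed, {
    block_type <- sample(rep(c("AllGo", "Mixed"), each = n_blocks / 2))
    cue_s <- 2
    trial_window_s <- 1
    t <- 0
    rows <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      types <- if (block_type[b] == "Mixed") {
        tt <- rep("Go", 12L)
        tt[sample.int(12L, 4L)] <- "NoGo"
        tt
      } else rep("Go", 12L)
      t <- t + cue_s
      onsets <- numeric(12L)
      for (k in 1:12) {
        t <- t + runif(1, 0.5, 1.5)  # jittered fixation ITI
        onsets[k] <- t
        t <- t + trial_window_s
      }
      rows[[b]] <- tibble::tibble(
        block_index = b, block_type = block_type[b],
        trial_index = 1:12, trial_type = types,
        onset_s = onsets, block_onset_s = onsets[1]
      )
      t <- t + runif(1, 16, 22)  # inter-block ISI
    }
    dplyr::bind_rows(rows)
  })
}

#' Block-level event table from a task schedule
#'
#' One event per block (onset of the block's first trial, condition, and
#' the 16-s modelled response duration), the format consumed by
#' [simulate_fnirs()] and [build_design_matrix()].
#'
#' @param schedule tibble from [simulate_task_schedule()].
#' @return Tibble with `onset`, `condition`, `duration`.
#' @export
schedule_events <- function(schedule) {
  schedule |>
    dplyr::distinct(.data$block_index, .data$block_type, .data$block_onset_s) |>
    dplyr::transmute(
      onset = .data$block_onset_s, condition = .data$block_type,
      duration = 16
    )
}
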