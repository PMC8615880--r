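#' Filter trials to the valid-response window
#'
#' Keeps non-premature responses with RT in the closed interval
#' `[150, 1500]` ms from target onset; only these enter RT statistics.
#' Premature responses are excluded here but remain available in the
#' full table for the premature-error proportion (PE).
#'
#' @param trials data frame with at least `rt_ms` and `premature`
#'   columns (as produced by [simulate_dtp_behavior()]).
#' @param window RT validity window in ms (closed interval).
#' @return the valid subset of `trials`; a warning is issued when no
#'   trial survives.
#' @export
filter_valid_responses <- function(trials, window = c(150, 1500)) {
  stopifnot(all(c("rt_ms", "premature") %in% names(trials)),
            length(window) == 2, window[1] <= window[2])
  keep <- !trials$premature & !is.na(trials$rt_ms) &
    trials$rt_ms >= window[1] & trials$rt_ms <= window[2]
  out <- trials[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("no valid responses in the ", window[1], "-", window[2],
            " ms window")
  out
}

#' Inverse efficiency score
#'
#' `IES = RT / (1 - PE)`: mean correct reaction time corrected for the
#' proportion of premature errors, controlling the speed-accuracy
#' trade-off.
#'
#' @param mean_rt mean correct RT in ms.
#' @param pe proportion of premature responses, `0 <= pe < 1`.
#' @return IES in ms.
#' @examples
#' inverse_efficiency(500, 0.2)  # 625
#' @export
inverse_efficiency <- function(mean_rt, pe) {
  if (any(pe < 0) || any(pe >= 1))
    stop("pe must lie in [0, 1); IES undefined at pe >= 1")
  mean_rt / (1 - pe)
}

# per-block-type summaries for one subject's trials
block_stats <- function(trials, block_type, window = c(150, 1500)) {
  tb <- trials[trials$block_type == block_type, , drop = FALSE]
  if (nrow(tb) == 0L)
    stop("subject '", trials$subject[1], "' has no '", block_type,
         "' block trials")
  valid <- suppressWarnings(filter_valid_responses(tb, window))
  responded <- !is.na(tb$rt_ms)
  list(mean_rt = mean(valid$rt_ms),
       acc = mean(!tb$premature & responded),
       pe = mean(tb$premature))
}

#' Delta-global behavioral index
#'
#' Fast-block minus slow-block difference of a behavioral statistic,
#' quantifying implicit adaptation of motor control to the covert block
#' bias. `rt` uses the mean valid (150-1500 ms, non-premature) RT;
#' `acc` the proportion of non-premature responses; `ies` the inverse
#' efficiency score computed blockwise from (mean RT, PE). Uniform
#' blocks never enter these indexes.
#'
#' @param trials one subject's trial data frame (columns `subject`,
#'   `block_type`, `rt_ms`, `premature`).
#' @param measure one of `"rt"`, `"acc"`, `"ies"`.
#' @param window RT validity window in ms.
#' @return scalar index (ms for rt/ies, proportion difference for acc).
#' @export
delta_global <- function(trials, measure = c("rt", "acc", "ies"),
                         window = c(150, 1500)) {
  measure <- match.arg(measure)
  if (length(unique(trials$subject)) > 1L)
    stop("delta_global expects a single subject's trials")
  fast <- block_stats(trials, "fast", window)
  slow <- block_stats(trials, "slow", window)
  switch(measure,
         rt  = fast$mean_rt - slow$mean_rt,
         acc = fast$acc - slow$acc,
         ies = inverse_efficiency(fast$mean_rt, fast$pe) -
               inverse_efficiency(slow$mean_rt, slow$pe))
}

#' Per-subject behavioral indexes for a cohort
#'
#' Applies [delta_global()] for all three measures to every subject in a
#' trial table.
#'
#' @param trials cohort trial data frame (multiple subjects).
#' @param window RT validity window in ms.
#' @return data frame with columns `subject`, `delta_global_rt`,
#'   `delta_global_acc`, `delta_global_ies`.
#' @export
behavioral_indexes <- function(trials, window = c(150, 1500)) {
  subjects <- unique(trials$subject)
  res <- lapply(subjects, function(s) {
    tr <- trials[trials$subject == s, , drop = FALSE]
    data.frame(subject = s,
               delta_global_rt = delta_global(tr, "rt", window),
               delta_global_acc = delta_global(tr, "acc", window),
               delta_global_ies = delta_global(tr, "ies", window))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
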