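#' Bin trials into mutually exclusive detection categories
#'
#' Each trial is assigned exactly one category from the set of response types
#' observed on it: express and/or regular saccades (classified events
#' attributed to the trial) and an explicit button press. A press belongs to
#' a trial if it falls after the displacement and before the next
#' displacement, capped at `press_window_ms` after the displacement.
#' Unclassified saccades are ignored.
#'
#' Categories: `express_only`, `regular_only`, `explicit_only`,
#' `express+regular`, `express+explicit`, `regular+explicit`,
#' `multiple_other` (all three response types) and `undetected`.
#'
#' @param displacements displacement table (`trial_id`, `time_ms`, ...).
#' @param saccades classified saccade events (`trial_id`, `klass`), e.g. from
#'   [detect_session_saccades()].
#' @param presses data frame of button presses (`time_ms`) or numeric vector.
#' @param press_window_ms longest accepted press latency (default 1500 ms).
#' @return data frame `trial_id, category, press_latency_ms` with one row per
#'   trial, in trial order.
#' @export
bin_trials <- function(displacements, saccades, presses,
                       press_window_ms = 1500) {
  if (is.data.frame(presses)) presses <- presses$time_ms
  n <- nrow(displacements)
  if (n == 0) stop("bin_trials: no trials", call. = FALSE)
  ord <- order(displacements$time_ms)
  t_disp <- displacements$time_ms[ord]
  ids <- displacements$trial_id[ord]
  t_next <- c(t_disp[-1], Inf)

  has_e <- ids %in% saccades$trial_id[saccades$klass == "express"]
  has_r <- ids %in% saccades$trial_id[saccades$klass == "regular"]

  press_lat <- rep(NA_real_, n)
  has_p <- logical(n)
  for (i in seq_len(n)) {
    hi <- min(t_next[i], t_disp[i] + press_window_ms)
    hit <- presses[presses > t_disp[i] & presses <= hi]
    if (length(hit) > 0) {
      has_p[i] <- TRUE
      press_lat[i] <- min(hit) - t_disp[i]
    }
  }

  category <- character(n)
  for (i in seq_len(n)) {
    category[i] <- if (has_e[i] && has_r[i] && has_p[i]) "multiple_other"
    else if (has_e[i] && has_r[i]) "express+regular"
    else if (has_e[i] && has_p[i]) "express+explicit"
    else if (has_r[i] && has_p[i]) "regular+explicit"
    else if (has_e[i]) "express_only"
    else if (has_r[i]) "regular_only"
    else if (has_p[i]) "explicit_only"
    else "undetected"
  }
  out <- data.frame(trial_id = ids, category = category,
                    press_latency_ms = press_lat)
  out[order(out$trial_id), , drop = FALSE]
}

#' Per-category detection rates
#'
#' Percentage of all trials falling in each detection category (including
#' `undetected`); the percentages sum to 100.
#'
#' @param outcomes trial outcome data frame from [bin_trials()].
#' @return named numeric vector of percentages over all 8 categories.
#' @export
detection_rates <- function(outcomes) {
  if (nrow(outcomes) == 0) stop("detection_rates: zero trials", call. = FALSE)
  cats <- c("express_only", "regular_only", "explicit_only",
            "express+regular", "express+explicit", "regular+explicit",
            "multiple_other", "undetected")
  counts <- table(factor(outcomes$category, levels = cats))
  100 * as.vector(counts) / nrow(outcomes) -> pct
  names(pct) <- cats
  pct
}

#' Write trial outcomes to CSV
#' @param outcomes data frame from [bin_trials()].
#' @param path file path.
#' @export
write_trials <- function(outcomes, path) {
  utils::write.csv(outcomes, path, row.names = FALSE)
  invisible(path)
}
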