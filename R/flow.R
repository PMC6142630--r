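#' Quadrant gating of two-channel flow events
#'
#' Classifies events into the four quadrants (-/-, +/-, -/+, +/+) by
#' per-channel thresholds: an event is positive on a channel iff its
#' intensity strictly exceeds the threshold (an event exactly at the
#' control quantile is negative). Thresholds are either given, or derived
#' from a negative-control event table as a per-channel quantile (default
#' 0.99). Fractions among positives are reported over the three
#' positive quadrants. Counts conserve total events exactly and gating is
#' independent of event order and of any common rescaling of intensities
#' and thresholds.
#'
#' @param events Tibble/data frame of events with two intensity channels.
#' @param channels Character vector of the two channel names (default: first
#'   two numeric columns).
#' @param thresholds Named numeric thresholds per channel; omit to use the
#'   control rule.
#' @param control Negative-control event table (same channels) for the
#'   quantile rule; a control under 100 events triggers a warning.
#' @param cfg A [pipeline_config()] (`flow_control_quantile`).
#' @return A list of class `hox_quadrants`: `thresholds`, `table` (tibble:
#'   quadrant, n_events, fraction, fraction_among_positive), `n_events`.
#' @export
gate_quadrants <- function(events, channels = NULL, thresholds = NULL,
                           control = NULL, cfg = pipeline_config()) {
  events <- tibble::as_tibble(events)
  if (nrow(events) == 0) stop("no events to gate", call. = FALSE)
  if (is.null(channels)) {
    channels <- names(events)[vapply(events, is.numeric, logical(1))][1:2]
  }
  if (length(channels) != 2 || anyNA(channels)) {
    stop("two channels must be named", call. = FALSE)
  }
  if (is.null(thresholds)) {
    if (is.null(control)) {
      stop("supply `thresholds` or a negative-control table", call. = FALSE)
    }
    if (nrow(control) < 100) {
      warning("negative control has fewer than 100 events; ",
              "quantile thresholds will be unstable")
    }
    thresholds <- vapply(channels, function(ch) {
      stats::quantile(control[[ch]], cfg$flow_control_quantile, names = FALSE)
    }, numeric(1))
  }
  thresholds <- thresholds[channels]
  pos1 <- events[[channels[1]]] > thresholds[[1]]
  pos2 <- events[[channels[2]]] > thresholds[[2]]
  quadrant <- dplyr::case_when(
    !pos1 & !pos2 ~ "-/-",
    pos1 & !pos2 ~ "+/-",
    !pos1 & pos2 ~ "-/+",
    TRUE ~ "+/+"
  )
  levels <- c("-/-", "+/-", "-/+", "+/+")
  n <- as.integer(table(factor(quadrant, levels = levels)))
  n_pos <- sum(n[-1])
  tab <- tibble::tibble(
    quadrant = levels,
    n_events = n,
    fraction = n / nrow(events),
    fraction_among_positive = c(NA_real_,
                                if (n_pos > 0) n[-1] / n_pos
                                else rep(NA_real_, 3))
  )
  structure(list(thresholds = thresholds, table = tab,
                 n_events = nrow(events), channels = channels),
            class = "hox_quadrants")
}

#' Bin events into negative / low / high expression levels
#'
#' Events at or below the negative threshold are `neg`; the remaining
#' (positive) events are split at their median into `low` and `high`, ties
#' going to `low`. Summaries (mean, median) of a second channel are reported
#' per bin, to relate the binned gene's level to a covarying channel.
#'
#' @param events Event table.
#' @param channel Channel to bin on.
#' @param neg_threshold Negativity threshold (`neg` iff <=).
#' @param summarise_channel Optional second channel to summarise per bin.
#' @return A list: `bins` (tibble: event row, intensity, bin) and `summary`
#'   (tibble per bin: n_events and, when requested, mean/median of the
#'   second channel).
#' @export
bin_levels <- function(events, channel, neg_threshold,
                       summarise_channel = NULL) {
  events <- tibble::as_tibble(events)
  x <- events[[channel]]
  pos <- x > neg_threshold
  if (sum(pos) == 0) {
    bin <- rep("neg", length(x))
  } else if (sum(pos) < 2) {
    stop("fewer than 2 positive events: low/high split undefined",
         call. = FALSE)
  } else {
    med <- stats::median(x[pos])
    bin <- dplyr::case_when(
      !pos ~ "neg",
      x <= med ~ "low",
      TRUE ~ "high"
    )
  }
  bins <- tibble::tibble(event = seq_along(x), intensity = x,
                         bin = factor(bin, levels = c("neg", "low", "high")))
  smry <- bins |>
    dplyr::count(.data$bin, name = "n_events", .drop = FALSE)
  if (!is.null(summarise_channel)) {
    y <- events[[summarise_channel]]
    extra <- tibble::tibble(bin = bins$bin, y = y) |>
      dplyr::group_by(.data$bin, .drop = FALSE) |>
      dplyr::summarise(mean = mean(.data$y), median = stats::median(.data$y),
                       .groups = "drop")
    names(extra)[-1] <- paste0(summarise_channel, "_", names(extra)[-1])
    smry <- dplyr::left_join(smry, extra, by = "bin")
  }
  list(bins = bins, summary = smry)
}

#' Percent positive from sorter counts
#'
#' `100 * n_pos / (n_pos + n_neg)`; the integer-rounded display value is
#' returned alongside the unrounded percentage.
#'
#' @param n_pos,n_neg Non-negative event counts, not both zero.
#' @return A tibble: `n_pos`, `n_neg`, `percent` (unrounded), `display`
#'   (rounded to the nearest integer).
#' @export
facs_percent_positive <- function(n_pos, n_neg) {
  if (any(n_pos < 0) || any(n_neg < 0)) stop("counts must be non-negative")
  if (any(n_pos + n_neg == 0)) stop("counts must not be both zero")
  pct <- unname(100 * n_pos / (n_pos + n_neg))
  tibble::tibble(n_pos = n_pos, n_neg = n_neg, percent = pct,
                 display = round(pct))
}
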