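# Observers: turning population states and trajectories into summaries,
# regime labels, bimodality flags, switch events and branching-level
# estimates.

#' Summarise the current population state
#'
#' A pure function of the living individuals: counts per sex and state,
#' mean/variance and integer histogram of the expressed care alleles per
#' sex, and mean preference and ornament.
#'
#' @param pop a `sexrole_pop` object.
#' @param hist_max top histogram bin (longer care durations are clamped
#'   into it).
#' @return A list: `day`, `counts` (2 x 4 matrix, sexes by states), `n_f`,
#'   `n_m`, `care_f_mean`, `care_f_var`, `care_m_mean`, `care_m_var`,
#'   `pref_mean`, `orn_mean`, `hist_f`, `hist_m` (named count vectors over
#'   care days `0:hist_max`).
#' @export
summarize_day <- function(pop, hist_max = pop$params$hist_max) {
  df <- get_individuals(pop)
  f <- df[df$sex == "F", ]
  m <- df[df$sex == "M", ]
  counts <- table(factor(df$sex, levels = SEX_LEVELS),
                  factor(df$state, levels = STATE_LEVELS))
  bins <- 0:hist_max
  hist_of <- function(x) {
    tab <- tabulate(pmin(x, hist_max) + 1L, nbins = hist_max + 1L)
    names(tab) <- bins
    tab
  }
  list(
    day = current_day(pop),
    counts = unclass(counts),
    n_f = nrow(f), n_m = nrow(m),
    care_f_mean = if (nrow(f)) mean(f$careF) else NA_real_,
    care_f_var = if (nrow(f) > 1) stats::var(f$careF) else NA_real_,
    care_m_mean = if (nrow(m)) mean(m$careM) else NA_real_,
    care_m_var = if (nrow(m) > 1) stats::var(m$careM) else NA_real_,
    pref_mean = if (nrow(f)) mean(f$pref) else NA_real_,
    orn_mean = if (nrow(m)) mean(m$orn) else NA_real_,
    hist_f = hist_of(f$careF),
    hist_m = hist_of(m$careM)
  )
}

rolling_mean <- function(x, k) {
  if (k <= 1 || length(x) < k) return(x)
  y <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  # fill the ends with shrunken windows so min/argmin stay defined
  n <- length(x)
  half <- (k - 1) %/% 2
  for (i in seq_len(n)) {
    if (is.na(y[i])) {
      lo <- max(1, i - half); hi <- min(n, i + half)
      y[i] <- mean(x[lo:hi])
    }
  }
  y
}

#' Care-bias index
#'
#' `b = (Tf - Tm) / (Tf + Tm + eps0)`: +1-ish for strongly female-biased care,
#' -1-ish for strongly male-biased care, 0 for egalitarian care. The small
#' `eps0` keeps the index defined when both sexes provide no care.
#'
#' @param Tf,Tm mean female and male care (days).
#' @param eps0 regularising constant in the denominator.
#' @return The bias index.
#' @export
care_bias <- function(Tf, Tm, eps0 = 0.5) {
  (Tf - Tm) / (Tf + Tm + eps0)
}

#' Detect bimodality of an integer care-allele histogram
#'
#' Flags a histogram as bimodal when two local maxima at least `min_sep`
#' care-days apart each carry at least `min_mass` of the total mass and some
#' interior bin falls below `valley_frac` of the smaller peak. This threshold
#' detector is regime bookkeeping, not a formal statistical test.
#'
#' @param counts integer vector of histogram counts; bin `i` holds care
#'   duration `i - 1` days (bins start at 0).
#' @param min_sep minimum mode separation in care-days.
#' @param min_mass minimum mass fraction per mode.
#' @param valley_frac interior bin must fall below this fraction of the
#'   smaller peak.
#' @param min_n minimum histogram mass for a verdict; below it the histogram
#'   is reported unimodal with `reliable = FALSE`.
#' @return A list: `bimodal` flag, `modes` (care durations of the two modes,
#'   or `NULL`), `reliable`.
#' @examples
#' h <- c(45, rep(0, 9), 45, rep(1, 10))  # 45 at 0 days, 45 at 10 days
#' detect_bimodality(h)$bimodal
#' @export
detect_bimodality <- function(counts, min_sep = 5, min_mass = 0.10,
                              valley_frac = 0.5, min_n = 50) {
  counts <- as.numeric(counts)
  n <- sum(counts)
  if (n < min_n) {
    return(list(bimodal = FALSE, modes = NULL, reliable = FALSE))
  }
  nb <- length(counts)
  # local maxima (plateaus count once, at their first bin)
  is_max <- logical(nb)
  for (i in seq_len(nb)) {
    left <- if (i == 1) -Inf else counts[i - 1]
    right <- if (i == nb) -Inf else counts[i + 1]
    is_max[i] <- counts[i] > 0 && counts[i] >= right && counts[i] > left
  }
  peaks <- which(is_max)
  # mass attributed to a peak: bins closer to it than to any other peak
  best <- list(bimodal = FALSE, modes = NULL, reliable = TRUE)
  if (length(peaks) < 2) return(best)
  for (a in seq_along(peaks)) {
    for (b in seq_along(peaks)) {
      if (b <= a) next
      i <- peaks[a]; j <- peaks[b]
      if ((j - i) < min_sep) next
      cut <- (i + j) / 2
      mass_i <- sum(counts[seq_len(nb) <= cut]) / n
      mass_j <- sum(counts[seq_len(nb) > cut]) / n
      if (mass_i < min_mass || mass_j < min_mass) next
      valley <- min(counts[(i + 1):(j - 1)])
      if (valley < valley_frac * min(counts[i], counts[j])) {
        return(list(bimodal = TRUE, modes = c(i, j) - 1L, reliable = TRUE))
      }
    }
  }
  best
}

#' Classify the care regime of a trajectory window
#'
#' Averages the mean care levels over the trailing `window` generations and
#' labels the regime from the care-bias index: `female_biased` if `b > 0.5`,
#' `male_biased` if `b < -0.5`, `polymorphic/transition` if either sex's
#' pooled care histogram is bimodal, otherwise `egalitarian`.
#'
#' @param traj a `sexrole_traj` object (or a list with `$summary`,
#'   `$hist_f`, `$hist_m` of the same layout).
#' @param window number of trailing generations to average.
#' @param bias_threshold absolute bias above which the window is sex-biased.
#' @param eps0 regulariser of the bias index.
#' @return A list: `label`, `bias`, `Tf`, `Tm`, `window`.
#' @export
classify_equilibrium <- function(traj, window = 50, bias_threshold = 0.5,
                                 eps0 = 0.5) {
  s <- traj$summary
  if (is.null(s) || nrow(s) == 0) stop("empty trajectory window")
  idx <- seq.int(max(1, nrow(s) - window + 1), nrow(s))
  Tf <- mean(s$care_f_mean[idx], na.rm = TRUE)
  Tm <- mean(s$care_m_mean[idx], na.rm = TRUE)
  b <- care_bias(Tf, Tm, eps0)
  label <- if (is.finite(b) && b > bias_threshold) {
    "female_biased"
  } else if (is.finite(b) && b < -bias_threshold) {
    "male_biased"
  } else {
    hf <- colSums(traj$hist_f[idx, , drop = FALSE])
    hm <- colSums(traj$hist_m[idx, , drop = FALSE])
    if (detect_bimodality(hf)$bimodal || detect_bimodality(hm)$bimodal) {
      "polymorphic/transition"
    } else {
      "egalitarian"
    }
  }
  list(label = label, bias = b, Tf = Tf, Tm = Tm, window = length(idx))
}

#' Label every window of a trajectory
#'
#' Slides [classify_equilibrium()] over consecutive windows; input to
#' [detect_switches()].
#'
#' @param traj a `sexrole_traj` object.
#' @param window window length in recorded intervals (generations).
#' @return A data frame with one row per window: `gen` (window end), `label`,
#'   `bias`, `Tf`, `Tm`.
#' @export
label_trajectory <- function(traj, window = 10) {
  s <- traj$summary
  n <- nrow(s)
  ends <- seq(window, n, by = window)
  out <- lapply(ends, function(e) {
    idx <- (e - window + 1):e
    sub <- list(summary = s[idx, , drop = FALSE],
                hist_f = traj$hist_f[idx, , drop = FALSE],
                hist_m = traj$hist_m[idx, , drop = FALSE])
    cl <- classify_equilibrium(sub, window = window)
    data.frame(gen = s$gen[e], label = cl$label, bias = cl$bias,
               Tf = cl$Tf, Tm = cl$Tm)
  })
  do.call(rbind, out)
}

#' Detect switches between the sex-biased regimes
#'
#' A switch is a change from a persistent female-biased regime to a
#' persistent male-biased regime (or vice versa), possibly via
#' egalitarian/transition labels in between. Persistence means the flanking
#' regimes each last at least `persistence` generations; shorter excursions
#' are ignored.
#'
#' @param labels a data frame as returned by [label_trajectory()] (columns
#'   `gen` and `label`), or a character vector of labels with an implied unit
#'   spacing.
#' @param persistence minimum duration (generations) of the flanking biased
#'   regimes.
#' @return A data frame of switch events: `gen` (first generation of the new
#'   regime), `from`, `to`. Zero rows when no switch qualifies.
#' @examples
#' labs <- c(rep("female_biased", 150), "polymorphic/transition",
#'           rep("male_biased", 150))
#' detect_switches(data.frame(gen = seq_along(labs), label = labs),
#'                 persistence = 100)
#' @export
detect_switches <- function(labels, persistence = 100) {
  if (is.character(labels)) {
    labels <- data.frame(gen = seq_along(labels), label = labels)
  }
  biased <- labels$label %in% c("female_biased", "male_biased")
  lb <- labels[biased, , drop = FALSE]
  if (nrow(lb) == 0) {
    return(data.frame(gen = numeric(0), from = character(0),
                      to = character(0)))
  }
  spacing <- if (nrow(labels) > 1) stats::median(diff(labels$gen)) else 1
  # run-length encode the biased labels (gaps of other labels are bridged)
  r <- rle(lb$label)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  dur <- (ends - starts + 1) * spacing
  keep <- dur >= persistence
  runs <- data.frame(label = r$values[keep],
                     gen = lb$gen[starts[keep]])
  if (nrow(runs) < 2) {
    return(data.frame(gen = numeric(0), from = character(0),
                      to = character(0)))
  }
  chg <- which(runs$label[-1] != runs$label[-nrow(runs)])
  data.frame(gen = runs$gen[chg + 1],
             from = runs$label[chg],
             to = runs$label[chg + 1])
}

#' Write events as JSON lines
#'
#' Serialises a data frame of events (e.g. the switches from
#' [detect_switches()], or extinction records) as one JSON object per line,
#' a format that downstream tools can append to and stream.
#'
#' @param events a data frame, one event per row.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_events <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    writeLines(as.character(
      jsonlite::toJSON(as.list(events[i, , drop = FALSE]),
                       auto_unbox = TRUE, digits = NA)), con)
  }
  invisible(path)
}

#' Care level at the bottom of the initial decline
#'
#' From a symmetric high-care start, the mean care of both sexes first
#' declines to the evolutionary branching level before sex roles diverge.
#' This helper smooths the sex-averaged mean care `(Tf + Tm) / 2` with a
#' rolling mean and returns its minimum, which estimates the branching care
#' level.
#'
#' @param traj a `sexrole_traj` object.
#' @param smooth rolling-mean window in generations.
#' @return A list: `level` (the minimum of the smoothed sex-average), `gen`
#'   (generation at which it is attained).
#' @export
branching_care_level <- function(traj, smooth = 25) {
  s <- traj$summary
  avg <- (s$care_f_mean + s$care_m_mean) / 2
  sm <- rolling_mean(avg, smooth)
  i <- which.min(sm)
  list(level = sm[i], gen = s$gen[i])
}
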