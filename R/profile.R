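# Fitness profiles: a renewal (absorbing-chain) estimator of expected
# lifetime reproductive success per probe care strategy, and a Monte-Carlo
# phantom-probe estimator run inside the engine as its independent check.

#' Mating-market statistics of a trajectory window
#'
#' Estimates, from the recorded summaries and the realized-care clutch log,
#' the quantities the fitness-profile estimator needs: the daily mating
#' probability of a searching individual of each sex (`m_f`, `m_m` = matings
#' per searcher-day), the mean population size `N_bar` (for the density
#' factor), the mean ornament and preference, and the availability-weighted
#' empirical distribution of realized partner care (`partner_f`: realized male
#' care in matings, faced by a female probe; `partner_m`: realized female
#' care).
#'
#' @param traj a `sexrole_traj` (or the live `sexrole_pop` in `traj$pop` is
#'   used for the clutch log when present).
#' @param window trailing window in recorded intervals (generations).
#' @return An object of class `sexrole_market` (a list).
#' @export
market_stats <- function(traj, window = 10) {
  s <- traj$summary
  if (nrow(s) == 0) stop("no recorded summaries")
  idx <- seq.int(max(1, nrow(s) - window + 1), nrow(s))
  w <- s[idx, , drop = FALSE]
  matings <- sum(w$matings)
  sdf <- sum(w$search_days_f)
  sdm <- sum(w$search_days_m)
  if (matings == 0 || sdf == 0 || sdm == 0) {
    stop("no matings in the window; market statistics undefined")
  }
  spacing <- if (nrow(s) > 1) stats::median(diff(s$day)) else s$day[1]
  min_day <- s$day[idx[1]] - spacing + 1
  log <- if (!is.null(traj$pop)) clutch_log(traj$pop, min_day = min_day) else
    NULL
  if (is.null(log) || nrow(log) < 30) {
    stop("clutch log too short; run with keep_pop = TRUE and a longer window")
  }
  structure(list(
    m_f = matings / sdf,
    m_m = matings / sdm,
    N_bar = mean(w$n),
    pref_bar = mean(w$pref_mean),
    orn_bar = mean(w$orn_mean),
    partner_f = log$realizedM,
    partner_m = log$realizedF,
    window = length(idx)
  ), class = "sexrole_market")
}

# per-day survival of one sex in each state, ornament cost included for males
state_survival <- function(params, sex, orn = 0) {
  m <- params$mortality[if (sex == "F") 1 else 2, ]
  s <- 1 - m
  if (sex == "M" && params$beta > 0) {
    s <- s * max(0, 1 - params$beta * orn^2)
  }
  names(s) <- colnames(params$mortality)
  s
}

#' Expected lifetime reproductive success of probe care strategies
#'
#' A renewal / absorbing-chain estimator of the fitness profile: for each
#' probe care duration the expected number of matings over life is computed
#' from the per-day state survivals and the market's daily mating
#' probability, and the expected offspring per mating from the focal's
#' realized-care distribution (it may die during care), the empirical
#' availability-weighted partner-care distribution, the synergy rule and the
#' mean density factor.
#'
#' The life cycle underlying the chain mirrors the engine: a mating is
#' followed by `T` days of caring, one transition day, the sex's pre-mating
#' period, and a geometric search wait with the market's daily mating
#' probability.
#'
#' @param stats a [market_stats()] object.
#' @param sex `"F"` or `"M"`: the sex of the probe.
#' @param grid integer vector of probe care durations.
#' @param params the [sim_params()] of the population the market was
#'   measured in.
#' @return A data frame of class `sexrole_profile`: `care`, `lrs` (expected
#'   lifetime reproductive success), `matings` (expected matings) and
#'   `clutch_value` (expected offspring per mating).
#' @export
estimate_fitness_profile <- function(stats, sex = c("F", "M"), grid = 0:20,
                                     params) {
  sex <- match.arg(sex)
  stopifnot(inherits(stats, "sexrole_market"),
            inherits(params, "sexrole_params"))
  m_hat <- if (sex == "F") stats$m_f else stats$m_m
  partners <- if (sex == "F") stats$partner_f else stats$partner_m
  orn <- if (sex == "M") stats$orn_bar else 0
  sv <- state_survival(params, sex, orn)
  q_s <- sv[["search"]]; q_c <- sv[["caring"]]; q_p <- sv[["premating"]]
  pre <- params$premating_days[if (sex == "F") 1 else 2]
  dens <- density_factor(stats$N_bar, params$gamma)
  # search wait: first attempt happens on the return day (no extra survival
  # draw), later attempts each cost one day of search-state survival
  pm <- m_hat + (1 - m_hat) * (q_s * m_hat) / (1 - q_s * (1 - m_hat))
  out <- lapply(grid, function(Tp) {
    # focal realized-care distribution: death on care day k (k = 1..Tp)
    # leaves k days of realized care; surviving the bout leaves Tp
    if (Tp > 0) {
      k <- seq_len(Tp)
      pr <- q_c^(k - 1) * (1 - q_c)
      pr[Tp] <- pr[Tp] + q_c^Tp
      own <- k
    } else {
      pr <- 1
      own <- 0
    }
    sv_mat <- outer(own, partners, function(a, b)
      offspring_survival(total_care(a, b, params$sigma), params$B))
    v <- sum(pr * rowMeans(sv_mat)) * dens * params$clutch_size *
      params$survival_scale
    # survive the care bout, the transition day (still in the caring state)
    # and the pre-mating period to search again
    R <- q_c^(Tp + 1) * q_p^pre
    if (pm * R >= 1) {
      stop("expected matings diverge: the chain needs positive mortality")
    }
    matings <- pm / (1 - pm * R)
    data.frame(care = Tp, lrs = matings * v, matings = matings,
               clutch_value = v)
  })
  out <- do.call(rbind, out)
  class(out) <- c("sexrole_profile", "data.frame")
  out
}

#' Monte-Carlo phantom-probe fitness estimate
#'
#' The independent check on [estimate_fitness_profile()]: non-reproducing
#' phantom individuals with a fixed care strategy are injected into a copy of
#' the population (mutation switched off so the residents stay near their
#' current composition) and followed until death. Phantoms take part in the
#' mating market and in caring like real individuals, but their clutches
#' yield no recruits; instead each resolved clutch credits the phantom with
#' its expected offspring number `S(Ttot) * density * clutch_size`. The mean
#' credit over phantoms estimates the expected lifetime reproductive success
#' of the probe strategy.
#'
#' @param pop a `sexrole_pop` to probe; it is snapshotted, not modified.
#' @param sex `"F"` or `"M"`: sex of the phantoms.
#' @param grid integer vector of probe care durations (one engine copy per
#'   grid point).
#' @param n_probe phantoms per grid point.
#' @param horizon_days days to run each probe population; phantoms still
#'   alive at the horizon are censored (with the default mortality an
#'   expected lifespan is 1000 days, so the default horizon censors ~0.2%).
#' @param seed engine seed for the probe runs.
#' @return A data frame: `care`, `lrs` (mean credit), `se` (standard error
#'   over phantoms), `n`.
#' @export
probe_fitness_mc <- function(pop, sex = c("F", "M"), grid = 0:20,
                             n_probe = 200, horizon_days = 6000,
                             seed = NULL) {
  sex <- match.arg(sex)
  stopifnot(inherits(pop, "sexrole_pop"))
  if (is.null(seed)) seed <- random_engine_seed()
  base <- get_individuals(pop)
  params0 <- update_params(pop$params, mu = 0)
  sx <- if (sex == "F") 0L else 1L
  # phantoms carry the resident mean preference/ornament so that mate choice
  # treats them like typical residents
  pref_val <- mean(base$pref[base$sex == "F"])
  orn_val <- mean(base$orn[base$sex == "M"])
  if (!is.finite(pref_val)) pref_val <- 0
  if (!is.finite(orn_val)) orn_val <- 0
  res <- lapply(seq_along(grid), function(gi) {
    Tp <- grid[gi]
    p <- update_params(params0, seed = seed + gi)
    cp <- new_population(p, individuals = base)
    cpp_pop_inject_probes(cp$ptr, sx, as.integer(Tp), as.integer(n_probe),
                          pref_val, orn_val)
    step_days(cp, horizon_days, record_every = 0)
    cr <- cpp_pop_probe_credits(cp$ptr)
    data.frame(care = Tp, lrs = mean(cr),
               se = stats::sd(cr) / sqrt(length(cr)), n = length(cr))
  })
  do.call(rbind, res)
}
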