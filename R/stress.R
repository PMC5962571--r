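#' Osmostress experiment configuration
#'
#' Holds the per-gene transcriptional repression durations `t_d` (minutes;
#' genes not under stress control, e.g. *SIC1*, use 0), the sampling times
#' after stress onset, and the number of random onsets. Defaults follow the
#' experimental design: sampling at 0/15/30/45/60/90 min after addition of
#' 0.4 M NaCl, onsets uniform over the cycle, 200 simulated onsets, and a
#' 250-min total simulation horizon (one cycle, the 15-min anaphase offset,
#' the stress delay and up to 90 min of stress).
#'
#' @param t_d named numeric vector of repression durations per gene (min).
#' @param sampling_times ascending non-negative minutes after onset.
#' @param n_onsets number of random stress onsets (= simulated cells).
#' @param total_sim_minutes total horizon (default 250).
#' @param cycle_length cycle length (default 129).
#' @return an object of class `stress_config`.
#' @export
stress_config <- function(t_d, sampling_times = c(0, 15, 30, 45, 60, 90),
                          n_onsets = 200, total_sim_minutes = 250,
                          cycle_length = 129) {
  if (is.null(names(t_d)) || any(!nzchar(names(t_d))))
    stop("t_d must be a named vector (one entry per stressed gene)")
  if (any(t_d < 0)) stop("t_d must be >= 0")
  if (any(diff(sampling_times) <= 0) || any(sampling_times < 0))
    stop("sampling_times must be non-negative and strictly ascending")
  if (total_sim_minutes < max(sampling_times) + 15 + cycle_length)
    stop("total_sim_minutes too short for the sampling design")
  structure(list(t_d = t_d, sampling_times = sampling_times,
                 n_onsets = n_onsets, total_sim_minutes = total_sim_minutes,
                 cycle_length = cycle_length),
            class = "stress_config")
}

#' Stress-modified transcription schedule for one gene
#'
#' Builds the effective piecewise-constant transcription-rate schedule on
#' absolute time (0 = stress onset) for a cell that is at cycle position
#' `onset` when stress hits. During the repression period `[0, t_d]` the rate
#' is forced to the basal `k_low`; scheduled high-window time is not consumed
#' while repressed — the gene's schedule clock freezes whenever it points
#' into a high window — so any un-executed portion of an interrupted window
#' resumes after `onset + t_d` with its remaining duration preserved, and all
#' later windows shift by the accumulated freeze (the cell-cycle delay).
#' `t_d = 0` returns the unstressed schedule.
#'
#' @param gene a [gene_params()].
#' @param onset cycle time (minutes) at which stress hits the cell.
#' @param t_d repression duration (minutes, `>= 0`).
#' @param horizon schedule length in minutes after onset (default 90).
#' @return list with `breaks` (ascending, `breaks[1] == 0`), `rates`
#'   (rate on `[breaks[i], breaks[i+1])`), `freeze` (total frozen clock
#'   minutes within `[0, t_d]`) and `freeze_intervals` (matrix of frozen
#'   absolute-time intervals).
#' @export
apply_stress_schedule <- function(gene, onset, t_d, horizon = 90) {
  stopifnot(inherits(gene, "gene_params"))
  if (t_d < 0) stop("t_d must be >= 0")
  T <- gene$cycle_length
  bnd <- cycle_breaks(gene)                    # includes 0 and T
  in_high <- function(cl) {
    w <- gene$windows
    any(cl >= w[, 1] - 1e-9 & cl < w[, 2] - 1e-9)
  }
  next_boundary <- function(cl) {
    # cyclic distance from clock position cl to the next schedule breakpoint
    nb <- bnd[bnd > cl + 1e-9]
    if (!length(nb)) nb <- T + bnd[bnd > 1e-9]
    nb[1] - cl
  }
  t <- 0; clock <- onset %% T
  breaks <- numeric(0); rates <- numeric(0)
  fr <- NULL
  emit <- function(rate, upto) {
    breaks <<- c(breaks, t); rates <<- c(rates, rate); t <<- upto
  }
  while (t < horizon - 1e-9) {
    if (t < t_d - 1e-9) {
      if (in_high(clock)) {
        # scheduled high time: clock frozen until repression ends
        fr <- rbind(fr, c(t, t_d))
        emit(gene$k_low, t_d)
      } else {
        step <- min(t_d - t, next_boundary(clock))
        emit(gene$k_low, t + step)
        clock <- (clock + step) %% T
      }
    } else {
      step <- min(horizon - t, next_boundary(clock))
      rate <- if (in_high(clock)) gene$k_high else gene$k_low
      emit(rate, t + step)
      clock <- (clock + step) %% T
    }
  }
  # merge adjacent equal-rate segments
  keep <- c(TRUE, diff(rates) != 0)
  list(breaks = breaks[keep], rates = rates[keep],
       freeze = if (is.null(fr)) 0 else sum(fr[, 2] - fr[, 1]),
       freeze_intervals = fr)
}

# cumulative frozen time of a schedule by absolute time s
freeze_by <- function(sched, s) {
  fr <- sched$freeze_intervals
  if (is.null(fr)) return(0)
  sum(pmax(0, pmin(fr[, 2], s) - fr[, 1]))
}

#' Simulate an osmostress-perturbed population
#'
#' Each cell receives a random stress onset (its cycle position when stress
#' hits, uniform over the cycle). The cell's pre-stress history is simulated
#' from anaphase (cycle time `cycle_length - 15`, initial counts Poisson at
#' the basal mean) up to the onset, then the SSA continues on the
#' stress-modified schedule of [apply_stress_schedule()]. At each sampling
#' time after onset the cell's counts and its (delayed-clock) phase are
#' recorded. The phase clock of a cell lags behind real time by a shared
#' fixed `max(t_d)` minutes (`delay = "fixed"`, the default), by the largest
#' accumulated window deferral among its own stressed genes
#' (`"per-cell-max"`), or not at all (`"none"`). The fixed rule is the
#' default because the per-cell rule ties every gene's phase label to the
#' most-deferred gene, which makes downstream distribution comparisons
#' discontinuous in `t_d`; see the package vignette.
#'
#' @param model a [model_spec()].
#' @param cfg a [stress_config()]; genes absent from `cfg$t_d` get `t_d = 0`.
#' @param n_cells number of cells (default `cfg$n_onsets`).
#' @param seed master seed.
#' @param delay phase-clock delay rule (see above).
#' @return named list of `cell_table`s, one per sampling time (names are the
#'   sampling times in minutes).
#' @export
simulate_stress_population <- function(model, cfg, n_cells = cfg$n_onsets,
                                       seed = NULL,
                                       delay = c("fixed", "per-cell-max",
                                                 "none")) {
  stopifnot(inherits(model, "model_spec"), inherits(cfg, "stress_config"))
  delay <- match.arg(delay)
  T <- model$phase_map$cycle_length
  st <- cfg$sampling_times
  genes <- names(model$genes)
  t_d <- setNames(rep(0, length(genes)), genes)
  t_d[names(cfg$t_d)[names(cfg$t_d) %in% genes]] <-
    cfg$t_d[names(cfg$t_d) %in% genes]
  horizon <- max(st) + 1e-6
  counts <- array(0L, dim = c(n_cells, length(st), length(genes)),
                  dimnames = list(NULL, NULL, genes))
  delay_min <- matrix(0, n_cells, length(st))
  onsets <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    # onset and each gene's trajectory get their own counter-derived RNG
    # substreams: with a shared master seed, a gene's event randomness is
    # then identical across repression-duration candidates (common random
    # numbers), so distance differences across the t_d grid reflect the
    # schedule change rather than resampling noise
    with_seed(if (is.null(seed)) NULL else derive_seed(seed, i, salt = 7L),
              onsets[i] <- runif(1, 0, T))
    onset <- onsets[i]
    freeze_at <- matrix(0, length(genes), length(st),
                        dimnames = list(genes, NULL))
    for (j in seq_along(genes)) {
      g <- genes[j]
      gene <- model$genes[[g]]
      with_seed(if (is.null(seed)) NULL
                else derive_seed(seed, i, salt = 100L + j), {
        # pre-stress burn-in: anaphase start of previous cycle to the onset
        burn <- (onset - (T - 15)) %% T
        n0 <- rpois(1, gene$k_low / gene$p)
        if (burn > 0) {
          sch0 <- unstressed_schedule(gene, T - 15, burn)
          n0 <- ssa_schedule_cpp(n0, gene$p, sch0$breaks, sch0$rates,
                                 burn, burn)[1]
        }
        sch <- apply_stress_schedule(gene, onset, t_d[[g]], horizon = horizon)
        counts[i, , g] <- ssa_schedule_cpp(n0, gene$p, sch$breaks, sch$rates,
                                           horizon, as.numeric(st))
        freeze_at[j, ] <- vapply(st, function(s) freeze_by(sch, s), numeric(1))
      })
    }
    delay_min[i, ] <- switch(delay,
      "per-cell-max" = apply(freeze_at, 2, max),
      "none" = 0,
      "fixed" = pmin(st, max(t_d)))
  }
  out <- lapply(seq_along(st), function(k) {
    phase <- phase_at(onsets + st[k] - delay_min[, k], model$phase_map)
    rows <- lapply(genes, function(g)
      data.frame(cell_id = seq_len(n_cells), phase = phase, gene = g,
                 count = counts[, k, g]))
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    as_cell_table(tab)
  })
  names(out) <- as.character(st)
  attr(out, "onsets") <- onsets
  out
}

#' Binned per-time, per-phase count distributions
#'
#' Converts a list of per-sampling-time `cell_table`s into nested relative-
#' frequency-ready histograms: counts binned at `0..bin_max` plus a
#' `> bin_max` tail bin, keyed by sampling time, gene and phase.
#'
#' @param tables named list of `cell_table`s keyed by sampling time.
#' @param bin_max largest explicit count bin (default 30).
#' @return object of class `stress_distributions`: nested list
#'   `[[time]][[gene]][[phase]]` of integer vectors of length `bin_max + 2`.
#' @export
stress_histograms <- function(tables, bin_max = 30) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  out <- lapply(tables, function(tab) {
    tab <- as_cell_table(as.data.frame(tab))
    lapply(split(tab, tab$gene), function(sg) {
      lapply(split(sg$count, sg$phase, drop = TRUE), function(v) {
        b <- pmin(v, bin_max + 1)
        tabulate(b + 1L, nbins = bin_max + 2L)
      })
    })
  })
  structure(out, bin_max = bin_max, class = "stress_distributions")
}

#' Total squared distance between simulated and observed distributions
#'
#' For every sampling time, gene and phase group, both histograms are
#' converted to relative frequencies over the `0..bin_max, >bin_max` bins and
#' the squared differences are summed across all bins and groups. Groups are
#' taken from the observed data; a group with no simulated cells contributes
#' the squared mass of the observed frequencies. Mismatched sampling times or
#' genes raise an error.
#'
#' @param sim,obs `stress_distributions` (see [stress_histograms()]).
#' @return scalar total squared distance.
#' @export
distribution_distance <- function(sim, obs) {
  stopifnot(inherits(sim, "stress_distributions"),
            inherits(obs, "stress_distributions"))
  if (!setequal(names(sim), names(obs)))
    stop("sampling times differ between simulated and observed data")
  total <- 0
  for (tm in names(obs)) {
    if (!setequal(names(sim[[tm]]), names(obs[[tm]])))
      stop("genes differ between simulated and observed data at time ", tm)
    for (g in names(obs[[tm]])) {
      for (ph in names(obs[[tm]][[g]])) {
        ho <- obs[[tm]][[g]][[ph]]
        fo <- ho / sum(ho)
        hs <- sim[[tm]][[g]][[ph]]
        fs <- if (is.null(hs) || sum(hs) == 0) rep(0, length(fo))
              else hs / sum(hs)
        total <- total + sum((fs - fo)^2)
      }
    }
  }
  total
}

#' Grid search for the repression durations
#'
#' Evaluates every combination of candidate repression durations for the
#' stressed genes: for each pair, `n_sims` cells (one random onset each) are
#' simulated with [simulate_stress_population()], their per-time, per-phase
#' distributions are built, and the total squared distance to the observed
#' distributions is computed. The same master seed is used for every
#' combination (common random numbers), so onsets and event randomness are
#' shared across the grid and the distance surface varies only through
#' `t_d`; the full search is deterministic given the seed.
#'
#' @param obs observed data: a `stress_distributions`, or a named list of
#'   `cell_table`s keyed by sampling time (binned automatically).
#' @param model a [model_spec()].
#' @param grid named list of integer-minute candidate vectors, one per
#'   stressed gene (default `list(CLN2 = 5:30, CLB5 = 5:30)`).
#' @param n_sims simulated cells per combination (default 200).
#' @param seed master seed.
#' @param sampling_times sampling design (default taken from `obs` names).
#' @param delay phase-clock delay rule, passed to
#'   [simulate_stress_population()].
#' @return list with `best` (named vector of argmin durations), `distance`
#'   (its distance), and `surface` (data frame of all combinations with
#'   their distances).
#' @export
grid_search_td <- function(obs, model, grid = list(CLN2 = 5:30, CLB5 = 5:30),
                           n_sims = 200, seed = NULL, sampling_times = NULL,
                           delay = "fixed") {
  stopifnot(inherits(model, "model_spec"))
  if (!length(grid)) stop("grid must be non-empty")
  if (!inherits(obs, "stress_distributions")) obs <- stress_histograms(obs)
  if (is.null(sampling_times)) sampling_times <- as.numeric(names(obs))
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  dist <- numeric(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    t_d <- setNames(as.numeric(combos[r, ]), names(combos))
    cfg <- stress_config(t_d, sampling_times = sampling_times,
                         n_onsets = n_sims,
                         total_sim_minutes =
                           max(sampling_times) + 15 +
                           model$phase_map$cycle_length + max(t_d),
                         cycle_length = model$phase_map$cycle_length)
    tabs <- simulate_stress_population(model, cfg, n_cells = n_sims,
                                       seed = seed, delay = delay)
    sim <- stress_histograms(tabs, bin_max = attr(obs, "bin_max"))
    dist[r] <- distribution_distance(sim, obs)
  }
  surface <- cbind(combos, distance = dist)
  best_row <- which.min(dist)
  list(best = setNames(as.numeric(combos[best_row, ]), names(combos)),
       distance = dist[best_row], surface = surface)
}
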