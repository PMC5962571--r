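#' Exact stochastic simulation of one cell
#'
#' Simulates the time-inhomogeneous birth-death process for every gene of the
#' model with the exact Gillespie algorithm. Rates are piecewise constant
#' (high/low windows), so standard SSA applies within constant-rate segments;
#' a tentative event crossing a segment boundary is re-drawn from the boundary
#' (exact by memorylessness). Genes evolve independently. Initial counts are
#' drawn Poisson with the basal mean `k_low / p` per gene unless `n0` is
#' given. Snapshots are recorded at integer minutes `0..duration` (state is
#' right-continuous at event times).
#'
#' @param model a [model_spec()].
#' @param t_start cycle time at simulation start (minutes; default
#'   `cycle_length - 15`, i.e. the start of anaphase).
#' @param duration simulated minutes (default `15 + cycle_length`: anaphase
#'   and telophase/cytokinesis of the current cycle plus one full next cycle).
#' @param seed optional integer seed.
#' @param n0 optional named integer vector of initial counts per gene.
#' @return integer matrix of counts, `(duration + 1)` rows (minutes) by
#'   `n_genes` columns, with attribute `times` (simulation minutes) and
#'   `cycle_time` (`(t_start + times) %% cycle_length`).
#' @export
simulate_cell <- function(model, t_start = model$phase_map$cycle_length - 15,
                          duration = 15 + model$phase_map$cycle_length,
                          seed = NULL, n0 = NULL) {
  stopifnot(inherits(model, "model_spec"))
  if (duration <= 0) stop("duration must be > 0")
  with_seed(seed, {
    times <- 0:floor(duration)
    out <- matrix(0L, nrow = length(times), ncol = length(model$genes),
                  dimnames = list(NULL, names(model$genes)))
    for (g in names(model$genes)) {
      gene <- model$genes[[g]]
      start <- if (is.null(n0)) rpois(1, gene$k_low / gene$p) else n0[[g]]
      sched <- unstressed_schedule(gene, t_start, duration)
      out[, g] <- ssa_schedule_cpp(start, gene$p, sched$breaks, sched$rates,
                                   duration, as.numeric(times))
    }
    attr(out, "times") <- times
    attr(out, "cycle_time") <- (t_start + times) %% model$phase_map$cycle_length
    out
  })
}

#' Simulate a population of cells with per-minute snapshots
#'
#' Each cell is simulated independently with [simulate_cell()], starting at
#' anaphase of the previous cycle (cycle time `cycle_length - 15`) and running
#' for `15 + cycle_length` minutes, so simulation time and cycle time are
#' offset by 15 min. Per-cell RNG streams are derived from the master seed by
#' a counter scheme, so results are reproducible and independent of
#' evaluation order.
#'
#' @param model a [model_spec()].
#' @param n_cells number of cells (default 2000).
#' @param seed master seed (optional but recommended).
#' @return an object of class `snapshot_matrix`: list with `counts` (integer
#'   array `n_cells x n_times x n_genes`), `times` (simulation minutes),
#'   `cycle_time`, `sim_origin` (cycle time at simulation start), `seed`, and
#'   `model`.
#' @export
simulate_population <- function(model, n_cells = 2000, seed = NULL) {
  stopifnot(inherits(model, "model_spec"), n_cells >= 1)
  T <- model$phase_map$cycle_length
  t_start <- T - 15
  duration <- 15 + T
  times <- 0:duration
  genes <- names(model$genes)
  counts <- array(0L, dim = c(n_cells, length(times), length(genes)),
                  dimnames = list(NULL, NULL, genes))
  for (i in seq_len(n_cells)) {
    cell_seed <- if (is.null(seed)) NULL else derive_seed(seed, i)
    counts[i, , ] <- simulate_cell(model, t_start, duration, seed = cell_seed)
  }
  structure(list(counts = counts, times = times,
                 cycle_time = (t_start + times) %% T,
                 sim_origin = t_start, seed = seed, model = model),
            class = "snapshot_matrix")
}

#' @export
print.snapshot_matrix <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("snapshot_matrix: %d cells x %d minutes x %d gene(s) [%s]\n",
              d[1], d[2], d[3], paste(dimnames(x$counts)[[3]], collapse = ", ")))
  cat(sprintf("simulation start at cycle time %.0f min; seed %s\n",
              x$sim_origin, ifelse(is.null(x$seed), "none", x$seed)))
  invisible(x)
}

#' Population noise (CV) time-course
#'
#' Coefficient of variation across cells at each snapshot minute:
#' `CV(t) = sd(t) / mean(t)` over all cells, per gene. Minutes with zero mean
#' yield `NA` rather than an error.
#'
#' @param snap a `snapshot_matrix` from [simulate_population()].
#' @return data frame with columns `time`, `cycle_time`, `gene`, `mean`,
#'   `sd`, `cv`.
#' @export
population_noise_timecourse <- function(snap) {
  stopifnot(inherits(snap, "snapshot_matrix"))
  if (dim(snap$counts)[1] < 2) stop("need at least 2 cells")
  genes <- dimnames(snap$counts)[[3]]
  res <- lapply(genes, function(g) {
    m <- apply(snap$counts[, , g, drop = FALSE], 2, mean)
    s <- apply(snap$counts[, , g, drop = FALSE], 2, sd)
    data.frame(time = snap$times, cycle_time = snap$cycle_time, gene = g,
               mean = m, sd = s, cv = ifelse(m > 0, s / m, NA_real_))
  })
  do.call(rbind, res)
}

#' Per-cell temporal noise over one cycle
#'
#' CV of each single cell's per-minute counts across one full cycle
#' (the `cycle_length` snapshot minutes covering cycle times
#' `0 .. cycle_length - 1`). Cells with zero temporal mean yield `NA`.
#'
#' @param snap a `snapshot_matrix` covering at least one full cycle.
#' @return data frame with columns `cell`, `gene`, `mean`, `cv`.
#' @export
per_cell_temporal_cv <- function(snap) {
  stopifnot(inherits(snap, "snapshot_matrix"))
  T <- snap$model$phase_map$cycle_length
  # snapshot columns whose cycle time is 0 .. T-1, one per minute
  sel <- match(0:(T - 1), snap$cycle_time)
  if (anyNA(sel)) stop("snapshot grid does not cover one full cycle")
  genes <- dimnames(snap$counts)[[3]]
  res <- lapply(genes, function(g) {
    x <- snap$counts[, sel, g, drop = FALSE]
    mu <- apply(x, 1, mean)
    s <- apply(x, 1, sd)
    data.frame(cell = seq_len(nrow(x)), gene = g, mean = mu,
               cv = ifelse(mu > 0, s / mu, NA_real_))
  })
  do.call(rbind, res)
}

#' Phase-binned snapshot counts (simulated smFISH sampling)
#'
#' Mimics fixed-cell smFISH sampling of an asynchronous population: each
#' simulated cell contributes one record whose phase is drawn with
#' probability proportional to phase duration and whose counts are read at a
#' uniformly chosen integer minute within that phase.
#'
#' @param snap a `snapshot_matrix` covering one full cycle.
#' @param map a [phase_map()] (default: the model's).
#' @param seed optional seed for the phase/minute draws.
#' @return a `cell_table` data frame with columns `cell_id`, `phase`, `gene`,
#'   `count` (long format; one row per cell and gene).
#' @export
phase_binned_counts <- function(snap, map = snap$model$phase_map, seed = NULL) {
  stopifnot(inherits(snap, "snapshot_matrix"), inherits(map, "phase_map"))
  T <- map$cycle_length
  sel <- match(0:(T - 1), snap$cycle_time)
  if (anyNA(sel)) stop("snapshot grid does not cover one full cycle")
  with_seed(seed, {
    n <- dim(snap$counts)[1]
    genes <- dimnames(snap$counts)[[3]]
    phase_of_min <- phase_at(0:(T - 1), map)
    phases <- sample(map$phase_names, n, replace = TRUE,
                     prob = map$durations / T)
    minute <- vapply(phases, function(ph) {
      cand <- which(phase_of_min == ph)
      cand[sample.int(length(cand), 1)]
    }, integer(1))
    rows <- lapply(seq_along(genes), function(j)
      data.frame(cell_id = seq_len(n), phase = phases, gene = genes[j],
                 count = snap$counts[cbind(seq_len(n), sel[minute], j)]))
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    as_cell_table(tab)
  })
}

#' Plot simulated population mean and noise
#'
#' Base-graphics diagnostic: per-gene mean with a +/- 1 sd band against cycle
#' time.
#'
#' @param x a `snapshot_matrix`.
#' @param ... passed to [plot()].
#' @export
plot.snapshot_matrix <- function(x, ...) {
  nt <- population_noise_timecourse(x)
  genes <- unique(nt$gene)
  op <- graphics::par(mfrow = c(length(genes), 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op))
  for (g in genes) {
    d <- nt[nt$gene == g, ]
    d <- d[order(d$time), ]
    plot(d$time, d$mean, type = "l", lwd = 2, xlab = "simulation time (min)",
         ylab = "mRNA / cell", main = g,
         ylim = c(0, max(d$mean + d$sd)), ...)
    polygon(c(d$time, rev(d$time)),
            c(pmax(0, d$mean - d$sd), rev(d$mean + d$sd)),
            col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
    lines(d$time, d$mean, lwd = 2)
  }
  invisible(x)
}
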