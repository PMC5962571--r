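#' Synthetic-data configuration
#'
#' Bundles the generative settings used by the fixture generators: the
#' kinetic model, the number of cells, the spot-intensity noise (lognormal
#' around a unit median, so median normalization is exactly self-consistent),
#' and the transcription-site emission rule (the probability that a cell
#' shows a nuclear TS spot scales with the instantaneous transcription rate,
#' peaking at `ts_max` inside high-expression windows).
#'
#' @param model a [model_spec()] (default [g1s_model()]).
#' @param n_cells number of cells to generate (default 2000).
#' @param sigma lognormal sdlog of the spot intensity noise (default 0.25).
#' @param ts_max maximal TS emission probability (default 0.5).
#' @param seed master seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(model = g1s_model(), n_cells = 2000, sigma = 0.25,
                         ts_max = 0.5, seed = NULL) {
  stopifnot(inherits(model, "model_spec"), n_cells >= 1, sigma >= 0,
            ts_max >= 0, ts_max <= 1)
  structure(list(model = model, n_cells = n_cells, sigma = sigma,
                 ts_max = ts_max, seed = seed),
            class = "synth_config")
}

#' Generate a phase-labeled cell table from the model
#'
#' Draws each cell a phase (probability proportional to phase duration), a
#' uniform age within the phase interval, and per-gene mRNA counts. With
#' `method = "analytic"` counts are Poisson draws at the cycle-periodic mean
#' of the cell's age (the exact CME law); with `method = "ssa"` each cell is
#' simulated by the Gillespie algorithm from anaphase up to its age and the
#' endpoint count is taken. Both paths sample the same law up to the
#' (negligible) residual of the pre-anaphase initial condition. A `ts`
#' column is drawn under the TS emission rule of [synth_config()]: a cell
#' carries a nuclear TS spot with probability
#' `ts_max * k(age)/k_high` provided it has at least 3 transcripts.
#'
#' @param cfg a [synth_config()], or a [model_spec()] (defaults applied).
#' @param map a [phase_map()] (default: the model's).
#' @param n_cells,seed override the config values.
#' @param method `"analytic"` (fast, default) or `"ssa"`.
#' @return a `cell_table` with columns `cell_id`, `phase`, `gene`, `count`,
#'   `ts`, plus attribute `age` (the sampled cycle times).
#' @export
generate_cell_table <- function(cfg, map = NULL, n_cells = NULL, seed = NULL,
                                method = c("analytic", "ssa")) {
  if (inherits(cfg, "model_spec")) cfg <- synth_config(model = cfg)
  stopifnot(inherits(cfg, "synth_config"))
  method <- match.arg(method)
  model <- cfg$model
  if (is.null(map)) map <- model$phase_map
  if (is.null(n_cells)) n_cells <- cfg$n_cells
  if (is.null(seed)) seed <- cfg$seed
  T <- map$cycle_length
  with_seed(seed, {
    phases <- sample(map$phase_names, n_cells, replace = TRUE,
                     prob = map$durations / T)
    iv <- vapply(phases, function(ph) phase_interval(ph, map), numeric(2))
    age <- runif(n_cells, iv[1, ], iv[2, ])
    genes <- names(model$genes)
    rows <- vector("list", length(genes))
    for (j in seq_along(genes)) {
      gene <- model$genes[[j]]
      counts <- if (method == "analytic") {
        rpois(n_cells, periodic_mean(gene, age))
      } else {
        vapply(seq_len(n_cells), function(i) {
          dur <- 15 + age[i]
          sch <- unstressed_schedule(gene, T - 15, dur)
          n0 <- rpois(1, gene$k_low / gene$p)
          ssa_schedule_cpp(n0, gene$p, sch$breaks, sch$rates, dur, dur)[1]
        }, integer(1))
      }
      p_ts <- cfg$ts_max * transcription_rate(gene, age) / gene$k_high
      ts <- as.integer(runif(n_cells) < p_ts & counts >= 3L)
      rows[[j]] <- data.frame(cell_id = seq_len(n_cells), phase = phases,
                              gene = genes[j], count = counts, ts = ts)
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    tab <- as_cell_table(tab)
    attr(tab, "age") <- age
    tab
  })
}

#' Generate a noisy spot table from a cell table
#'
#' Inverse of the spot-quantification step, for round-trip testing. Each
#' mRNA becomes a single-molecule cytoplasmic spot, except that a cell with
#' `ts >= 1` concentrates `min(count, 3 + Poisson(1))` molecules into one
#' nuclear TS spot. Spot intensities are `molecules * Lognormal(0, sigma)`
#' (unit median), so at `sigma = 0` median normalization recovers every
#' cell's count and TS call exactly.
#'
#' @param cells a `cell_table` (needs a `ts` column; cells with `ts` NA are
#'   treated as 0).
#' @param cfg a [synth_config()] (only `sigma` is used), or a number taken
#'   as `sigma`.
#' @param seed optional seed.
#' @return a `spot_table`.
#' @export
generate_spot_table <- function(cells, cfg = synth_config(), seed = NULL) {
  if (is.numeric(cfg)) cfg <- synth_config(sigma = cfg)
  stopifnot(inherits(cfg, "synth_config"))
  cells <- as_cell_table(as.data.frame(cells))
  ts <- if ("ts" %in% names(cells)) ifelse(is.na(cells$ts), 0L, cells$ts)
        else rep(0L, nrow(cells))
  with_seed(seed, {
    per_row <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
      n <- cells$count[i]
      if (n == 0) next
      mols <- integer(0); nuc <- logical(0)
      if (ts[i] >= 1L && n >= 3L) {
        m_ts <- min(n, 3L + rpois(1, 1))
        mols <- m_ts; nuc <- TRUE
        n <- n - m_ts
      }
      if (n > 0) {
        mols <- c(mols, rep(1L, n))
        nuc <- c(nuc, rep(FALSE, n))
      }
      per_row[[i]] <- data.frame(cell_id = cells$cell_id[i],
                                 gene = cells$gene[i],
                                 molecules = mols, nuclear = nuc)
    }
    spots <- do.call(rbind, per_row)
    if (is.null(spots))
      return(as_spot_table(data.frame(spot_id = integer(0),
                                      cell_id = integer(0),
                                      gene = character(0),
                                      intensity = numeric(0),
                                      nuclear = logical(0))))
    noise <- if (cfg$sigma > 0) rlnorm(nrow(spots), 0, cfg$sigma) else 1
    out <- data.frame(spot_id = seq_len(nrow(spots)),
                      cell_id = spots$cell_id, gene = spots$gene,
                      intensity = spots$molecules * noise,
                      nuclear = spots$nuclear)
    rownames(out) <- NULL
    as_spot_table(out)
  })
}

#' Generate a synthetic osmostress experiment
#'
#' Wraps [simulate_stress_population()] to emit one `cell_table` per
#' sampling time in the observed-data dialect (and optionally write them as
#' CSV files).
#'
#' @param cfg a [synth_config()] (model and n_cells used).
#' @param stress a [stress_config()].
#' @param seed master seed (default `cfg$seed`).
#' @param dir optional output directory; when given, tables are written as
#'   `stress_t<minutes>.csv`.
#' @return named list of `cell_table`s keyed by sampling time.
#' @export
generate_stress_experiment <- function(cfg, stress, seed = NULL, dir = NULL) {
  stopifnot(inherits(cfg, "synth_config"), inherits(stress, "stress_config"))
  if (is.null(seed)) seed <- cfg$seed
  tabs <- simulate_stress_population(cfg$model, stress,
                                     n_cells = cfg$n_cells, seed = seed)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (tm in names(tabs))
      write_cell_table(tabs[[tm]], file.path(dir, paste0("stress_t", tm, ".csv")))
  }
  tabs
}
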