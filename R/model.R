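#' Kinetic parameterization of one gene
#'
#' Transcription is modeled as a birth-death process with first-order
#' degradation (rate constant `p`, per molecule per minute) and a
#' piecewise-constant transcription rate: `k_high` molecules/min while the
#' cycle time lies inside one of the gene's high-expression windows, `k_low`
#' otherwise. Windows are half-open `[start, end)` intervals in cycle minutes;
#' a gene may have one or two windows (a window crossing the cycle boundary
#' must be supplied as two windows after modulo reduction).
#'
#' @param name gene label.
#' @param k_high,k_low transcription rate constants (molecules/min),
#'   `0 <= k_low <= k_high`.
#' @param p degradation rate constant (1/min), `p > 0`.
#' @param windows numeric matrix with columns `start`, `end` (1 or 2 rows), or
#'   a vector `c(start, end)` for a single window; cycle minutes.
#' @param cycle_length cycle length the windows live in (default 129).
#' @return an object of class `gene_params`.
#' @examples
#' gene_params("SIC1", 22.15, 1.72, 0.56, c(118.09, 124.05))
#' @export
gene_params <- function(name, k_high, k_low, p, windows, cycle_length = 129) {
  if (is.null(dim(windows))) windows <- matrix(windows, ncol = 2, byrow = TRUE)
  windows <- as.matrix(windows)
  colnames(windows) <- c("start", "end")
  if (!is.finite(k_high) || !is.finite(k_low) || k_low < 0 || k_low > k_high)
    stop("require 0 <= k_low <= k_high")
  if (!is.finite(p) || p <= 0) stop("degradation rate p must be > 0")
  if (nrow(windows) < 1 || nrow(windows) > 2)
    stop("a gene carries 1 or 2 high-expression windows")
  if (any(windows[, "end"] <= windows[, "start"]))
    stop("each window must satisfy start < end")
  if (any(windows < 0) || any(windows > cycle_length))
    stop("windows must lie inside [0, cycle_length]")
  windows <- windows[order(windows[, "start"]), , drop = FALSE]
  if (nrow(windows) == 2 && windows[1, "end"] > windows[2, "start"])
    stop("windows must not overlap")
  structure(list(name = as.character(name), k_high = k_high, k_low = k_low,
                 p = p, windows = windows, cycle_length = cycle_length),
            class = "gene_params")
}

#' @export
print.gene_params <- function(x, ...) {
  cat(sprintf("gene_params %s: k_high=%.4g k_low=%.4g p=%.4g /min\n",
              x$name, x$k_high, x$k_low, x$p))
  for (i in seq_len(nrow(x$windows)))
    cat(sprintf("  high window %d: [%.2f, %.2f) min\n", i,
                x$windows[i, 1], x$windows[i, 2]))
  invisible(x)
}

#' Bundle of gene parameterizations plus a phase map
#'
#' @param genes list of [gene_params()] objects with unique names.
#' @param phase_map a [phase_map()]; all gene windows must lie within its
#'   cycle length.
#' @return object of class `model_spec`; genes are accessible by name via
#'   `model$genes[[name]]`.
#' @export
model_spec <- function(genes, phase_map = default_phase_map()) {
  stopifnot(inherits(phase_map, "phase_map"))
  if (inherits(genes, "gene_params")) genes <- list(genes)
  nm <- vapply(genes, function(g) g$name, character(1))
  if (anyDuplicated(nm)) stop("gene names must be unique")
  for (g in genes) {
    if (any(g$windows > phase_map$cycle_length))
      stop("windows of gene ", g$name, " exceed the cycle length")
  }
  structure(list(genes = setNames(genes, nm), phase_map = phase_map),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec with", length(x$genes), "gene(s):",
      paste(names(x$genes), collapse = ", "), "\n")
  cat("cycle length:", x$phase_map$cycle_length, "min\n")
  invisible(x)
}

#' The packaged G1/S regulator model
#'
#' Loads the shipped kinetic parameterization of the three G1/S transition
#' regulators *SIC1*, *CLN2* and *CLB5*: per-gene high/low transcription rate
#' constants, degradation rate constants, and one (*SIC1*) or two
#' (*CLN2*, *CLB5*) high-expression windows on the 129-min cycle.
#'
#' @param phase_map optional [phase_map()] (default [default_phase_map()]).
#' @return a [model_spec()].
#' @export
g1s_model <- function(phase_map = default_phase_map()) {
  path <- system.file("extdata", "g1s_model.json", package = "cycleFISH",
                      mustWork = TRUE)
  read_model(path, phase_map = phase_map)
}

#' Instantaneous transcription rate
#'
#' @param gene a [gene_params()].
#' @param t numeric vector of cycle times (minutes); reduced modulo the
#'   cycle length before the window test.
#' @return numeric vector: `k_high` where the reduced time falls inside a
#'   high-expression window (half-open `[start, end)`), else `k_low`.
#' @export
transcription_rate <- function(gene, t) {
  stopifnot(inherits(gene, "gene_params"))
  tr <- t %% gene$cycle_length
  high <- rep(FALSE, length(tr))
  for (i in seq_len(nrow(gene$windows)))
    high <- high | (tr >= gene$windows[[i, 1]] & tr < gene$windows[[i, 2]])
  unname(ifelse(high, gene$k_high, gene$k_low))
}

#' Relative promoter activity
#'
#' Basal (low-window) transcription as a percentage of the high-window rate,
#' `100 * k_low / k_high`. A non-zero value quantifies how far transcription
#' is from a strict on/off switch.
#'
#' @param gene a [gene_params()].
#' @return percentage (scalar).
#' @examples
#' promoter_activity(g1s_model()$genes$SIC1)  # ~7.7
#' @export
promoter_activity <- function(gene) {
  stopifnot(inherits(gene, "gene_params"))
  if (gene$k_high == 0) stop("k_high is zero; promoter activity undefined")
  100 * gene$k_low / gene$k_high
}

# --- rate schedules on absolute time -------------------------------------

# breakpoints of the cyclic rate function within one cycle: window edges + 0/T
cycle_breaks <- function(gene) {
  sort(unique(c(0, as.vector(gene$windows), gene$cycle_length)))
}

# unstressed schedule on absolute time [0, duration), starting at cycle
# position t_start; returns list(breaks, rates) with breaks[1] == 0
unstressed_schedule <- function(gene, t_start, duration) {
  T <- gene$cycle_length
  cb <- cycle_breaks(gene)                 # includes 0 and T
  start <- t_start %% T
  # absolute times of all cycle breakpoints in (0, duration)
  n_cyc <- ceiling((start + duration) / T) + 1L
  abs_breaks <- as.vector(outer(cb[-length(cb)], T * (0:(n_cyc - 1L)), "+")) - start
  abs_breaks <- sort(abs_breaks[abs_breaks > 1e-12 & abs_breaks < duration - 1e-12])
  breaks <- c(0, abs_breaks)
  mids <- c(breaks[-1], duration)
  mids <- (breaks + mids) / 2
  rates <- transcription_rate(gene, t_start + mids)
  list(breaks = breaks, rates = rates)
}
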