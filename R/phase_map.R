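#' Seven-phase partition of the cell cycle
#'
#' A `phase_map` carries the ordered seven-phase partition of the cell cycle
#' (early G1, late G1, S, G2, prometa-/metaphase, anaphase,
#' telophase/cytokinesis) together with the duration of each phase in minutes.
#' Cycle time 0 is the start of early G1; phase intervals are half-open
#' `[start, end)` and tile `[0, cycle_length)` exactly.
#'
#' @param durations numeric vector of 7 positive phase durations (minutes)
#'   summing to `cycle_length`. May be named; names must then equal
#'   `c("eG1","lG1","S","G2","P/M","Ana","T/C")` in that order.
#' @param cycle_length total cycle length in minutes (default 129).
#' @return an object of class `phase_map` with elements `phase_names`,
#'   `durations`, `cycle_length` and derived `boundaries` (length 8,
#'   `boundaries[i]` is the start of phase i, `boundaries[8] == cycle_length`).
#' @examples
#' pm <- default_phase_map()
#' phase_interval("Ana", pm)
#' @export
phase_map <- function(durations, cycle_length = 129) {
  if (length(durations) != 7L)
    stop("exactly 7 phase durations are required")
  if (!is.null(names(durations)) && !identical(names(durations), PHASE_LABELS))
    stop("phase names must be ", paste(PHASE_LABELS, collapse = ", "),
         " in that order")
  durations <- as.numeric(durations)
  if (any(!is.finite(durations)) || any(durations <= 0))
    stop("all phase durations must be positive and finite")
  if (abs(sum(durations) - cycle_length) > 1e-9)
    stop("phase durations must sum to the cycle length (",
         format(cycle_length), " min); got ", format(sum(durations)))
  structure(
    list(phase_names = PHASE_LABELS,
         durations = setNames(durations, PHASE_LABELS),
         cycle_length = as.numeric(cycle_length),
         boundaries = c(0, cumsum(durations))),
    class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat("phase_map:", format(x$cycle_length), "min cycle\n")
  df <- data.frame(phase = x$phase_names,
                   start = round(x$boundaries[1:7], 2),
                   end = round(x$boundaries[2:8], 2),
                   duration = round(x$durations, 2))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Default phase map for synthetic work
#'
#' Phase occupancy fractions (eG1 0.211, lG1 0.18, S 0.18, G2 0.166,
#' P/M 0.147, Ana 0.086, T/C 0.03) scaled to the 129-min cycle. The early G1,
#' G2 and T/C fractions are the experimentally reported unstressed occupancy
#' values; the remaining fractions are package defaults chosen so that
#' anaphase plus telophase/cytokinesis last about 15 min (the anaphase-to-
#' cycle-start offset used by the population simulator). Fully configurable
#' via [build_phase_map()] or [phase_map()].
#'
#' @param cycle_length cycle length in minutes (default 129).
#' @return a [phase_map()].
#' @export
default_phase_map <- function(cycle_length = 129) {
  frac <- c(eG1 = 0.211, lG1 = 0.18, S = 0.18, G2 = 0.166,
            `P/M` = 0.147, Ana = 0.086, `T/C` = 0.03)
  phase_map(frac * cycle_length, cycle_length)
}

#' Build a phase map from observed phase occupancy
#'
#' Converts counts of cells observed in each phase of an asynchronous
#' population into phase durations, assuming each phase's duration is
#' proportional to the fraction of cells found in it (the steady-state
#' occupancy argument behind in silico synchronization):
#' `duration_i = cycle_length * count_i / total`.
#'
#' @param phase_counts integer-valued vector of 7 cell counts, one per phase
#'   in canonical order (named or unnamed; names checked if present).
#' @param cycle_length cycle length in minutes (default 129).
#' @return a [phase_map()].
#' @examples
#' build_phase_map(c(211, 180, 180, 166, 147, 86, 30))
#' @export
build_phase_map <- function(phase_counts, cycle_length = 129) {
  if (length(phase_counts) != 7L)
    stop("exactly 7 phase counts are required")
  if (!is.null(names(phase_counts)) &&
      !identical(names(phase_counts), PHASE_LABELS))
    stop("phase names must be ", paste(PHASE_LABELS, collapse = ", "),
         " in that order")
  counts <- as.numeric(phase_counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("phase counts must be non-negative")
  if (sum(counts) <= 0) stop("total phase count is zero")
  zero <- counts == 0
  if (any(zero))
    stop("phase(s) with zero count: ",
         paste(PHASE_LABELS[zero], collapse = ", "),
         "; every phase needs at least one observed cell")
  phase_map(cycle_length * counts / sum(counts), cycle_length)
}

#' Phase containing a cycle time
#'
#' Reduces `t` modulo the cycle length and returns the label of the phase
#' whose half-open interval `[start, end)` contains it. Total on all real `t`.
#'
#' @param t numeric vector of cycle times (minutes, any real values).
#' @param map a [phase_map()].
#' @return character vector of phase labels, same length as `t`.
#' @export
phase_at <- function(t, map) {
  stopifnot(inherits(map, "phase_map"))
  tr <- t %% map$cycle_length
  idx <- findInterval(tr, map$boundaries, rightmost.closed = FALSE)
  idx[idx > 7L] <- 7L  # guard fp round-up at the top boundary
  map$phase_names[idx]
}

#' Time interval of a phase
#'
#' @param phase one of the 7 canonical phase labels.
#' @param map a [phase_map()].
#' @return numeric `c(start, end)` in minutes; the interval is half-open
#'   `[start, end)`. Consecutive phases abut and together cover
#'   `[0, cycle_length)`.
#' @export
phase_interval <- function(phase, map) {
  stopifnot(inherits(map, "phase_map"))
  i <- match(phase, map$phase_names)
  if (is.na(i)) stop("unknown phase label: ", phase)
  c(start = map$boundaries[i], end = map$boundaries[i + 1])
}

#' Read or write a phase map as JSON
#'
#' Serialized as `{"cycle_length": ..., "phases": [{"name","duration"}, ...]}`.
#' YAML files (extension `.yaml`/`.yml`) are also accepted.
#'
#' @param path file path.
#' @return `read_phase_map` returns a [phase_map()]; `write_phase_map`
#'   invisibly returns `path`.
#' @export
read_phase_map <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  ph <- obj$phases
  if (is.data.frame(ph)) {
    nm <- ph$name; dur <- ph$duration
  } else {
    nm <- vapply(ph, `[[`, character(1), "name")
    dur <- vapply(ph, `[[`, numeric(1), "duration")
  }
  if (!identical(as.character(nm), PHASE_LABELS))
    stop("phase map file must list the 7 canonical phases in order")
  phase_map(setNames(as.numeric(dur), PHASE_LABELS),
            cycle_length = obj$cycle_length)
}

#' @rdname read_phase_map
#' @param map a [phase_map()].
#' @export
write_phase_map <- function(map, path) {
  stopifnot(inherits(map, "phase_map"))
  obj <- list(cycle_length = map$cycle_length,
              phases = data.frame(name = map$phase_names,
                                  duration = unname(map$durations)))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(list(cycle_length = map$cycle_length,
                          phases = lapply(seq_len(7), function(i)
                            list(name = map$phase_names[i],
                                 duration = unname(map$durations[i])))), path,
                     precision = 15L)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
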