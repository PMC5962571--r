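#' Spot tables
#'
#' A `spot_table` is a data frame of detected smFISH spots: columns
#' `spot_id`, `cell_id`, `gene`, `intensity` (arbitrary fluorescence units,
#' strictly positive) and `nuclear` (logical).
#'
#' @param x a data frame with the columns above.
#' @return validated `spot_table`.
#' @export
as_spot_table <- function(x) {
  stopifnot(is.data.frame(x))
  required <- c("spot_id", "cell_id", "gene", "intensity", "nuclear")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("spot table is missing column(s): ", paste(missing, collapse = ", "))
  bad <- which(!is.finite(x$intensity) | x$intensity <= 0)
  if (length(bad))
    stop("intensities must be > 0; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  x$nuclear <- as.logical(x$nuclear)
  class(x) <- unique(c("spot_table", class(x)))
  x
}

#' @rdname as_spot_table
#' @param path CSV path with header `spot_id,cell_id,gene,intensity,nuclear`.
#' @export
read_spot_table <- function(path) {
  as_spot_table(read.csv(path, stringsAsFactors = FALSE, comment.char = "#"))
}

#' @rdname as_spot_table
#' @param spots a `spot_table`.
#' @export
write_spot_table <- function(spots, path) {
  spots <- as_spot_table(as.data.frame(spots))
  write.csv(spots, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

#' Molecules per spot by median-intensity normalization
#'
#' Each spot's intensity is divided by the median intensity of that gene's
#' whole spot population and rounded (half away from zero) to a molecule
#' count, floored at 1 molecule per retained spot (upstream detection already
#' removed sub-threshold noise). Because the median spot contains a single
#' mRNA, the normalization makes the molecule calls invariant to any overall
#' intensity scale.
#'
#' @param spots a `spot_table`.
#' @param gene gene to quantify.
#' @return the gene's rows of `spots` with an added integer column
#'   `molecules`.
#' @export
molecules_per_spot <- function(spots, gene) {
  spots <- as_spot_table(as.data.frame(spots))
  sub <- spots[spots$gene == gene, , drop = FALSE]
  if (nrow(sub) == 0) stop("no spots for gene ", gene)
  med <- median(sub$intensity)
  sub$molecules <- pmax(1L, as.integer(round_half_up(sub$intensity / med)))
  sub
}

#' Transcription-site calls per cell
#'
#' A transcription site (TS) is a nuclear spot containing at least 3 mRNA
#' molecules (nascent transcripts accumulated at the gene locus).
#' Cytoplasmic spots are never TS regardless of intensity.
#'
#' @param spots a `spot_table`.
#' @param gene gene to call.
#' @return data frame `cell_id`, `ts` (number of TS in that cell); cells
#'   of the gene with no qualifying spot get `ts = 0`.
#' @export
call_transcription_sites <- function(spots, gene) {
  mol <- molecules_per_spot(spots, gene)
  is_ts <- mol$nuclear & mol$molecules >= 3L
  cells <- unique(mol$cell_id)
  ts <- vapply(cells, function(cl) sum(is_ts[mol$cell_id == cl]), integer(1))
  data.frame(cell_id = cells, ts = ts)
}

#' Quantify spots into a cell table
#'
#' Per-cell mRNA counts (sum of molecules over the cell's spots) and TS
#' counts for every gene in the spot table, joined with the externally
#' provided phase labels.
#'
#' @param spots a `spot_table`.
#' @param cell_phases data frame `cell_id`, `phase` covering every cell in
#'   `spots`.
#' @return a `cell_table` (columns `cell_id`, `phase`, `gene`, `count`,
#'   `ts`). Cells listed in `cell_phases` but without spots for a gene are
#'   reported with count 0.
#' @export
quantify_cells <- function(spots, cell_phases) {
  spots <- as_spot_table(as.data.frame(spots))
  stopifnot(all(c("cell_id", "phase") %in% names(cell_phases)))
  if (!all(spots$cell_id %in% cell_phases$cell_id))
    stop("cell_phases must cover every cell present in the spot table")
  rows <- lapply(unique(spots$gene), function(g) {
    mol <- molecules_per_spot(spots, g)
    cnt <- tapply(mol$molecules, mol$cell_id, sum)
    ts <- call_transcription_sites(spots, g)
    df <- data.frame(cell_id = cell_phases$cell_id,
                     phase = cell_phases$phase, gene = g)
    df$count <- as.integer(cnt[as.character(df$cell_id)])
    df$count[is.na(df$count)] <- 0L
    df$ts <- ts$ts[match(df$cell_id, ts$cell_id)]
    df$ts[is.na(df$ts)] <- 0L
    df
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  as_cell_table(tab)
}

#' Per-phase descriptive statistics
#'
#' Mean, median, SEM, CV (sample standard deviation over mean, `n - 1`
#' denominator), the fraction of cells with at least `k` transcripts, and —
#' when a `ts` column is present — the fraction of cells with at least one
#' transcription site, for every phase and gene. Phases with zero mean
#' report `NA` for the CV.
#'
#' @param cells a `cell_table`.
#' @param map a [phase_map()] (fixes phase order in the output).
#' @param k count threshold for the expressing-cell fraction (default 1).
#' @return data frame with one row per phase and gene.
#' @export
phase_summary <- function(cells, map = default_phase_map(), k = 1) {
  cells <- as_cell_table(as.data.frame(cells))
  has_ts <- "ts" %in% names(cells) && !all(is.na(cells$ts))
  groups <- split(cells, list(factor(cells$phase, levels = map$phase_names),
                              cells$gene), drop = TRUE, sep = "\1")
  rows <- lapply(groups, function(gr) {
    v <- gr$count
    mu <- mean(v); s <- sd(v)
    data.frame(phase = gr$phase[1], gene = gr$gene[1], n = length(v),
               mean = mu, median = median(v), sd = s,
               sem = s / sqrt(length(v)),
               cv = if (mu > 0) s / mu else NA_real_,
               frac_expressing = mean(v >= k),
               frac_ts = if (has_ts) mean(gr$ts >= 1) else NA_real_)
  })
  if (!length(rows))
    return(data.frame(phase = character(0), gene = character(0),
                      n = integer(0), mean = numeric(0), median = numeric(0),
                      sd = numeric(0), sem = numeric(0), cv = numeric(0),
                      frac_expressing = numeric(0), frac_ts = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[order(match(out$gene, unique(cells$gene)),
                   match(out$phase, map$phase_names)), ]
  rownames(out) <- NULL
  out
}
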