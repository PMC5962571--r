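#' Cell tables
#'
#' A `cell_table` is a long-format data frame describing fixed cells: columns
#' `cell_id`, `phase` (one of the 7 canonical labels), `gene`, `count`
#' (non-negative integer mRNA molecules) and optionally `ts` (non-negative
#' integer number of transcription sites). One row per cell and gene.
#'
#' @param x a data frame with the columns above.
#' @return `x` validated, with class `c("cell_table", "data.frame")`.
#' @export
as_cell_table <- function(x) {
  stopifnot(is.data.frame(x))
  required <- c("cell_id", "phase", "gene", "count")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("cell table is missing column(s): ", paste(missing, collapse = ", "))
  bad <- which(!(x$phase %in% PHASE_LABELS))
  if (length(bad))
    stop("unknown phase label(s) in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), ": ",
         paste(unique(x$phase[utils::head(bad, 5)]), collapse = ", "))
  check_int_col(x, "count")
  if ("ts" %in% names(x)) check_int_col(x, "ts", allow_na = TRUE)
  x$count <- as.integer(x$count)
  class(x) <- unique(c("cell_table", class(x)))
  x
}

check_int_col <- function(x, col, allow_na = FALSE) {
  v <- x[[col]]
  na_ok <- if (allow_na) is.na(v) else rep(FALSE, length(v))
  bad <- which(!na_ok & (!is.finite(v) | v < 0 | v != round(v)))
  if (length(bad))
    stop("column '", col, "' must hold non-negative integers; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  invisible(TRUE)
}

#' Read / write a cell table CSV
#'
#' CSV with header `cell_id,phase,gene,count[,ts]`, UTF-8, "." decimal.
#' Counts must be integers; malformed rows are reported with their row
#' numbers. Writing then reading restores the table exactly.
#'
#' @param path CSV file path.
#' @return `read_cell_table` returns a validated `cell_table`;
#'   `write_cell_table` invisibly returns `path`.
#' @export
read_cell_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  as_cell_table(df)
}

#' @rdname read_cell_table
#' @param table a `cell_table` (or coercible data frame).
#' @export
write_cell_table <- function(table, path) {
  table <- as_cell_table(as.data.frame(table))
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a kinetic model file
#'
#' JSON (or YAML, by extension) mirroring the model parameter table: a
#' `cycle_length` and, per gene, `k_high`, `k_low`, `p` (all per minute) and
#' `windows` as a list of `[start, end)` pairs in cycle minutes.
#'
#' @param path model file (`.json`, `.yaml` or `.yml`).
#' @param phase_map a [phase_map()] to bundle (default [default_phase_map()]
#'   with the file's cycle length).
#' @return `read_model` returns a [model_spec()]; `write_model` invisibly
#'   returns `path`.
#' @export
read_model <- function(path, phase_map = NULL) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  T <- obj$cycle_length
  if (is.null(T)) stop("model file lacks 'cycle_length'")
  if (is.null(phase_map)) phase_map <- default_phase_map(cycle_length = T)
  genes <- lapply(obj$genes, function(g) {
    w <- do.call(rbind, lapply(g$windows, as.numeric))
    gene_params(g$name, g$k_high, g$k_low, g$p, w, cycle_length = T)
  })
  model_spec(genes, phase_map)
}

#' @rdname read_model
#' @param model a [model_spec()].
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "model_spec"))
  obj <- list(
    cycle_length = model$phase_map$cycle_length,
    genes = lapply(unname(model$genes), function(g)
      list(name = g$name, k_high = g$k_high, k_low = g$k_low, p = g$p,
           windows = lapply(seq_len(nrow(g$windows)), function(i)
             c(g$windows[i, 1], g$windows[i, 2])))))
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(obj, path, precision = 15L)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an analysis result as JSON with provenance
#'
#' Wraps the object in `{provenance: {package, version, seed}, result: ...}`
#' so every written result records how it was produced.
#'
#' @param obj a list-like result (e.g. a fit summary).
#' @param path output JSON path.
#' @param seed the seed the computation used (optional, recorded as given).
#' @export
write_results <- function(obj, path, seed = NULL) {
  out <- list(provenance = list(package = "cycleFISH",
                                version = as.character(packageVersion("cycleFISH")),
                                seed = seed),
              result = obj)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  invisible(path)
}
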