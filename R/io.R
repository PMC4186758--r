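#' Write / read a connectivity matrix as TSV
#'
#' Channel labels form the header and first column; a JSON sidecar
#' (`<path>.json`) records the measure, band and level.
#'
#' @param m A `conn_matrix`.
#' @param path Output TSV path.
#' @return `read_conn_matrix` returns a `conn_matrix`.
#' @export
write_conn_matrix <- function(m, path) {
  w <- unclass(m)
  utils::write.table(data.frame(label = rownames(w), w, check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  band <- attr(m, "band")
  jsonlite::write_json(list(measure = attr(m, "measure"),
                            band = if (!is.null(band)) unclass(band),
                            level = attr(m, "level")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_conn_matrix
#' @export
read_conn_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  w <- as.matrix(df[, -1, drop = FALSE])
  rownames(w) <- df$label
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  band <- if (!is.null(meta$band))
    band_spec(meta$band$name, meta$band$lo, meta$band$hi)
  new_conn_matrix(w, meta$measure, band, meta$level, rownames(w))
}

#' Write / read a long-format cohort table as TSV
#'
#' Columns: `subject`, `session`, `band`, `measure`, `value`.
#'
#' @param table Data frame.
#' @param path File path.
#' @export
write_cohort_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

write_sidecar <- function(path, config, seed, stage) {
  jsonlite::write_json(list(stage = stage, seed = seed, config = config,
                            package_version =
                              as.character(utils::packageVersion("phaselag"))),
                       path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
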