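#' Read and write omics tables as TSV
#'
#' Wide tables: first column `feature`, remaining columns
#' `<condition>_R<replicate>` intensities. The value scale (`raw` or
#' `log2`) travels in a `# value_scale:` comment line so tables round-trip
#' through files. Numbers are written with 12 significant digits.
#'
#' @param path File path.
#' @param table A wide omics tibble.
#' @param scale Value scale to record; defaults to the table's
#'   `value_scale` attribute.
#' @return `read_omics_table()` returns the tibble (with the
#'   `value_scale` attribute set); `write_omics_table()` returns `path`
#'   invisibly.
#' @export
read_omics_table <- function(path) {
  first <- readLines(path, n = 1L)
  scale <- "raw"
  if (grepl("^# value_scale:", first)) {
    scale <- trimws(sub("^# value_scale:", "", first))
  }
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  names(out)[1L] <- "feature"
  attr(out, "value_scale") <- scale
  out
}

#' @rdname read_omics_table
#' @export
write_omics_table <- function(table, path, scale = NULL) {
  scale <- scale %||% attr(table, "value_scale") %||% "raw"
  tab <- dplyr::mutate(table, dplyr::across(
    dplyr::where(is.numeric), ~ as.numeric(sprintf("%.12g", .x))
  ))
  writeLines(sprintf("# value_scale: %s", scale), path)
  readr::write_tsv(tab, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Read and write condition design tables as TSV
#'
#' Columns: `condition`, `oc_index`, `formate_mM`, `replicates`.
#'
#' @param path File path.
#' @param design A design tibble (see [gen_condition_design()]).
#' @export
read_condition_design <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("condition", "oc_index")
  if (!all(need %in% names(out))) {
    abort("design table must have `condition` and `oc_index` columns.",
          class = "formateswitch_domain_error")
  }
  if (!all(out$oc_index %in% 0:2)) {
    abort("design `oc_index` values must be 0, 1 or 2.",
          class = "formateswitch_domain_error")
  }
  out
}

#' @rdname read_condition_design
#' @export
write_condition_design <- function(design, path) {
  readr::write_tsv(design, path, progress = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: set name, description, then member feature IDs, all
#' tab-separated.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) {
    abort(sprintf("read_gmt: line(s) %s have fewer than 3 fields.",
                  paste(which(bad), collapse = ", ")),
          class = "formateswitch_domain_error")
  }
  setNames(lapply(parts, function(x) unique(x[-(1:2)])),
           vapply(parts, `[[`, character(1), 1L))
}

#' @rdname read_gmt
#' @param sets Named list of feature-ID vectors.
#' @param description Second GMT column (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a production-rate sweep as TSV
#'
#' One row per grid point with all state and flux columns, floats at 12
#' significant digits.
#'
#' @param sweep A [sweep_production()] result.
#' @param path File path.
#' @export
write_sweep_tsv <- function(sweep, path) {
  out <- dplyr::mutate(sweep, dplyr::across(
    dplyr::where(is.numeric), ~ as.numeric(sprintf("%.12g", .x))
  ))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
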