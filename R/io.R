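#' Read analysis inputs from headered CSV/TSV files
#'
#' `read_runout_histogram()` expects columns `fluorescence` and `count`
#' (or any two numeric columns in that order); `read_size_sample()` a
#' single `area` column of cross-sectional areas in square micrometers;
#' `read_qpcr_table()` the tidy quantification layout
#' (`sample_id`, `target`, `role`, `cq`, `efficiency`). Delimiter is
#' guessed from the extension (`.tsv` = tab, otherwise comma). Each
#' reader reports the number of rows read.
#'
#' @param path Path to the file.
#' @return A tibble with the validated columns.
#' @export
read_runout_histogram <- function(path) {
  df <- read_delim_checked(path)
  h <- tryCatch(as_runout_histogram(df), error = function(e) {
    rlang::abort(sprintf("'%s': %s", path, conditionMessage(e)),
                 class = "replicycle_parse_error")
  })
  rlang::inform(sprintf("Read run-out histogram '%s': %d bins, %.0f events.",
                        path, nrow(h), sum(h$count)))
  h
}

#' @rdname read_runout_histogram
#' @export
read_size_sample <- function(path) {
  df <- read_delim_checked(path)
  if (!"area" %in% names(df)) {
    if (ncol(df) == 1 && is.numeric(df[[1]])) {
      names(df) <- "area"
    } else {
      rlang::abort(sprintf("'%s': expected an `area` column of cell cross-sectional areas.", path),
                   class = "replicycle_parse_error")
    }
  }
  if (any(!is.finite(df$area)) || any(df$area <= 0)) {
    rlang::abort(sprintf("'%s': areas must be finite and positive.", path),
                 class = "replicycle_parse_error")
  }
  rlang::inform(sprintf("Read size sample '%s': %d cells.", path, nrow(df)))
  tibble::as_tibble(df["area"])
}

#' @rdname read_runout_histogram
#' @export
read_qpcr_table <- function(path) {
  df <- read_delim_checked(path)
  required <- c("sample_id", "target", "role", "cq", "efficiency")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    rlang::abort(sprintf("'%s': missing column(s) %s.", path,
                         paste(missing, collapse = ", ")),
                 class = "replicycle_parse_error")
  }
  rlang::inform(sprintf("Read qPCR table '%s': %d wells.", path, nrow(df)))
  tibble::as_tibble(df)
}

read_delim_checked <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    rlang::abort(sprintf("Input file '%s' does not exist.", as.character(path)[1]),
                 class = "replicycle_parse_error")
  }
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- tryCatch(
    readr::read_delim(path, delim = delim, show_col_types = FALSE,
                      progress = FALSE),
    error = function(e) {
      rlang::abort(sprintf("Failed to parse '%s': %s", path, conditionMessage(e)),
                   class = "replicycle_parse_error")
    }
  )
  if (nrow(df) == 0) {
    rlang::abort(sprintf("'%s' contains no data rows.", path),
                 class = "replicycle_parse_error")
  }
  df
}
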