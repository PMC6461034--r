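# Internal helpers shared across readers.

# Read a tab-separated file with a header row, all columns as character;
# numeric conversion is done per logical field so a bad cell can be reported
# with its row index.
read_tsv_chr <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("input file not found: ", path))
  }
  readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE,
    na = character()
  )
}

# Resolve logical field names to actual headers, failing loudly when a
# required column is missing.
require_columns <- function(tbl, columns, path) {
  missing <- setdiff(unname(unlist(columns)), names(tbl))
  if (length(missing) > 0) {
    abort(paste0(
      "missing required column(s) in ", path, ": ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(tbl)
}

# Convert a character column to numeric; unparsable cells are fatal and named
# by 1-based data row index.
parse_numeric <- function(x, field, blank_as = NA_real_) {
  out <- suppressWarnings(as.numeric(x))
  blank <- !is.na(blank_as) & (is.na(x) | trimws(x) == "")
  out[blank] <- blank_as
  bad <- which(is.na(out) & !blank & !(is.na(x) | trimws(x) == ""))
  if (length(bad) > 0) {
    abort(paste0(
      "unparsable numeric value in column '", field, "' at data row ",
      bad[1], ": '", x[bad[1]], "'"
    ))
  }
  out
}

# Split a ";"-separated multi-value cell into a character vector, dropping
# empties.
split_multi <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)
  lapply(parts, function(p) {
    p <- trimws(p)
    p[nzchar(p)]
  })
}

is_flagged <- function(x) {
  !is.na(x) & trimws(x) %in% c("+", "1", "TRUE", "true", "yes")
}
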