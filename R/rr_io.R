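#' Write predictions in CASP RR format
#'
#' Serializes a prediction list in the community RR dialect: header lines
#' `PFRMAT RR`, `TARGET <id>`, `MODEL 1`; one body line `i j 0 8 p` per
#' contact (`i < j`, probability with 6 decimals); terminator `END`.
#' Output is byte-deterministic for identical input.
#'
#' @param pl A `contact_prediction` (see [select_top()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @examples
#' \dontrun{
#' write_rr(preds, "T0618.rr")
#' }
#' @export
write_rr <- function(pl, path) {
  stopifnot(inherits(pl, "contact_prediction"))
  header <- c(
    "PFRMAT RR",
    paste("TARGET", attr(pl, "target_id") %||% "TARGET"),
    "MODEL 1"
  )
  body <- sprintf("%d %d 0 8 %.6f", pl$i, pl$j, pl$score)
  writeLines(c(header, body, "END"), path)
  invisible(path)
}

#' Read a CASP RR contact prediction file
#'
#' Accepts the dialect written by [write_rr()] and tolerates extra
#' whitespace, comment/remark headers and an optional sequence block
#' (lines of amino-acid letters between the header and the contacts).
#' Pairs are normalized to `i < j`; `i == j` is an error.
#'
#' @param path RR file path.
#' @param params A [contact_params()] used to classify ranges.
#' @return A `contact_prediction` tibble (`i`, `j`, `sep`, `range`, `score`)
#'   with attribute `target_id`.
#' @export
read_rr <- function(path, params = contact_params()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  target_id <- "TARGET"
  i <- integer(0)
  j <- integer(0)
  p <- numeric(0)
  for (ln in lines) {
    up <- toupper(ln)
    if (startsWith(up, "PFRMAT") || startsWith(up, "MODEL") ||
      startsWith(up, "AUTHOR") || startsWith(up, "METHOD") ||
      startsWith(up, "REMARK") || startsWith(up, "#")) {
      next
    }
    if (startsWith(up, "TARGET")) {
      tk <- strsplit(ln, "[[:space:]]+")[[1]]
      if (length(tk) >= 2) target_id <- tk[2]
      next
    }
    if (up == "END") break
    if (grepl("^[A-Z]+$", up)) next # sequence block
    tk <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(tk) < 5 || anyNA(suppressWarnings(as.numeric(tk[1:5])))) {
      stop("malformed RR line: ", sQuote(ln), call. = FALSE)
    }
    a <- as.integer(tk[1])
    b <- as.integer(tk[2])
    if (a == b) stop("malformed RR line (i == j): ", sQuote(ln), call. = FALSE)
    i <- c(i, min(a, b))
    j <- c(j, max(a, b))
    p <- c(p, as.numeric(tk[5]))
  }
  sep <- j - i
  out <- tibble::tibble(
    i = i, j = j, sep = sep,
    range = range_of_sep(sep, params), score = p
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$i, .data$j)
  new_contact_prediction(out, target_id = target_id)
}

#' Read a model-quality table
#'
#' Two-column tab-separated file `model_id<TAB>score`; `#` comments and a
#' header line are allowed. Scores are external model-quality values
#' (predicted GDT-TS, TM-score, ...) on whatever scale the table declares;
#' the package only compares them within one table.
#'
#' @param path TSV path.
#' @return Tibble with columns `model_id` (character) and `score` (numeric).
#' @export
read_quality_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path,
    header = FALSE, comment.char = "#",
    col.names = c("model_id", "score"),
    colClasses = c("character", "character"),
    strip.white = TRUE
  )
  # tolerate an optional header row
  if (nrow(df) > 0 && is.na(suppressWarnings(as.numeric(df$score[1])))) {
    df <- df[-1, , drop = FALSE]
  }
  df$score <- as.numeric(df$score)
  if (anyNA(df$score)) stop("non-numeric score in quality table ", path, call. = FALSE)
  tibble::as_tibble(df)
}

#' Write a model-quality table
#'
#' @param quality Data frame with columns `model_id`, `score`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_quality_table <- function(quality, path) {
  stopifnot(all(c("model_id", "score") %in% names(quality)))
  writeLines(
    c(
      "# model_id\tscore",
      sprintf("%s\t%.6f", quality$model_id, quality$score)
    ),
    path
  )
  invisible(path)
}
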