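#' Parse a domain definition string
#'
#' Domain definitions follow the CASP bracket notation: comma-separated
#' 1-based inclusive residue ranges on the target sequence, e.g.
#' `"31-80,257-384"`. Segments must be well-formed (`start <= end`),
#' non-overlapping, and are returned sorted ascending.
#'
#' @param text Domain string, e.g. `"31-80,257-384"` or `"1-135"`.
#' @param target_id Optional target identifier carried along as an attribute.
#'
#' @return A tibble of class `domain_def` with columns `start` and `end`
#'   (integers), one row per segment, and attributes `target_id` and `L`
#'   (the domain length, the sum of segment lengths).
#' @examples
#' d <- parse_domain("31-80,257-384", target_id = "T0534")
#' domain_length(d) # 178
#' @export
parse_domain <- function(text, target_id = NA_character_) {
  stopifnot(is.character(text), length(text) == 1, !is.na(text))
  text <- gsub("[][]", "", gsub("[[:space:]]", "", text))
  if (!grepl("^[0-9]+-[0-9]+(,[0-9]+-[0-9]+)*$", text)) {
    stop("malformed domain definition: ", sQuote(text),
      " (expected comma-separated 'a-b' integer ranges)",
      call. = FALSE
    )
  }
  parts <- strsplit(text, ",", fixed = TRUE)[[1]]
  bounds <- lapply(strsplit(parts, "-", fixed = TRUE), as.integer)
  seg <- tibble::tibble(
    start = vapply(bounds, `[`, integer(1), 1L),
    end = vapply(bounds, `[`, integer(1), 2L)
  )
  if (any(seg$start > seg$end)) {
    stop("inverted segment (start > end) in domain definition: ", sQuote(text),
      call. = FALSE
    )
  }
  if (any(seg$start < 1L)) {
    stop("domain positions are 1-based; got a segment starting below 1", call. = FALSE)
  }
  seg <- dplyr::arrange(seg, .data$start)
  if (nrow(seg) > 1 && any(seg$start[-1] <= seg$end[-nrow(seg)])) {
    stop("overlapping segments in domain definition: ", sQuote(text), call. = FALSE)
  }
  new_domain_def(seg, target_id = target_id)
}

new_domain_def <- function(segments, target_id = NA_character_) {
  out <- tibble::as_tibble(segments[c("start", "end")])
  attr(out, "target_id") <- target_id
  attr(out, "L") <- sum(out$end - out$start + 1L)
  class(out) <- c("domain_def", class(out))
  out
}

#' Domain length
#'
#' Total number of residues covered by a domain definition; the `L` in
#' top-L/5 prediction depths.
#'
#' @param domain A `domain_def` (see [parse_domain()]).
#' @return Integer length.
#' @export
domain_length <- function(domain) {
  stopifnot(inherits(domain, "domain_def"))
  attr(domain, "L")
}

#' Test residue indices for domain membership
#'
#' @param index Integer vector of residue indices.
#' @param domain A `domain_def`.
#' @return Logical vector, `TRUE` where the index falls inside a segment.
#' @export
in_domain <- function(index, domain) {
  stopifnot(inherits(domain, "domain_def"))
  out <- rep(FALSE, length(index))
  for (k in seq_len(nrow(domain))) {
    out <- out | (index >= domain$start[k] & index <= domain$end[k])
  }
  out
}

#' @export
format.domain_def <- function(x, ...) {
  paste0(x$start, "-", x$end, collapse = ",")
}

#' @export
print.domain_def <- function(x, ...) {
  cat(sprintf(
    "<domain_def> %s [%s]  L = %d\n",
    attr(x, "target_id"), format(x), domain_length(x)
  ))
  invisible(x)
}
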