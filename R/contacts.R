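new_contact_map <- function(data, source_id = NA_character_) {
  out <- tibble::as_tibble(data[c("i", "j", "sep", "range")])
  attr(out, "source_id") <- source_id
  class(out) <- c("contact_map", class(out))
  out
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf(
    "<contact_map> %s: %d contacts (%d medium, %d long)\n",
    attr(x, "source_id"), nrow(x),
    sum(x$range == "medium"), sum(x$range == "long")
  ))
  NextMethod()
}

range_of_sep <- function(sep, params = contact_params()) {
  dplyr::case_when(
    sep >= params$long_lo ~ "long",
    sep >= params$medium_lo & sep <= params$medium_hi ~ "medium",
    TRUE ~ "short"
  )
}

#' Classify the sequence-separation range of a residue pair
#'
#' A contacting pair is *medium range* when the two residues are 12 to 23
#' positions apart in sequence and *long range* at a separation of 24 or
#' more; anything closer is *short range*. A pure function of `|j - i|`.
#'
#' @param i,j Residue indices (vectorized); `i == j` is an error.
#' @param params A [contact_params()].
#' @return Character vector: `"short"`, `"medium"` or `"long"`.
#' @examples
#' classify_range(1, 13) # medium
#' classify_range(1, 25) # long
#' @export
classify_range <- function(i, j, params = contact_params()) {
  if (any(i == j)) stop("i == j: a residue has no separation from itself", call. = FALSE)
  range_of_sep(abs(j - i), params)
}

#' Chebyshev sequence distance between two contacts
#'
#' The shared proximity metric for delta-neighborhood matching and contact
#' clustering: `max(|a_i - b_i|, |a_j - b_j|)` on ordered (i < j) pairs.
#' Both endpoints must be within the tolerance for two contacts to be
#' "within d residues" of each other, and distance 0 is exact equality.
#'
#' @param a,b Contacts, each a length-2 integer vector `c(i, j)` with
#'   `i < j`, or a one-row data frame with columns `i` and `j`.
#' @return Non-negative integer.
#' @examples
#' contact_distance(c(10, 50), c(12, 52)) # 2
#' @export
contact_distance <- function(a, b) {
  as_pair <- function(p) {
    if (is.data.frame(p)) p <- c(p$i[1], p$j[1])
    stopifnot(length(p) == 2, p[1] < p[2])
    as.integer(p)
  }
  a <- as_pair(a)
  b <- as_pair(b)
  max(abs(a - b))
}

# Vectorized Chebyshev distances: rows of (i1,j1) x rows of (i2,j2) -> matrix
cheb_cross <- function(i1, j1, i2, j2) {
  di <- abs(outer(i1, i2, "-"))
  dj <- abs(outer(j1, j2, "-"))
  pmax(di, dj)
}

#' Extract residue-residue contacts from a model
#'
#' Two residues are in contact when the Euclidean distance between their
#' representative atoms (C-beta; C-alpha for glycine) is strictly less than
#' the threshold (default 8 Angstrom). All separations >= 1 are retained and
#' classified into short/medium/long ranges; range filtering is applied
#' downstream, not here.
#'
#' @param model A [structure_model()] with at least 2 residues.
#' @param params A [contact_params()].
#' @return A tibble of class `contact_map` with columns `i`, `j` (`i < j`),
#'   `sep` and `range`, and attribute `source_id` (the model id).
#' @examples
#' ref <- make_reference(40, seed = 1)
#' extract_contacts(ref)
#' @export
extract_contacts <- function(model, params = contact_params()) {
  stopifnot(inherits(model, "structure_model"))
  if (nrow(model) < 2) stop("need at least 2 residues to extract contacts", call. = FALSE)
  d <- as.matrix(stats::dist(as.matrix(model[c("x", "y", "z")])))
  hit <- which(upper.tri(d) & d < params$distance_threshold, arr.ind = TRUE)
  i <- model$index[hit[, 1]]
  j <- model$index[hit[, 2]]
  sep <- j - i
  out <- tibble::tibble(i = i, j = j, sep = sep, range = range_of_sep(sep, params))
  out <- dplyr::arrange(out, .data$i, .data$j)
  new_contact_map(out, source_id = model_id(model) %||% "model")
}

#' Contact map of a native structure restricted to a domain
#'
#' Applies the standard contact definition to an experimental (native)
#' structure and keeps only pairs with both endpoints inside the domain.
#' This is the ground truth that predictions are evaluated against.
#'
#' @param native A [structure_model()] of the experimental structure.
#' @param domain A `domain_def` (see [parse_domain()]).
#' @param params A [contact_params()].
#' @return A `contact_map` (all ranges retained).
#' @export
true_contacts <- function(native, domain, params = contact_params()) {
  stopifnot(inherits(native, "structure_model"), inherits(domain, "domain_def"))
  if (sum(in_domain(native$index, domain)) < 2) {
    stop("native structure covers fewer than 2 domain residues", call. = FALSE)
  }
  cm <- extract_contacts(native, params)
  keep <- in_domain(cm$i, domain) & in_domain(cm$j, domain)
  new_contact_map(cm[keep, , drop = FALSE], source_id = attr(cm, "source_id"))
}
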