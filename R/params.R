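#' Contact-definition parameters
#'
#' Bundles the constants that define a residue-residue contact and how
#' predictions are ranked and matched. The defaults are the community-standard
#' CASP settings: two residues are in contact when their representative atoms
#' (C-beta; C-alpha for glycine) are closer than 8 Angstrom; a contacting pair
#' is *medium range* when separated by 12-23 positions in sequence and *long
#' range* at >= 24; prediction lists are truncated at L/5 of the domain
#' length; contact clusters use a 4-residue linkage.
#'
#' @param distance_threshold Contact distance cut-off in Angstrom (strict
#'   less-than). Default 8.
#' @param medium_lo,medium_hi Inclusive sequence-separation bounds of the
#'   medium range. Defaults 12 and 23.
#' @param long_lo Minimum separation of the long range. Default 24.
#' @param delta Non-negative integer tolerance for neighborhood matching of
#'   predictions against true contacts. Default 0 (exact).
#' @param cluster_linkage Chebyshev sequence distance (residues) under which
#'   two predicted contacts join the same cluster. Default 4.
#' @param top_fraction Fraction of the domain length kept when truncating a
#'   ranked prediction list. Default 1/5.
#'
#' @return A list of class `contact_params`.
#' @examples
#' contact_params()
#' contact_params(delta = 2)
#' @export
contact_params <- function(distance_threshold = 8,
                           medium_lo = 12L,
                           medium_hi = 23L,
                           long_lo = 24L,
                           delta = 0L,
                           cluster_linkage = 4L,
                           top_fraction = 1 / 5) {
  stopifnot(
    is.numeric(distance_threshold), length(distance_threshold) == 1,
    distance_threshold > 0,
    medium_lo <= medium_hi, medium_hi < long_lo,
    delta >= 0, cluster_linkage >= 0,
    top_fraction > 0, top_fraction <= 1
  )
  structure(
    list(
      distance_threshold = as.numeric(distance_threshold),
      medium_lo = as.integer(medium_lo),
      medium_hi = as.integer(medium_hi),
      long_lo = as.integer(long_lo),
      delta = as.integer(delta),
      cluster_linkage = as.integer(cluster_linkage),
      top_fraction = top_fraction
    ),
    class = "contact_params"
  )
}

#' @export
print.contact_params <- function(x, ...) {
  cat("<contact_params>\n")
  cat(sprintf("  distance threshold: < %g Angstrom\n", x$distance_threshold))
  cat(sprintf(
    "  ranges: medium %d-%d, long >= %d\n",
    x$medium_lo, x$medium_hi, x$long_lo
  ))
  cat(sprintf(
    "  delta: %d   cluster linkage: %d   top fraction: %s\n",
    x$delta, x$cluster_linkage, format(x$top_fraction)
  ))
  invisible(x)
}
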