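#' Pool contacts across an ensemble into a ranked consensus list
#'
#' The heart of the conformation-ensemble predictor. Every contact observed
#' in any model is counted across all models, counts are normalized to
#' frequencies (count / number of models, i.e. the fraction of models
#' containing the contact) and the list is sorted by frequency, descending.
#' Recurrent contacts -- those supported by many independently generated
#' conformations -- rise to the top and become the predictions.
#'
#' Ties in frequency are broken by `(i, j)` ascending so output is
#' deterministic. Models that omit residues still count in the denominator
#' for every pair: the frequency is always "fraction of ensemble models
#' containing this contact".
#'
#' @param maps List of `contact_map`s (see [extract_contacts()]), or a list
#'   of [structure_model()]s which are converted first.
#' @param params A [contact_params()].
#' @return A tibble of class `contact_consensus` with columns `i`, `j`,
#'   `sep`, `range`, `count`, `freq`, sorted by `freq` descending, and
#'   attribute `n_models`.
#' @examples
#' ens <- make_ensemble(make_reference(40, seed = 1), n_models = 10, seed = 2)
#' build_consensus(ens$models)
#' @export
build_consensus <- function(maps, params = contact_params()) {
  if (length(maps) == 0) stop("empty ensemble: no contact maps", call. = FALSE)
  maps <- lapply(maps, function(m) {
    if (inherits(m, "structure_model")) extract_contacts(m, params) else m
  })
  n_models <- length(maps)
  pooled <- dplyr::bind_rows(lapply(maps, function(m) m[c("i", "j", "sep", "range")]))
  out <- dplyr::count(pooled, .data$i, .data$j, .data$sep, .data$range, name = "count")
  out$freq <- out$count / n_models
  out <- dplyr::arrange(out, dplyr::desc(.data$freq), .data$i, .data$j)
  out <- tibble::as_tibble(out)
  attr(out, "n_models") <- n_models
  class(out) <- c("contact_consensus", class(out))
  out
}

#' @export
print.contact_consensus <- function(x, ...) {
  cat(sprintf(
    "<contact_consensus> %d contacts pooled over %d models\n",
    nrow(x), attr(x, "n_models")
  ))
  NextMethod()
}

#' @method tidy contact_consensus
#' @export
tidy.contact_consensus <- function(x, ...) {
  tibble::as_tibble(unclass_tbl(x))
}

#' @method glance contact_consensus
#' @export
glance.contact_consensus <- function(x, ...) {
  tibble::tibble(
    n_models = attr(x, "n_models"),
    n_contacts = nrow(x),
    n_medium = sum(x$range == "medium"),
    n_long = sum(x$range == "long"),
    max_freq = if (nrow(x)) max(x$freq) else NA_real_
  )
}

unclass_tbl <- function(x) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

#' Restrict a consensus (or contact map) to a domain and to ranges
#'
#' Keeps entries whose endpoints both lie inside the domain segments and
#' whose range class is among `ranges`. Order is preserved. By default only
#' medium and long range contacts survive, the two ranges the method
#' predicts and evaluates.
#'
#' @param contacts A `contact_consensus`, `contact_map` or any tibble with
#'   columns `i`, `j`, `range`.
#' @param domain A `domain_def`, or `NULL` to skip the domain restriction.
#' @param ranges Character vector of range classes to keep.
#' @return Object of the same class, possibly with zero rows.
#' @export
filter_to_domain <- function(contacts, domain, ranges = c("medium", "long")) {
  keep <- contacts$range %in% ranges
  if (!is.null(domain)) {
    stopifnot(inherits(domain, "domain_def"))
    keep <- keep & in_domain(contacts$i, domain) & in_domain(contacts$j, domain)
  }
  contacts[keep, , drop = FALSE]
}

#' Truncate a ranked consensus to the top L x fraction predictions
#'
#' The standard prediction depth is L/5 contacts, L being the domain length.
#' The first `max(1, floor(L * fraction))` entries are kept (fewer, with a
#' message, when the list is shorter) and returned as a prediction list
#' whose score is the consensus frequency.
#'
#' @param cl A `contact_consensus` (already filtered as desired).
#' @param L Domain length; defaults to `domain_length(domain)` when a
#'   domain is supplied.
#' @param fraction Fraction of L to keep, default 1/5.
#' @param target_id Target identifier for the RR header.
#' @param domain Optional `domain_def` carried along.
#' @return A tibble of class `contact_prediction` with columns `i`, `j`,
#'   `sep`, `range`, `score` (non-increasing), and attributes `target_id`
#'   and `domain`.
#' @examples
#' # L = 178 (e.g. a two-segment domain of 50 + 128 residues) keeps
#' # floor(178 / 5) = 35 predictions
#' @export
select_top <- function(cl, L = NULL, fraction = 1 / 5, target_id = NULL, domain = NULL) {
  if (is.null(L)) {
    if (is.null(domain)) stop("supply L or a domain", call. = FALSE)
    L <- domain_length(domain)
  }
  stopifnot(L >= 1)
  k <- max(1L, as.integer(floor(L * fraction)))
  if (nrow(cl) < k) {
    message(
      "consensus holds only ", nrow(cl), " contacts; requested top ", k
    )
    k <- nrow(cl)
  }
  out <- utils::head(tibble::as_tibble(unclass_tbl(cl)), k)
  out <- out[c("i", "j", "sep", "range")]
  out$score <- utils::head(cl$freq, k)
  new_contact_prediction(out,
    target_id = target_id %||% attr(domain, "target_id") %||% "TARGET",
    domain = domain
  )
}

new_contact_prediction <- function(data, target_id = "TARGET", domain = NULL) {
  out <- tibble::as_tibble(data[c("i", "j", "sep", "range", "score")])
  if (nrow(out) > 1 && any(diff(out$score) > 1e-12)) {
    stop("prediction scores must be non-increasing", call. = FALSE)
  }
  attr(out, "target_id") <- target_id
  attr(out, "domain") <- domain
  class(out) <- c("contact_prediction", class(out))
  out
}

#' @export
print.contact_prediction <- function(x, ...) {
  cat(sprintf(
    "<contact_prediction> %s: %d contacts (%d medium, %d long)\n",
    attr(x, "target_id"), nrow(x),
    sum(x$range == "medium"), sum(x$range == "long")
  ))
  NextMethod()
}

#' Filter an ensemble by a model-quality table
#'
#' Three quality-driven filters over an ensemble (models or contact maps),
#' driven by an external per-model score such as a predicted GDT-TS or a
#' TM-score: drop models scoring below a threshold (`remove_below`, e.g.
#' predicted GDT-TS < 30), drop the k best (`remove_top_k`, a robustness
#' probe), or keep only the k best (`keep_top_k`). Ties at a top-k cut are
#' broken by model id ascending. Members without a score are dropped with a
#' warning.
#'
#' @param ensemble Named list of [structure_model()]s or `contact_map`s;
#'   names (or `model_id`s) must match the quality table.
#' @param quality Data frame with columns `model_id` and `score`
#'   (see [read_quality_table()]).
#' @param mode One of `"remove_below"`, `"remove_top_k"`, `"keep_top_k"`.
#' @param value Threshold (for `remove_below`, kept when `score >=` it)
#'   or integer k.
#' @return The filtered list, in the original order; error if empty.
#' @export
filter_ensemble <- function(ensemble, quality,
                            mode = c("remove_below", "remove_top_k", "keep_top_k"),
                            value) {
  mode <- match.arg(mode)
  stopifnot(all(c("model_id", "score") %in% names(quality)))
  ids <- vapply(ensemble, function(m) model_id(m) %||% NA_character_, character(1))
  if (!is.null(names(ensemble))) ids <- ifelse(is.na(ids), names(ensemble), ids)
  scored <- match(ids, quality$model_id)
  if (anyNA(scored)) {
    warning(
      "dropping ", sum(is.na(scored)), " ensemble member(s) without a quality score: ",
      paste(utils::head(ids[is.na(scored)], 5), collapse = ", "),
      call. = FALSE
    )
    ensemble <- ensemble[!is.na(scored)]
    ids <- ids[!is.na(scored)]
    scored <- scored[!is.na(scored)]
  }
  sc <- quality$score[scored]
  keep <- switch(mode,
    remove_below = sc >= value,
    remove_top_k = {
      k <- min(as.integer(value), length(ids))
      drop <- order(-sc, ids, method = "radix")[seq_len(k)]
      !seq_along(ids) %in% drop
    },
    keep_top_k = {
      k <- as.integer(value)
      if (k >= length(ids)) {
        warning("keep_top_k: k >= ensemble size, keeping all ", length(ids),
          " models",
          call. = FALSE
        )
        rep(TRUE, length(ids))
      } else {
        seq_along(ids) %in% order(-sc, ids, method = "radix")[seq_len(k)]
      }
    }
  )
  if (!any(keep)) stop("filter removed every model from the ensemble", call. = FALSE)
  ensemble[keep]
}
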