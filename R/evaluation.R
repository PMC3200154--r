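# Correctness of one prediction: some true contact of the evaluated range
# within Chebyshev distance <= delta. Each prediction is judged
# independently (a true contact may validate several nearby predictions).
match_flags <- function(pred, truth, delta) {
  if (nrow(pred) == 0) {
    return(logical(0))
  }
  if (nrow(truth) == 0) {
    return(rep(FALSE, nrow(pred)))
  }
  d <- cheb_cross(pred$i, pred$j, truth$i, truth$j)
  apply(d, 1, min) <= delta
}

eval_one_range <- function(pl, truth, delta, rng) {
  pred_r <- pl[pl$range == rng, , drop = FALSE]
  truth_r <- truth[truth$range == rng, , drop = FALSE]
  correct <- match_flags(pred_r, truth_r, delta)
  exact <- match_flags(pred_r, truth_r, 0L)
  # recall counts distinct true contacts hit exactly (delta = 0 by design)
  hit_truth <- if (nrow(truth_r) == 0 || nrow(pred_r) == 0) {
    0L
  } else {
    sum(apply(cheb_cross(truth_r$i, truth_r$j, pred_r$i, pred_r$j), 1, min) == 0)
  }
  list(
    n_considered = nrow(pred_r), n_correct = sum(correct),
    n_true = nrow(truth_r), n_true_hit = hit_truth
  )
}

#' Evaluate a contact prediction list against true contacts
#'
#' Precision is the number of correct predictions over the number of
#' predictions considered; a prediction is correct when some true contact of
#' the evaluated range lies within `delta` residues of it (Chebyshev
#' distance on both endpoints; `delta = 0` is exact matching). Recall is the
#' number of true contacts recovered exactly over the number of true
#' contacts of that range -- recall is always computed at `delta = 0`, over
#' the same (typically top-L/5-truncated) prediction list.
#'
#' With `range = "both"`, medium and long predictions are pooled but each
#' prediction is matched only against true contacts of its own range class.
#'
#' @param pl A `contact_prediction` (see [select_top()], [read_rr()]).
#' @param truth A `contact_map` of true contacts (see [true_contacts()]).
#' @param delta Non-negative integer matching tolerance (0, 1, 2 in
#'   standard reporting).
#' @param range `"medium"`, `"long"` or `"both"`.
#' @param params A [contact_params()].
#' @return One-row tibble of class `contact_eval`: `range`, `delta`,
#'   `n_considered`, `n_correct`, `precision`, `n_true`, `recall`,
#'   `undefined` (`TRUE` when no prediction of the range existed, in which
#'   case precision is reported as 0).
#' @examples
#' ref <- make_reference(60, seed = 1)
#' dom <- parse_domain("1-60")
#' truth <- true_contacts(ref, dom)
#' cons <- build_consensus(list(extract_contacts(ref)))
#' pl <- select_top(filter_to_domain(cons, dom), domain = dom)
#' evaluate_predictions(pl, truth, delta = 0, range = "long")
#' @export
evaluate_predictions <- function(pl, truth, delta = 0L, range = c("both", "medium", "long"),
                                 params = contact_params()) {
  range <- match.arg(range)
  stopifnot(delta >= 0)
  ranges <- if (range == "both") c("medium", "long") else range
  parts <- lapply(ranges, function(r) eval_one_range(pl, truth, delta, r))
  n_considered <- sum(vapply(parts, `[[`, integer(1), "n_considered"))
  n_correct <- sum(vapply(parts, `[[`, integer(1), "n_correct"))
  n_true <- sum(vapply(parts, `[[`, integer(1), "n_true"))
  n_true_hit <- sum(vapply(parts, `[[`, integer(1), "n_true_hit"))
  undefined <- n_considered == 0
  out <- tibble::tibble(
    range = range, delta = as.integer(delta),
    n_considered = n_considered, n_correct = n_correct,
    precision = if (undefined) 0 else n_correct / n_considered,
    n_true = n_true,
    recall = if (n_true == 0) 0 else n_true_hit / n_true,
    undefined = undefined
  )
  class(out) <- c("contact_eval", class(out))
  out
}

#' Evaluation report over ranges and deltas
#'
#' Convenience wrapper producing the standard report grid: one row per
#' (range, delta) combination, mirroring how contact-prediction assessments
#' tabulate precision at delta = 0, 1, 2 for medium and long range.
#'
#' @inheritParams evaluate_predictions
#' @param deltas Integer vector of tolerances, default `c(0, 1, 2)`.
#' @param ranges Character vector of ranges, default medium and long.
#' @return Tibble with one row per (range, delta).
#' @export
evaluation_report <- function(pl, truth, deltas = c(0L, 1L, 2L),
                              ranges = c("medium", "long"),
                              params = contact_params()) {
  grid <- expand.grid(range = ranges, delta = deltas, stringsAsFactors = FALSE)
  out <- purrr::pmap(grid, function(range, delta) {
    evaluate_predictions(pl, truth, delta = delta, range = range, params = params)
  })
  dplyr::bind_rows(out)
}
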