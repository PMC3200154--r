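frac_satisfied <- function(preds, map, delta) {
  if (nrow(preds) == 0) {
    return(0)
  }
  if (nrow(map) == 0) {
    return(0)
  }
  if (delta == 0) {
    # exact membership of the (i, j) pair in the model's contact map
    mean(paste(preds$i, preds$j) %in% paste(map$i, map$j))
  } else {
    d <- cheb_cross(preds$i, preds$j, map$i, map$j)
    mean(apply(d, 1, min) <= delta)
  }
}

#' Contact-satisfaction score of one model
#'
#' Scores a model by how well it realizes the consensus predictions: the
#' fraction of predicted medium range contacts present in the model exactly,
#' the fraction present within 1 residue (delta = 1), and the same two
#' fractions for the long range predictions. The model's score is the sum of
#' the four fractions, in `[0, 4]` (equivalently, the sum of four
#' percentages) -- models that realize the interactions recurring across the
#' whole ensemble score high.
#'
#' @param model_map A `contact_map` (see [extract_contacts()]), or a
#'   [structure_model()] which is converted first.
#' @param med_preds,long_preds `contact_prediction` tibbles holding the
#'   medium and long range prediction lists. An empty list contributes 0 to
#'   both of its fractions (with a message).
#' @param params A [contact_params()].
#' @return One-row tibble: `model_id`, `med_exact`, `med_d1`, `long_exact`,
#'   `long_d1`, `total`.
#' @export
satisfaction_score <- function(model_map, med_preds, long_preds,
                               params = contact_params()) {
  if (inherits(model_map, "structure_model")) {
    model_map <- extract_contacts(model_map, params)
  }
  if (nrow(med_preds) == 0) message("no medium range predictions: both medium terms are 0")
  if (nrow(long_preds) == 0) message("no long range predictions: both long terms are 0")
  med_exact <- frac_satisfied(med_preds, model_map, 0L)
  med_d1 <- frac_satisfied(med_preds, model_map, 1L)
  long_exact <- frac_satisfied(long_preds, model_map, 0L)
  long_d1 <- frac_satisfied(long_preds, model_map, 1L)
  tibble::tibble(
    model_id = model_id(model_map) %||% "model",
    med_exact = med_exact, med_d1 = med_d1,
    long_exact = long_exact, long_d1 = long_d1,
    total = med_exact + med_d1 + long_exact + long_d1
  )
}

#' Rank ensemble models by contact satisfaction
#'
#' Scores every model with [satisfaction_score()] and sorts by total score,
#' descending; ties are broken by model id ascending so the ranking is
#' deterministic. The standard usage scores models against the top L medium
#' range consensus contacts and the long range consensus contacts (see
#' [consensus_prediction_sets()]).
#'
#' @param models List of [structure_model()]s or `contact_map`s.
#' @param med_preds,long_preds Prediction lists as in [satisfaction_score()].
#' @param params A [contact_params()].
#' @return Tibble of class `contact_ranking`, one row per model, sorted;
#'   column `rank` added.
#' @export
rank_models <- function(models, med_preds, long_preds, params = contact_params()) {
  if (length(models) == 0) stop("empty model list", call. = FALSE)
  rows <- lapply(models, satisfaction_score,
    med_preds = med_preds, long_preds = long_preds, params = params
  )
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, dplyr::desc(.data$total), .data$model_id)
  out$rank <- seq_len(nrow(out))
  out <- out[c("rank", setdiff(names(out), "rank"))]
  class(out) <- c("contact_ranking", class(out))
  out
}

#' @method glance contact_ranking
#' @export
glance.contact_ranking <- function(x, ...) {
  tibble::tibble(
    n_models = nrow(x),
    top_model = x$model_id[1],
    top_total = x$total[1],
    mean_total = mean(x$total)
  )
}

#' Medium/long prediction sets for model ranking
#'
#' Builds the two prediction lists the ranking scheme consumes from a
#' consensus: the top L medium range contacts and the long range contacts,
#' both drawn from the *recurrent* part of the consensus. By default a
#' contact qualifies when it appears in at least a quarter of the ensemble
#' (`min_freq = 0.25`): scoring models against contacts observed in only a
#' model or two would reward reproduction of incidental noise rather than
#' of the interactions the ensemble agrees on. Pass `min_count` to set an
#' absolute count floor instead, or `long_top` to truncate the long list.
#'
#' @param cons A `contact_consensus`.
#' @param domain A `domain_def`; L is its length, and predictions are
#'   restricted to it.
#' @param min_freq Minimum fraction of models containing a contact for it
#'   to enter either list. Default 0.25.
#' @param min_count Absolute count floor overriding `min_freq` when given.
#' @param long_top Optional truncation depth for the long range list
#'   (`NULL` = all qualifying long contacts).
#' @param params A [contact_params()].
#' @return List with elements `medium` and `long`, both `contact_prediction`.
#' @export
consensus_prediction_sets <- function(cons, domain, min_freq = 0.25,
                                      min_count = NULL,
                                      long_top = NULL, params = contact_params()) {
  stopifnot(inherits(cons, "contact_consensus"))
  n_models <- attr(cons, "n_models")
  floor_count <- if (!is.null(min_count)) {
    as.integer(min_count)
  } else {
    max(1L, as.integer(ceiling(min_freq * n_models)))
  }
  eligible <- cons[cons$count >= floor_count, , drop = FALSE]
  attr(eligible, "n_models") <- n_models
  med <- filter_to_domain(eligible, domain, ranges = "medium")
  lng <- filter_to_domain(eligible, domain, ranges = "long")
  L <- domain_length(domain)
  med_pl <- suppressMessages(select_top(med, L = L, fraction = 1, domain = domain))
  long_pl <- suppressMessages(select_top(lng,
    L = if (is.null(long_top)) max(1L, nrow(lng)) else long_top,
    fraction = 1, domain = domain
  ))
  list(medium = med_pl, long = long_pl)
}

#' GDT-TS selection loss of a ranking
#'
#' The loss of a ranking is the quality (e.g. GDT-TS) of the best model in
#' the pool minus the quality of the model the ranking puts first: 0 when
#' the ranking finds the best model.
#'
#' @param ranking A `contact_ranking`, or a character vector of model ids in
#'   rank order.
#' @param quality Data frame with columns `model_id`, `score`; every ranked
#'   id must be present.
#' @return Non-negative numeric loss on the quality table's scale.
#' @examples
#' qt <- tibble::tibble(model_id = c("a", "b"), score = c(0.50, 0.43))
#' selection_loss(c("b", "a"), qt) # 0.07
#' @export
selection_loss <- function(ranking, quality) {
  ids <- if (inherits(ranking, "data.frame")) ranking$model_id else as.character(ranking)
  stopifnot(length(ids) >= 1)
  pos <- match(ids, quality$model_id)
  if (anyNA(pos)) {
    stop(
      "ranked model(s) missing from quality table: ",
      paste(utils::head(ids[is.na(pos)], 5), collapse = ", "),
      call. = FALSE
    )
  }
  max(quality$score[pos]) - quality$score[pos[1]]
}

#' Random-baseline selection loss
#'
#' Baseline loss of a quality-blind selection: rank all models by their true
#' quality and take the middlemost as the selected model (lower median for
#' even counts), so the loss is best-minus-median quality.
#'
#' @param quality Data frame with columns `model_id`, `score`.
#' @return Non-negative numeric loss.
#' @export
random_baseline_loss <- function(quality) {
  n <- nrow(quality)
  if (n == 0) stop("empty quality table", call. = FALSE)
  sc <- sort(quality$score, decreasing = TRUE)
  # middlemost model; lower median (the worse of the two middle) when even
  mid <- if (n %% 2 == 1) (n + 1) / 2 else n / 2 + 1
  sc[1] - sc[mid]
}
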