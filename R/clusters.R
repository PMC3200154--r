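#' Group predicted contacts into sequence clusters
#'
#' Predicted contacts tend to concentrate in distinct regions of
#' interaction. Two contacts within `linkage` residues of each other in
#' sequence (Chebyshev distance on both endpoints, see
#' [contact_distance()]) are placed in the same cluster; grouping is
#' transitive (single linkage), so a chain of pairwise-close contacts forms
#' one cluster even when its extremes are far apart. By convention the
#' procedure operates on long range predictions.
#'
#' @param preds A `contact_prediction` (or any tibble with columns `i`, `j`).
#' @param linkage Linkage distance in residues, default 4.
#' @return The input tibble of class `contact_clusters` with an integer
#'   `cluster` column; clusters are numbered by their representative's
#'   `(i, j)` ascending. Attribute `representatives` holds one row per
#'   cluster (see [cluster_representative()]).
#' @export
cluster_contacts <- function(preds, linkage = 4L) {
  if (nrow(preds) == 0) stop("no contacts to cluster", call. = FALSE)
  d <- cheb_cross(preds$i, preds$j, preds$i, preds$j)
  adj <- d <= linkage
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  memb <- igraph::components(g)$membership
  reps <- dplyr::bind_rows(lapply(
    split(preds[c("i", "j")], memb),
    cluster_representative
  ))
  reps$cluster_raw <- as.integer(names(split(seq_len(nrow(preds)), memb)))
  ord <- order(reps$i, reps$j)
  reps <- reps[ord, , drop = FALSE]
  relabel <- match(memb, reps$cluster_raw)
  reps$cluster <- seq_len(nrow(reps))
  reps <- tibble::as_tibble(reps[c("cluster", "i", "j")])
  out <- tibble::as_tibble(as.data.frame(preds))
  out$cluster <- relabel
  attr(out, "representatives") <- reps
  class(out) <- c("contact_clusters", class(out))
  out
}

#' @export
print.contact_clusters <- function(x, ...) {
  cat(sprintf(
    "<contact_clusters> %d contacts in %d clusters\n",
    nrow(x), max(x$cluster)
  ))
  NextMethod()
}

#' Representatives of a clustering
#'
#' @param clusters A `contact_clusters` (see [cluster_contacts()]).
#' @return Tibble with columns `cluster`, `i`, `j`, one row per cluster.
#' @export
cluster_representatives <- function(clusters) {
  stopifnot(inherits(clusters, "contact_clusters"))
  attr(clusters, "representatives")
}

#' Representative contact of a cluster
#'
#' The member closest in sequence to the average position of the cluster:
#' the contact minimizing `|i - mean(i)| + |j - mean(j)|`, ties broken by
#' `(i, j)` ascending.
#'
#' @param members Tibble with columns `i`, `j`, one row per member contact.
#' @return One-row tibble with columns `i`, `j`.
#' @examples
#' cluster_representative(tibble::tibble(i = c(10, 12, 14), j = c(50, 52, 54)))
#' @export
cluster_representative <- function(members) {
  stopifnot(nrow(members) >= 1)
  cost <- abs(members$i - mean(members$i)) + abs(members$j - mean(members$j))
  best <- order(cost, members$i, members$j)[1]
  tibble::tibble(i = members$i[best], j = members$j[best])
}

#' Keep representatives close to a true contact
#'
#' Truth filtering of the cluster representatives: a representative is
#' retained only when some true contact lies within `tol` residues of it.
#'
#' @param reps Tibble with columns `i`, `j` (e.g. from
#'   [cluster_representatives()]).
#' @param truth A `contact_map` of true contacts.
#' @param tol Tolerance in residues, default 4.
#' @return The retained rows of `reps`.
#' @export
filter_representatives <- function(reps, truth, tol = 4L) {
  stopifnot(tol >= 0)
  if (nrow(reps) == 0 || nrow(truth) == 0) {
    return(reps[integer(0), , drop = FALSE])
  }
  d <- cheb_cross(reps$i, reps$j, truth$i, truth$j)
  reps[apply(d, 1, min) <= tol, , drop = FALSE]
}

#' Per-model coverage of contact clusters
#'
#' For each model of the ensemble, counts how many cluster representatives
#' are covered -- a cluster is covered when the model contains a contact
#' within `tol` residues of the cluster's representative. The distribution
#' of these counts shows whether the consensus consolidates interactions
#' scattered across models (few models cover everything) or merely reflects
#' what every model already contains.
#'
#' @param maps List of `contact_map`s (or [structure_model()]s).
#' @param reps Representative contacts (tibble with `i`, `j`).
#' @param tol Tolerance in residues, default 4.
#' @param params A [contact_params()].
#' @return List of class `coverage_report`: `per_model` (tibble `model_id`,
#'   `covered`), `histogram` (tibble `covered`, `n_models`, `fraction`,
#'   `fraction_at_least` -- exact-count and cumulative shares of models),
#'   and `n_clusters`.
#' @export
cluster_coverage <- function(maps, reps, tol = 4L, params = contact_params()) {
  if (length(maps) == 0) stop("no models", call. = FALSE)
  if (nrow(reps) == 0) stop("no cluster representatives", call. = FALSE)
  maps <- lapply(maps, function(m) {
    if (inherits(m, "structure_model")) extract_contacts(m, params) else m
  })
  covered <- vapply(maps, function(m) {
    if (nrow(m) == 0) {
      return(0L)
    }
    d <- cheb_cross(reps$i, reps$j, m$i, m$j)
    sum(apply(d, 1, min) <= tol)
  }, integer(1))
  per_model <- tibble::tibble(
    model_id = vapply(maps, function(m) model_id(m) %||% "model", character(1)),
    covered = covered
  )
  counts <- table(factor(covered, levels = 0:nrow(reps)))
  hist <- tibble::tibble(
    covered = as.integer(names(counts)),
    n_models = as.integer(counts),
    fraction = as.integer(counts) / length(maps)
  )
  hist$fraction_at_least <- rev(cumsum(rev(hist$fraction)))
  out <- list(
    per_model = per_model, histogram = hist,
    n_clusters = nrow(reps), n_models = length(maps)
  )
  class(out) <- "coverage_report"
  out
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf(
    "<coverage_report> %d clusters, %d models\n",
    x$n_clusters, x$n_models
  ))
  top <- x$histogram[x$histogram$n_models > 0, , drop = FALSE]
  top <- top[order(-top$covered), , drop = FALSE]
  cat("  coverage (exact-count fraction of models): ")
  cat(sprintf("%d(%.2f)", top$covered, top$fraction), sep = "  ")
  cat("\n")
  invisible(x)
}

#' @method tidy coverage_report
#' @export
tidy.coverage_report <- function(x, ...) {
  x$per_model
}

#' @method glance coverage_report
#' @export
glance.coverage_report <- function(x, ...) {
  tibble::tibble(
    n_clusters = x$n_clusters,
    n_models = x$n_models,
    mean_covered = mean(x$per_model$covered),
    fraction_full = mean(x$per_model$covered == x$n_clusters)
  )
}
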