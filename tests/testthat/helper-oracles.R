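# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use plain loops / direct arithmetic, never the package's own
# vectorized code paths.

# all-pairs O(n^2) contact scan on a residue table
oracle_contacts <- function(model, threshold = 8) {
  n <- nrow(model)
  out <- list()
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      dx <- model$x[a] - model$x[b]
      dy <- model$y[a] - model$y[b]
      dz <- model$z[a] - model$z[b]
      if (sqrt(dx^2 + dy^2 + dz^2) < threshold) {
        out[[length(out) + 1]] <- c(model$index[a], model$index[b])
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(i = integer(0), j = integer(0)))
  }
  m <- do.call(rbind, out)
  data.frame(i = m[, 1], j = m[, 2])
}

# per-pair dictionary tally across maps
oracle_tally <- function(maps) {
  env <- new.env()
  for (m in maps) {
    for (r in seq_len(nrow(m))) {
      key <- paste(m$i[r], m$j[r])
      env[[key]] <- (env[[key]] %||% 0L) + 1L
    }
  }
  keys <- ls(env)
  parts <- do.call(rbind, strsplit(keys, " "))
  data.frame(
    i = as.integer(parts[, 1]), j = as.integer(parts[, 2]),
    count = vapply(keys, function(k) env[[k]], integer(1))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive matcher: is each prediction within delta of some truth row?
oracle_match <- function(pred, truth, delta) {
  vapply(seq_len(nrow(pred)), function(p) {
    for (t in seq_len(nrow(truth))) {
      d <- max(abs(pred$i[p] - truth$i[t]), abs(pred$j[p] - truth$j[t]))
      if (d <= delta) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1))
}

pair_key <- function(df) paste(df$i, df$j)

# random contact map over indices 1..n_res with n_pairs distinct pairs
random_map <- function(n_res, n_pairs, id = "m") {
  pairs <- unique(t(replicate(n_pairs * 3, sort(sample.int(n_res, 2)))))
  pairs <- pairs[seq_len(min(n_pairs, nrow(pairs))), , drop = FALSE]
  sep <- pairs[, 2] - pairs[, 1]
  cm <- tibble::tibble(
    i = as.integer(pairs[, 1]), j = as.integer(pairs[, 2]), sep = sep,
    range = ifelse(sep >= 24, "long", ifelse(sep >= 12, "medium", "short"))
  )
  cm <- dplyr::arrange(cm, i, j)
  attr(cm, "source_id") <- id
  class(cm) <- c("contact_map", class(cm))
  cm
}

# random residue table in a cube, strictly increasing indices
random_model <- function(n_res, box = 20, id = "m") {
  structure_model(
    tibble::tibble(
      index = seq_len(n_res),
      aa = sample(c("ALA", "GLY", "LEU"), n_res, replace = TRUE),
      x = runif(n_res, 0, box), y = runif(n_res, 0, box), z = runif(n_res, 0, box)
    ),
    model_id = id
  )
}

# prediction list from a plain pair table (scores descending by construction)
as_pred <- function(df, target_id = "T") {
  df$sep <- df$j - df$i
  df$range <- ifelse(df$sep >= 24, "long", ifelse(df$sep >= 12, "medium", "short"))
  if (is.null(df$score)) df$score <- seq(1, 0.5, length.out = nrow(df))
  contactensemble:::new_contact_prediction(
    tibble::as_tibble(df[c("i", "j", "sep", "range", "score")]),
    target_id = target_id
  )
}

# hand-written 3-residue PDB exercising the CB / glycine-CA rule
write_tiny_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB  ALA A   1       1.500   1.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  GLY A   2       4.800   0.000   0.000  1.00  0.00           C",
    "ATOM      5  CA  ALA A   3       8.600   0.000   0.000  1.00  0.00           C",
    "ATOM      6  CB  ALA A   3       9.100   1.000   0.000  1.00  0.00           C",
    "TER",
    "END"
  ), path)
  path
}
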