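# Run `code` with a private RNG state seeded by `seed`, restoring the
# caller's state afterwards. Keeps generator determinism independent of the
# surrounding session.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

helix_points <- function(n, origin, direction = 1, phase = 0) {
  # idealized C-alpha-like helix trace: rise 1.5 A/residue, radius 2.3 A,
  # 100 degrees per residue; consecutive points ~3.8 A apart
  t <- seq_len(n) - 1
  theta <- phase + direction * t * 100 * pi / 180
  cbind(
    origin[1] + 2.3 * cos(theta),
    origin[2] + 2.3 * sin(theta),
    origin[3] + direction * t * 1.5
  )
}

#' Generate a reference structure with known contacts
#'
#' Builds a deterministic synthetic single-chain structure whose
#' representative-atom trace has consecutive atoms ~3.8 Angstrom apart.
#' `"helix_bundle"` packs several antiparallel helices side by side
#' (about 9 Angstrom between axes) joined by short loops, guaranteeing
#' inter-helix medium and long range contacts -- a desk-scale stand-in for
#' the helical-bundle topologies on which ensemble methods are typically
#' exercised. `"random_coil"` grows a clash-avoiding random walk with
#' 3.8 Angstrom steps.
#'
#' Every 7th residue is a glycine so the C-alpha representative-atom rule is
#' exercised by files written from these models.
#'
#' @param n_res Number of residues, at least 25 (so pairs with separation
#'   >= 24 exist).
#' @param motif `"helix_bundle"` (default) or `"random_coil"`.
#' @param seed Integer seed; the same seed always yields identical
#'   coordinates.
#' @return A [structure_model()] with `model_id = "reference"`.
#' @examples
#' ref <- make_reference(60, seed = 7)
#' sum(extract_contacts(ref)$range == "long") > 0
#' @export
make_reference <- function(n_res, motif = c("helix_bundle", "random_coil"), seed = 1L) {
  motif <- match.arg(motif)
  if (n_res < 25) stop("n_res must be >= 25 so long range pairs exist", call. = FALSE)
  coords <- with_seed(seed, {
    if (motif == "helix_bundle") {
      n_helices <- max(2L, as.integer(round(n_res / 30)))
      loop_len <- 3L
      per <- (n_res - loop_len * (n_helices - 1L)) %/% n_helices
      extra <- (n_res - loop_len * (n_helices - 1L)) %% n_helices
      loop_span <- (loop_len + 1) * 3.6 # total junction path length
      pts <- NULL
      for (h in seq_len(n_helices)) {
        len <- per + as.integer(h <= extra)
        dir <- if (h %% 2 == 1) 1 else -1
        x0 <- (h - 1) * 9.0
        phase <- (h - 1) * pi / 3
        if (is.null(pts)) {
          z0 <- 0
        } else {
          # start the next helix so the junction is exactly loop_span long:
          # steps of ~3.6 A for the loop_len interpolated loop residues
          a <- pts[nrow(pts), ]
          sx <- x0 + 2.3 * cos(phase)
          sy <- 2.3 * sin(phase)
          dxy2 <- (sx - a[1])^2 + (sy - a[2])^2
          dz <- sqrt(max(3.8^2, loop_span^2 - dxy2))
          z0 <- if (dir == -1) a[3] + dz else a[3] - dz
        }
        hp <- helix_points(len, c(x0, 0, z0), direction = dir, phase = phase)
        if (!is.null(pts)) {
          a <- pts[nrow(pts), ]
          b <- hp[1, ]
          for (s in seq_len(loop_len)) {
            pts <- rbind(pts, a + (s / (loop_len + 1)) * (b - a))
          }
        }
        pts <- rbind(pts, hp)
      }
      pts
    } else {
      pts <- matrix(0, nrow = n_res, ncol = 3)
      for (k in 2:n_res) {
        for (try in 1:200) {
          u <- stats::rnorm(3)
          u <- u / sqrt(sum(u^2))
          cand <- pts[k - 1, ] + 3.8 * u
          dmin <- if (k > 2) {
            min(sqrt(rowSums(sweep(pts[1:(k - 2), , drop = FALSE], 2, cand)^2)))
          } else {
            Inf
          }
          if (dmin > 3.0) break
        }
        pts[k, ] <- cand
      }
      pts
    }
  })
  structure_model(
    tibble::tibble(
      index = seq_len(nrow(coords)),
      aa = ifelse(seq_len(nrow(coords)) %% 7 == 0, "GLY", "ALA"),
      x = coords[, 1], y = coords[, 2], z = coords[, 3]
    ),
    model_id = "reference"
  )
}

#' Generate a synthetic model ensemble with known ground truth
#'
#' Emulates a pool of server-predicted models for one target: each model is
#' the reference plus i.i.d. Gaussian coordinate noise, and a fraction of
#' "corrupted" models additionally rigid-shift a contiguous C-terminal
#' segment far away -- destroying that segment's long range contacts, the
#' way badly assembled models misplace whole helical bundles. The ground
#' truth is the reference's own contact map, and each model's quality score
#' is the fraction of true contacts it preserves (a contact-level stand-in
#' for GDT-TS, on `[0, 1]`).
#'
#' @param ref Reference [structure_model()] (see [make_reference()]).
#' @param n_models Number of models, default 50.
#' @param noise_sigma Gaussian noise s.d. per coordinate in Angstrom,
#'   default 1. Every model receives the same sigma unless `noise_range`
#'   is given.
#' @param noise_range Optional length-2 numeric `c(lo, hi)`: each model
#'   draws its own noise s.d. uniformly from this range, emulating a pool
#'   whose members span a spectrum of quality (as real server pools do).
#'   Overrides `noise_sigma`.
#' @param corrupt_fraction Fraction of models with a displaced segment,
#'   default 0.2.
#' @param corrupt_shift Rigid displacement of the corrupted segment in
#'   Angstrom, default 15.
#' @param seed Integer seed driving all randomness.
#' @param params A [contact_params()].
#' @return List with elements `models` (named list of `structure_model`s,
#'   ids `model_001` ...), `truth` (the reference `contact_map`), `quality`
#'   (tibble `model_id`, `score`) and `corrupted` (character vector of
#'   corrupted model ids).
#' @export
make_ensemble <- function(ref, n_models = 50L, noise_sigma = 1.0,
                          noise_range = NULL,
                          corrupt_fraction = 0.2, corrupt_shift = 15.0,
                          seed = 1L, params = contact_params()) {
  stopifnot(inherits(ref, "structure_model"), n_models >= 1)
  stopifnot(corrupt_fraction >= 0, corrupt_fraction <= 1)
  if (!is.null(noise_range)) stopifnot(length(noise_range) == 2, noise_range[1] <= noise_range[2])
  truth <- extract_contacts(ref, params)
  n_res <- nrow(ref)
  seg <- seq.int(max(1L, floor(0.65 * n_res)), n_res) # displaced segment
  with_seed(seed, {
    n_bad <- round(corrupt_fraction * n_models)
    bad <- sort(sample.int(n_models, n_bad))
    sigmas <- if (is.null(noise_range)) {
      rep(noise_sigma, n_models)
    } else {
      stats::runif(n_models, noise_range[1], noise_range[2])
    }
    models <- vector("list", n_models)
    ids <- sprintf("model_%03d", seq_len(n_models))
    for (m in seq_len(n_models)) {
      xyz <- as.matrix(ref[c("x", "y", "z")]) +
        matrix(stats::rnorm(3 * n_res, sd = sigmas[m]), ncol = 3)
      if (m %in% bad) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        xyz[seg, ] <- sweep(xyz[seg, , drop = FALSE], 2, corrupt_shift * u, "+")
      }
      models[[m]] <- structure_model(
        tibble::tibble(
          index = ref$index, aa = ref$aa,
          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
        ),
        model_id = ids[m]
      )
    }
    names(models) <- ids
    truth_key <- paste(truth$i, truth$j)
    quality <- tibble::tibble(
      model_id = ids,
      score = vapply(models, function(mod) {
        cm <- extract_contacts(mod, params)
        mean(truth_key %in% paste(cm$i, cm$j))
      }, numeric(1))
    )
    list(
      models = models, truth = truth, quality = quality,
      corrupted = ids[bad]
    )
  })
}

#' Write a synthetic ensemble to disk
#'
#' Writes one PDB file per model into `dir/models/`, and the ground-truth
#' contacts (`truth.rr`) plus the quality table (`quality.tsv`) into `dir`.
#' Keeping the models in their own subdirectory lets directory-level tools
#' (`predict`, `rank`, `clusters`) consume the model pool without also
#' sweeping up reference or native structures stored alongside.
#'
#' @param ens Result of [make_ensemble()].
#' @param dir Output directory (created if needed).
#' @param target_id Target id for the truth RR header.
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ens, dir, target_id = "SYNTH") {
  dir.create(file.path(dir, "models"), showWarnings = FALSE, recursive = TRUE)
  for (id in names(ens$models)) {
    write_model(ens$models[[id]], file.path(dir, "models", paste0(id, ".pdb")))
  }
  truth <- ens$truth[order(ens$truth$i, ens$truth$j), ]
  pl <- new_contact_prediction(
    tibble::tibble(
      i = truth$i, j = truth$j, sep = truth$sep,
      range = truth$range, score = 1
    ),
    target_id = target_id
  )
  write_rr(pl, file.path(dir, "truth.rr"))
  write_quality_table(ens$quality, file.path(dir, "quality.tsv"))
  invisible(dir)
}

#' Contact maps planting cluster subsets across models
#'
#' Builds an ensemble of contact maps in which every model carries a random
#' *strict* subset of a set of planted contact clusters (at least one
#' cluster, never all). This reproduces the regime where each model
#' realizes only part of the true interaction pattern, so no single model
#' covers every cluster although every cluster is well represented across
#' the ensemble.
#'
#' @param n_models Number of maps.
#' @param clusters List of tibbles with columns `i`, `j`: the planted
#'   clusters.
#' @param seed Integer seed.
#' @param params A [contact_params()].
#' @return List with `maps` (list of `contact_map`) and `membership`
#'   (logical matrix, models x clusters).
#' @export
make_cluster_subset_maps <- function(n_models, clusters, seed = 1L,
                                     params = contact_params()) {
  k <- length(clusters)
  stopifnot(k >= 2, n_models >= 1)
  with_seed(seed, {
    memb <- matrix(FALSE, n_models, k)
    for (m in seq_len(n_models)) {
      n_take <- sample.int(k - 1L, 1L) # strict, non-empty subset
      memb[m, sample.int(k, n_take)] <- TRUE
    }
    maps <- lapply(seq_len(n_models), function(m) {
      rows <- dplyr::bind_rows(clusters[memb[m, ]])
      rows$sep <- rows$j - rows$i
      rows$range <- range_of_sep(rows$sep, params)
      new_contact_map(rows, source_id = sprintf("model_%03d", m))
    })
    list(maps = maps, membership = memb)
  })
}
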