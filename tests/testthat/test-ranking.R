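mk_map <- function(df, id = "m") {
  df$sep <- df$j - df$i
  df$range <- ifelse(df$sep >= 24, "long", ifelse(df$sep >= 12, "medium", "short"))
  attr(df, "source_id") <- id
  class(df) <- c("contact_map", class(df))
  df
}

test_that("satisfaction scores bound, decompose and hit the extremes", {
  med <- as_pred(tibble::tibble(i = c(5L, 10L), j = c(20L, 25L), score = c(1, 1)))
  lng <- as_pred(tibble::tibble(i = c(5L, 10L), j = c(40L, 60L), score = c(1, 1)))

  # model containing every predicted contact exactly: total 4
  full <- mk_map(tibble::tibble(i = c(5L, 10L, 5L, 10L), j = c(20L, 25L, 40L, 60L)))
  s <- satisfaction_score(full, med, lng)
  expect_equal(s$total, 4.0)

  # model sharing nothing within distance 1 of any prediction: total 0
  none <- mk_map(tibble::tibble(i = c(70L, 75L), j = c(90L, 99L)))
  expect_equal(satisfaction_score(none, med, lng)$total, 0.0)

  # delta-1 terms dominate the exact terms
  set.seed(83)
  for (rep in 1:20) {
    mm <- random_map(60, sample(5:25, 1))
    s <- satisfaction_score(
      mm,
      as_pred(tibble::tibble(
        i = 1:5, j = (1:5) + 15L,
        score = seq(1, 0.9, length.out = 5)
      )),
      as_pred(tibble::tibble(
        i = 1:5, j = (1:5) + 40L,
        score = seq(1, 0.9, length.out = 5)
      ))
    )
    expect_gte(s$med_d1, s$med_exact)
    expect_gte(s$long_d1, s$long_exact)
    expect_true(all(unlist(s[c("med_exact", "med_d1", "long_exact", "long_d1")]) >= 0))
    expect_true(all(unlist(s[c("med_exact", "med_d1", "long_exact", "long_d1")]) <= 1))
    expect_equal(s$total, s$med_exact + s$med_d1 + s$long_exact + s$long_d1)
  }
})

test_that("satisfaction fractions equal a brute-force per-prediction scan", {
  set.seed(89)
  for (rep in 1:15) {
    mm <- random_map(70, sample(10:40, 1))
    med_tbl <- random_map(70, 8)
    lng_tbl <- random_map(70, 8)
    med <- as_pred(tibble::tibble(
      i = med_tbl$i, j = med_tbl$j, score = seq(1, 0.9, length.out = nrow(med_tbl))
    ))
    lng <- as_pred(tibble::tibble(
      i = lng_tbl$i, j = lng_tbl$j, score = seq(1, 0.9, length.out = nrow(lng_tbl))
    ))
    s <- satisfaction_score(mm, med, lng)
    expect_equal(s$med_exact, sum(oracle_match(med, mm, 0)) / nrow(med))
    expect_equal(s$med_d1, sum(oracle_match(med, mm, 1)) / nrow(med))
    expect_equal(s$long_exact, sum(oracle_match(lng, mm, 0)) / nrow(lng))
    expect_equal(s$long_d1, sum(oracle_match(lng, mm, 1)) / nrow(lng))
  }
})

test_that("models rank by total descending with id-ascending ties", {
  med <- as_pred(tibble::tibble(i = c(5L, 10L), j = c(20L, 25L), score = c(1, 1)))
  lng <- as_pred(tibble::tibble(i = c(5L, 10L), j = c(40L, 60L), score = c(1, 1)))
  full <- tibble::tibble(i = c(5L, 10L, 5L, 10L), j = c(20L, 25L, 40L, 60L))
  part <- tibble::tibble(i = c(5L, 5L), j = c(20L, 40L))
  models <- list(
    zz_full = mk_map(full, "zz_full"),
    aa_part = mk_map(part, "aa_part"),
    bb_full = mk_map(full, "bb_full")
  )
  rk <- rank_models(models, med, lng)
  # two models tie at 4.0: id ascending breaks the tie
  expect_equal(rk$model_id, c("bb_full", "zz_full", "aa_part"))
  expect_equal(rk$rank, 1:3)
  expect_error(rank_models(list(), med, lng), "empty")
})

test_that("selection loss is best-minus-selected and zero for a perfect pick", {
  qt <- tibble::tibble(model_id = c("a", "b"), score = c(0.50, 0.43))
  expect_equal(selection_loss(c("a", "b"), qt), 0.0)
  expect_equal(selection_loss(c("b", "a"), qt), 0.07)
  expect_error(selection_loss(c("zz"), qt), "missing")

  set.seed(97)
  for (rep in 1:20) {
    n <- sample(3:30, 1)
    q <- tibble::tibble(model_id = sprintf("m%02d", 1:n), score = runif(n))
    pick <- sample(q$model_id)
    expect_equal(selection_loss(pick, q), max(q$score) - q$score[q$model_id == pick[1]])
  }
})

test_that("random baseline loss uses the middlemost (lower-median) model", {
  expect_equal(
    random_baseline_loss(tibble::tibble(model_id = c("a", "b", "c"), score = c(0.9, 0.5, 0.1))),
    0.4
  )
  expect_equal(random_baseline_loss(tibble::tibble(model_id = "a", score = 0.7)), 0.0)
  # even count: lower median (the worse of the two middle scores)
  expect_equal(
    random_baseline_loss(tibble::tibble(
      model_id = c("a", "b", "c", "d"),
      score = c(0.8, 0.6, 0.4, 0.2)
    )),
    0.8 - 0.4
  )
})

test_that("consensus prediction sets split by range and respect min_count", {
  entries <- tibble::tibble(
    i = c(1L, 2L, 3L, 4L), j = c(16L, 17L, 30L, 31L),
    sep = c(15L, 15L, 27L, 27L),
    range = c("medium", "medium", "long", "long"),
    count = c(5L, 1L, 5L, 1L), freq = c(1, 0.2, 1, 0.2)
  )
  entries <- entries[order(-entries$freq, entries$i), ]
  attr(entries, "n_models") <- 5
  class(entries) <- c("contact_consensus", class(entries))
  sets <- consensus_prediction_sets(entries, parse_domain("1-40"), min_count = 2)
  expect_equal(pair_key(sets$medium), "1 16") # the singleton is dropped
  expect_equal(pair_key(sets$long), "3 30")
  sets_all <- consensus_prediction_sets(entries, parse_domain("1-40"), min_count = 1)
  expect_equal(nrow(sets_all$medium), 2)
  expect_equal(nrow(sets_all$long), 2)
})
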