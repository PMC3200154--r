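test_that("consensus frequencies are counts over the number of models", {
  one <- tibble::tibble(i = 5L, j = 30L, sep = 25L, range = "long")
  both <- tibble::tibble(
    i = c(5L, 7L), j = c(30L, 20L), sep = c(25L, 13L),
    range = c("long", "medium")
  )
  mk <- function(df, id) {
    attr(df, "source_id") <- id
    class(df) <- c("contact_map", class(df))
    df
  }
  cl1 <- build_consensus(list(mk(both, "a")))
  expect_true(all(cl1$freq == 1.0)) # single model: everything at 1

  maps <- list(mk(both, "a"), mk(one, "b"), mk(one, "c"), mk(both[2, ], "d"))
  cl <- build_consensus(maps)
  expect_equal(attr(cl, "n_models"), 4)
  expect_equal(cl$freq[cl$i == 5 & cl$j == 30], 3 / 4)
  expect_equal(cl$freq[cl$i == 7 & cl$j == 20], 2 / 4)
  expect_equal(cl$freq, cl$count / 4)
  expect_error(build_consensus(list()), "empty")
})

test_that("consensus counts equal an independent dictionary tally on 50 maps", {
  set.seed(41)
  maps <- lapply(1:50, function(k) random_map(60, sample(5:30, 1), id = paste0("m", k)))
  cl <- build_consensus(maps)
  want <- oracle_tally(maps)
  merged <- merge(as.data.frame(cl[c("i", "j", "count")]), want,
    by = c("i", "j"), all = TRUE
  )
  expect_false(anyNA(merged$count.x))
  expect_false(anyNA(merged$count.y))
  expect_equal(merged$count.x, merged$count.y)
  # sorted by freq desc, ties (i, j) ascending lexicographic
  expect_true(all(diff(cl$freq) <= 0))
  key <- cl$i * 1000 + cl$j
  same <- which(diff(cl$freq) == 0)
  expect_true(all(key[same] < key[same + 1]))
  expect_true(all(cl$freq > 0 & cl$freq <= 1))
  expect_equal(max(cl$freq), max(cl$count) / attr(cl, "n_models"))
})

test_that("adding a disjoint map does not reorder existing entries", {
  set.seed(43)
  maps <- lapply(1:10, function(k) random_map(40, 10, id = paste0("m", k)))
  cl0 <- build_consensus(maps)
  extra <- tibble::tibble(i = 90L, j = 130L, sep = 40L, range = "long")
  class(extra) <- c("contact_map", class(extra))
  cl1 <- build_consensus(c(maps, list(extra)))
  keep <- pair_key(cl1) %in% pair_key(cl0)
  expect_equal(pair_key(cl1)[keep], pair_key(cl0))
})

test_that("domain and range filtering keeps both-endpoints-inside entries", {
  rows <- tibble::tibble(
    i = c(10L, 40L, 40L, 35L), j = c(50L, 70L, 300L, 40L),
    sep = c(40L, 30L, 260L, 5L),
    range = c("long", "long", "long", "short"),
    count = 1L, freq = 1
  )
  cl <- rows
  attr(cl, "n_models") <- 1
  class(cl) <- c("contact_consensus", class(cl))

  d1 <- parse_domain("31-80")
  f1 <- filter_to_domain(cl, d1, ranges = c("medium", "long"))
  expect_equal(pair_key(f1), "40 70") # (10,50) outside, (40,300) outside, sep-5 removed

  d2 <- parse_domain("31-80,257-384")
  f2 <- filter_to_domain(cl, d2, ranges = c("medium", "long"))
  expect_setequal(pair_key(f2), c("40 70", "40 300")) # one endpoint per segment is fine
})

test_that("top-L/5 truncation floors with a minimum of one", {
  entries <- tibble::tibble(
    i = 1:40, j = (1:40) + 30L, sep = 30L, range = "long",
    count = 40:1, freq = (40:1) / 40
  )
  attr(entries, "n_models") <- 40
  class(entries) <- c("contact_consensus", class(entries))

  expect_equal(nrow(select_top(entries, L = 100, fraction = 1 / 5)), 20)
  expect_equal(nrow(select_top(entries, L = 178, fraction = 1 / 5)), 35) # floor(178/5)
  expect_equal(nrow(select_top(entries, L = 3, fraction = 1 / 5)), 1) # max(1, .)
  expect_message(
    short <- select_top(entries, L = 400, fraction = 1 / 5),
    "only"
  )
  expect_equal(nrow(short), 40)
  p <- select_top(entries, L = 100, fraction = 1 / 5)
  expect_s3_class(p, "contact_prediction")
  expect_true(all(diff(p$score) <= 0))
})

test_that("quality filters implement remove-below, remove-top-k and keep-top-k", {
  qt <- tibble::tibble(model_id = c("a", "b", "c"), score = c(25, 35, 40))
  ens <- list(a = random_map(30, 3, "a"), b = random_map(30, 3, "b"), c = random_map(30, 3, "c"))
  expect_equal(names(filter_ensemble(ens, qt, "remove_below", 30)), c("b", "c"))
  expect_equal(names(filter_ensemble(ens, qt, "remove_top_k", 1)), c("a", "b"))
  expect_equal(names(filter_ensemble(ens, qt, "keep_top_k", 2)), c("b", "c"))
  expect_error(filter_ensemble(ens, qt, "remove_below", 99), "every model")

  # 301-model pool: removing the top 20 leaves 281
  set.seed(3)
  big_qt <- tibble::tibble(
    model_id = sprintf("m%03d", 1:301),
    score = runif(301, 0, 100)
  )
  big <- setNames(
    lapply(big_qt$model_id, function(id) random_map(30, 2, id)),
    big_qt$model_id
  )
  expect_length(filter_ensemble(big, big_qt, "remove_top_k", 20), 281)

  # ties at the cut break by model id ascending
  tie_qt <- tibble::tibble(model_id = c("a", "b", "c"), score = c(50, 50, 10))
  expect_equal(
    names(filter_ensemble(ens, tie_qt, "keep_top_k", 1)),
    "a"
  )
  expect_warning(kept <- filter_ensemble(ens, tie_qt, "keep_top_k", 10), "keeping all")
  expect_length(kept, 3)
  # members without a score are dropped with a warning
  expect_warning(
    res <- filter_ensemble(ens, qt[1:2, ], "remove_below", 0),
    "without a quality score"
  )
  expect_equal(names(res), c("a", "b"))
})

test_that("RR serialization is exact, stable and round-trips", {
  pl <- as_pred(tibble::tibble(i = 16L, j = 53L, score = 0.82))
  f <- withr::local_tempfile(fileext = ".rr")
  write_rr(pl, f)
  expect_equal(
    readLines(f),
    c("PFRMAT RR", "TARGET T", "MODEL 1", "16 53 0 8 0.820000", "END")
  )

  # byte-identical output on identical input
  f2 <- withr::local_tempfile(fileext = ".rr")
  write_rr(pl, f2)
  expect_identical(readLines(f), readLines(f2))

  # empty list: header + END only
  empty <- as_pred(tibble::tibble(i = integer(0), j = integer(0), score = numeric(0)))
  fe <- withr::local_tempfile(fileext = ".rr")
  write_rr(empty, fe)
  expect_equal(readLines(fe), c("PFRMAT RR", "TARGET T", "MODEL 1", "END"))

  # round trip on 100 random entries preserves (i, j, score) triples
  set.seed(59)
  pairs <- unique(t(replicate(300, sort(sample.int(150, 2)))))[1:100, ]
  big <- as_pred(tibble::tibble(
    i = as.integer(pairs[, 1]), j = as.integer(pairs[, 2]),
    score = round(sort(runif(100), decreasing = TRUE), 6)
  ))
  fb <- withr::local_tempfile(fileext = ".rr")
  write_rr(big, fb)
  back <- read_rr(fb)
  ord <- function(d) d[order(d$i, d$j), c("i", "j", "score")]
  expect_equal(ord(as.data.frame(back)), ord(as.data.frame(big)), ignore_attr = TRUE)
})

test_that("the RR reader tolerates sequence blocks and rejects malformed lines", {
  f <- withr::local_tempfile(fileext = ".rr")
  writeLines(c(
    "PFRMAT RR", "TARGET T0618", "AUTHOR x", "MODEL 1",
    "MVLSEGEWQLVLHVWAKVEA", "DVAGHGQDILIRLFKSH",
    "  16   53   0   8   0.900000", "5 40 0 8 0.500000", "END"
  ), f)
  pl <- read_rr(f)
  expect_equal(attr(pl, "target_id"), "T0618")
  expect_equal(pl$i, c(16L, 5L))
  expect_equal(pl$score, c(0.9, 0.5))

  g <- withr::local_tempfile(fileext = ".rr")
  writeLines(c("PFRMAT RR", "MODEL 1", "16 53 0 eight 0.9", "END"), g)
  expect_error(read_rr(g), "malformed RR line")
  h <- withr::local_tempfile(fileext = ".rr")
  writeLines(c("PFRMAT RR", "MODEL 1", "16 16 0 8 0.9", "END"), h)
  expect_error(read_rr(h), "i == j")
})

test_that("quality tables read back what was written", {
  qt <- tibble::tibble(model_id = c("m1", "m2"), score = c(0.5, 0.25))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_quality_table(qt, f)
  back <- read_quality_table(f)
  expect_equal(back$model_id, qt$model_id)
  expect_equal(back$score, qt$score)
})
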