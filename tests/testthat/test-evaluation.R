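test_that("stratified split produces 81/9/10 with exact class balance", {
  labels <- rep(c(0L, 1L), each = 500)
  s <- stratified_split(labels, seed = 1)
  expect_equal(length(s$train), 810)
  expect_equal(length(s$validation), 90)
  expect_equal(length(s$test), 100)
  for (part in s) {
    expect_equal(sum(labels[part] == 0), length(part) / 2)
  }
  expect_equal(sort(c(s$train, s$validation, s$test)), seq_along(labels))
  expect_identical(stratified_split(labels, seed = 1), s)
  expect_false(identical(stratified_split(labels, seed = 2), s))
  expect_error(stratified_split(c(rep(0, 100), rep(1, 3))), "too small")
})

test_that("confusion counts enumerate the 2x2 table", {
  cc <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unclass(cc), list(TP = 1L, TN = 1L, FP = 1L, FN = 1L),
               ignore_attr = TRUE)
  same <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(same$FP + same$FN, 0L)
  allpos <- confusion(c(1, 0), c(1, 1))
  expect_equal(unclass(allpos), list(TP = 1L, TN = 0L, FP = 1L, FN = 0L),
               ignore_attr = TRUE)
  expect_error(confusion(c(1, 0), c(1)), "length")
  expect_error(confusion(c(1, 2), c(1, 0)), "0 or 1")
})

test_that("metric formulas reproduce the worked example and edge rules", {
  m <- compute_metrics(list(TP = 4, TN = 3, FP = 1, FN = 2))
  expect_equal(m$Acc, 0.70)
  expect_equal(m$Sn, 2 / 3, tolerance = 1e-12)
  expect_equal(m$Sp, 0.75)
  expect_equal(m$MCC, 10 / sqrt(600), tolerance = 1e-12)  # ~0.4082
  perfect <- compute_metrics(list(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_equal(unlist(perfect[, c("Acc", "Sn", "Sp", "MCC")]),
               c(Acc = 1, Sn = 1, Sp = 1, MCC = 1))
  # everything misclassified: all four denominator factors are 1, MCC = -1
  flipped <- compute_metrics(list(TP = 0, TN = 0, FP = 1, FN = 1))
  expect_equal(flipped$MCC, -1)
  # all predicted negative: TP+FP = 0 zeroes the denominator, MCC = 0 by rule
  degen <- compute_metrics(list(TP = 0, TN = 1, FP = 0, FN = 1))
  expect_equal(degen$MCC, 0)
  nosn <- compute_metrics(list(TP = 0, TN = 5, FP = 0, FN = 0))
  expect_true(is.na(nosn$Sn))  # undefined, reported missing rather than 0
  expect_error(compute_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)), "no samples")
})

test_that("metrics agree with a brute-force recount on random label pairs", {
  withr::with_seed(99, {
    for (i in 1:1000) {
      n <- sample(2:40, 1)
      yt <- rbinom(n, 1, 0.5)
      yp <- rbinom(n, 1, runif(1, 0.2, 0.8))
      got <- compute_metrics(confusion(yt, yp))
      want <- brute_metrics(yt, yp)
      expect_equal(unlist(got[, c("Acc", "Sn", "Sp", "MCC")]),
                   want, tolerance = 1e-12)
    }
  })
})

test_that("MCC is symmetric under simultaneous class swap", {
  withr::with_seed(7, {
    for (i in 1:50) {
      yt <- rbinom(30, 1, 0.5)
      yp <- rbinom(30, 1, 0.5)
      a <- compute_metrics(confusion(yt, yp))$MCC
      b <- compute_metrics(confusion(1 - yt, 1 - yp))$MCC
      expect_equal(a, b, tolerance = 1e-12)
    }
  })
})

test_that("multiclass metrics: hand case, perfection and chance behaviour", {
  perf <- multiclass_metrics(c(0, 1, 2), c(0, 1, 2), 3)
  expect_equal(unlist(perf), c(Acc = 1, Sn = 1, Sp = 1, MCC = 1))
  m <- multiclass_metrics(c(0L, 1L, 2L), c(0L, 1L, 1L), 3)
  expect_equal(m$Acc, 2 / 3, tolerance = 1e-12)
  expect_equal(m$Sn, 2 / 3, tolerance = 1e-12)  # per-class recalls 1, 1, 0
  expect_error(multiclass_metrics(c(0, 3), c(0, 1), 3), "labels must be")
  # uniform random predictions on balanced classes give MCC ~ 0
  withr::with_seed(123, {
    yt <- rep(0:2, length.out = 10000)
    yp <- sample(0:2, 10000, replace = TRUE)
    expect_lt(abs(multiclass_metrics(yt, yp, 3)$MCC), 0.03)
  })
})

test_that("binary experiment rows are complete, valid and RF-reproducible", {
  ds <- toy_binary_dataset(n = 100, length = 60, seed = 73)
  row <- run_binary_experiment(ds, model = "rf", encoder = "fbt", k = 1,
                               seed = 3)
  expect_s3_class(row, "promoter_results")
  expect_equal(row$experiment, "binary")
  expect_true(all(unlist(row[, c("Acc", "Sn", "Sp")]) >= 0 &
                  unlist(row[, c("Acc", "Sn", "Sp")]) <= 1))
  expect_true(row$MCC >= -1 && row$MCC <= 1)
  expect_equal(row$n_train, 162)
  expect_equal(row$n_test, 20)
  row2 <- run_binary_experiment(ds, model = "rf", encoder = "fbt", k = 1,
                                seed = 3)
  keep <- setdiff(names(row), "wall_time")
  expect_identical(as.data.frame(row)[, keep], as.data.frame(row2)[, keep])
  expect_error(run_binary_experiment(ds[ds$label == 1, ], model = "rf"),
               "binary labels")
  p <- autoplot(row)
  expect_s3_class(p, "ggplot")
})

test_that("experiment splits never leak records across parts", {
  ds <- toy_binary_dataset(n = 100, length = 60, seed = 83)
  row <- run_binary_experiment(ds, model = "rf", encoder = "fbt", k = 1,
                               seed = 9)
  s <- attr(row, "split")
  expect_length(intersect(s$train, s$test), 0)
  expect_length(intersect(s$train, s$validation), 0)
  expect_length(intersect(s$validation, s$test), 0)
  expect_setequal(c(s$train, s$validation, s$test), seq_len(nrow(ds)))
})

test_that("cross-species runner validates inputs and covers ordered pairs", {
  a <- toy_binary_dataset(n = 60, length = 40, seed = 93)
  expect_error(run_cross_species(list(a = a), model = "rf"), ">= 2")
  expect_error(run_cross_species(list(a, a), model = "rf"), "named")
  b <- a; b$bases <- paste0(b$bases, "A")
  expect_error(run_cross_species(list(a = a, b = b), model = "rf"),
               "one sequence length")
  pfb <- species_profile("toyb", 40,
                         motifs = list(list(pattern = "GGCGCGCC", offset = 5,
                                            mutation_rate = 0.1)),
                         background_gc = 0.5)
  a2 <- toy_binary_dataset(n = 60, length = 40, seed = 94)
  b2 <- build_binary_dataset(generate_promoters(pfb, 60, seed = 95), seed = 96)
  cs <- run_cross_species(list(a = a2, b = b2), model = "rf", k = 1, seed = 4)
  expect_equal(nrow(cs), 4)  # 2 within + 2 ordered cross pairs
  expect_equal(sum(cs$setting == "cross"), 2)
  expect_true(all(cs$species_train[cs$setting == "cross"] !=
                  cs$species_test[cs$setting == "cross"]))
  expect_s3_class(autoplot(cs), "ggplot")
})

test_that("random-negative test validates its preconditions", {
  ds <- toy_binary_dataset(n = 60, length = 40, seed = 103)
  row <- run_binary_experiment(ds, model = "rf", encoder = "fbt", k = 1,
                               seed = 5)
  m <- attr(row, "model")
  prom <- ds[ds$label == 1, ][1:10, ]
  expect_error(run_random_negative_test(m, prom, prom[0, ]), "empty background")
  short_bg <- seq_records("x", "ACGTACGT")
  expect_error(run_random_negative_test(m, prom, short_bg), "length")
  bg <- seq_records(paste0("bg", 1:20), random_acgt(20, 40, seed = 6))
  rn <- run_random_negative_test(m, prom, bg)
  expect_equal(rn$experiment, "random_negative")
  expect_equal(rn$n_test, 30)
  expect_true(rn$Acc >= 0 && rn$Acc <= 1)
})

test_that("multiclass runner pools corpora with species-index labels", {
  profs <- default_profiles(length = 100)
  corpora <- lapply(profs, function(p) generate_promoters(p, 60, seed = 113))
  row <- run_multiclass_experiment(corpora, model = "rf", encoder = "fbt",
                                   k = 1, seed = 6)
  expect_equal(row$experiment, "multiclass")
  expect_true(all(unlist(row[, c("Acc", "Sn", "Sp")]) >= 0 &
                  unlist(row[, c("Acc", "Sn", "Sp")]) <= 1))
  m <- attr(row, "model")
  expect_equal(m$n_classes, 3)
  expect_error(run_multiclass_experiment(corpora[1], model = "rf"), ">= 2")
})
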