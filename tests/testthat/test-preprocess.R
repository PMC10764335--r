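make_missing_table <- function() {
  # 100 patients, 3 indicators: a missing in 31, b missing in 30, c complete
  set.seed(10)
  vals <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  vals[1:31, 1] <- NA
  vals[1:30, 2] <- NA
  patient_table(vals, labels = rep(c(0, 1), 50),
                patient_ids = sprintf("P%03d", 1:100))
}

test_that("indicator filter drops strictly above the threshold", {
  filt <- filter_indicators(make_missing_table(), threshold = 0.30)
  expect_identical(filt$dropped, "a")               # 31% > 30%
  expect_identical(filt$table$indicator_names, c("b", "c"))  # 30% retained

  full <- toy_table(n = 10)
  filt2 <- filter_indicators(full, 0.30)
  expect_identical(filt2$table, full)
  expect_length(filt2$dropped, 0)

  allna <- patient_table(matrix(NA_real_, 10, 1, dimnames = list(NULL, "x")),
                         labels = rep(c(0, 1), 5),
                         patient_ids = letters[1:10])
  expect_error(filter_indicators(allna), "nothing to model")
})

test_that("reference imputation fills exactly the missing cells", {
  tab <- make_missing_table()
  ref <- c(a = 7.4, b = -1, c = 99)
  imp <- impute_reference(tab, ref)
  expect_true(all(imp$missing_mask))
  expect_true(all(imp$values[1:31, 1] == 7.4))
  expect_true(all(imp$values[1:30, 2] == -1))
  # observed cells untouched
  expect_identical(imp$values[32:100, 1], tab$values[32:100, 1])
  expect_identical(imp$values[, 3], tab$values[, 3])
  # missing reference -> configuration error
  expect_error(impute_reference(tab, c(a = 1, b = 2)), "no reference value")
  # fully observed table unchanged
  expect_identical(impute_reference(imp, ref), imp)
})

test_that("filter then impute is idempotent", {
  tab <- make_missing_table()
  ref <- c(a = 0, b = 0, c = 0)
  once <- impute_reference(filter_indicators(tab)$table, ref)
  twice <- impute_reference(filter_indicators(once)$table, ref)
  expect_identical(once, twice)
})

test_that("stratified split gives exact 7:3 allocation per class", {
  tab <- toy_table(n = 1000, labels = rep(c(1, 0, 0, 0, 0), 200), seed = 3)
  sp <- split_train_test(tab, split_ratio = 0.7, seed = 1)
  expect_length(sp$train$labels, 700)
  expect_length(sp$test$labels, 300)
  expect_identical(sum(sp$train$labels), 140L)
  expect_identical(sum(sp$test$labels), 60L)
  # disjoint ids whose union is the cohort
  expect_length(intersect(sp$train$patient_ids, sp$test$patient_ids), 0)
  expect_setequal(c(sp$train$patient_ids, sp$test$patient_ids),
                  tab$patient_ids)
  # deterministic under the seed
  sp2 <- split_train_test(tab, split_ratio = 0.7, seed = 1)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_train_test(tab, split_ratio = 0.7, seed = 2)))
})

test_that("standardization fitted on train yields mean 0 / sd 1 train columns", {
  tab <- toy_table(n = 300, seed = 8)
  sp <- split_train_test(tab, standardize = TRUE, seed = 2)
  expect_equal(unname(colMeans(sp$train$values)), rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(apply(sp$train$values, 2, sd)), rep(1, 3),
               tolerance = 1e-9)
  # test columns transformed with the train statistics, not refitted
  raw_test <- tab$values[match(sp$test$patient_ids, tab$patient_ids), ]
  rescaled <- sweep(sweep(raw_test, 2, sp$scaler_stats$center), 2,
                    sp$scaler_stats$scale, "/")
  expect_equal(unname(sp$test$values), unname(rescaled), tolerance = 1e-12)
})

test_that("split refuses unimputed tables and degenerate classes", {
  expect_error(split_train_test(make_missing_table()), "impute")
  tiny <- toy_table(n = 4, labels = c(1, 0, 0, 0))
  expect_error(split_train_test(tiny), "at least 2")
})

test_that("SMOTE balances classes and preserves the original rows", {
  set.seed(20)
  x <- matrix(rnorm(300), 150, 2)
  y <- c(rep(1, 50), rep(0, 100))
  out <- smote_oversample(x, y, k = 5, seed = 3)
  expect_identical(as.integer(table(out$y)), c(100L, 100L))
  expect_identical(out$x[1:150, ], x)
  expect_identical(out$y[1:150], as.integer(y))
  expect_identical(sum(out$synthetic), 50L)

  balanced <- smote_oversample(x[1:100, ], rep(c(0, 1), 50), seed = 3)
  expect_identical(balanced$x, x[1:100, ])
  expect_identical(balanced$n_synthetic, 0L)
})

test_that("every SMOTE synthetic point lies on a segment between minority rows", {
  set.seed(21)
  x <- matrix(rnorm(120), 60, 2)
  y <- c(rep(1, 20), rep(0, 40))
  out <- smote_oversample(x, y, k = 4, seed = 9)
  minority <- x[y == 1, , drop = FALSE]
  syn <- out$x[out$synthetic, , drop = FALSE]
  on_segment <- function(s) {
    for (i in seq_len(nrow(minority) - 1)) for (j in (i + 1):nrow(minority)) {
      a <- minority[i, ]; b <- minority[j, ]
      ab <- b - a
      denom <- sum(ab^2)
      if (denom == 0) next
      lam <- sum((s - a) * ab) / denom
      if (lam >= -1e-9 && lam <= 1 + 1e-9 &&
          sqrt(sum((s - (a + lam * ab))^2)) < 1e-8) return(TRUE)
    }
    FALSE
  }
  expect_true(all(apply(syn, 1, on_segment)))
})

test_that("SMOTE edge cases: single class errors, singleton minority duplicates", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(smote_oversample(x, rep(1, 10)), "both classes")
  y1 <- c(1, rep(0, 9))
  expect_warning(out <- smote_oversample(x, y1, seed = 1), "single member")
  expect_identical(as.integer(table(out$y)), c(9L, 9L))
  syn <- out$x[out$synthetic, , drop = FALSE]
  expect_true(all(apply(syn, 1, function(s) all(s == x[1, ]))))
})
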