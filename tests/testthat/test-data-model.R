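test_that("constructor enforces the binary-tensor invariants", {
  expect_error(classification_data(array(2L, dim = c(1, 2, 1))), "0 or 1")
  expect_error(classification_data(array(0L, dim = c(1, 1, 1))), "two raters")
  expect_error(classification_data(matrix(0, 2, 2)), "array")
  arr <- array(0L, dim = c(2, 2, 2)); arr[1, 1, 1] <- 1L
  expect_error(classification_data(arr, rated = matrix(c(0, 1, 1, 1), 2, 2)),
               "unrated pair")
  cd <- classification_data(arr)
  expect_s3_class(cd, "classification_data")
  expect_identical(dim(cd$rated), c(2L, 2L))
})

test_that("per-rater matrix lists build the same tensor as arrays", {
  arr <- random_tensor(4, 3, 2)
  lst <- lapply(1:3, function(j) arr[, j, ])
  a <- classification_data(arr)
  b <- classification_data(lst)
  expect_identical(unname(a$selections), unname(b$selections))
})

test_that("agreement table equals the brute-force triple-loop count", {
  set.seed(42)
  for (rep in 1:10) {
    arr <- random_tensor(3, 4, 2)
    tab <- agreement_table(classification_data(arr))
    expect_identical(unname(tab$counts), counts_bruteforce(arr))
  }
  zero <- agreement_table(classification_data(array(0L, dim = c(2, 3, 2))))
  expect_true(all(zero$counts == 0L))
})

test_that("long CSV reading round-trips, collapses duplicates, checks roster", {
  set.seed(7)
  arr <- random_tensor(5, 3, 4)
  rated <- matrix(rbinom(15, 1, 0.8), 5, 3)
  rated[rowSums(rated) == 0, 1] <- 1L  # keep every subject rated
  arr[rep(rated, 4) == 0] <- 0L
  cd <- classification_data(arr, rated = rated)
  f <- tempfile(fileext = ".csv"); r <- tempfile(fileext = ".csv")
  write_ratings_long(cd, f, roster = r)
  back <- read_ratings_long(f, roster = r,
                            subjects = cd$subjects, raters = cd$raters,
                            categories = cd$categories)
  expect_identical(back$selections, cd$selections)
  expect_identical(back$rated, cd$rated)

  # duplicates collapse with a warning, not an error
  lines <- readLines(f)
  writeLines(c(lines, lines[2]), f)
  expect_warning(
    dup <- read_ratings_long(f, roster = r, subjects = cd$subjects,
                             raters = cd$raters, categories = cd$categories),
    "duplicate")
  expect_identical(unname(dup$selections), unname(cd$selections))

  # a selection for a pair outside the roster is an error
  writeLines(c("subject,rater,category", "ghost,R1,C1"), f)
  expect_error(read_ratings_long(f, roster = r), "absent from the roster")

  # unknown columns are reported by name
  writeLines(c("subj,rater,category", "S1,R1,C1"), f)
  expect_error(read_ratings_long(f), "'subject'")
})

test_that("empty selection file with a roster yields an all-zero tensor", {
  f <- tempfile(fileext = ".csv"); r <- tempfile(fileext = ".csv")
  writeLines("subject,rater,category", f)
  writeLines(c("subject,rater", "S1,R1", "S1,R2"), r)
  cd <- read_ratings_long(f, roster = r)
  expect_identical(length(cd$subjects), 1L)
  expect_identical(length(cd$raters), 2L)
  expect_true(all(cd$selections == 0L))
})

test_that("wide format agrees with the long format", {
  b <- load_fixture("math_exam")
  f <- tempfile(fileext = ".csv")
  rows <- do.call(rbind, lapply(seq_along(b$data$subjects), function(i)
    do.call(rbind, lapply(seq_along(b$data$raters), function(j)
      data.frame(subject = b$data$subjects[i], rater = b$data$raters[j],
                 t(b$data$selections[i, j, ]), check.names = FALSE)))))
  names(rows)[3:7] <- b$data$categories
  utils::write.csv(rows, f, row.names = FALSE)
  wide <- read_ratings_wide(f)
  expect_identical(unname(wide$selections), unname(b$data$selections))
})

test_that("per-subject availability is the matching per-cell special case", {
  ji <- c(3L, 2L, 4L)
  a <- rater_availability(per_subject = ji)
  b <- rater_availability(per_cell = matrix(ji, 3, 5))
  expect_identical(availability_matrix(a, 3, 5), availability_matrix(b, 3, 5))
  X <- matrix(1L, 3, 5)
  ka <- multi_kappa(agreement_table(X, J = NA), availability = a)
  kb <- multi_kappa(agreement_table(X, J = NA), availability = b)
  expect_equal(ka$kappa, kb$kappa)
})

test_that("validation flags unused, always-selected and impossible counts", {
  ex1 <- load_fixture("table1_ex1")
  f1 <- validate_ratings(agreement_table(ex1$data))
  expect_setequal(f1$category[f1$code == "unused_category"], c("1", "2"))
  ex3 <- load_fixture("table1_ex3")
  f3 <- validate_ratings(agreement_table(ex3$data))
  expect_setequal(f3$category[f3$code == "always_selected"], c("1", "2"))
  bad <- agreement_table(matrix(5L, 1, 1), J = 4)
  fb <- validate_ratings(bad)
  expect_true(any(fb$severity == "error" & fb$code == "impossible_count"))
})
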