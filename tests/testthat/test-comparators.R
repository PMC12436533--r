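test_that("proportional overlap follows the set definition", {
  # {blue, yellow, brown} vs {blue, green}: 1 shared of 4 selected
  expect_equal(multikappa:::jaccard_overlap(c("blue", "yellow", "brown"),
                                            c("blue", "green")), 0.25)
  expect_equal(multikappa:::jaccard_overlap(1:3, 1:3), 1)
  expect_equal(multikappa:::jaccard_overlap(1:2, 3:4), 0)
  expect_equal(multikappa:::jaccard_overlap(1:2, 3:4),
               multikappa:::jaccard_overlap(3:4, 1:2))  # symmetric
})

test_that("overlap kappa excludes pairs with empty selection sets", {
  b <- load_fixture("math_exam")
  ov <- kappa_overlap(b$data)
  # student 2 has two empty ratings: all three of its pairs are undefined,
  # so the subject drops out of Po entirely
  expect_equal(ov$excluded$subjects, 1)
  expect_equal(ov$excluded$po_pairs, 3)
  expect_equal(ov$excluded$pe_pairs, 2 * 16 + 1)  # two empty units vs the rest
  near_printed(ov$kappa, 0.602)
})

test_that("overlap Pe matches a literal double loop on small data", {
  set.seed(3)
  arr <- random_tensor(3, 3, 4, p = 0.6)
  arr[1, 1, ] <- 1L  # ensure at least one non-empty
  cd <- classification_data(arr)
  ov <- kappa_overlap(cd)
  sets <- list()
  for (i in 1:3) for (j in 1:3) sets[[length(sets) + 1]] <- which(arr[i, j, ] == 1)
  vals <- c()
  for (a in 1:8) for (b in (a + 1):9) {
    if (length(sets[[a]]) == 0 || length(sets[[b]]) == 0) next
    vals <- c(vals, length(intersect(sets[[a]], sets[[b]])) /
                    length(union(sets[[a]], sets[[b]])))
  }
  expect_equal(ov$pe, mean(vals))
})

test_that("two mutually exclusive raters reduce overlap Po to percent agreement", {
  set.seed(8)
  arr <- array(0L, dim = c(10, 2, 4))
  for (i in 1:10) for (j in 1:2) arr[i, j, sample(4, 1)] <- 1L
  cd <- classification_data(arr)
  ov <- kappa_overlap(cd)
  agree <- mean(sapply(1:10, function(i)
    all(arr[i, 1, ] == arr[i, 2, ])))
  expect_equal(ov$po, agree)
})

test_that("pooled Cohen's kappa survives categories that void the average", {
  arr <- array(0L, dim = c(8, 2, 3))
  arr[1:5, , 1] <- 1L          # agreement on category 1
  arr[6, 1, 2] <- 1L           # lone disagreement on category 2
  cd <- classification_data(arr)          # category 3 unused by both raters
  ck <- kappa_cohen(cd)
  expect_true(is.nan(ck$per_category$kappa[3]))
  expect_true(is.nan(ck$averaged))
  expect_false(is.nan(ck$pooled$kappa))
  # oracle: pooled kappa from the three 2x2 tables by hand
  po <- pe <- numeric(3)
  for (c in 1:3) {
    a <- arr[, 1, c]; b <- arr[, 2, c]
    po[c] <- mean(a == b)
    pe[c] <- mean(a) * mean(b) + (1 - mean(a)) * (1 - mean(b))
  }
  expect_equal(ck$pooled$kappa, (mean(po) - mean(pe)) / (1 - mean(pe)))
  # perfect two-rater agreement pools to 1
  set.seed(44)
  one <- matrix(rbinom(18, 1, 0.5), 6, 3)
  one[1, 1] <- 1L  # avoid the fully empty degenerate draw
  parr <- array(0L, dim = c(6, 2, 3))
  parr[, 1, ] <- one; parr[, 2, ] <- one
  perf <- classification_data(parr)
  expect_equal(kappa_cohen(perf)$pooled$kappa, 1)
  expect_error(kappa_cohen(load_fixture("math_exam")$data), "two raters")
})

test_that("identical classification vectors give an intraclass rho of 1", {
  arr <- array(0L, dim = c(3, 4, 5))
  arr[, , 1] <- 1L; arr[2, , 3] <- 1L  # raters unanimous everywhere
  ic <- kappa_icc(classification_data(arr))
  expect_equal(unname(ic$details$rho[1:3]), c(1, 1, 1))
  # a subject with < 2 raters is excluded with a warning
  rated <- matrix(1L, 3, 4); rated[1, 2:4] <- 0L
  arr2 <- arr; arr2[1, 2:4, ] <- 0L
  expect_warning(ic2 <- kappa_icc(classification_data(arr2, rated = rated)),
                 "fewer than two raters")
  expect_equal(ic2$excluded$subjects, 1)
})

test_that("rank vectors place unselected categories at the mean leftover rank", {
  cats <- c("blue", "brown", "green", "pink", "purple", "orange", "red", "yellow")
  rv <- rank_vectors(list(list("green", c("brown", "orange", "red"), "yellow")),
                     cats)
  expect_equal(unname(rv[1, ]), c(7, 3, 1, 7, 7, 3, 3, 5))
  # a full untied ranking is a permutation of 1..C
  full <- rank_vectors(list(sample(cats)), cats)
  expect_setequal(full[1, ], 1:8)
  # nothing selected: all categories tie at (C + 1)/2
  none <- rank_vectors(list(character(0)), cats)
  expect_true(all(none[1, ] == 4.5))
  expect_error(rank_vectors(list(c("blue", "blue")), cats), "duplicate")
})

test_that("rank kappa behaves on perfectly agreeing and reversed rankings", {
  cats <- as.character(1:5)
  same <- rank_vectors(list(cats, cats), cats)
  rk <- kappa_rank(same, subjects = c(1, 1))
  expect_equal(rk$po, 1)
  rev2 <- rank_vectors(list(cats, rev(cats)), cats)
  expect_equal(multikappa:::spearman_pair(rev2[1, ], rev2[2, ], "classic"), -1)
  expect_equal(multikappa:::spearman_pair(rev2[1, ], rev2[2, ], "pearson"), -1)
  # constant vectors make a pair undefined and excluded
  const <- rank_vectors(list(character(0), cats), cats)
  expect_true(is.na(multikappa:::spearman_pair(const[1, ], const[2, ], "classic")))
})

test_that("the method comparison table marks inapplicable methods", {
  tab <- compare_methods(load_fixture("math_exam")$data)
  expect_match(tab$note[tab$method == "averaged/pooled Cohen's kappa"],
               "two raters")
  expect_match(tab$note[tab$method == "chance-corrected rank correlation"],
               "no ordered classifications")
  set.seed(2)
  two <- classification_data(random_tensor(6, 2, 3))
  tab2 <- compare_methods(two)
  expect_true("pooled Cohen's kappa" %in% tab2$method)
})
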