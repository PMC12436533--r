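test_that("per-category observed agreement matches pair enumeration", {
  # the worked math-exam item: 16 of 18 ticks, one partial subject
  near_printed(po_category(c(3, 1, 3, 3, 3, 3), rep(3, 6)), 0.889)
  expect_equal(po_category(c(4, 4), c(4, 4)), 1)  # everyone selects: perfect
  set.seed(31)
  for (rep in 1:25) {
    s <- sample(0:6, 5, replace = TRUE)
    x <- vapply(s, function(si) sample(0:si, 1), integer(1))
    expect_equal(po_category(x, s), po_bruteforce(x, s))
  }
  expect_error(po_category(c(3), c(2)), "x > s")
  expect_true(is.na(po_category(c(0, 1), c(1, 1))))  # no pairs -> skip signal
})

test_that("expected agreement follows the closed form 2p^2 - 2p + 1", {
  near_printed(pe_category(c(3, 1, 3, 3, 3, 3), rep(3, 6)), 0.802)
  expect_equal(pe_category(rep(2, 10), rep(4, 10)), 0.5)  # p = 1/2 minimum
  expect_equal(pe_category(rep(0, 3), rep(4, 3)), 1)
  expect_equal(pe_category(rep(4, 3), rep(4, 3)), 1)
  set.seed(5)
  p <- runif(20)
  expect_true(all(2 * p^2 - 2 * p + 1 >= 0.5))
})

test_that("partial kappa handles the undefined Pe = 1 case as NaN", {
  x1 <- c(3, 1, 3, 3, 3, 3); s1 <- rep(3, 6)
  near_printed(kappa_category(po_category(x1, s1), pe_category(x1, s1)), 0.438)
  expect_equal(kappa_category(1, 0.3), 1)
  expect_true(is.nan(kappa_category(1, 1)))
})

test_that("the paradox examples all collapse to the minimum kappa", {
  for (nm in c("table1_ex1", "table1_ex2", "table1_ex3")) {
    mk <- multi_kappa(load_fixture(nm)$data)
    expect_equal(mk$kappa, -1/3, tolerance = 1e-12)
  }
  # the per-category table records the NaN partial kappas of degenerate cats
  mk3 <- multi_kappa(load_fixture("table1_ex3")$data)
  expect_true(all(is.nan(mk3$categories$kappa[1:2])))
  expect_true(all(mk3$categories$always_selected[1:2]))
})

test_that("the always-selected correction restores the lost agreement", {
  ex3 <- load_fixture("table1_ex3")
  mk <- multi_kappa(ex3$data, correct = c("1", "2"))
  expect_equal(mk$kappa, 11/15, tolerance = 1e-12)  # 0.733
  expect_true(all(mk$categories$pe_used[1:2] == 0))
  expect_error(multi_kappa(ex3$data, correct = "99"), "unknown categories")
})

test_that("generalized kappa equals classic Fleiss on mutually exclusive data", {
  set.seed(1234)
  for (rep in 1:1000) {
    I <- sample(2:10, 1); J <- sample(2:6, 1); C <- sample(2:6, 1)
    X <- random_exclusive_table(I, J, C)
    tab <- agreement_table(X, J = J)
    f <- fleiss_kappa(tab)
    if (f$Pe == 1) next  # degenerate: all raters in one category everywhere
    g <- multi_kappa(tab)
    expect_lt(abs(g$kappa - f$kappa), 1e-10)
  }
})

test_that("classic Fleiss reproduces its textbook boundary cases", {
  onehot <- diag(3) * 4  # unanimity, J = 4, but every subject a different cat
  expect_equal(fleiss_kappa(agreement_table(onehot, J = 4))$kappa, 1)
  # J = C, each rater a different category: Po = 0, Pe = 1/J, kappa = -1/(J-1)
  for (J in 2:5) {
    X <- matrix(1L, 6, J)
    f <- fleiss_kappa(agreement_table(X, J = J))
    expect_equal(f$Po, 0)
    expect_equal(f$Pe, 1 / J)
    expect_equal(f$kappa, -1 / (J - 1))
  }
  expect_error(fleiss_kappa(agreement_table(matrix(1L, 2, 3), J = 4)),
               "mutually exclusive")
})

test_that("unused and always-selected categories leave kappa unchanged", {
  set.seed(99)
  for (rep in 1:20) {
    arr <- random_tensor(6, 4, 3)
    base <- multi_kappa(classification_data(arr))
    ext <- array(0L, dim = c(6, 4, 5))
    ext[, , 1:3] <- arr
    ext[, , 5] <- 1L  # always selected
    aug <- multi_kappa(classification_data(ext))
    expect_equal(aug$kappa, base$kappa, tolerance = 1e-12)
    expect_true(aug$categories$unused[4])
    expect_true(aug$categories$always_selected[5])
  }
})

test_that("kappa is invariant to rescaling the weight vector", {
  set.seed(17)
  arr <- random_tensor(8, 3, 4)
  cd <- classification_data(arr)
  w <- runif(4, 0.2, 2)
  k1 <- multi_kappa(cd, weights = w)$kappa
  for (lambda in c(0.001, 7, 1e6))
    expect_equal(multi_kappa(cd, weights = lambda * w)$kappa, k1,
                 tolerance = 1e-12)
})

test_that("kappa stays inside [-1/(J-1), 1] for fixed-panel data", {
  set.seed(2024)
  for (rep in 1:200) {
    J <- sample(2:6, 1)
    arr <- random_tensor(sample(2:8, 1), J, sample(1:5, 1),
                         p = runif(1, 0.1, 0.9))
    mk <- multi_kappa(classification_data(arr))
    if (is.na(mk$kappa)) next  # fully degenerate draw
    expect_gte(mk$kappa, -1 / (J - 1) - 1e-12)
    expect_lte(mk$kappa, 1 + 1e-12)
  }
  # the even-split pattern attains the lower bound
  even <- matrix(2L, 10, 3)
  expect_equal(multi_kappa(agreement_table(even, J = 4))$kappa, -1/3,
               tolerance = 1e-12)
})

test_that("an entirely degenerate table yields an undefined pooled kappa", {
  X <- matrix(c(0L, 4L), 5, 2, byrow = TRUE)  # one unused, one always-selected
  mk <- multi_kappa(agreement_table(X, J = 4))
  expect_true(mk$undefined)
  expect_true(is.na(mk$kappa))
  expect_equal(mk$denominator, 0)
})

test_that("perfect agreement gives kappa 1 under any weighting", {
  arr <- array(0L, dim = c(4, 3, 3))
  arr[, , 1] <- 1L; arr[1:2, , 2] <- 1L
  cd <- classification_data(arr, categories = as.character(1:3))
  expect_equal(multi_kappa(cd, correct = "1")$kappa, 1)
  expect_equal(multi_kappa(cd, weights = c(3, 1, 2), correct = "1")$kappa, 1)
})
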