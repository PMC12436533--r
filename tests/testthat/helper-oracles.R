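# Shared helpers: independent brute-force oracles and small generators.

# printed-value comparison: the references print k decimals, rounded half
# away from zero, so equality holds up to half a unit in the last place
near_printed <- function(x, printed, digits = 3) {
  expect_lt(abs(x - printed), 0.5 * 10^(-digits) + 1e-9)
}

# oracle: observed pairwise agreement by explicit enumeration of rater pairs
po_bruteforce <- function(x, s) {
  agree <- 0; total <- 0
  for (i in seq_along(x)) {
    if (s[i] < 2) next
    # raters 1..s[i]; the first x[i] selected, the rest did not
    sel <- c(rep(1L, x[i]), rep(0L, s[i] - x[i]))
    for (a in seq_len(s[i] - 1)) for (b in (a + 1):s[i]) {
      total <- total + 1
      if (sel[a] == sel[b]) agree <- agree + 1
    }
  }
  if (total == 0) NA_real_ else agree / total
}

# oracle: agreement-table counts by triple loop
counts_bruteforce <- function(arr) {
  d <- dim(arr)
  out <- matrix(0L, d[1], d[3])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (c in seq_len(d[3]))
    out[i, c] <- out[i, c] + arr[i, j, c]
  out
}

# random binary classification tensor with all subjects rated by all raters
random_tensor <- function(I, J, C, p = 0.4) {
  array(stats::rbinom(I * J * C, 1L, p), dim = c(I, J, C))
}

# random mutually exclusive counts table: every rater picks one category
random_exclusive_table <- function(I, J, C) {
  X <- matrix(0L, I, C)
  for (i in seq_len(I)) {
    picks <- sample.int(C, J, replace = TRUE)
    for (k in picks) X[i, k] <- X[i, k] + 1L
  }
  X
}

fixture_md5 <- c(
  "math_exam/ratings.csv" = "b6d8df2cd05445a4664391620bd04f3c",
  "math_exam/roster.csv" = "fdabafe822c8e5b34694397ca74a7dbf",
  "math_exam/rules.json" = "adb69c456a9e6a4fd7391235d8dcafec",
  "math_exam/scores.csv" = "7fec9b63d6295d3067a520f3043445e3",
  "psychiatric/ratings.csv" = "21c83ab43a37bc89ed95c25b7d82e88b",
  "psychiatric/roster.csv" = "18de812bfa409952143588a63dd76721",
  "table1_ex1/ratings.csv" = "57ec51f3aad3666f0a4f620fe4b47b06",
  "table1_ex1/roster.csv" = "484ce20430f94e4e921666c11c66305e",
  "table1_ex2/ratings.csv" = "9b07515af417d755bb9b2d9061589c93",
  "table1_ex2/roster.csv" = "484ce20430f94e4e921666c11c66305e",
  "table1_ex3/ratings.csv" = "a0eb50097103b293ffeb646fdf274108",
  "table1_ex3/roster.csv" = "484ce20430f94e4e921666c11c66305e")
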