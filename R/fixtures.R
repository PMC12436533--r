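#' Packaged worked-example datasets
#'
#' Ships the datasets used throughout the documentation and tests as
#' plain-CSV fixtures:
#'
#' * `math_exam` — three teachers assessing six students' answers to a
#'   checkbox-graded drawing question with five feedback items, two of
#'   them hierarchical (item 4 requires items 1 and 3, item 5 requires
#'   item 4) and score-weighted.
#' * `psychiatric` — 27 child psychiatric cases, each independently
#'   diagnosed by three or four psychiatrists into up to three of 20
#'   DSM-III Axis I broad categories (Mezzich et al., 1981). Diagnosis
#'   order is preserved (first-listed = primary), so the same fixture
#'   serves the rank-correlation comparator.
#' * `table1_ex1`, `table1_ex2`, `table1_ex3` — constructed illustrations
#'   of the always-selected-category paradox: ten subjects, four raters,
#'   three categories, with unused (ex. 1), maximally split (ex. 2) and
#'   always-selected (ex. 3) categories.
#'
#' @param name fixture name.
#' @return a `fixture_bundle`: list with `name`, `data`
#'   (`classification_data`), `availability`, and where applicable
#'   `rules`, `scores`, `ordered` (per rated unit, subject-major), plus a
#'   `citation` string.
#' @export
load_fixture <- function(name = c("math_exam", "psychiatric",
                                  "table1_ex1", "table1_ex2", "table1_ex3")) {
  name <- match.arg(name)
  dir <- system.file("extdata", name, package = "multikappa", mustWork = TRUE)
  p <- function(f) file.path(dir, f)
  if (name == "math_exam") {
    data <- read_ratings_long(p("ratings.csv"), roster = p("roster.csv"),
                              categories = as.character(1:5))
    bundle <- list(
      name = name, data = data, availability = data_availability(data),
      rules = read_hierarchy(p("rules.json")),
      scores = read_category_values(p("scores.csv")),
      citation = paste("Checkbox grading of a drawing question:",
                       "3 teachers x 6 students x 5 feedback items"))
  } else if (name == "psychiatric") {
    data <- read_ratings_long(p("ratings.csv"), roster = p("roster.csv"),
                              categories = as.character(1:20))
    raw <- utils::read.csv(p("ratings.csv"), colClasses = "character")
    ros <- utils::read.csv(p("roster.csv"), colClasses = "character")
    key <- paste(raw$subject, raw$rater)
    ordered <- lapply(paste(ros$subject, ros$rater), function(k) {
      rows <- raw[key == k, , drop = FALSE]
      rows$category[order(as.integer(rows$rank))]
    })
    bundle <- list(
      name = name, data = data, availability = data_availability(data),
      ordered = ordered,
      citation = paste("27 child psychiatric cases diagnosed by 30",
                       "psychiatrists into DSM-III Axis I broad categories",
                       "(Mezzich, Kraemer, Worthington & Coffman, 1981)"))
  } else {
    data <- read_ratings_long(p("ratings.csv"), roster = p("roster.csv"),
                              categories = as.character(1:3))
    bundle <- list(
      name = name, data = data, availability = data_availability(data),
      citation = "Constructed always-selected-category paradox example")
  }
  structure(bundle, class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("fixture_bundle:", x$name, "\n ", x$citation, "\n")
  print(x$data)
  invisible(x)
}

#' Simulate multi-label classification data
#'
#' Generates synthetic rater data under a simple latent-label mechanism:
#' each subject owns a latent binary label set drawn per category from
#' `prevalence`; each rater copies each latent label with probability
#' `fidelity` and otherwise draws independently from `prevalence`. So
#' `fidelity = 1` makes all raters identical (kappa 1) and `fidelity = 0`
#' yields chance-level agreement (kappa near 0). When hierarchy rules are
#' supplied, selections whose rule fails for that rater are zeroed in
#' topological order, so the generated data respect the hierarchy by
#' construction. The mechanism is a deliberately stylised test harness:
#' real raters are neither exchangeable nor conditionally independent.
#'
#' @param I,J,C numbers of subjects, raters, categories.
#' @param prevalence per-category selection probability (scalar or length
#'   `C`).
#' @param fidelity probability a rater copies the subject's latent label.
#' @param rules optional `hierarchy_rules` (or named list) over the
#'   categories `"1" ... "C"`.
#' @param seed integer seed (mandatory).
#' @return a `fixture_bundle` with the generated `classification_data`.
#' @export
simulate_ratings <- function(I, J, C, prevalence = 0.3, fidelity = 0.8,
                             rules = NULL, seed) {
  if (missing(seed)) stop("a reproducible 'seed' is mandatory")
  stopifnot(I >= 1, J >= 2, C >= 1,
            all(prevalence >= 0 & prevalence <= 1),
            fidelity >= 0, fidelity <= 1)
  prevalence <- rep_len(prevalence, C)
  set.seed(as.integer(seed))
  latent <- matrix(stats::rbinom(I * C, 1L, rep(prevalence, each = I)), I, C)
  arr <- array(0L, dim = c(I, J, C))
  for (j in seq_len(J)) {
    copy <- matrix(stats::runif(I * C) < fidelity, I, C)
    indep <- matrix(stats::rbinom(I * C, 1L, rep(prevalence, each = I)), I, C)
    arr[, j, ] <- ifelse(copy, latent, indep)
  }
  categories <- as.character(seq_len(C))
  if (!is.null(rules)) {
    if (!inherits(rules, "hierarchy_rules")) rules <- hierarchy_rules(rules)
    for (cat in rules$order) {
      c_idx <- match(cat, categories)
      for (i in seq_len(I)) for (j in seq_len(J)) {
        if (arr[i, j, c_idx] == 0L) next
        selected <- as.logical(arr[i, j, ])
        names(selected) <- categories
        if (!eval_rule(rules$rules[[cat]], selected)) arr[i, j, c_idx] <- 0L
      }
    }
  }
  data <- classification_data(arr, categories = categories)
  structure(list(name = "synthetic", data = data,
                 availability = data_availability(data), rules = rules,
                 citation = sprintf(
                   "Synthetic latent-label data (I=%d, J=%d, C=%d, prevalence=%s, fidelity=%s, seed=%d)",
                   I, J, C, paste(unique(prevalence), collapse = "/"),
                   format(fidelity), as.integer(seed))),
            class = "fixture_bundle")
}
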