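#' Benchmark scales for agreement coefficients
#'
#' An ordered set of agreement levels, each covering a half-open kappa
#' interval `(lower, upper]`, from the highest level of agreement down to
#' the lowest. [landis_koch()] returns the ubiquitous Landis-Koch scale
#' (Almost perfect above 0.8 down to Poor below 0).
#'
#' @param labels level labels, highest agreement first.
#' @param lower lower bounds, one per level, strictly decreasing; a kappa
#'   value belongs to the highest level whose lower bound it exceeds. The
#'   last bound is typically `-Inf` so the scale covers every value.
#' @return a `benchmark_scale` data.frame with columns `label` and `lower`.
#' @export
benchmark_scale <- function(labels, lower) {
  if (length(labels) != length(lower)) stop("one lower bound per label")
  if (any(diff(lower) >= 0)) stop("lower bounds must be strictly decreasing")
  structure(data.frame(label = as.character(labels), lower = as.numeric(lower),
                       stringsAsFactors = FALSE),
            class = c("benchmark_scale", "data.frame"))
}

#' @rdname benchmark_scale
#' @export
landis_koch <- function() {
  benchmark_scale(
    labels = c("Almost perfect", "Substantial", "Moderate", "Fair",
               "Slight", "Poor"),
    lower = c(0.8, 0.6, 0.4, 0.2, 0, -Inf))
}

#' Bootstrap replicates of the generalized kappa
#'
#' Resamples subjects with replacement (`n = I` per replicate) and
#' recomputes the coefficient, for use in Interval Membership Probability
#' benchmarking. Two resampling designs are available:
#'
#' * `"bundle"` (default): each drawn subject carries its entire row bundle
#'   — selection counts, rater availability, and hierarchy-derived possible
#'   classifications — so every replicate is a coherent dataset. This is
#'   the statistically sound scheme.
#' * `"fixed"`: only the rows of the count matrix `X` are resampled, while
#'   the possible-classification matrix and availability stay fixed at the
#'   observed design (resampled counts are paired with the original rows'
#'   selectability). Under hierarchies this can pair a count with an
#'   incompatible possible-classification row; it is provided because the
#'   published worked-example benchmarking tables for hierarchical data are
#'   reproduced by exactly this scheme, and it can be read as conditioning
#'   on the observed selectability design.
#'
#' Replicates with an undefined kappa (zero denominator) are excluded and
#' counted, never silently dropped.
#'
#' @inheritParams multi_kappa
#' @param B number of bootstrap replicates (10,000 is the usual advice).
#' @param seed integer seed; mandatory, so runs are reproducible.
#' @param design `"bundle"` or `"fixed"`; see Details.
#' @return a `kappa_bootstrap` object: `kappas` (defined replicates),
#'   `n_undefined`, `B`, `seed`, `design`, and the point `estimate`.
#' @export
bootstrap_kappa <- function(data, weights = NULL, rules = NULL, possible = NULL,
                            availability = NULL, correct = NULL,
                            B = 10000, seed, design = c("bundle", "fixed")) {
  design <- match.arg(design)
  if (missing(seed)) stop("a reproducible 'seed' is mandatory")
  if (B < 1) stop("B must be >= 1")
  point <- multi_kappa(data, weights = weights, rules = rules,
                       possible = possible, availability = availability,
                       correct = correct)
  # rebuild the row bundles the point estimate used
  if (inherits(data, "classification_data")) {
    table <- agreement_table(data)
    availability <- availability %||% data_availability(data)
    if (is.null(possible) && !is.null(rules))
      possible <- possible_matrix(data, rules, availability)
  } else {
    table <- data
    availability <- availability %||% rater_availability(fixed = table$J)
  }
  X <- table$counts
  I <- nrow(X); C <- ncol(X)
  Jm <- availability_matrix(availability, I, C)
  S <- if (is.null(possible)) Jm else possible$s
  w <- resolve_weights(weights, table$categories)
  pe_zero <- rep(FALSE, C)
  if (!is.null(correct)) pe_zero[match(as.character(correct), table$categories)] <- TRUE

  set.seed(as.integer(seed))
  kappas <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample.int(I, I, replace = TRUE)
    kappas[b] <- if (design == "bundle")
      kappa_from_rows(X[idx, , drop = FALSE], S[idx, , drop = FALSE],
                      Jm[idx, , drop = FALSE], w, pe_zero)$kappa
    else
      kappa_from_rows(X[idx, , drop = FALSE], S, Jm, w, pe_zero)$kappa
  }
  und <- is.na(kappas)
  structure(list(kappas = kappas[!und], n_undefined = sum(und), B = B,
                 seed = as.integer(seed), design = design,
                 estimate = point$kappa),
            class = "kappa_bootstrap")
}

#' @export
print.kappa_bootstrap <- function(x, ...) {
  cat(sprintf(
    "kappa_bootstrap: B = %d (%s design, seed %d), %d undefined excluded\n",
    x$B, x$design, x$seed, x$n_undefined))
  cat(sprintf("  point estimate %.4f; replicate quartiles %s\n", x$estimate,
              paste(round(stats::quantile(x$kappas, c(.25, .5, .75)), 4),
                    collapse = " / ")))
  invisible(x)
}

#' Interval membership probabilities
#'
#' The IMP of a benchmark level is the share of bootstrap kappa replicates
#' falling inside that level's interval; cumulative IMPs accumulate from
#' the highest-agreement level downward.
#'
#' @param kappas a `kappa_bootstrap` object or a bare numeric vector of
#'   replicate kappa values.
#' @param scale a `benchmark_scale`; default [landis_koch()].
#' @return an `imp_result`: data.frame `table` (label, lower, imp,
#'   cumulative), plus `B`, `n_undefined`, `seed` when known.
#' @export
imp <- function(kappas, scale = landis_koch()) {
  meta <- list(B = NA_integer_, n_undefined = NA_integer_, seed = NA_integer_,
               estimate = NA_real_, design = NA_character_)
  if (inherits(kappas, "kappa_bootstrap")) {
    meta <- kappas[c("B", "n_undefined", "seed", "estimate", "design")]
    kappas <- kappas$kappas
  }
  kappas <- kappas[!is.na(kappas)]
  if (length(kappas) == 0L)
    stop("no defined kappa replicates; increase the number of bootstrap samples")
  stopifnot(inherits(scale, "benchmark_scale"))
  n <- length(kappas)
  cum <- vapply(scale$lower, function(b) sum(kappas > b) / n, numeric(1))
  impv <- diff(c(0, cum))
  structure(c(list(table = data.frame(label = scale$label, lower = scale$lower,
                                      imp = impv, cumulative = cum,
                                      stringsAsFactors = FALSE),
                   n = n), meta),
            class = "imp_result")
}

#' Final agreement level at a confidence level
#'
#' Scans the benchmark levels from the highest agreement downward and
#' returns the first whose cumulative IMP reaches `1 - alpha` — i.e. the
#' strongest claim about the level of agreement that holds with the
#' requested confidence. If no level qualifies the lowest level is
#' returned.
#'
#' @param x an `imp_result`.
#' @param alpha significance level in `(0, 1)`; default 0.05.
#' @return the level label (character).
#' @export
agreement_level <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "imp_result"), alpha > 0, alpha < 1)
  hit <- which(x$table$cumulative >= 1 - alpha)
  if (length(hit) == 0L) x$table$label[nrow(x$table)] else x$table$label[hit[1]]
}

#' One-call IMP benchmarking
#'
#' Bootstrap + IMP + final level in one step.
#'
#' @inheritParams bootstrap_kappa
#' @param alpha significance level for the final agreement level.
#' @param scale a `benchmark_scale`.
#' @return an `imp_result` with the chosen `alpha` and `level` filled in.
#' @export
imp_benchmark <- function(data, weights = NULL, rules = NULL, possible = NULL,
                          availability = NULL, correct = NULL,
                          B = 10000, seed, alpha = 0.05,
                          scale = landis_koch(), design = c("bundle", "fixed")) {
  bt <- bootstrap_kappa(data, weights = weights, rules = rules,
                        possible = possible, availability = availability,
                        correct = correct, B = B, seed = seed,
                        design = match.arg(design))
  res <- imp(bt, scale)
  res$alpha <- alpha
  res$level <- agreement_level(res, alpha)
  res
}

#' @export
print.imp_result <- function(x, digits = 4, ...) {
  cat("Interval membership probabilities")
  if (!is.na(x$B))
    cat(sprintf(" (B = %d, seed %s, %d undefined excluded)",
                x$B, x$seed, x$n_undefined))
  cat("\n")
  tab <- x$table
  tab$imp <- round(tab$imp, digits)
  tab$cumulative <- round(tab$cumulative, digits)
  print(tab, row.names = FALSE)
  if (!is.null(x$level))
    cat(sprintf("final level at alpha = %s: %s\n", format(x$alpha), x$level))
  invisible(x)
}
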