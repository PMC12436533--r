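#' Per-category observed pairwise agreement
#'
#' The proportion of agreeing rater pairs for one category, pooled over
#' subjects: a pair agrees on category `c` for subject `i` when both raters
#' selected it or both did not. With `x` selections out of `s` available
#' raters the agreeing pairs are `choose(x, 2) + choose(s - x, 2)` of
#' `choose(s, 2)`; the fixed-panel and varying-rater forms are the special
#' cases `s = J` and `s = j_i`.
#'
#' @param x per-subject selection counts for the category.
#' @param s per-subject availability (possible classifications) for the
#'   category; subjects with `s < 2` contribute no pairs.
#' @return the pooled observed agreement in `[0, 1]`, or `NA` when the
#'   category has no rater pairs at all (the caller skips it).
#' @examples
#' po_category(c(3, 1, 3, 3, 3, 3), rep(3, 6))  # 0.889
#' @export
po_category <- function(x, s) {
  x <- as.numeric(x); s <- as.numeric(s)
  if (length(x) != length(s)) stop("x and s must have the same length")
  if (any(x > s)) stop("selection counts exceed availability (x > s)")
  if (any(x < 0) || any(s < 0)) stop("negative counts")
  denom <- sum(s * (s - 1))
  if (denom == 0) return(NA_real_)
  sum(x * (x - 1) + (s - x) * (s - x - 1)) / denom
}

#' Per-category expected chance agreement
#'
#' With overall selection proportion `p = sum(x) / sum(s)`, two independent
#' random raters agree on the category with probability
#' `p^2 + (1 - p)^2 = 2 p^2 - 2 p + 1`, which lies in `[0.5, 1]` and
#' equals 1 exactly for unused or always-selected categories.
#'
#' @inheritParams po_category
#' @return expected agreement in `[0.5, 1]`, or `NA` when `sum(s) = 0`.
#' @examples
#' pe_category(c(3, 1, 3, 3, 3, 3), rep(3, 6))  # 0.802
#' @export
pe_category <- function(x, s) {
  x <- as.numeric(x); s <- as.numeric(s)
  if (any(x > s)) stop("selection counts exceed availability (x > s)")
  tot <- sum(s)
  if (tot == 0) return(NA_real_)
  p <- sum(x) / tot
  2 * p^2 - 2 * p + 1
}

#' Partial kappa for one category
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)` for a single category.
#' Undefined (returned as `NaN`, never an error) when `pe = 1`, i.e. for
#' unused and always-selected categories.
#'
#' @param po,pe observed and expected agreement in `[0, 1]`.
#' @return the partial kappa, or `NaN` when `pe = 1`.
#' @export
kappa_category <- function(po, pe) {
  if (is.na(po) || is.na(pe)) return(NA_real_)
  if (pe == 1) return(NaN)
  (po - pe) / (1 - pe)
}

# Round half away from zero (display convention for printed tables).
round_half_away <- function(x, digits = 3) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Core pooled kappa from row bundles. X, S, Jm: I x C matrices; w: weights;
# pe_zero: logical per category (always-selected correction). Returns the
# overall kappa plus the per-category pieces. Used by multi_kappa() and,
# with resampled rows, by the bootstrap.
kappa_from_rows <- function(X, S, Jm, w, pe_zero) {
  C <- ncol(X)
  po <- pe <- phi <- numeric(C)
  skipped <- logical(C)
  for (c in seq_len(C)) {
    x <- X[, c]; s <- S[, c]
    pairs <- sum(s * (s - 1))
    jtot <- sum(Jm[, c])
    phi[c] <- if (jtot > 0) sum(s) / jtot else 0
    if (pairs == 0 || sum(s) == 0) {
      skipped[c] <- TRUE
      po[c] <- NA_real_; pe[c] <- NA_real_
      next
    }
    po[c] <- sum(x * (x - 1) + (s - x) * (s - x - 1)) / pairs
    p <- sum(x) / sum(s)
    pe[c] <- 2 * p^2 - 2 * p + 1
  }
  pe_used <- ifelse(pe_zero, 0, pe)
  contrib <- !skipped & phi > 0
  num <- sum((w * phi * (po - pe_used))[contrib])
  den <- sum((w * phi * (1 - pe_used))[contrib])
  kappa <- if (den == 0) NA_real_ else num / den
  list(kappa = kappa, numerator = num, denominator = den,
       po = po, pe = pe, pe_used = pe_used, phi = phi, skipped = skipped)
}

#' Generalized multi-category kappa
#'
#' The chance-corrected agreement coefficient for several raters
#' classifying subjects into one or more categories:
#' \deqn{\kappa = \frac{\sum_c w_c \phi_c (Po_c - Pe_c)}
#'                     {\sum_c w_c \phi_c (1 - Pe_c)}}
#' where `Po_c`/`Pe_c` are the per-category observed and expected pairwise
#' agreements, `w_c` optional importance weights, and `phi_c` scale factors
#' that discount categories only selectable under a hierarchy. With equal
#' weights, no hierarchy and a fixed panel, it reduces exactly to Fleiss'
#' kappa on mutually exclusive data.
#'
#' Unused and always-selected categories have `Po_c = Pe_c = 1` and
#' contribute nothing; the opt-in `correct` argument zeroes `Pe_c` for
#' chosen categories so that, e.g., a category deliberately ticked by every
#' rater for every subject counts as the full agreement it is (the
#' always-selected-category correction).
#'
#' @param data a `classification_data` or an `agreement_table`.
#' @param weights optional per-category weights (named, or positional);
#'   default equal weights. Scaling all weights by a positive constant does
#'   not change kappa.
#' @param rules optional `hierarchy_rules` (or named list of expression
#'   strings); requires `data` to be a `classification_data`.
#' @param possible optional precomputed `possible_classifications`;
#'   overrides `rules`.
#' @param availability optional `rater_availability`; defaults to the
#'   table's fixed `J` or the data's `rated` matrix.
#' @param correct character vector of category identifiers whose expected
#'   agreement is set to 0 (always-selected correction; may also be applied
#'   to unused categories where that is appropriate).
#' @return a `multi_kappa` object: overall `kappa`, `numerator`,
#'   `denominator`, a per-category data.frame `categories` (po, pe,
#'   pe_used, kappa, weight, phi, flags), and a `settings` echo.
#' @examples
#' x <- matrix(c(0, 0, 2), 10, 3, byrow = TRUE)  # disagreement on one category
#' multi_kappa(agreement_table(x, J = 4))$kappa  # -1/3
#' @export
multi_kappa <- function(data, weights = NULL, rules = NULL, possible = NULL,
                        availability = NULL, correct = NULL) {
  if (inherits(data, "classification_data")) {
    table <- agreement_table(data)
    availability <- availability %||% data_availability(data)
    if (is.null(possible) && !is.null(rules))
      possible <- possible_matrix(data, rules, availability)
  } else if (inherits(data, "agreement_table")) {
    table <- data
    if (is.null(availability)) {
      if (is.na(table$J)) stop("varying raters: supply 'availability'")
      availability <- rater_availability(fixed = table$J)
    }
    if (!is.null(rules) && is.null(possible))
      stop("hierarchy rules need full classification data, not a bare table")
  } else stop("'data' must be classification_data or agreement_table")

  X <- table$counts
  I <- nrow(X); C <- ncol(X)
  Jm <- availability_matrix(availability, I, C)
  if (any(X > Jm))
    stop("impossible counts: x_ic exceeds the available raters; see validate_ratings()")
  S <- if (is.null(possible)) Jm else {
    if (!all(dim(possible$s) == c(I, C))) stop("possible matrix shape mismatch")
    possible$s
  }
  if (any(X > S))
    stop("selection counts exceed possible classifications (x_ic > s_ic)")

  w <- resolve_weights(weights, table$categories)
  pe_zero <- rep(FALSE, C)
  if (!is.null(correct)) {
    idx <- match(as.character(correct), table$categories)
    if (anyNA(idx))
      stop("unknown categories in 'correct': ",
           paste(correct[is.na(idx)], collapse = ", "))
    pe_zero[idx] <- TRUE
  }

  core <- kappa_from_rows(X, S, Jm, w, pe_zero)
  kc <- mapply(kappa_category, core$po, core$pe)
  unused <- colSums(X) == 0L
  always <- !unused & apply(X == S, 2, all) & colSums(S) > 0L
  cats <- data.frame(
    category = table$categories,
    x_total = colSums(X), s_total = colSums(S), j_total = colSums(Jm),
    po = core$po, pe = core$pe, pe_used = core$pe_used,
    kappa = kc, weight = w, phi = core$phi,
    unused = unused, always_selected = always,
    skipped_no_pairs = core$skipped, pe_zeroed = pe_zero,
    stringsAsFactors = FALSE, row.names = NULL)
  structure(
    list(kappa = core$kappa, numerator = core$numerator,
         denominator = core$denominator, categories = cats,
         undefined = is.na(core$kappa),
         settings = list(
           weights = w, correct = as.character(correct %||% character(0)),
           availability_mode = availability$mode,
           hierarchical = !is.null(possible))),
    class = "multi_kappa")
}

resolve_weights <- function(weights, categories) {
  C <- length(categories)
  if (is.null(weights)) return(rep(1, C))
  w <- as.numeric(weights)
  if (!is.null(names(weights))) {
    idx <- match(categories, names(weights))
    if (anyNA(idx))
      stop("weights missing for categories: ",
           paste(categories[is.na(idx)], collapse = ", "))
    w <- w[idx]
  } else if (length(w) != C)
    stop("need one weight per category")
  if (any(w < 0) || all(w == 0)) stop("weights must be >= 0 and not all zero")
  w
}

#' @export
print.multi_kappa <- function(x, digits = 3, ...) {
  cat("Generalized multi-category kappa\n")
  tab <- x$categories
  show <- data.frame(category = tab$category,
                     Po = round_half_away(tab$po, digits), Pe = round_half_away(tab$pe, digits),
                     kappa = round_half_away(tab$kappa, digits),
                     w = round_half_away(tab$weight, digits), phi = round_half_away(tab$phi, digits))
  flags <- ifelse(tab$unused, "unused",
           ifelse(tab$always_selected, "always-selected",
           ifelse(tab$skipped_no_pairs, "skipped", "")))
  flags[tab$pe_zeroed] <- paste(flags[tab$pe_zeroed], "Pe:=0")
  show$flags <- trimws(flags)
  print(show, row.names = FALSE)
  if (x$undefined)
    cat("kappa: undefined (all categories degenerate, denominator 0)\n")
  else
    cat(sprintf("kappa = %.*f  (numerator %.4f / denominator %.4f)\n",
                digits, x$kappa, x$numerator, x$denominator))
  invisible(x)
}

#' @export
as.data.frame.multi_kappa <- function(x, ...) x$categories

#' Classic Fleiss' kappa
#'
#' The original coefficient for `J` raters each assigning exactly one of
#' `C` mutually exclusive categories per subject. Serves as the reference
#' the generalized coefficient reduces to on such data.
#'
#' @param table an `agreement_table` or a plain `I x C` counts matrix.
#' @param J number of raters; defaults to the table's fixed `J`.
#' @return a `fleiss_kappa` object with per-subject agreement `P_i`,
#'   overall `Po`, `Pe` and `kappa`.
#' @export
fleiss_kappa <- function(table, J = NULL) {
  X <- if (inherits(table, "agreement_table")) table$counts else as.matrix(table)
  J <- J %||% (if (inherits(table, "agreement_table")) table$J else NULL)
  if (is.null(J) || is.na(J)) stop("supply the fixed number of raters J")
  if (!all(rowSums(X) == J))
    stop("Fleiss' kappa needs mutually exclusive data: every row of counts ",
         "must sum to J")
  if (J < 2) stop("need J >= 2 raters")
  Pi <- (rowSums(X^2) - J) / (J * (J - 1))
  Po <- mean(Pi)
  p <- colSums(X) / (nrow(X) * J)
  Pe <- sum(p^2)
  structure(list(P_i = Pi, Po = Po, Pe = Pe,
                 kappa = (Po - Pe) / (1 - Pe)),
            class = "fleiss_kappa")
}

#' @export
print.fleiss_kappa <- function(x, digits = 3, ...) {
  cat(sprintf("Fleiss' kappa: %.*f  (Po = %.*f, Pe = %.*f)\n",
              digits, x$kappa, digits, x$Po, digits, x$Pe))
  invisible(x)
}

#' Write a kappa report
#'
#' Exports the per-category breakdown and the overall coefficient as CSV
#' (per-category rows plus a trailing overall row) or JSON (full structure
#' including settings).
#'
#' @param x a `multi_kappa` object.
#' @param path output file.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_kappa_report <- function(x, path, format = NULL) {
  stopifnot(inherits(x, "multi_kappa"))
  format <- format %||% tolower(tools::file_ext(path))
  if (format == "json") {
    jsonlite::write_json(
      list(kappa = x$kappa, numerator = x$numerator,
           denominator = x$denominator, categories = x$categories,
           settings = x$settings),
      path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  } else if (format == "csv") {
    utils::write.csv(x$categories, path, row.names = FALSE)
  } else stop("unsupported report format: ", format)
  invisible(path)
}
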