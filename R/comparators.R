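# Literature comparator methods: averaged/pooled Cohen's kappa, Mezzich's
# proportional overlap, chance-corrected intraclass correlation, and
# Kraemer's chance-corrected rank correlation. All are pair-based
# coefficients plugged into kappa = (Po - Pe)/(1 - Pe); none supports
# category weights or hierarchies.

pair_agreement <- function(method, po, pe, kappa, excluded = list(), details = list()) {
  structure(list(method = method, po = po, pe = pe, kappa = kappa,
                 excluded = excluded, details = details),
            class = "pair_agreement")
}

#' @export
print.pair_agreement <- function(x, digits = 3, ...) {
  cat(sprintf("%s: kappa = %.*f  (Po = %.*f, Pe = %.*f)\n", x$method,
              digits, x$kappa, digits, x$po, digits, x$pe))
  ex <- unlist(x$excluded)
  if (length(ex) > 0 && any(ex > 0))
    cat("  excluded:", paste(names(ex[ex > 0]), ex[ex > 0],
                             sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

# selection sets of all rated (subject, rater) units, in subject-major order
rated_units <- function(data) {
  idx <- which(t(data$rated) == 1L, arr.ind = TRUE)  # rater-fast within subject
  lapply(seq_len(nrow(idx)), function(r) {
    j <- idx[r, 1]; i <- idx[r, 2]
    list(subject = i, rater = j,
         set = which(data$selections[i, j, ] == 1L))
  })
}

#' Averaged and pooled Cohen's kappa per category
#'
#' For exactly two raters, computes a 2x2 (selected / not selected)
#' Cohen's kappa for every category, their average, and the pooled kappa
#' obtained by averaging the per-category `Po` and `Pe` first and applying
#' the chance correction once. A category unused by both raters has an
#' undefined kappa, which makes the *averaged* kappa undefined too, while
#' the pooled version remains defined.
#'
#' @param data a `classification_data` with `J = 2` raters.
#' @return a `cohen_kappa` object: `per_category` data.frame, `averaged`,
#'   and a `pooled` [pair-agreement][print.pair_agreement] component.
#' @export
kappa_cohen <- function(data) {
  stopifnot(inherits(data, "classification_data"))
  if (length(data$raters) != 2L)
    stop("averaging/pooling Cohen's kappas is limited to exactly two raters")
  both <- data$rated[, 1] == 1L & data$rated[, 2] == 1L
  if (!any(both)) stop("no subject rated by both raters")
  a <- data$selections[both, 1, , drop = FALSE][, 1, ]
  b <- data$selections[both, 2, , drop = FALSE][, 1, ]
  if (is.null(dim(a))) { a <- matrix(a, ncol = length(data$categories))
                         b <- matrix(b, ncol = length(data$categories)) }
  C <- length(data$categories)
  po <- pe <- kc <- numeric(C)
  for (c in seq_len(C)) {
    po[c] <- mean(a[, c] == b[, c])
    pa <- mean(a[, c]); pb <- mean(b[, c])
    pe[c] <- pa * pb + (1 - pa) * (1 - pb)
    kc[c] <- if (pe[c] == 1) NaN else (po[c] - pe[c]) / (1 - pe[c])
  }
  pooled <- pair_agreement("pooled Cohen's kappa", mean(po), mean(pe),
                           (mean(po) - mean(pe)) / (1 - mean(pe)))
  structure(list(
    per_category = data.frame(category = data$categories, po = po, pe = pe,
                              kappa = kc, stringsAsFactors = FALSE),
    averaged = if (any(is.nan(kc))) NaN else mean(kc),
    pooled = pooled),
    class = "cohen_kappa")
}

#' @export
print.cohen_kappa <- function(x, digits = 3, ...) {
  print(x$per_category, row.names = FALSE)
  cat(sprintf("averaged kappa: %s\n",
              if (is.nan(x$averaged)) "undefined (some category kappa is NaN)"
              else format(round(x$averaged, digits))))
  print(x$pooled, digits = digits)
  invisible(x)
}

jaccard_overlap <- function(a, b) length(intersect(a, b)) / length(union(a, b))

#' Proportional-overlap (Mezzich) kappa
#'
#' The proportional overlap of two raters' selection sets is the number of
#' categories selected by both divided by the number selected by either.
#' `Po` averages, per subject, the overlaps over that subject's rater
#' pairs, then averages over subjects; `Pe` averages the overlap over all
#' pairs of individual selection sets across all rated units. Pairs
#' involving an empty selection set have no computable overlap; they are
#' excluded and counted, and a subject with no computable pair drops out
#' of `Po` entirely.
#'
#' @param data a `classification_data` (varying raters allowed).
#' @param exclude_same_rater if `TRUE`, drop pairs of sets produced by the
#'   same rater from the chance term (sensitivity analysis; the standard
#'   computation loops over all pairs).
#' @return a `pair_agreement` object.
#' @export
kappa_overlap <- function(data, exclude_same_rater = FALSE) {
  stopifnot(inherits(data, "classification_data"))
  units <- rated_units(data)
  I <- length(data$subjects)
  by_subject <- split(units, vapply(units, `[[`, 0L, "subject"))
  po_excl <- 0L; subj_excl <- 0L
  po_i <- c()
  for (us in by_subject) {
    n <- length(us)
    if (n < 2L) next
    vals <- c()
    for (aa in 1:(n - 1)) for (bb in (aa + 1):n) {
      sa <- us[[aa]]$set; sb <- us[[bb]]$set
      if (length(sa) == 0L || length(sb) == 0L) { po_excl <- po_excl + 1L; next }
      vals <- c(vals, jaccard_overlap(sa, sb))
    }
    if (length(vals) == 0L) subj_excl <- subj_excl + 1L
    else po_i <- c(po_i, mean(vals))
  }
  if (length(po_i) == 0L) stop("no subject has a computable overlap pair")
  N <- length(units)
  pe_vals <- c(); pe_excl <- 0L
  for (aa in 1:(N - 1)) for (bb in (aa + 1):N) {
    if (exclude_same_rater && units[[aa]]$rater == units[[bb]]$rater) next
    sa <- units[[aa]]$set; sb <- units[[bb]]$set
    if (length(sa) == 0L || length(sb) == 0L) { pe_excl <- pe_excl + 1L; next }
    pe_vals <- c(pe_vals, jaccard_overlap(sa, sb))
  }
  if (length(pe_vals) == 0L) stop("no computable pair for the chance term")
  po <- mean(po_i); pe <- mean(pe_vals)
  pair_agreement("proportional overlap", po, pe, (po - pe) / (1 - pe),
                 excluded = list(po_pairs = po_excl, pe_pairs = pe_excl,
                                 subjects = subj_excl))
}

# One-way ANOVA intraclass correlation of a set of classification vectors:
# groups are the categories, observations the vectors' entries, so the
# coefficient is 1 when all vectors are identical (no within-category
# variance). A constant matrix has no estimable correlation and scores 0.
icc_oneway <- function(mat) {
  k <- nrow(mat); C <- ncol(mat)
  gm <- mean(mat); cm <- colMeans(mat)
  msb <- k * sum((cm - gm)^2) / (C - 1)
  msw <- sum(sweep(mat, 2, cm)^2) / (C * (k - 1))
  if (msb == 0 && msw == 0) return(structure(0, degenerate = TRUE))
  (msb - msw) / (msb + (k - 1) * msw)
}

#' Chance-corrected intraclass-correlation kappa
#'
#' `Po` averages, over subjects, the one-way-ANOVA intraclass correlation
#' of that subject's binary classification vectors (categories as groups,
#' the rating raters as observations); `Pe` is the same coefficient over
#' all subjects' and raters' vectors pooled. Subjects rated by fewer than
#' two raters are excluded from `Po` with a warning; a subject whose
#' vectors are all identical *and* constant across categories has no
#' estimable correlation and contributes 0, flagged in the diagnostics.
#'
#' @param data a `classification_data`.
#' @return a `pair_agreement` object; `details$rho` holds the per-subject
#'   coefficients.
#' @export
kappa_icc <- function(data) {
  stopifnot(inherits(data, "classification_data"))
  I <- length(data$subjects)
  rho <- rep(NA_real_, I); degen <- 0L; skipped <- 0L
  for (i in seq_len(I)) {
    js <- which(data$rated[i, ] == 1L)
    if (length(js) < 2L) { skipped <- skipped + 1L; next }
    mat <- data$selections[i, js, , drop = FALSE][1, , ]
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(js))
    r <- icc_oneway(mat)
    if (isTRUE(attr(r, "degenerate"))) degen <- degen + 1L
    rho[i] <- as.numeric(r)
  }
  if (skipped > 0L)
    warning(skipped, " subject(s) with fewer than two raters excluded from Po")
  if (all(is.na(rho))) stop("no subject with at least two raters")
  units <- rated_units(data)
  big <- do.call(rbind, lapply(units, function(u)
    data$selections[u$subject, u$rater, ]))
  pe <- as.numeric(icc_oneway(big))
  po <- mean(rho, na.rm = TRUE)
  pair_agreement("chance-corrected ICC", po, pe, (po - pe) / (1 - pe),
                 excluded = list(subjects = skipped, degenerate = degen),
                 details = list(rho = rho))
}

#' Rank vectors from ordered category selections
#'
#' Kraemer's rank-correlation method needs, per (subject, rater), a full
#' rank vector over all `C` categories: selected categories are ranked by
#' preference (ties allowed), and every unselected category receives the
#' average of the remaining ranks.
#'
#' @param selections a list with one element per rated unit; each element
#'   is either a vector of category identifiers in preference order, or a
#'   list of vectors (each inner vector a tie group sharing a rank
#'   position).
#' @param categories the full category universe (ordering defines the
#'   columns of the result).
#' @return a numeric matrix, one row per unit, one column per category.
#' @examples
#' rank_vectors(
#'   list(list("green", c("brown", "orange", "red"), "yellow")),
#'   categories = c("blue", "brown", "green", "pink", "purple",
#'                  "orange", "red", "yellow"))
#' @export
rank_vectors <- function(selections, categories) {
  categories <- as.character(categories)
  C <- length(categories)
  out <- matrix(NA_real_, length(selections), C,
                dimnames = list(NULL, categories))
  for (u in seq_along(selections)) {
    sel <- selections[[u]]
    if (!is.list(sel)) sel <- as.list(as.character(sel))
    flat <- as.character(unlist(sel))
    if (anyDuplicated(flat))
      stop("duplicate category in one rater's ordered selection")
    if (!all(flat %in% categories))
      stop("unknown categories in selection: ",
           paste(setdiff(flat, categories), collapse = ", "))
    r <- rep(NA_real_, C); pos <- 1L
    for (grp in sel) {
      grp <- as.character(grp)
      ranks <- pos:(pos + length(grp) - 1L)
      r[match(grp, categories)] <- mean(ranks)
      pos <- pos + length(grp)
    }
    if (pos <= C) r[is.na(r)] <- mean(pos:C)
    out[u, ] <- r
  }
  out
}

spearman_pair <- function(a, b, method) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  if (method == "classic") {
    n <- length(a)
    1 - 6 * sum((a - b)^2) / (n * (n^2 - 1))
  } else stats::cor(a, b)
}

#' Chance-corrected rank-correlation (Kraemer) kappa
#'
#' Agreement between ranked classification vectors via Spearman
#' correlation: `Po` averages, per subject, the correlations over that
#' subject's rater pairs and then over subjects; `Pe` averages the
#' correlation over all pairs of rank vectors across all units. Pairs in
#' which either vector is constant have no defined correlation and are
#' excluded with a count.
#'
#' @param ranks a matrix of rank vectors as built by [rank_vectors()].
#' @param subjects vector (length `nrow(ranks)`) assigning each rank
#'   vector to its subject.
#' @param method `"classic"` applies Spearman's difference formula
#'   `1 - 6 sum(d^2) / (n (n^2 - 1))` directly to the (possibly tied)
#'   rank vectors — the form used in the reference analyses this package
#'   reproduces; `"pearson"` uses the tie-corrected product-moment
#'   correlation of the ranks.
#' @return a `pair_agreement` object.
#' @export
kappa_rank <- function(ranks, subjects, method = c("classic", "pearson")) {
  method <- match.arg(method)
  ranks <- as.matrix(ranks)
  if (length(subjects) != nrow(ranks))
    stop("'subjects' must assign every rank vector to a subject")
  po_i <- c(); po_excl <- 0L
  for (sid in unique(subjects)) {
    rows <- which(subjects == sid)
    if (length(rows) < 2L) next
    vals <- c()
    for (aa in 1:(length(rows) - 1)) for (bb in (aa + 1):length(rows)) {
      v <- spearman_pair(ranks[rows[aa], ], ranks[rows[bb], ], method)
      if (is.na(v)) po_excl <- po_excl + 1L else vals <- c(vals, v)
    }
    if (length(vals) > 0L) po_i <- c(po_i, mean(vals))
  }
  if (length(po_i) == 0L) stop("no subject has a defined rank-correlation pair")
  N <- nrow(ranks)
  pe_vals <- c(); pe_excl <- 0L
  for (aa in 1:(N - 1)) for (bb in (aa + 1):N) {
    v <- spearman_pair(ranks[aa, ], ranks[bb, ], method)
    if (is.na(v)) pe_excl <- pe_excl + 1L else pe_vals <- c(pe_vals, v)
  }
  if (length(pe_vals) == 0L) stop("no defined pair for the chance term")
  po <- mean(po_i); pe <- mean(pe_vals)
  pair_agreement("chance-corrected rank correlation", po, pe,
                 (po - pe) / (1 - pe),
                 excluded = list(po_pairs = po_excl, pe_pairs = pe_excl))
}

#' Side-by-side comparison of agreement methods
#'
#' Runs the generalized kappa and every applicable literature comparator
#' on one dataset and returns a single table. Cohen-based rows appear only
#' for two raters; the rank method only when ordered selections are
#' supplied.
#'
#' @inheritParams multi_kappa
#' @param ordered optional list of ordered selections (one element per
#'   rated unit, subject-major order) for the rank method; see
#'   [rank_vectors()].
#' @return a data.frame with columns `method`, `po`, `pe`, `kappa`,
#'   `excluded`, `note`.
#' @export
compare_methods <- function(data, weights = NULL, rules = NULL,
                            availability = NULL, correct = NULL,
                            ordered = NULL) {
  stopifnot(inherits(data, "classification_data"))
  rows <- list()
  add <- function(method, po, pe, kappa, excluded = 0L, note = "")
    rows[[length(rows) + 1L]] <<- data.frame(
      method = method, po = po, pe = pe, kappa = kappa,
      excluded = excluded, note = note, stringsAsFactors = FALSE)
  mk <- multi_kappa(data, weights = weights, rules = rules,
                    availability = availability, correct = correct)
  add("generalized kappa", NA_real_, NA_real_, mk$kappa)
  if (length(data$raters) == 2L) {
    ck <- kappa_cohen(data)
    add("averaged Cohen's kappa", NA_real_, NA_real_, ck$averaged,
        note = if (is.nan(ck$averaged)) "undefined category kappas" else "")
    add("pooled Cohen's kappa", ck$pooled$po, ck$pooled$pe, ck$pooled$kappa)
  } else {
    add("averaged/pooled Cohen's kappa", NA_real_, NA_real_, NA_real_,
        note = "not applicable: needs exactly two raters")
  }
  ov <- kappa_overlap(data)
  add("proportional overlap", ov$po, ov$pe, ov$kappa,
      excluded = ov$excluded$po_pairs + ov$excluded$pe_pairs)
  ic <- suppressWarnings(kappa_icc(data))
  add("chance-corrected ICC", ic$po, ic$pe, ic$kappa,
      excluded = ic$excluded$subjects)
  if (!is.null(ordered)) {
    units <- rated_units(data)
    rk <- kappa_rank(rank_vectors(ordered, data$categories),
                     vapply(units, `[[`, 0L, "subject"))
    add("chance-corrected rank correlation", rk$po, rk$pe, rk$kappa,
        excluded = rk$excluded$po_pairs + rk$excluded$pe_pairs)
  } else {
    add("chance-corrected rank correlation", NA_real_, NA_real_, NA_real_,
        note = "not applicable: no ordered classifications")
  }
  do.call(rbind, rows)
}
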