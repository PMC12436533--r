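#' Rater classification data
#'
#' Container for the binary selection indicators of a study in which `J`
#' raters may classify each of `I` subjects into one or more of `C`
#' categories. The tensor entry `selections[i, j, c]` is 1 when rater `j`
#' classified subject `i` into category `c`. An optional `rated` matrix
#' distinguishes "rated the subject but selected nothing" (a row of zeros
#' with `rated = 1`) from "did not rate the subject at all" (`rated = 0`),
#' which matters for designs with a varying number of raters.
#'
#' @param selections a binary `I x J x C` array, or a list of `J` binary
#'   `I x C` matrices (one per rater).
#' @param subjects,raters,categories identifier vectors; defaults are taken
#'   from dimnames or generated (`S1...`, `R1...`, `C1...`).
#' @param rated optional binary `I x J` matrix marking which rater rated
#'   which subject. Defaults to all ones (a fixed panel of raters). Where
#'   `rated` is 0, all selections for that (subject, rater) pair must be 0.
#' @return an object of class `classification_data` with elements
#'   `selections` (integer array), `subjects`, `raters`, `categories`,
#'   and `rated`.
#' @examples
#' x <- array(0L, dim = c(2, 2, 3))
#' x[1, , 1] <- 1         # both raters pick category 1 for subject 1
#' cd <- classification_data(x)
#' agreement_table(cd)
#' @export
classification_data <- function(selections, subjects = NULL, raters = NULL,
                                categories = NULL, rated = NULL) {
  if (is.list(selections) && !is.array(selections)) {
    mats <- lapply(selections, as.matrix)
    dims <- unique(lapply(mats, dim))
    if (length(dims) != 1L)
      stop("all per-rater matrices must share the same dimensions")
    arr <- array(0L, dim = c(dims[[1]][1], length(mats), dims[[1]][2]))
    for (j in seq_along(mats)) arr[, j, ] <- as.integer(mats[[j]])
    if (is.null(raters) && !is.null(names(selections)))
      raters <- names(selections)
    if (is.null(subjects) && !is.null(rownames(mats[[1]])))
      subjects <- rownames(mats[[1]])
    if (is.null(categories) && !is.null(colnames(mats[[1]])))
      categories <- colnames(mats[[1]])
    selections <- arr
  }
  if (!is.array(selections) || length(dim(selections)) != 3L)
    stop("'selections' must be an I x J x C array or a list of I x C matrices")
  dm <- dim(selections)
  I <- dm[1]; J <- dm[2]; C <- dm[3]
  if (I < 1L) stop("need at least one subject (I >= 1)")
  if (J < 2L) stop("agreement needs at least two raters (J >= 2)")
  if (C < 1L) stop("need at least one category (C >= 1)")
  if (!all(selections %in% c(0L, 1L)))
    stop("selection indicators must be 0 or 1 (no counts, no ranks)")
  dn <- dimnames(selections)
  subjects <- as.character(subjects %||% dn[[1]] %||% paste0("S", seq_len(I)))
  raters <- as.character(raters %||% dn[[2]] %||% paste0("R", seq_len(J)))
  categories <- as.character(categories %||% dn[[3]] %||% paste0("C", seq_len(C)))
  stopifnot(length(subjects) == I, length(raters) == J, length(categories) == C)
  if (anyDuplicated(subjects) || anyDuplicated(raters) || anyDuplicated(categories))
    stop("subject, rater and category identifiers must be unique")
  if (is.null(rated)) {
    rated <- matrix(1L, I, J)
  } else {
    rated <- matrix(as.integer(rated), I, J)
    if (!all(rated %in% c(0L, 1L))) stop("'rated' entries must be 0 or 1")
    sel_any <- apply(selections, c(1, 2), max)
    bad <- which(rated == 0L & sel_any == 1L, arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop(sprintf("selections present for unrated pair (subject %s, rater %s)",
                   subjects[bad[1, 1]], raters[bad[1, 2]]))
  }
  storage.mode(selections) <- "integer"
  dimnames(selections) <- list(subjects, raters, categories)
  dimnames(rated) <- list(subjects, raters)
  structure(
    list(selections = selections, subjects = subjects, raters = raters,
         categories = categories, rated = rated),
    class = "classification_data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.classification_data <- function(x, ...) {
  cat(sprintf("classification_data: %d subjects x %d raters x %d categories\n",
              length(x$subjects), length(x$raters), length(x$categories)))
  cat(sprintf("  selections: %d; rated units: %d of %d\n",
              sum(x$selections), sum(x$rated), length(x$rated)))
  invisible(x)
}

#' Agreement table of selection counts
#'
#' Collapses classification data over raters into the `I x C` matrix `X`
#' with entries `x_ic`, the number of raters classifying subject `i` into
#' category `c` — often called the agreement table. A plain counts matrix
#' (as printed in publications) can also be wrapped directly.
#'
#' @param x a `classification_data` object, or an `I x C` matrix of counts.
#' @param ... further arguments; for the matrix method, `J` (the fixed
#'   number of raters) and optional `subjects`/`categories` identifiers.
#' @return an `agreement_table`: list with `counts`, `subjects`,
#'   `categories`, `J` (fixed rater count or `NA` when varying), and
#'   `rated` (the `I x J` participation matrix, when known).
#' @export
agreement_table <- function(x, ...) UseMethod("agreement_table")

#' @rdname agreement_table
#' @export
agreement_table.classification_data <- function(x, ...) {
  counts <- apply(x$selections, c(1, 3), sum)
  dimnames(counts) <- list(x$subjects, x$categories)
  ji <- rowSums(x$rated)
  structure(
    list(counts = counts, subjects = x$subjects, categories = x$categories,
         J = if (all(ji == ji[1])) ji[1] else NA_integer_, rated = x$rated),
    class = "agreement_table")
}

#' @rdname agreement_table
#' @export
agreement_table.matrix <- function(x, J, subjects = NULL, categories = NULL, ...) {
  counts <- x
  storage.mode(counts) <- "integer"
  if (any(counts < 0L)) stop("counts must be non-negative")
  subjects <- as.character(subjects %||% rownames(counts) %||%
                             paste0("S", seq_len(nrow(counts))))
  categories <- as.character(categories %||% colnames(counts) %||%
                               paste0("C", seq_len(ncol(counts))))
  dimnames(counts) <- list(subjects, categories)
  structure(
    list(counts = counts, subjects = subjects, categories = categories,
         J = as.integer(J), rated = NULL),
    class = "agreement_table")
}

#' @export
print.agreement_table <- function(x, ...) {
  cat(sprintf("agreement_table: %d subjects x %d categories (J = %s)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.na(x$J)) "varying" else x$J))
  print(x$counts)
  invisible(x)
}

#' Rater availability
#'
#' Describes how many raters had the opportunity to classify each subject
#' (and, if the design demands it, each subject-category cell). Three modes
#' are supported: a fixed panel of `J` raters, a per-subject vector `j_i`,
#' or a full `I x C` matrix `j_ic`.
#'
#' @param fixed fixed number of raters `J`.
#' @param per_subject integer vector `j_i` of length `I`.
#' @param per_cell integer `I x C` matrix `j_ic`.
#' @return a `rater_availability` object.
#' @export
rater_availability <- function(fixed = NULL, per_subject = NULL, per_cell = NULL) {
  given <- c(!is.null(fixed), !is.null(per_subject), !is.null(per_cell))
  if (sum(given) != 1L)
    stop("supply exactly one of 'fixed', 'per_subject', 'per_cell'")
  if (!is.null(fixed)) {
    fixed <- as.integer(fixed)
    if (fixed < 0L) stop("availability must be non-negative")
    out <- list(mode = "fixed", J = fixed)
  } else if (!is.null(per_subject)) {
    ji <- as.integer(per_subject)
    if (any(ji < 0L)) stop("availability must be non-negative")
    out <- list(mode = "per_subject", j = ji)
  } else {
    jm <- as.matrix(per_cell)
    storage.mode(jm) <- "integer"
    if (any(jm < 0L)) stop("availability must be non-negative")
    out <- list(mode = "per_cell", jmat = jm)
  }
  structure(out, class = "rater_availability")
}

#' Availability implied by the data
#'
#' Derives per-subject availability `j_i` from the `rated` participation
#' matrix of a `classification_data` object; collapses to fixed `J` when
#' all subjects were rated by the same number of raters.
#'
#' @param data a `classification_data` object.
#' @return a `rater_availability`.
#' @export
data_availability <- function(data) {
  ji <- rowSums(data$rated)
  if (all(ji == ji[1])) rater_availability(fixed = ji[1])
  else rater_availability(per_subject = ji)
}

# Expand any availability mode to the I x C matrix j_ic.
availability_matrix <- function(availability, I, C) {
  switch(availability$mode,
    fixed = matrix(availability$J, I, C),
    per_subject = {
      if (length(availability$j) != I)
        stop("per-subject availability has length ", length(availability$j),
             " but there are ", I, " subjects")
      matrix(availability$j, I, C)
    },
    per_cell = {
      if (!all(dim(availability$jmat) == c(I, C)))
        stop("per-cell availability matrix has the wrong shape")
      availability$jmat
    })
}

#' @export
print.rater_availability <- function(x, ...) {
  cat("rater_availability:", x$mode,
      switch(x$mode, fixed = paste0("(J = ", x$J, ")"),
             per_subject = paste0("(j_i in ", min(x$j), "..", max(x$j), ")"),
             per_cell = paste0("(", nrow(x$jmat), " x ", ncol(x$jmat), ")")),
      "\n")
  invisible(x)
}

#' Consistency and paradox screening of an agreement table
#'
#' Screens an agreement table against its rater availability and returns a
#' structured list of findings: impossible counts (`x_ic` exceeding the
#' number of available raters) are errors; unused categories, categories
#' selected by every available rater for every subject (the
#' always-selected-category paradox), and categories with no rater pairs at
#' all are informational.
#'
#' @param table an `agreement_table`.
#' @param availability a `rater_availability`; defaults to the fixed `J`
#'   carried by the table.
#' @return a data.frame with columns `severity` ("error" or "info"),
#'   `code`, `category`, `subject` and `message`. Zero rows means a clean
#'   table.
#' @export
validate_ratings <- function(table, availability = NULL) {
  stopifnot(inherits(table, "agreement_table"))
  if (is.null(availability)) {
    if (is.na(table$J)) stop("varying raters: supply 'availability'")
    availability <- rater_availability(fixed = table$J)
  }
  X <- table$counts
  I <- nrow(X); C <- ncol(X)
  jm <- availability_matrix(availability, I, C)
  f <- list()
  add <- function(severity, code, category, subject, message)
    f[[length(f) + 1L]] <<- data.frame(
      severity = severity, code = code, category = category,
      subject = subject, message = message, stringsAsFactors = FALSE)
  over <- which(X > jm, arr.ind = TRUE)
  for (r in seq_len(nrow(over))) {
    i <- over[r, 1]; c <- over[r, 2]
    add("error", "impossible_count", table$categories[c], table$subjects[i],
        sprintf("x = %d selections but only %d raters available", X[i, c], jm[i, c]))
  }
  for (c in seq_len(C)) {
    if (sum(X[, c]) == 0L)
      add("info", "unused_category", table$categories[c], NA_character_,
          "category never selected; it contributes nothing to kappa")
    else if (all(X[, c] == jm[, c]) && sum(jm[, c]) > 0L)
      add("info", "always_selected", table$categories[c], NA_character_,
          paste("category selected by every available rater for every subject;",
                "always-selected-category paradox (zero contribution to kappa)"))
    if (sum(jm[, c] * (jm[, c] - 1L)) == 0L)
      add("info", "no_pairs", table$categories[c], NA_character_,
          "no rater pairs available; category will be skipped")
  }
  if (length(f) == 0L)
    return(data.frame(severity = character(), code = character(),
                      category = character(), subject = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, f)
}
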