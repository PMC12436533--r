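#' Read classification data from a long-format CSV
#'
#' The long format has one row per selection: columns `subject`, `rater`,
#' `category` (names configurable). An optional roster CSV with columns
#' `subject`, `rater` lists every (subject, rater) pair that was actually
#' rated, so that "rated but selected nothing" is distinguishable from
#' "did not rate". Without a roster, every listed rater is assumed to have
#' rated every listed subject.
#'
#' Subjects, raters and categories are ordered by first appearance unless
#' explicit orderings are supplied. Duplicate selection rows collapse to a
#' single indicator with a warning.
#'
#' @param path CSV file of selections.
#' @param roster optional CSV file of rated (subject, rater) pairs.
#' @param columns named character vector mapping the roles `subject`,
#'   `rater`, `category` to column names in the file.
#' @param subjects,raters,categories optional explicit orderings (and, for
#'   subjects/raters absent from the file, padding of the universe).
#' @return a `classification_data`.
#' @export
read_ratings_long <- function(path, roster = NULL,
                              columns = c(subject = "subject", rater = "rater",
                                          category = "category"),
                              subjects = NULL, raters = NULL, categories = NULL) {
  df <- utils::read.csv(path, colClasses = "character")
  for (role in c("subject", "rater", "category"))
    if (!columns[[role]] %in% names(df))
      stop(sprintf("column '%s' (role: %s) not found in %s",
                   columns[[role]], role, path))
  sel <- data.frame(subject = df[[columns[["subject"]]]],
                    rater = df[[columns[["rater"]]]],
                    category = df[[columns[["category"]]]],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(sel)) {
    warning("duplicate selection rows collapsed to single indicators")
    sel <- unique(sel)
  }
  ros <- NULL
  if (!is.null(roster)) {
    rdf <- utils::read.csv(roster, colClasses = "character")
    for (role in c("subject", "rater"))
      if (!columns[[role]] %in% names(rdf))
        stop(sprintf("column '%s' (role: %s) not found in %s",
                     columns[[role]], role, roster))
    ros <- unique(data.frame(subject = rdf[[columns[["subject"]]]],
                             rater = rdf[[columns[["rater"]]]],
                             stringsAsFactors = FALSE))
    missing <- !paste(sel$subject, sel$rater) %in% paste(ros$subject, ros$rater)
    if (any(missing))
      stop(sprintf("selection rows for pairs absent from the roster, e.g. (%s, %s)",
                   sel$subject[missing][1], sel$rater[missing][1]))
  }
  first_seen <- function(given, observed) {
    if (!is.null(given)) {
      extra <- setdiff(observed, given)
      if (length(extra) > 0L)
        stop("identifiers in file but not in supplied ordering: ",
             paste(extra, collapse = ", "))
      as.character(given)
    } else unique(observed)
  }
  subjects <- first_seen(subjects, c(ros$subject, sel$subject))
  raters <- first_seen(raters, c(ros$rater, sel$rater))
  categories <- first_seen(categories, sel$category)
  if (length(categories) == 0L) categories <- "C1"
  I <- length(subjects); J <- length(raters); C <- length(categories)
  arr <- array(0L, dim = c(I, J, C))
  if (nrow(sel) > 0L)
    arr[cbind(match(sel$subject, subjects), match(sel$rater, raters),
              match(sel$category, categories))] <- 1L
  rated <- matrix(if (is.null(ros)) 1L else 0L, I, J)
  if (!is.null(ros))
    rated[cbind(match(ros$subject, subjects), match(ros$rater, raters))] <- 1L
  classification_data(arr, subjects = subjects, raters = raters,
                      categories = categories, rated = rated)
}

#' Write classification data as a long-format CSV
#'
#' Inverse of [read_ratings_long()]: one row per selection, plus (when
#' `roster` is given) a roster of rated pairs so that unrated pairs and
#' empty ratings survive a round-trip.
#'
#' @param data a `classification_data`.
#' @param path output CSV path for the selections.
#' @param roster optional output path for the rated-pairs roster.
#' @return `path`, invisibly.
#' @export
write_ratings_long <- function(data, path, roster = NULL) {
  idx <- which(data$selections == 1L, arr.ind = TRUE)
  df <- data.frame(subject = data$subjects[idx[, 1]],
                   rater = data$raters[idx[, 2]],
                   category = data$categories[idx[, 3]],
                   stringsAsFactors = FALSE)
  df <- df[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(roster)) {
    ri <- which(data$rated == 1L, arr.ind = TRUE)
    rdf <- data.frame(subject = data$subjects[ri[, 1]],
                      rater = data$raters[ri[, 2]], stringsAsFactors = FALSE)
    rdf <- rdf[order(ri[, 1], ri[, 2]), , drop = FALSE]
    utils::write.csv(rdf, roster, row.names = FALSE)
  }
  invisible(path)
}

#' Read classification data from wide binary matrices
#'
#' The wide format stacks one binary block per rater: columns `subject`,
#' `rater`, then one 0/1 column per category. An all-zero row records that
#' the rater rated the subject but selected nothing.
#'
#' @param path CSV file.
#' @param columns named character vector giving the `subject` and `rater`
#'   column names; all remaining columns are taken as categories.
#' @return a `classification_data`.
#' @export
read_ratings_wide <- function(path, columns = c(subject = "subject", rater = "rater")) {
  df <- utils::read.csv(path, check.names = FALSE)
  for (role in c("subject", "rater"))
    if (!columns[[role]] %in% names(df))
      stop(sprintf("column '%s' (role: %s) not found in %s",
                   columns[[role]], role, path))
  cat_cols <- setdiff(names(df), columns)
  if (length(cat_cols) == 0L) stop("no category columns found")
  subjects <- unique(as.character(df[[columns[["subject"]]]]))
  raters <- unique(as.character(df[[columns[["rater"]]]]))
  arr <- array(0L, dim = c(length(subjects), length(raters), length(cat_cols)))
  rated <- matrix(0L, length(subjects), length(raters))
  for (r in seq_len(nrow(df))) {
    i <- match(as.character(df[[columns[["subject"]]]][r]), subjects)
    j <- match(as.character(df[[columns[["rater"]]]][r]), raters)
    v <- as.integer(df[r, cat_cols])
    if (!all(v %in% c(0L, 1L))) stop("wide-format cells must be 0 or 1")
    arr[i, j, ] <- pmax(arr[i, j, ], v)
    rated[i, j] <- 1L
  }
  classification_data(arr, subjects = subjects, raters = raters,
                      categories = cat_cols, rated = rated)
}

#' Read hierarchy rules from JSON or YAML
#'
#' The file maps category identifiers to selectability expressions over
#' other categories, e.g. `{"4": "1 and 3", "5": "4"}`. See
#' [hierarchy_rules()] for the expression grammar.
#'
#' @param path a `.json`, `.yaml` or `.yml` file.
#' @return a `hierarchy_rules` object.
#' @export
read_hierarchy <- function(path) {
  ext <- tolower(tools::file_ext(path))
  rules <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    yaml = , yml = yaml::read_yaml(path),
    stop("unsupported rules format: .", ext, " (use JSON or YAML)"))
  hierarchy_rules(as.list(rules))
}

#' Read category weights or scores from CSV
#'
#' Expects columns `category` and either `weight` or `score`.
#'
#' @param path CSV file.
#' @return a named numeric vector (names are category identifiers), with
#'   attribute `kind` set to `"weight"` or `"score"`.
#' @export
read_category_values <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "numeric"))
  if (!"category" %in% names(df)) stop("column 'category' not found in ", path)
  kind <- intersect(c("weight", "score"), names(df))
  if (length(kind) == 0L) stop("need a 'weight' or 'score' column in ", path)
  v <- df[[kind[1]]]
  names(v) <- df$category
  attr(v, "kind") <- kind[1]
  v
}
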