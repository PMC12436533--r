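#' Hierarchy rules for category selectability
#'
#' In hierarchical codebooks a (sub)category can only be ticked when some
#' condition on the rater's other selections holds — e.g. a child category
#' requires its parent, or an item is only offered when another item was
#' *not* chosen. Each rule is a boolean expression over category
#' identifiers with the grammar
#'
#' ```
#' expr := atom | "(" expr ")" | expr "and" expr | expr "or" expr | "not" expr
#' ```
#'
#' where an atom names a category and means "that category was selected by
#' this rater". Categories without a rule are main categories, always
#' selectable. A rule may never reference its own category and the
#' dependency graph must be acyclic.
#'
#' @param rules named list (or named character vector): category id ->
#'   expression string.
#' @return a `hierarchy_rules` object: parsed expressions plus a
#'   topological evaluation order.
#' @examples
#' hierarchy_rules(list(`4` = "1 and 3", `5` = "4"))
#' @export
hierarchy_rules <- function(rules) {
  rules <- as.list(rules)
  if (length(rules) > 0 && is.null(names(rules)))
    stop("rules must be named by category identifier")
  parsed <- lapply(rules, parse_rule)
  deps <- lapply(parsed, rule_atoms)
  for (cat in names(parsed))
    if (cat %in% deps[[cat]])
      stop(sprintf("rule for category '%s' references itself", cat))
  order <- topo_order(deps)
  structure(list(rules = parsed, sources = lapply(rules, as.character),
                 deps = deps, order = order),
            class = "hierarchy_rules")
}

#' @export
print.hierarchy_rules <- function(x, ...) {
  if (length(x$rules) == 0L) {
    cat("hierarchy_rules: none (all categories are main categories)\n")
  } else {
    cat("hierarchy_rules:\n")
    for (cat in names(x$sources))
      cat(sprintf("  %s <- %s\n", cat, x$sources[[cat]]))
  }
  invisible(x)
}

# --- expression parser -------------------------------------------------
# Tokens: "(", ")", keywords and/or/not (case-insensitive), atoms (any other
# run of non-space, non-paren characters; or a single- or double-quoted
# string for identifiers containing spaces or keywords).

tokenize_rule <- function(src) {
  chars <- strsplit(src, "")[[1]]
  toks <- list(); i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch); i <- i + 1L; next
    }
    if (ch %in% c("'", '"')) {
      j <- i + 1L
      while (j <= n && chars[j] != ch) j <- j + 1L
      if (j > n) stop("unterminated quoted identifier in rule: ", src)
      toks[[length(toks) + 1L]] <-
        list(type = "atom", value = paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + 1L; next
    }
    j <- i
    while (j <= n && !grepl("^[\\s()'\"]$", chars[j], perl = TRUE)) j <- j + 1L
    word <- paste(chars[i:(j - 1L)], collapse = "")
    lw <- tolower(word)
    if (lw %in% c("and", "or", "not"))
      toks[[length(toks) + 1L]] <- list(type = lw)
    else
      toks[[length(toks) + 1L]] <- list(type = "atom", value = word)
    i <- j
  }
  toks
}

parse_rule <- function(src) {
  src <- as.character(src)
  toks <- tokenize_rule(src)
  if (length(toks) == 0L) stop("empty rule expression")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]]$type else NA_character_
  take <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  parse_or <- function() {
    node <- parse_and()
    while (!is.na(peek()) && peek() == "or") {
      take()
      node <- list(op = "or", args = list(node, parse_and()))
    }
    node
  }
  parse_and <- function() {
    node <- parse_not()
    while (!is.na(peek()) && peek() == "and") {
      take()
      node <- list(op = "and", args = list(node, parse_not()))
    }
    node
  }
  parse_not <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of rule: ", src)
    if (t == "not") { take(); return(list(op = "not", args = list(parse_not()))) }
    if (t == "(") {
      take()
      node <- parse_or()
      if (is.na(peek()) || peek() != ")") stop("missing ')' in rule: ", src)
      take()
      return(node)
    }
    if (t == "atom") return(list(op = "atom", id = take()$value))
    stop("unexpected token '", t, "' in rule: ", src)
  }
  node <- parse_or()
  if (pos <= length(toks))
    stop("trailing tokens in rule: ", src)
  node
}

rule_atoms <- function(node) {
  if (node$op == "atom") return(node$id)
  unique(unlist(lapply(node$args, rule_atoms)))
}

eval_rule <- function(node, selected) {
  switch(node$op,
    atom = {
      if (!node$id %in% names(selected))
        stop("rule references unknown category '", node$id, "'")
      selected[[node$id]]
    },
    not = !eval_rule(node$args[[1]], selected),
    and = eval_rule(node$args[[1]], selected) && eval_rule(node$args[[2]], selected),
    or = eval_rule(node$args[[1]], selected) || eval_rule(node$args[[2]], selected))
}

topo_order <- function(deps) {
  ruled <- names(deps)
  order <- character(0)
  marked <- setdiff(unique(unlist(deps)), ruled)  # main categories resolve first
  remaining <- ruled
  while (length(remaining) > 0L) {
    ready <- remaining[vapply(remaining, function(cat)
      all(deps[[cat]] %in% c(marked, order)), logical(1))]
    if (length(ready) == 0L)
      stop("cyclic hierarchy rules among: ", paste(remaining, collapse = ", "))
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  order
}

#' Possible-classifications matrix S
#'
#' For each subject `i` and category `c`, `s_ic` counts the raters (among
#' those who rated subject `i`) whose own selections satisfy category `c`'s
#' selectability rule — the number of *possible* classifications of subject
#' `i` into `c`. Main categories get `s_ic = j_ic`, the full availability.
#' A simple parent-child rule reproduces `s_ic' = x_ip`: the child was
#' selectable exactly for the raters who ticked the parent.
#'
#' @param data a `classification_data`.
#' @param rules a `hierarchy_rules` object (or a bare named list of
#'   expression strings).
#' @param availability optional `rater_availability`; defaults to the
#'   availability implied by the data's `rated` matrix.
#' @return a `possible_classifications` object: the `s` matrix, the
#'   availability matrix `j` it was bounded by, and the rule sources.
#' @export
possible_matrix <- function(data, rules, availability = NULL) {
  stopifnot(inherits(data, "classification_data"))
  if (!inherits(rules, "hierarchy_rules")) rules <- hierarchy_rules(rules)
  unknown <- setdiff(unique(c(names(rules$rules), unlist(rules$deps))),
                     data$categories)
  if (length(unknown) > 0L)
    stop("rules reference unknown categories: ", paste(unknown, collapse = ", "))
  availability <- availability %||% data_availability(data)
  I <- length(data$subjects); J <- length(data$raters); C <- length(data$categories)
  jm <- availability_matrix(availability, I, C)
  s <- jm
  for (cat in names(rules$rules)) {
    c_idx <- match(cat, data$categories)
    for (i in seq_len(I)) {
      cnt <- 0L
      for (j in seq_len(J)) {
        if (data$rated[i, j] == 0L) next
        selected <- as.logical(data$selections[i, j, ])
        names(selected) <- data$categories
        if (eval_rule(rules$rules[[cat]], selected)) cnt <- cnt + 1L
      }
      s[i, c_idx] <- cnt
    }
  }
  x <- apply(data$selections, c(1, 3), sum)
  if (any(x > s))
    warning("selections exceed possible classifications somewhere: ",
            "the data violate the hierarchy rules")
  dimnames(s) <- list(data$subjects, data$categories)
  structure(list(s = s, j = jm, subjects = data$subjects,
                 categories = data$categories,
                 sources = rules$sources),
            class = "possible_classifications")
}

#' @export
print.possible_classifications <- function(x, ...) {
  cat("possible_classifications (s_ic):\n")
  print(x$s)
  invisible(x)
}

#' Hierarchy scale factors
#'
#' The per-category scale factor `phi_c = sum_i s_ic / sum_i j_ic`
#' contrasts a category's possible classifications with the availability a
#' main category enjoys; with a fixed panel the denominator is `I * J`.
#' Main categories always have `phi_c = 1`; a category that was never
#' selectable gets `phi_c = 0` and drops out of the pooled kappa.
#'
#' @param possible a `possible_classifications` object.
#' @return named numeric vector of scale factors in `[0, 1]`.
#' @export
scale_factors <- function(possible) {
  stopifnot(inherits(possible, "possible_classifications"))
  denom <- colSums(possible$j)
  phi <- ifelse(denom > 0, colSums(possible$s) / denom, 0)
  names(phi) <- possible$categories
  phi
}

#' Checkbox-grading weights from item scores
#'
#' Maps per-category scores (e.g. partial grades attached to feedback
#' items) to weights via
#' `w_c = (|score_c| + max_k |score_k|) / (2 * max_k |score_k|)`,
#' so a score-neutral item still weighs 0.5 (its selection carries
#' feedback) and the largest-scoring item weighs 1. Signs are ignored:
#' a deduction matters as much as a bonus of the same size.
#'
#' @param scores numeric vector of per-category scores (may be named).
#' @return named numeric weight vector in `[0.5, 1]`.
#' @examples
#' checkbox_weights(c(1, 0, 1.5, 0.5, -0.5))
#' @export
checkbox_weights <- function(scores) {
  a <- abs(as.numeric(scores))
  m <- max(a)
  if (m == 0) stop("all scores are zero; use uniform weights instead")
  w <- (a + m) / (2 * m)
  names(w) <- names(scores)
  w
}
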