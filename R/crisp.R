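#' Crisp predicate
#'
#' A single comparison `feature op value`. Numeric features admit
#' `<, >, <=, >=`; categorical features admit `==, !=`.
#'
#' @param feature feature name.
#' @param op comparison operator (ASCII token).
#' @param value numeric threshold or category label, matching the feature kind.
#' @return an object of class `fdx_predicate`.
#' @export
crisp_predicate <- function(feature, op, value) {
  stopifnot(is.character(feature), length(feature) == 1L)
  if (!op %in% c(NUMERIC_OPS, CATEGORICAL_OPS))
    stop_fdx("unknown operator '%s'", op)
  if (op %in% NUMERIC_OPS && !is.numeric(value))
    stop_fdx("operator '%s' needs a numeric value", op)
  if (op %in% CATEGORICAL_OPS && !is.character(value))
    stop_fdx("operator '%s' needs a categorical value", op)
  structure(list(feature = feature, op = op, value = value),
            class = "fdx_predicate")
}

#' Crisp rule
#'
#' A conjunction of predicates with one consequent class and a non-negative
#' relevance weight; an empty antecedent is always true.
#'
#' @param predicates list of [crisp_predicate()] (at most one per categorical
#'   feature).
#' @param consequent predicted class value.
#' @param weight non-negative relevance weight.
#' @return an object of class `fdx_rule`.
#' @export
crisp_rule <- function(predicates, consequent, weight = 1) {
  stopifnot(is.list(predicates), weight >= 0)
  cat_feats <- vapply(predicates, function(p)
    if (p$op %in% CATEGORICAL_OPS) p$feature else NA_character_, character(1))
  cat_feats <- cat_feats[!is.na(cat_feats)]
  if (anyDuplicated(cat_feats))
    stop_fdx("a rule may use each categorical feature at most once")
  structure(list(predicates = predicates,
                 consequent = as.character(consequent),
                 weight = as.numeric(weight)),
            class = "fdx_rule")
}

#' Weighted-DNF crisp rule base
#'
#' An ordered set of crisp rules, each predicting one of the known classes.
#' The disjunction is expected (not assumed) to be mutually exclusive; see
#' [check_mutual_exclusivity()].
#'
#' @param rules list of [crisp_rule()].
#' @param classes character vector of all class values.
#' @return an object of class `fdx_crb`.
#' @export
crisp_rulebase <- function(rules, classes) {
  stopifnot(is.list(rules))
  classes <- as.character(classes)
  cons <- vapply(rules, function(r) r$consequent, character(1))
  if (length(rules) > 0L && !all(cons %in% classes))
    stop_fdx("rule consequent(s) outside the declared classes: %s",
             paste(setdiff(cons, classes), collapse = ", "))
  structure(list(rules = rules, classes = classes), class = "fdx_crb")
}

#' Evaluate a crisp predicate on one record
#'
#' @param p an [crisp_predicate()].
#' @param item named list or one-row data.frame covering `p$feature`.
#' @return logical.
#' @export
evaluate_predicate <- function(p, item) {
  v <- item[[p$feature]]
  if (is.null(v)) stop_fdx("item has no value for feature '%s'", p$feature)
  if (p$op %in% NUMERIC_OPS && !is.numeric(v))
    stop_fdx("feature '%s': numeric operator on non-numeric value", p$feature)
  if (p$op %in% CATEGORICAL_OPS && is.numeric(v))
    stop_fdx("feature '%s': categorical operator on numeric value", p$feature)
  switch(p$op,
         "<"  = v <  p$value,
         ">"  = v >  p$value,
         "<=" = v <= p$value,
         ">=" = v >= p$value,
         "==" = v == p$value,
         "!=" = v != p$value)
}

#' Fire a crisp rule on one record
#'
#' True iff every antecedent predicate holds; a rule with no predicates fires
#' on every record.
#'
#' @param r a [crisp_rule()].
#' @param item named list or one-row data.frame.
#' @return logical.
#' @export
fire_rule <- function(r, item) {
  for (p in r$predicates) if (!evaluate_predicate(p, item)) return(FALSE)
  TRUE
}

# Vectorised firing over the rows of a data.frame.
fire_rule_vec <- function(r, data) {
  fired <- rep(TRUE, nrow(data))
  for (p in r$predicates) {
    v <- data[[p$feature]]
    if (is.null(v)) stop_fdx("data has no column '%s'", p$feature)
    fired <- fired & switch(p$op,
                            "<"  = v <  p$value,
                            ">"  = v >  p$value,
                            "<=" = v <= p$value,
                            ">=" = v >= p$value,
                            "==" = v == p$value,
                            "!=" = v != p$value)
  }
  fired
}

#' Classify records with a crisp rule base
#'
#' If exactly one rule fires its consequent is returned. If several fire the
#' highest-weight rule wins, ties broken by longest antecedent then rule
#' order. If none fires the result is `NA` (abstention).
#'
#' @param rb an [crisp_rulebase()].
#' @param newdata a data.frame (or single named list) of records.
#' @return character vector of class values, `NA` for abstentions.
#' @export
classify_crisp <- function(rb, newdata) {
  stopifnot(inherits(rb, "fdx_crb"))
  if (!is.data.frame(newdata)) newdata <- as.data.frame(newdata)
  n <- nrow(newdata)
  if (length(rb$rules) == 0L) return(rep(NA_character_, n))
  fired <- vapply(rb$rules, fire_rule_vec, logical(n), data = newdata)
  fired <- matrix(fired, nrow = n)
  wts <- vapply(rb$rules, `[[`, numeric(1), "weight")
  lens <- vapply(rb$rules, function(r) length(r$predicates), integer(1))
  # lexicographic key: weight desc, antecedent length desc, rule order asc
  ord <- order(-wts, -lens, seq_along(rb$rules))
  out <- rep(NA_character_, n)
  cons <- vapply(rb$rules, `[[`, character(1), "consequent")
  for (j in ord) {
    hit <- is.na(out) & fired[, j]
    out[hit] <- cons[j]
  }
  out
}

#' Rule coverage
#'
#' Number of dataset items on which the rule fires and whose class equals the
#' rule's consequent (the correctly classified matching items).
#'
#' @param r a [crisp_rule()].
#' @param ds an [fdx_dataset()].
#' @return integer count.
#' @export
rule_coverage <- function(r, ds) {
  stopifnot(inherits(ds, "fdx_dataset"))
  fired <- fire_rule_vec(r, ds$data)
  sum(fired & ds$data[[ds$class]] == r$consequent)
}

#' Rule confidence
#'
#' Fraction of matching items whose class equals the rule's consequent;
#' defined as 0 for a rule that matches no item.
#'
#' @inheritParams rule_coverage
#' @return number in `[0, 1]`.
#' @export
rule_confidence <- function(r, ds) {
  stopifnot(inherits(ds, "fdx_dataset"))
  fired <- fire_rule_vec(r, ds$data)
  nf <- sum(fired)
  if (nf == 0L) return(0)
  sum(fired & ds$data[[ds$class]] == r$consequent) / nf
}

#' Check mutual exclusivity of a rule base
#'
#' A weighted-DNF base is mutually exclusive on a dataset when no item fires
#' two or more rules.
#'
#' @param rb an [crisp_rulebase()].
#' @param ds an [fdx_dataset()].
#' @return list with `exclusive` (logical) and `violations` (item indices
#'   firing more than one rule).
#' @export
check_mutual_exclusivity <- function(rb, ds) {
  stopifnot(inherits(rb, "fdx_crb"), inherits(ds, "fdx_dataset"))
  n <- nrow(ds$data)
  counts <- integer(n)
  for (r in rb$rules) counts <- counts + fire_rule_vec(r, ds$data)
  viol <- which(counts >= 2L)
  list(exclusive = length(viol) == 0L, violations = viol)
}

#' @export
format.fdx_predicate <- function(x, ...) {
  val <- if (is.numeric(x$value)) format(x$value) else x$value
  sprintf("%s %s %s", x$feature, x$op, val)
}

#' @export
format.fdx_rule <- function(x, ...) {
  lhs <- if (length(x$predicates) == 0L) "TRUE"
         else paste(vapply(x$predicates, format, character(1)), collapse = " and ")
  sprintf("if %s then %s (%g)", lhs, x$consequent, x$weight)
}

#' @export
print.fdx_rule <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' @export
print.fdx_crb <- function(x, ...) {
  cat(sprintf("Crisp rule base: %d rule(s), classes {%s}\n",
              length(x$rules), paste(x$classes, collapse = ", ")))
  for (i in seq_along(x$rules))
    cat(sprintf("  [%d] %s\n", i, format(x$rules[[i]])))
  invisible(x)
}

#' Serialise a crisp rule base to JSON
#'
#' Operators are written as the ASCII tokens `<, >, <=, >=, ==, !=`.
#'
#' @param rb an [crisp_rulebase()].
#' @param path optional file path; when omitted the JSON text is returned.
#' @return JSON string (invisibly when written to file).
#' @export
crb_to_json <- function(rb, path = NULL) {
  stopifnot(inherits(rb, "fdx_crb"))
  obj <- list(
    classes = rb$classes,
    rules = lapply(rb$rules, function(r) list(
      predicates = lapply(r$predicates, function(p)
        list(feature = p$feature, op = p$op, value = p$value)),
      class = r$consequent,
      weight = r$weight)))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' Deserialise a crisp rule base from JSON
#'
#' @param text_or_path JSON text or a path to a JSON file.
#' @return an [crisp_rulebase()].
#' @export
crb_from_json <- function(text_or_path) {
  obj <- jsonlite::fromJSON(text_or_path, simplifyVector = FALSE)
  rules <- lapply(obj$rules, function(r) {
    preds <- lapply(r$predicates, function(p) {
      val <- if (p$op %in% NUMERIC_OPS) as.numeric(p$value) else as.character(p$value)
      crisp_predicate(p$feature, p$op, val)
    })
    crisp_rule(preds, r$class, r$weight)
  })
  crisp_rulebase(rules, unlist(obj$classes))
}
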