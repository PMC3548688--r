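# Stage 3: merge same-feature numeric predicates so every rule satisfies the
# fuzzifiable forms — a single upper bound (x < v), a single lower bound
# (x > v), or a non-empty interval (x < v1 AND x > v2 with v1 > v2).
# Categorical predicates are never touched: a conjunctive rule cannot
# meaningfully constrain one categorical feature twice.

is_lower_op <- function(op) op %in% c(">", ">=")
is_upper_op <- function(op) op %in% c("<", "<=")

#' Are two numeric comparison operators comparable (mergeable)?
#'
#' Two operators are comparable when they bound the same side: both lower
#' bounds (`>`, `>=`) or both upper bounds (`<`, `<=`), in any order and
#' including same-operator pairs. Opposite-direction pairs form an interval
#' and are not merged.
#'
#' @param op1,op2 numeric operator tokens.
#' @return logical.
#' @export
comparable <- function(op1, op2) {
  if (!op1 %in% NUMERIC_OPS || !op2 %in% NUMERIC_OPS)
    stop_fdx("comparable() is defined for numeric operators only")
  (is_lower_op(op1) && is_lower_op(op2)) ||
    (is_upper_op(op1) && is_upper_op(op2))
}

#' Merge two comparable predicates on the same feature
#'
#' Two lower bounds collapse to the strict predicate `x > max(v1, v2)`; two
#' upper bounds to `x < min(v1, v2)`. The merged operator is strict even when
#' the surviving source predicate was not: the crisp boundary is discharged
#' at fuzzification anyway.
#'
#' @param p1,p2 [crisp_predicate()]s on the same feature with comparable
#'   operators.
#' @return a single [crisp_predicate()].
#' @export
merge_pair <- function(p1, p2) {
  if (p1$feature != p2$feature)
    stop_fdx("merge_pair: predicates on different features (%s, %s)",
             p1$feature, p2$feature)
  if (!comparable(p1$op, p2$op))
    stop_fdx("merge_pair: operators '%s' and '%s' are not comparable",
             p1$op, p2$op)
  if (is_lower_op(p1$op))
    crisp_predicate(p1$feature, ">", max(p1$value, p2$value))
  else
    crisp_predicate(p1$feature, "<", min(p1$value, p2$value))
}

#' Reduce one rule to fuzzifiable form
#'
#' Iterates [merge_pair()] to its fixed point: after reduction each numeric
#' feature retains at most one lower-bound and one upper-bound predicate.
#' When both survive they must describe a non-empty interval (upper bound
#' strictly above lower bound), otherwise the rule is rejected as
#' contradictory. Categorical predicates, weight and consequent pass through
#' unchanged; predicate order is preserved (the first occurrence of a
#' feature's bound keeps its position).
#'
#' @param r a [crisp_rule()].
#' @return a [crisp_rule()] whose every numeric feature matches one of the
#'   fuzzifiable forms.
#' @export
reduce_rule <- function(r) {
  keep <- list()       # output predicates in order
  slot <- list()       # feature -> list(lower = idx in keep, upper = idx)
  same_op_merge <- FALSE
  for (p in r$predicates) {
    if (p$op %in% CATEGORICAL_OPS) {
      keep[[length(keep) + 1L]] <- p
      next
    }
    side <- if (is_lower_op(p$op)) "lower" else "upper"
    s <- slot[[p$feature]] %||% list()
    if (is.null(s[[side]])) {
      keep[[length(keep) + 1L]] <- p
      s[[side]] <- length(keep)
      slot[[p$feature]] <- s
    } else {
      if (keep[[s[[side]]]]$op == p$op) same_op_merge <- TRUE
      keep[[s[[side]]]] <- merge_pair(keep[[s[[side]]]], p)
    }
  }
  for (feat in names(slot)) {
    s <- slot[[feat]]
    if (!is.null(s$lower) && !is.null(s$upper)) {
      lo <- keep[[s$lower]]$value
      hi <- keep[[s$upper]]$value
      if (hi <= lo)
        stop_fdx(paste0("rule '%s': contradictory bounds on '%s' ",
                        "(upper %g <= lower %g leaves an empty interval)"),
                 format(r), feat, hi, lo)
    }
  }
  if (same_op_merge)
    message(sprintf(
      "reduction merged a same-operator predicate pair (extended comparability) in rule: %s",
      format(r)))
  crisp_rule(keep, r$consequent, r$weight)
}

#' Is a rule fuzzifiable?
#'
#' True iff every numeric feature appears in at most two predicates forming a
#' lone upper bound, a lone lower bound, or a non-empty two-sided interval
#' (upper threshold strictly greater than the lower one). Boundaries are
#' classified by direction; strict and non-strict variants count alike since
#' crisp boundaries are discharged at fuzzification.
#'
#' @param r a [crisp_rule()].
#' @return logical.
#' @export
is_fuzzifiable <- function(r) {
  num <- Filter(function(p) p$op %in% NUMERIC_OPS, r$predicates)
  if (length(num) == 0L) return(TRUE)
  feats <- vapply(num, `[[`, character(1), "feature")
  for (f in unique(feats)) {
    ps <- num[feats == f]
    if (length(ps) > 2L) return(FALSE)
    lower <- Filter(function(p) is_lower_op(p$op), ps)
    upper <- Filter(function(p) is_upper_op(p$op), ps)
    if (length(lower) > 1L || length(upper) > 1L) return(FALSE)
    if (length(lower) == 1L && length(upper) == 1L &&
        upper[[1]]$value <= lower[[1]]$value) return(FALSE)
  }
  TRUE
}

#' Reduce every rule of a base
#'
#' Applies [reduce_rule()] to each rule; the rule count is preserved and a
#' contradictory rule aborts the reduction naming the offender.
#'
#' @param rb an [crisp_rulebase()].
#' @return an [crisp_rulebase()] whose rules all pass [is_fuzzifiable()].
#' @export
reduce_rulebase <- function(rb) {
  stopifnot(inherits(rb, "fdx_crb"))
  rules <- vector("list", length(rb$rules))
  for (i in seq_along(rb$rules)) {
    rules[[i]] <- tryCatch(reduce_rule(rb$rules[[i]]), error = function(e)
      stop_fdx("reduction failed at rule %d: %s", i, conditionMessage(e)))
  }
  crisp_rulebase(rules, rb$classes)
}
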