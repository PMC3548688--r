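# Stage 2: rank rules by a pluggable usefulness criterion and keep the n best,
# guaranteeing at least one rule per represented class. Selecting rules also
# implicitly selects features: only features used by the surviving rules reach
# the fuzzification stage.

rule_stats <- function(rb, ds) {
  data.frame(
    idx = seq_along(rb$rules),
    confidence = vapply(rb$rules, rule_confidence, numeric(1), ds = ds),
    coverage = vapply(rb$rules, rule_coverage, numeric(1), ds = ds),
    length = vapply(rb$rules, function(r) length(r$predicates), integer(1)),
    matched = vapply(rb$rules, function(r) sum(fire_rule_vec(r, ds$data)),
                     numeric(1)),
    class = vapply(rb$rules, `[[`, character(1), "consequent"))
}

#' Rank rules by confidence (most-confident criterion)
#'
#' Orders rules by descending confidence on the dataset; ties prefer the
#' longer antecedent, then higher coverage, then original rule order. The
#' rationale: a rule confident on the training data should stay confident on
#' exchangeable test data.
#'
#' @param rb an [crisp_rulebase()].
#' @param ds an [fdx_dataset()] (typically the training fold).
#' @return integer vector of rule indices, best first.
#' @export
rank_most_confident <- function(rb, ds) {
  st <- rule_stats(rb, ds)
  st$idx[order(-st$confidence, -st$length, -st$coverage, st$idx)]
}

#' Rank rules by antecedent length (longest-match criterion)
#'
#' Orders rules that match at least one item by descending antecedent length
#' (a longer left-hand side carries richer information); ties prefer higher
#' coverage, then original order. Rules matching no item rank last.
#'
#' @inheritParams rank_most_confident
#' @return integer vector of rule indices, best first.
#' @export
rank_longest_match <- function(rb, ds) {
  st <- rule_stats(rb, ds)
  st$no_match <- st$matched == 0
  st$idx[order(st$no_match, -st$length, -st$coverage, st$idx)]
}

#' Select the n most useful rules
#'
#' Keeps exactly `n` rules: every class that has at least one rule keeps its
#' top-ranked rule, and the remaining slots are filled walking down the
#' global ranking. Weights are preserved.
#'
#' @param rb an [crisp_rulebase()].
#' @param ds an [fdx_dataset()] used to compute the ranking.
#' @param n number of rules to keep; must be at least the number of classes
#'   holding a rule and at most the total rule count.
#' @param criterion `"most_confident"` or `"longest_match"`.
#' @return an [crisp_rulebase()] with `n` rules in ranking order.
#' @export
select_rules <- function(rb, ds, n,
                         criterion = c("most_confident", "longest_match")) {
  criterion <- match.arg(criterion)
  cons <- vapply(rb$rules, `[[`, character(1), "consequent")
  represented <- unique(cons)
  if (n < length(represented))
    stop_fdx(paste0("n = %d is below the per-class minimum: every one of the ",
                    "%d represented classes keeps at least one rule"),
             n, length(represented))
  if (n > length(rb$rules))
    stop_fdx("n = %d exceeds the rule count (%d)", n, length(rb$rules))
  ranking <- switch(criterion,
                    most_confident = rank_most_confident(rb, ds),
                    longest_match = rank_longest_match(rb, ds))
  chosen <- integer(0)
  for (cl in represented) {
    top <- ranking[cons[ranking] == cl][1]
    chosen <- c(chosen, top)
  }
  for (j in ranking) {
    if (length(chosen) >= n) break
    if (!j %in% chosen) chosen <- c(chosen, j)
  }
  chosen <- ranking[ranking %in% chosen]  # ranking order
  crisp_rulebase(rb$rules[chosen], rb$classes)
}
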