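feats_fixture <- function() {
  list(x = feature_spec("x", "numeric", universe = c(0, 10)),
       y = feature_spec("y", "numeric", universe = c(0, 10)),
       col = feature_spec("col", "categorical", categories = c("red", "blue")))
}

test_that("predicate forms map to Low/Medium/High and thresholds become metadata only", {
  rb <- crisp_rulebase(list(
    crisp_rule(list(crisp_predicate("x", "<", 5)), "a", weight = 2),
    crisp_rule(list(crisp_predicate("x", ">", 6),
                    crisp_predicate("y", ">", 2),
                    crisp_predicate("y", "<", 9)), "b", weight = 3)),
    c("a", "b"))
  frb <- fuzzify_rulebase(rb, feats_fixture(), output_name = "cls")
  expect_equal(frb$rules[[1]]$predicates[[1]],
               list(variable = "x", term = "Low"))
  expect_equal(frb$rules[[2]]$predicates[[1]],
               list(variable = "x", term = "High"))
  expect_equal(frb$rules[[2]]$predicates[[2]],
               list(variable = "y", term = "Medium"))  # interval form
  expect_setequal(names(frb$variables$x$terms), c("Low", "High"))
  expect_equal(names(frb$variables$y$terms), "Medium")
  # output variable: one term per class
  expect_setequal(names(frb$variables$cls$terms), c("a", "b"))
  # only used features become variables (y, x, cls; col unused)
  expect_setequal(names(frb$variables), c("x", "y", "cls"))
})

test_that("equal forms with different thresholds share a single term across rules", {
  rb <- crisp_rulebase(list(
    crisp_rule(list(crisp_predicate("x", "<", 5)), "a", weight = 1),
    crisp_rule(list(crisp_predicate("x", "<", 8)), "b", weight = 1)),
    c("a", "b"))
  frb <- fuzzify_rulebase(rb, feats_fixture())
  expect_equal(names(frb$variables$x$terms), "Low")
  expect_equal(length(frb$variables$x$terms$Low$thresholds), 2L)
  expect_equal(frb$rules[[1]]$predicates[[1]]$term, "Low")
  expect_equal(frb$rules[[2]]$predicates[[1]]$term, "Low")
})

test_that("rule count, weights and consequents are conserved through fuzzification", {
  set.seed(91)
  for (rep in 1:10) {
    rules <- Filter(Negate(is.null), lapply(1:5, function(i)
      tryCatch(suppressMessages(reduce_rule(rand_rule(4, feats = c("x", "y")))),
               error = function(e) NULL)))
    if (length(rules) == 0) next
    rb <- crisp_rulebase(rules, c("a", "b"))
    frb <- fuzzify_rulebase(rb, feats_fixture())
    expect_equal(length(frb$rules), length(rb$rules))
    expect_equal(sort(vapply(frb$rules, `[[`, numeric(1), "weight")),
                 sort(vapply(rb$rules, `[[`, numeric(1), "weight")))
    expect_equal(vapply(frb$rules, function(r) r$consequent$term, character(1)),
                 vapply(rb$rules, `[[`, character(1), "consequent"))
    # term counts equal the census of distinct forms, never exceeding 3
    for (vn in setdiff(names(frb$variables), frb$output)) {
      forms <- unique(unlist(lapply(rb$rules, function(r) {
        ps <- Filter(function(p) p$feature == vn, r$predicates)
        if (length(ps) == 0) return(NULL)
        has_lo <- any(vapply(ps, function(p) p$op %in% c(">", ">="), logical(1)))
        has_up <- any(vapply(ps, function(p) p$op %in% c("<", "<="), logical(1)))
        if (has_lo && has_up) "Medium" else if (has_lo) "High" else "Low"
      })))
      expect_setequal(names(frb$variables[[vn]]$terms), forms)
      expect_lte(length(frb$variables[[vn]]$terms), 3L)
      expect_gte(length(frb$variables[[vn]]$terms), 1L)
    }
  }
})

test_that("categorical features get one term per assigned value; != is rejected", {
  rb <- crisp_rulebase(list(
    crisp_rule(list(crisp_predicate("col", "==", "red")), "a"),
    crisp_rule(list(crisp_predicate("col", "==", "blue")), "b")),
    c("a", "b"))
  frb <- fuzzify_rulebase(rb, feats_fixture())
  expect_setequal(names(frb$variables$col$terms), c("red", "blue"))
  rb_neq <- crisp_rulebase(list(
    crisp_rule(list(crisp_predicate("col", "!=", "red")), "a")), c("a", "b"))
  expect_error(fuzzify_rulebase(rb_neq, feats_fixture()), "!=")
})

test_that("non-fuzzifiable rules are rejected by name", {
  rb <- crisp_rulebase(list(
    crisp_rule(list(crisp_predicate("x", ">", 1),
                    crisp_predicate("x", ">", 4)), "a")), c("a", "b"))
  expect_error(fuzzify_rulebase(rb, feats_fixture()), "rule 1")
})

test_that("membership initialisation places ramps around the mean threshold", {
  rb <- crisp_rulebase(list(
    crisp_rule(list(crisp_predicate("x", "<", 5)), "a", weight = 1),
    crisp_rule(list(crisp_predicate("x", ">", 7)), "b", weight = 1)),
    c("a", "b"))
  frb <- init_membership_functions(fuzzify_rulebase(rb, feats_fixture()),
                                   overlap = 0.05)
  low <- frb$variables$x$terms$Low$mf
  expect_equal(low$u, c(4.5, 5.5))
  expect_equal(low$mu, c(1, 0))
  expect_equal(membership_degree(low, 0), 1)   # constant extension left
  expect_equal(membership_degree(low, 10), 0)  # constant extension right
  high <- frb$variables$x$terms$High$mf
  expect_equal(high$u, c(6.5, 7.5))
  expect_equal(high$mu, c(0, 1))
  # output classes become singletons at 0 and 1
  pos <- vapply(frb$variables$class$terms, function(t) t$mf$position,
                numeric(1))
  expect_equal(sort(unname(pos)), c(0, 1))
  expect_equal(anyDuplicated(pos), 0L)
})

test_that("a term generated by two thresholds is centred on their mean", {
  rb <- crisp_rulebase(list(
    crisp_rule(list(crisp_predicate("x", "<", 4)), "a", weight = 1),
    crisp_rule(list(crisp_predicate("x", "<", 6)), "b", weight = 1)),
    c("a", "b"))
  frb <- init_membership_functions(fuzzify_rulebase(rb, feats_fixture()),
                                   overlap = 0.05)
  expect_equal(frb$variables$x$terms$Low$mf$u, c(4.5, 5.5))  # centred at 5
})

test_that("the medium trapezoid rises over the lower and falls over the upper threshold", {
  rb <- crisp_rulebase(list(
    crisp_rule(list(crisp_predicate("x", ">", 2),
                    crisp_predicate("x", "<", 8)), "a")), c("a", "b"))
  frb <- init_membership_functions(fuzzify_rulebase(rb, feats_fixture()),
                                   overlap = 0.05)
  med <- frb$variables$x$terms$Medium$mf
  expect_equal(med$u, c(1.5, 2.5, 7.5, 8.5))
  expect_equal(med$mu, c(0, 1, 1, 0))
  expect_equal(membership_degree(med, 5), 1)
  expect_equal(membership_degree(med, 2), 0.5)
})

test_that("degenerate overlap is rejected", {
  rb <- crisp_rulebase(list(
    crisp_rule(list(crisp_predicate("x", "<", 5)), "a")), c("a", "b"))
  frb <- fuzzify_rulebase(rb, feats_fixture())
  expect_error(init_membership_functions(frb, overlap = 0.5), "overlap")
  expect_error(init_membership_functions(frb, overlap = 0), "overlap")
})
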