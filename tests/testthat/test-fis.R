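test_that("membership evaluation interpolates linearly and extends constantly", {
  ramp <- mf_piecewise(c(4.5, 5.5), c(1, 0))
  expect_equal(membership_degree(ramp, 5.0), 0.5)
  expect_equal(membership_degree(ramp, 4.5), 1)
  expect_equal(membership_degree(ramp, -2), 1)
  expect_equal(membership_degree(ramp, 12), 0)
  s <- mf_singleton(1)
  expect_equal(membership_degree(s, 1), 1)
  expect_equal(membership_degree(s, 0.3), 0)
  expect_error(mf_piecewise(c(2, 2), c(0, 1)), "strictly increasing")
  expect_error(mf_piecewise(c(1, 2), c(0, 1.5)), "\\[0, 1\\]")
})

test_that("rule activation combines antecedents by the t-norm and scales by weight", {
  f <- fis_fixture()
  r2 <- list(predicates = list(list(variable = "x", term = "Low"),
                               list(variable = "y", term = "High")),
             consequent = list(variable = "out", term = "a"), weight = 0.5)
  fy <- fis_fixture()
  fy$frb$variables$y <- fy$frb$variables$x
  fy$frb$variables$y$name <- "y"
  # degrees at x=5.2, y=5.2: Low=0.3, High=0.7
  expect_equal(rule_activation(r2, list(x = 5.2, y = 5.2), fy), 0.3)
  fyp <- fy; fyp$config$tnorm <- "product"
  expect_equal(rule_activation(r2, list(x = 5.2, y = 5.2), fyp), 0.21)
  fyw <- fy; fyw$config$use_rule_weights <- TRUE
  expect_equal(rule_activation(r2, list(x = 4.0, y = 6.0), fyw), 0.5)
  empty <- list(predicates = list(),
                consequent = list(variable = "out", term = "a"), weight = 1)
  expect_equal(rule_activation(empty, list(x = 0), f), 1)
  expect_error(rule_activation(r2, list(x = 1), fy), "no value")
})

test_that("singleton center-of-gravity defuzzification follows the weighted mean", {
  f <- fis_fixture()
  # x = 5.3: Low = 0.2, High = 0.8 -> cog = (0*0.2 + 1*0.8) / 1.0
  res <- infer(f, list(x = 5.3))
  expect_equal(unname(res$activations[1, ]), c(0.2, 0.8))
  expect_equal(res$defuzzified, 0.8)
  # worked micro-example: activations {0.2 on s=0, 0.6 on s=1} -> 0.75
  g <- fis_fixture(use_weights = TRUE)
  g$frb$rules[[1]]$weight <- 0.25   # Low deg 0.8 * 0.25 = 0.2
  g$frb$rules[[2]]$weight <- 3      # High deg 0.2 * 3 = 0.6
  res2 <- infer(g, list(x = 4.7))
  expect_equal(unname(res2$activations[1, ]), c(0.2, 0.6))
  expect_equal(res2$defuzzified, 0.75)
  # fully active single rule on a singleton at 1
  expect_equal(infer(f, list(x = 10))$defuzzified, 1)
})

test_that("zero total activation yields an abstention, not a value", {
  f <- fis_fixture()
  f$frb$variables$x$terms$Low$mf <- mf_piecewise(c(1, 2), c(0, 0))
  f$frb$variables$x$terms$High$mf <- mf_piecewise(c(1, 2), c(0, 0))
  res <- infer(f, list(x = 5))
  expect_true(is.na(res$defuzzified))
  cls <- classify_fuzzy(f, list(x = 5))
  expect_true(is.na(cls$class))
  expect_true(is.na(cls$chi))
})

test_that("classification picks the dominant term and normalises the confidence", {
  f <- fis_fixture()
  cls <- classify_fuzzy(f, data.frame(x = c(5.3, 4.6)))
  expect_equal(cls$class, c("b", "a"))
  expect_equal(cls$chi[1], 0.8)
  expect_equal(cls$chi[2], 0.9)
  # exact tie: defuzzified value decides (nearest singleton)
  tie <- classify_fuzzy(f, list(x = 5))          # Low = High = 0.5, cog = 0.5
  expect_equal(tie$defuzzified, 0.5)
  expect_equal(tie$class, "a")                   # equidistant -> declaration order
})

test_that("random FISs match the independent mini-engine to 1e-9", {
  set.seed(404)
  for (rep in 1:60) {
    f <- rand_fis()
    items <- as.data.frame(lapply(
      setdiff(names(f$frb$variables), "out"), function(v) runif(5, -1, 11)))
    names(items) <- setdiff(names(f$frb$variables), "out")
    got <- infer(f, items)$defuzzified
    want <- vapply(seq_len(5), function(i)
      oracle_cog(f, as.list(items[i, , drop = FALSE])), numeric(1))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("activations and confidence stay within [0,1] for weight-bounded systems", {
  set.seed(505)
  for (rep in 1:30) {
    f <- rand_fis()
    nms <- setdiff(names(f$frb$variables), "out")
    items <- as.data.frame(lapply(nms, function(v) runif(8, -1, 11)))
    names(items) <- nms
    agg <- infer(f, items)$activations
    expect_true(all(agg >= 0 & agg <= 1))
    cls <- classify_fuzzy(f, items)
    ok <- !is.na(cls$chi)
    expect_true(all(cls$chi[ok] >= 0 & cls$chi[ok] <= 1))
    # cog output bounded by the active singleton positions
    expect_true(all(is.na(cls$defuzzified) |
                      (cls$defuzzified >= 0 & cls$defuzzified <= 1)))
  }
})

test_that("mean-of-maxima and mamdani/COA defuzzification run on suitable systems", {
  f <- fis_fixture()
  f$config$defuzzifier <- "mom"
  res <- infer(f, data.frame(x = c(5.3, 4.7)))
  expect_equal(res$defuzzified, c(1, 0))  # position of the max-activation term
  # mamdani with piecewise-linear output terms and COA
  vars <- f$frb$variables
  vars$out$terms$a$mf <- mf_piecewise(c(0, 0.2, 0.4), c(0, 1, 0))
  vars$out$terms$b$mf <- mf_piecewise(c(0.6, 0.8, 1.0), c(0, 1, 0))
  frb <- structure(list(rules = f$frb$rules, variables = vars, output = "out"),
                   class = "fdx_frb")
  fm <- fis(frb, fis_config(defuzzifier = "coa", reasoning = "mamdani"))
  v <- infer(fm, list(x = 5.0))$defuzzified   # symmetric -> centre of universe
  expect_equal(v, 0.5, tolerance = 1e-3)
  v2 <- infer(fm, list(x = 4.0))$defuzzified  # only the Low rule active
  expect_equal(v2, 0.2, tolerance = 1e-3)
  expect_error(fis(frb, fis_config(defuzzifier = "coa")), "singleton")
})

test_that("FCL export/import round-trips breakpoints, weights and pointwise behaviour", {
  f <- fis_fixture(use_weights = TRUE)
  txt <- export_fcl(f)
  expect_equal(sum(grepl("^  RULE ", txt)), 2L)
  f2 <- import_fcl(txt)
  expect_equal(f2$frb$variables$x$terms$Low$mf$u, c(4.5, 5.5))
  expect_equal(vapply(f2$frb$rules, `[[`, numeric(1), "weight"),
               vapply(f$frb$rules, `[[`, numeric(1), "weight"))
  xs <- seq(-1, 11, by = 0.37)
  for (tn in c("Low", "High"))
    expect_equal(membership_degree(f2$frb$variables$x$terms[[tn]]$mf, xs),
                 membership_degree(f$frb$variables$x$terms[[tn]]$mf, xs))
  # behaviourally identical after the round trip
  items <- data.frame(x = runif(50, 0, 10))
  expect_equal(infer(f2, items)$defuzzified, infer(f, items)$defuzzified)
  # file round trip
  path <- withr::local_tempfile(fileext = ".fcl")
  export_fcl(f, path)
  f3 <- import_fcl(path)
  expect_equal(infer(f3, items)$defuzzified, infer(f, items)$defuzzified)
})

test_that("a sharpened FIS reproduces its crisp origin away from the boundary", {
  set.seed(88)
  df <- data.frame(x1 = c(runif(40, 0, 4.8), runif(40, 5.2, 10)),
                   cls = rep(c("a", "b"), each = 40))
  ds <- fdx_dataset(df, "cls", universes = list(x1 = c(0, 10)))
  crisp <- run_crisp_generator(ds, pipeline_config())
  frb <- init_membership_functions(
    fuzzify_rulebase(crisp$reduced, ds$features, output_name = "cls"),
    overlap = 1e-6)
  f <- fis(frb, fis_config())
  crisp_pred <- classify_crisp(crisp$reduced, df)
  fuzzy_pred <- classify_fuzzy(f, df)$class
  expect_gte(mean(fuzzy_pred == crisp_pred, na.rm = TRUE), 0.99)
})
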