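test_that("class encodings are the output singleton positions, pairwise distinct", {
  f <- fis_fixture()
  enc <- class_encoding(f)
  expect_equal(enc, c(a = 0, b = 1))
  # three classes
  f3 <- f
  f3$frb$variables$out$terms$c <- list(label = "c", form = "output",
                                       mf = mf_singleton(2), thresholds = list())
  enc3 <- class_encoding(f3)
  expect_equal(unname(enc3), c(0, 1, 2))
  expect_equal(anyDuplicated(enc3), 0L)
  # non-singleton outputs are rejected
  fbad <- f
  fbad$frb$variables$out$terms$a$mf <- mf_piecewise(c(0, 1), c(1, 0))
  expect_error(class_encoding(fbad), "singleton")
})

test_that("the MSE objective matches a brute-force per-item loop and penalises abstention", {
  f <- fis_fixture()
  ds1 <- suppressWarnings(fdx_dataset(data.frame(x = 5.0, out = "b"), "out",
                                      universes = list(x = c(0, 10))))
  # defuzzified output at x=5 is 0.5, target 1 -> (0.5-1)^2
  expect_equal(mse_objective(f, ds1), 0.25)
  # a perfectly separating input gives 0
  ds0 <- fdx_dataset(data.frame(x = c(0, 10), out = c("a", "b")), "out",
                     universes = list(x = c(0, 10)))
  expect_equal(mse_objective(f, ds0), 0)
  set.seed(61)
  for (rep in 1:20) {
    g <- rand_fis()
    nms <- setdiff(names(g$frb$variables), "out")
    df <- as.data.frame(lapply(nms, function(v) runif(15, 0, 10)))
    names(df) <- nms
    df$out <- sample(c("a", "b"), 15, TRUE)
    ds <- fdx_dataset(df, "out")
    enc <- class_encoding(g)
    want <- mean(vapply(seq_len(15), function(i) {
      d <- oracle_cog(g, as.list(df[i, nms, drop = FALSE]))
      if (is.na(d)) (max(enc) - min(enc))^2 else (d - enc[[df$out[i]]])^2
    }, numeric(1)))
    expect_equal(mse_objective(g, ds), want, tolerance = 1e-12)
  }
})

test_that("the classification rate counts abstentions as errors and matches a confusion matrix", {
  rb <- crisp_rulebase(list(
    crisp_rule(list(crisp_predicate("x", "<", 3)), "a", 1),
    crisp_rule(list(crisp_predicate("x", ">", 7)), "b", 1)), c("a", "b"))
  df <- data.frame(x = c(1, 2, 8, 5), cls = c("a", "b", "b", "a"))
  ds <- fdx_dataset(df, "cls")
  # x=1 -> a (correct), x=2 -> a (wrong), x=8 -> b (correct), x=5 abstains
  expect_equal(classification_rate(rb, ds), 0.5)
  pred <- classify_crisp(rb, df)
  cm <- table(factor(pred, levels = c("a", "b")),
              factor(df$cls, levels = c("a", "b")))
  expect_equal(classification_rate(rb, ds), sum(diag(cm)) / nrow(df))
})

test_that("a coordinate-wise minimum is returned unchanged with zero accepted steps", {
  f <- fis_fixture()
  ds <- fdx_dataset(data.frame(x = c(0, 10), out = c("a", "b")), "out",
                    universes = list(x = c(0, 10)))
  res <- delta_jump_optimize(f, ds, adapt_config(max_iterations = 10))
  expect_equal(res$report$accepted, 0L)
  expect_equal(res$report$final_objective, 0)
  expect_equal(res$fis$frb, f$frb)
})

test_that("a single tunable breakpoint converges to the grid-search minimum", {
  # one Low ramp with a frozen right breakpoint: make only u[1] effectively
  # matter by a dataset straddling the transition
  f <- fis_fixture()
  set.seed(12)
  x <- runif(120, 0, 10)
  cls <- ifelse(x <= 6.5, "a", "b")
  ds <- fdx_dataset(data.frame(x = x, out = cls), "out",
                    universes = list(x = c(0, 10)))
  res <- delta_jump_optimize(f, ds, adapt_config(max_iterations = 120,
                                                 tolerance = 1e-5))
  # dense grid search over symmetric ramp positions (the structure the
  # optimizer explores coordinate-wise)
  grid <- seq(0.5, 9.5, by = 0.005)
  gmse <- vapply(grid, function(c0) {
    g <- f
    g$frb$variables$x$terms$Low$mf$u <- c(c0 - 0.5, c0 + 0.5)
    g$frb$variables$x$terms$High$mf$u <- c(c0 - 0.5, c0 + 0.5)
    mse_objective(g, ds)
  }, numeric(1))
  expect_lte(res$report$final_objective, min(gmse) + 1e-3)
})

test_that("the objective trajectory is non-increasing and the search is deterministic", {
  set.seed(303)
  gt <- synthetic_ground_truth(threshold = 4, n_noise = 0)
  ds <- generate_synthetic(gt$features, gt$rulebase, 150, seed = 5)
  crisp <- run_crisp_generator(ds, pipeline_config())
  frb <- init_membership_functions(
    fuzzify_rulebase(crisp$reduced, ds$features, output_name = "class"),
    overlap = 0.2)
  f <- fis(frb, fis_config())
  cfg <- adapt_config(max_iterations = 25)
  res1 <- delta_jump_optimize(f, ds, cfg)
  expect_true(all(diff(res1$report$trajectory) <= 1e-12))
  expect_lte(res1$report$final_objective, res1$report$initial_objective)
  res2 <- delta_jump_optimize(f, ds, cfg)
  expect_identical(res1$fis, res2$fis)
  expect_identical(res1$report$trajectory, res2$report$trajectory)
})

test_that("membership invariants survive every accepted step", {
  set.seed(99)
  gt <- synthetic_ground_truth(threshold = 6, n_noise = 1)
  ds <- generate_synthetic(gt$features, gt$rulebase, 120, seed = 8)
  crisp <- run_crisp_generator(ds, pipeline_config(weights = "equal"))
  frb <- init_membership_functions(
    fuzzify_rulebase(crisp$reduced, ds$features, output_name = "class"),
    overlap = 0.15)
  f <- fis(frb, fis_config(use_rule_weights = TRUE))
  res <- delta_jump_optimize(f, ds, adapt_config(max_iterations = 30,
                                                 tune_weights = TRUE))
  for (v in res$fis$frb$variables) {
    if (v$kind != "numeric") next
    for (t in v$terms) {
      expect_true(all(diff(t$mf$u) > 0))
      expect_gte(min(t$mf$u), v$universe[1])
      expect_lte(max(t$mf$u), v$universe[2])
    }
  }
  w <- vapply(res$fis$frb$rules, `[[`, numeric(1), "weight")
  expect_true(all(w >= 0 & w <= 1))
})

test_that("tuning with no enabled parameters is rejected", {
  f <- fis_fixture()
  ds <- fdx_dataset(data.frame(x = c(0, 10), out = c("a", "b")), "out")
  expect_error(
    delta_jump_optimize(f, ds, adapt_config(tune_mfs = FALSE,
                                            tune_weights = FALSE)),
    "no tunable")
})
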