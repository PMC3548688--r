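#' Fit a fuzzy rule-based diagnostic classifier
#'
#' Runs the full six-stage pipeline on a training dataset: a gain-ratio
#' decision tree is induced and flattened into a weighted-DNF crisp rule
#' base (stage 1), the most useful rules are selected with at least one per
#' class (stage 2), same-feature numeric predicates are merged into
#' fuzzifiable form (stage 3), the reduced rules are translated into
#' linguistic variables and a weighted fuzzy rule base (stage 4), assembled
#' into a fuzzy inference system (stage 5), and the membership-function
#' breakpoints are tuned by adaptive-step cyclic coordinate descent
#' minimising the mean squared error against the numeric class encoding
#' (stage 6).
#'
#' @param formula model formula `class ~ .` or `class ~ f1 + f2 + ...`.
#' @param data a data.frame of complete records (no missing values).
#' @param select_n number of rules to keep in stage 2; default one per class.
#' @param select_criterion `"most_confident"` (default) or `"longest_match"`.
#' @param weights rule weighting, `"coverage"` (default) or `"equal"`.
#' @param min_leaf,max_depth decision-tree controls.
#' @param overlap initial membership transition half-width as a fraction of
#'   each universe.
#' @param config an [fis_config()] with the logical parameters.
#' @param adapt an [adapt_config()], or `NULL` to skip tuning.
#' @param universes optional named list of numeric-universe overrides.
#' @return an object of class `fuzzydx` with components `dataset`, `tree`,
#'   `crisp` (extracted/selected/reduced bases), `fis_initial`, `fis`,
#'   `report` and `call`. Methods: [print.fuzzydx()], [summary.fuzzydx()],
#'   [predict.fuzzydx()], [coef.fuzzydx()], [plot.fuzzydx()],
#'   [residuals.fuzzydx()], [simulate.fuzzydx()].
#' @examples
#' gt <- synthetic_ground_truth()
#' ds <- generate_synthetic(gt$features, gt$rulebase, 300, seed = 7)
#' fit <- fuzzydx(class ~ ., data = ds$data)
#' fit
#' predict(fit, ds$data[1:3, ])
#' @export
fuzzydx <- function(formula, data, select_n = NULL,
                    select_criterion = c("most_confident", "longest_match"),
                    weights = c("coverage", "equal"),
                    min_leaf = 2L, max_depth = Inf, overlap = 0.1,
                    config = fis_config(), adapt = adapt_config(),
                    universes = NULL) {
  cl <- match.call()
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  class_attr <- all.vars(formula[[2]])
  if (length(class_attr) != 1L)
    stop_fdx("formula must have a single class attribute on the left")
  rhs <- attr(stats::terms(formula, data = data), "term.labels")
  keep <- c(rhs, class_attr)
  ds <- fdx_dataset(data[, keep, drop = FALSE], class_attr,
                    universes = universes)
  cfg <- pipeline_config(min_leaf = min_leaf, max_depth = max_depth,
                         weights = match.arg(weights), select_n = select_n,
                         select_criterion = match.arg(select_criterion),
                         overlap = overlap, fis_config = config,
                         adapt = adapt)
  crisp <- run_crisp_generator(ds, cfg)
  fuzzy <- run_fis_generator(crisp$reduced, ds, cfg)
  structure(list(dataset = ds, tree = crisp$tree,
                 crisp = crisp[c("extracted", "selected", "reduced")],
                 fis_initial = fuzzy$fis_initial, fis = fuzzy$fis,
                 report = fuzzy$report, pipeline_config = cfg, call = cl),
            class = "fuzzydx")
}

#' @export
print.fuzzydx <- function(x, ...) {
  cat("Fuzzy rule-based classifier\n")
  cat("Call: ", deparse(x$call), "\n\n")
  print(x$crisp$reduced)
  if (!is.null(x$report))
    cat(sprintf("Adapted in %d cycle(s): training MSE %.4g -> %.4g\n",
                length(x$report$trajectory), x$report$initial_objective,
                x$report$final_objective))
  cat(sprintf("Training classification rate: %.3f\n",
              classification_rate(x$fis, x$dataset)))
  invisible(x)
}

#' Summarise a fitted fuzzy classifier
#'
#' @param object a [fuzzydx()] fit.
#' @param ... unused.
#' @return the object, invisibly; prints per-stage training classification
#'   rates, the linguistic variables and the adaptation report.
#' @export
summary.fuzzydx <- function(object, ...) {
  cat("Fuzzy rule-based classifier -- six-stage pipeline\n\n")
  stages <- list("extracted crisp base" = object$crisp$extracted,
                 "selected crisp base" = object$crisp$selected,
                 "reduced crisp base" = object$crisp$reduced,
                 "initial FIS" = object$fis_initial,
                 "adapted FIS" = object$fis)
  cat("Training classification rate by stage:\n")
  for (nm in names(stages))
    cat(sprintf("  %-22s %.3f\n", nm,
                classification_rate(stages[[nm]], object$dataset)))
  cat("\n")
  print(object$fis$frb)
  if (!is.null(object$report)) { cat("\n"); print(object$report) }
  invisible(object)
}

#' Predict with a fitted fuzzy classifier
#'
#' @param object a [fuzzydx()] fit.
#' @param newdata data.frame of records; defaults to the training data.
#' @param type `"class"` (character vector, `NA` = abstention),
#'   `"confidence"` (data.frame with class, chi and the defuzzified value) or
#'   `"defuzzified"` (numeric vector).
#' @param ... unused.
#' @return per `type`.
#' @export
predict.fuzzydx <- function(object, newdata = NULL,
                            type = c("class", "confidence", "defuzzified"),
                            ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$dataset$data
  res <- classify_fuzzy(object$fis, newdata)
  switch(type, class = res$class, confidence = res,
         defuzzified = res$defuzzified)
}

#' Tuned membership-function breakpoints
#'
#' @param object a [fuzzydx()] fit.
#' @param ... unused.
#' @return named numeric vector `variable.term.k` -> breakpoint abscissa.
#' @export
coef.fuzzydx <- function(object, ...) {
  out <- numeric(0)
  for (v in object$fis$frb$variables) {
    if (v$kind != "numeric") next
    for (tn in names(v$terms)) {
      mf <- v$terms[[tn]]$mf
      if (mf$variant != "piecewise_linear") next
      nm <- paste(v$name, tn, seq_along(mf$u), sep = ".")
      out[nm] <- mf$u
    }
  }
  out
}

#' Training residuals on the defuzzified scale
#'
#' @param object a [fuzzydx()] fit.
#' @param ... unused.
#' @return numeric vector of defuzzified output minus encoded true class
#'   (`NA` for abstentions).
#' @export
residuals.fuzzydx <- function(object, ...) {
  enc <- class_encoding(object$fis)
  pred <- infer(object$fis, object$dataset$data)$defuzzified
  pred - enc[object$dataset$data[[object$dataset$class]]]
}

#' Plot the (tuned) membership functions
#'
#' One panel per numeric linguistic variable, drawing every term's
#' membership function over the universe of discourse.
#'
#' @param x a [fuzzydx()] fit.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.fuzzydx <- function(x, ...) {
  vars <- Filter(function(v) v$kind == "numeric", x$fis$frb$variables)
  if (length(vars) == 0L) { message("no numeric variables to plot"); return(invisible(x)) }
  old <- graphics::par(mfrow = c(length(vars), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (v in vars) {
    grid <- seq(v$universe[1], v$universe[2], length.out = 400)
    graphics::plot(NA, xlim = v$universe, ylim = c(0, 1),
                   xlab = v$name, ylab = "membership", main = v$name, ...)
    i <- 1
    for (tn in names(v$terms)) {
      graphics::lines(grid, membership_degree(v$terms[[tn]]$mf, grid),
                      col = i, lwd = 2)
      i <- i + 1
    }
    graphics::legend("right", legend = names(v$terms),
                     col = seq_along(v$terms), lwd = 2, bty = "n")
  }
  invisible(x)
}

#' Simulate records from a fitted classifier
#'
#' Draws feature values uniformly over each universe and labels them with
#' the fitted fuzzy inference system — the fitted model acting as its own
#' synthetic-data ground truth.
#'
#' @param object a [fuzzydx()] fit.
#' @param nsim number of records.
#' @param seed integer seed.
#' @param ... unused.
#' @return a data.frame of simulated records with a class column.
#' @export
simulate.fuzzydx <- function(object, nsim = 100L, seed = 1L, ...) {
  ds <- generate_synthetic(object$dataset$features, object$fis, nsim,
                           label_noise = 0,
                           class_attribute = object$dataset$class,
                           seed = seed)
  ds$data
}
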