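# Orchestration: the crisp-rule generator (extraction -> selection ->
# reduction), the FIS generator (fuzzification -> MF initialisation ->
# logical configuration -> adaptation), and stratified cross-validation
# reporting per-stage classification rates.

#' Pipeline configuration
#'
#' One declarative object covering every stage's algorithm choices.
#'
#' @param min_leaf,max_depth tree induction controls (see [induce_tree()]).
#' @param weights rule weighting mode, `"coverage"` or `"equal"`.
#' @param select_n number of rules to keep; `NULL` keeps one per class.
#' @param select_criterion `"most_confident"` or `"longest_match"`.
#' @param overlap initial membership transition half-width fraction.
#' @param fis_config an [fis_config()].
#' @param adapt an [adapt_config()], or `NULL` to skip adaptation.
#' @return an object of class `fdx_pipeline_config`.
#' @export
pipeline_config <- function(min_leaf = 2L, max_depth = Inf,
                            weights = c("coverage", "equal"),
                            select_n = NULL,
                            select_criterion = c("most_confident",
                                                 "longest_match"),
                            overlap = 0.1,
                            fis_config = fuzzydx::fis_config(),
                            adapt = adapt_config()) {
  structure(list(min_leaf = min_leaf, max_depth = max_depth,
                 weights = match.arg(weights), select_n = select_n,
                 select_criterion = match.arg(select_criterion),
                 overlap = overlap, fis_config = fis_config,
                 adapt = adapt),
            class = "fdx_pipeline_config")
}

#' Run the crisp rule generator (stages 1-3)
#'
#' Extraction, selection and reduction in sequence; each stage's output is
#' validated (selection cardinality, fuzzifiability) before the next stage
#' runs, and all intermediate bases are returned for reporting.
#'
#' @param ds training [fdx_dataset()].
#' @param cfg a [pipeline_config()].
#' @return list with crisp rule bases `extracted`, `selected`, `reduced` and
#'   the induced `tree`.
#' @export
run_crisp_generator <- function(ds, cfg = pipeline_config()) {
  stopifnot(inherits(ds, "fdx_dataset"))
  tree <- tryCatch(induce_tree(ds, min_leaf = cfg$min_leaf,
                               max_depth = cfg$max_depth),
                   error = function(e)
                     stop_fdx("extraction: %s", conditionMessage(e)))
  extracted <- tree_to_rules(tree, ds$class_levels, weights = cfg$weights)
  n <- cfg$select_n %||% length(unique(vapply(extracted$rules, `[[`,
                                              character(1), "consequent")))
  n <- min(n, length(extracted$rules))
  selected <- tryCatch(select_rules(extracted, ds, n,
                                    criterion = cfg$select_criterion),
                       error = function(e)
                         stop_fdx("selection: %s", conditionMessage(e)))
  reduced <- tryCatch(reduce_rulebase(selected), error = function(e)
    stop_fdx("reduction: %s", conditionMessage(e)))
  for (i in seq_along(reduced$rules))
    if (!is_fuzzifiable(reduced$rules[[i]]))
      stop_fdx("reduction: rule %d is still not fuzzifiable", i)
  list(tree = tree, extracted = extracted, selected = selected,
       reduced = reduced)
}

#' Run the FIS generator (stages 4-6)
#'
#' Fuzzification, membership initialisation, logical configuration and
#' adaptation; the adapted system's training objective never exceeds the
#' initial one.
#'
#' @param crb a reduced, fuzzifiable [crisp_rulebase()].
#' @param ds training [fdx_dataset()].
#' @param cfg a [pipeline_config()].
#' @return list with `fis_initial`, `fis` (adapted; identical to
#'   `fis_initial` when adaptation is disabled) and `report`
#'   (`NULL` without adaptation).
#' @export
run_fis_generator <- function(crb, ds, cfg = pipeline_config()) {
  frb <- tryCatch(
    init_membership_functions(
      fuzzify_rulebase(crb, ds$features, output_name = ds$class),
      overlap = cfg$overlap),
    error = function(e) stop_fdx("fuzzification: %s", conditionMessage(e)))
  fis0 <- tryCatch(fis(frb, cfg$fis_config), error = function(e)
    stop_fdx("configuration: %s", conditionMessage(e)))
  if (is.null(cfg$adapt))
    return(list(fis_initial = fis0, fis = fis0, report = NULL))
  res <- tryCatch(delta_jump_optimize(fis0, ds, cfg$adapt),
                  error = function(e)
                    stop_fdx("adaptation: %s", conditionMessage(e)))
  list(fis_initial = fis0, fis = res$fis, report = res$report)
}

#' Cross-validate the full pipeline
#'
#' Stratified k-fold evaluation reporting, per fold, the train- and test-set
#' classification rate after each stage: (a) the extracted crisp base,
#' (b) the selected base, (c) the reduced base, (d) the fuzzified,
#' unadapted FIS and (e) the adapted FIS.
#'
#' @param ds an [fdx_dataset()].
#' @param cfg a [pipeline_config()].
#' @param k number of folds.
#' @param seed integer seed driving the fold assignment.
#' @return an object of class `fdx_cv`: list with `metrics` (long-format
#'   data.frame: fold, stage, train, test) and `summary` (mean and sd per
#'   stage).
#' @export
cross_validate <- function(ds, cfg = pipeline_config(), k = 10L, seed = 1L) {
  folds <- stratified_kfold(ds, k, seed = seed)
  stages <- c(extracted = "a", selected = "b", reduced = "c",
              fis_initial = "d", fis_adapted = "e")
  rows <- list()
  for (fold in seq_len(k)) {
    test_idx <- which(folds$assignments == fold)
    train <- dataset_subset(ds, setdiff(seq_len(nrow(ds$data)), test_idx))
    test <- dataset_subset(ds, test_idx)
    crisp <- run_crisp_generator(train, cfg)
    fuzzy <- run_fis_generator(crisp$reduced, train, cfg)
    models <- list(extracted = crisp$extracted, selected = crisp$selected,
                   reduced = crisp$reduced, fis_initial = fuzzy$fis_initial,
                   fis_adapted = fuzzy$fis)
    for (st in names(models)) {
      rows[[length(rows) + 1L]] <- data.frame(
        fold = fold, stage = st,
        train = classification_rate(models[[st]], train),
        test = classification_rate(models[[st]], test),
        stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, rows)
  metrics$stage <- factor(metrics$stage, levels = names(stages))
  summ <- do.call(rbind, lapply(split(metrics, metrics$stage), function(m)
    data.frame(stage = m$stage[1],
               train_mean = mean(m$train), train_sd = stats::sd(m$train),
               test_mean = mean(m$test), test_sd = stats::sd(m$test))))
  rownames(summ) <- NULL
  structure(list(metrics = metrics, summary = summ, k = k, seed = seed),
            class = "fdx_cv")
}

#' @export
print.fdx_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$k, x$seed))
  cat("classification rate, mean (sd) across folds:\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s train %.3f (%.3f)  test %.3f (%.3f)\n",
                s$stage[i], s$train_mean[i], s$train_sd[i],
                s$test_mean[i], s$test_sd[i]))
  invisible(x)
}
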