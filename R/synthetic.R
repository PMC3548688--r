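# Synthetic clinical-style datasets labelled by a known crisp rule base or a
# known FIS, with configurable label noise. The generator doubles as the
# ground-truth oracle in tests: at zero noise the generating rule base scores
# a classification rate of 1 on its own output.

#' Generate a synthetic labelled dataset
#'
#' Draws feature values uniformly over their universes (numeric) or
#' categories (categorical), labels each item with the ground-truth
#' classifier, and then flips each label with probability `label_noise` to a
#' uniformly chosen different class. Items on which the ground truth abstains
#' are redrawn (up to `max_retries` each); persistent abstention is an error,
#' signalling a non-exhaustive ground truth.
#'
#' @param features named list of [feature_spec()].
#' @param ground_truth an [crisp_rulebase()] or an [fis()].
#' @param n_items number of records to generate.
#' @param label_noise flip probability in `[0, 1]`.
#' @param class_attribute name of the class column.
#' @param seed integer seed.
#' @param max_retries redraw budget per item.
#' @return an [fdx_dataset()] whose feature universes are the declared ones.
#' @export
generate_synthetic <- function(features, ground_truth, n_items,
                               label_noise = 0, class_attribute = "class",
                               seed = 1L, max_retries = 100L) {
  stopifnot(label_noise >= 0, label_noise <= 1, n_items >= 1)
  is_crisp <- inherits(ground_truth, "fdx_crb")
  if (!is_crisp && !inherits(ground_truth, "fdx_fis"))
    stop_fdx("ground_truth must be a crisp rule base or a FIS")
  classes <- if (is_crisp) ground_truth$classes
             else names(ground_truth$frb$variables[[ground_truth$frb$output]]$terms)
  used <- if (is_crisp)
    unique(unlist(lapply(ground_truth$rules, function(r)
      vapply(r$predicates, `[[`, character(1), "feature"))))
  else
    setdiff(names(ground_truth$frb$variables), ground_truth$frb$output)
  missing_feats <- setdiff(used, names(features))
  if (length(missing_feats) > 0L)
    stop_fdx("ground truth references undeclared feature(s): %s",
             paste(missing_feats, collapse = ", "))
  draw <- function(n) {
    cols <- lapply(features, function(f) {
      if (f$kind == "numeric")
        stats::runif(n, f$universe[1], f$universe[2])
      else
        sample(f$categories, n, replace = TRUE)
    })
    as.data.frame(cols, optional = TRUE, stringsAsFactors = FALSE)
  }
  label <- function(data) {
    if (is_crisp) classify_crisp(ground_truth, data)
    else classify_fuzzy(ground_truth, data)$class
  }
  with_seed(seed, {
    data <- draw(n_items)
    lab <- label(data)
    tries <- 0L
    while (anyNA(lab)) {
      tries <- tries + 1L
      if (tries > max_retries)
        stop_fdx("ground truth keeps abstaining after %d redraws; it does not cover the feature space",
                 max_retries)
      idx <- which(is.na(lab))
      repl <- draw(length(idx))
      data[idx, ] <- repl
      lab[idx] <- label(repl)
    }
    if (label_noise > 0) {
      flip <- stats::runif(n_items) < label_noise
      for (i in which(flip))
        lab[i] <- sample(setdiff(classes, lab[i]), 1L)
    }
    data[[class_attribute]] <- lab
  })
  uni <- lapply(Filter(function(f) f$kind == "numeric", features),
                function(f) f$universe)
  fdx_dataset(data, class_attribute, universes = uni)
}

#' Default two-rule ground truth for simulation studies
#'
#' A minimal diagnostic scenario: one informative marker `x1` split at a
#' threshold (low values benign, high values malignant) plus `n_noise`
#' uninformative uniform features, emulating the situation where rule
#' selection must discard irrelevant attributes.
#'
#' @param threshold decision threshold on `x1`.
#' @param n_noise number of uninformative numeric features.
#' @param universe universe of discourse shared by all features.
#' @return list with `features` (named list of [feature_spec()]) and
#'   `rulebase` (a 2-rule [crisp_rulebase()]).
#' @export
synthetic_ground_truth <- function(threshold = 5, n_noise = 2,
                                   universe = c(0, 10)) {
  feats <- list(x1 = feature_spec("x1", "numeric", universe = universe))
  for (i in seq_len(n_noise)) {
    nm <- paste0("z", i)
    feats[[nm]] <- feature_spec(nm, "numeric", universe = universe)
  }
  rb <- crisp_rulebase(list(
    crisp_rule(list(crisp_predicate("x1", "<=", threshold)), "benign", 1),
    crisp_rule(list(crisp_predicate("x1", ">", threshold)), "malignant", 1)),
    classes = c("benign", "malignant"))
  list(features = feats, rulebase = rb)
}
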