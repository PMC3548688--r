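# Stage 5: the runnable fuzzy inference system — input fuzzification, rule
# evaluation, aggregation of rule outputs, defuzzification and classification.

#' Logical configuration of a fuzzy inference system
#'
#' Collects the logical parameters of the inference: conjunction (t-norm),
#' disjunction (s-norm), implication, aggregation, defuzzifier and reasoning
#' mechanism. The defaults mirror a singleton-reasoning proof-of-concept
#' setup: min t-norm, max s-norm, min implication, center-of-gravity over
#' singletons, rule weights off.
#'
#' @param tnorm `"min"` or `"product"`.
#' @param snorm `"max"`, `"probabilistic_sum"` or `"bounded_sum"`.
#' @param implication `"min"` or `"product"`.
#' @param aggregation `"max"` or `"sum"`.
#' @param defuzzifier `"cog_singleton"`, `"coa"` or `"mom"`.
#' @param reasoning `"singleton"` or `"mamdani"`.
#' @param use_rule_weights multiply each rule's activation by its weight?
#' @return an object of class `fdx_config`.
#' @export
fis_config <- function(tnorm = c("min", "product"),
                       snorm = c("max", "probabilistic_sum", "bounded_sum"),
                       implication = c("min", "product"),
                       aggregation = c("max", "sum"),
                       defuzzifier = c("cog_singleton", "coa", "mom"),
                       reasoning = c("singleton", "mamdani"),
                       use_rule_weights = FALSE) {
  structure(list(tnorm = match.arg(tnorm), snorm = match.arg(snorm),
                 implication = match.arg(implication),
                 aggregation = match.arg(aggregation),
                 defuzzifier = match.arg(defuzzifier),
                 reasoning = match.arg(reasoning),
                 use_rule_weights = isTRUE(use_rule_weights)),
            class = "fdx_config")
}

#' Assemble a fuzzy inference system
#'
#' @param frb an [fuzzify_rulebase()] result with concrete membership
#'   functions (see [init_membership_functions()]).
#' @param config an [fis_config()].
#' @return an object of class `fdx_fis`.
#' @export
fis <- function(frb, config = fis_config()) {
  stopifnot(inherits(frb, "fdx_frb"), inherits(config, "fdx_config"))
  out <- frb$variables[[frb$output]]
  singleton_out <- all(vapply(out$terms, function(t)
    identical(t$mf$variant, "singleton"), logical(1)))
  if (config$reasoning == "singleton" && !singleton_out)
    stop_fdx("singleton reasoning requires singleton output terms")
  if (config$defuzzifier == "cog_singleton" && !singleton_out)
    stop_fdx("cog_singleton defuzzification requires singleton output terms")
  if (config$defuzzifier == "coa" && singleton_out)
    stop_fdx("coa requires piecewise-linear output terms")
  for (r in frb$rules) {
    for (p in r$predicates) {
      v <- frb$variables[[p$variable]]
      if (is.null(v) || is.null(v$terms[[p$term]]) ||
          is.null(v$terms[[p$term]]$mf))
        stop_fdx("unresolvable predicate: %s is %s", p$variable, p$term)
    }
  }
  structure(list(frb = frb, config = config), class = "fdx_fis")
}

#' Membership degree of a value
#'
#' Evaluates a membership function: linear interpolation between breakpoints
#' with constant extension beyond the first and last one, or the singleton
#' indicator.
#'
#' @param mf an `fdx_mf` (see [mf_piecewise()], [mf_singleton()]).
#' @param u numeric value(s).
#' @return degree(s) in `[0, 1]`.
#' @export
membership_degree <- function(mf, u) {
  stopifnot(inherits(mf, "fdx_mf"))
  if (mf$variant == "singleton") return(as.numeric(u == mf$position))
  if (length(mf$u) == 1L) return(rep(mf$mu, length(u)))
  stats::approx(mf$u, mf$mu, xout = u, method = "linear",
                yleft = mf$mu[1], yright = mf$mu[length(mf$mu)])$y
}

# Degree of one fuzzy predicate for a column of raw input values.
predicate_degree <- function(fisv, p, values) {
  var <- fisv[[p$variable]]
  term <- var$terms[[p$term]]
  if (var$kind == "categorical") as.numeric(values == term$label)
  else membership_degree(term$mf, as.numeric(values))
}

apply_tnorm <- function(tnorm, a, b) {
  switch(tnorm, min = pmin(a, b), product = a * b)
}

apply_aggregation <- function(agg, a, b) {
  switch(agg, max = pmax(a, b), sum = a + b)
}

#' Activation degree of one fuzzy rule
#'
#' Combines the antecedent membership degrees with the configured t-norm;
#' when rule weights are enabled the result is multiplied by the rule's
#' weight, modulating its firing strength. An empty antecedent activates
#' fully.
#'
#' @param r a fuzzy rule (element of `fis$frb$rules`).
#' @param item named list / one-row data.frame of raw feature values.
#' @param fis an [fis()].
#' @return activation degree.
#' @export
rule_activation <- function(r, item, fis) {
  if (!is.data.frame(item)) item <- as.data.frame(item, optional = TRUE)
  act <- rep(1, nrow(item))
  for (p in r$predicates) {
    if (is.null(item[[p$variable]]))
      stop_fdx("item has no value for variable '%s'", p$variable)
    act <- apply_tnorm(fis$config$tnorm, act,
                       predicate_degree(fis$frb$variables, p, item[[p$variable]]))
  }
  if (fis$config$use_rule_weights) act <- act * r$weight
  act
}

# Aggregated activation per output term for all rows: matrix n x n_terms.
activation_matrix <- function(fis, newdata) {
  out <- fis$frb$variables[[fis$frb$output]]
  labs <- names(out$terms)
  n <- nrow(newdata)
  agg <- matrix(0, n, length(labs), dimnames = list(NULL, labs))
  for (r in fis$frb$rules) {
    a <- rule_activation(r, newdata, fis)
    j <- match(r$consequent$term, labs)
    agg[, j] <- apply_aggregation(fis$config$aggregation, agg[, j], a)
  }
  agg
}

defuzzify <- function(fis, agg) {
  out <- fis$frb$variables[[fis$frb$output]]
  cfg <- fis$config
  total <- rowSums(agg)
  n <- nrow(agg)
  val <- rep(NA_real_, n)
  active <- total > 0
  if (cfg$defuzzifier == "cog_singleton") {
    s <- vapply(out$terms, function(t) t$mf$position, numeric(1))
    val[active] <- as.vector(agg[active, , drop = FALSE] %*% s) / total[active]
  } else if (cfg$defuzzifier == "mom") {
    s <- vapply(out$terms, function(t) {
      if (t$mf$variant == "singleton") t$mf$position
      else mean(t$mf$u[t$mf$mu == max(t$mf$mu)])
    }, numeric(1))
    for (i in which(active)) {
      mx <- max(agg[i, ])
      val[i] <- mean(s[agg[i, ] >= mx - 1e-12])
    }
  } else {  # coa over the mamdani-aggregated output shape
    uni <- out$universe
    grid <- seq(uni[1], uni[2], length.out = 1001L)
    mgrid <- vapply(out$terms, function(t) membership_degree(t$mf, grid),
                    numeric(length(grid)))
    for (i in which(active)) {
      shape <- rep(0, length(grid))
      for (j in seq_along(out$terms)) {
        clipped <- switch(cfg$implication,
                          min = pmin(agg[i, j], mgrid[, j]),
                          product = agg[i, j] * mgrid[, j])
        shape <- apply_aggregation(cfg$aggregation, shape, clipped)
      }
      area <- sum(shape)
      val[i] <- if (area > 0) sum(shape * grid) / area else NA_real_
    }
  }
  val
}

#' Run fuzzy inference
#'
#' Performs the four inference steps — input fuzzification, rule evaluation,
#' aggregation of rule outputs, defuzzification — for each record.
#'
#' @param fis an [fis()].
#' @param newdata a data.frame (or single named list) of raw feature values.
#' @return list with `activations` (records x output terms matrix of
#'   aggregated activations) and `defuzzified` (numeric vector, `NA` where
#'   the total activation is zero: the system abstains).
#' @export
infer <- function(fis, newdata) {
  stopifnot(inherits(fis, "fdx_fis"))
  if (!is.data.frame(newdata)) newdata <- as.data.frame(newdata, optional = TRUE)
  agg <- activation_matrix(fis, newdata)
  list(activations = agg, defuzzified = defuzzify(fis, agg))
}

#' Classify records with a fuzzy inference system
#'
#' The winning class is the output term with the highest aggregated
#' activation (ties go to the term whose singleton lies nearest the
#' defuzzified value, then declaration order). The confidence `chi` is the
#' winning activation divided by the total activation. Records with zero
#' total activation abstain (`NA` class).
#'
#' @inheritParams infer
#' @return data.frame with columns `class`, `chi` and `defuzzified`.
#' @export
classify_fuzzy <- function(fis, newdata) {
  res <- infer(fis, newdata)
  agg <- res$activations
  labs <- colnames(agg)
  out <- fis$frb$variables[[fis$frb$output]]
  pos <- vapply(out$terms, function(t)
    if (t$mf$variant == "singleton") t$mf$position else
      mean(t$mf$u[t$mf$mu == max(t$mf$mu)]), numeric(1))
  n <- nrow(agg)
  cls <- rep(NA_character_, n)
  chi <- rep(NA_real_, n)
  total <- rowSums(agg)
  for (i in which(total > 0)) {
    mx <- max(agg[i, ])
    cand <- which(agg[i, ] >= mx - 1e-12)
    if (length(cand) > 1L) {
      d <- abs(pos[cand] - res$defuzzified[i])
      cand <- cand[d <= min(d) + 1e-12]
    }
    win <- cand[1]  # declaration order breaks any remaining tie
    cls[i] <- labs[win]
    chi[i] <- agg[i, win] / total[i]
  }
  data.frame(class = cls, chi = chi, defuzzified = res$defuzzified,
             stringsAsFactors = FALSE)
}

#' @export
print.fdx_fis <- function(x, ...) {
  cfg <- x$config
  cat("Fuzzy inference system\n")
  cat(sprintf("  reasoning=%s tnorm=%s snorm=%s implication=%s aggregation=%s defuzzifier=%s weights=%s\n",
              cfg$reasoning, cfg$tnorm, cfg$snorm, cfg$implication,
              cfg$aggregation, cfg$defuzzifier,
              if (cfg$use_rule_weights) "on" else "off"))
  print(x$frb)
  invisible(x)
}
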