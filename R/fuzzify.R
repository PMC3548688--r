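# Stage 4: translate a reduced (fuzzifiable) crisp rule base into linguistic
# variables with Low/Medium/High terms and a weighted fuzzy rule base, then
# give every term a concrete membership function.

#' Piecewise-linear membership function
#'
#' Defined by breakpoints `(u_i, mu_i)` with strictly increasing `u` and
#' `mu` in `[0, 1]`; evaluation interpolates linearly between breakpoints and
#' extends the first/last `mu` constantly beyond them.
#'
#' @param u strictly increasing breakpoint abscissae.
#' @param mu membership ordinates in `[0, 1]`, same length as `u`.
#' @return an object of class `fdx_mf`.
#' @export
mf_piecewise <- function(u, mu) {
  stopifnot(length(u) == length(mu), length(u) >= 1L)
  if (any(diff(u) <= 0)) stop_fdx("breakpoints must be strictly increasing")
  if (any(mu < 0 | mu > 1)) stop_fdx("membership values must lie in [0, 1]")
  structure(list(variant = "piecewise_linear",
                 u = as.numeric(u), mu = as.numeric(mu)),
            class = "fdx_mf")
}

#' Singleton membership function
#'
#' Membership 1 exactly at `position`, 0 elsewhere.
#'
#' @param position the support point.
#' @return an object of class `fdx_mf`.
#' @export
mf_singleton <- function(position) {
  structure(list(variant = "singleton", position = as.numeric(position)),
            class = "fdx_mf")
}

# Classify a reduced numeric-predicate group into its fuzzifiable form.
# Returns list(form, thresholds): form "low" (upper bound), "high" (lower
# bound) or "medium" (interval); thresholds named per side.
predicate_form <- function(preds) {
  lower <- Filter(function(p) is_lower_op(p$op), preds)
  upper <- Filter(function(p) is_upper_op(p$op), preds)
  if (length(lower) == 1L && length(upper) == 0L)
    list(form = "high", lower = lower[[1]]$value)
  else if (length(upper) == 1L && length(lower) == 0L)
    list(form = "low", upper = upper[[1]]$value)
  else if (length(upper) == 1L && length(lower) == 1L)
    list(form = "medium", lower = lower[[1]]$value, upper = upper[[1]]$value)
  else
    stop_fdx("predicate group is not in fuzzifiable form")
}

form_label <- c(low = "Low", medium = "Medium", high = "High")

#' Fuzzify a reduced crisp rule base
#'
#' Builds one linguistic variable per feature that appears in the rules (the
#' implicit feature selection carries over) and one fuzzy rule per crisp
#' rule, preserving weights. Numeric predicate groups map by form only:
#' an upper bound becomes `X is Low`, an interval `X is Medium`, a lower
#' bound `X is High`, so the same term is shared by every rule exhibiting
#' that form on that feature regardless of its crisp threshold — the crisp
#' boundaries are discharged, and recorded only as term metadata for the
#' initial membership functions. A variable's universe is never
#' sub-partitioned by overlapping thresholds from different rules: extra cut
#' points would overfit the universe of discourse and hurt interpretability.
#' Categorical features receive one term per distinct assigned value; the
#' output variable one term per class.
#'
#' @param rb a reduced [crisp_rulebase()] (every rule must pass
#'   [is_fuzzifiable()]).
#' @param features named list of [feature_spec()] covering all used features
#'   (e.g. `ds$features`).
#' @param output_name name for the output linguistic variable.
#' @return an object of class `fdx_frb`: list with `rules` and `variables`
#'   (terms carry no membership functions yet; see
#'   [init_membership_functions()]).
#' @export
fuzzify_rulebase <- function(rb, features, output_name = "class") {
  stopifnot(inherits(rb, "fdx_crb"))
  for (i in seq_along(rb$rules))
    if (!is_fuzzifiable(rb$rules[[i]]))
      stop_fdx("rule %d is not fuzzifiable: %s", i, format(rb$rules[[i]]))
  variables <- list()
  ensure_var <- function(feat) {
    if (is.null(variables[[feat$name]]))
      variables[[feat$name]] <<- list(
        name = feat$name, kind = feat$kind,
        universe = feat$universe, source_feature = feat$name,
        terms = list())
  }
  frules <- vector("list", length(rb$rules))
  for (i in seq_along(rb$rules)) {
    r <- rb$rules[[i]]
    fpreds <- list()
    feats_in_rule <- unique(vapply(r$predicates, `[[`, character(1), "feature"))
    for (fname in feats_in_rule) {
      feat <- features[[fname]]
      if (is.null(feat)) stop_fdx("no feature spec for '%s'", fname)
      ensure_var(feat)
      ps <- Filter(function(p) p$feature == fname, r$predicates)
      if (feat$kind == "numeric") {
        pf <- predicate_form(ps)
        lab <- form_label[[pf$form]]
        term <- variables[[fname]]$terms[[lab]]
        if (is.null(term))
          term <- list(label = lab, form = pf$form, mf = NULL,
                       thresholds = list())
        term$thresholds[[length(term$thresholds) + 1L]] <-
          pf[setdiff(names(pf), "form")]
        variables[[fname]]$terms[[lab]] <- term
      } else {
        if (ps[[1]]$op != "==")
          stop_fdx(paste0("categorical predicate '%s' uses '!=': only ",
                          "assigned values are fuzzifiable"), format(ps[[1]]))
        lab <- as.character(ps[[1]]$value)
        if (is.null(variables[[fname]]$terms[[lab]]))
          variables[[fname]]$terms[[lab]] <-
            list(label = lab, form = "categorical", mf = NULL,
                 thresholds = list())
      }
      fpreds[[length(fpreds) + 1L]] <-
        list(variable = fname,
             term = if (feat$kind == "numeric") form_label[[predicate_form(ps)$form]]
                    else as.character(ps[[1]]$value))
    }
    frules[[i]] <- list(predicates = fpreds,
                        consequent = list(variable = output_name,
                                          term = r$consequent),
                        weight = r$weight)
  }
  out_terms <- list()
  for (cl in rb$classes)
    out_terms[[cl]] <- list(label = cl, form = "output", mf = NULL,
                            thresholds = list())
  variables[[output_name]] <- list(
    name = output_name, kind = "output", universe = NULL,
    source_feature = "output", terms = out_terms)
  structure(list(rules = frules, variables = variables,
                 output = output_name),
            class = "fdx_frb")
}

#' Initialise membership functions for a fuzzy rule base
#'
#' Gives every term a concrete membership function. For a numeric variable
#' with universe width `W`, transitions have half-width `delta = overlap * W`
#' and are centred on the mean of the crisp thresholds that generated the
#' term: `Low` is 1 up to `v - delta` and ramps to 0 at `v + delta`; `High`
#' mirrors it; `Medium` is a trapezoid rising across the lower threshold and
#' falling across the upper one (collapsing to a triangle when the interval
#' is narrower than `2 * delta`). Breakpoints are clamped to the universe.
#' Categorical input terms and output class terms become singletons at
#' positions 0, 1, 2, ... in declaration order.
#'
#' @param frb an [fuzzify_rulebase()] result.
#' @param overlap transition half-width as a fraction of the universe width,
#'   in `(0, 0.5)`.
#' @return the `fdx_frb` with concrete membership functions.
#' @export
init_membership_functions <- function(frb, overlap = 0.1) {
  stopifnot(inherits(frb, "fdx_frb"))
  if (!(overlap > 0 && overlap < 0.5))
    stop_fdx("overlap must lie in (0, 0.5): delta >= half the universe is degenerate")
  for (vn in names(frb$variables)) {
    var <- frb$variables[[vn]]
    if (var$kind == "numeric") {
      lo <- var$universe[1]; hi <- var$universe[2]
      delta <- overlap * (hi - lo)
      for (tn in names(var$terms)) {
        term <- var$terms[[tn]]
        thr <- term$thresholds
        if (term$form == "low") {
          v <- mean(vapply(thr, `[[`, numeric(1), "upper"))
          term$mf <- clamped_pwl(c(v - delta, v + delta), c(1, 0), lo, hi)
        } else if (term$form == "high") {
          v <- mean(vapply(thr, `[[`, numeric(1), "lower"))
          term$mf <- clamped_pwl(c(v - delta, v + delta), c(0, 1), lo, hi)
        } else {  # medium
          v2 <- mean(vapply(thr, `[[`, numeric(1), "lower"))  # rising edge
          v1 <- mean(vapply(thr, `[[`, numeric(1), "upper"))  # falling edge
          if (v2 + delta < v1 - delta) {
            term$mf <- clamped_pwl(c(v2 - delta, v2 + delta,
                                     v1 - delta, v1 + delta),
                                   c(0, 1, 1, 0), lo, hi)
          } else {  # narrow interval: triangle at the midpoint
            m <- (v1 + v2) / 2
            term$mf <- clamped_pwl(c(m - delta, m, m + delta),
                                   c(0, 1, 0), lo, hi)
          }
        }
        var$terms[[tn]] <- term
      }
    } else {
      pos <- 0
      for (tn in names(var$terms)) {
        var$terms[[tn]]$mf <- mf_singleton(pos)
        pos <- pos + 1
      }
      var$universe <- c(0, max(pos - 1, 1))
    }
    frb$variables[[vn]] <- var
  }
  frb
}

# Clamp breakpoints into [lo, hi], nudging collided points apart so the
# strictly-increasing invariant survives thresholds near the universe edge.
clamped_pwl <- function(u, mu, lo, hi) {
  u <- pmin(pmax(u, lo), hi)
  eps <- (hi - lo) * 1e-9
  for (i in seq_along(u)[-1])
    if (u[i] <= u[i - 1]) u[i] <- u[i - 1] + eps
  mf_piecewise(u, mu)
}

#' @export
print.fdx_frb <- function(x, ...) {
  cat(sprintf("Fuzzy rule base: %d rule(s), %d variable(s)\n",
              length(x$rules), length(x$variables)))
  for (r in x$rules) {
    lhs <- paste(vapply(r$predicates, function(p)
      sprintf("%s is %s", p$variable, p$term), character(1)),
      collapse = " and ")
    if (!nzchar(lhs)) lhs <- "TRUE"
    cat(sprintf("  if %s then %s is %s (%g)\n",
                lhs, r$consequent$variable, r$consequent$term, r$weight))
  }
  for (v in x$variables) {
    cat(sprintf("  var %s [%s]: %s\n", v$name, v$kind,
                paste(names(v$terms), collapse = ", ")))
  }
  invisible(x)
}
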