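# Stage 6: derivative-free tuning of membership-function breakpoints (and
# optionally rule weights) by adaptive-step cyclic coordinate descent on the
# mean squared error between the defuzzified output and the numeric class
# encoding.

#' Adaptation configuration
#'
#' @param tune_mfs tune piecewise-linear breakpoint abscissae of the numeric
#'   input variables?
#' @param tune_weights tune rule weights (kept in `[0, 1]`)?
#' @param initial_delta initial step size as a fraction of each parameter's
#'   natural range (universe width for breakpoints, 1 for weights).
#' @param expand_factor step multiplier after an accepted move (> 1).
#' @param shrink_factor step multiplier after a rejected cycle move (in (0,1)).
#' @param max_iterations maximum number of full coordinate cycles.
#' @param tolerance stop when every step size falls below `tolerance` times
#'   the parameter's natural range.
#' @param seed integer seed (the search itself is deterministic; the seed is
#'   recorded for provenance and future stochastic tuners).
#' @return an object of class `fdx_adapt_config`.
#' @export
adapt_config <- function(tune_mfs = TRUE, tune_weights = FALSE,
                         initial_delta = 0.05, expand_factor = 2,
                         shrink_factor = 0.5, max_iterations = 50L,
                         tolerance = 1e-3, seed = 1L) {
  stopifnot(expand_factor > 1, shrink_factor > 0, shrink_factor < 1,
            initial_delta > 0, tolerance > 0, max_iterations >= 1)
  structure(list(tune_mfs = isTRUE(tune_mfs),
                 tune_weights = isTRUE(tune_weights),
                 initial_delta = initial_delta,
                 expand_factor = expand_factor,
                 shrink_factor = shrink_factor,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, seed = as.integer(seed)),
            class = "fdx_adapt_config")
}

#' Numeric encoding of the output classes
#'
#' Maps every class to the position of its output singleton; these encodings
#' are the regression targets of the mean-squared-error objective.
#'
#' @param fis an [fis()].
#' @return named numeric vector, class value -> singleton position.
#' @export
class_encoding <- function(fis) {
  stopifnot(inherits(fis, "fdx_fis"))
  out <- fis$frb$variables[[fis$frb$output]]
  if (!all(vapply(out$terms, function(t) t$mf$variant == "singleton",
                  logical(1))))
    stop_fdx("class encoding requires singleton output terms")
  vapply(out$terms, function(t) t$mf$position, numeric(1))
}

#' Mean squared error of a FIS on a dataset
#'
#' Mean over items of the squared distance between the defuzzified output and
#' the encoded true class. An abstaining item (zero total activation)
#' contributes the maximum squared encoding distance, a defined and bounded
#' penalty.
#'
#' @param fis an [fis()].
#' @param ds an [fdx_dataset()].
#' @return non-negative number.
#' @export
mse_objective <- function(fis, ds) {
  stopifnot(inherits(ds, "fdx_dataset"))
  enc <- class_encoding(fis)
  target <- enc[ds$data[[ds$class]]]
  if (anyNA(target))
    stop_fdx("dataset contains class value(s) unknown to the FIS")
  pred <- infer(fis, ds$data)$defuzzified
  pen <- (max(enc) - min(enc))^2
  err <- (pred - target)^2
  err[is.na(pred)] <- pen
  mean(err)
}

#' Classification rate
#'
#' Fraction of correctly classified items; abstentions count as
#' misclassifications. Works for both crisp rule bases and fuzzy inference
#' systems.
#'
#' @param model an [crisp_rulebase()] or an [fis()].
#' @param ds an [fdx_dataset()].
#' @return fraction in `[0, 1]`.
#' @export
classification_rate <- function(model, ds) {
  stopifnot(inherits(ds, "fdx_dataset"))
  truth <- ds$data[[ds$class]]
  pred <- if (inherits(model, "fdx_crb")) classify_crisp(model, ds$data)
          else if (inherits(model, "fdx_fis")) classify_fuzzy(model, ds$data)$class
          else stop_fdx("model must be a crisp rule base or a FIS")
  mean(!is.na(pred) & pred == truth)
}

# --- parameter vector plumbing -------------------------------------------

# Enumerate tunable parameters: every breakpoint abscissa of every
# piecewise-linear MF on a numeric input variable, and rule weights when
# enabled. Returns a data.frame descriptor.
tunable_params <- function(fis, cfg) {
  rows <- list()
  if (cfg$tune_mfs) {
    for (vn in names(fis$frb$variables)) {
      v <- fis$frb$variables[[vn]]
      if (v$kind != "numeric") next
      for (tn in names(v$terms)) {
        mf <- v$terms[[tn]]$mf
        if (mf$variant != "piecewise_linear") next
        for (k in seq_along(mf$u))
          rows[[length(rows) + 1L]] <- data.frame(
            kind = "breakpoint", variable = vn, term = tn, index = k,
            range = v$universe[2] - v$universe[1], stringsAsFactors = FALSE)
      }
    }
  }
  if (cfg$tune_weights) {
    for (ri in seq_along(fis$frb$rules))
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "weight", variable = NA, term = NA, index = ri, range = 1,
        stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    stop_fdx("no tunable parameters (enable tune_mfs and/or tune_weights)")
  do.call(rbind, rows)
}

get_param <- function(fis, d) {
  if (d$kind == "breakpoint")
    fis$frb$variables[[d$variable]]$terms[[d$term]]$mf$u[d$index]
  else fis$frb$rules[[d$index]]$weight
}

# Apply a value to one parameter; returns NULL when the move violates an
# invariant (breakpoint ordering, universe bounds, weight range).
set_param <- function(fis, d, value) {
  if (d$kind == "breakpoint") {
    v <- fis$frb$variables[[d$variable]]
    mf <- v$terms[[d$term]]$mf
    u <- mf$u
    u[d$index] <- value
    if (any(diff(u) <= 0)) return(NULL)
    if (value < v$universe[1] || value > v$universe[2]) return(NULL)
    fis$frb$variables[[d$variable]]$terms[[d$term]]$mf$u <- u
  } else {
    if (value < 0 || value > 1) return(NULL)
    fis$frb$rules[[d$index]]$weight <- value
  }
  fis
}

#' Tune a FIS by adaptive-step cyclic coordinate descent
#'
#' A derivative-free search with one adaptive step size per parameter. Each
#' cycle visits every tunable parameter in turn and probes the objective at
#' the current value plus and minus the parameter's step; the best strictly
#' improving probe is accepted and that parameter's step expands
#' (`expand_factor`), otherwise the value is kept and the step shrinks
#' (`shrink_factor`). Probes that would break a membership-function invariant
#' (breakpoint ordering, universe bounds) or push a weight out of `[0, 1]`
#' count as non-improving. The search stops after `max_iterations` cycles or
#' once every step has fallen below `tolerance` times its parameter's range.
#' The returned objective never exceeds the initial one.
#'
#' @param fis an [fis()].
#' @param ds training [fdx_dataset()].
#' @param cfg an [adapt_config()].
#' @return list with `fis` (tuned system) and `report` (an
#'   `fdx_adapt_report`: objective trajectory per cycle, accepted-step count,
#'   initial and final objective, final parameter vector).
#' @export
delta_jump_optimize <- function(fis, ds, cfg = adapt_config()) {
  stopifnot(inherits(fis, "fdx_fis"), inherits(cfg, "fdx_adapt_config"))
  pars <- tunable_params(fis, cfg)
  deltas <- cfg$initial_delta * pars$range
  f <- mse_objective(fis, ds)
  f0 <- f
  trajectory <- numeric(0)
  accepted <- 0L
  for (iter in seq_len(cfg$max_iterations)) {
    for (pi in seq_len(nrow(pars))) {
      d <- pars[pi, ]
      x <- get_param(fis, d)
      best_f <- f
      best_fis <- NULL
      for (cand in c(x + deltas[pi], x - deltas[pi])) {
        trial <- set_param(fis, d, cand)
        if (is.null(trial)) next
        ft <- mse_objective(trial, ds)
        if (ft < best_f - 1e-15) { best_f <- ft; best_fis <- trial }
      }
      if (!is.null(best_fis)) {
        fis <- best_fis
        f <- best_f
        accepted <- accepted + 1L
        deltas[pi] <- deltas[pi] * cfg$expand_factor
      } else {
        deltas[pi] <- deltas[pi] * cfg$shrink_factor
      }
    }
    trajectory <- c(trajectory, f)
    if (all(deltas < cfg$tolerance * pars$range)) break
  }
  final_params <- vapply(seq_len(nrow(pars)), function(pi)
    get_param(fis, pars[pi, ]), numeric(1))
  report <- structure(list(trajectory = trajectory, accepted = accepted,
                           initial_objective = f0, final_objective = f,
                           parameters = pars, values = final_params),
                      class = "fdx_adapt_report")
  list(fis = fis, report = report)
}

#' @export
print.fdx_adapt_report <- function(x, ...) {
  cat(sprintf("Adaptation: %d cycle(s), %d accepted step(s)\n",
              length(x$trajectory), x$accepted))
  cat(sprintf("  objective (MSE): %.6g -> %.6g\n",
              x$initial_objective, x$final_objective))
  invisible(x)
}
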