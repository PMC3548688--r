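# Fixture builders and independent brute-force oracles. The oracles re-derive
# expected results with naive loops, deliberately sharing no code with the
# package internals they check.

# --- fixtures -------------------------------------------------------------

toy_dataset <- function() {
  df <- data.frame(
    x = c(1, 2, 3, 6, 8, 9),
    col = c("red", "red", "blue", "blue", "red", "blue"),
    cls = c("a", "a", "a", "b", "b", "b"),
    stringsAsFactors = FALSE)
  fdx_dataset(df, "cls")
}

# Random crisp rule over numeric features x1..x3 on [0, 10].
rand_rule <- function(max_preds = 6L, feats = c("x1", "x2", "x3"),
                      classes = c("a", "b")) {
  k <- sample.int(max_preds, 1L)
  preds <- lapply(seq_len(k), function(i)
    crisp_predicate(sample(feats, 1L),
                    sample(c("<", ">", "<=", ">="), 1L),
                    round(runif(1, 0, 10), 2)))
  crisp_rule(preds, sample(classes, 1L), runif(1))
}

rand_items <- function(n, feats = c("x1", "x2", "x3")) {
  out <- as.data.frame(lapply(feats, function(f) runif(n, -1, 11)))
  names(out) <- feats
  out
}

# Random small FIS: one or two numeric variables with ramp Low/High terms,
# two singleton output classes, one rule per class.
rand_fis <- function() {
  nv <- sample(1:2, 1L)
  vars <- list()
  for (i in seq_len(nv)) {
    nm <- paste0("v", i)
    thr <- runif(1, 2, 8)
    d <- runif(1, 0.3, 1.5)
    vars[[nm]] <- list(
      name = nm, kind = "numeric", universe = c(0, 10), source_feature = nm,
      terms = list(
        Low = list(label = "Low", form = "low",
                   mf = mf_piecewise(c(thr - d, thr + d), c(1, 0)),
                   thresholds = list()),
        High = list(label = "High", form = "high",
                    mf = mf_piecewise(c(thr - d, thr + d), c(0, 1)),
                    thresholds = list())))
  }
  vars[["out"]] <- list(
    name = "out", kind = "output", universe = c(0, 1),
    source_feature = "output",
    terms = list(
      a = list(label = "a", form = "output", mf = mf_singleton(0),
               thresholds = list()),
      b = list(label = "b", form = "output", mf = mf_singleton(1),
               thresholds = list())))
  rules <- list(
    list(predicates = lapply(seq_len(nv), function(i)
      list(variable = paste0("v", i), term = "Low")),
      consequent = list(variable = "out", term = "a"), weight = runif(1)),
    list(predicates = lapply(seq_len(nv), function(i)
      list(variable = paste0("v", i), term = "High")),
      consequent = list(variable = "out", term = "b"), weight = runif(1)))
  frb <- structure(list(rules = rules, variables = vars, output = "out"),
                   class = "fdx_frb")
  fis(frb, fis_config(tnorm = sample(c("min", "product"), 1L),
                      use_rule_weights = sample(c(TRUE, FALSE), 1L)))
}

# Synthetic stand-in for a breast-mass FNA dataset: 10 numeric mean-value
# features, 357 benign / 212 malignant records. Purely generated; used to
# exercise loader reporting, not to reproduce the real measurements.
write_synthetic_breast_csv <- function(path) {
  feats <- c("radius", "texture", "perimeter", "area", "smoothness",
             "compactness", "concavity", "concave_points", "symmetry",
             "fractal_dimension")
  n <- c(benign = 357, malignant = 212)
  set.seed(42)
  rows <- do.call(rbind, lapply(names(n), function(cl) {
    shift <- if (cl == "malignant") 3 else 0
    m <- as.data.frame(lapply(feats, function(f)
      round(runif(n[[cl]], 5 + shift, 15 + shift), 3)))
    names(m) <- feats
    m$diagnosis <- cl
    m
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}

# Hand-built one-input FIS with ramps at 4.5-5.5 and singleton outputs 0/1.
fis_fixture <- function(tnorm = "min", use_weights = FALSE,
                        aggregation = "max") {
  vars <- list(
    x = list(name = "x", kind = "numeric", universe = c(0, 10),
             source_feature = "x",
             terms = list(
               Low = list(label = "Low", form = "low",
                          mf = mf_piecewise(c(4.5, 5.5), c(1, 0)),
                          thresholds = list()),
               High = list(label = "High", form = "high",
                           mf = mf_piecewise(c(4.5, 5.5), c(0, 1)),
                           thresholds = list()))),
    out = list(name = "out", kind = "output", universe = c(0, 1),
               source_feature = "output",
               terms = list(
                 a = list(label = "a", form = "output", mf = mf_singleton(0),
                          thresholds = list()),
                 b = list(label = "b", form = "output", mf = mf_singleton(1),
                          thresholds = list()))))
  rules <- list(
    list(predicates = list(list(variable = "x", term = "Low")),
         consequent = list(variable = "out", term = "a"), weight = 1),
    list(predicates = list(list(variable = "x", term = "High")),
         consequent = list(variable = "out", term = "b"), weight = 0.5))
  frb <- structure(list(rules = rules, variables = vars, output = "out"),
                   class = "fdx_frb")
  fis(frb, fis_config(tnorm = tnorm, aggregation = aggregation,
                      use_rule_weights = use_weights))
}

# --- independent oracles --------------------------------------------------

# Naive per-item predicate check.
oracle_pred <- function(p, item) {
  v <- item[[p$feature]]
  switch(p$op,
         "<" = v < p$value, ">" = v > p$value,
         "<=" = v <= p$value, ">=" = v >= p$value,
         "==" = v == p$value, "!=" = v != p$value)
}

oracle_fire <- function(r, item) all(vapply(r$predicates, oracle_pred,
                                            logical(1), item = item))

# Brute-force classification with the multi-fire tie policy: highest weight,
# then longest antecedent, then earliest rule.
oracle_classify <- function(rb, item) {
  fired <- which(vapply(rb$rules, oracle_fire, logical(1), item = item))
  if (length(fired) == 0L) return(NA_character_)
  w <- vapply(rb$rules[fired], `[[`, numeric(1), "weight")
  fired <- fired[w == max(w)]
  len <- vapply(rb$rules[fired], function(r) length(r$predicates), integer(1))
  fired <- fired[len == max(len)]
  rb$rules[[min(fired)]]$consequent
}

# Exhaustive candidate-split search with independently coded gain ratio.
oracle_root_split <- function(df, class, min_leaf = 2L) {
  ent <- function(v) {
    p <- as.numeric(table(v)) / length(v)
    -sum(p * log2(p))
  }
  cls <- df[[class]]
  n <- nrow(df)
  best <- NULL
  for (f in setdiff(names(df), class)) {
    x <- df[[f]]
    stopifnot(is.numeric(x))
    su <- sort(unique(x))
    if (length(su) < 2L) next
    for (thr in (su[-1] + su[-length(su)]) / 2) {
      l <- cls[x <= thr]; r <- cls[x > thr]
      if (length(l) < min_leaf || length(r) < min_leaf) next
      gain <- ent(cls) - (length(l) / n) * ent(l) - (length(r) / n) * ent(r)
      if (gain <= 1e-12) next
      si <- ent(c(rep("L", length(l)), rep("R", length(r))))
      ratio <- gain / si
      if (is.null(best) || ratio > best$ratio + 1e-12)
        best <- list(feature = f, threshold = thr, ratio = ratio)
    }
  }
  best
}

# Manual linear interpolation with constant extension.
oracle_interp <- function(u, mu, x) {
  if (x <= u[1]) return(mu[1])
  if (x >= u[length(u)]) return(mu[length(mu)])
  i <- max(which(u <= x))
  mu[i] + (mu[i + 1] - mu[i]) * (x - u[i]) / (u[i + 1] - u[i])
}

# Independent mini inference engine for singleton-output FISs: per-term max
# aggregation of per-rule t-normed memberships, then the weighted mean of
# singleton positions.
oracle_cog <- function(fis, item) {
  vars <- fis$frb$variables
  out <- vars[[fis$frb$output]]
  acts <- setNames(rep(0, length(out$terms)), names(out$terms))
  for (r in fis$frb$rules) {
    degs <- vapply(r$predicates, function(p) {
      mf <- vars[[p$variable]]$terms[[p$term]]$mf
      if (mf$variant == "singleton") as.numeric(item[[p$variable]] == mf$position)
      else oracle_interp(mf$u, mf$mu, item[[p$variable]])
    }, numeric(1))
    a <- if (length(degs) == 0L) 1
         else if (fis$config$tnorm == "min") min(degs) else prod(degs)
    if (fis$config$use_rule_weights) a <- a * r$weight
    tn <- r$consequent$term
    acts[tn] <- max(acts[tn], a)
  }
  if (sum(acts) == 0) return(NA_real_)
  s <- vapply(out$terms, function(t) t$mf$position, numeric(1))
  sum(acts * s) / sum(acts)
}
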