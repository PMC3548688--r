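# Stage 1: gain-ratio decision-tree induction and conversion of root-to-leaf
# paths into a weighted-DNF crisp rule base.

entropy <- function(cls) {
  p <- table(cls) / length(cls)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Candidate numeric thresholds: midpoints between consecutive sorted distinct
# values observed at the node.
numeric_candidates <- function(x) {
  u <- sort(unique(x))
  if (length(u) < 2L) return(numeric(0))
  (u[-1] + u[-length(u)]) / 2
}

# Score a split given the branch assignment (integer vector, NA excluded
# branches not allowed). Returns c(gain, gain_ratio).
split_score <- function(cls, branch) {
  n <- length(cls)
  h0 <- entropy(cls)
  sizes <- table(branch)
  hw <- 0
  for (b in names(sizes)) hw <- hw + (sizes[[b]] / n) * entropy(cls[branch == b])
  gain <- h0 - hw
  p <- as.numeric(sizes) / n
  split_info <- -sum(p * log2(p))
  ratio <- if (split_info > 0) gain / split_info else 0
  c(gain = gain, ratio = ratio)
}

# Vectorised scoring of every numeric threshold for one feature: sort once,
# score all candidate cuts from cumulative class counts.
numeric_split_scores <- function(x, cls, min_leaf) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  ind <- outer(cls[ord], sort(unique(cls)), `==`) + 0
  cum <- apply(ind, 2L, cumsum)
  cut_after <- which(xs[-n] < xs[-1])        # boundary between distinct values
  if (length(cut_after) == 0L) return(NULL)
  thr <- (xs[cut_after] + xs[cut_after + 1L]) / 2
  left <- cum[cut_after, , drop = FALSE]
  total <- cum[n, ]
  right <- sweep(-left, 2L, total, `+`)
  nl <- rowSums(left); nr <- rowSums(right)
  hcounts <- function(m, sz) {
    p <- m / sz
    rowSums(ifelse(p > 0, -p * log2(p), 0))
  }
  h0 <- hcounts(matrix(total, 1L), n)
  gain <- h0 - (nl / n) * hcounts(left, nl) - (nr / n) * hcounts(right, nr)
  pl <- nl / n; pr <- nr / n
  split_info <- -(pl * log2(pl) + pr * log2(pr))
  ratio <- ifelse(split_info > 0, gain / split_info, 0)
  ok <- nl >= min_leaf & nr >= min_leaf & gain > 1e-12
  if (!any(ok)) return(NULL)
  list(threshold = thr[ok], ratio = ratio[ok])
}

best_split <- function(ds, idx, min_leaf) {
  data <- ds$data[idx, , drop = FALSE]
  cls <- data[[ds$class]]
  best <- NULL
  for (fi in seq_along(ds$features)) {
    f <- ds$features[[fi]]
    x <- data[[f$name]]
    if (f$kind == "numeric") {
      sc <- numeric_split_scores(x, cls, min_leaf)
      if (is.null(sc)) next
      for (ci in seq_along(sc$threshold)) {
        key <- c(sc$ratio[ci], -fi, -sc$threshold[ci])
        if (is.null(best) || lex_gt(key, best$key))
          best <- list(key = key, feature = f$name, kind = "numeric",
                       threshold = sc$threshold[ci], ratio = sc$ratio[ci])
      }
    } else {
      vals <- sort(unique(x))
      if (length(vals) < 2L) next
      branch <- match(x, vals)
      if (min(table(branch)) < min_leaf) next
      sc <- split_score(cls, branch)
      if (sc[["gain"]] <= 1e-12) next
      key <- c(sc[["ratio"]], -fi, 0)
      if (is.null(best) || lex_gt(key, best$key))
        best <- list(key = key, feature = f$name, kind = "categorical",
                     values = vals, ratio = sc[["ratio"]])
    }
  }
  best
}

# Lexicographic strict greater-than with a small tolerance on the first
# component (gain ratio) so float noise cannot flip the feature/threshold
# tie-break.
lex_gt <- function(a, b) {
  if (a[1] > b[1] + 1e-12) return(TRUE)
  if (a[1] < b[1] - 1e-12) return(FALSE)
  for (i in 2:length(a)) {
    if (a[i] > b[i]) return(TRUE)
    if (a[i] < b[i]) return(FALSE)
  }
  FALSE
}

make_leaf <- function(ds, idx) {
  cls <- ds$data[idx, ds$class]
  tab <- table(cls)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1L) {
    # tie: globally most frequent class, then lexicographic
    gtab <- table(ds$data[[ds$class]])[top]
    top <- names(gtab)[gtab == max(gtab)]
    top <- sort(top)[1]
  }
  list(type = "leaf", class = top, n_items = length(idx),
       n_correct = as.integer(sum(cls == top)))
}

#' Induce a gain-ratio decision tree
#'
#' Greedy top-down induction in the C4.5 style: numeric features are split
#' binarily at midpoints between consecutive sorted distinct values
#' (`<= v` / `> v`), categorical features by multiway equality; the candidate
#' with the highest gain ratio (among positive-information-gain splits whose
#' children all hold at least `min_leaf` items) is chosen. Recursion stops on
#' node purity, `min_leaf`, `max_depth`, or when no admissible split remains.
#' Leaves predict the majority class, ties resolved by the globally most
#' frequent class then lexicographic order. No pruning is applied by default:
#' the selection stage plays the generalisation role in this methodology.
#'
#' @param ds an [fdx_dataset()].
#' @param min_leaf minimum number of items per child node (default 2).
#' @param max_depth maximum tree depth, `Inf` for unbounded.
#' @return an object of class `fdx_tree` (nested list of internal and leaf
#'   nodes).
#' @export
induce_tree <- function(ds, min_leaf = 2L, max_depth = Inf) {
  stopifnot(inherits(ds, "fdx_dataset"))
  n <- nrow(ds$data)
  if (n == 0L) stop_fdx("cannot induce a tree from an empty dataset")
  if (n < min_leaf) stop_fdx("fewer items (%d) than min_leaf (%d)", n, min_leaf)
  grow <- function(idx, depth) {
    cls <- ds$data[idx, ds$class]
    if (length(unique(cls)) == 1L || depth >= max_depth)
      return(make_leaf(ds, idx))
    sp <- best_split(ds, idx, min_leaf)
    if (is.null(sp)) return(make_leaf(ds, idx))
    x <- ds$data[idx, sp$feature]
    if (sp$kind == "numeric") {
      kids <- list(grow(idx[x <= sp$threshold], depth + 1L),
                   grow(idx[x > sp$threshold], depth + 1L))
      list(type = "split", feature = sp$feature, kind = "numeric",
           threshold = sp$threshold, children = kids)
    } else {
      kids <- lapply(sp$values, function(v) grow(idx[x == v], depth + 1L))
      list(type = "split", feature = sp$feature, kind = "categorical",
           values = sp$values, children = kids)
    }
  }
  structure(grow(seq_len(n), 0L), class = "fdx_tree")
}

#' @export
print.fdx_tree <- function(x, ...) {
  rec <- function(node, indent, label) {
    pad <- strrep("|   ", indent)
    if (nzchar(label)) cat(pad, label, "\n", sep = "")
    if (node$type == "leaf") {
      cat(pad, sprintf("-> %s (%d/%d)", node$class, node$n_correct,
                       node$n_items), "\n", sep = "")
    } else if (node$kind == "numeric") {
      rec(node$children[[1]], indent + 1L,
          sprintf("%s <= %g", node$feature, node$threshold))
      rec(node$children[[2]], indent + 1L,
          sprintf("%s > %g", node$feature, node$threshold))
    } else {
      for (i in seq_along(node$values))
        rec(node$children[[i]], indent + 1L,
            sprintf("%s = %s", node$feature, node$values[i]))
    }
  }
  rec(unclass(x), 0L, "")
  invisible(x)
}

# Predict with the tree directly (used to check path/rule equivalence).
tree_predict <- function(tree, newdata) {
  one <- function(node, item) {
    while (node$type != "leaf") {
      if (node$kind == "numeric") {
        node <- if (item[[node$feature]] <= node$threshold)
          node$children[[1]] else node$children[[2]]
      } else {
        j <- match(item[[node$feature]], node$values)
        if (is.na(j)) return(NA_character_)  # unseen category
        node <- node$children[[j]]
      }
    }
    node$class
  }
  vapply(seq_len(nrow(newdata)), function(i)
    one(unclass(tree), as.list(newdata[i, , drop = FALSE])), character(1))
}

#' Convert a decision tree into a weighted-DNF rule base
#'
#' Emits one crisp rule per leaf: the antecedent is the conjunction of path
#' tests (numeric tests as `<=` / `>` predicates, categorical as `==`), the
#' consequent is the leaf class. With `weights = "coverage"` (default) the
#' rule weight is the leaf's count of correctly classified training items —
#' the coverage figure printed in brackets alongside extracted rules; with
#' `weights = "equal"` all weights are 1. Rules are ordered per class by
#' descending weight.
#'
#' @param tree an [induce_tree()] result.
#' @param classes character vector of all class values.
#' @param weights `"coverage"` or `"equal"`.
#' @return an [crisp_rulebase()].
#' @export
tree_to_rules <- function(tree, classes, weights = c("coverage", "equal")) {
  weights <- match.arg(weights)
  rules <- list()
  rec <- function(node, preds) {
    if (node$type == "leaf") {
      w <- if (weights == "coverage") node$n_correct else 1
      rules[[length(rules) + 1L]] <<- crisp_rule(preds, node$class, w)
      return(invisible())
    }
    if (node$kind == "numeric") {
      rec(node$children[[1]],
          c(preds, list(crisp_predicate(node$feature, "<=", node$threshold))))
      rec(node$children[[2]],
          c(preds, list(crisp_predicate(node$feature, ">", node$threshold))))
    } else {
      for (i in seq_along(node$values))
        rec(node$children[[i]],
            c(preds, list(crisp_predicate(node$feature, "==", node$values[i]))))
    }
  }
  rec(unclass(tree), list())
  cons <- vapply(rules, `[[`, character(1), "consequent")
  wts <- vapply(rules, `[[`, numeric(1), "weight")
  ord <- order(match(cons, classes), -wts)
  crisp_rulebase(rules[ord], classes)
}
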