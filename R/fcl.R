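# IEC 61131-7 Fuzzy Control Language import/export for the subset of FISs the
# pipeline produces: piecewise-linear input terms, singleton output terms,
# COGS defuzzification, MIN/MAX rule blocks with weighted rules.

fcl_ident <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Export a fuzzy inference system to FCL text
#'
#' Writes an IEC 61131-7 Fuzzy Control Language FUNCTION_BLOCK: FUZZIFY
#' blocks with piecewise-linear term points, a DEFUZZIFY block with singleton
#' terms and method COGS, and a RULEBLOCK with the configured operators and
#' weighted rules. Numbers are printed at full precision so that re-importing
#' reproduces the system. Variable and term names are sanitised to FCL
#' identifiers (non-alphanumeric characters become underscores); categorical
#' input terms are exported as singletons at their declaration positions.
#'
#' @param fis an [fis()].
#' @param path optional output file.
#' @return the FCL document as a character vector of lines (invisibly when
#'   written to file).
#' @export
export_fcl <- function(fis, path = NULL) {
  stopifnot(inherits(fis, "fdx_fis"))
  frb <- fis$frb
  cfg <- fis$config
  if (cfg$defuzzifier != "cog_singleton")
    stop_fdx("FCL export supports the COGS (cog_singleton) defuzzifier only")
  out_name <- frb$output
  vars <- frb$variables
  in_names <- setdiff(names(vars), out_name)
  L <- c("FUNCTION_BLOCK fuzzydx", "", "VAR_INPUT")
  for (vn in in_names) L <- c(L, sprintf("  %s : REAL;", fcl_ident(vn)))
  L <- c(L, "END_VAR", "", "VAR_OUTPUT",
         sprintf("  %s : REAL;", fcl_ident(out_name)), "END_VAR", "")
  for (vn in in_names) {
    v <- vars[[vn]]
    L <- c(L, sprintf("FUZZIFY %s", fcl_ident(vn)))
    pos <- 0
    for (tn in names(v$terms)) {
      mf <- v$terms[[tn]]$mf
      if (mf$variant == "piecewise_linear") {
        pts <- paste(sprintf("(%s, %s)", fmt_num(mf$u), fmt_num(mf$mu)),
                     collapse = " ")
        L <- c(L, sprintf("  TERM %s := %s;", fcl_ident(tn), pts))
      } else {
        L <- c(L, sprintf("  TERM %s := %s;", fcl_ident(tn),
                          fmt_num(mf$position)))
      }
      pos <- pos + 1
    }
    L <- c(L, "END_FUZZIFY", "")
  }
  ov <- vars[[out_name]]
  L <- c(L, sprintf("DEFUZZIFY %s", fcl_ident(out_name)))
  for (tn in names(ov$terms))
    L <- c(L, sprintf("  TERM %s := %s;", fcl_ident(tn),
                      fmt_num(ov$terms[[tn]]$mf$position)))
  L <- c(L, "  METHOD : COGS;", "  DEFAULT := NC;", "END_DEFUZZIFY", "")
  and_op <- toupper(cfg$tnorm)            # MIN | PRODUCT
  or_op <- switch(cfg$snorm, max = "MAX", probabilistic_sum = "ASUM",
                  bounded_sum = "BSUM")
  act_op <- toupper(cfg$implication)
  accu_op <- switch(cfg$aggregation, max = "MAX", sum = "SUM")
  L <- c(L, "RULEBLOCK rules",
         sprintf("  AND : %s;", and_op),
         sprintf("  OR : %s;", or_op),
         sprintf("  ACT : %s;", act_op),
         sprintf("  ACCU : %s;", accu_op))
  for (i in seq_along(frb$rules)) {
    r <- frb$rules[[i]]
    lhs <- paste(vapply(r$predicates, function(p)
      sprintf("%s IS %s", fcl_ident(p$variable), fcl_ident(p$term)),
      character(1)), collapse = " AND ")
    if (!nzchar(lhs)) lhs <- "TRUE"
    # WITH clauses are emitted only when weights participate in inference, so
    # that their presence round-trips the use_rule_weights flag
    with_part <- if (cfg$use_rule_weights)
      sprintf(" WITH %s", fmt_num(r$weight)) else ""
    L <- c(L, sprintf("  RULE %d : IF %s THEN %s IS %s%s;",
                      i, lhs, fcl_ident(out_name),
                      fcl_ident(r$consequent$term), with_part))
  }
  L <- c(L, "END_RULEBLOCK", "", "END_FUNCTION_BLOCK")
  if (!is.null(path)) { writeLines(L, path); return(invisible(L)) }
  L
}

#' Import a fuzzy inference system from FCL text
#'
#' Parses the FCL subset written by [export_fcl()] and rebuilds the
#' [fis()]: term breakpoints, output singletons, operators and rule weights
#' survive the round trip exactly.
#'
#' @param text_or_path FCL document (character vector of lines or a single
#'   string) or a path to an `.fcl` file.
#' @return an [fis()].
#' @export
import_fcl <- function(text_or_path) {
  if (length(text_or_path) == 1L && file.exists(text_or_path))
    lines <- readLines(text_or_path)
  else
    lines <- unlist(strsplit(text_or_path, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  variables <- list()
  rules <- list()
  output <- NULL
  cfg_ops <- list(AND = "MIN", OR = "MAX", ACT = "MIN", ACCU = "MAX")
  saw_with <- FALSE
  i <- 1L
  parse_term <- function(line) {
    m <- regmatches(line, regexec("^TERM\\s+(\\S+)\\s*:=\\s*(.+);\\s*$", line))[[1]]
    if (length(m) == 0L) stop_fdx("malformed TERM line: %s", line)
    label <- m[2]; rhs <- m[3]
    pts <- regmatches(rhs, gregexpr("\\(([^,]+),\\s*([^)]+)\\)", rhs))[[1]]
    if (length(pts) > 0L) {
      u <- as.numeric(sub("\\(([^,]+),.*", "\\1", pts))
      mu <- as.numeric(sub(".*,\\s*([^)]+)\\)", "\\1", pts))
      list(label = label, mf = mf_piecewise(u, mu))
    } else {
      list(label = label, mf = mf_singleton(as.numeric(rhs)))
    }
  }
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^FUZZIFY\\s", ln) || grepl("^DEFUZZIFY\\s", ln)) {
      is_out <- grepl("^DEFUZZIFY", ln)
      vn <- sub("^(DE)?FUZZIFY\\s+", "", ln)
      terms <- list()
      i <- i + 1L
      while (!grepl("^END_(DE)?FUZZIFY", lines[i])) {
        if (grepl("^TERM\\s", lines[i])) {
          t <- parse_term(lines[i])
          terms[[t$label]] <- list(label = t$label,
                                   form = if (is_out) "output" else "imported",
                                   mf = t$mf, thresholds = list())
        }
        i <- i + 1L
      }
      us <- unlist(lapply(terms, function(t)
        if (t$mf$variant == "singleton") t$mf$position else t$mf$u))
      uni <- range(us)
      if (uni[1] == uni[2]) uni <- uni + c(0, 1)
      kind <- if (is_out) "output"
              else if (all(vapply(terms, function(t)
                t$mf$variant == "singleton", logical(1)))) "categorical"
              else "numeric"
      variables[[vn]] <- list(name = vn, kind = kind, universe = uni,
                              source_feature = if (is_out) "output" else vn,
                              terms = terms)
      if (is_out) output <- vn
    } else if (grepl("^RULEBLOCK", ln)) {
      i <- i + 1L
      while (!grepl("^END_RULEBLOCK", lines[i])) {
        rl <- lines[i]
        m <- regmatches(rl, regexec(
          "^(AND|OR|ACT|ACCU)\\s*:\\s*(\\S+?);", rl))[[1]]
        if (length(m) > 0L) cfg_ops[[m[2]]] <- m[3]
        m <- regmatches(rl, regexec(
          "^RULE\\s+\\d+\\s*:\\s*IF\\s+(.*)\\s+THEN\\s+(\\S+)\\s+IS\\s+(\\S+?)(\\s+WITH\\s+(\\S+))?;\\s*$",
          rl))[[1]]
        if (length(m) > 0L) {
          lhs <- m[2]
          preds <- list()
          if (lhs != "TRUE") {
            for (part in strsplit(lhs, "\\s+AND\\s+")[[1]]) {
              pm <- regmatches(part, regexec("^(\\S+)\\s+IS\\s+(\\S+)$", part))[[1]]
              if (length(pm) == 0L) stop_fdx("malformed predicate: %s", part)
              preds[[length(preds) + 1L]] <- list(variable = pm[2], term = pm[3])
            }
          }
          has_with <- nzchar(m[6] %||% "")
          if (has_with) saw_with <- TRUE
          w <- if (has_with) as.numeric(m[6]) else 1
          rules[[length(rules) + 1L]] <-
            list(predicates = preds,
                 consequent = list(variable = m[3], term = m[4]),
                 weight = w)
        }
        i <- i + 1L
      }
    }
    i <- i + 1L
  }
  if (is.null(output)) stop_fdx("no DEFUZZIFY block found")
  frb <- structure(list(rules = rules, variables = variables,
                        output = output), class = "fdx_frb")
  cfg <- fis_config(
    tnorm = switch(cfg_ops$AND, MIN = "min", PRODUCT = "product",
                   stop_fdx("unsupported AND operator '%s'", cfg_ops$AND)),
    snorm = switch(cfg_ops$OR, MAX = "max", ASUM = "probabilistic_sum",
                   BSUM = "bounded_sum",
                   stop_fdx("unsupported OR operator '%s'", cfg_ops$OR)),
    implication = switch(cfg_ops$ACT, MIN = "min", PRODUCT = "product",
                         stop_fdx("unsupported ACT operator '%s'", cfg_ops$ACT)),
    aggregation = switch(cfg_ops$ACCU, MAX = "max", SUM = "sum",
                         stop_fdx("unsupported ACCU operator '%s'", cfg_ops$ACCU)),
    defuzzifier = "cog_singleton", reasoning = "singleton",
    use_rule_weights = saw_with)
  fis(frb, cfg)
}
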