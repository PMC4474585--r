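# Token-pattern rule language
#
# One rule per line:   LABEL => [attr=v1|v2, attr!="v"]{m,n}, [..]?, [..]
# Attributes: token (surface, case-insensitive), syn (POS), sem (semantic
# tag), orth (compressed word shape). A bare spec matches exactly one
# token; "?" makes it optional; "{m,n}" allows m..n consecutive tokens.

RULE_ATTRS <- c("token", "syn", "sem", "orth")

rule_error <- function(line, col, ...) {
  stop("rule parse error at column ", col, ": ", paste0(..., collapse = ""),
       "\n  in: ", line, call. = FALSE)
}

# scanner over a single rule body; returns specs list
parse_specs <- function(body, line, col0) {
  i <- 1L; n <- nchar(body)
  ch <- function(k) substring(body, k, k)
  skip_ws <- function() while (i <= n && grepl("^\\s$", ch(i))) i <<- i + 1L
  specs <- list()
  repeat {
    skip_ws()
    if (i > n) break
    if (ch(i) != "[")
      rule_error(line, col0 + i, "expected '['")
    open_col <- i
    i <- i + 1L
    # find matching ']' respecting quotes
    inner_start <- i; depth_q <- FALSE
    while (i <= n && (depth_q || ch(i) != "]")) {
      if (ch(i) == "\"") depth_q <- !depth_q
      i <- i + 1L
    }
    if (i > n)
      rule_error(line, col0 + open_col, "unbalanced bracket")
    inner <- substring(body, inner_start, i - 1L)
    i <- i + 1L
    constraints <- parse_constraints(inner, line, col0 + inner_start)
    min_count <- 1L; max_count <- 1L
    skip_ws()
    if (i <= n && ch(i) == "?") { min_count <- 0L; i <- i + 1L }
    else if (i <= n && ch(i) == "{") {
      close <- regexpr("}", substring(body, i))[1]
      if (close == -1L) rule_error(line, col0 + i, "unbalanced '{'")
      iter <- substring(body, i + 1L, i + close - 2L)
      m <- regexec("^\\s*(\\d+)\\s*,\\s*(\\d+)\\s*$", iter)[[1]]
      if (m[1] == -1L)
        rule_error(line, col0 + i, "bad iterator '{", iter, "}'")
      parts <- regmatches(iter, regexec("^\\s*(\\d+)\\s*,\\s*(\\d+)\\s*$",
                                        iter))[[1]]
      min_count <- as.integer(parts[2]); max_count <- as.integer(parts[3])
      if (min_count > max_count)
        rule_error(line, col0 + i,
                   sprintf("iterator min %d > max %d", min_count, max_count))
      if (max_count < 1L)
        rule_error(line, col0 + i, "iterator max must be >= 1")
      i <- i + close
    }
    specs[[length(specs) + 1L]] <- list(constraints = constraints,
                                        min_count = min_count,
                                        max_count = max_count)
    skip_ws()
    if (i > n) break
    if (ch(i) != ",")
      rule_error(line, col0 + i, "expected ',' between token specifications")
    i <- i + 1L
  }
  specs
}

# split "attr=v1|v2, attr!=\"v\"" on commas outside quotes
split_outside_quotes <- function(x, sep) {
  out <- character(); buf <- ""; inq <- FALSE
  for (c_ in strsplit(x, "")[[1]]) {
    if (c_ == "\"") inq <- !inq
    if (c_ == sep && !inq) { out <- c(out, buf); buf <- "" }
    else buf <- paste0(buf, c_)
  }
  c(out, buf)
}

parse_constraints <- function(inner, line, col0) {
  parts <- split_outside_quotes(inner, ",")
  if (!length(parts) || all(!nzchar(trimws(parts))))
    rule_error(line, col0, "empty token specification")
  lapply(parts, function(p) {
    p <- trimws(p)
    m <- regmatches(p, regexec("^([a-z]+)\\s*(!?=)\\s*(.+)$", p))[[1]]
    if (!length(m))
      rule_error(line, col0, paste0("cannot parse constraint '", p, "'"))
    attr <- m[2]; op <- m[3]
    if (!attr %in% RULE_ATTRS)
      rule_error(line, col0, paste0("unknown attribute '", attr, "'"))
    vals <- trimws(split_outside_quotes(m[4], "|"))
    vals <- sub("^\"(.*)\"$", "\\1", vals)
    if (!length(vals) || any(!nzchar(vals)))
      rule_error(line, col0, "empty value list")
    list(attr = attr, op = op, values = vals)
  })
}

#' Parse one token-pattern rule
#'
#' Grammar: `LABEL => spec (, spec)*` where each spec is a bracketed
#' constraint list with an optional quantifier, e.g.
#' `SignSymptom => [syn=NN|NNP]{1,3}, [sem=beverb]?, [syn=VBN|JJ,
#' token!="normal"|"regular"|"stable"]`. Commas inside brackets separate
#' constraints; commas between brackets separate specs; values may be
#' double-quoted; `?` means 0..1 occurrences, `{m,n}` means m..n.
#'
#' @param line rule text.
#' @param rule_id identifier recorded on the rule.
#' @param source_line line number in the originating file (conflict
#'   tie-break).
#' @return A `pheno_rule`.
#' @export
parse_rule <- function(line, rule_id = "r1", source_line = 1L) {
  m <- regexec("^\\s*([A-Za-z]+)\\s*=>\\s*(.*\\S)\\s*$", line)[[1]]
  if (m[1] == -1L)
    rule_error(line, 1L, "expected 'LABEL => specs'")
  parts <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=>\\s*(.*\\S)\\s*$",
                                    line))[[1]]
  label <- parts[2]
  if (!label %in% phenotype_classes())
    rule_error(line, 1L, paste0("unknown entity label '", label, "'"))
  body_col <- regexpr("=>", line)[1] + 2L
  specs <- parse_specs(parts[3], line, body_col)
  if (!length(specs)) rule_error(line, body_col, "rule has no specs")
  if (all(vapply(specs, function(s) s$min_count, 0L) == 0L))
    rule_error(line, body_col,
               "rule could match the empty sequence (all specs optional)")
  structure(list(label = label, specs = specs, rule_id = rule_id,
                 source_line = as.integer(source_line)),
            class = "pheno_rule")
}

#' Format a rule back into its source syntax
#'
#' `parse_rule(format_rule(r))` reproduces `r` structurally.
#'
#' @param rule a `pheno_rule`.
#' @return A single rule line.
#' @export
format_rule <- function(rule) {
  spec_str <- vapply(rule$specs, function(s) {
    cons <- vapply(s$constraints, function(cn) {
      vals <- vapply(cn$values, function(v) {
        if (cn$attr == "token" || grepl("[ ,|\\]\"]", v))
          paste0("\"", v, "\"") else v
      }, "")
      paste0(cn$attr, cn$op, paste(vals, collapse = "|"))
    }, "")
    q <- if (s$min_count == 1L && s$max_count == 1L) ""
         else if (s$min_count == 0L && s$max_count == 1L) "?"
         else sprintf("{%d,%d}", s$min_count, s$max_count)
    paste0("[", paste(cons, collapse = ", "), "]", q)
  }, "")
  paste0(rule$label, " => ", paste(spec_str, collapse = ", "))
}

#' @export
print.pheno_rule <- function(x, ...) {
  cat("<pheno_rule>", x$rule_id, ":", format_rule(x), "\n")
  invisible(x)
}

#' Read a rule file
#'
#' One rule per line; `#` starts a comment; blank lines are ignored.
#'
#' @param path rule file.
#' @return List of `pheno_rule`.
#' @export
read_rules <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  rules <- list()
  for (ln in seq_along(lines)) {
    line <- sub("#.*$", "", lines[ln])
    if (!nzchar(trimws(line))) next
    rules[[length(rules) + 1L]] <-
      parse_rule(line, rule_id = sprintf("%s:%d", basename(path), ln),
                 source_line = ln)
  }
  rules
}

#' Starter rule pack
#'
#' Loads the small bundled rule set built around the documented
#' noun-phrase + copula + participle/adjective pattern and its variants.
#' It is a worked example, not a full production grammar.
#'
#' @return List of `pheno_rule`.
#' @export
starter_rules <- function() {
  read_rules(system.file("extdata", "starter.rules", package = "phenoNER"))
}

# Closed word list realizing the `sem=beverb` tag, so the worked example
# needs no lexicon pass.
BEVERB <- c("is", "are", "was", "were", "be", "been", "being", "'s")

token_attr <- function(token, attr) {
  switch(attr,
         token = token$text,
         syn = token$pos,
         sem = {
           s <- token$sem
           if ((is.na(s) || !nzchar(s)) && tolower(token$text) %in% BEVERB)
             "beverb" else s
         },
         orth = word_shape(token$text))
}

#' Test one token specification against one token
#'
#' Every `=` constraint must be satisfied by membership of the token's
#' attribute in the value list, every `!=` by non-membership. Surface
#' (`token`) comparison is case-insensitive; `syn`/`sem`/`orth` are
#' case-sensitive. A missing attribute (e.g. no semantic tag) fails `=`
#' constraints and passes `!=` constraints.
#'
#' @param spec one spec from a parsed rule.
#' @param token one row of a token data frame.
#' @return `TRUE` or `FALSE`.
#' @export
spec_matches <- function(spec, token) {
  for (cn in spec$constraints) {
    val <- token_attr(token, cn$attr)
    if (is.null(val) || length(val) == 0L || is.na(val) || !nzchar(val)) {
      if (cn$op == "=") return(FALSE) else next
    }
    vals <- cn$values
    if (cn$attr == "token") { val <- tolower(val); vals <- tolower(vals) }
    hit <- val %in% vals
    if (cn$op == "=" && !hit) return(FALSE)
    if (cn$op == "!=" && hit) return(FALSE)
  }
  TRUE
}

# longest end position (token index, exclusive) reachable matching
# specs[s..] starting at token p; -1 if no expansion succeeds
match_from <- function(specs, s, tokens, p) {
  if (s > length(specs)) return(p)
  spec <- specs[[s]]
  n <- nrow(tokens)
  best <- -1L
  k <- 0L
  repeat {
    if (k >= spec$min_count) {
      e <- match_from(specs, s + 1L, tokens, p + k)
      if (e > best) best <- e
    }
    if (k == spec$max_count) break
    if (p + k > n) break
    if (!spec_matches(spec, tokens[p + k, , drop = FALSE])) break
    k <- k + 1L
  }
  best
}

#' Match one rule against one sentence
#'
#' Reports leftmost-longest matches: at each start token all iterator
#' expansions are explored and the longest successful span wins; the scan
#' resumes after each reported match, so one rule never yields overlapping
#' matches.
#'
#' @param rule a `pheno_rule`.
#' @param tokens a sentence token data frame.
#' @param sentence sentence index recorded on matches.
#' @return Data frame of matches (`rule_id`, `sentence`, `tok_start`,
#'   `tok_end`, `start`, `end`, `label`), possibly empty.
#' @export
match_rule <- function(rule, tokens, sentence = 1L) {
  n <- nrow(tokens)
  res <- list()
  t <- 1L
  while (t <= n) {
    e <- match_from(rule$specs, 1L, tokens, t)
    if (e > t) {
      res[[length(res) + 1L]] <- data.frame(
        rule_id = rule$rule_id, sentence = sentence, tok_start = t,
        tok_end = e, start = tokens$start[t], end = tokens$end[e - 1L],
        label = rule$label, stringsAsFactors = FALSE)
      t <- e
    } else t <- t + 1L
  }
  if (!length(res))
    return(data.frame(rule_id = character(), sentence = integer(),
                      tok_start = integer(), tok_end = integer(),
                      start = integer(), end = integer(),
                      label = character(), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Apply a rule set to a document
#'
#' Pools per-rule matches over all sentences and resolves overlap
#' conflicts by earlier start, then longer span, then lower source line;
#' the surviving mentions never overlap.
#'
#' @param rules list of `pheno_rule`.
#' @param doc a tokenized, POS-tagged `pheno_document`.
#' @return Data frame of entity mentions.
#' @export
apply_ruleset <- function(rules, doc) {
  stopifnot(inherits(doc, "pheno_document"))
  all_m <- list()
  for (r in rules)
    for (si in seq_along(doc$sentences)) {
      m <- match_rule(r, doc$sentences[[si]], si)
      if (nrow(m)) {
        m$source_line <- r$source_line
        all_m[[length(all_m) + 1L]] <- m
      }
    }
  empty <- data.frame(doc_id = character(), start = integer(),
                      end = integer(), label = character(),
                      text = character(), stringsAsFactors = FALSE)
  if (!length(all_m)) return(empty)
  m <- do.call(rbind, all_m)
  m <- m[order(m$start, -(m$end - m$start), m$source_line), , drop = FALSE]
  keep <- logical(nrow(m))
  kept <- m[0, , drop = FALSE]
  for (i in seq_len(nrow(m))) {
    if (!nrow(kept) || all(m$start[i] >= kept$end | m$end[i] <= kept$start)) {
      keep[i] <- TRUE
      kept <- rbind(kept, m[i, , drop = FALSE])
    }
  }
  m <- m[keep, , drop = FALSE]
  out <- data.frame(doc_id = doc$doc_id, start = m$start, end = m$end,
                    label = m$label,
                    text = substring(doc$text, m$start + 1L, m$end),
                    stringsAsFactors = FALSE)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
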