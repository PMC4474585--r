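# Shared fixture builders and independent brute-force oracles.

# token frame from words (+ optional POS), single-space separated
tok <- function(words, pos = NA_character_, chunk = "B-NP") {
  starts <- cumsum(c(0L, utils::head(nchar(words), -1L) + 1L))
  phenoNER:::new_token_frame(words, starts, starts + nchar(words),
                             pos, chunk)
}

# one-sentence document from words/POS
doc1 <- function(words, pos = NA_character_, doc_id = "d1",
                 style = "discharge") {
  document_from_tokens(doc_id, style, list(tok(words, pos)))
}

# random mention set over a corpus, token-aligned and non-overlapping
random_mentions <- function(docs, n_per_doc = 3L,
                            classes = phenotype_classes()) {
  rows <- list()
  for (doc in docs) {
    for (si in seq_along(doc$sentences)) {
      s <- doc$sentences[[si]]
      if (nrow(s) < 2L) next
      picked <- 0L
      used <- rep(FALSE, nrow(s))
      for (try in seq_len(10L)) {
        if (picked >= n_per_doc) break
        a <- sample.int(nrow(s), 1L)
        b <- min(nrow(s), a + sample.int(2L, 1L) - 1L)
        if (any(used[a:b])) next
        used[a:b] <- TRUE
        picked <- picked + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          doc_id = doc$doc_id, start = s$start[a], end = s$end[b],
          label = sample(classes, 1L),
          text = substring(doc$text, s$start[a] + 1L, s$end[b]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

# ---- rule-engine oracle ----------------------------------------------------

# every expansion of the specs consuming tokens p..? exactly; returns all
# reachable end positions (exclusive), by full enumeration
oracle_ends <- function(specs, tokens, p, s = 1L) {
  if (s > length(specs)) return(p)
  spec <- specs[[s]]
  ends <- integer()
  for (k in spec$min_count:spec$max_count) {
    if (p + k - 1L > nrow(tokens)) break
    ok <- k == 0L ||
      all(vapply(p:(p + k - 1L), function(t)
        spec_matches(spec, tokens[t, , drop = FALSE]), TRUE))
    if (!ok) next
    ends <- c(ends, oracle_ends(specs, tokens, p + k, s + 1L))
  }
  unique(ends)
}

# leftmost-longest scan built on the enumeration above
oracle_match_rule <- function(rule, tokens) {
  t <- 1L; res <- list()
  while (t <= nrow(tokens)) {
    ends <- oracle_ends(rule$specs, tokens, t)
    ends <- ends[ends > t]
    if (length(ends)) {
      e <- max(ends)
      res[[length(res) + 1L]] <- c(start = t, end = e)
      t <- e
    } else t <- t + 1L
  }
  res
}

# random rule generator for the parse/format round trip
random_rule <- function() {
  word_pool <- c("normal", "regular", "stable", "pain", "edema", "NN",
                 "NNP", "JJ", "VBN", "beverb", "dsyn", "Xx", "x")
  n_specs <- sample(1:3, 1L)
  repeat {
    specs <- replicate(n_specs, {
      n_con <- sample(1:2, 1L)
      cons <- replicate(n_con, {
        attr <- sample(c("token", "syn", "sem", "orth"), 1L)
        op <- sample(c("=", "!="), 1L)
        vals <- sample(word_pool, sample(1:3, 1L))
        paste0(attr, op, paste0('"', vals, '"', collapse = "|"))
      })
      q <- sample(c("", "?", "{1,3}", "{2,2}", "{0,2}"), 1L)
      paste0("[", paste(cons, collapse = ", "), "]", q)
    })
    quant_min0 <- grepl("\\]\\?$|\\]\\{0", specs)
    if (!all(quant_min0)) break
  }
  paste0(sample(phenotype_classes(), 1L), " => ",
         paste(specs, collapse = ", "))
}

# ---- evaluation oracle -----------------------------------------------------

# direct double-loop scorer, independent of span_prf internals
oracle_prf <- function(gold, pred, mode, classes = phenotype_classes()) {
  per_class <- lapply(classes, function(cls) {
    g <- gold[gold$label == cls, , drop = FALSE]
    p <- pred[pred$label == cls, , drop = FALSE]
    if (mode == "exact") {
      tp <- 0L
      for (i in seq_len(nrow(p)))
        for (j in seq_len(nrow(g)))
          if (p$doc_id[i] == g$doc_id[j] && p$start[i] == g$start[j] &&
              p$end[i] == g$end[j]) { tp <- tp + 1L; break }
      tp_p <- tp; tp_g <- tp
    } else {
      ov <- function(a, i, b, j)
        a$doc_id[i] == b$doc_id[j] && a$start[i] < b$end[j] &&
          a$end[i] > b$start[j]
      tp_g <- 0L
      for (j in seq_len(nrow(g)))
        for (i in seq_len(nrow(p)))
          if (ov(g, j, p, i)) { tp_g <- tp_g + 1L; break }
      tp_p <- 0L
      for (i in seq_len(nrow(p)))
        for (j in seq_len(nrow(g)))
          if (ov(p, i, g, j)) { tp_p <- tp_p + 1L; break }
    }
    c(tp_p = tp_p, n_pred = nrow(p), tp_g = tp_g, n_gold = nrow(g))
  })
  cnt <- do.call(rbind, per_class)
  rownames(cnt) <- classes
  prf <- function(tp_p, np, tp_g, ng) {
    p <- if (np == 0) 0 else tp_p / np
    r <- if (ng == 0) 0 else tp_g / ng
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(p, r, f)
  }
  rows <- t(apply(cnt, 1L, function(z) prf(z[1], z[2], z[3], z[4])))
  tot <- colSums(cnt)
  micro <- prf(tot[1], tot[2], tot[3], tot[4])
  mp <- mean(rows[, 1]); mr <- mean(rows[, 2])
  macro <- c(mp, mr, if (mp + mr == 0) 0 else 2 * mp * mr / (mp + mr))
  w <- cnt[, "n_gold"]
  wts <- if (sum(w) == 0) rep(1 / length(w), length(w)) else w / sum(w)
  wp <- sum(wts * rows[, 1]); wr <- sum(wts * rows[, 2])
  weighted <- c(wp, wr, if (wp + wr == 0) 0 else 2 * wp * wr / (wp + wr))
  out <- rbind(rows, micro, macro, weighted)
  colnames(out) <- c("precision", "recall", "f1")
  out
}

# random gold/pred configuration over a tiny document set
random_eval_config <- function(classes = phenotype_classes()) {
  mk <- function() {
    n <- sample(0:8, 1L)
    if (n == 0L)
      return(data.frame(doc_id = character(), start = integer(),
                        end = integer(), label = character(),
                        stringsAsFactors = FALSE))
    data.frame(doc_id = sample(c("a", "b"), n, replace = TRUE),
               start = st <- sample(0:40, n, replace = TRUE),
               end = st + sample(1:10, n, replace = TRUE),
               label = sample(classes, n, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  list(gold = mk(), pred = mk())
}

# ---- labeler fixtures ------------------------------------------------------

# tiny separable one-class corpus for oracle-scale models (3 BIO states)
toy_corpus <- function(n_docs = 8L, seed = 1L) {
  phenoNER:::with_seed(seed, {
    docs <- list(); rows <- list()
    for (i in seq_len(n_docs)) {
      words <- c("patient", "has", "aortic", "stenosis", "today")
      pos <- c("NN", "VBZ", "JJ", "NN", "RB")
      d <- doc1(words, pos, doc_id = paste0("t", i))
      s <- d$sentences[[1]]
      docs[[i]] <- d
      rows[[i]] <- data.frame(doc_id = d$doc_id, start = s$start[3],
                              end = s$end[4], label = "Cause",
                              text = "aortic stenosis",
                              stringsAsFactors = FALSE)
    }
    list(documents = docs,
         annotations = annotation_set(do.call(rbind, rows)))
  })
}

# branch-structured corpus exhibiting label bias: mentions share the first
# token ("renal"), the class is decided by the second token, and the two
# branches have unbalanced priors. With a window-0 bag-of-words config the
# disambiguating token is invisible when the B- tag is chosen, so a locally
# normalized model commits to the majority branch.
branch_corpus <- function(n_major = 40L, n_minor = 10L, seed = 1L) {
  phenoNER:::with_seed(seed, {
    docs <- list(); rows <- list(); i <- 0L
    plant <- function(second, label) {
      i <<- i + 1L
      words <- c("note", "shows", "renal", second, "today")
      pos <- c("NN", "VBZ", "JJ", "NN", "RB")
      d <- doc1(words, pos, doc_id = paste0("b", i))
      s <- d$sentences[[1]]
      docs[[i]] <<- d
      rows[[i]] <<- data.frame(doc_id = d$doc_id, start = s$start[3],
                               end = s$end[4], label = label,
                               text = paste("renal", second),
                               stringsAsFactors = FALSE)
    }
    for (k in seq_len(n_major)) plant("failure", "Cause")
    for (k in seq_len(n_minor)) plant("insufficiency",
                                      "NonTraditionalRiskFactor")
    ord <- sample.int(i)
    list(documents = docs[ord],
         annotations = annotation_set(do.call(rbind, rows[ord])))
  })
}

# exact-path enumeration: best score over all label sequences
oracle_best_path <- function(model, tokens) {
  states <- model$states
  T_ <- nrow(tokens)
  grid <- do.call(expand.grid,
                  c(rep(list(states), T_), stringsAsFactors = FALSE))
  best <- -Inf; arg <- NULL
  for (r in seq_len(nrow(grid))) {
    labs <- as.character(unlist(grid[r, ]))
    sc <- sequence_score(model, tokens, labs)
    if (sc > best) { best <- sc; arg <- labs }
  }
  list(score = best, labels = arg)
}

micro_f <- function(report, mode = "exact") {
  df <- report[[mode]]
  df$f1[df$class == "micro"]
}
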