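# Span-matching evaluation, inter-annotator agreement, and experiment
# splitting/harness.

f1 <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)

prf_row <- function(tp_p, n_pred, tp_g, n_gold) {
  p <- if (n_pred == 0) 0 else tp_p / n_pred
  r <- if (n_gold == 0) 0 else tp_g / n_gold
  c(precision = p, recall = r, f1 = f1(p, r))
}

mode_counts <- function(gold, pred, mode, classes) {
  # per class: exact TP is a (doc,start,end,label) identity; relaxed TP is
  # counted separately on the gold side (recall) and prediction side
  # (precision): a gold mention with >=1 same-label character-overlapping
  # prediction, and vice versa
  out <- matrix(0, nrow = length(classes), ncol = 4,
                dimnames = list(classes,
                                c("tp_p", "n_pred", "tp_g", "n_gold")))
  for (cls in classes) {
    g <- gold[gold$label == cls, , drop = FALSE]
    p <- pred[pred$label == cls, , drop = FALSE]
    out[cls, "n_gold"] <- nrow(g)
    out[cls, "n_pred"] <- nrow(p)
    if (!nrow(g) || !nrow(p)) next
    if (mode == "exact") {
      gk <- paste(g$doc_id, g$start, g$end)
      pk <- paste(p$doc_id, p$start, p$end)
      tp <- sum(pk %in% gk)
      out[cls, "tp_p"] <- tp
      out[cls, "tp_g"] <- tp
    } else {
      overlaps <- function(a, b)
        vapply(seq_len(nrow(a)), function(i)
          any(b$doc_id == a$doc_id[i] & b$start < a$end[i] &
              b$end > a$start[i]), TRUE)
      out[cls, "tp_g"] <- sum(overlaps(g, p))
      out[cls, "tp_p"] <- sum(overlaps(p, g))
    }
  }
  out
}

mode_report <- function(cnt, classes) {
  rows <- lapply(classes, function(cls)
    prf_row(cnt[cls, "tp_p"], cnt[cls, "n_pred"],
            cnt[cls, "tp_g"], cnt[cls, "n_gold"]))
  df <- do.call(rbind, rows)
  tot <- colSums(cnt)
  micro <- prf_row(tot["tp_p"], tot["n_pred"], tot["tp_g"], tot["n_gold"])
  macro_p <- mean(df[, "precision"]); macro_r <- mean(df[, "recall"])
  w <- cnt[, "n_gold"]
  wts <- if (sum(w) == 0) rep(1 / length(w), length(w)) else w / sum(w)
  wp <- sum(wts * df[, "precision"]); wr <- sum(wts * df[, "recall"])
  out <- rbind(df,
               micro = micro,
               macro = c(macro_p, macro_r, f1(macro_p, macro_r)),
               weighted = c(wp, wr, f1(wp, wr)))
  data.frame(class = c(classes, "micro", "macro", "weighted"),
             precision = out[, "precision"], recall = out[, "recall"],
             f1 = out[, "f1"],
             support = c(cnt[, "n_gold"], rep(sum(cnt[, "n_gold"]), 3)),
             n_pred = c(cnt[, "n_pred"], rep(sum(cnt[, "n_pred"]), 3)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Span-matching precision/recall/F1
#'
#' Scores predicted spans against a gold standard under two matching
#' modes. Exact: a prediction is a true positive only if its document,
#' boundaries and label all match a gold mention. Relaxed: a gold mention
#' counts as found (recall side) if at least one same-label prediction
#' shares at least one character with it, and a prediction counts as
#' correct (precision side) if it overlaps at least one same-label gold
#' mention; the two sides are counted separately so many-to-one overlaps
#' behave monotonically. F1 is the harmonic mean of each row's precision
#' and recall; empty denominators score 0 with the support column making
#' the condition visible. Three aggregates are reported: micro (pooled
#' counts), macro (unweighted class mean), weighted (gold-support
#' weighted).
#'
#' @param gold gold annotations (data frame with `doc_id`, `start`,
#'   `end`, `label`).
#' @param pred predicted mentions, same columns.
#' @param mode `"both"`, `"exact"` or `"relaxed"`.
#' @param classes the entity label set; unknown labels in either input
#'   are an error.
#' @return A `pheno_eval` object: list of per-mode data frames.
#' @export
span_prf <- function(gold, pred, mode = c("both", "exact", "relaxed"),
                     classes = phenotype_classes()) {
  mode <- match.arg(mode)
  gold <- as.data.frame(gold); pred <- as.data.frame(pred)
  bad <- setdiff(unique(c(gold$label, pred$label)), classes)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  modes <- if (mode == "both") c("exact", "relaxed") else mode
  out <- lapply(modes, function(md)
    mode_report(mode_counts(gold, pred, md, classes), classes))
  names(out) <- modes
  structure(out, class = "pheno_eval",
            n_gold = nrow(gold), n_pred = nrow(pred))
}

#' @export
print.pheno_eval <- function(x, digits = 3, ...) {
  for (md in names(x)) {
    cat("==", md, "match ==\n")
    df <- x[[md]]
    df$precision <- round(df$precision, digits)
    df$recall <- round(df$recall, digits)
    df$f1 <- round(df$f1, digits)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Inter-annotator agreement by F-score
#'
#' Takes one annotation set as the gold standard and scores the other
#' against it with [span_prf()]. The F1 values are symmetric in the two
#' sets (precision and recall exchange), which is why F-score is a usable
#' agreement measure when the total number of annotatable items is
#' unknown (ruling out chance-corrected coefficients).
#'
#' @param set_a annotation set treated as gold.
#' @param set_b annotation set treated as predictions.
#' @param mode,classes as in [span_prf()].
#' @return A `pheno_eval`.
#' @export
iaa <- function(set_a, set_b, mode = c("both", "exact", "relaxed"),
                classes = phenotype_classes()) {
  span_prf(set_a, set_b, mode = mode, classes = classes)
}

# --- splits ----------------------------------------------------------------

doc_ids <- function(docs) vapply(docs, function(d) d$doc_id, "")

#' Random document-level train/test split
#'
#' Assigns whole documents (never parts of one) to train or test;
#' `round(ratio * N)` documents go to training. Reproducible from `seed`.
#'
#' @param docs list of `pheno_document`.
#' @param ratio training fraction (default 0.8).
#' @param seed integer RNG seed.
#' @return A `pheno_split`: list with `train` and `test` id vectors.
#' @export
train_test_split <- function(docs, ratio = 0.8, seed = 1L) {
  ids <- doc_ids(docs)
  n_train <- round(ratio * length(ids))
  perm <- with_seed(seed, sample(ids))
  structure(list(train = sort(perm[seq_len(n_train)]),
                 test = sort(perm[-seq_len(n_train)]),
                 ratio = ratio, seed = seed),
            class = "pheno_split")
}

#' Document-level k-fold assignment
#'
#' Folds partition the corpus and differ in size by at most one; the
#' first `N mod k` folds take the extra document.
#'
#' @param docs list of `pheno_document`.
#' @param k number of folds (default 5); must not exceed the number of
#'   documents.
#' @param seed integer RNG seed.
#' @return A `pheno_split` with a `folds` list of id vectors.
#' @export
kfold_split <- function(docs, k = 5L, seed = 1L) {
  ids <- doc_ids(docs)
  N <- length(ids)
  if (k > N) stop("k = ", k, " exceeds number of documents (", N, ")")
  perm <- with_seed(seed, sample(ids))
  sizes <- rep(N %/% k, k) + c(rep(1L, N %% k), rep(0L, k - N %% k))
  folds <- split(perm, rep(seq_len(k), times = sizes))
  structure(list(folds = lapply(folds, sort), k = k, seed = seed),
            class = "pheno_split")
}

#' @export
print.pheno_split <- function(x, ...) {
  if (!is.null(x$folds))
    cat(sprintf("<pheno_split> %d folds of sizes {%s}, seed %d\n", x$k,
                paste(lengths(x$folds), collapse = ","), x$seed))
  else
    cat(sprintf("<pheno_split> %d train / %d test (ratio %.2f), seed %d\n",
                length(x$train), length(x$test), x$ratio, x$seed))
  invisible(x)
}

subset_docs <- function(docs, ids) docs[doc_ids(docs) %in% ids]
subset_ann <- function(ann, ids) {
  out <- as.data.frame(ann)[as.data.frame(ann)$doc_id %in% ids, ,
                            drop = FALSE]
  annotation_set(out, annotator_id = attr(ann, "annotator_id") %||% "gold")
}

# --- experiment harness ----------------------------------------------------

fit_method <- function(method, train_docs, train_ann, config, rules,
                       lexicon, class_map, ...) {
  switch(method,
         hmm = hmm_tagger(train_docs, train_ann, config = config, ...),
         memm = memm_tagger(train_docs, train_ann, config = config, ...),
         crf = crf_tagger(train_docs, train_ann, config = config, ...),
         rules = {
           if (is.null(rules)) stop("method 'rules' needs a rule set")
           structure(list(rules = rules), class = "rules_method")
         },
         lexicon = {
           if (is.null(lexicon)) stop("method 'lexicon' needs a lexicon")
           structure(list(lexicon = lexicon, class_map = class_map),
                     class = "lexicon_method")
         },
         stop("unknown method: ", method))
}

predict_method <- function(fit, docs) {
  if (inherits(fit, "rules_method")) {
    out <- lapply(docs, function(d) apply_ruleset(fit$rules, d))
    do.call(rbind, out)
  } else if (inherits(fit, "lexicon_method")) {
    out <- lapply(docs, function(d)
      tag_with_lexicon(d, fit$lexicon, fit$class_map)$mentions)
    do.call(rbind, out)
  } else predict(fit, docs)
}

#' Run a complete extraction experiment
#'
#' Executes one of three regimes and scores each condition in both
#' matching modes:
#' \describe{
#'   \item{holdout}{random 80/20 document split; train on 80, test on 20.}
#'   \item{kfold}{k-fold cross-validation; per-fold reports plus a pooled
#'     report over the concatenated out-of-fold predictions.}
#'   \item{cross-type}{train on one text style, test on the other, in
#'     both directions (two conditions).}
#' }
#' Rule and lexicon methods need no training and are applied to the test
#' side only.
#'
#' @param docs list of `pheno_document` (both styles for `cross-type`).
#' @param gold gold `pheno_annotations`.
#' @param method `"hmm"`, `"memm"`, `"crf"`, `"rules"` or `"lexicon"`.
#' @param regime `"holdout"`, `"kfold"` or `"cross-type"`.
#' @param config feature configuration for the labelers.
#' @param rules rule list for `method = "rules"`.
#' @param lexicon,class_map lexicon and semtype-to-class map for
#'   `method = "lexicon"`.
#' @param ratio,k split parameters.
#' @param seed RNG seed for the split and any stochastic step.
#' @param ... extra arguments passed to the tagger fit.
#' @return Named list of conditions, each holding `report`
#'   (`pheno_eval`), `predictions` and the split/ids used.
#' @export
run_experiment <- function(docs, gold,
                           method = c("crf", "hmm", "memm", "rules",
                                      "lexicon"),
                           regime = c("holdout", "kfold", "cross-type"),
                           config = feature_config(), rules = NULL,
                           lexicon = NULL, class_map = NULL,
                           ratio = 0.8, k = 5L, seed = 1L, ...) {
  method <- match.arg(method)
  regime <- match.arg(regime)
  if (!length(docs)) stop("no documents supplied")
  gold <- annotation_set(as.data.frame(gold),
                         attr(gold, "annotator_id") %||% "gold")
  run_one <- function(train_ids, test_ids, name) {
    fit <- fit_method(method, subset_docs(docs, train_ids),
                      subset_ann(gold, train_ids), config, rules,
                      lexicon, class_map, ...)
    pred <- predict_method(fit, subset_docs(docs, test_ids))
    report <- span_prf(subset_ann(gold, test_ids), pred, mode = "both")
    list(name = name, report = report, predictions = pred,
         train = train_ids, test = test_ids)
  }
  if (regime == "holdout") {
    sp <- train_test_split(docs, ratio, seed)
    out <- list(holdout = run_one(sp$train, sp$test, "holdout"))
  } else if (regime == "kfold") {
    sp <- kfold_split(docs, k, seed)
    out <- list()
    all_pred <- list()
    for (fi in seq_len(sp$k)) {
      test_ids <- sp$folds[[fi]]
      train_ids <- setdiff(doc_ids(docs), test_ids)
      res <- run_one(train_ids, test_ids, paste0("fold", fi))
      out[[res$name]] <- res
      all_pred[[fi]] <- res$predictions
    }
    pooled_pred <- do.call(rbind, all_pred)
    out$pooled <- list(name = "pooled",
                       report = span_prf(gold, pooled_pred, mode = "both"),
                       predictions = pooled_pred,
                       train = NULL, test = doc_ids(docs))
  } else {
    styles <- vapply(docs, function(d) d$style, "")
    a <- doc_ids(docs)[styles == "discharge"]
    b <- doc_ids(docs)[styles == "article"]
    if (!length(a) || !length(b))
      stop("cross-type regime needs documents of both styles")
    out <- list(discharge_to_article = run_one(a, b,
                                               "discharge_to_article"),
                article_to_discharge = run_one(b, a,
                                               "article_to_discharge"))
  }
  out
}

#' Write an evaluation report as TSV
#'
#' @param report a `pheno_eval`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_eval_tsv <- function(report, path) {
  rows <- do.call(rbind, lapply(names(report), function(md) {
    df <- report[[md]]; df$mode <- md; df
  }))
  utils::write.table(rows[, c("mode", "class", "precision", "recall",
                              "f1", "support", "n_pred")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
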