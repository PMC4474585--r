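mk_ann <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  df$text <- NA_character_
  df
}

test_that("identical gold and prediction score 1 in both modes", {
  g <- mk_ann(doc_id = c("a", "a", "b"), start = c(0L, 10L, 5L),
              end = c(4L, 20L, 9L),
              label = c("Cause", "SignSymptom", "RiskFactor"))
  r <- span_prf(g, g, "both")
  for (md in c("exact", "relaxed")) {
    df <- r[[md]]
    per_class <- df[!df$class %in% c("micro", "macro", "weighted"), ]
    expect_true(all(per_class$f1[per_class$support > 0] == 1))
    expect_equal(df$f1[df$class == "micro"], 1)
    expect_equal(df$f1[df$class == "weighted"], 1)
    # the macro row averages in classes with no gold support, so it is
    # deliberately below 1 here; its support column exposes that
  }
})

test_that("modifier disagreement scores 0 exact but 1 relaxed", {
  # one annotator marks the span with its modifier, the other without
  g <- mk_ann(doc_id = "a", start = 0L, end = 33L, label = "SignSymptom")
  p <- mk_ann(doc_id = "a", start = 12L, end = 33L,
              label = "SignSymptom")  # "left atrial dilation" only
  r <- span_prf(g, p, "both")
  expect_equal(r$exact$f1[r$exact$class == "micro"], 0)
  expect_equal(r$relaxed$f1[r$relaxed$class == "micro"], 1)
})

test_that("span_prf equals the brute-force double-loop oracle", {
  set.seed(12)
  for (i in 1:300) {
    cfgs <- random_eval_config()
    r <- span_prf(cfgs$gold, cfgs$pred, "both")
    for (md in c("exact", "relaxed")) {
      want <- oracle_prf(cfgs$gold, cfgs$pred, md)
      got <- as.matrix(r[[md]][, c("precision", "recall", "f1")])
      rownames(got) <- r[[md]]$class
      expect_equal(unname(got), unname(want), tolerance = 1e-12,
                   info = paste("case", i, md))
      # relaxed F >= exact F for every row
    }
    expect_true(all(r$relaxed$f1 >= r$exact$f1 - 1e-12), info = i)
  }
})

test_that("label-blind overlap does not count as a relaxed match", {
  g <- mk_ann(doc_id = "a", start = 0L, end = 10L, label = "Cause")
  p <- mk_ann(doc_id = "a", start = 0L, end = 10L, label = "RiskFactor")
  r <- span_prf(g, p, "relaxed")
  expect_equal(r$relaxed$f1[r$relaxed$class == "micro"], 0)
})

test_that("unknown labels are rejected", {
  g <- mk_ann(doc_id = "a", start = 0L, end = 3L, label = "Oddity")
  expect_error(span_prf(g, g[0, ], "exact"), "unknown label")
})

test_that("IAA is an F-score with exchanged precision and recall", {
  set.seed(77)
  for (i in 1:40) {
    cfgs <- random_eval_config()
    ab <- iaa(cfgs$gold, cfgs$pred, "both")
    ba <- iaa(cfgs$pred, cfgs$gold, "both")
    # the weighted row is excluded: its weights come from the gold side's
    # support, so it is not swap-symmetric by construction
    sym <- which(ab$exact$class != "weighted")
    for (md in c("exact", "relaxed")) {
      expect_equal(ab[[md]]$f1[sym], ba[[md]]$f1[sym], tolerance = 1e-12)
      expect_equal(ab[[md]]$precision[sym], ba[[md]]$recall[sym],
                   tolerance = 1e-12)
    }
  }
  g <- mk_ann(doc_id = "a", start = 0L, end = 3L, label = "Cause")
  self <- iaa(g, g, "both")
  expect_equal(self$exact$f1[self$exact$class == "micro"], 1)
  p <- mk_ann(doc_id = "a", start = 10L, end = 13L, label = "Cause")
  disj <- iaa(g, p, "both")
  expect_equal(disj$exact$f1[disj$exact$class == "micro"], 0)
  expect_equal(disj$relaxed$f1[disj$relaxed$class == "micro"], 0)
})

docs10 <- lapply(1:11, function(i)
  doc1(c("renal", "failure", "noted"), c("JJ", "NN", "VBN"),
       doc_id = sprintf("doc%02d", i)))

test_that("holdout and k-fold splits obey their contracts", {
  sp <- train_test_split(docs10[1:10], ratio = 0.8, seed = 4)
  expect_length(sp$train, 8L)
  expect_length(sp$test, 2L)
  expect_setequal(c(sp$train, sp$test),
                  vapply(docs10[1:10], function(d) d$doc_id, ""))
  expect_identical(train_test_split(docs10[1:10], 0.8, 4), sp)
  expect_false(identical(train_test_split(docs10[1:10], 0.8, 5), sp))

  kf <- kfold_split(docs10, k = 5, seed = 4)
  expect_equal(sort(unname(lengths(kf$folds)), decreasing = TRUE),
               c(3L, 2L, 2L, 2L, 2L))
  expect_setequal(unlist(kf$folds),
                  vapply(docs10, function(d) d$doc_id, ""))
  expect_identical(kfold_split(docs10, 5, 4), kf)
  expect_error(kfold_split(docs10[1:3], k = 5), "exceeds")
})

test_that("the harness composes methods, regimes and the scorer", {
  corp <- generate_corpus(generator_config(12, "discharge", seed = 41))
  rules <- starter_rules()
  # rules inside the harness equal the direct pipeline
  res <- run_experiment(corp$documents, corp$annotations,
                        method = "rules", regime = "holdout",
                        rules = rules, seed = 6)
  test_docs <- phenoNER:::subset_docs(corp$documents, res$holdout$test)
  direct_pred <- do.call(rbind, lapply(test_docs, function(d)
    apply_ruleset(rules, d)))
  direct <- span_prf(phenoNER:::subset_ann(corp$annotations,
                                           res$holdout$test),
                     direct_pred, "both")
  expect_equal(res$holdout$report$exact, direct$exact)
  expect_equal(res$holdout$predictions, direct_pred)
})

test_that("k-fold pooled micro counts conserve the per-fold counts", {
  corp <- generate_corpus(generator_config(10, "discharge", seed = 43))
  res <- run_experiment(corp$documents, corp$annotations,
                        method = "rules", regime = "kfold",
                        rules = starter_rules(), k = 5, seed = 2)
  expect_length(res, 6L)  # 5 folds + pooled
  # predictions pool exactly
  n_pool <- nrow(res$pooled$predictions)
  n_folds <- sum(vapply(res[paste0("fold", 1:5)],
                        function(r) nrow(r$predictions), 0L))
  expect_equal(n_pool, n_folds)
  # pooled micro equals scoring the concatenated predictions directly
  direct <- span_prf(corp$annotations, res$pooled$predictions, "both")
  expect_equal(res$pooled$report$exact, direct$exact)
  # folds partition the corpus
  expect_setequal(unlist(lapply(res[paste0("fold", 1:5)],
                                function(r) r$test)),
                  vapply(corp$documents, function(d) d$doc_id, ""))
})

test_that("cross-type regime trains each style against the other", {
  c1 <- generate_corpus(generator_config(8, "discharge", seed = 51))
  c2 <- generate_corpus(generator_config(8, "article", seed = 52))
  docs <- c(c1$documents, c2$documents)
  gold <- annotation_set(rbind(as.data.frame(c1$annotations),
                               as.data.frame(c2$annotations)))
  res <- run_experiment(docs, gold, method = "hmm",
                        regime = "cross-type", seed = 1)
  expect_named(res, c("discharge_to_article", "article_to_discharge"))
  expect_setequal(res$discharge_to_article$test,
                  vapply(c2$documents, function(d) d$doc_id, ""))
  expect_setequal(res$article_to_discharge$test,
                  vapply(c1$documents, function(d) d$doc_id, ""))
})

test_that("reports serialize to TSV", {
  g <- mk_ann(doc_id = "a", start = 0L, end = 3L, label = "Cause")
  r <- span_prf(g, g, "both")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_eval_tsv(r, p)
  tab <- utils::read.delim(p)
  expect_equal(nrow(tab), 14L)  # 7 rows x 2 modes
  expect_true(all(c("mode", "class", "f1") %in% names(tab)))
})
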