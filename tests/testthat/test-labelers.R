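# shared small configs
cfg_bow0 <- feature_config(use_pos = FALSE, use_chunk = FALSE,
                           use_affix = FALSE, use_shape = FALSE,
                           window = 0L)

test_that("HMM tables equal hand-computed add-alpha MLE on a 6-token toy", {
  words <- c("aa", "bb", "cc", "dd", "ee", "ff")
  d <- doc1(words, "NN")
  s <- d$sentences[[1]]
  gold <- annotation_set(data.frame(
    doc_id = "d1", start = s$start[3], end = s$end[4], label = "Cause",
    text = "cc dd"))
  a <- 0.5
  m <- hmm_tagger(list(d), gold, classes = "Cause", config = cfg_bow0,
                  alpha = a)
  # states sorted: B-Cause, I-Cause, O; label path O O B I O O
  expect_equal(m$states, c("B-Cause", "I-Cause", "O"))
  # initial: one sentence starting at O
  expect_equal(unname(exp(m$init_lp)),
               c(a, a, 1 + a) / (1 + 3 * a))
  # transitions: O->O twice, O->B, B->I, I->O once each
  tr <- exp(m$trans_lp)
  expect_equal(unname(tr["O", ]),
               c(1 + a, a, 2 + a) / (3 + 3 * a))
  expect_equal(unname(tr["B-Cause", ]),
               c(a, 1 + a, a) / (1 + 3 * a))
  expect_equal(unname(tr["I-Cause", ]),
               c(a, a, 1 + a) / (1 + 3 * a))
  # emissions, family w[0]: 6 seen values + 1 unseen outcome, so the
  # denominator for each state is count(state) + 7a
  em <- exp(m$emis_lp[["w[0]"]])
  expect_equal(unname(em["B-Cause", "cc"]), (1 + a) / (1 + 7 * a))
  expect_equal(unname(em["B-Cause", "aa"]), a / (1 + 7 * a))
  expect_equal(unname(em["O", "aa"]), (1 + a) / (4 + 7 * a))
  expect_equal(unname(em["O", "__UNSEEN__"]), a / (4 + 7 * a))
})

test_that("HMM probability tables normalize to one", {
  corp <- generate_corpus(generator_config(10, "discharge", seed = 3))
  m <- hmm_tagger(corp$documents, corp$annotations)
  expect_equal(sum(exp(m$init_lp)), 1, tolerance = 1e-9)
  expect_equal(unname(rowSums(exp(m$trans_lp))), rep(1, 9),
               tolerance = 1e-9)
  for (fam in names(m$emis_lp))
    expect_equal(unname(rowSums(exp(m$emis_lp[[fam]]))), rep(1, 9),
                 tolerance = 1e-9, info = fam)
})

test_that("training on all-O data decodes everything as O", {
  d <- doc1(c("plain", "words", "only"), "NN")
  expect_warning(
    m <- hmm_tagger(list(d), annotation_set(NULL), classes = "Cause",
                    config = cfg_bow0),
    "never observed")
  got <- viterbi_decode(m, tok(c("anything", "else"), "NN"))
  expect_equal(got, c("O", "O"))
})

test_that("MEMM trained on single-class data predicts that class", {
  words <- c("dyspnea", "edema", "fatigue")
  d <- doc1(words, "NN")
  s <- d$sentences[[1]]
  gold <- annotation_set(data.frame(
    doc_id = "d1", start = s$start, end = s$end, label = "SignSymptom",
    text = words))
  suppressWarnings(
    m <- memm_tagger(list(d), gold, classes = "SignSymptom",
                     config = cfg_bow0))
  got <- viterbi_decode(m, tok(c("dyspnea", "fatigue"), "NN"))
  expect_equal(got, c("B-SignSymptom", "B-SignSymptom"))
})

test_that("MEMM conditionals match a direct grid-search maxent fit", {
  # four length-1 sentences: token "x" labeled B-Cause three times and
  # O once; a single feature w[0]=x drives the START sub-model
  docs <- list(); rows <- list()
  for (i in 1:4) {
    d <- doc1("x", "NN", doc_id = paste0("g", i))
    docs[[i]] <- d
    if (i <= 3)
      rows[[length(rows) + 1L]] <- data.frame(
        doc_id = d$doc_id, start = 0L, end = 1L, label = "Cause",
        text = "x")
  }
  gold <- annotation_set(do.call(rbind, rows))
  lambda <- 0.5
  suppressWarnings(
    m <- memm_tagger(docs, gold, classes = "Cause", config = cfg_bow0,
                     lambda = lambda, tol = 1e-8))
  W <- m$W[["__START__"]]  # 1 feature x 3 states
  p_fit <- exp(W[1, ] - phenoNER:::log_sum_exp(W[1, ]))
  # independent oracle: coarse-to-fine grid search over the three weights
  nll <- function(w) {
    p <- exp(w - max(w)); p <- p / sum(p)
    -(3 * log(p[1]) + log(p[3])) + lambda / 2 * sum(w^2)
  }
  centre <- c(0, 0, 0); width <- 2
  for (round in 1:6) {
    gr <- expand.grid(b = seq(centre[1] - width, centre[1] + width,
                              length.out = 11),
                      i = seq(centre[2] - width, centre[2] + width,
                              length.out = 11),
                      o = seq(centre[3] - width, centre[3] + width,
                              length.out = 11))
    vals <- apply(gr, 1L, nll)
    centre <- as.numeric(gr[which.min(vals), ])
    width <- width * 0.25
  }
  p_grid <- exp(centre - max(centre)); p_grid <- p_grid / sum(p_grid)
  expect_equal(unname(p_fit), p_grid, tolerance = 1e-3)
})

test_that("CRF separates a trivially separable corpus perfectly", {
  corp <- toy_corpus(n_docs = 8L, seed = 2)
  m <- crf_tagger(corp$documents, corp$annotations, classes = "Cause",
                  config = cfg_bow0)
  held <- doc1(c("patient", "has", "aortic", "stenosis", "today"),
               c("NN", "VBZ", "JJ", "NN", "RB"), doc_id = "new")
  pred <- predict(m, held)
  expect_equal(nrow(pred), 1L)
  expect_equal(pred$text, "aortic stenosis")
  expect_equal(pred$label, "Cause")
})

test_that("Viterbi equals exhaustive path enumeration for all models", {
  corp <- toy_corpus(n_docs = 6L, seed = 5)
  cfg <- feature_config(use_affix = FALSE, use_chunk = FALSE, window = 1L)
  models <- list(
    hmm = hmm_tagger(corp$documents, corp$annotations, classes = "Cause",
                     config = cfg),
    memm = memm_tagger(corp$documents, corp$annotations,
                       classes = "Cause", config = cfg),
    crf = crf_tagger(corp$documents, corp$annotations, classes = "Cause",
                     config = cfg))
  set.seed(31)
  pool <- c("patient", "has", "aortic", "stenosis", "today", "zzz")
  pos_pool <- c("NN", "VBZ", "JJ", "RB")
  for (L in c(2L, 4L, 6L)) {
    sent <- tok(sample(pool, L, replace = TRUE),
                sample(pos_pool, L, replace = TRUE))
    for (nm in names(models)) {
      mod <- models[[nm]]
      labs <- viterbi_decode(mod, sent)
      sc <- sequence_score(mod, sent, labs)
      oracle <- oracle_best_path(mod, sent)
      expect_equal(sc, oracle$score, tolerance = 1e-10,
                   info = paste(nm, "L =", L))
    }
  }
})

test_that("decoding is deterministic and ties break lexicographically", {
  corp <- toy_corpus(n_docs = 4L, seed = 9)
  m <- hmm_tagger(corp$documents, corp$annotations, classes = "Cause",
                  config = cfg_bow0)
  sent <- tok(c("patient", "has"), c("NN", "VBZ"))
  expect_identical(viterbi_decode(m, sent), viterbi_decode(m, sent))
  # empty-sentence decode is an empty label vector
  expect_equal(viterbi_decode(m, phenoNER:::new_token_frame()),
               character(0))
})

test_that("training is reproducible given identical input", {
  corp <- generate_corpus(generator_config(8, "discharge", seed = 19))
  m1 <- crf_tagger(corp$documents, corp$annotations, max_iter = 40,
                   tol = 1e-2)
  m2 <- crf_tagger(corp$documents, corp$annotations, max_iter = 40,
                   tol = 1e-2)
  expect_identical(coef(m1), coef(m2))
  te <- generate_corpus(generator_config(3, "discharge", seed = 20))
  expect_identical(predict(m1, te$documents), predict(m2, te$documents))
})

test_that("predict() composes per-sentence decoding with BIO decoding", {
  corp <- generate_corpus(generator_config(6, "discharge", seed = 29))
  m <- hmm_tagger(corp$documents, corp$annotations)
  te <- generate_corpus(generator_config(2, "discharge", seed = 30))
  got <- predict(m, te$documents)
  manual <- list()
  for (doc in te$documents)
    for (s in doc$sentences) {
      mm <- from_bio(list(tokens = s, labels = viterbi_decode(m, s)),
                     doc_id = doc$doc_id, text = doc$text)
      if (nrow(mm)) manual[[length(manual) + 1L]] <- mm
    }
  manual <- do.call(rbind, manual); rownames(manual) <- NULL
  expect_equal(got, manual)
})

test_that("model files round trip and refuse tampered configurations", {
  tdir <- withr::local_tempdir()
  corp <- toy_corpus(n_docs = 4L, seed = 3)
  m <- crf_tagger(corp$documents, corp$annotations, classes = "Cause",
                  config = cfg_bow0)
  p <- file.path(tdir, "m.rds")
  save_tagger(m, p)
  m2 <- load_tagger(p)
  expect_identical(coef(m2), coef(m))
  sent <- tok(c("aortic", "stenosis"), c("JJ", "NN"))
  expect_identical(viterbi_decode(m2, sent), viterbi_decode(m, sent))
  # tamper with the stored feature config: hash check must refuse
  obj <- readRDS(p)
  obj$model$config$window <- 4L
  saveRDS(obj, p)
  expect_error(load_tagger(p), "hash mismatch")
})

test_that("label bias appears on a branch-structured corpus", {
  # mentions share their first token; the class-deciding second token is
  # outside a window-0 view when the B- tag is committed, and the two
  # branches are unbalanced, so the locally normalized MEMM follows the
  # majority branch while the globally normalized CRF recovers; the
  # generative HMM also recovers through its emission model
  tr <- branch_corpus(n_major = 40L, n_minor = 10L, seed = 1)
  te <- branch_corpus(n_major = 8L, n_minor = 8L, seed = 2)
  # POS stays visible, so a sub-model that never saw the rare word still
  # confidently continues its own class from pos[0]=NN - the channel
  # through which local normalization ignores the observation
  cfg_bp0 <- feature_config(use_chunk = FALSE, use_affix = FALSE,
                            use_shape = FALSE, window = 0L)
  fit <- function(f) suppressWarnings(
    f(tr$documents, tr$annotations,
      classes = c("Cause", "NonTraditionalRiskFactor"),
      config = cfg_bp0))
  f_of <- function(m) micro_f(span_prf(te$annotations,
                                       predict(m, te$documents), "exact"))
  f_crf <- f_of(fit(crf_tagger))
  f_hmm <- f_of(fit(hmm_tagger))
  f_memm <- f_of(fit(memm_tagger))
  expect_lt(f_memm, f_crf)
  expect_lte(f_memm, f_hmm)
  expect_gte(f_crf, 0.99)
})

test_that("a training label outside the model's label set errors", {
  corp <- toy_corpus(4L, seed = 1)
  expect_error(
    suppressWarnings(hmm_tagger(corp$documents, corp$annotations,
                                classes = "SignSymptom",
                                config = cfg_bow0)),
    "outside the model's label set")
})
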