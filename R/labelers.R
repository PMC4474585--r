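# Three BIO sequence labelers over a shared feature layer:
#   hmm_tagger()  - generative HMM whose emission factorizes naive-Bayes
#                   style across feature families, add-alpha smoothed
#   memm_tagger() - locally normalized maxent with a previous-label
#                   feature (label bias and all)
#   crf_tagger()  - globally normalized linear-chain CRF
# All return classed S3 objects with print/summary/coef/predict methods.

# emission families the generative HMM may use: focus-position
# observations only (offset-0 window families and affixes)
hmm_family_ok <- function(feature_names) {
  !grepl("\\[-?[1-9][0-9]*\\]=", feature_names)
}

# transition legality for BIO tags: I-x may only follow B-x or I-x
legal_transition_matrix <- function(states) {
  K <- length(states)
  ok <- matrix(TRUE, K, K, dimnames = list(states, states))
  for (b in seq_len(K)) {
    if (startsWith(states[b], "I-")) {
      cls <- sub("^I-", "", states[b])
      for (a in seq_len(K))
        ok[a, b] <- states[a] %in% paste0(c("B-", "I-"), cls)
    }
  }
  ok
}

legal_initial <- function(states) !startsWith(states, "I-")

# shared training-data assembly: BIO-encode every document and extract
# features per token
assemble_training <- function(x, annotations, classes, config) {
  if (inherits(x, "pheno_document")) x <- list(x)
  stopifnot(length(x) > 0L)
  registry <- if (isTRUE(config$use_affix))
    compile_affix_registry(annotations, x) else NULL
  states <- bio_states(classes)
  sents <- list()
  for (doc in x) {
    bio <- to_bio(doc, annotations)
    for (ex in bio) {
      fs <- sentence_features(ex$tokens, config, registry)
      y <- match(ex$labels, states)
      if (anyNA(y))
        stop("training label outside the model's label set: ",
             ex$labels[which(is.na(y))[1]])
      sents[[length(sents) + 1L]] <- list(features = fs, y = y,
                                          labels = ex$labels)
    }
  }
  seen <- sort(unique(unlist(lapply(sents, function(s) s$labels))))
  missing <- setdiff(states, seen)
  if (length(missing))
    warning("label(s) never observed in training (unreachable at decode): ",
            paste(missing, collapse = ", "))
  list(sentences = sents, states = states, registry = registry)
}

# integer feature vocabulary over assembled sentences
build_vocab <- function(sents) {
  vocab <- sort(unique(unlist(lapply(sents, function(s)
    unlist(s$features)))))
  structure(seq_along(vocab), names = vocab)
}

# encode one sentence's features as 0-based ids + token pointer array
encode_sentence <- function(features, vocab) {
  ids <- integer(); ptr <- integer(length(features) + 1L)
  for (t in seq_along(features)) {
    f <- vocab[features[[t]]]
    f <- f[!is.na(f)]           # decode-time unknown features drop out
    ids <- c(ids, as.integer(f) - 1L)
    ptr[t + 1L] <- length(ids)
  }
  list(feats = ids, ptr = ptr)
}

# ---------------------------------------------------------------------------
# HMM
# ---------------------------------------------------------------------------

#' Fit a feature-augmented hidden Markov model tagger
#'
#' Transitions and initial-state probabilities are add-`alpha` smoothed
#' maximum-likelihood counts over BIO tag sequences. The emission
#' distribution integrates multiple features by factorizing, naive-Bayes
#' style, across feature families (token identity, POS, chunk, shape per
#' window offset, and registered affixes): each family holds an
#' add-`alpha` smoothed multinomial over its observed values plus one
#' unseen-value outcome that receives the smoothing floor at decode time.
#'
#' Unlike the discriminative taggers, the HMM emission uses only the
#' focus position's feature families (window offset 0 plus affixes): a
#' generative chain emits each token's attributes once, and folding
#' neighboring tokens' features into the emission would count the same
#' observation several times, violating the model's independence
#' structure. Context is carried by the transition chain instead.
#'
#' @param x list of `pheno_document` (training corpus).
#' @param annotations gold `pheno_annotations` over `x`.
#' @param classes entity classes; the label set is their BIO expansion.
#' @param config a [feature_config()].
#' @param alpha additive smoothing constant (default 0.1).
#' @return An object of class `c("hmm_tagger", "pheno_tagger")`.
#' @export
hmm_tagger <- function(x, annotations, classes = phenotype_classes(),
                       config = feature_config(), alpha = 0.1) {
  tr <- assemble_training(x, annotations, classes, config)
  states <- tr$states
  K <- length(states)
  init_n <- structure(numeric(K), names = states)
  trans_n <- matrix(0, K, K, dimnames = list(states, states))
  fam_counts <- list()  # family -> list(values -> K-vector of counts)
  for (s in tr$sentences) {
    y <- s$y
    init_n[y[1]] <- init_n[y[1]] + 1
    if (length(y) > 1L)
      for (t in 2:length(y))
        trans_n[y[t - 1L], y[t]] <- trans_n[y[t - 1L], y[t]] + 1
    for (t in seq_along(y)) {
      for (f in s$features[[t]][hmm_family_ok(s$features[[t]])]) {
        fam <- sub("=.*$", "", f)
        val <- sub("^[^=]*=", "", f)
        if (is.null(fam_counts[[fam]]))
          fam_counts[[fam]] <- new.env(parent = emptyenv())
        e <- fam_counts[[fam]]
        cur <- get0(val, envir = e, ifnotfound = numeric(K))
        cur[y[t]] <- cur[y[t]] + 1
        assign(val, cur, envir = e)
      }
    }
  }
  # smoothed log-probability tables; last emission column = unseen value
  init_lp <- log((init_n + alpha) / (sum(init_n) + alpha * K))
  trans_lp <- log(sweep(trans_n + alpha, 1L,
                        rowSums(trans_n) + alpha * K, "/"))
  emis_lp <- lapply(fam_counts, function(e) {
    vals <- sort(ls(envir = e))
    cnt <- vapply(vals, get, numeric(K), envir = e)  # K x V
    if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = K)
    cnt <- cbind(cnt, 0)                             # unseen outcome
    colnames(cnt) <- c(vals, "__UNSEEN__")
    rownames(cnt) <- states
    log(sweep(cnt + alpha, 1L, rowSums(cnt) + alpha * ncol(cnt), "/"))
  })
  observed <- vapply(seq_len(K), function(k)
    any(vapply(tr$sentences, function(s) k %in% s$y, TRUE)), TRUE)
  structure(list(states = states, classes = classes, config = config,
                 registry = tr$registry, alpha = alpha,
                 init_lp = init_lp, trans_lp = trans_lp,
                 emis_lp = emis_lp, observed = observed,
                 n_sentences = length(tr$sentences)),
            class = c("hmm_tagger", "pheno_tagger"))
}

hmm_node_scores <- function(model, features) {
  K <- length(model$states)
  node <- matrix(0, length(features), K)
  for (t in seq_along(features)) {
    for (f in features[[t]][hmm_family_ok(features[[t]])]) {
      fam <- sub("=.*$", "", f)
      val <- sub("^[^=]*=", "", f)
      lp <- model$emis_lp[[fam]]
      if (is.null(lp)) next                 # family absent from training
      col <- match(val, colnames(lp))
      if (is.na(col)) col <- ncol(lp)       # unseen value -> floor mass
      node[t, ] <- node[t, ] + lp[, col]
    }
  }
  node
}

# ---------------------------------------------------------------------------
# MEMM
# ---------------------------------------------------------------------------

#' Fit a maximum-entropy Markov model tagger
#'
#' The classical locally normalized formulation: one L2-penalized
#' multinomial logistic (maximum-entropy) model per source state, each
#' trained only on the positions whose previous gold tag is that state
#' (a synthetic START state covers sentence-initial positions). Decoding
#' multiplies the local conditionals along the chain. This per-source
#' fragmentation of the training data - positions following the rare
#' B-/I- states are few - together with local normalization is what
#' makes MEMMs data-hungry and prone to the label bias effect. Each
#' sub-model's concave objective is maximized with L-BFGS to a
#' projected-gradient tolerance `tol`.
#'
#' @inheritParams hmm_tagger
#' @param lambda L2 penalty strength per sub-model (default 1).
#' @param max_iter iteration cap per sub-model.
#' @param tol gradient-norm convergence tolerance.
#' @return An object of class `c("memm_tagger", "pheno_tagger")`.
#' @export
memm_tagger <- function(x, annotations, classes = phenotype_classes(),
                        config = feature_config(), lambda = 1.0,
                        max_iter = 200L, tol = 1e-4) {
  tr <- assemble_training(x, annotations, classes, config)
  states <- tr$states
  K <- length(states)
  vocab <- build_vocab(tr$sentences)
  d <- length(vocab)
  # pooled design: one row per token, grouped by previous label
  ii <- list(); jj <- list(); previ <- integer(); yy <- integer()
  row <- 0L
  for (s in tr$sentences) {
    for (t in seq_along(s$y)) {
      row <- row + 1L
      f <- unname(vocab[s$features[[t]]])
      ii[[row]] <- rep.int(row, length(f)); jj[[row]] <- f
      previ[row] <- if (t == 1L) K + 1L else s$y[t - 1L]
      yy[row] <- s$y[t]
    }
  }
  N <- row
  X <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = 1,
                            dims = c(N, d))
  W <- vector("list", K + 1L)
  nll_total <- 0; gnorm_max <- 0
  for (j in seq_len(K + 1L)) {
    rows <- which(previ == j)
    if (!length(rows)) {            # state never a predecessor: uniform
      W[[j]] <- matrix(0, d, K, dimnames = list(names(vocab), states))
      next
    }
    Xj <- X[rows, , drop = FALSE]
    yj <- yy[rows]
    Yind <- cbind(seq_along(rows), yj)
    objective <- function(par) {
      Wj <- matrix(par, d, K)
      logits <- as.matrix(Xj %*% Wj)
      m <- apply(logits, 1L, max)
      lse <- m + log(rowSums(exp(logits - m)))
      nll <- sum(lse - logits[Yind]) + lambda / 2 * sum(Wj^2)
      probs <- exp(logits - lse)
      D <- probs; D[Yind] <- D[Yind] - 1
      attr(nll, "gradient") <-
        as.numeric(as.matrix(Matrix::crossprod(Xj, D))) + lambda * par
      nll
    }
    obj <- cache_objective(objective)
    fit <- optim(numeric(d * K), fn = obj$fn, gr = obj$gr,
                 method = "L-BFGS-B",
                 control = list(maxit = max_iter, pgtol = tol,
                                factr = 1e7))
    gnorm <- max(abs(attr(objective(fit$par), "gradient")))
    if (fit$convergence != 0L && gnorm > 10 * tol)
      stop(sprintf(paste0(
        "MEMM sub-model for previous state '%s' did not converge within ",
        "%d iterations (|grad|_inf = %.3g)"),
        c(states, "__START__")[j], max_iter, gnorm))
    nll_total <- nll_total + fit$value
    gnorm_max <- max(gnorm_max, gnorm)
    W[[j]] <- matrix(fit$par, d, K,
                     dimnames = list(names(vocab), states))
  }
  names(W) <- c(states, "__START__")
  structure(list(states = states, classes = classes, config = config,
                 registry = tr$registry, lambda = lambda, vocab = vocab,
                 W = W, nll = nll_total, gnorm = gnorm_max,
                 n_sentences = length(tr$sentences)),
            class = c("memm_tagger", "pheno_tagger"))
}

# per-position log P(y_t | y_{t-1}, x): list over t of (K x K), plus the
# sentence-initial K-vector; illegal BIO transitions are masked to -Inf
# after normalization (decode-time hard constraint)
memm_logprobs <- function(model, features, constrain = TRUE) {
  K <- length(model$states)
  T_ <- length(features)
  fidx <- lapply(features, function(fs) {
    f <- model$vocab[fs]
    as.integer(f[!is.na(f)])
  })
  legal <- legal_transition_matrix(model$states)
  Wstart <- model$W[["__START__"]]
  first_logit <- if (length(fidx[[1]]))
    colSums(Wstart[fidx[[1]], , drop = FALSE]) else numeric(K)
  first <- first_logit - log_sum_exp(first_logit)
  if (constrain) first[!legal_initial(model$states)] <- -Inf
  steps <- vector("list", T_)
  if (T_ > 1L)
    for (t in 2:T_) {
      mat <- matrix(-Inf, K, K)
      for (j in seq_len(K)) {
        Wj <- model$W[[j]]
        logit <- if (length(fidx[[t]]))
          colSums(Wj[fidx[[t]], , drop = FALSE]) else numeric(K)
        mat[j, ] <- logit - log_sum_exp(logit)
      }
      if (constrain) mat[!legal] <- -Inf
      steps[[t]] <- mat
    }
  list(first = first, steps = steps)
}

# ---------------------------------------------------------------------------
# CRF
# ---------------------------------------------------------------------------

#' Fit a linear-chain conditional random field tagger
#'
#' Globally normalized linear-chain model with per-state emission weights
#' for every indicator feature of the shared feature layer, plus
#' transition and initial-state weights. The L2-penalized negative
#' log-likelihood (convex) is minimized by L-BFGS using exact
#' forward-backward gradients computed in compiled code.
#'
#' @inheritParams hmm_tagger
#' @param lambda L2 penalty strength (default 0.1).
#' @param max_iter iteration cap for the optimizer.
#' @param tol gradient-norm convergence tolerance.
#' @return An object of class `c("crf_tagger", "pheno_tagger")`.
#' @export
crf_tagger <- function(x, annotations, classes = phenotype_classes(),
                       config = feature_config(), lambda = 0.1,
                       max_iter = 200L, tol = 1e-2) {
  tr <- assemble_training(x, annotations, classes, config)
  states <- tr$states
  K <- length(states)
  vocab <- build_vocab(tr$sentences)
  d <- length(vocab)
  enc <- lapply(tr$sentences, function(s) {
    e <- encode_sentence(s$features, vocab)
    list(feats = e$feats, ptr = e$ptr, y = s$y - 1L)
  })
  npar_w <- d * K
  unpack <- function(par) list(
    W = matrix(par[seq_len(npar_w)], d, K),
    trans = matrix(par[npar_w + seq_len(K * K)], K, K),
    start = par[npar_w + K * K + seq_len(K)])
  objective <- function(par) {
    p <- unpack(par)
    r <- crf_nll_grad(enc, p$W, p$trans, p$start)
    nll <- r$nll + lambda / 2 * sum(par^2)
    attr(nll, "gradient") <-
      c(r$gW, r$gT, r$gS) + lambda * par
    nll
  }
  par0 <- numeric(npar_w + K * K + K)
  obj <- cache_objective(objective)
  fit <- optim(par0, fn = obj$fn, gr = obj$gr, method = "L-BFGS-B",
               control = list(maxit = max_iter, pgtol = tol,
                              factr = 1e7))
  gnorm <- max(abs(attr(objective(fit$par), "gradient")))
  if (fit$convergence != 0L && gnorm > 10 * tol)
    stop(sprintf(
      "CRF training did not converge within %d iterations (|grad|_inf = %.3g)",
      max_iter, gnorm))
  p <- unpack(fit$par)
  dimnames(p$W) <- list(names(vocab), states)
  dimnames(p$trans) <- list(states, states)
  names(p$start) <- states
  structure(list(states = states, classes = classes, config = config,
                 registry = tr$registry, lambda = lambda, vocab = vocab,
                 W = p$W, trans = p$trans, start = p$start,
                 nll = fit$value, gnorm = gnorm,
                 n_sentences = length(tr$sentences)),
            class = c("crf_tagger", "pheno_tagger"))
}

crf_node_scores <- function(model, features) {
  K <- length(model$states)
  node <- matrix(0, length(features), K)
  for (t in seq_along(features)) {
    f <- model$vocab[features[[t]]]
    f <- f[!is.na(f)]
    if (length(f))
      node[t, ] <- colSums(model$W[f, , drop = FALSE])
  }
  node
}

# ---------------------------------------------------------------------------
# shared decoding
# ---------------------------------------------------------------------------

# chain potentials for a sentence under any of the three models:
# either constant-transition form (node/trans/start) or the MEMM's
# position-dependent form
model_potentials <- function(model, features) {
  if (inherits(model, "hmm_tagger")) {
    node <- hmm_node_scores(model, features)
    trans <- model$trans_lp
    start <- model$init_lp
    trans[!legal_transition_matrix(model$states)] <- -Inf
    start[!legal_initial(model$states)] <- -Inf
    # a label never observed in training is unreachable at decode: its
    # uniform smoothing-floor emission would otherwise out-score trained
    # states on unseen tokens
    trans[, !model$observed] <- -Inf
    start[!model$observed] <- -Inf
    list(form = "const", node = node, trans = trans, start = start)
  } else if (inherits(model, "crf_tagger")) {
    list(form = "const", node = crf_node_scores(model, features),
         trans = model$trans, start = model$start)
  } else if (inherits(model, "memm_tagger")) {
    c(list(form = "dyn"), memm_logprobs(model, features))
  } else stop("unknown model class")
}

#' Viterbi decoding of one sentence
#'
#' Returns the highest-scoring BIO label path under the model's scoring
#' in log space. Ties break toward the lexicographically smallest label
#' (the state set is kept sorted). For the HMM and MEMM, structurally
#' illegal BIO transitions are excluded; the CRF is left unconstrained
#' and relies on learned transition weights.
#'
#' @param model a fitted `pheno_tagger`.
#' @param tokens sentence token data frame.
#' @return Character vector of BIO labels (empty for an empty sentence).
#' @export
viterbi_decode <- function(model, tokens) {
  if (is.null(tokens) || nrow(tokens) == 0L) return(character())
  features <- sentence_features(tokens, model$config, model$registry)
  pot <- model_potentials(model, features)
  K <- length(model$states)
  if (pot$form == "const") {
    r <- chain_viterbi(pot$node, pot$trans, pot$start)
    return(model$states[r$path])
  }
  T_ <- length(features)
  delta <- matrix(-Inf, T_, K)
  back <- matrix(1L, T_, K)
  delta[1, ] <- pot$first
  if (T_ > 1L)
    for (t in 2:T_) {
      for (k in seq_len(K)) {
        v <- delta[t - 1L, ] + pot$steps[[t]][, k]
        j <- which.max(v)
        delta[t, k] <- v[j]; back[t, k] <- j
      }
    }
  path <- integer(T_)
  path[T_] <- which.max(delta[T_, ])
  if (T_ > 1L)
    for (t in T_:2) path[t - 1L] <- back[t, path[t]]
  model$states[path]
}

#' Log score of a full label path
#'
#' The quantity Viterbi decoding maximizes: the log joint score for the
#' HMM, the sum of masked local log-probabilities for the MEMM, and the
#' unnormalized clique score for the CRF. Useful as an enumeration oracle
#' on short sentences.
#'
#' @param model a fitted `pheno_tagger`.
#' @param tokens sentence token data frame.
#' @param labels candidate BIO label vector, one per token.
#' @return A single numeric score (possibly `-Inf`).
#' @export
sequence_score <- function(model, tokens, labels) {
  stopifnot(nrow(tokens) == length(labels))
  if (length(labels) == 0L) return(-Inf)
  features <- sentence_features(tokens, model$config, model$registry)
  pot <- model_potentials(model, features)
  y <- match(labels, model$states)
  if (anyNA(y)) stop("label outside the model's label set")
  if (pot$form == "const") {
    sc <- pot$start[y[1]] + pot$node[1, y[1]]
    if (length(y) > 1L)
      for (t in 2:length(y))
        sc <- sc + pot$trans[y[t - 1L], y[t]] + pot$node[t, y[t]]
  } else {
    sc <- pot$first[y[1]]
    if (length(y) > 1L)
      for (t in 2:length(y))
        sc <- sc + pot$steps[[t]][y[t - 1L], y[t]]
  }
  unname(sc)
}

#' Predict entity mentions in documents
#'
#' Decodes each sentence with [viterbi_decode()] and converts the BIO
#' labels back to character-offset mentions with [from_bio()] (invalid
#' `I-` continuations, possible for the unconstrained CRF, are repaired
#' there).
#'
#' @param object a fitted `pheno_tagger`.
#' @param newdata a `pheno_document` or list of them.
#' @param ... unused.
#' @return Data frame of predicted mentions.
#' @export
predict.pheno_tagger <- function(object, newdata, ...) {
  docs <- if (inherits(newdata, "pheno_document")) list(newdata) else newdata
  out <- list()
  for (doc in docs) {
    for (si in seq_along(doc$sentences)) {
      s <- doc$sentences[[si]]
      labels <- viterbi_decode(object, s)
      m <- from_bio(list(tokens = s, labels = labels), doc_id = doc$doc_id,
                    text = doc$text)
      if (nrow(m)) out[[length(out) + 1L]] <- m
    }
  }
  if (!length(out))
    return(data.frame(doc_id = character(), start = integer(),
                      end = integer(), label = character(),
                      text = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---------------------------------------------------------------------------
# methods and persistence
# ---------------------------------------------------------------------------

#' @export
print.hmm_tagger <- function(x, ...) {
  cat(sprintf(
    "<hmm_tagger> %d states, %d feature families, alpha = %g (%d sentences)\n",
    length(x$states), length(x$emis_lp), x$alpha, x$n_sentences))
  invisible(x)
}

#' @export
print.memm_tagger <- function(x, ...) {
  cat(sprintf(paste0(
    "<memm_tagger> %d states (one maxent model per source state), ",
    "%d features, lambda = %g (%d sentences)\n"),
    length(x$states), nrow(x$W[[1]]), x$lambda, x$n_sentences))
  invisible(x)
}

#' @export
print.crf_tagger <- function(x, ...) {
  cat(sprintf(
    "<crf_tagger> %d states, %d features, lambda = %g (%d sentences)\n",
    length(x$states), nrow(x$W), x$lambda, x$n_sentences))
  invisible(x)
}

#' @export
summary.pheno_tagger <- function(object, ...) {
  print(object)
  cat("  states:", paste(object$states, collapse = " "), "\n")
  cat("  window:", object$config$window, " families:",
      paste(names(object$config)[vapply(object$config, isTRUE, TRUE)],
            collapse = " "), "\n")
  if (!is.null(object$nll))
    cat(sprintf("  penalized NLL at optimum: %.4f (|grad| = %.2g)\n",
                object$nll, object$gnorm))
  invisible(object)
}

#' @export
coef.crf_tagger <- function(object, ...) {
  list(emission = object$W, transition = object$trans,
       start = object$start)
}

#' @export
coef.memm_tagger <- function(object, ...) {
  object$W  # one weight matrix per source state (plus __START__)
}

#' @export
coef.hmm_tagger <- function(object, ...) {
  list(initial = object$init_lp, transition = object$trans_lp,
       emission = object$emis_lp)
}

#' Save / load a fitted tagger
#'
#' The container records a format version and a hash of the feature
#' configuration; loading refuses containers whose stored hash does not
#' match their stored configuration (a corrupted or hand-edited file).
#'
#' @param model a fitted `pheno_tagger`.
#' @param path file path.
#' @return `save_tagger` returns `path` invisibly; `load_tagger` the
#'   restored model.
#' @export
save_tagger <- function(model, path) {
  stopifnot(inherits(model, "pheno_tagger"))
  saveRDS(list(format = "phenoNER-tagger", version = 1L,
               config_hash = config_hash(model$config), model = model),
          path)
  invisible(path)
}

#' @rdname save_tagger
#' @export
load_tagger <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "phenoNER-tagger"))
    stop("not a phenoNER tagger file: ", path)
  if (!identical(obj$version, 1L))
    stop("unsupported tagger container version: ", obj$version)
  if (!identical(obj$config_hash, config_hash(obj$model$config)))
    stop("feature-config hash mismatch in ", path,
         ": refusing to load")
  obj$model
}
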