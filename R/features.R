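#' Compile an affix registry from gold annotations
#'
#' For every token lying (fully or partly) inside a gold mention, all
#' lowercased prefixes and suffixes of lengths 2 up to `min(5, nchar)` are
#' collected. The registry then serves as a look-up list during feature
#' extraction: affix features fire only for registered affixes, so the
#' affix vocabulary is closed over the training annotations (e.g. the
#' prefix "hyper" from hypertension, the suffix "emia" from anemia and
#' lipidemia).
#'
#' @param gold a `pheno_annotations` frame (training-set gold standard).
#' @param docs list of `pheno_document` the mentions resolve into.
#' @param min_len,max_len affix length bounds.
#' @return An `affix_registry` with character-set members `prefixes` and
#'   `suffixes`.
#' @export
compile_affix_registry <- function(gold, docs, min_len = 2L, max_len = 5L) {
  words <- character()
  gold <- as.data.frame(gold)
  if (nrow(gold) == 0L)
    warning("empty gold set: affix registry is empty")
  by_doc <- split(gold, gold$doc_id)
  for (doc in docs) {
    m <- by_doc[[doc$doc_id]]
    if (is.null(m) || !nrow(m)) next
    for (s in doc$sentences) {
      for (mi in seq_len(nrow(m))) {
        cov <- which(s$start < m$end[mi] & s$end > m$start[mi])
        if (length(cov)) words <- c(words, s$text[cov])
      }
    }
  }
  words <- tolower(unique(words))
  prefixes <- character(); suffixes <- character()
  for (w in words) {
    L <- nchar(w)
    if (L < min_len) next
    for (k in min_len:min(max_len, L)) {
      prefixes <- c(prefixes, substring(w, 1L, k))
      suffixes <- c(suffixes, substring(w, L - k + 1L, L))
    }
  }
  structure(list(prefixes = sort(unique(prefixes)),
                 suffixes = sort(unique(suffixes)),
                 min_len = min_len, max_len = max_len),
            class = "affix_registry")
}

#' @export
print.affix_registry <- function(x, ...) {
  cat(sprintf("<affix_registry> %d prefixes, %d suffixes (lengths %d-%d)\n",
              length(x$prefixes), length(x$suffixes), x$min_len, x$max_len))
  invisible(x)
}

#' Feature configuration for the sequence labelers
#'
#' All labelers share the same binary indicator features, extracted per
#' token over a symmetric context window: lowercased token identity
#' (bag-of-words), POS tag, chunk tag, compressed word shape, and (at the
#' focus position only) registered prefixes/suffixes.
#'
#' @param use_bow,use_pos,use_chunk,use_affix,use_shape feature family
#'   switches.
#' @param window context width in tokens on each side (default 2).
#' @return A `feature_config`.
#' @export
feature_config <- function(use_bow = TRUE, use_pos = TRUE,
                           use_chunk = TRUE, use_affix = TRUE,
                           use_shape = TRUE, window = 2L) {
  stopifnot(window >= 0L)
  structure(list(use_bow = use_bow, use_pos = use_pos,
                 use_chunk = use_chunk, use_affix = use_affix,
                 use_shape = use_shape, window = as.integer(window)),
            class = "feature_config")
}

config_hash <- function(config) {
  paste(vapply(config, as.character, ""), collapse = "|")
}

#' Extract the indicator features for one token position
#'
#' Deterministic given (sentence, position, config, registry). Positions
#' off the sentence edge contribute boundary markers so window features
#' keep a fixed arity.
#'
#' @param tokens sentence token data frame.
#' @param i 1-based token position.
#' @param config a [feature_config()].
#' @param registry an `affix_registry`; required when `use_affix`.
#' @return Character vector of active feature names.
#' @export
extract_features <- function(tokens, i, config = feature_config(),
                             registry = NULL) {
  if (isTRUE(config$use_affix) && is.null(registry))
    stop("affix features requested but no registry supplied")
  n <- nrow(tokens)
  feats <- character()
  for (o in -config$window:config$window) {
    j <- i + o
    if (j < 1L) { w <- "__BOS__"; p <- "__BOS__"; ck <- "__BOS__" }
    else if (j > n) { w <- "__EOS__"; p <- "__EOS__"; ck <- "__EOS__" }
    else {
      w <- tolower(tokens$text[j])
      p <- if (is.na(tokens$pos[j])) "__NA__" else tokens$pos[j]
      ck <- if (is.na(tokens$chunk[j])) "__NA__" else tokens$chunk[j]
    }
    if (isTRUE(config$use_bow))
      feats <- c(feats, sprintf("w[%d]=%s", o, w))
    if (isTRUE(config$use_pos))
      feats <- c(feats, sprintf("pos[%d]=%s", o, p))
    if (isTRUE(config$use_chunk))
      feats <- c(feats, sprintf("chk[%d]=%s", o, ck))
    if (isTRUE(config$use_shape)) {
      sh <- if (j < 1L || j > n) "__EDGE__" else word_shape(tokens$text[j])
      feats <- c(feats, sprintf("shape[%d]=%s", o, sh))
    }
  }
  if (isTRUE(config$use_affix)) {
    w <- tolower(tokens$text[i])
    L <- nchar(w)
    if (L >= registry$min_len) {
      for (k in registry$min_len:min(registry$max_len, L)) {
        pre <- substring(w, 1L, k)
        suf <- substring(w, L - k + 1L, L)
        if (pre %in% registry$prefixes)
          feats <- c(feats, paste0("pre=", pre))
        if (suf %in% registry$suffixes)
          feats <- c(feats, paste0("suf=", suf))
      }
    }
  }
  feats
}

# features for every position of a sentence: list of character vectors
sentence_features <- function(tokens, config, registry = NULL) {
  lapply(seq_len(nrow(tokens)), extract_features, tokens = tokens,
         config = config, registry = registry)
}
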