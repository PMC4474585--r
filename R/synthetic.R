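# Synthetic annotated corpora in two text styles, so every component is
# testable without the access-restricted clinical corpora. The generator
# emulates the structural properties the methods depend on: four entity
# classes with style-skewed distributions, telegraphic sectioned discharge
# text vs full-sentence article text, ~10% character-level misspellings in
# the EHR style, generator-assigned gold POS/chunk tags, and a simulated
# second annotator whose disagreements are modifier-inclusion boundary
# shifts.

# closed mention vocabulary: surface tokens + POS per term, per class;
# "hypertension" and "diabetes mellitus" deliberately occur under both
# RiskFactor and Cause (the context template carries the class)
mention_vocab <- function() {
  term <- function(tokens, pos) list(tokens = tokens, pos = pos)
  list(
    SignSymptom = list(
      term("chest pain", "NN NN"),
      term("shortness of breath", "NN IN NN"),
      term("dyspnea", "NN"),
      term("orthopnea", "NN"),
      term("fatigue", "NN"),
      term("palpitations", "NNS"),
      term("peripheral edema", "JJ NN"),
      term("left atrial dilation", "JJ JJ NN"),
      term("jugular venous distension", "JJ JJ NN"),
      term("leg swelling", "NN NN")),
    RiskFactor = list(
      term("hypertension", "NN"),
      term("hypercholesterolemia", "NN"),
      term("hyperlipidemia", "NN"),
      term("diabetes mellitus", "NN NN"),
      term("obesity", "NN"),
      term("atrial fibrillation", "JJ NN"),
      term("tobacco use", "NN NN")),
    Cause = list(
      term("coronary artery disease", "JJ NN NN"),
      term("myocardial infarction", "JJ NN"),
      term("ischemic cardiomyopathy", "JJ NN"),
      term("aortic stenosis", "JJ NN"),
      term("mitral regurgitation", "JJ NN"),
      term("valvular heart disease", "JJ NN NN"),
      term("hypertension", "NN"),
      term("diabetes mellitus", "NN NN")),
    NonTraditionalRiskFactor = list(
      term("proteinuria", "NN"),
      term("dysuria", "NN"),
      term("anemia", "NN"),
      term("hematuria", "NN"),
      term("microalbuminuria", "NN"),
      term("renal insufficiency", "JJ NN"),
      term("chronic kidney disease", "JJ NN NN"),
      term("elevated creatinine", "VBN NN")))
}

MODIFIERS <- data.frame(
  text = c("significant", "mild", "severe", "moderate", "worsening"),
  pos = c("JJ", "JJ", "JJ", "JJ", "VBG"), stringsAsFactors = FALSE)

# sentence templates: "<M>" marks the mention slot; parallel POS/chunk
# strings use "M" in the slot position
tmpl <- function(words, pos, chunk) list(words = strsplit(words, " ")[[1]],
                                         pos = strsplit(pos, " ")[[1]],
                                         chunk = strsplit(chunk, " ")[[1]])

style_templates <- function(style) {
  if (style == "discharge") {
    list(
      generic = list(
        tmpl("Patient admitted with <M> .", "NN VBN IN M .",
             "B-NP B-VP B-PP M O"),
        tmpl("History of <M> .", "NN IN M .", "B-NP B-PP M O"),
        tmpl("Exam notable for <M> .", "NN JJ IN M .",
             "B-NP B-ADJP B-PP M O"),
        tmpl("Reports <M> .", "VBZ M .", "B-VP M O"),
        tmpl("Denies <M> .", "VBZ M .", "B-VP M O")),
      Cause = list(
        tmpl("CHF secondary to <M> .", "NN JJ TO M .",
             "B-NP B-ADJP B-PP M O"),
        tmpl("Heart failure due to <M> .", "NN NN JJ TO M .",
             "B-NP I-NP B-ADJP B-PP M O")),
      RiskFactor = list(
        tmpl("Risk factors include <M> .", "NN NNS VBP M .",
             "B-NP I-NP B-VP M O")),
      NonTraditionalRiskFactor = list(
        tmpl("Labs show <M> .", "NNS VBP M .", "B-NP B-VP M O"),
        tmpl("Renal workup revealed <M> .", "JJ NN VBD M .",
             "B-NP I-NP B-VP M O")),
      SignSymptom = list(
        tmpl("Presents with <M> .", "VBZ IN M .", "B-VP B-PP M O")),
      filler = list(
        tmpl("Vital signs stable .", "JJ NNS JJ .",
             "B-NP I-NP B-ADJP O"),
        tmpl("Continue current medications .", "VB JJ NNS .",
             "B-VP B-NP I-NP O"),
        tmpl("Follow up in clinic .", "VB RP IN NN .",
             "B-VP I-VP B-PP B-NP O"),
        tmpl("Labs reviewed .", "NNS VBN .", "B-NP B-VP O"),
        tmpl("Patient tolerated the procedure well .",
             "NN VBD DT NN RB .", "B-NP B-VP B-NP I-NP B-ADVP O")),
      headers = c("HISTORY OF PRESENT ILLNESS :", "PAST MEDICAL HISTORY :",
                  "PHYSICAL EXAMINATION :", "HOSPITAL COURSE :",
                  "DISCHARGE DIAGNOSIS :"))
  } else {
    list(
      generic = list(
        tmpl("Patients with <M> were enrolled in the study .",
             "NNS IN M VBD VBN IN DT NN .",
             "B-NP B-PP M B-VP I-VP B-PP B-NP I-NP O"),
        tmpl("The prevalence of <M> was high in this cohort .",
             "DT NN IN M VBD JJ IN DT NN .",
             "B-NP I-NP B-PP M B-VP B-ADJP B-PP B-NP I-NP O"),
        tmpl("We observed that <M> predicted mortality .",
             "PRP VBD IN M VBD NN .",
             "B-NP B-VP B-SBAR M B-VP B-NP O"),
        tmpl("Prior studies have linked <M> to adverse outcomes .",
             "JJ NNS VBP VBN M TO JJ NNS .",
             "B-NP I-NP B-VP I-VP M B-PP B-NP I-NP O")),
      Cause = list(
        tmpl("Heart failure was attributed to <M> in most cases .",
             "NN NN VBD VBN TO M IN JJS NNS .",
             "B-NP I-NP B-VP I-VP B-PP M B-PP B-NP I-NP O")),
      RiskFactor = list(
        tmpl("Established risk factors include <M> .",
             "VBN NN NNS VBP M .", "B-NP I-NP I-NP B-VP M O")),
      NonTraditionalRiskFactor = list(
        tmpl("Markers of kidney dysfunction such as <M> were common .",
             "NNS IN NN NN JJ IN M VBD JJ .",
             "B-NP B-PP B-NP I-NP B-PP I-PP M B-VP B-ADJP O")),
      SignSymptom = list(
        tmpl("Admission was preceded by <M> .", "NN VBD VBN IN M .",
             "B-NP B-VP I-VP B-PP M O")),
      filler = list(
        tmpl("Statistical analyses used standard methods .",
             "JJ NNS VBD JJ NNS .", "B-NP I-NP B-VP B-NP I-NP O"),
        tmpl("The protocol was approved by the review board .",
             "DT NN VBD VBN IN DT NN NN .",
             "B-NP I-NP B-VP I-VP B-PP B-NP I-NP I-NP O"),
        tmpl("Baseline characteristics are shown in the table .",
             "NN NNS VBP VBN IN DT NN .",
             "B-NP I-NP B-VP I-VP B-PP B-NP I-NP O")),
      headers = character())
  }
}

style_class_mix <- function(style) {
  if (style == "discharge")
    c(Cause = 0.20, RiskFactor = 0.20, SignSymptom = 0.45,
      NonTraditionalRiskFactor = 0.15)
  else
    c(Cause = 0.35, RiskFactor = 0.15, SignSymptom = 0.15,
      NonTraditionalRiskFactor = 0.35)
}

#' Generator configuration
#'
#' @param n_docs number of documents to generate.
#' @param style `"discharge"` (telegraphic, sectioned, misspelling-prone)
#'   or `"article"` (full sentences, clean).
#' @param seed integer RNG seed; the corpus is byte-identical per seed.
#' @param mentions_per_doc Poisson mean of planted mentions per document.
#' @param class_mix probability vector over the four classes; default is
#'   style-dependent (sign/symptom-heavy for discharge summaries,
#'   cause/non-traditional-risk-factor-heavy for articles).
#' @param misspell_rate per-token probability of a single-character edit
#'   on non-mention word tokens; defaults to 0.10 for the discharge style
#'   (the reported misspelling load of EHR text) and 0 for articles.
#' @param annotator_noise per-mention boundary-perturbation probability
#'   used by [simulate_second_annotator()].
#' @param misspell_mentions also misspell tokens inside gold mentions
#'   (off by default so planted mentions keep their canonical forms).
#' @return A `generator_config`.
#' @export
generator_config <- function(n_docs, style = c("discharge", "article"),
                             seed = 1L, mentions_per_doc = 8,
                             class_mix = NULL, misspell_rate = NULL,
                             annotator_noise = 0.2,
                             misspell_mentions = FALSE) {
  style <- match.arg(style)
  if (n_docs <= 0L) stop("n_docs must be positive")
  class_mix <- class_mix %||% style_class_mix(style)
  stopifnot(abs(sum(class_mix) - 1) < 1e-8, all(class_mix >= 0))
  misspell_rate <- misspell_rate %||%
    (if (style == "discharge") 0.10 else 0.0)
  stopifnot(misspell_rate >= 0, misspell_rate <= 1,
            annotator_noise >= 0, annotator_noise <= 1)
  structure(list(n_docs = as.integer(n_docs), style = style,
                 seed = as.integer(seed),
                 mentions_per_doc = mentions_per_doc,
                 class_mix = class_mix, misspell_rate = misspell_rate,
                 annotator_noise = annotator_noise,
                 misspell_mentions = misspell_mentions),
            class = "generator_config")
}

# single-character edit (substitute, delete, insert or transpose),
# guaranteed to return a different string so the configured rate is the
# realized rate of perturbed tokens
misspell_word <- function(w) {
  L <- nchar(w)
  ops <- c("sub", "ins", if (L > 1L) "del")
  swap_at <- if (L > 1L)
    which(substring(w, 1:(L - 1), 1:(L - 1)) !=
          substring(w, 2:L, 2:L)) else integer()
  if (length(swap_at)) ops <- c(ops, "swap")
  op <- ops[sample.int(length(ops), 1L)]
  i <- sample.int(L, 1L)
  switch(op,
         sub = {
           cur <- substring(w, i, i)
           letter <- sample(setdiff(letters, tolower(cur)), 1L)
           paste0(substring(w, 1, i - 1), letter, substring(w, i + 1, L))
         },
         del = paste0(substring(w, 1, i - 1), substring(w, i + 1, L)),
         ins = paste0(substring(w, 1, i), sample(letters, 1L),
                      substring(w, i + 1, L)),
         swap = {
           i <- swap_at[sample.int(length(swap_at), 1L)]
           paste0(substring(w, 1, i - 1), substring(w, i + 1, i + 1),
                  substring(w, i, i), substring(w, i + 2, L))
         })
}

#' Generate a synthetic annotated corpus
#'
#' Documents are built from style-specific sentence templates; phenotype
#' mentions are drawn from a closed class vocabulary and planted with
#' exact gold character offsets; every token carries generator-assigned
#' POS and chunk tags, removing any external-tagger dependency. An
#' optional adjectival modifier precedes a planted mention (outside the
#' gold span), giving the simulated second annotator a boundary to
#' disagree about. Non-mention word tokens of length >= 3 are misspelled
#' by a single random character edit with probability `misspell_rate`.
#'
#' @param config a [generator_config()].
#' @return List with `documents`, `annotations` and `config`; the
#'   `misspell_stats` attribute counts eligible and perturbed tokens.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  vocab <- mention_vocab()
  templates <- style_templates(config$style)
  classes <- names(config$class_mix)
  with_seed(config$seed, {
    docs <- vector("list", config$n_docs)
    anns <- list()
    eligible <- 0L; perturbed <- 0L
    for (di in seq_len(config$n_docs)) {
      doc_id <- sprintf("%s_%04d", config$style, di)
      n_m <- rpois(1L, config$mentions_per_doc)
      m_classes <- if (n_m > 0L)
        sample(classes, n_m, replace = TRUE, prob = config$class_mix)
      else character()
      n_fill <- 2L + rpois(1L, 2)
      # sentence plan: headers (discharge) interleaved with content
      plan <- c(lapply(m_classes, function(cl) list(kind = "mention",
                                                    class = cl)),
                rep(list(list(kind = "filler")), n_fill))
      plan <- plan[sample.int(length(plan))]
      if (config$style == "discharge") {
        n_sec <- min(1L + rpois(1L, 1.2) + 1L, 4L)
        hdrs <- sample(templates$headers, n_sec)
        cuts <- sort(sample.int(length(plan) + 1L, n_sec - 1L,
                                replace = TRUE)) - 1L
        bounds <- c(0L, cuts, length(plan))
      }
      sentences <- list()
      text_parts <- character()
      offset <- 0L
      doc_anns <- list()
      emit_sentence <- function(words, pos, chunk, mention_span,
                                mention_class) {
        starts <- integer(length(words))
        cur <- offset
        for (k in seq_along(words)) {
          starts[k] <- cur
          cur <- cur + nchar(words[k]) + 1L
        }
        ends <- starts + nchar(words)
        tf <- new_token_frame(words, starts, ends, pos, chunk)
        sentences[[length(sentences) + 1L]] <<- tf
        text_parts[[length(text_parts) + 1L]] <<-
          paste(words, collapse = " ")
        if (!is.null(mention_span)) {
          i1 <- mention_span[1]; i2 <- mention_span[2]
          doc_anns[[length(doc_anns) + 1L]] <<- data.frame(
            doc_id = doc_id, start = starts[i1], end = ends[i2],
            label = mention_class,
            text = paste(words[i1:i2], collapse = " "),
            stringsAsFactors = FALSE)
        }
        offset <<- ends[length(ends)] + 1L  # "\n" separator
      }
      build_content <- function(item) {
        if (item$kind == "filler") {
          tm <- templates$filler[[sample.int(length(templates$filler), 1L)]]
          return(list(words = tm$words, pos = tm$pos, chunk = tm$chunk,
                      span = NULL, class = NULL, protect = integer()))
        }
        cl <- item$class
        pool <- if (runif(1) < 0.5 && !is.null(templates[[cl]]))
          templates[[cl]] else templates$generic
        tm <- pool[[sample.int(length(pool), 1L)]]
        trm <- vocab[[cl]][[sample.int(length(vocab[[cl]]), 1L)]]
        m_words <- strsplit(trm$tokens, " ")[[1]]
        m_pos <- strsplit(trm$pos, " ")[[1]]
        slot <- which(tm$words == "<M>")
        use_mod <- runif(1) < 0.25
        mod_i <- if (use_mod) sample.int(nrow(MODIFIERS), 1L) else NA
        pre_w <- tm$words[seq_len(slot - 1L)]
        pre_p <- tm$pos[seq_len(slot - 1L)]
        pre_c <- tm$chunk[seq_len(slot - 1L)]
        post_idx <- if (slot < length(tm$words))
          (slot + 1L):length(tm$words) else integer()
        m_chunk <- c("B-NP", rep("I-NP", length(m_words) - 1L))
        if (use_mod) {
          pre_w <- c(pre_w, MODIFIERS$text[mod_i])
          pre_p <- c(pre_p, MODIFIERS$pos[mod_i])
          pre_c <- c(pre_c, "B-NP")
          m_chunk <- rep("I-NP", length(m_words))
        }
        words <- c(pre_w, m_words, tm$words[post_idx])
        pos <- c(pre_p, m_pos, tm$pos[post_idx])
        chunk <- c(pre_c, m_chunk, tm$chunk[post_idx])
        span <- c(length(pre_w) + 1L, length(pre_w) + length(m_words))
        list(words = words, pos = pos, chunk = chunk, span = span,
             class = cl, protect = span[1]:span[2])
      }
      emit_with_noise <- function(ct) {
        words <- ct$words
        for (k in seq_along(words)) {
          protect_tok <- k %in% ct$protect && !config$misspell_mentions
          if (grepl("^[A-Za-z]{3,}$", words[k]) && !protect_tok) {
            eligible <<- eligible + 1L
            if (runif(1) < config$misspell_rate) {
              nw <- misspell_word(words[k])
              if (nw != words[k]) {
                words[k] <- nw
                perturbed <<- perturbed + 1L
              }
            }
          }
        }
        emit_sentence(words, ct$pos, ct$chunk, ct$span, ct$class)
      }
      if (config$style == "discharge") {
        for (sec in seq_along(hdrs)) {
          hw <- strsplit(hdrs[sec], " ")[[1]]
          emit_sentence(hw, c(rep("NN", length(hw) - 1L), ":"),
                        c("B-NP", rep("I-NP", length(hw) - 2L), "O"),
                        NULL, NULL)
          lo <- bounds[sec] + 1L; hi <- bounds[sec + 1L]
          if (hi >= lo)
            for (pi in lo:hi) emit_with_noise(build_content(plan[[pi]]))
        }
      } else {
        for (item in plan) emit_with_noise(build_content(item))
      }
      text <- paste(text_parts, collapse = "\n")
      docs[[di]] <- document_from_tokens(doc_id, config$style, sentences,
                                         text = text)
      if (length(doc_anns)) anns <- c(anns, doc_anns)
    }
    annotations <- annotation_set(
      if (length(anns)) do.call(rbind, anns) else NULL, "gold")
    structure(list(documents = docs, annotations = annotations,
                   config = config),
              misspell_stats = c(eligible = eligible,
                                 perturbed = perturbed),
              class = "pheno_corpus")
  })
}

#' @export
print.pheno_corpus <- function(x, ...) {
  cat(sprintf("<pheno_corpus> %d %s documents, %d gold mentions (seed %d)\n",
              length(x$documents), x$config$style, nrow(x$annotations),
              x$config$seed))
  invisible(x)
}

# locate the sentence and token range of a mention inside a document
locate_mention <- function(doc, start, end) {
  for (si in seq_along(doc$sentences)) {
    s <- doc$sentences[[si]]
    cov <- which(s$start < end & s$end > start)
    if (length(cov)) return(list(sentence = si, tokens = cov))
  }
  NULL
}

#' Simulate a second annotator
#'
#' Reproduces the dominant human disagreement pattern: whether modifiers
#' belong inside an annotated span. With probability `noise` a mention is
#' perturbed: extended one token left when the preceding token is an
#' adjectival/participial modifier, shrunk by its leading modifier token
#' when it has one, or (less often) dropped entirely. Labels are never
#' changed.
#'
#' @param gold gold `pheno_annotations`.
#' @param docs documents the mentions live in.
#' @param noise per-mention perturbation probability.
#' @param seed RNG seed.
#' @return A `pheno_annotations` with `annotator_id = "annotator2"`.
#' @export
simulate_second_annotator <- function(gold, docs, noise = 0.2, seed = 1L) {
  stopifnot(noise >= 0, noise <= 1)
  gold <- as.data.frame(gold)
  by_id <- structure(docs, names = doc_ids(docs))
  mod_pos <- c("JJ", "VBG", "VBN")
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(gold))) {
      m <- gold[i, ]
      doc <- by_id[[m$doc_id]]
      keep <- TRUE
      if (runif(1) < noise) {
        loc <- locate_mention(doc, m$start, m$end)
        s <- doc$sentences[[loc$sentence]]
        first <- loc$tokens[1]; last <- loc$tokens[length(loc$tokens)]
        can_extend <- first > 1L && s$pos[first - 1L] %in% mod_pos
        can_shrink <- length(loc$tokens) > 1L && s$pos[first] %in% mod_pos
        acts <- c(if (can_extend) "extend", if (can_shrink) "shrink",
                  "drop")
        wts <- c(if (can_extend) 0.45, if (can_shrink) 0.45, 0.10)
        act <- sample(acts, 1L, prob = wts)
        if (act == "extend") {
          m$start <- s$start[first - 1L]
        } else if (act == "shrink") {
          m$start <- s$start[first + 1L]
        } else keep <- FALSE
        m$text <- substring(doc$text, m$start + 1L, m$end)
      }
      if (keep) rows[[length(rows) + 1L]] <- m
    }
    annotation_set(if (length(rows)) do.call(rbind, rows) else NULL,
                   annotator_id = "annotator2")
  })
}

#' Write a corpus in the standard layout
#'
#' Creates `text/*.txt`, `ann/*.ann` and `conll/*.tsv` under `dir`, and
#' echoes the generator configuration and seed into `manifest.json`.
#'
#' @param corpus result of [generate_corpus()].
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_corpus <- function(corpus, dir) {
  for (sub in c("text", "ann", "conll"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  for (doc in corpus$documents) {
    write_standoff(doc, corpus$annotations,
                   file.path(dir, "text", paste0(doc$doc_id, ".txt")),
                   file.path(dir, "ann", paste0(doc$doc_id, ".ann")))
    write_conll(doc, file.path(dir, "conll", paste0(doc$doc_id, ".tsv")),
                corpus$annotations)
  }
  manifest <- c(unclass(corpus$config),
                list(n_mentions = nrow(corpus$annotations)))
  manifest$class_mix <- as.list(manifest$class_mix)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
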