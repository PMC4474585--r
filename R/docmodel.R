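#' Phenotype entity classes
#'
#' The four phenotype concept classes used throughout the package: any
#' medical problem contributing to the occurrence of congestive heart
#' failure (`Cause`), conditions increasing the chance of developing it
#' (`RiskFactor`), observable disease manifestations (`SignSymptom`), and
#' kidney-function-related conditions elevating risk
#' (`NonTraditionalRiskFactor`).
#'
#' @return Character vector of the four class names.
#' @export
phenotype_classes <- function() {
  c("Cause", "RiskFactor", "SignSymptom", "NonTraditionalRiskFactor")
}

#' BIO tag set for a set of entity classes
#'
#' @param classes character vector of entity classes.
#' @return Sorted character vector of BIO tags: `B-`/`I-` per class plus
#'   `O`. Sorting fixes the tie-break order used by the decoder.
#' @export
bio_states <- function(classes = phenotype_classes()) {
  sort(c("O", paste0("B-", classes), paste0("I-", classes)))
}

new_token_frame <- function(text = character(), start = integer(),
                            end = integer(), pos = NA_character_,
                            chunk = NA_character_, sem = NA_character_) {
  n <- length(text)
  data.frame(text = as.character(text), start = as.integer(start),
             end = as.integer(end),
             pos = rep_len(as.character(pos), n),
             chunk = rep_len(as.character(chunk), n),
             sem = rep_len(as.character(sem), n),
             stringsAsFactors = FALSE)
}

#' Construct a document from a pre-built token layer
#'
#' @param doc_id document identifier, unique within a corpus.
#' @param style text style, `"discharge"` or `"article"`.
#' @param sentences list of token data frames (columns `text`, `start`,
#'   `end`, `pos`, `chunk`, `sem`; offsets 0-based, end-exclusive).
#' @param text the full document text. If `NULL` it is reconstructed from
#'   the token offsets, filling gaps with spaces.
#' @return A `pheno_document`.
#' @export
document_from_tokens <- function(doc_id, style, sentences, text = NULL) {
  style <- match.arg(style, c("discharge", "article"))
  sentences <- lapply(sentences, function(s) {
    if (is.null(s$sem)) s$sem <- NA_character_
    if (is.null(s$pos)) s$pos <- NA_character_
    if (is.null(s$chunk)) s$chunk <- NA_character_
    s[, c("text", "start", "end", "pos", "chunk", "sem")]
  })
  if (is.null(text)) {
    len <- max(0L, unlist(lapply(sentences, function(s) s$end)))
    chars <- rep(" ", len)
    for (s in sentences)
      for (i in seq_len(nrow(s))) {
        idx <- (s$start[i] + 1L):s$end[i]
        chars[idx] <- strsplit(s$text[i], "")[[1]]
      }
    text <- paste(chars, collapse = "")
  }
  doc <- structure(list(doc_id = as.character(doc_id), text = text,
                        style = style, sentences = sentences),
                   class = "pheno_document")
  validate_document(doc)
  doc
}

#' Validate a document's token layer
#'
#' Checks the structural invariants: token offsets in bounds and
#' end-exclusive, each token's surface equal to the corresponding text
#' slice, tokens within a sentence sorted and non-overlapping.
#'
#' @param doc a `pheno_document`.
#' @return The document, invisibly. Errors on the first violation.
#' @export
validate_document <- function(doc) {
  stopifnot(inherits(doc, "pheno_document"))
  n <- nchar(doc$text)
  for (si in seq_along(doc$sentences)) {
    s <- doc$sentences[[si]]
    if (nrow(s) == 0L) stop("empty sentence ", si, " in ", doc$doc_id)
    if (any(s$start < 0L | s$end > n | s$start >= s$end))
      stop("token offsets out of bounds in ", doc$doc_id, " sentence ", si)
    slices <- substring(doc$text, s$start + 1L, s$end)
    bad <- which(slices != s$text)
    if (length(bad))
      stop("token surface mismatch in ", doc$doc_id, " sentence ", si,
           ": token ", bad[1], " '", s$text[bad[1]], "' vs slice '",
           slices[bad[1]], "'")
    if (nrow(s) > 1L && any(s$start[-1] < s$end[-nrow(s)]))
      stop("overlapping or unsorted tokens in ", doc$doc_id,
           " sentence ", si)
  }
  invisible(doc)
}

#' @export
print.pheno_document <- function(x, ...) {
  cat(sprintf("<pheno_document> %s [%s]: %d sentences, %d tokens, %d chars\n",
              x$doc_id, x$style, length(x$sentences),
              sum(vapply(x$sentences, nrow, 0L)), nchar(x$text)))
  invisible(x)
}

# --- tokenization of raw text -----------------------------------------------

# Split one whitespace-delimited chunk into tokens, peeling single leading
# and trailing punctuation characters off as their own tokens. Internal
# punctuation (hyphens, apostrophes) stays attached.
split_chunk <- function(chunk, offset) {
  out_text <- character(); out_start <- integer()
  lead <- regmatches(chunk, regexpr("^[[:punct:]]+", chunk))
  core <- chunk; pos <- offset
  if (length(lead) && nchar(lead) < nchar(chunk)) {
    for (i in seq_len(nchar(lead))) {
      out_text <- c(out_text, substring(lead, i, i))
      out_start <- c(out_start, pos); pos <- pos + 1L
    }
    core <- substring(chunk, nchar(lead) + 1L)
  }
  trail <- regmatches(core, regexpr("[[:punct:]]+$", core))
  trail_n <- if (length(trail) && nchar(trail) < nchar(core)) nchar(trail) else 0L
  body <- substring(core, 1L, nchar(core) - trail_n)
  out_text <- c(out_text, body); out_start <- c(out_start, pos)
  pos <- pos + nchar(body)
  if (trail_n)
    for (i in seq_len(trail_n)) {
      out_text <- c(out_text, substring(core, nchar(core) - trail_n + i,
                                        nchar(core) - trail_n + i))
      out_start <- c(out_start, pos); pos <- pos + 1L
    }
  keep <- nchar(out_text) > 0L
  list(text = out_text[keep], start = out_start[keep])
}

tokenize_segment <- function(text, seg_start, seg_end) {
  seg <- substring(text, seg_start + 1L, seg_end)
  m <- gregexpr("\\S+", seg)[[1]]
  if (m[1] == -1L) return(NULL)
  texts <- character(); starts <- integer()
  for (i in seq_along(m)) {
    chunk <- substring(seg, m[i], m[i] + attr(m, "match.length")[i] - 1L)
    got <- split_chunk(chunk, seg_start + m[i] - 1L)
    texts <- c(texts, got$text); starts <- c(starts, got$start)
  }
  new_token_frame(texts, starts, starts + nchar(texts))
}

# Sentence segmentation for clinical-style raw text. Newlines always end a
# sentence (telegraphic EHR lines and list items are line-delimited); within
# a line, sentences break after . ? ! followed by whitespace and an
# uppercase letter or digit; an all-caps section header ending in ":" is its
# own sentence.
segment_sentences <- function(text) {
  segs <- list()
  line_m <- gregexpr("[^\n]+", text)[[1]]
  if (line_m[1] == -1L) return(segs)
  for (i in seq_along(line_m)) {
    l_start <- line_m[i] - 1L
    l_len <- attr(line_m, "match.length")[i]
    line <- substring(text, l_start + 1L, l_start + l_len)
    hdr <- regexpr("^\\s*[A-Z][A-Z0-9 ,/'-]*:", line)
    parts_start <- integer(); parts_end <- integer()
    cur <- 0L
    if (hdr[1] == 1L) {
      h_end <- attr(hdr, "match.length")
      parts_start <- c(parts_start, 0L); parts_end <- c(parts_end, h_end)
      cur <- h_end
    }
    rest <- substring(line, cur + 1L)
    br <- gregexpr("[.?!](?=\\s+[A-Z0-9(])", rest, perl = TRUE)[[1]]
    last <- cur
    if (br[1] != -1L) {
      for (b in br) {
        parts_start <- c(parts_start, last)
        parts_end <- c(parts_end, cur + b)
        last <- cur + b
      }
    }
    if (last < l_len) {
      parts_start <- c(parts_start, last); parts_end <- c(parts_end, l_len)
    }
    for (j in seq_along(parts_start))
      segs[[length(segs) + 1L]] <- c(l_start + parts_start[j],
                                     l_start + parts_end[j])
  }
  segs
}

#' Build a document from raw text
#'
#' Tokenizes deterministically (whitespace split, then leading/trailing
#' punctuation peeled off as separate tokens) and segments sentences
#' (newlines; sentence-final punctuation followed by an uppercase start;
#' all-caps section headers such as "HISTORY OF PRESENT ILLNESS:" become
#' their own sentences). POS/chunk tags are left `NA`; supply pre-tagged
#' input via [read_conll()] when a method needs them.
#'
#' @param text raw document text.
#' @param doc_id document identifier.
#' @param style `"discharge"` or `"article"`.
#' @return A `pheno_document`.
#' @export
document <- function(text, doc_id, style = "discharge") {
  segs <- segment_sentences(text)
  sentences <- list()
  for (sg in segs) {
    tf <- tokenize_segment(text, sg[1], sg[2])
    if (!is.null(tf) && nrow(tf)) sentences[[length(sentences) + 1L]] <- tf
  }
  document_from_tokens(doc_id, style, sentences, text = text)
}

# --- annotation sets --------------------------------------------------------

#' Construct an annotation set
#'
#' An annotation set is a data frame of labeled character spans
#' (`doc_id`, `start`, `end`, `label`, `text`; offsets 0-based,
#' end-exclusive) with an `annotator_id` attribute. Duplicate
#' (doc, span, label) rows are rejected.
#'
#' @param mentions data frame with columns `doc_id`, `start`, `end`,
#'   `label` and optionally `text`.
#' @param annotator_id identifier of the annotator that produced the set.
#' @param classes allowed entity labels.
#' @return A `pheno_annotations` data frame.
#' @export
annotation_set <- function(mentions, annotator_id = "gold",
                           classes = phenotype_classes()) {
  if (is.null(mentions) || nrow(mentions) == 0L) {
    mentions <- data.frame(doc_id = character(), start = integer(),
                           end = integer(), label = character(),
                           text = character(), stringsAsFactors = FALSE)
  }
  if (is.null(mentions$text)) mentions$text <- NA_character_
  mentions <- mentions[, c("doc_id", "start", "end", "label", "text")]
  mentions$start <- as.integer(mentions$start)
  mentions$end <- as.integer(mentions$end)
  bad <- setdiff(unique(mentions$label), classes)
  if (length(bad))
    stop("unknown entity label(s): ", paste(bad, collapse = ", "))
  if (any(mentions$start >= mentions$end))
    stop("mention with start >= end")
  key <- paste(mentions$doc_id, mentions$start, mentions$end, mentions$label)
  if (anyDuplicated(key))
    stop("duplicate mention: ", key[duplicated(key)][1])
  o <- order(mentions$doc_id, mentions$start, mentions$end)
  mentions <- mentions[o, , drop = FALSE]
  rownames(mentions) <- NULL
  structure(mentions, annotator_id = annotator_id,
            class = c("pheno_annotations", "data.frame"))
}

# mentions belonging to one document
doc_mentions <- function(mentions, doc_id) {
  mentions[mentions$doc_id == doc_id, , drop = FALSE]
}

# --- BIO encoding -----------------------------------------------------------

#' Encode a document's annotations in BIO format
#'
#' Produces one sequence example per sentence: the sentence tokens plus a
#' parallel vector of `O` / `B-<class>` / `I-<class>` labels. Mention
#' boundaries that fall strictly inside a token are snapped outward to the
#' token boundaries (with a warning): annotators mark character spans while
#' sequence labelers operate on whole tokens.
#'
#' @param doc a `pheno_document`.
#' @param mentions annotation rows for this document (non-overlapping).
#' @return List of sequence examples, each a list with elements `tokens`
#'   (token data frame), `labels` (character vector), `sentence` (index),
#'   `doc_id`.
#' @export
to_bio <- function(doc, mentions) {
  stopifnot(inherits(doc, "pheno_document"))
  m <- doc_mentions(as.data.frame(mentions), doc$doc_id)
  if (nrow(m) > 1L) {
    o <- order(m$start, m$end); m <- m[o, , drop = FALSE]
    ov <- which(m$start[-1] < m$end[-nrow(m)])
    if (length(ov))
      stop("overlapping mentions in ", doc$doc_id, ": [",
           m$start[ov[1]], ",", m$end[ov[1]], ") and [",
           m$start[ov[1] + 1L], ",", m$end[ov[1] + 1L], ")")
  }
  out <- vector("list", length(doc$sentences))
  assigned <- rep(FALSE, nrow(m))
  for (si in seq_along(doc$sentences)) {
    s <- doc$sentences[[si]]
    labels <- rep("O", nrow(s))
    hit <- which(m$start < max(s$end) & m$end > min(s$start))
    for (mi in hit) {
      cov <- which(s$start < m$end[mi] & s$end > m$start[mi])
      if (!length(cov)) next
      if (assigned[mi])
        stop("mention [", m$start[mi], ",", m$end[mi], ") '", m$text[mi],
             "' in ", doc$doc_id, " crosses a sentence boundary")
      assigned[mi] <- TRUE
      if (m$start[mi] > s$start[cov[1]] || m$end[mi] < s$end[cov[length(cov)]])
        warning("mention [", m$start[mi], ",", m$end[mi], ") in ",
                doc$doc_id, " snapped outward to token boundaries [",
                s$start[cov[1]], ",", s$end[cov[length(cov)]], ")")
      labels[cov[1]] <- paste0("B-", m$label[mi])
      if (length(cov) > 1L)
        labels[cov[-1]] <- paste0("I-", m$label[mi])
    }
    out[[si]] <- list(tokens = s, labels = labels, sentence = si,
                      doc_id = doc$doc_id)
  }
  if (any(!assigned & nrow(m) > 0L)) {
    miss <- which(!assigned)
    if (length(miss))
      stop("mention [", m$start[miss[1]], ",", m$end[miss[1]],
           ") in ", doc$doc_id, " covers no tokens")
  }
  out
}

#' Decode BIO labels back into entity mentions
#'
#' Each maximal `B-`/`I-` run of one class becomes one mention spanning
#' from the first token's start to the last token's end. An `I-<class>`
#' continuation without a compatible predecessor is repaired by treating it
#' as `B-<class>`, so any label sequence decodes to a valid mention set.
#'
#' @param example a sequence example (list with `tokens` and `labels`), or
#'   a token data frame when `labels` is supplied separately.
#' @param doc_id document the mentions are anchored to.
#' @param labels optional label vector overriding `example$labels`.
#' @param text optional document text used to recover exact surfaces;
#'   when absent, surfaces are rebuilt from token texts and offsets.
#' @return Data frame of mentions (`doc_id`, `start`, `end`, `label`,
#'   `text`).
#' @export
from_bio <- function(example, doc_id = example$doc_id, labels = NULL,
                     text = NULL) {
  tokens <- if (is.data.frame(example)) example else example$tokens
  labels <- labels %||% example$labels
  if (length(labels) != nrow(tokens))
    stop("length mismatch: ", length(labels), " labels for ",
         nrow(tokens), " tokens")
  n <- length(labels)
  res <- list()
  i <- 1L
  while (i <= n) {
    lab <- labels[i]
    if (lab == "O") { i <- i + 1L; next }
    cls <- sub("^[BI]-", "", lab)
    j <- i
    while (j < n && labels[j + 1L] == paste0("I-", cls)) j <- j + 1L
    surface <- if (!is.null(text)) {
      substring(text, tokens$start[i] + 1L, tokens$end[j])
    } else if (j > i) {
      gaps <- tokens$start[(i + 1L):j] - tokens$end[i:(j - 1L)]
      parts <- tokens$text[i:j]
      paste0(paste0(parts[-length(parts)], strrep(" ", gaps),
                    collapse = ""), parts[length(parts)])
    } else tokens$text[i]
    res[[length(res) + 1L]] <- data.frame(
      doc_id = doc_id, start = tokens$start[i], end = tokens$end[j],
      label = cls, text = surface, stringsAsFactors = FALSE)
    i <- j + 1L
  }
  if (!length(res))
    return(data.frame(doc_id = character(), start = integer(),
                      end = integer(), label = character(),
                      text = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# --- standoff format --------------------------------------------------------

#' Read a text + standoff annotation pair
#'
#' The standoff dialect is brat-compatible entity lines only:
#' `T<n><TAB><Label> <start> <end><TAB><surface>`. Offsets are validated
#' against the text and the surface must equal the text slice.
#'
#' @param text_path path to the UTF-8 document text.
#' @param ann_path path to the annotation file.
#' @param doc_id document id; defaults to the text file name without
#'   extension.
#' @param style document style tag.
#' @param annotator_id annotator id recorded on the returned set.
#' @return List with elements `document` and `annotations`.
#' @export
read_standoff <- function(text_path, ann_path, doc_id = NULL,
                          style = "discharge", annotator_id = "gold") {
  text <- paste(readLines(text_path, warn = FALSE, encoding = "UTF-8"),
                collapse = "\n")
  doc_id <- doc_id %||% sub("\\.[^.]*$", "", basename(text_path))
  doc <- document(text, doc_id, style)
  lines <- readLines(ann_path, warn = FALSE, encoding = "UTF-8")
  rows <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) next
    if (!startsWith(line, "T")) next  # only entity (T) lines carried
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop(ann_path, ":", ln, ": expected 3 tab-separated fields")
    head_parts <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
    if (length(head_parts) != 3L)
      stop(ann_path, ":", ln, ": expected '<Label> <start> <end>'")
    label <- head_parts[1]
    start <- suppressWarnings(as.integer(head_parts[2]))
    end <- suppressWarnings(as.integer(head_parts[3]))
    if (is.na(start) || is.na(end))
      stop(ann_path, ":", ln, ": non-numeric offsets")
    if (!label %in% phenotype_classes())
      stop(ann_path, ":", ln, ": unknown label '", label, "'")
    if (start < 0L || end > nchar(text) || start >= end)
      stop(ann_path, ":", ln, ": offsets [", start, ",", end,
           ") outside text of length ", nchar(text))
    slice <- substring(text, start + 1L, end)
    if (slice != parts[3])
      stop(ann_path, ":", ln, ": surface mismatch: file has '", parts[3],
           "', text slice is '", slice, "'")
    rows[[length(rows) + 1L]] <- data.frame(
      doc_id = doc_id, start = start, end = end, label = label,
      text = slice, stringsAsFactors = FALSE)
  }
  ann <- annotation_set(if (length(rows)) do.call(rbind, rows) else NULL,
                        annotator_id = annotator_id)
  list(document = doc, annotations = ann)
}

#' Write a text + standoff annotation pair
#'
#' @param doc a `pheno_document`.
#' @param mentions annotation rows for this document.
#' @param text_path,ann_path output paths.
#' @return Invisibly, the annotation path.
#' @export
write_standoff <- function(doc, mentions, text_path, ann_path) {
  writeLines(doc$text, text_path, useBytes = TRUE)
  m <- doc_mentions(as.data.frame(mentions), doc$doc_id)
  lines <- character(nrow(m))
  for (i in seq_len(nrow(m)))
    lines[i] <- sprintf("T%d\t%s %d %d\t%s", i, m$label[i], m$start[i],
                        m$end[i],
                        substring(doc$text, m$start[i] + 1L, m$end[i]))
  writeLines(lines, ann_path, useBytes = TRUE)
  invisible(ann_path)
}

# --- CoNLL-style format -----------------------------------------------------

#' Read a CoNLL-style tab-separated corpus file
#'
#' Columns: `token<TAB>start<TAB>end<TAB>pos<TAB>chunk[<TAB>label]`; a
#' blank line ends a sentence; a line `#doc id=<id> style=<style>` starts
#' a new document. This carrier lets pre-tokenized, POS/chunk-tagged text
#' enter the pipeline so no external tagger is required.
#'
#' @param path input file.
#' @return List with `documents` (list of `pheno_document`) and
#'   `annotations` (a `pheno_annotations` frame if a label column was
#'   present, otherwise `NULL`).
#' @export
read_conll <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  docs <- list(); anns <- list()
  cur_id <- sub("\\.[^.]*$", "", basename(path)); cur_style <- "discharge"
  sent_rows <- list(); sentences <- list(); sent_labels <- list()
  labels_cur <- character()
  has_labels <- FALSE
  flush_sentence <- function() {
    if (length(sent_rows)) {
      tf <- do.call(rbind, sent_rows)
      sentences[[length(sentences) + 1L]] <<- tf
      sent_labels[[length(sent_labels) + 1L]] <<- labels_cur
    }
    sent_rows <<- list(); labels_cur <<- character()
  }
  flush_doc <- function() {
    flush_sentence()
    if (length(sentences)) {
      doc <- document_from_tokens(cur_id, cur_style, sentences)
      docs[[length(docs) + 1L]] <<- doc
      if (has_labels)
        for (si in seq_along(sentences))
          anns[[length(anns) + 1L]] <<- from_bio(
            list(tokens = doc$sentences[[si]], labels = sent_labels[[si]]),
            doc_id = cur_id, text = doc$text)
    }
    sentences <<- list(); sent_labels <<- list()
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (startsWith(line, "#doc")) {
      flush_doc()
      id_m <- regmatches(line, regexpr("id=\\S+", line))
      st_m <- regmatches(line, regexpr("style=\\S+", line))
      cur_id <- if (length(id_m)) sub("^id=", "", id_m) else cur_id
      cur_style <- if (length(st_m)) sub("^style=", "", st_m) else "discharge"
      next
    }
    if (!nzchar(trimws(line))) { flush_sentence(); next }
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (!length(f) %in% c(5L, 6L))
      stop(path, ":", ln, ": expected 5 or 6 tab-separated columns, got ",
           length(f))
    if (length(f) == 6L) has_labels <- TRUE
    if (has_labels && length(f) == 5L)
      stop(path, ":", ln, ": ragged row (label column missing)")
    sent_rows[[length(sent_rows) + 1L]] <- new_token_frame(
      f[1], as.integer(f[2]), as.integer(f[3]), f[4], f[5])
    labels_cur <- c(labels_cur, if (length(f) == 6L) f[6] else NA_character_)
  }
  flush_doc()
  annotations <- if (has_labels)
    annotation_set(do.call(rbind, anns)) else NULL
  list(documents = docs, annotations = annotations)
}

#' Write documents (optionally with gold labels) in the CoNLL-style dialect
#'
#' @param docs list of `pheno_document`.
#' @param path output file.
#' @param annotations optional gold annotations; when given a sixth BIO
#'   label column is written.
#' @return Invisibly, `path`.
#' @export
write_conll <- function(docs, path, annotations = NULL) {
  if (inherits(docs, "pheno_document")) docs <- list(docs)
  out <- character()
  for (doc in docs) {
    out <- c(out, sprintf("#doc id=%s style=%s", doc$doc_id, doc$style))
    bio <- if (!is.null(annotations)) to_bio(doc, annotations) else NULL
    for (si in seq_along(doc$sentences)) {
      s <- doc$sentences[[si]]
      cols <- cbind(s$text, s$start, s$end,
                    ifelse(is.na(s$pos), "_", s$pos),
                    ifelse(is.na(s$chunk), "_", s$chunk))
      if (!is.null(bio)) cols <- cbind(cols, bio[[si]]$labels)
      out <- c(out, apply(cols, 1L, paste, collapse = "\t"), "")
    }
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

# --- document selection -----------------------------------------------------

#' Select documents mentioning target diseases
#'
#' Keeps exactly the documents containing at least one lexicon entry:
#' short all-caps entries (acronyms such as `CRF`, `CRI`) match whole
#' tokens case-sensitively on the uppercased form; other entries (full
#' forms and synonyms such as `renal insufficiency`) match
#' case-insensitively as substrings of the text.
#'
#' @param docs list of `pheno_document`.
#' @param lexicon character vector of disease names, acronyms, synonyms.
#' @return The selected documents, input order preserved.
#' @export
select_documents <- function(docs, lexicon) {
  if (length(lexicon) == 0L) stop("empty selection lexicon")
  is_acro <- grepl("^[A-Z0-9]{2,6}$", lexicon) & !grepl(" ", lexicon)
  acro <- lexicon[is_acro]
  terms <- tolower(lexicon[!is_acro])
  keep <- vapply(docs, function(doc) {
    toks <- unlist(lapply(doc$sentences, function(s) s$text))
    if (length(acro) && any(toupper(toks) %in% acro)) return(TRUE)
    if (length(terms)) {
      lo <- tolower(doc$text)
      if (any(vapply(terms, function(tm) grepl(tm, lo, fixed = TRUE), TRUE)))
        return(TRUE)
    }
    FALSE
  }, TRUE)
  docs[keep]
}
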