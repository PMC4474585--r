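#' Construct a gazetteer lexicon
#'
#' A lexicon maps terms (possibly multiword) to semantic types, playing the
#' role of a dictionary tagger restricted to disorder-like semantic types.
#' Lookup is case-insensitive; multiword terms are stored token-split and
#' matched against token sequences.
#'
#' @param entries data frame with columns `term` and `semtype`. Duplicate
#'   terms with different semantic types are allowed and retained.
#' @param allowed_semtypes semantic types permitted to produce mentions;
#'   `NULL` allows all types present.
#' @return A `pheno_lexicon`.
#' @export
pheno_lexicon <- function(entries, allowed_semtypes = NULL) {
  stopifnot(is.data.frame(entries), all(c("term", "semtype") %in%
                                        names(entries)))
  entries$term <- as.character(entries$term)
  entries$semtype <- as.character(entries$semtype)
  if (any(!nzchar(entries$term))) stop("empty term in lexicon")
  toks <- strsplit(tolower(entries$term), "\\s+")
  structure(list(entries = entries, tokens = toks,
                 first = vapply(toks, `[`, "", 1L),
                 allowed_semtypes = allowed_semtypes %||%
                   unique(entries$semtype)),
            class = "pheno_lexicon")
}

#' @export
print.pheno_lexicon <- function(x, ...) {
  cat(sprintf("<pheno_lexicon> %d entries, %d semantic types (%d allowed)\n",
              nrow(x$entries), length(unique(x$entries$semtype)),
              length(x$allowed_semtypes)))
  invisible(x)
}

#' Read a lexicon from a TSV file
#'
#' Lines are `term<TAB>semtype`; `#` comments and blank lines ignored.
#'
#' @param path input file.
#' @param allowed_semtypes see [pheno_lexicon()].
#' @return A `pheno_lexicon`.
#' @export
read_lexicon <- function(path, allowed_semtypes = NULL) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  rows <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line)) || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 2L)
      stop(path, ":", ln, ": expected 'term<TAB>semtype', got ",
           length(f), " fields")
    rows[[length(rows) + 1L]] <- data.frame(term = f[1], semtype = f[2],
                                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop(path, ": empty lexicon")
  pheno_lexicon(do.call(rbind, rows), allowed_semtypes)
}

#' Write a lexicon to TSV
#'
#' @param lexicon a `pheno_lexicon`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_lexicon <- function(lexicon, path) {
  writeLines(paste(lexicon$entries$term, lexicon$entries$semtype,
                   sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}

#' Bundled disorder-style lexicon
#'
#' A small lexicon of cardiovascular and renal disorder terms shipped for
#' tests, examples and the synthetic corpus. Semantic types follow the
#' UMLS-style short codes (`dsyn` disease or syndrome, `sosy` sign or
#' symptom, `patf` pathologic function, `fndg` finding).
#'
#' @param allowed_semtypes see [pheno_lexicon()].
#' @return A `pheno_lexicon`.
#' @export
disorder_lexicon <- function(allowed_semtypes = NULL) {
  read_lexicon(system.file("extdata", "disorder_lexicon.tsv",
                           package = "phenoNER"), allowed_semtypes)
}

#' Bundled disease-selection term list
#'
#' Full forms, acronyms and synonyms of the target diseases (congestive
#' heart failure and kidney failure) used by [select_documents()] to pick
#' out relevant documents.
#'
#' @return Character vector of terms.
#' @export
chf_selection_terms <- function() {
  readLines(system.file("extdata", "chf_selection.txt",
                        package = "phenoNER"), warn = FALSE)
}

#' Tag a document with a lexicon (dictionary baseline)
#'
#' Greedy longest-match scan, left to right within each sentence: at each
#' token the longest lexicon entry whose token sequence matches
#' (case-insensitively) is taken, the scan resumes after it, and shorter
#' or overlapping candidates are discarded. Only entries whose semantic
#' type is in `allowed_semtypes` produce mentions; matched tokens get
#' their `sem` attribute set to the entry's semantic type. There is no
#' fuzzy matching: a misspelled surface form is simply missed, and a
#' multiword expression absent from the lexicon is matched only through
#' whatever sub-spans the lexicon does contain.
#'
#' @param doc a `pheno_document`.
#' @param lexicon a `pheno_lexicon`.
#' @param class_map named character vector mapping semantic types to
#'   phenotype classes; types not named map to `default_class`.
#' @param default_class phenotype class assigned when `class_map` has no
#'   entry for a semantic type.
#' @return List with `document` (tokens' `sem` filled in) and `mentions`.
#' @export
tag_with_lexicon <- function(doc, lexicon, class_map = NULL,
                             default_class = "SignSymptom") {
  stopifnot(inherits(doc, "pheno_document"),
            inherits(lexicon, "pheno_lexicon"))
  res <- list()
  allowed <- lexicon$allowed_semtypes
  for (si in seq_along(doc$sentences)) {
    s <- doc$sentences[[si]]
    lo <- tolower(s$text)
    t <- 1L
    while (t <= nrow(s)) {
      cand <- which(lexicon$first == lo[t])
      best_len <- 0L; best_entry <- NA_integer_; best_allowed <- FALSE
      for (ci in cand) {
        etoks <- lexicon$tokens[[ci]]
        L <- length(etoks)
        if (t + L - 1L > nrow(s) || !all(lo[t:(t + L - 1L)] == etoks)) next
        ok <- lexicon$entries$semtype[ci] %in% allowed
        # longest span wins; among equal spans an allowed semtype wins,
        # then the earlier lexicon entry (deterministic)
        if (L > best_len || (L == best_len && ok && !best_allowed)) {
          best_len <- L; best_entry <- ci; best_allowed <- ok
        }
      }
      if (best_len > 0L) {
        semtype <- lexicon$entries$semtype[best_entry]
        idx <- t:(t + best_len - 1L)
        doc$sentences[[si]]$sem[idx] <- semtype
        if (best_allowed) {
          label <- if (!is.null(class_map) && semtype %in% names(class_map))
            unname(class_map[semtype]) else default_class
          res[[length(res) + 1L]] <- data.frame(
            doc_id = doc$doc_id, start = s$start[t],
            end = s$end[t + best_len - 1L], label = label,
            text = substring(doc$text, s$start[t] + 1L,
                             s$end[t + best_len - 1L]),
            stringsAsFactors = FALSE)
        }
        t <- t + best_len
      } else t <- t + 1L
    }
  }
  mentions <- if (length(res)) do.call(rbind, res) else
    data.frame(doc_id = character(), start = integer(), end = integer(),
               label = character(), text = character(),
               stringsAsFactors = FALSE)
  rownames(mentions) <- NULL
  list(document = doc, mentions = mentions)
}
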