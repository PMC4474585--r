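test_that("raw-text tokenization splits punctuation and finds headers", {
  txt <- "HISTORY OF PRESENT ILLNESS :\nPatient has chest pain. Denies edema.\n- fatigue noted"
  d <- document(txt, "d1", "discharge")
  expect_equal(length(d$sentences), 4L)
  expect_equal(d$sentences[[1]]$text,
               c("HISTORY", "OF", "PRESENT", "ILLNESS", ":"))
  expect_equal(d$sentences[[2]]$text[5], ".")
  # offsets always slice back to the surface
  expect_silent(validate_document(d))
  # leading punctuation peeled off
  d2 <- document("(CHF) noted.", "d2")
  expect_equal(d2$sentences[[1]]$text[1:3], c("(", "CHF", ")"))
})

test_that("to_bio encodes mentions and handles edge cases", {
  d <- doc1(c("has", "chest", "pain", "and", "edema"),
            c("VBZ", "NN", "NN", "CC", "NN"))
  s <- d$sentences[[1]]
  # zero mentions -> all O
  bio0 <- to_bio(d, data.frame(doc_id = character(), start = integer(),
                               end = integer(), label = character(),
                               text = character()))
  expect_equal(bio0[[1]]$labels, rep("O", 5))
  # mention over tokens 2-3
  m <- data.frame(doc_id = "d1", start = s$start[2], end = s$end[3],
                  label = "SignSymptom", text = "chest pain")
  bio <- to_bio(d, m)
  expect_equal(bio[[1]]$labels,
               c("O", "B-SignSymptom", "I-SignSymptom", "O", "O"))
  # mid-token boundaries snap outward with a warning
  m2 <- m; m2$start <- s$start[2] + 1L
  expect_warning(bio2 <- to_bio(d, m2), "snapped")
  expect_equal(bio2[[1]]$labels, bio[[1]]$labels)
  # overlapping mentions rejected, pair named
  m3 <- rbind(m, data.frame(doc_id = "d1", start = s$start[3],
                            end = s$end[4], label = "Cause",
                            text = "pain and"))
  expect_error(to_bio(d, m3), "overlapping")
  # cross-sentence mention rejected
  s2 <- tok(c("c", "d")); s2$start <- s2$start + 5L; s2$end <- s2$end + 5L
  d2 <- document_from_tokens("d2", "discharge",
                             list(tok(c("a", "b")), s2))
  mx <- data.frame(doc_id = "d2", start = 2L, end = 7L, label = "Cause",
                   text = substring(d2$text, 3, 7))
  expect_error(to_bio(d2, mx), "crosses a sentence boundary")
})

test_that("from_bio decodes runs and repairs orphan continuations", {
  tks <- tok(c("a", "b", "c", "d"))
  expect_equal(nrow(from_bio(tks, "d", labels = rep("O", 4))), 0L)
  m <- from_bio(tks, "d", labels = c("B-Cause", "I-Cause", "O", "B-Cause"))
  expect_equal(nrow(m), 2L)
  expect_equal(m$label, c("Cause", "Cause"))
  expect_equal(m$start, c(tks$start[1], tks$start[4]))
  # orphan I- at position 1 starts a mention (repair policy)
  m2 <- from_bio(tks, "d", labels = c("I-Cause", "O", "O", "O"))
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$start, tks$start[1])
  # class switch without B- starts a new mention
  m3 <- from_bio(tks, "d",
                 labels = c("B-Cause", "I-RiskFactor", "O", "O"))
  expect_equal(m3$label, c("Cause", "RiskFactor"))
  expect_error(from_bio(tks, "d", labels = c("O", "O")), "length mismatch")
})

test_that("BIO round trip is the identity on generated corpora", {
  corp <- generate_corpus(generator_config(30, "discharge", seed = 7))
  gold <- as.data.frame(corp$annotations)
  for (doc in corp$documents) {
    bio <- to_bio(doc, corp$annotations)
    back <- do.call(rbind, lapply(bio, from_bio, text = doc$text))
    g <- gold[gold$doc_id == doc$doc_id, c("start", "end", "label", "text")]
    g <- g[order(g$start), ]; rownames(g) <- NULL
    if (is.null(back)) {
      expect_equal(nrow(g), 0L)
    } else {
      b <- back[order(back$start), c("start", "end", "label", "text")]
      rownames(b) <- NULL
      expect_equal(b, g)
    }
  }
  # and the encodings always satisfy the BIO invariant
  for (doc in corp$documents[1:5]) {
    for (ex in to_bio(doc, corp$annotations)) {
      labs <- ex$labels
      for (t in seq_along(labs)) {
        if (startsWith(labs[t], "I-")) {
          cls <- sub("^I-", "", labs[t])
          expect_true(t > 1 &&
                      labs[t - 1] %in% paste0(c("B-", "I-"), cls))
        }
      }
    }
  }
})

test_that("standoff files round trip and reject bad input", {
  tdir <- withr::local_tempdir()
  corp <- generate_corpus(generator_config(10, "discharge", seed = 3))
  # accumulate a few hundred random mentions across docs
  set.seed(42)
  for (doc in corp$documents) {
    m <- random_mentions(list(doc), n_per_doc = 4L)
    if (is.null(m)) next
    m <- annotation_set(m)
    tp <- file.path(tdir, paste0(doc$doc_id, ".txt"))
    ap <- file.path(tdir, paste0(doc$doc_id, ".ann"))
    write_standoff(doc, m, tp, ap)
    got <- read_standoff(tp, ap, doc_id = doc$doc_id)
    a <- as.data.frame(m); b <- as.data.frame(got$annotations)
    o <- function(x) { x <- x[order(x$start, x$end, x$label), ]
                       rownames(x) <- NULL; x }
    expect_equal(o(b), o(a))
  }
  # surface mismatch reported with line number
  writeLines("chest pain here", file.path(tdir, "x.txt"))
  writeLines("T1\tSignSymptom 0 5\twrong", file.path(tdir, "x.ann"))
  expect_error(read_standoff(file.path(tdir, "x.txt"),
                             file.path(tdir, "x.ann")),
               "x.ann:1.*surface mismatch")
  writeLines("T1\tSignSymptom 0 999\tchest", file.path(tdir, "y.ann"))
  expect_error(read_standoff(file.path(tdir, "x.txt"),
                             file.path(tdir, "y.ann")), "outside text")
  writeLines("T1\tBogus 0 5\tchest", file.path(tdir, "z.ann"))
  expect_error(read_standoff(file.path(tdir, "x.txt"),
                             file.path(tdir, "z.ann")), "unknown label")
})

test_that("CoNLL files round trip with and without labels", {
  tdir <- withr::local_tempdir()
  corp <- generate_corpus(generator_config(6, "article", seed = 5))
  path <- file.path(tdir, "c.tsv")
  write_conll(corp$documents, path, corp$annotations)
  got <- read_conll(path)
  expect_equal(length(got$documents), 6L)
  for (i in seq_along(corp$documents)) {
    a <- corp$documents[[i]]; b <- got$documents[[i]]
    expect_equal(b$doc_id, a$doc_id)
    expect_equal(b$style, a$style)
    expect_equal(length(b$sentences), length(a$sentences))
    for (si in seq_along(a$sentences))
      expect_equal(b$sentences[[si]][, c("text", "start", "end", "pos",
                                         "chunk")],
                   a$sentences[[si]][, c("text", "start", "end", "pos",
                                         "chunk")])
  }
  o <- function(x) { x <- as.data.frame(x)
                     x <- x[order(x$doc_id, x$start), ]
                     rownames(x) <- NULL
                     x[, c("doc_id", "start", "end", "label")] }
  expect_equal(o(got$annotations), o(corp$annotations))
  # without labels: tagging columns survive, annotations NULL
  path2 <- file.path(tdir, "c2.tsv")
  write_conll(corp$documents, path2)
  got2 <- read_conll(path2)
  expect_null(got2$annotations)
  expect_equal(got2$documents[[1]]$sentences[[1]]$pos,
               corp$documents[[1]]$sentences[[1]]$pos)
  # ragged rows are reported with their line number
  bad <- readLines(path)
  bad[3] <- paste(strsplit(bad[3], "\t")[[1]][1:3], collapse = "\t")
  writeLines(bad, file.path(tdir, "bad.tsv"))
  expect_error(read_conll(file.path(tdir, "bad.tsv")), ":3")
})

test_that("document selection matches acronyms and term substrings", {
  lex <- c("CRF", "CRI", "renal insufficiency", "kidney failure")
  d1 <- document("Patient with CRF on dialysis.", "s1")
  d2 <- document("Has Renal Insufficiency since 2009.", "s2")
  d3 <- document("Unremarkable visit, healthy.", "s3")
  d4 <- document("The crf protocol form was filed.", "s4")  # lowercase token
  got <- select_documents(list(d1, d2, d3, d4), lex)
  ids <- vapply(got, function(d) d$doc_id, "")
  expect_true(all(c("s1", "s2", "s4") %in% ids))
  expect_false("s3" %in% ids)
  expect_error(select_documents(list(d1), character()), "empty")
})
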