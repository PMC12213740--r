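# Corpus data model and I/O for labeled short clinical texts.
#
# A tf_corpus is a list with
#   documents: data.frame(id, text, label) -- one row per document
#   labels:    character vector of class names, sorted lexicographically
#   splits:    NULL, or list(train=, val=, test=) of document ids

#' Construct a corpus from documents
#'
#' @param id character vector of unique document identifiers.
#' @param text character vector of raw document texts.
#' @param label character vector of department labels.
#' @param splits optional list with elements `train`, `val`, `test` holding
#'   disjoint, exhaustive sets of document ids.
#' @return An object of class `tf_corpus`.
#' @export
new_corpus <- function(id, text, label, splits = NULL) {
  stopifnot(length(id) == length(text), length(text) == length(label))
  id <- as.character(id); text <- as.character(text); label <- as.character(label)
  if (anyDuplicated(id)) stop("duplicate document ids")
  docs <- data.frame(id = id, text = text, label = label,
                     stringsAsFactors = FALSE)
  structure(list(documents = docs,
                 labels = sort(unique(label)),
                 splits = splits),
            class = "tf_corpus")
}

#' Coerce a data frame to a corpus
#'
#' @param x a data.frame with columns `text` and `label` (and optionally `id`).
#' @return A `tf_corpus`.
#' @export
as_corpus <- function(x) {
  if (inherits(x, "tf_corpus")) return(x)
  stopifnot(is.data.frame(x))
  if (!all(c("text", "label") %in% names(x)))
    stop("data frame must have 'text' and 'label' columns")
  id <- if ("id" %in% names(x)) as.character(x$id) else sprintf("doc%06d", seq_len(nrow(x)))
  new_corpus(id, x$text, x$label)
}

#' @export
print.tf_corpus <- function(x, ...) {
  cat(sprintf("Labeled text corpus: %d documents, %d classes\n",
              nrow(x$documents), length(x$labels)))
  tab <- table(factor(x$documents$label, levels = x$labels))
  for (l in x$labels) cat(sprintf("  %-18s %6d\n", l, tab[[l]]))
  if (!is.null(x$splits)) {
    cat(sprintf("Splits: train=%d val=%d test=%d\n",
                length(x$splits$train), length(x$splits$val),
                length(x$splits$test)))
  }
  invisible(x)
}

#' Number of documents in a corpus
#' @param x a `tf_corpus`.
#' @param ... unused.
#' @export
length.tf_corpus <- function(x) nrow(x$documents)

#' Read a labeled corpus from JSONL or CSV
#'
#' JSONL holds one object per line with keys `id`, `text`, `label`
#' (a missing `id` is filled in from the line number). CSV must carry a
#' header with columns `id`, `text`, `label` (RFC-4180 quoting).
#' The label vocabulary is built from the observed labels, sorted
#' lexicographically so class indices are reproducible across runs.
#'
#' @param path file path.
#' @param format `"jsonl"` or `"csv"`; default guesses from the extension.
#' @return A `tf_corpus`.
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty corpus: ", path)
    recs <- lapply(seq_along(lines), function(i) {
      rec <- jsonlite::fromJSON(lines[[i]])
      for (f in c("text", "label")) {
        if (is.null(rec[[f]]))
          stop(sprintf("record %d is missing field '%s'", i, f))
      }
      if (is.null(rec$id)) rec$id <- sprintf("doc%06d", i)
      rec
    })
    new_corpus(vapply(recs, function(r) as.character(r$id), ""),
               vapply(recs, function(r) as.character(r$text), ""),
               vapply(recs, function(r) as.character(r$label), ""))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character", encoding = "UTF-8")
    if (nrow(df) == 0L) stop("empty corpus: ", path)
    for (f in c("text", "label")) {
      if (!f %in% names(df)) stop(sprintf("CSV is missing column '%s'", f))
      bad <- which(is.na(df[[f]]) | !nzchar(df[[f]]))
      if (f == "label" && length(bad))
        stop(sprintf("record %d is missing field 'label'", bad[1]))
    }
    if (!"id" %in% names(df)) df$id <- sprintf("doc%06d", seq_len(nrow(df)))
    new_corpus(df$id, df$text, df$label)
  }
}

#' Write a corpus to JSONL or CSV
#'
#' @param corpus a `tf_corpus`.
#' @param path output file path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  docs <- corpus$documents
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(docs)), function(i) {
      jsonlite::toJSON(list(id = docs$id[i], text = docs$text[i],
                            label = docs$label[i]), auto_unbox = TRUE)
    }, "")
    writeLines(lines, path, useBytes = TRUE)
  } else {
    utils::write.csv(docs[, c("id", "text", "label")], path,
                     row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Stratified train/validation/test split
#'
#' Partitions document ids into train/val/test strata per label, following
#' the configured proportions (default 8:1:1) within rounding. Classes with
#' fewer than 3 members cannot populate all three splits and are placed
#' wholly in train with a warning. Deterministic given `seed`.
#'
#' @param corpus a `tf_corpus`.
#' @param ratios numeric length-3 vector of train/val/test proportions,
#'   positive, summing to 1.
#' @param seed integer seed for the permutation within each class.
#' @return The corpus with a `splits` field filled in.
#' @export
split_corpus <- function(corpus, ratios = c(0.8, 0.1, 0.1), seed = 0L) {
  stopifnot(length(ratios) == 3, all(ratios > 0))
  if (abs(sum(ratios) - 1) > 1e-9) stop("split ratios must sum to 1")
  docs <- corpus$documents
  splits <- list(train = character(0), val = character(0), test = character(0))
  rng <- local_rng(seed)
  for (lab in corpus$labels) {
    ids <- docs$id[docs$label == lab]
    n <- length(ids)
    if (n == 0L) next
    if (n < 3L) {
      warning(sprintf("class '%s' has %d member(s); placed wholly in train",
                      lab, n))
      splits$train <- c(splits$train, ids)
      next
    }
    perm <- ids[rng$sample_int(n, n)]
    n_train <- round(ratios[1] * n)
    n_val <- round(ratios[2] * n)
    # keep at least one document in every split for a 3+ class
    n_train <- min(max(n_train, 1L), n - 2L)
    n_val <- min(max(n_val, 1L), n - n_train - 1L)
    splits$train <- c(splits$train, perm[seq_len(n_train)])
    splits$val <- c(splits$val, perm[n_train + seq_len(n_val)])
    splits$test <- c(splits$test, perm[(n_train + n_val + 1L):n])
  }
  corpus$splits <- splits
  corpus
}

#' Subset of a corpus belonging to one split
#' @param corpus a split `tf_corpus`.
#' @param split one of `"train"`, `"val"`, `"test"`.
#' @return A data.frame of documents in the split.
#' @export
split_docs <- function(corpus, split = c("train", "val", "test")) {
  split <- match.arg(split)
  if (is.null(corpus$splits)) stop("corpus has no splits; call split_corpus()")
  docs <- corpus$documents
  docs[match(corpus$splits[[split]], docs$id), , drop = FALSE]
}

# ---- tokenization & vocabulary ----------------------------------------------

# Reserved token ids (1-based). Content tokens start at RESERVED_N + 1.
TOK_PAD <- 1L; TOK_UNK <- 2L; TOK_CLS <- 3L; TOK_SEP <- 4L; TOK_MASK <- 5L
RESERVED <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")

#' Tokenize raw text
#'
#' Lower-cases and splits on whitespace and punctuation. This is the
#' deterministic scratch tokenizer used in self-contained mode; a pretrained
#' encoder adapter may supply its own sub-word tokenizer instead.
#'
#' @param text character scalar.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize_text <- function(text) {
  x <- tolower(text)
  x <- gsub("[^a-z0-9]+", " ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Build a token vocabulary from the training split
#'
#' @param corpus a `tf_corpus`; the train split is used when splits exist,
#'   otherwise all documents.
#' @param min_count minimum token frequency; rarer tokens map to `[UNK]`.
#' @return A `tf_vocab`: named integer vector token -> id, with the reserved
#'   tokens `[PAD]`, `[UNK]`, `[CLS]`, `[SEP]`, `[MASK]` always present.
#' @export
build_vocab <- function(corpus, min_count = 1L) {
  texts <- if (!is.null(corpus$splits)) split_docs(corpus, "train")$text
           else corpus$documents$text
  counts <- table(unlist(lapply(texts, tokenize_text)))
  keep <- sort(names(counts[counts >= min_count]))
  ids <- seq_along(c(RESERVED, keep))
  names(ids) <- c(RESERVED, keep)
  structure(ids, class = "tf_vocab")
}

#' @export
print.tf_vocab <- function(x, ...) {
  cat(sprintf("Token vocabulary: %d entries (%d reserved)\n",
              length(x), length(RESERVED)))
  invisible(x)
}

#' Encode text into a fixed-length token-id sequence
#'
#' Produces `[CLS] tokens... [SEP]` truncated to `pad_size` (keeping `[CLS]`
#' and forcing the final kept position to `[SEP]`), then padded with `[PAD]`.
#' `length` counts real (non-pad) positions including `[CLS]`/`[SEP]`.
#'
#' @param text character scalar.
#' @param vocab a `tf_vocab`.
#' @param pad_size fixed sequence capacity L (>= 3).
#' @return A `tf_tokenseq`: list(ids, length, pad_size).
#' @export
encode_text <- function(text, vocab, pad_size) {
  if (pad_size < 3L) stop("pad_size must be at least 3")
  toks <- tokenize_text(text)
  ids <- unname(vocab[toks])
  ids[is.na(ids)] <- TOK_UNK
  seq_ids <- c(TOK_CLS, ids, TOK_SEP)
  if (length(seq_ids) > pad_size) {
    seq_ids <- seq_ids[seq_len(pad_size)]
    seq_ids[pad_size] <- TOK_SEP
  }
  len <- length(seq_ids)
  seq_ids <- c(seq_ids, rep(TOK_PAD, pad_size - len))
  structure(list(ids = as.integer(seq_ids), length = len,
                 pad_size = as.integer(pad_size)),
            class = "tf_tokenseq")
}

#' Write the label map as JSON
#' @param corpus a `tf_corpus`.
#' @param path output path; `{name: 0-based index}`.
#' @export
write_label_map <- function(corpus, path) {
  m <- as.list(seq_along(corpus$labels) - 1L)
  names(m) <- corpus$labels
  jsonlite::write_json(m, path, auto_unbox = TRUE)
  invisible(path)
}

#' Write the split manifest as JSON
#' @param corpus a split `tf_corpus`.
#' @param path output path; `{split: [ids]}`.
#' @export
write_split_manifest <- function(corpus, path) {
  if (is.null(corpus$splits)) stop("corpus has no splits")
  jsonlite::write_json(corpus$splits, path)
  invisible(path)
}
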