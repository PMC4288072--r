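## Core data model: documents, tokens, entity mentions, BIO encoding, and
## the standoff / CoNLL corpus formats.

#' The nine entity classes
#'
#' Closed set of entity classes recognised by the tagger: drug name
#' (Medication), single-administration amount (Dosage), administration
#' method (Route), dosing schedule (Frequency), length of administration
#' (Duration), condition the drug was given for (Indication), harm caused
#' by the drug (AdverseEvent), other signs/symptoms/diseases (OSSD), and
#' non-drug treatment received (Treatment).
#'
#' @return Character vector of the nine class names, in canonical order.
#' @export
entity_classes <- function() {
  c("Medication", "Dosage", "Route", "Frequency", "Duration",
    "Indication", "AdverseEvent", "OSSD", "Treatment")
}

#' The BIO label alphabet
#'
#' Nineteen labels: \code{"O"} first, then \code{B-<class>} and
#' \code{I-<class>} for each entity class. Label order is the tie-break
#' order used by the Viterbi decoder (\code{"O"} has index 1).
#'
#' @return Character vector of length 19.
#' @export
bio_labels <- function() {
  cls <- entity_classes()
  c("O", as.vector(rbind(paste0("B-", cls), paste0("I-", cls))))
}

#' Tokenize narrative text
#'
#' Splits on whitespace, then detaches leading/trailing punctuation
#' \code{. , ; : ! ? ( ) "} into their own tokens, and splits a slash
#' between two purely lowercase alphabetic words (\code{"and/or"}) while
#' keeping alphanumeric codes (\code{"NCI/CTC"}, \code{"T200"}) and
#' digits-with-units (\code{"0.9%"}, \code{"280"}) intact. Internal
#' punctuation of numbers is preserved.
#'
#' @param text Character scalar (UTF-8 narrative text).
#' @return A data.frame with columns \code{index} (0-based), \code{start},
#'   \code{end} (0-based, half-open character offsets) and \code{surface};
#'   zero rows for empty input.
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(index = integer(), start = integer(), end = integer(),
                      surface = character(), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)

  # locate whitespace-separated chunks with their character offsets
  m <- gregexpr("\\S+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m) - 1L            # to 0-based
  lens <- attr(m, "match.length")

  edge <- c(".", ",", ";", ":", "!", "?", "(", ")", "\"")
  out_start <- integer(0); out_end <- integer(0); out_surf <- character(0)
  emit <- function(s, e, surf) {
    out_start <<- c(out_start, s); out_end <<- c(out_end, e)
    out_surf <<- c(out_surf, surf)
  }
  split_core <- function(s, core) {
    # slash between two lowercase alphabetic words -> three tokens
    if (grepl("^[a-z]+/[a-z]+$", core)) {
      parts <- strsplit(core, "/", fixed = TRUE)[[1]]
      emit(s, s + nchar(parts[1]), parts[1])
      emit(s + nchar(parts[1]), s + nchar(parts[1]) + 1L, "/")
      emit(s + nchar(parts[1]) + 1L, s + nchar(core), parts[2])
    } else {
      emit(s, s + nchar(core), core)
    }
  }
  for (i in seq_along(starts)) {
    s <- starts[i]
    chunk <- substr(text, s + 1L, s + lens[i])
    # peel leading edge punctuation
    while (nchar(chunk) > 1L && substr(chunk, 1L, 1L) %in% edge) {
      emit(s, s + 1L, substr(chunk, 1L, 1L))
      s <- s + 1L
      chunk <- substr(chunk, 2L, nchar(chunk))
    }
    # peel trailing edge punctuation (collect, emit after core)
    trail <- character(0)
    while (nchar(chunk) > 1L && substr(chunk, nchar(chunk), nchar(chunk)) %in% edge) {
      trail <- c(substr(chunk, nchar(chunk), nchar(chunk)), trail)
      chunk <- substr(chunk, 1L, nchar(chunk) - 1L)
    }
    split_core(s, chunk)
    e <- s + nchar(chunk)
    for (p in trail) {
      emit(e, e + 1L, p)
      e <- e + 1L
    }
  }
  data.frame(index = seq_along(out_start) - 1L, start = out_start,
             end = out_end, surface = out_surf, stringsAsFactors = FALSE)
}

#' Construct a document
#'
#' @param doc_id Character identifier.
#' @param text Narrative text.
#' @return An object of class \code{aet_document}: a list with
#'   \code{doc_id}, \code{text} and the token table from [tokenize()].
#' @export
document <- function(doc_id, text) {
  toks <- tokenize(text)
  structure(list(doc_id = doc_id, text = text, tokens = toks),
            class = "aet_document")
}

#' @export
print.aet_document <- function(x, ...) {
  cat(sprintf("<aet_document %s: %d chars, %d tokens>\n",
              x$doc_id, nchar(x$text), nrow(x$tokens)))
  invisible(x)
}

#' Create an entity-mention table
#'
#' @param entity_class Character vector of class names (must be in
#'   [entity_classes()]).
#' @param start,end Integer character offsets (0-based, half-open).
#' @param surface Character vector of covered text.
#' @return A data.frame with those four columns, sorted by \code{start}.
#' @export
mentions <- function(entity_class = character(), start = integer(),
                     end = integer(), surface = character()) {
  bad <- setdiff(unique(entity_class), entity_classes())
  if (length(bad) > 0)
    stop("unknown entity class: ", paste(bad, collapse = ", "))
  df <- data.frame(entity_class = as.character(entity_class),
                   start = as.integer(start), end = as.integer(end),
                   surface = as.character(surface), stringsAsFactors = FALSE)
  df[order(df$start, df$end), , drop = FALSE]
}

#' Construct an annotation set
#'
#' Holds one annotator's (or system's) mentions over a corpus, keyed by
#' document id. Mentions of one annotator may not overlap within a
#' document.
#'
#' @param annotator_id Character, e.g. \code{"gold"}, \code{"system"}.
#' @param mention_list Named list (by doc_id) of mention data.frames.
#' @return An object of class \code{aet_annotations}.
#' @export
annotation_set <- function(annotator_id, mention_list = list()) {
  for (id in names(mention_list)) {
    m <- mention_list[[id]]
    if (nrow(m) > 1) {
      m <- m[order(m$start), , drop = FALSE]
      if (any(m$start[-1] < m$end[-nrow(m)]))
        stop("overlapping mentions in document ", id)
    }
    mention_list[[id]] <- m
  }
  structure(list(annotator_id = annotator_id, mentions = mention_list),
            class = "aet_annotations")
}

#' @export
print.aet_annotations <- function(x, ...) {
  n <- sum(vapply(x$mentions, nrow, integer(1)))
  cat(sprintf("<aet_annotations %s: %d mentions over %d documents>\n",
              x$annotator_id, n, length(x$mentions)))
  invisible(x)
}

# map a character span to a (first token, last token) pair, or error
.span_to_tokens <- function(doc, start, end, what = "mention") {
  toks <- doc$tokens
  first <- which(toks$start == start)
  last <- which(toks$end == end)
  if (length(first) != 1L || length(last) != 1L || first > last)
    stop(sprintf("%s span [%d,%d) in document %s does not align to token boundaries",
                 what, start, end, doc$doc_id))
  c(first, last)
}

#' Encode mentions as per-token BIO labels
#'
#' The first token of each mention receives \code{B-<class>}, following
#' tokens \code{I-<class>}, all remaining tokens \code{O}. Adjacent
#' same-class mentions stay distinct (\code{B} restarts).
#'
#' @param doc An [document()].
#' @param mention_df A mention data.frame ([mentions()]); must be
#'   non-overlapping and token-aligned.
#' @return Character vector of BIO labels, one per token.
#' @export
encode_bio <- function(doc, mention_df) {
  labels <- rep("O", nrow(doc$tokens))
  if (is.null(mention_df) || nrow(mention_df) == 0) return(labels)
  m <- mention_df[order(mention_df$start), , drop = FALSE]
  if (any(m$start[-1] < m$end[-nrow(m)]) && nrow(m) > 1)
    stop("overlapping mentions in document ", doc$doc_id)
  for (i in seq_len(nrow(m))) {
    rng <- .span_to_tokens(doc, m$start[i], m$end[i])
    labels[rng[1]] <- paste0("B-", m$entity_class[i])
    if (rng[2] > rng[1])
      labels[(rng[1] + 1):rng[2]] <- paste0("I-", m$entity_class[i])
  }
  labels
}

#' Decode per-token BIO labels to mentions
#'
#' Inverse of [encode_bio()] on valid sequences. An \code{I-X} whose
#' predecessor is neither \code{B-X} nor \code{I-X} is repaired to
#' \code{B-X} (tokens are kept, never dropped).
#'
#' @param doc An [document()].
#' @param labels Character vector of BIO labels, one per token.
#' @return A mention data.frame.
#' @export
decode_bio <- function(doc, labels) {
  ntok <- nrow(doc$tokens)
  if (length(labels) != ntok)
    stop(sprintf("label sequence length %d does not match %d tokens",
                 length(labels), ntok))
  bad <- setdiff(unique(labels), bio_labels())
  if (length(bad) > 0) stop("label outside alphabet: ", paste(bad, collapse = ", "))
  labels <- repair_bio(labels)
  out <- mentions()
  if (ntok == 0) return(out)
  cls <- character(0); s <- integer(0); e <- integer(0)
  cur <- NULL
  for (i in seq_len(ntok)) {
    lab <- labels[i]
    if (startsWith(lab, "B-")) {
      if (!is.null(cur)) { cls <- c(cls, cur$c); s <- c(s, cur$s); e <- c(e, cur$e) }
      cur <- list(c = substring(lab, 3), s = doc$tokens$start[i], e = doc$tokens$end[i])
    } else if (startsWith(lab, "I-")) {
      cur$e <- doc$tokens$end[i]       # repair guarantees cur exists, class matches
    } else {
      if (!is.null(cur)) { cls <- c(cls, cur$c); s <- c(s, cur$s); e <- c(e, cur$e) }
      cur <- NULL
    }
  }
  if (!is.null(cur)) { cls <- c(cls, cur$c); s <- c(s, cur$s); e <- c(e, cur$e) }
  if (length(s) == 0) return(mentions())
  mentions(cls, s, e, substring(doc$text, s + 1L, e))
}

#' Repair an invalid BIO sequence
#'
#' Rewrites any \code{I-X} whose left neighbour is not \code{B-X} or
#' \code{I-X} as \code{B-X}.
#'
#' @param labels Character vector of BIO labels.
#' @return Repaired label vector.
#' @export
repair_bio <- function(labels) {
  if (length(labels) == 0) return(labels)
  for (i in seq_along(labels)) {
    if (startsWith(labels[i], "I-")) {
      cls <- substring(labels[i], 3)
      prev <- if (i == 1L) "O" else labels[i - 1L]
      if (!(prev %in% c(paste0("B-", cls), paste0("I-", cls))))
        labels[i] <- paste0("B-", cls)
    }
  }
  labels
}

#' Read a standoff-annotated document
#'
#' Reads a narrative text file plus a BRAT-style \code{.ann} file whose
#' lines are \code{"T<n>\\t<Class> <start> <end>\\t<surface>"}.
#'
#' @param text_path Path to the UTF-8 text file.
#' @param ann_path Path to the standoff annotation file.
#' @param doc_id Document id; defaults to the text file's base name.
#' @return A list with elements \code{doc} ([document()]) and
#'   \code{mentions} (mention data.frame).
#' @export
read_standoff <- function(text_path, ann_path, doc_id = NULL) {
  if (is.null(doc_id))
    doc_id <- sub("\\.txt$", "", basename(text_path))
  text <- paste(readLines(text_path, encoding = "UTF-8", warn = FALSE),
                collapse = "\n")
  doc <- document(doc_id, text)
  lines <- readLines(ann_path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(list(doc = doc, mentions = mentions()))
  cls <- character(0); s <- integer(0); e <- integer(0); surf <- character(0)
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3 || !grepl("^T[0-9]+$", parts[1]))
      stop("malformed standoff line: ", ln)
    mid <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
    if (length(mid) != 3) stop("malformed standoff line: ", ln)
    if (!(mid[1] %in% entity_classes()))
      stop("unknown entity class in standoff file: ", mid[1])
    a <- as.integer(mid[2]); b <- as.integer(mid[3])
    if (is.na(a) || is.na(b) || a < 0 || b > nchar(text) || a >= b)
      stop("offset out of range in standoff line: ", ln)
    cov <- substring(text, a + 1L, b)
    if (cov != parts[3])
      stop(sprintf("surface mismatch in %s: annotation says %s, text has %s",
                   ann_path, parts[3], cov))
    cls <- c(cls, mid[1]); s <- c(s, a); e <- c(e, b); surf <- c(surf, cov)
  }
  list(doc = doc, mentions = mentions(cls, s, e, surf))
}

#' Write a document with standoff annotations
#'
#' @param doc An [document()].
#' @param mention_df Mention data.frame.
#' @param text_path,ann_path Output paths.
#' @return Invisibly, the annotation path.
#' @export
write_standoff <- function(doc, mention_df, text_path, ann_path) {
  writeLines(doc$text, text_path, useBytes = TRUE)
  lines <- character(0)
  if (nrow(mention_df) > 0)
    lines <- sprintf("T%d\t%s %d %d\t%s", seq_len(nrow(mention_df)),
                     mention_df$entity_class, mention_df$start,
                     mention_df$end, mention_df$surface)
  writeLines(lines, ann_path, useBytes = TRUE)
  invisible(ann_path)
}

#' Write a labelled corpus in CoNLL-style TSV
#'
#' One token per line: \code{surface \\t start \\t end \\t label}; a
#' \code{#doc <id>} header line starts each document and a blank line ends
#' it. Round-trips losslessly with [encode_bio()] output (document text is
#' reconstructed by joining surfaces with single spaces; character offsets
#' are preserved verbatim in the file).
#'
#' @param docs List of [document()]s.
#' @param labels_list List of BIO label vectors, parallel to \code{docs}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_conll <- function(docs, labels_list, path) {
  stopifnot(length(docs) == length(labels_list))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_along(docs)) {
    d <- docs[[i]]; lab <- labels_list[[i]]
    stopifnot(length(lab) == nrow(d$tokens))
    writeLines(paste0("#doc ", d$doc_id), con)
    if (nrow(d$tokens) > 0)
      writeLines(sprintf("%s\t%d\t%d\t%s", d$tokens$surface,
                         d$tokens$start, d$tokens$end, lab), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a CoNLL-style TSV corpus
#'
#' @param path Path written by [write_conll()].
#' @return A list with \code{tokens} (named list of token data.frames) and
#'   \code{labels} (named list of BIO label vectors).
#' @export
read_conll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  tokens <- list(); labels <- list()
  cur_id <- NULL; surf <- character(0); s <- integer(0); e <- integer(0)
  lab <- character(0)
  flush_doc <- function() {
    if (is.null(cur_id)) return()
    tokens[[cur_id]] <<- data.frame(index = seq_along(surf) - 1L, start = s,
                                    end = e, surface = surf,
                                    stringsAsFactors = FALSE)
    labels[[cur_id]] <<- lab
  }
  alphabet <- bio_labels()
  for (ln in lines) {
    if (startsWith(ln, "#doc ")) {
      flush_doc()
      cur_id <- substring(ln, 6)
      surf <- character(0); s <- integer(0); e <- integer(0); lab <- character(0)
    } else if (!nzchar(ln)) {
      next
    } else {
      if (is.null(cur_id)) stop("token line before #doc header: ", ln)
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) != 4) stop("malformed CoNLL line: ", ln)
      if (!(parts[4] %in% alphabet)) stop("label outside alphabet: ", parts[4])
      a <- as.integer(parts[2]); b <- as.integer(parts[3])
      if (is.na(a) || is.na(b) || a >= b) stop("malformed CoNLL line: ", ln)
      surf <- c(surf, parts[1]); s <- c(s, a); e <- c(e, b)
      lab <- c(lab, parts[4])
    }
  }
  flush_doc()
  list(tokens = tokens, labels = labels)
}
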