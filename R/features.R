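## Per-token feature extraction: seven independently switchable families.
## Every feature is an indicator string "family:name=value"; a family
## contributes nothing when disabled, so ablation runs are exact set
## differences.

#' Feature configuration
#'
#' @param families Character vector of enabled families, a subset of
#'   \code{c("default", "affix", "connective", "morphological",
#'   "neghedge", "semantic", "syntactic")}. \code{"default"} (bag of
#'   words + word shape + context window) is the base family every
#'   tagger uses.
#' @param window Context half-width for the default family (tokens on
#'   each side whose identity/shape are added with positional prefixes).
#' @return An object of class \code{aet_feature_config}.
#' @export
feature_config <- function(families = "default", window = 1L) {
  all_fam <- c("default", "affix", "connective", "morphological",
               "neghedge", "semantic", "syntactic")
  bad <- setdiff(families, all_fam)
  if (length(bad) > 0) stop("unknown feature family: ", paste(bad, collapse = ", "))
  families <- union("default", families)
  structure(list(families = sort(families), window = as.integer(window)),
            class = "aet_feature_config")
}

#' All-families feature configuration
#' @param window Context half-width, as in [feature_config()].
#' @return An \code{aet_feature_config} with every family enabled.
#' @export
all_features_config <- function(window = 1L) {
  feature_config(c("default", "affix", "connective", "morphological",
                   "neghedge", "semantic", "syntactic"), window)
}

# word shape: A->X, a->x, 0->d, everything else kept
.word_shape <- function(w) {
  s <- gsub("[A-Z]", "X", w)
  s <- gsub("[a-z]", "x", s)
  gsub("[0-9]", "d", s)
}

#' Morphological features of a single token surface
#'
#' Character-pattern indicators: all-digit, capitalized, all-caps,
#' alphanumeric order (letters-then-digits, digits-then-letters, or mixed
#' for other letter/digit combinations), hyphen, comma, pure punctuation.
#'
#' @param surface Token surface string.
#' @return Character vector of \code{morph:*} features.
#' @export
morphological_features <- function(surface) {
  f <- character(0)
  if (grepl("^[0-9][0-9.,]*%?$", surface)) f <- c(f, "morph:is_digit")
  if (grepl("^[A-Z]", surface)) f <- c(f, "morph:is_capitalized")
  if (grepl("[A-Z]", surface) && !grepl("[a-z]", surface) &&
      grepl("^[A-Z][A-Z0-9-]*$", surface)) f <- c(f, "morph:all_caps")
  if (grepl("^[A-Za-z]+[0-9]+$", surface)) f <- c(f, "morph:alnum=letters_digits")
  else if (grepl("^[0-9]+[A-Za-z]+$", surface)) f <- c(f, "morph:alnum=digits_letters")
  else if (grepl("[0-9]", surface) && grepl("[A-Za-z]", surface))
    f <- c(f, "morph:alnum=mixed")
  if (grepl("-", surface, fixed = TRUE)) f <- c(f, "morph:has_hyphen")
  if (grepl(",", surface, fixed = TRUE)) f <- c(f, "morph:has_comma")
  if (grepl("^[[:punct:]]+$", surface)) f <- c(f, "morph:is_punct")
  f
}

#' Affix features of a single token surface
#'
#' Lowercased 3- and 4-character prefixes and suffixes; shorter tokens
#' contribute the whole token for the affected slots.
#'
#' @param surface Token surface string.
#' @return Character vector of four \code{affix:*} features.
#' @export
affix_features <- function(surface) {
  w <- tolower(surface)
  n <- nchar(w)
  c(paste0("affix:pre3=", substr(w, 1, min(3, n))),
    paste0("affix:pre4=", substr(w, 1, min(4, n))),
    paste0("affix:suf3=", substr(w, max(1, n - 2), n)),
    paste0("affix:suf4=", substr(w, max(1, n - 3), n)))
}

#' Syntactic features for a document
#'
#' POS tag, coarse phrasal class, and the POS of the token immediately to
#' the left (\code{NONE} at sentence starts), from a pluggable annotator
#' (see [rule_pos_annotator()]).
#'
#' @param doc An [document()].
#' @param pos_annotator Function mapping a document to per-token
#'   \code{pos} and \code{phrase} vectors.
#' @return List of character vectors, one per token.
#' @export
syntactic_features <- function(doc, pos_annotator) {
  n <- nrow(doc$tokens)
  ann <- pos_annotator(doc)
  if (length(ann$pos) != n || length(ann$phrase) != n)
    stop("POS annotator output length does not match token count")
  sent <- sentence_ids(doc$tokens)
  lapply(seq_len(n), function(i) {
    left <- if (i == 1L || sent[i] != sent[i - 1L]) "NONE" else ann$pos[i - 1L]
    c(paste0("pos:pos=", ann$pos[i]),
      paste0("pos:phrase=", ann$phrase[i]),
      paste0("pos:left_pos=", left))
  })
}

#' Semantic (dictionary) features for a document
#'
#' Tokens covered by a greedy longest lexicon match carry the matched
#' semantic type code and their position (\code{B} first token, \code{I}
#' later tokens) within the match.
#'
#' @param doc An [document()].
#' @param lexicon An [load_lexicon()] object.
#' @return List of character vectors, one per token.
#' @export
semantic_features <- function(doc, lexicon) {
  n <- nrow(doc$tokens)
  out <- rep(list(character(0)), n)
  m <- longest_match(doc$tokens, lexicon)
  for (i in seq_len(nrow(m))) {
    idx <- m$first[i]:m$last[i]
    for (k in seq_along(idx)) {
      out[[idx[k]]] <- c(paste0("sem:type=", m$type[i]),
                         paste0("sem:match_position=", if (k == 1L) "B" else "I"))
    }
  }
  out
}

# forward scope from each cue occurrence to the first terminator,
# sentence end, or `cap` tokens, whichever comes first
.cue_scope_features <- function(doc, cues, prefix, cap = 6L) {
  n <- nrow(doc$tokens)
  out <- rep(list(character(0)), n)
  if (n == 0) return(out)
  hits <- match_cues(doc$tokens, cues)
  if (nrow(hits) == 0) return(out)
  sent <- sentence_ids(doc$tokens)
  low <- tolower(doc$tokens$surface)
  for (i in seq_len(nrow(hits))) {
    for (t in hits$first[i]:hits$last[i])
      out[[t]] <- union(out[[t]], paste0(prefix, ":cue"))
    j <- hits$last[i] + 1L
    taken <- 0L
    while (j <= n && taken < cap && sent[j] == sent[hits$last[i]]) {
      if (low[j] %in% cues$terminators) break
      out[[j]] <- union(out[[j]], paste0(prefix, ":in_scope"))
      j <- j + 1L; taken <- taken + 1L
    }
  }
  out
}

#' Negation and hedge cue/scope features
#'
#' Cue tokens carry \code{neg:cue} / \code{hedge:cue}; tokens in the
#' cue's forward scope (until a terminator, the sentence end, or the
#' scope cap of 6 tokens) carry \code{neg:in_scope} / \code{hedge:in_scope}.
#'
#' @param doc An [document()].
#' @param negation,hedge [load_cues()] objects.
#' @param cap Scope cap in tokens.
#' @return List of character vectors, one per token.
#' @export
neghedge_features <- function(doc, negation, hedge, cap = 6L) {
  a <- .cue_scope_features(doc, negation, "neg", cap)
  b <- .cue_scope_features(doc, hedge, "hedge", cap)
  mapply(c, a, b, SIMPLIFY = FALSE)
}

#' Discourse-connective features
#'
#' The first token of each connective match carries
#' \code{conn:cue=<cue_with_underscores>}; every token of a sentence
#' containing a connective carries \code{conn:present}.
#'
#' @param doc An [document()].
#' @param connectives A [load_cues()] object.
#' @return List of character vectors, one per token.
#' @export
connective_features <- function(doc, connectives) {
  n <- nrow(doc$tokens)
  out <- rep(list(character(0)), n)
  if (n == 0) return(out)
  hits <- match_cues(doc$tokens, connectives)
  if (nrow(hits) == 0) return(out)
  sent <- sentence_ids(doc$tokens)
  for (i in seq_len(nrow(hits))) {
    t <- hits$first[i]
    out[[t]] <- c(out[[t]], paste0("conn:cue=", gsub(" ", "_", hits$cue[i])))
  }
  marked <- unique(sent[hits$first])
  for (t in which(sent %in% marked))
    out[[t]] <- union(out[[t]], "conn:present")
  out
}

#' Default (bag-of-words and orthographic) features
#'
#' Lowercased word identity and word shape for the token itself and for
#' neighbours inside the context window, with positional prefixes
#' (\code{w[-1]=}, \code{w[+1]=}, ...); the window truncates at document
#' boundaries.
#'
#' @param doc An [document()].
#' @param window Context half-width.
#' @return List of character vectors, one per token.
#' @export
default_features <- function(doc, window = 1L) {
  n <- nrow(doc$tokens)
  low <- tolower(doc$tokens$surface)
  shape <- vapply(doc$tokens$surface, .word_shape, "", USE.NAMES = FALSE)
  lapply(seq_len(n), function(i) {
    f <- c(paste0("default:w=", low[i]), paste0("default:shape=", shape[i]))
    if (window > 0L) for (d in seq_len(window)) {
      if (i - d >= 1L)
        f <- c(f, sprintf("default:w[-%d]=%s", d, low[i - d]),
               sprintf("default:shape[-%d]=%s", d, shape[i - d]))
      if (i + d <= n)
        f <- c(f, sprintf("default:w[+%d]=%s", d, low[i + d]),
               sprintf("default:shape[+%d]=%s", d, shape[i + d]))
    }
    f
  })
}

#' Extract per-token feature sets
#'
#' Union of the enabled families, each feature a deterministic indicator
#' string. Feature vectors are sorted, duplicate-free character vectors.
#'
#' @param doc An [document()].
#' @param config An [feature_config()].
#' @param resources Resource list as from [default_resources()]; only the
#'   components needed by enabled families are required.
#' @return List of sorted character vectors, one per token.
#' @export
extract_features <- function(doc, config = feature_config(),
                             resources = NULL) {
  n <- nrow(doc$tokens)
  fam <- config$families
  need <- function(x, what) {
    if (is.null(x)) stop("feature family enabled but resource missing: ", what)
    x
  }
  sets <- rep(list(character(0)), n)
  add <- function(lst) sets <<- mapply(c, sets, lst, SIMPLIFY = FALSE)
  if ("default" %in% fam) add(default_features(doc, config$window))
  if ("affix" %in% fam)
    add(lapply(doc$tokens$surface, affix_features))
  if ("morphological" %in% fam)
    add(lapply(doc$tokens$surface, morphological_features))
  if ("syntactic" %in% fam)
    add(syntactic_features(doc, need(resources$pos_annotator, "pos_annotator")))
  if ("semantic" %in% fam)
    add(semantic_features(doc, need(resources$lexicon, "lexicon")))
  if ("neghedge" %in% fam)
    add(neghedge_features(doc, need(resources$negation, "negation cues"),
                          need(resources$hedge, "hedge cues")))
  if ("connective" %in% fam)
    add(connective_features(doc, need(resources$connective, "connective cues")))
  lapply(sets, function(f) sort(unique(f)))
}
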