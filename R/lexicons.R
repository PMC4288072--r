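## File-backed term resources: a semantic lexicon with UMLS-style type
## codes (T200 = clinical drug -> Medication, T047 = disease or symptom ->
## AdverseEvent) and cue lists for negation, hedging and discourse
## connectives.

#' Load a semantic lexicon
#'
#' Reads a TSV of \code{term \\t type-code [\\t entity-class]}. Lookup is
#' case-insensitive; duplicate terms are resolved last-wins with a
#' warning. The type-to-class map always contains \code{T200 ->
#' Medication} and \code{T047 -> AdverseEvent}; a third column adds or
#' overrides mappings for other codes.
#'
#' @param path Path to the lexicon TSV.
#' @return An object of class \code{aet_lexicon}: list with
#'   \code{entries} (named character vector, lowercase term -> type code),
#'   \code{type_to_class} (named character vector) and \code{max_len}
#'   (longest entry in tokens).
#' @export
load_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty lexicon file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2)) stop("malformed lexicon row: ", lines[which(nf < 2)[1]])
  terms <- tolower(vapply(parts, `[`, "", 1L))
  if (any(!nzchar(terms))) stop("empty term in lexicon: ", path)
  codes <- vapply(parts, `[`, "", 2L)
  if (anyDuplicated(terms)) {
    warning("duplicate lexicon terms resolved last-wins: ",
            paste(unique(terms[duplicated(terms)]), collapse = ", "))
  }
  entries <- setNames(codes, terms)
  entries <- entries[!duplicated(names(entries), fromLast = TRUE)]
  type_to_class <- c(T200 = "Medication", T047 = "AdverseEvent")
  has_cls <- nf >= 3
  if (any(has_cls)) {
    cls <- vapply(parts[has_cls], `[`, "", 3L)
    bad <- setdiff(unique(cls), entity_classes())
    if (length(bad) > 0) stop("unknown entity class in lexicon: ", bad[1])
    extra <- setNames(cls, codes[has_cls])
    extra <- extra[!duplicated(names(extra), fromLast = TRUE)]
    type_to_class[names(extra)] <- extra
  }
  max_len <- max(lengths(strsplit(names(entries), " ", fixed = TRUE)))
  structure(list(entries = entries, type_to_class = type_to_class,
                 max_len = max_len),
            class = "aet_lexicon")
}

#' @export
print.aet_lexicon <- function(x, ...) {
  cat(sprintf("<aet_lexicon: %d terms, max %d tokens, %d type codes>\n",
              length(x$entries), x$max_len, length(unique(x$entries))))
  invisible(x)
}

#' Load a cue list
#'
#' One cue (possibly multi-word) per line; lines after a
#' \code{##terminators} marker are scope terminators (negation/hedge cue
#' lists only).
#'
#' @param path Path to the cue file.
#' @param kind One of \code{"negation"}, \code{"hedge"},
#'   \code{"connective"}.
#' @return An object of class \code{aet_cues}: list with \code{kind},
#'   \code{cues} and \code{terminators} (lowercase character vectors).
#' @export
load_cues <- function(path, kind = c("negation", "hedge", "connective")) {
  kind <- match.arg(kind)
  lines <- tolower(trimws(readLines(path, encoding = "UTF-8", warn = FALSE)))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") | lines == "##terminators"]
  term_at <- match("##terminators", lines)
  if (is.na(term_at)) {
    cues <- lines; terms <- character(0)
  } else {
    cues <- lines[seq_len(term_at - 1L)]
    terms <- lines[-seq_len(term_at)]
  }
  if (length(intersect(cues, terms)) > 0)
    stop("cue list and terminator list overlap in ", path)
  structure(list(kind = kind, cues = unique(cues),
                 terminators = unique(terms)),
            class = "aet_cues")
}

# path to a bundled resource file
aet_resource <- function(name) {
  p <- system.file("extdata", name, package = "aetagger")
  if (!nzchar(p)) stop("bundled resource not found: ", name)
  p
}

#' Load the bundled default resources
#'
#' Convenience loader for the packaged drug/adverse-event lexicon, cue
#' lists, and POS annotator. All components can be replaced by the
#' corresponding \code{load_*} functions on user files.
#'
#' @return A list with \code{lexicon}, \code{negation}, \code{hedge},
#'   \code{connective} and \code{pos_annotator}.
#' @export
default_resources <- function() {
  list(lexicon = load_lexicon(aet_resource("lexicon.tsv")),
       negation = load_cues(aet_resource("cues_negation.txt"), "negation"),
       hedge = load_cues(aet_resource("cues_hedge.txt"), "hedge"),
       connective = load_cues(aet_resource("cues_connective.txt"), "connective"),
       pos_annotator = rule_pos_annotator())
}

#' Greedy longest-match dictionary lookup
#'
#' Scans tokens left to right; at each position takes the longest
#' case-insensitive lexicon entry starting there (up to the lexicon's
#' longest entry), then continues after the match, so output spans never
#' overlap.
#'
#' @param tokens Token data.frame from [tokenize()].
#' @param lexicon An [load_lexicon()] object.
#' @return A data.frame with \code{first}, \code{last} (1-based token row
#'   indices), \code{start}, \code{end} (character offsets), \code{term}
#'   (matched lexicon key) and \code{type} (semantic type code).
#' @export
longest_match <- function(tokens, lexicon) {
  n <- nrow(tokens)
  out <- data.frame(first = integer(), last = integer(), start = integer(),
                    end = integer(), term = character(), type = character(),
                    stringsAsFactors = FALSE)
  if (n == 0) return(out)
  low <- tolower(tokens$surface)
  i <- 1L
  while (i <= n) {
    hit_len <- 0L; hit_term <- NULL
    for (len in seq_len(min(lexicon$max_len, n - i + 1L))) {
      key <- paste(low[i:(i + len - 1L)], collapse = " ")
      if (!is.na(lexicon$entries[key])) { hit_len <- len; hit_term <- key }
    }
    if (hit_len > 0L) {
      j <- i + hit_len - 1L
      out <- rbind(out, data.frame(first = i, last = j,
                                   start = tokens$start[i], end = tokens$end[j],
                                   term = hit_term,
                                   type = unname(lexicon$entries[hit_term]),
                                   stringsAsFactors = FALSE))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Find multi-word cue occurrences
#'
#' Same greedy longest-match scan as [longest_match()], over a cue list.
#'
#' @param tokens Token data.frame.
#' @param cues An [load_cues()] object.
#' @return Data.frame with \code{first}, \code{last}, \code{cue}.
#' @export
match_cues <- function(tokens, cues) {
  if (length(cues$cues) == 0 || nrow(tokens) == 0)
    return(data.frame(first = integer(), last = integer(), cue = character(),
                      stringsAsFactors = FALSE))
  lex <- structure(list(entries = setNames(rep("CUE", length(cues$cues)), cues$cues),
                        type_to_class = character(0),
                        max_len = max(lengths(strsplit(cues$cues, " ")))),
                   class = "aet_lexicon")
  m <- longest_match(tokens, lex)
  data.frame(first = m$first, last = m$last, cue = m$term,
             stringsAsFactors = FALSE)
}
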