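## Lightweight rule-and-lexicon part-of-speech / chunk annotation.
## Any object satisfying the same contract (a function taking a document
## and returning per-token `pos` and `phrase` vectors) can be plugged in
## where syntactic features are extracted.

# closed-class word lists
.POS_DT <- c("a", "an", "the", "this", "that", "these", "those", "each",
             "every", "no", "any", "some", "all", "both")
.POS_IN <- c("of", "in", "on", "at", "by", "for", "with", "without", "to",
             "from", "after", "before", "during", "due", "per", "into",
             "under", "over", "since", "until", "because", "as", "than")
.POS_CC <- c("and", "or", "but", "nor")
.POS_PRP <- c("he", "she", "it", "they", "him", "her", "them", "his", "its",
              "their", "patient's")
.POS_MD <- c("may", "might", "could", "can", "should", "would", "will",
             "must", "shall")
.POS_VB <- c("is", "was", "were", "are", "be", "been", "being", "has",
             "had", "have", "received", "developed", "experienced",
             "reported", "administered", "given", "treated", "noted",
             "occurred", "appeared", "recovered", "continued", "initiated",
             "discontinued", "hospitalized", "admitted", "died", "expired",
             "resolved", "started", "stopped", "prescribed", "considered",
             "managed", "scheduled", "included", "presented", "denies")
.POS_RB <- c("not", "never", "subsequently", "however", "therefore",
             "possibly", "approximately", "previously", "later",
             "initially", "prior", "also")
.POS_JJ <- c("female", "male", "severe", "mild", "moderate", "acute",
             "chronic", "serious", "intravenous", "oral", "subcutaneous",
             "normal", "abnormal", "elevated", "decreased", "increased",
             "recurrent", "transient", "progressive", "daily", "unknown",
             "concomitant", "several", "first", "second", "third",
             "life", "threatening", "unresponsive", "unlikely", "presumed",
             "suspected", "probable", "likely", "questionable")

#' Rule-based part-of-speech and chunk annotator
#'
#' A deterministic tagger built from closed-class word lists plus suffix
#' heuristics (\code{-ed} past verb, \code{-ing} gerund, \code{-ly}
#' adverb, digits \code{CD}, default noun), followed by a base
#' noun-phrase chunk rule (optional determiner, any adjectives, one or
#' more nouns) and a verb-phrase rule (runs of verbs/modals). It stands
#' in for a full constituency parser: the tagger only has to supply a POS
#' tag and a coarse phrasal class (\code{NP}/\code{VP}/\code{O}) per
#' token.
#'
#' @return A function of one argument (an [document()]) returning a list
#'   with character vectors \code{pos} and \code{phrase}, one element per
#'   token.
#' @export
rule_pos_annotator <- function() {
  function(doc) {
    toks <- doc$tokens$surface
    n <- length(toks)
    if (n == 0) return(list(pos = character(0), phrase = character(0)))
    low <- tolower(toks)
    pos <- character(n)
    for (i in seq_len(n)) {
      w <- low[i]
      pos[i] <-
        if (grepl("^[[:punct:]]+$", toks[i])) "PUNCT"
        else if (grepl("^[0-9][0-9.,%/]*$", w)) "CD"
        else if (w %in% .POS_DT) "DT"
        else if (w %in% .POS_MD) "MD"
        else if (w %in% .POS_VB) {
          if (grepl("ing$", w)) "VBG" else if (grepl("ed$", w)) "VBD" else "VB"
        }
        else if (w %in% .POS_IN) "IN"
        else if (w %in% .POS_CC) "CC"
        else if (w %in% .POS_PRP) "PRP"
        else if (w %in% .POS_RB || grepl("ly$", w)) "RB"
        else if (w %in% .POS_JJ ||
                 grepl("(ous|ive|al|ic|ary|ful|less)$", w)) "JJ"
        else if (grepl("ing$", w) && nchar(w) > 4) "VBG"
        else "NN"
    }
    # base chunks: NP = DT? JJ* NN+ (CD allowed inside), VP = (MD|VB*)+
    phrase <- rep("O", n)
    i <- 1L
    while (i <= n) {
      if (pos[i] %in% c("VB", "VBD", "VBG", "MD")) {
        j <- i
        while (j < n && pos[j + 1L] %in% c("VB", "VBD", "VBG", "MD")) j <- j + 1L
        phrase[i:j] <- "VP"
        i <- j + 1L
      } else if (pos[i] %in% c("DT", "JJ", "NN", "CD", "PRP")) {
        j <- i
        while (j < n && pos[j + 1L] %in% c("JJ", "NN", "CD")) j <- j + 1L
        if (any(pos[i:j] %in% c("NN", "PRP", "CD"))) phrase[i:j] <- "NP"
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
    list(pos = pos, phrase = phrase)
  }
}

#' Sentence segmentation over a token table
#'
#' Sentences end at \code{.}, \code{!} or \code{?} tokens.
#'
#' @param tokens Token data.frame.
#' @return Integer vector of 1-based sentence ids, one per token.
#' @export
sentence_ids <- function(tokens) {
  n <- nrow(tokens)
  if (n == 0) return(integer(0))
  ends <- tokens$surface %in% c(".", "!", "?")
  c(1L, 1L + cumsum(ends))[seq_len(n)]
}
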