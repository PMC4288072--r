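## Synthetic spontaneous-report narrative generator with gold annotations,
## and a perturbation model that simulates a second annotator whose
## disagreements follow the boundary / missed / category taxonomy.

# modifier pools used to build unique ("singleton") mention surfaces
.DECOR <- list(
  AdverseEvent = c("grade 1", "grade 2", "grade 3", "grade 4", "severe",
                   "mild", "moderate", "acute", "recurrent", "transient",
                   "progressive", "worsening", "life threatening",
                   "persistent", "intermittent", "marked"),
  Indication = c("advanced", "metastatic", "early stage", "refractory",
                 "relapsed", "newly diagnosed", "stage ii", "stage iii",
                 "recently confirmed", "longstanding"),
  OSSD = c("mild", "chronic", "longstanding", "intermittent", "borderline",
           "known", "stable", "untreated"),
  Treatment = c("urgent", "repeated", "prolonged", "supportive", "empirical",
                "immediate", "elective"),
  Route = c("slow", "rapid", "continuous", "short", "brief", "peripheral",
            "central", "direct"),
  Frequency = c("approximately", "strictly", "initially", "nominally",
                "usually", "typically"),
  Duration = c("approximately", "nearly", "almost", "about", "roughly",
               "over"))

# carrier sentences: filler words around a single mention slot; filler
# vocabulary is kept disjoint from the bundled lexicon so dictionary
# matches occur only inside gold mentions
.CARRIERS <- list(
  Medication = list(
    c("The patient received", "@", "during the study period"),
    c("Therapy with", "@", "was initiated at baseline"),
    c("Treatment with", "@", "was discontinued on the same day"),
    c("She was maintained on", "@", "throughout the admission"),
    c("Concomitant therapy included", "@", "at that time")),
  Dosage = list(
    c("A dose of", "@", "was administered each cycle"),
    c("The dose was increased to", "@", "thereafter"),
    c("He received", "@", "in a single administration")),
  Route = list(
    c("The drug was given by", "@", "administration"),
    c("Study therapy was delivered via the", "@", "route"),
    c("Administration was switched to the", "@", "route later")),
  Frequency = list(
    c("Dosing was scheduled", "@", "throughout therapy"),
    c("The regimen was continued", "@", "as planned"),
    c("Doses were taken", "@", "at home")),
  Duration = list(
    c("Therapy continued for", "@", "before onset of symptoms"),
    c("The infusion lasted", "@", "in total"),
    c("Treatment was planned for", "@", "from the start")),
  Indication = list(
    c("Therapy was prescribed for", "@", "at enrollment"),
    c("The patient was enrolled in a study of", "@", "at that center"),
    c("Medication was indicated for", "@", "according to the report")),
  AdverseEvent = list(
    c("The patient developed", "@", "shortly after the first administration"),
    c("She subsequently experienced", "@", "and was hospitalized"),
    c("The reporter described", "@", "as related to study therapy"),
    c("Following the second cycle the patient presented with", "@", ""),
    c("The event of", "@", "was considered serious by the investigator")),
  OSSD = list(
    c("Medical history included", "@", "noted previously"),
    c("Baseline examination revealed", "@", "before dosing"),
    c("The report also mentioned", "@", "unrelated to therapy")),
  Treatment = list(
    c("The event was managed with", "@", "in hospital"),
    c("The patient required", "@", "for recovery"),
    c("Management consisted of", "@", "until discharge")))

.FILLERS <- c(
  "The reporting physician considered the event serious",
  "The outcome was reported as recovered at the time of writing",
  "No further information was available from the sender",
  "Follow up information has been requested from the reporter",
  "The case was received from a consumer via the local authority",
  "Causality assessment was not provided in the initial report",
  "The batch number of the suspect product was unknown",
  "The investigator assessed the case as medically significant")

#' Generator configuration
#'
#' Defaults reproduce the study conditions the generator emulates: 122
#' documents averaging 190.2 words (SD 130.3) with per-class mention
#' frequencies proportional to the reference corpus mix (adverse events
#' most frequent, then medications; frequency and duration rare).
#'
#' @param n_docs Number of narratives.
#' @param seed Integer RNG seed.
#' @param words_mean,words_sd Mean/SD of words per narrative (truncated
#'   normal, minimum 30).
#' @param class_weights Named positive weights over [entity_classes()].
#' @param singleton_rate Probability that a mention receives a surface
#'   form unique in the corpus (data sparseness).
#' @param punct_noise Probability that a sentence-final mention absorbs
#'   the trailing period (punctuation-attachment inconsistency).
#' @param filler_rate Proportion of sentences carrying no entity.
#' @return An object of class \code{aet_generator_config}.
#' @export
generator_config <- function(n_docs = 122L, seed = 0L,
                             words_mean = 190.2, words_sd = 130.3,
                             class_weights = c(AdverseEvent = 1646,
                                               Medication = 1152,
                                               Dosage = 137, Route = 107,
                                               Indication = 126, OSSD = 90,
                                               Treatment = 62, Duration = 24,
                                               Frequency = 21),
                             singleton_rate = 0.15, punct_noise = 0.05,
                             filler_rate = 0.15) {
  stopifnot(n_docs >= 1, all(class_weights > 0),
            setequal(names(class_weights), entity_classes()),
            singleton_rate >= 0, singleton_rate <= 1,
            punct_noise >= 0, punct_noise <= 1,
            filler_rate >= 0, filler_rate < 1)
  structure(list(n_docs = as.integer(n_docs), seed = as.integer(seed),
                 words_mean = words_mean, words_sd = words_sd,
                 class_weights = class_weights[entity_classes()],
                 singleton_rate = singleton_rate, punct_noise = punct_noise,
                 filler_rate = filler_rate),
            class = "aet_generator_config")
}

# load the bundled per-class surface pools; Medication/AdverseEvent come
# from the semantic lexicon, Dosage is pattern-generated
.load_pools <- function(lexicon) {
  tab <- read.delim(aet_resource("surface_pools.tsv"), header = FALSE,
                    col.names = c("cls", "surface"),
                    stringsAsFactors = FALSE)
  pools <- split(tab$surface, tab$cls)
  pools$Medication <- names(lexicon$entries)[lexicon$entries == "T200"]
  pools$AdverseEvent <- names(lexicon$entries)[lexicon$entries == "T047"]
  pools
}

.dosage_surface <- function() {
  unit <- sample(c("mg", "g", "mcg", "ml", "units"), 1)
  num <- sample(c(as.character(sample(5:950, 1)),
                  sprintf("%.1f", runif(1, 0.1, 99))), 1)
  paste(num, unit)
}

#' Generate a synthetic annotated corpus
#'
#' Narratives are assembled sentence by sentence from class-specific
#' carrier templates (each carrying one mention) plus entity-free filler
#' sentences, until the document's sampled word budget is reached. Every
#' mention is recorded in a generation ledger with its lexicon
#' provenance: the base term, the character span of that base term
#' inside the mention (\code{core_start}/\code{core_end}), whether the
#' surface was decorated to be a corpus-unique singleton, and whether
#' punctuation-attachment noise extended the span over the sentence
#' period.
#'
#' @param config An [generator_config()].
#' @param resources Resource list; the semantic lexicon supplies the
#'   medication and adverse-event surface pools.
#' @return List with \code{docs} (named list of [document()]s),
#'   \code{gold} (an [annotation_set()]) and \code{ledger} (data.frame).
#' @export
generate_corpus <- function(config = generator_config(),
                            resources = default_resources()) {
  set.seed(config$seed)
  pools <- .load_pools(resources$lexicon)
  lex_keys <- names(resources$lexicon$entries)
  used_surfaces <- new.env(parent = emptyenv())
  mark_used <- function(s) assign(tolower(s), TRUE, envir = used_surfaces)
  is_used <- function(s) !is.null(used_surfaces[[tolower(s)]])

  draw_surface <- function(cl) {
    singleton <- runif(1) < config$singleton_rate
    if (cl == "Dosage") {
      for (i in 1:200) {
        s <- .dosage_surface()
        if (!singleton || !is_used(s))
          return(list(surface = s, base = NA_character_, off = 0L,
                      singleton = singleton))
      }
      stop("could not draw a fresh dosage surface")
    }
    pool <- pools[[cl]]
    # undecorated classes reserve the tail of the pool for singleton
    # draws so that flagged singletons are truly corpus-unique
    head_n <- if (cl %in% names(.DECOR)) length(pool)
              else max(1L, floor(0.6 * length(pool)))
    if (!singleton) {
      s <- sample(pool[seq_len(head_n)], 1)
      return(list(surface = s, base = tolower(s), off = 0L, singleton = FALSE))
    }
    if (cl %in% names(.DECOR)) {
      for (i in 1:500) {
        mod <- sample(.DECOR[[cl]], 1)
        base <- sample(pool, 1)
        s <- paste(mod, base)
        if (!is_used(s))
          return(list(surface = s, base = tolower(base),
                      off = nchar(mod) + 1L, singleton = TRUE))
      }
      stop("insufficient surface pool for requested singleton rate (", cl, ")")
    }
    tail_pool <- if (head_n < length(pool)) pool[(head_n + 1L):length(pool)]
                 else pool
    fresh <- tail_pool[!vapply(tail_pool, is_used, logical(1))]
    if (length(fresh) == 0)
      stop("insufficient surface pool for requested singleton rate (", cl, ")")
    s <- sample(fresh, 1)
    list(surface = s, base = tolower(s), off = 0L, singleton = TRUE)
  }

  classes <- entity_classes()
  wts <- config$class_weights / sum(config$class_weights)
  docs <- list(); gold <- list()
  led <- list()
  for (d in seq_len(config$n_docs)) {
    doc_id <- sprintf("doc%03d", d)
    target <- max(30, round(rnorm(1, config$words_mean, config$words_sd)))
    words <- 0L
    text <- ""
    ms <- mentions()
    while (words < target) {
      if (runif(1) < config$filler_rate) {
        sent <- sample(.FILLERS, 1)
        sent_txt <- paste0(sent, ".")
        nref <- NULL
      } else {
        cl <- sample(classes, 1, prob = wts)
        tpl <- .CARRIERS[[cl]][[sample(length(.CARRIERS[[cl]]), 1)]]
        sv <- draw_surface(cl)
        mark_used(sv$surface)
        pre <- tpl[1]; post <- tpl[3]
        base_off <- nchar(text) + if (nzchar(text)) 1L else 0L
        m_start <- base_off + nchar(pre) + 1L
        m_end <- m_start + nchar(sv$surface)
        body <- if (nzchar(post)) paste(pre, sv$surface, post)
                else paste(pre, sv$surface)
        punct_attached <- FALSE
        if (!nzchar(post) && runif(1) < config$punct_noise) {
          m_end <- m_end + 1L           # absorb the sentence period
          punct_attached <- TRUE
        }
        sent_txt <- paste0(body, ".")
        nref <- list(cls = cl, start = m_start, end = m_end,
                     base = sv$base, off = sv$off, singleton = sv$singleton,
                     punct = punct_attached)
      }
      text <- if (nzchar(text)) paste(text, sent_txt) else sent_txt
      words <- words + length(strsplit(sent_txt, " ", fixed = TRUE)[[1]])
      if (!is.null(nref)) {
        surf <- substring(text, nref$start + 1L, nref$end)
        core_start <- if (is.na(nref$base)) NA_integer_
                      else nref$start + nref$off
        core_end <- if (is.na(nref$base)) NA_integer_
                    else core_start + nchar(nref$base)
        ms <- rbind(ms, mentions(nref$cls, nref$start, nref$end, surf))
        led[[length(led) + 1L]] <- data.frame(
          doc_id = doc_id, entity_class = nref$cls, start = nref$start,
          end = nref$end, surface = surf, base_term = nref$base,
          core_start = core_start, core_end = core_end,
          singleton = nref$singleton, punct_attached = nref$punct,
          lexicon_exact = tolower(surf) %in% lex_keys,
          stringsAsFactors = FALSE)
      }
    }
    docs[[doc_id]] <- document(doc_id, text)
    gold[[doc_id]] <- ms
  }
  list(docs = docs, gold = annotation_set("gold", gold),
       ledger = do.call(rbind, led))
}

#' Perturbation configuration
#'
#' Per-mention probabilities of the three disagreement events, sampled
#' mutually exclusively in the order boundary, miss, category confusion.
#'
#' @param boundary_rate,miss_rate,confusion_rate Probabilities in
#'   \eqn{[0, 1]} with sum at most 1.
#' @param seed Integer RNG seed.
#' @return An object of class \code{aet_perturb_config}.
#' @export
perturb_config <- function(boundary_rate = 0.05, miss_rate = 0.2,
                           confusion_rate = 0.02, seed = 0L) {
  stopifnot(boundary_rate >= 0, miss_rate >= 0, confusion_rate >= 0,
            boundary_rate + miss_rate + confusion_rate <= 1)
  structure(list(boundary_rate = boundary_rate, miss_rate = miss_rate,
                 confusion_rate = confusion_rate, seed = as.integer(seed)),
            class = "aet_perturb_config")
}

#' Calibrate perturbation rates from a target token mixture
#'
#' Boundary events displace one token per mention while miss and
#' confusion events affect every token of the mention, so matching a
#' disagreeing-token mixture requires scaling the per-mention rates by
#' the mean mention token length.
#'
#' @param corpus A [generate_corpus()] result.
#' @param shares Target token shares for (boundary, missed, category),
#'   summing to 1.
#' @param total Overall per-mention perturbation probability.
#' @param seed Seed stored in the returned config.
#' @return An [perturb_config()].
#' @export
calibrate_perturb_rates <- function(corpus,
                                    shares = c(boundary = 0.1394,
                                               missed = 0.7969,
                                               category = 0.0636),
                                    total = 0.3, seed = 0L) {
  shares <- shares / sum(shares)
  lens <- vapply(seq_len(nrow(corpus$ledger)), function(i) {
    led <- corpus$ledger[i, ]
    toks <- corpus$docs[[led$doc_id]]$tokens
    sum(toks$start >= led$start & toks$end <= led$end)
  }, numeric(1))
  lbar <- mean(lens)
  raw <- unname(c(shares[1], shares[2] / lbar, shares[3] / lbar))
  rates <- raw / sum(raw) * total
  perturb_config(rates[1], rates[2], rates[3], seed)
}

#' Simulate a second annotator by perturbing gold annotations
#'
#' Each mention independently receives at most one event: a boundary
#' event extends or trims the span by one token (direction chosen among
#' the feasible moves; a single-token mention can only extend); a miss
#' event deletes the mention; a confusion event relabels it to another
#' class, with adverse-event/OSSD swaps weighted highest and
#' medication/treatment swaps next.
#'
#' @param corpus A [generate_corpus()] result (token boundaries are
#'   needed for boundary moves).
#' @param config An [perturb_config()].
#' @return An [annotation_set()] with annotator id \code{"simulated"}.
#' @export
perturb_annotations <- function(corpus, config = perturb_config()) {
  set.seed(config$seed)
  classes <- entity_classes()
  conf_weights <- function(cl) {
    w <- setNames(rep(1, length(classes)), classes)
    w[cl] <- 0
    if (cl == "AdverseEvent") w["OSSD"] <- 6
    if (cl == "OSSD") w["AdverseEvent"] <- 6
    if (cl == "Medication") w["Treatment"] <- 3
    if (cl == "Treatment") w["Medication"] <- 3
    w
  }
  out <- list()
  for (id in names(corpus$docs)) {
    doc <- corpus$docs[[id]]
    toks <- doc$tokens
    m <- corpus$gold$mentions[[id]]
    if (is.null(m) || nrow(m) == 0) { out[[id]] <- mentions(); next }
    m <- m[order(m$start), , drop = FALSE]
    keep <- rep(TRUE, nrow(m))
    for (i in seq_len(nrow(m))) {
      u <- runif(1)
      if (u < config$boundary_rate) {
        first <- which(toks$start == m$start[i])
        last <- which(toks$end == m$end[i])
        ntok_m <- last - first + 1L
        moves <- character(0)
        prev_end <- if (i > 1) m$end[i - 1] else -1L
        next_start <- if (i < nrow(m)) m$start[i + 1] else .Machine$integer.max
        if (first > 1L && toks$start[first - 1L] >= prev_end &&
            !(toks$surface[first - 1L] %in% c(".", "!", "?")))
          moves <- c(moves, "extend_left")
        if (last < nrow(toks) && toks$end[last + 1L] <= next_start &&
            !(toks$surface[last + 1L] %in% c(".", "!", "?")))
          moves <- c(moves, "extend_right")
        if (ntok_m >= 2L) moves <- c(moves, "trim_left", "trim_right")
        if (length(moves) > 0) {
          mv <- sample(moves, 1)
          if (mv == "extend_left") m$start[i] <- toks$start[first - 1L]
          if (mv == "extend_right") m$end[i] <- toks$end[last + 1L]
          if (mv == "trim_left") m$start[i] <- toks$start[first + 1L]
          if (mv == "trim_right") m$end[i] <- toks$end[last - 1L]
          m$surface[i] <- substring(doc$text, m$start[i] + 1L, m$end[i])
        }
      } else if (u < config$boundary_rate + config$miss_rate) {
        keep[i] <- FALSE
      } else if (u < config$boundary_rate + config$miss_rate +
                 config$confusion_rate) {
        w <- conf_weights(m$entity_class[i])
        m$entity_class[i] <- sample(classes, 1, prob = w)
      }
    }
    out[[id]] <- m[keep, , drop = FALSE]
  }
  annotation_set("simulated", out)
}

#' Write a corpus to the standard on-disk layout
#'
#' \code{texts/<doc>.txt} narrative files, \code{ann/<annotator>/}
#' standoff files for each annotation set, and \code{ledger.tsv}.
#'
#' @param corpus A [generate_corpus()] result.
#' @param dir Output directory (created if needed).
#' @param extra_annotations Optional list of further [annotation_set()]s.
#' @return Invisibly, \code{dir}.
#' @export
write_corpus <- function(corpus, dir, extra_annotations = list()) {
  anns <- c(list(corpus$gold), extra_annotations)
  dir.create(file.path(dir, "texts"), recursive = TRUE, showWarnings = FALSE)
  for (ann in anns)
    dir.create(file.path(dir, "ann", ann$annotator_id), recursive = TRUE,
               showWarnings = FALSE)
  for (id in names(corpus$docs)) {
    doc <- corpus$docs[[id]]
    writeLines(doc$text, file.path(dir, "texts", paste0(id, ".txt")),
               useBytes = TRUE)
    for (ann in anns) {
      m <- ann$mentions[[id]]
      if (is.null(m)) m <- mentions()
      write_standoff(doc, m,
                     file.path(dir, "texts", paste0(id, ".txt")),
                     file.path(dir, "ann", ann$annotator_id,
                               paste0(id, ".ann")))
    }
  }
  if (!is.null(corpus$ledger))
    write.table(corpus$ledger, file.path(dir, "ledger.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(dir)
}
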