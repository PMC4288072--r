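## Measurement machinery: strict/unstrict mention matching, P/R/F1,
## token-level Cohen's kappa, k-fold cross-validation, paired t-tests,
## Pearson correlation, and the annotator-disagreement report.

#' Match predicted against gold mentions
#'
#' One-to-one matching within a single document. \code{strict} requires
#' identical span and class; \code{unstrict} requires identical class and
#' at least one shared token (spans are token-aligned, so any character
#' overlap is a token overlap). Unstrict matching is greedy by gold
#' position: each gold mention takes the first unmatched overlapping
#' same-class prediction.
#'
#' @param gold,pred Mention data.frames for the same document.
#' @param mode \code{"strict"} or \code{"unstrict"}.
#' @return List with \code{tp}, \code{fp}, \code{fn} counts and logical
#'   vectors \code{gold_matched}, \code{pred_matched}.
#' @export
match_mentions <- function(gold, pred, mode = c("strict", "unstrict")) {
  mode <- match.arg(mode)
  ng <- nrow(gold); np <- nrow(pred)
  gm <- rep(FALSE, ng); pm <- rep(FALSE, np)
  if (ng > 0 && np > 0) {
    og <- order(gold$start); op <- order(pred$start)
    for (gi in og) {
      for (pi in op) {
        if (pm[pi] || pred$entity_class[pi] != gold$entity_class[gi]) next
        hit <- if (mode == "strict")
          pred$start[pi] == gold$start[gi] && pred$end[pi] == gold$end[gi]
        else
          pred$start[pi] < gold$end[gi] && gold$start[gi] < pred$end[pi]
        if (hit) { gm[gi] <- TRUE; pm[pi] <- TRUE; break }
      }
    }
  }
  list(tp = sum(gm), fp = sum(!pm), fn = sum(!gm),
       gold_matched = gm, pred_matched = pm)
}

.prf_from_counts <- function(tp, fp, fn) {
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f)
}

#' Corpus precision, recall and F1
#'
#' Per-class and overall scores over a corpus. Overall is micro-averaged
#' (counts pooled over classes); a macro average (unweighted mean of
#' per-class scores over classes present in gold or prediction) is also
#' reported.
#'
#' @param gold_ann,pred_ann [annotation_set()]s covering the same
#'   documents.
#' @param mode \code{"strict"} or \code{"unstrict"}.
#' @return Data.frame with one row per entity class plus
#'   \code{overall_micro} and \code{overall_macro}; columns \code{class},
#'   \code{tp}, \code{fp}, \code{fn}, \code{precision}, \code{recall},
#'   \code{f1}.
#' @export
prf <- function(gold_ann, pred_ann, mode = c("strict", "unstrict")) {
  mode <- match.arg(mode)
  cls <- entity_classes()
  tab <- matrix(0, length(cls), 3, dimnames = list(cls, c("tp", "fp", "fn")))
  ids <- union(names(gold_ann$mentions), names(pred_ann$mentions))
  for (id in ids) {
    g <- gold_ann$mentions[[id]]; p <- pred_ann$mentions[[id]]
    if (is.null(g)) g <- mentions()
    if (is.null(p)) p <- mentions()
    for (cl in cls) {
      m <- match_mentions(g[g$entity_class == cl, , drop = FALSE],
                          p[p$entity_class == cl, , drop = FALSE], mode)
      tab[cl, ] <- tab[cl, ] + c(m$tp, m$fp, m$fn)
    }
  }
  rows <- lapply(cls, function(cl) {
    s <- .prf_from_counts(tab[cl, 1], tab[cl, 2], tab[cl, 3])
    data.frame(class = cl, tp = tab[cl, 1], fp = tab[cl, 2], fn = tab[cl, 3],
               precision = s[1], recall = s[2], f1 = s[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tot <- colSums(tab)
  mic <- .prf_from_counts(tot[1], tot[2], tot[3])
  present <- out$tp + out$fp + out$fn > 0
  mac <- if (any(present)) colMeans(out[present, c("precision", "recall", "f1")])
         else c(precision = 0, recall = 0, f1 = 0)
  out <- rbind(out,
               data.frame(class = "overall_micro", tp = tot[1], fp = tot[2],
                          fn = tot[3], precision = mic[1], recall = mic[2],
                          f1 = mic[3], stringsAsFactors = FALSE),
               data.frame(class = "overall_macro", tp = NA, fp = NA, fn = NA,
                          precision = mac[1], recall = mac[2], f1 = mac[3],
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

# per-token in-class indicator for one annotator/class over one document
.token_in_class <- function(doc, mset, cl) {
  toks <- doc$tokens
  out <- rep(FALSE, nrow(toks))
  if (is.null(mset) || nrow(mset) == 0) return(out)
  m <- mset[mset$entity_class == cl, , drop = FALSE]
  for (i in seq_len(nrow(m)))
    out <- out | (toks$start >= m$start[i] & toks$end <= m$end[i])
  out
}

#' Token-level Cohen's kappa for one entity class
#'
#' Each token is a binary trial (in-class vs not) for each annotator;
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)}. In \code{unstrict} mode a token
#' covered by one annotator's class-\eqn{c} mention also counts as
#' in-class for the other annotator whenever the other annotator has a
#' same-class mention overlapping that mention (boundary differences are
#' forgiven; applied symmetrically). When \eqn{p_e = 1}, kappa is
#' defined as 1 if \eqn{p_o = 1} and 0 otherwise (with a message).
#'
#' @param annA,annB [annotation_set()]s.
#' @param docs Named list of [document()]s covering both sets.
#' @param entity_class One of [entity_classes()].
#' @param mode \code{"strict"} or \code{"unstrict"}.
#' @return Numeric kappa in \eqn{[-1, 1]}.
#' @export
cohens_kappa <- function(annA, annB, docs, entity_class,
                         mode = c("strict", "unstrict")) {
  mode <- match.arg(mode)
  a_tot <- logical(0); b_tot <- logical(0)
  for (id in names(docs)) {
    doc <- docs[[id]]
    if (nrow(doc$tokens) == 0) next
    mA <- annA$mentions[[id]]; mB <- annB$mentions[[id]]
    a <- .token_in_class(doc, mA, entity_class)
    b <- .token_in_class(doc, mB, entity_class)
    if (mode == "unstrict") {
      fa <- if (is.null(mA)) mentions() else mA[mA$entity_class == entity_class, , drop = FALSE]
      fb <- if (is.null(mB)) mentions() else mB[mB$entity_class == entity_class, , drop = FALSE]
      overlaps_any <- function(s, e, other) {
        nrow(other) > 0 && any(other$start < e & s < other$end)
      }
      for (i in seq_len(nrow(fa)))
        if (overlaps_any(fa$start[i], fa$end[i], fb)) {
          cov <- doc$tokens$start >= fa$start[i] & doc$tokens$end <= fa$end[i]
          b[cov] <- TRUE
        }
      for (i in seq_len(nrow(fb)))
        if (overlaps_any(fb$start[i], fb$end[i], fa)) {
          cov <- doc$tokens$start >= fb$start[i] & doc$tokens$end <= fb$end[i]
          a[cov] <- TRUE
        }
    }
    a_tot <- c(a_tot, a); b_tot <- c(b_tot, b)
  }
  n <- length(a_tot)
  if (n == 0) stop("no tokens to compare")
  po <- mean(a_tot == b_tot)
  pe <- mean(a_tot) * mean(b_tot) + mean(!a_tot) * mean(!b_tot)
  if (pe >= 1 - 1e-12) {
    message("degenerate marginals (p_e = 1); kappa set by convention")
    return(if (po >= 1 - 1e-12) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' Shuffle document ids into k folds
#'
#' Ids are shuffled by \code{seed} and dealt round-robin, so fold sizes
#' differ by at most one.
#'
#' @param doc_ids Character vector.
#' @param k Number of folds.
#' @param seed Integer RNG seed.
#' @return List with \code{k}, \code{seed} and \code{fold} (named
#'   integer vector, doc id -> fold in 1..k).
#' @export
kfold_split <- function(doc_ids, k, seed = 0L) {
  stopifnot(k >= 1, length(doc_ids) >= k)
  set.seed(seed)
  shuffled <- sample(doc_ids)
  fold <- setNames(rep_len(seq_len(k), length(shuffled)), shuffled)
  list(k = k, seed = as.integer(seed), fold = fold)
}

#' Two-sided paired t-test on per-fold scores
#'
#' Degenerate cases are handled explicitly: all-zero differences give
#' \code{t = 0, p = 1}; a nonzero constant difference gives
#' \code{t = +/-Inf, p = 0} (the limit as the difference SD goes to 0).
#'
#' @param scores_a,scores_b Equal-length numeric vectors (length >= 2).
#' @return List with \code{t}, \code{p} and \code{df}.
#' @export
paired_t_test <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 2)
  d <- scores_a - scores_b
  if (sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1, df = length(d) - 1L))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = length(d) - 1L))
  }
  ht <- stats::t.test(scores_a, scores_b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Pearson sample correlation
#'
#' @param x,y Equal-length numeric vectors (length >= 2) with nonzero
#'   variance.
#' @return Correlation coefficient in \eqn{[-1, 1]}.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  stats::cor(x, y)
}

#' Categorize annotator disagreements
#'
#' Every token whose class assignment differs between the two annotators
#' is placed in exactly one category: \code{category} if both annotate
#' the token but with different classes; \code{boundary} if the covering
#' annotator's mention overlaps a same-class mention of the other
#' annotator (they agree on the entity, not its extent); \code{missed}
#' otherwise (one annotator has no corresponding entity at all).
#'
#' @param annA,annB [annotation_set()]s.
#' @param docs Named list of [document()]s.
#' @return List with integer counts \code{boundary}, \code{missed},
#'   \code{category} and \code{total}.
#' @export
disagreement_report <- function(annA, annB, docs) {
  nb <- 0L; nm <- 0L; nc <- 0L
  for (id in names(docs)) {
    doc <- docs[[id]]
    ntok <- nrow(doc$tokens)
    if (ntok == 0) next
    mA <- annA$mentions[[id]]; mB <- annB$mentions[[id]]
    if (is.null(mA)) mA <- mentions()
    if (is.null(mB)) mB <- mentions()
    covering <- function(m, ts, te) {
      hit <- which(m$start <= ts & m$end >= te)
      if (length(hit) == 0) NA_integer_ else hit[1]
    }
    for (t in seq_len(ntok)) {
      ts <- doc$tokens$start[t]; te <- doc$tokens$end[t]
      ia <- covering(mA, ts, te); ib <- covering(mB, ts, te)
      ca <- if (is.na(ia)) NA_character_ else mA$entity_class[ia]
      cb <- if (is.na(ib)) NA_character_ else mB$entity_class[ib]
      if (identical(ca, cb)) next
      if (!is.na(ca) && !is.na(cb)) {
        nc <- nc + 1L
      } else {
        # exactly one annotator covers the token
        cov_m <- if (!is.na(ca)) mA[ia, ] else mB[ib, ]
        other <- if (!is.na(ca)) mB else mA
        same <- other[other$entity_class == cov_m$entity_class, , drop = FALSE]
        over <- nrow(same) > 0 &&
          any(same$start < cov_m$end & cov_m$start < same$end)
        if (over) nb <- nb + 1L else nm <- nm + 1L
      }
    }
  }
  list(boundary = nb, missed = nm, category = nc, total = nb + nm + nc)
}
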