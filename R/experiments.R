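## Experiment orchestration: document-level k-fold cross-validation and
## the feature-ablation runner (one tagger per feature-group addition and
## one per removal).

#' Specify a tagger for cross-validation
#'
#' @param type One of \code{"crf"}, \code{"nb"}, \code{"basedict"},
#'   \code{"gold"} (gold passthrough, for harness checks).
#' @param config Feature configuration (\code{crf}/\code{nb}).
#' @param l2,max_iter,tol,mask_illegal CRF training controls.
#' @return An object of class \code{aet_tagger_spec}.
#' @export
tagger_spec <- function(type = c("crf", "nb", "basedict", "gold"),
                        config = feature_config(), l2 = 1.0,
                        max_iter = 200L, tol = 1e-5, mask_illegal = TRUE) {
  type <- match.arg(type)
  structure(list(type = type, config = config, l2 = l2,
                 max_iter = as.integer(max_iter), tol = tol,
                 mask_illegal = mask_illegal),
            class = "aet_tagger_spec")
}

# train on `train_ids`, return an annotation set over `test_ids`;
# `feat_cache` holds per-document feature sets shared across folds
.fit_and_tag <- function(corpus, spec, train_ids, test_ids, resources, seed,
                         feat_cache = NULL) {
  fs <- function(id) if (is.null(feat_cache)) NULL else feat_cache[[id]]
  tag_fun <- switch(spec$type,
    gold = function(doc) {
      m <- corpus$gold$mentions[[doc$doc_id]]
      if (is.null(m)) mentions() else m
    },
    basedict = function(doc) basedict_tag(doc, resources$lexicon),
    crf = {
      pre <- if (is.null(feat_cache)) NULL else feat_cache[train_ids]
      model <- crf_train(corpus$docs[train_ids],
                         lapply(train_ids, function(id)
                           encode_bio(corpus$docs[[id]],
                                      corpus$gold$mentions[[id]])),
                         config = spec$config, resources = resources,
                         l2 = spec$l2, max_iter = spec$max_iter,
                         tol = spec$tol, seed = seed,
                         mask_illegal = spec$mask_illegal,
                         feature_sets_list = pre)
      function(doc) crf_tag(doc, model, resources, fs(doc$doc_id))
    },
    nb = {
      feats <- if (!is.null(feat_cache)) feat_cache[train_ids]
               else lapply(train_ids, function(id)
                 extract_features(corpus$docs[[id]], spec$config, resources))
      labs <- lapply(train_ids, function(id)
        encode_bio(corpus$docs[[id]], corpus$gold$mentions[[id]]))
      model <- nb_train(feats, labs)
      function(doc) nb_tag(doc, model, spec$config, resources)
    })
  annotation_set("system", setNames(lapply(test_ids, function(id)
    tag_fun(corpus$docs[[id]])), test_ids))
}

#' Document-level k-fold cross-validation
#'
#' For each fold, trains the tagger on the remaining folds and evaluates
#' on the held-out documents; reports per-fold scores and their mean and
#' SD. Deterministic given \code{seed}.
#'
#' @param corpus A [generate_corpus()]-shaped corpus (\code{docs} +
#'   \code{gold}).
#' @param spec An [tagger_spec()].
#' @param k Number of folds.
#' @param seed RNG seed (fold shuffling and training metadata).
#' @param mode Matching mode for evaluation.
#' @param resources Resource list.
#' @return List with \code{per_fold} (long data.frame: fold, class,
#'   precision, recall, f1), \code{summary} (mean and SD per class) and
#'   \code{folds} (the [kfold_split()]).
#' @export
cross_validate <- function(corpus, spec = tagger_spec("crf"), k = 10L,
                           seed = 0L, mode = "strict",
                           resources = default_resources()) {
  ids <- names(corpus$docs)
  folds <- kfold_split(ids, k, seed)
  feat_cache <- if (spec$type %in% c("crf", "nb"))
    setNames(lapply(corpus$docs, extract_features,
                    config = spec$config, resources = resources), ids)
  else NULL
  rows <- list()
  for (f in seq_len(k)) {
    test_ids <- names(folds$fold)[folds$fold == f]
    train_ids <- if (k == 1L) test_ids else setdiff(ids, test_ids)
    pred <- .fit_and_tag(corpus, spec, train_ids, test_ids, resources, seed,
                         feat_cache)
    gold_f <- annotation_set("gold", corpus$gold$mentions[test_ids])
    sc <- prf(gold_f, pred, mode)
    sc$fold <- f
    rows[[f]] <- sc
  }
  per_fold <- do.call(rbind, rows)
  agg <- lapply(split(per_fold, per_fold$class), function(g) {
    data.frame(class = g$class[1],
               precision_mean = mean(g$precision), precision_sd = sd(g$precision),
               recall_mean = mean(g$recall), recall_sd = sd(g$recall),
               f1_mean = mean(g$f1), f1_sd = sd(g$f1),
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, agg)
  ord <- c(entity_classes(), "overall_micro", "overall_macro")
  summary <- summary[match(ord, summary$class), ]
  rownames(summary) <- NULL
  list(per_fold = per_fold, summary = summary, folds = folds)
}

#' Feature-ablation experiment
#'
#' Runs cross-validation for the default-features tagger, for the
#' default plus each single feature family ("addition" runs), for the
#' all-features tagger, and optionally for the all-features tagger with
#' each family removed ("removal" runs).
#'
#' @param corpus Corpus as in [cross_validate()].
#' @param k,seed,mode,resources As in [cross_validate()].
#' @param l2,max_iter CRF training controls.
#' @param removals Also run the leave-one-family-out settings.
#' @return List of two data.frames, \code{addition} and \code{removal}
#'   (NULL unless requested): rows are feature settings, columns
#'   per-class and overall F1 mean (SD).
#' @export
run_ablation <- function(corpus, k = 10L, seed = 0L, mode = "strict",
                         resources = default_resources(), l2 = 1.0,
                         max_iter = 200L, removals = TRUE) {
  fams <- c("affix", "connective", "morphological", "neghedge",
            "semantic", "syntactic")
  settings <- c(list(Default = "default"),
                setNames(lapply(fams, function(f) c("default", f)),
                         paste0("+", fams)),
                list(All = c("default", fams)))
  one_row <- function(name, families) {
    cv <- cross_validate(corpus,
                         tagger_spec("crf", feature_config(families),
                                     l2 = l2, max_iter = max_iter),
                         k = k, seed = seed, mode = mode,
                         resources = resources)
    s <- cv$summary
    vals <- sprintf("%.2f (%.2f)", s$f1_mean, s$f1_sd)
    setNames(data.frame(setting = name, t(vals), stringsAsFactors = FALSE),
             c("setting", s$class))
  }
  addition <- do.call(rbind, lapply(names(settings), function(nm)
    one_row(nm, settings[[nm]])))
  removal <- NULL
  if (removals) {
    rem_settings <- c(list(All = c("default", fams)),
                      setNames(lapply(fams, function(f)
                        c("default", setdiff(fams, f))),
                        paste0("-", fams)))
    removal <- do.call(rbind, lapply(names(rem_settings), function(nm)
      one_row(nm, rem_settings[[nm]])))
  }
  list(addition = addition, removal = removal)
}
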