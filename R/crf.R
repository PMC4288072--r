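## Linear-chain conditional random field, implemented from first
## principles: log-space lattice scoring, forward-backward, Viterbi, and
## L2-regularised maximum-likelihood training via L-BFGS.

# transition legality over the 19-label BIO alphabet: I-X may only follow
# B-X or I-X; returns TRUE where the transition is allowed
.bio_transition_mask <- function(labels = bio_labels()) {
  L <- length(labels)
  ok <- matrix(TRUE, L, L, dimnames = list(labels, labels))
  for (j in seq_len(L)) {
    lab <- labels[j]
    if (startsWith(lab, "I-")) {
      cls <- substring(lab, 3)
      allowed <- c(paste0("B-", cls), paste0("I-", cls))
      ok[, j] <- labels %in% allowed
    }
  }
  ok
}

.bio_begin_mask <- function(labels = bio_labels()) !startsWith(labels, "I-")

#' Construct a scoring lattice
#'
#' A lattice holds the log-potentials of one token sequence: per-position
#' unary scores and shared transition scores, plus begin/end scores.
#' Masked (illegal) transitions are \code{-Inf}.
#'
#' @param unary Numeric matrix, positions x labels.
#' @param trans Numeric matrix, labels x labels (from-row, to-column).
#' @param begin,end Numeric vectors of per-label start/stop scores;
#'   default zero.
#' @return An object of class \code{aet_lattice}.
#' @export
lattice <- function(unary, trans, begin = rep(0, ncol(unary)),
                    end = rep(0, ncol(unary))) {
  stopifnot(is.matrix(unary), is.matrix(trans),
            ncol(unary) == ncol(trans), nrow(trans) == ncol(trans),
            length(begin) == ncol(unary), length(end) == ncol(unary))
  if (nrow(unary) < 1) stop("lattice needs at least one position")
  structure(list(unary = unary, trans = trans, begin = as.numeric(begin),
                 end = as.numeric(end)),
            class = "aet_lattice")
}

#' Log partition function of a lattice
#'
#' Forward recursion in log space; equals \eqn{\log \sum_{paths}
#' \exp(\mathrm{score})} over all label sequences.
#'
#' @param lat An [lattice()].
#' @return Numeric scalar; \code{-Inf} (with a warning) if every path is
#'   masked.
#' @export
log_partition <- function(lat) {
  r <- .crf_forward_backward(lat$unary, lat$trans, lat$begin, lat$end)
  if (!is.finite(r$logZ) && r$logZ < 0)
    warning("all paths masked: log partition is -Inf")
  r$logZ
}

#' Viterbi decoding of a lattice
#'
#' Returns an argmax label path; ties are broken towards the lowest label
#' index at every backtracking step, so decoding is deterministic.
#'
#' @param lat An [lattice()].
#' @return List with \code{path} (1-based label indices) and
#'   \code{score}.
#' @export
viterbi <- function(lat) {
  r <- .crf_viterbi(lat$unary, lat$trans, lat$begin, lat$end)
  list(path = as.integer(r$path) + 1L, score = r$score)
}

#' Posterior marginals of a lattice
#'
#' Forward-backward label posteriors per position and expected transition
#' counts (summed over positions).
#'
#' @param lat An [lattice()].
#' @return List with \code{node} (positions x labels, rows sum to 1),
#'   \code{trans} (labels x labels expected counts) and \code{logZ}.
#' @export
marginals <- function(lat) {
  r <- .crf_forward_backward(lat$unary, lat$trans, lat$begin, lat$end)
  list(node = r$node, trans = r$trans_exp, logZ = r$logZ)
}

# ---- model -----------------------------------------------------------

.crf_version <- "1"

# parameter vector layout: [vec(w_unary) | vec(w_trans) | w_begin | w_end]
.par_split <- function(par, n_feat, L) {
  nu <- n_feat * L; nt <- L * L
  list(unary = matrix(par[seq_len(nu)], n_feat, L),
       trans = matrix(par[nu + seq_len(nt)], L, L),
       begin = par[nu + nt + seq_len(L)],
       end = par[nu + nt + L + seq_len(L)])
}

#' Create a CRF model
#'
#' @param feat_names Character vector of known feature strings.
#' @param config Feature configuration the model was (or will be) trained
#'   with.
#' @param weights Numeric parameter vector (unary block, transition
#'   block, begin, end); zero if omitted.
#' @param l2 L2 regularisation constant (>= 0).
#' @param mask_illegal Hard-mask transitions that violate BIO structure
#'   (\code{O -> I-X}, \code{B-Y/I-Y -> I-X} for \code{Y != X}, and
#'   starting in \code{I-X}).
#' @param meta List of training metadata.
#' @return An object of class \code{aet_crf}.
#' @export
crf_model <- function(feat_names, config = feature_config(), weights = NULL,
                      l2 = 1.0, mask_illegal = TRUE, meta = list()) {
  labels <- bio_labels()
  L <- length(labels)
  npar <- length(feat_names) * L + L * L + 2L * L
  if (is.null(weights)) weights <- numeric(npar)
  stopifnot(length(weights) == npar, l2 >= 0)
  structure(list(labels = labels, feat_names = feat_names,
                 weights = weights, l2 = l2, mask_illegal = mask_illegal,
                 config = config, meta = meta, version = .crf_version),
            class = "aet_crf")
}

#' @export
print.aet_crf <- function(x, ...) {
  cat(sprintf("<aet_crf: %d features, %d labels, %d parameters, l2=%g>\n",
              length(x$feat_names), length(x$labels), length(x$weights), x$l2))
  invisible(x)
}

# sparse indicator matrix (tokens x features) for a list of feature sets;
# features not in `feat_names` are dropped (score 0 at test time)
.design_matrix <- function(feature_sets, feat_names) {
  n <- length(feature_sets)
  ii <- integer(0); jj <- integer(0)
  for (t in seq_len(n)) {
    j <- match(unique(feature_sets[[t]]), feat_names)
    j <- j[!is.na(j)]
    ii <- c(ii, rep.int(t, length(j))); jj <- c(jj, j)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                       dims = c(n, length(feat_names)))
}

#' Build the scoring lattice for one feature sequence
#'
#' Unary score of (position, label) is the sum of the weights of the
#' position's active (feature, label) parameters; duplicate feature
#' strings at one position count once. Unseen features contribute zero.
#'
#' @param feature_sets List of per-token feature-string vectors
#'   ([extract_features()]).
#' @param model An [crf_model()].
#' @return An [lattice()].
#' @export
build_lattice <- function(feature_sets, model) {
  L <- length(model$labels)
  w <- .par_split(model$weights, length(model$feat_names), L)
  X <- .design_matrix(feature_sets, model$feat_names)
  unary <- as.matrix(X %*% w$unary)
  trans <- w$trans
  begin <- w$begin
  if (model$mask_illegal) {
    trans[!.bio_transition_mask(model$labels)] <- -Inf
    begin[!.bio_begin_mask(model$labels)] <- -Inf
  }
  lattice(unary, trans, begin, w$end)
}

# observed sufficient statistics of a labelled batch; constant across
# optimizer iterations (the gold score is linear in the parameters)
.crf_observed <- function(X, ptr, gold, n_feat, L) {
  ntok <- nrow(X)
  allg <- unlist(gold); allrows <- unlist(ptr)
  Y <- Matrix::sparseMatrix(i = allrows, j = allg, x = 1, dims = c(ntok, L))
  oU <- as.matrix(Matrix::crossprod(X, Y))
  oT <- matrix(0, L, L); oB <- numeric(L); oE <- numeric(L)
  for (s in seq_along(ptr)) {
    y <- gold[[s]]; Tn <- length(y)
    oB[y[1]] <- oB[y[1]] + 1; oE[y[Tn]] <- oE[y[Tn]] + 1
    if (Tn > 1) for (t in 2:Tn) oT[y[t - 1], y[t]] <- oT[y[t - 1], y[t]] + 1
  }
  list(vec = c(as.vector(oU), as.vector(oT), oB, oE), Y = Y)
}

# objective/gradient engine shared by nll_and_gradient and crf_train.
# X: stacked sparse design matrix; ptr: list of row index vectors per
# sequence; gold: list of 1-based label index vectors; obs: output of
# .crf_observed for the same batch.
.crf_obj <- function(par, X, ptr, gold, obs, n_feat, L, l2, mask_illegal) {
  w <- .par_split(par, n_feat, L)
  tsc <- w$trans; bsc <- w$begin
  if (mask_illegal) {
    tsc[!.bio_transition_mask()] <- -Inf
    bsc[!.bio_begin_mask()] <- -Inf
  }
  U <- as.matrix(X %*% w$unary)
  fb <- .crf_fb_batch(U, tsc, bsc, w$end, lengths(ptr))
  if (!is.finite(fb$logZ))
    stop("non-finite objective: log partition is ", fb$logZ)
  obj <- fb$logZ - sum(par * obs$vec)    # minus the gold path scores
  gU <- as.matrix(Matrix::crossprod(X, fb$node))
  grad <- c(as.vector(gU), as.vector(fb$trans_exp), fb$first, fb$last) -
    obs$vec
  # masked transition parameters are unused: no data gradient, no penalty
  if (mask_illegal) {
    mtr <- !.bio_transition_mask(); mb <- !.bio_begin_mask()
    sel <- c(rep(FALSE, n_feat * L), as.vector(mtr), mb, rep(FALSE, L))
    grad[sel] <- 0
    pen_par <- par; pen_par[sel] <- 0
  } else pen_par <- par
  obj <- obj + l2 / 2 * sum(pen_par^2)
  grad <- grad + l2 * pen_par
  list(objective = obj, gradient = grad)
}

#' Regularised negative log-likelihood and gradient
#'
#' Computes \eqn{\sum_d (\log Z_d - \mathrm{score}(y_d)) +
#' \frac{\lambda}{2}\|w\|^2} and its gradient (expected minus observed
#' feature counts plus \eqn{\lambda w}) for a batch of labelled feature
#' sequences, at the model's current weights.
#'
#' @param model An [crf_model()].
#' @param feature_sets_list List of per-sequence feature-set lists.
#' @param labels_list List of BIO label vectors (gold).
#' @return List with \code{objective} and \code{gradient}.
#' @export
nll_and_gradient <- function(model, feature_sets_list, labels_list) {
  stopifnot(length(feature_sets_list) == length(labels_list))
  L <- length(model$labels)
  gold <- lapply(labels_list, function(lab) {
    idx <- match(lab, model$labels)
    if (anyNA(idx)) stop("gold label outside alphabet: ",
                         paste(unique(lab[is.na(idx)]), collapse = ", "))
    idx
  })
  lens <- lengths(gold)
  ptr <- split(seq_len(sum(lens)), rep(seq_along(lens), lens))
  X <- .design_matrix(do.call(c, feature_sets_list), model$feat_names)
  obs <- .crf_observed(X, ptr, gold, length(model$feat_names), L)
  .crf_obj(model$weights, X, ptr, gold, obs, length(model$feat_names), L,
           model$l2, model$mask_illegal)
}

#' Train a CRF tagger
#'
#' Extracts features for every document, indexes the training vocabulary,
#' and minimises the L2-regularised negative conditional log-likelihood
#' with L-BFGS until the projected-gradient sup-norm drops below
#' \code{tol} or \code{max_iter} iterations. Training is deterministic
#' given the corpus order and configuration; \code{seed} is recorded in
#' the model metadata.
#'
#' @param docs List of [document()]s.
#' @param labels_list List of gold BIO label vectors, parallel to
#'   \code{docs}.
#' @param config An [feature_config()].
#' @param resources Resource list ([default_resources()]).
#' @param l2 Regularisation constant.
#' @param max_iter Maximum optimizer iterations (0 returns the
#'   zero-weight model).
#' @param tol Projected-gradient sup-norm stopping tolerance.
#' @param seed Integer recorded in metadata.
#' @param mask_illegal Hard-mask structurally illegal BIO transitions.
#' @param feature_sets_list Optional precomputed per-document feature
#'   sets (as from [extract_features()] with the same \code{config}),
#'   to avoid re-extraction across cross-validation folds.
#' @return A trained [crf_model()].
#' @export
crf_train <- function(docs, labels_list, config = feature_config(),
                      resources = NULL, l2 = 1.0, max_iter = 200L,
                      tol = 1e-5, seed = 0L, mask_illegal = TRUE,
                      feature_sets_list = NULL) {
  stopifnot(length(docs) >= 1, length(docs) == length(labels_list))
  keep <- vapply(docs, function(d) nrow(d$tokens) > 0, logical(1))
  docs <- docs[keep]; labels_list <- labels_list[keep]
  if (length(docs) == 0) stop("no non-empty training documents")
  feats <- if (!is.null(feature_sets_list)) feature_sets_list[keep]
           else lapply(docs, extract_features, config = config,
                       resources = resources)
  stopifnot(length(feats) == length(docs))
  feat_names <- sort(unique(unlist(feats)))
  L <- length(bio_labels())
  model <- crf_model(feat_names, config, l2 = l2,
                     mask_illegal = mask_illegal,
                     meta = list(seed = as.integer(seed)))
  if (max_iter == 0L) {
    model$meta$iterations <- 0L
    model$meta$objective <- NA_real_
    return(model)
  }
  gold <- lapply(labels_list, function(lab) match(lab, model$labels))
  if (anyNA(unlist(gold))) stop("gold label outside alphabet")
  lens <- lengths(gold)
  ptr <- split(seq_len(sum(lens)), rep(seq_along(lens), lens))
  X <- .design_matrix(do.call(c, feats), feat_names)
  obs <- .crf_observed(X, ptr, gold, length(feat_names), L)

  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$res)
    res <- .crf_obj(par, X, ptr, gold, obs, length(feat_names), L, l2, mask_illegal)
    cache$par <- par; cache$res <- res
    res
  }
  trace_obj <- numeric(0)
  fn <- function(par) {
    v <- evaluate(par)$objective
    trace_obj <<- c(trace_obj, v)
    v
  }
  gr <- function(par) evaluate(par)$gradient
  opt <- stats::optim(model$weights, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = max_iter, pgtol = tol,
                                     factr = 1e4))
  model$weights <- opt$par
  model$meta$iterations <- unname(opt$counts[1])
  model$meta$objective <- opt$value
  model$meta$objective_trace <- trace_obj
  model$meta$convergence <- opt$convergence
  model
}

#' Tag a document with a trained CRF
#'
#' Extracts features with the model's configuration, scores the lattice,
#' decodes with Viterbi, and converts the BIO sequence to mentions (the
#' decode-time repair never fires when illegal transitions are masked).
#'
#' @param doc An [document()].
#' @param model A trained [crf_model()].
#' @param resources Resource list matching the model's feature families.
#' @param feature_sets Optional precomputed feature sets for \code{doc}.
#' @return A mention data.frame.
#' @export
crf_tag <- function(doc, model, resources = NULL, feature_sets = NULL) {
  if (nrow(doc$tokens) == 0) return(mentions())
  feats <- if (!is.null(feature_sets)) feature_sets
           else extract_features(doc, model$config, resources)
  lat <- build_lattice(feats, model)
  v <- viterbi(lat)
  decode_bio(doc, model$labels[v$path])
}

#' Serialize a CRF model to versioned JSON
#'
#' @param model An [crf_model()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
crf_save <- function(model, path) {
  obj <- list(format = "aetagger-crf", version = model$version,
              labels = model$labels, feat_names = model$feat_names,
              weights = model$weights, l2 = model$l2,
              mask_illegal = model$mask_illegal,
              config = list(families = model$config$families,
                            window = model$config$window),
              meta = model$meta[setdiff(names(model$meta), "objective_trace")])
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(path)
}

#' Load a CRF model from JSON
#'
#' @param path Path written by [crf_save()].
#' @return An [crf_model()].
#' @export
crf_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "aetagger-crf"))
    stop("not an aetagger CRF model file: ", path)
  crf_model(obj$feat_names,
            feature_config(obj$config$families, obj$config$window),
            weights = obj$weights, l2 = obj$l2,
            mask_illegal = obj$mask_illegal, meta = as.list(obj$meta))
}
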