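# Shared fixtures and independent oracles for the test suite.

.fixture_env <- new.env(parent = emptyenv())

# memoize expensive fixtures across test files
fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

test_resources <- function() fixture("resources", default_resources)

# the study-scale corpus at generator defaults (seed 0, 122 docs)
default_corpus <- function() {
  fixture("default_corpus",
          function() generate_corpus(generator_config(), test_resources()))
}

# a small, fast corpus for unit tests
small_corpus <- function() {
  fixture("small_corpus", function()
    generate_corpus(generator_config(n_docs = 8L, seed = 42L,
                                     words_mean = 60, words_sd = 20),
                    test_resources()))
}

# ---- exhaustive-enumeration oracle for small lattices ----------------

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# all label paths of length T over L labels, as a matrix (rows = paths)
enum_paths <- function(T_, L) {
  as.matrix(expand.grid(rep(list(seq_len(L)), T_)))
}

enum_path_scores <- function(lat) {
  T_ <- nrow(lat$unary); L <- ncol(lat$unary)
  paths <- enum_paths(T_, L)
  scores <- apply(paths, 1, function(y) {
    s <- lat$begin[y[1]] + lat$end[y[T_]]
    for (t in seq_len(T_)) s <- s + lat$unary[t, y[t]]
    if (T_ > 1) for (t in 2:T_) s <- s + lat$trans[y[t - 1], y[t]]
    s
  })
  list(paths = paths, scores = scores)
}

enum_log_partition <- function(lat) log_sum_exp(enum_path_scores(lat)$scores)

enum_viterbi <- function(lat) {
  ps <- enum_path_scores(lat)
  best <- max(ps$scores)
  list(score = best, paths = ps$paths[ps$scores == best, , drop = FALSE])
}

enum_marginals <- function(lat) {
  ps <- enum_path_scores(lat)
  logZ <- log_sum_exp(ps$scores)
  p <- exp(ps$scores - logZ)
  T_ <- nrow(lat$unary); L <- ncol(lat$unary)
  node <- matrix(0, T_, L)
  trans <- matrix(0, L, L)
  for (r in seq_along(p)) {
    y <- ps$paths[r, ]
    for (t in seq_len(T_)) node[t, y[t]] <- node[t, y[t]] + p[r]
    if (T_ > 1) for (t in 2:T_)
      trans[y[t - 1], y[t]] <- trans[y[t - 1], y[t]] + p[r]
  }
  list(node = node, trans = trans, logZ = logZ)
}

# random lattice with optional -Inf masking; guaranteed to keep at least
# one unmasked path (label 1 everywhere)
random_lattice <- function(T_, L, mask_prob = 0) {
  unary <- matrix(rnorm(T_ * L, sd = 2), T_, L)
  trans <- matrix(rnorm(L * L, sd = 2), L, L)
  begin <- rnorm(L); endw <- rnorm(L)
  if (mask_prob > 0) {
    trans[matrix(runif(L * L) < mask_prob, L, L)] <- -Inf
    trans[1, 1] <- abs(trans[1, 1])
    if (!is.finite(trans[1, 1])) trans[1, 1] <- 0
  }
  lattice(unary, trans, begin, endw)
}

# random legal BIO sequence of length n (for masked-model training data)
random_bio <- function(n) {
  cls <- entity_classes()
  labs <- character(n)
  i <- 1L
  while (i <= n) {
    if (runif(1) < 0.5) { labs[i] <- "O"; i <- i + 1L }
    else {
      cl <- sample(cls, 1)
      len <- min(sample(1:3, 1), n - i + 1L)
      labs[i] <- paste0("B-", cl)
      if (len > 1) labs[(i + 1L):(i + len - 1L)] <- paste0("I-", cl)
      i <- i + len
    }
  }
  labs
}

# random training instance over a small feature vocabulary
random_instance <- function(n_tok, vocab) {
  feats <- lapply(seq_len(n_tok), function(t)
    sort(sample(vocab, sample(1:3, 1))))
  list(feats = feats, labels = random_bio(n_tok))
}
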