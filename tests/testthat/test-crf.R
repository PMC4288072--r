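# CRF inference and training, validated against exhaustive enumeration
# and finite differences.

test_that("log partition, Viterbi and marginals match enumeration", {
  set.seed(101)
  for (rep in 1:60) {
    T_ <- sample(1:4, 1); L <- sample(2:4, 1)
    lat <- random_lattice(T_, L, mask_prob = if (rep %% 3 == 0) 0.25 else 0)
    ez <- enum_log_partition(lat)
    if (!is.finite(ez)) next
    expect_equal(log_partition(lat), ez, tolerance = 1e-10)
    ev <- enum_viterbi(lat)
    v <- viterbi(lat)
    expect_equal(v$score, ev$score, tolerance = 1e-10)
    # random continuous scores: the argmax is unique
    expect_identical(nrow(ev$paths), 1L)
    expect_identical(v$path, unname(ev$paths[1, ]))
    em <- enum_marginals(lat)
    mg <- marginals(lat)
    expect_equal(mg$node, em$node, tolerance = 1e-10)
    expect_equal(mg$trans, em$trans, tolerance = 1e-10)
    expect_true(all(abs(rowSums(mg$node) - 1) < 1e-12))
  }
})

test_that("Viterbi tie-break picks the lowest label index", {
  lat <- lattice(matrix(0, 3, 4), matrix(0, 4, 4))
  v <- viterbi(lat)
  expect_identical(v$path, c(1L, 1L, 1L))
  expect_identical(v$score, 0)
})

test_that("fully masked lattices warn and return -Inf", {
  lat <- lattice(matrix(c(-Inf, -Inf), 1, 2), matrix(0, 2, 2))
  expect_warning(z <- log_partition(lat), "masked")
  expect_identical(z, -Inf)
  expect_error(lattice(matrix(0, 0, 2), matrix(0, 2, 2)), "at least one")
})

test_that("analytic gradient matches central differences", {
  set.seed(202)
  vocab <- paste0("f", 1:6)
  for (rep in 1:8) {
    mask <- rep %% 2 == 0
    insts <- lapply(1:2, function(i) random_instance(sample(2:5, 1), vocab))
    model <- crf_model(vocab, l2 = runif(1, 0.1, 2), mask_illegal = mask)
    model$weights <- rnorm(length(model$weights), sd = 0.2)
    feats <- lapply(insts, `[[`, "feats")
    labs <- lapply(insts, `[[`, "labels")
    g <- nll_and_gradient(model, feats, labs)
    h <- 1e-4
    coords <- sample(length(model$weights), 20)
    for (j in coords) {
      mp <- model; mp$weights[j] <- mp$weights[j] + h
      mm <- model; mm$weights[j] <- mm$weights[j] - h
      fd <- (nll_and_gradient(mp, feats, labs)$objective -
             nll_and_gradient(mm, feats, labs)$objective) / (2 * h)
      expect_lt(abs(fd - g$gradient[j]) / max(1, abs(fd), abs(g$gradient[j])),
                1e-6)
    }
  }
})

test_that("objective and gradient are consistent with the enumeration oracle", {
  set.seed(303)
  vocab <- paste0("f", 1:4)
  inst <- random_instance(3, vocab)
  model <- crf_model(vocab, l2 = 0.5, mask_illegal = FALSE)
  model$weights <- rnorm(length(model$weights), sd = 0.3)
  g <- nll_and_gradient(model, list(inst$feats), list(inst$labels))
  # oracle: logZ by brute force over the built lattice, gold score by
  # direct summation
  lat <- build_lattice(inst$feats, model)
  w <- aetagger:::.par_split(model$weights, 4L, 19L)
  y <- match(inst$labels, bio_labels())
  gold <- w$begin[y[1]] + w$end[y[3]] +
    sum(vapply(1:3, function(t) lat$unary[t, y[t]], 0)) +
    w$trans[y[1], y[2]] + w$trans[y[2], y[3]]
  expect_equal(g$objective,
               enum_log_partition(lat) - gold +
                 model$l2 / 2 * sum(model$weights^2),
               tolerance = 1e-8)
})

test_that("masking removes illegal transitions from decoding", {
  set.seed(404)
  vocab <- paste0("f", 1:5)
  model <- crf_model(vocab, mask_illegal = TRUE)
  model$weights <- rnorm(length(model$weights))
  feats <- lapply(1:6, function(t) sample(vocab, 2))
  lat <- build_lattice(feats, model)
  v <- viterbi(lat)
  labs <- bio_labels()[v$path]
  # decoded sequence is structurally valid: repair changes nothing
  expect_identical(repair_bio(labs), labs)
  # begin mask: first label is never I-
  expect_false(startsWith(labs[1], "I-"))
})

test_that("training reduces the objective and is deterministic", {
  corpus <- small_corpus()
  res <- test_resources()
  ids <- names(corpus$docs)[1:4]
  docs <- corpus$docs[ids]
  labs <- lapply(ids, function(id)
    encode_bio(corpus$docs[[id]], corpus$gold$mentions[[id]]))
  m1 <- crf_train(docs, labs, feature_config(), res, max_iter = 15L)
  expect_lt(m1$meta$objective, m1$meta$objective_trace[1])
  m2 <- crf_train(docs, labs, feature_config(), res, max_iter = 15L)
  expect_identical(m1$weights, m2$weights)
  # zero-iteration training returns the zero model
  m0 <- crf_train(docs, labs, feature_config(), res, max_iter = 0L)
  expect_true(all(m0$weights == 0))
  # tagging the training data recovers most mentions even at 15 iters
  pred <- crf_tag(docs[[1]], m1, res)
  expect_s3_class(pred, "data.frame")
})

test_that("a trained model fits a small training set almost exactly", {
  corpus <- small_corpus()
  res <- test_resources()
  ids <- names(corpus$docs)
  labs <- lapply(ids, function(id)
    encode_bio(corpus$docs[[id]], corpus$gold$mentions[[id]]))
  m <- crf_train(corpus$docs, labs, all_features_config(), res,
                 max_iter = 100L)
  pred <- annotation_set("system", setNames(lapply(ids, function(id)
    crf_tag(corpus$docs[[id]], m, res)), ids))
  sc <- prf(corpus$gold, pred, "strict")
  expect_gt(sc$f1[sc$class == "overall_micro"], 0.95)
})

test_that("model serialization round-trips exactly", {
  corpus <- small_corpus()
  res <- test_resources()
  ids <- names(corpus$docs)[1:3]
  labs <- lapply(ids, function(id)
    encode_bio(corpus$docs[[id]], corpus$gold$mentions[[id]]))
  m <- crf_train(corpus$docs[ids], labs, feature_config(), res,
                 max_iter = 10L)
  p <- withr::local_tempfile(fileext = ".json")
  crf_save(m, p)
  m2 <- crf_load(p)
  expect_identical(m2$feat_names, m$feat_names)
  expect_equal(m2$weights, m$weights, tolerance = 0)
  d <- corpus$docs[[ids[1]]]
  expect_identical(crf_tag(d, m2, res), crf_tag(d, m, res))
  bad <- withr::local_tempfile(lines = "{\"format\": \"other\"}")
  expect_error(crf_load(bad), "not an aetagger CRF model")
})

test_that("training rejects inconsistent input", {
  corpus <- small_corpus()
  d <- corpus$docs[[1]]
  expect_error(crf_train(list(d), list(rep("Nope", nrow(d$tokens)))),
               "alphabet")
  empty <- document("e", "")
  expect_error(crf_train(list(empty), list(character(0))), "non-empty")
})
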