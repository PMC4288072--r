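# Synthetic corpus generator and the annotator-perturbation model.

test_that("generation is deterministic and well-formed", {
  res <- test_resources()
  cfg <- generator_config(n_docs = 5L, seed = 11L, words_mean = 60,
                          words_sd = 15)
  c1 <- generate_corpus(cfg, res)
  c2 <- generate_corpus(cfg, res)
  expect_identical(lapply(c1$docs, `[[`, "text"),
                   lapply(c2$docs, `[[`, "text"))
  expect_identical(c1$ledger, c2$ledger)
  expect_length(c1$docs, 5L)
  # every mention aligns to token boundaries and matches its surface
  for (id in names(c1$docs)) {
    doc <- c1$docs[[id]]
    m <- c1$gold$mentions[[id]]
    labs <- encode_bio(doc, m)          # errors if misaligned
    expect_identical(decode_bio(doc, labs)$surface, m$surface)
    expect_identical(m$surface,
                     substring(doc$text, m$start + 1L, m$end))
  }
  # ledger rows correspond 1:1 to gold mentions
  n_gold <- sum(vapply(c1$gold$mentions, nrow, 0L))
  expect_identical(nrow(c1$ledger), n_gold)
})

test_that("documents respect the word-count floor and seed changes text", {
  res <- test_resources()
  c1 <- generate_corpus(generator_config(n_docs = 3L, seed = 1L,
                                         words_mean = 40, words_sd = 60), res)
  for (doc in c1$docs)
    expect_gte(length(strsplit(doc$text, " ", fixed = TRUE)[[1]]), 30L)
  c2 <- generate_corpus(generator_config(n_docs = 3L, seed = 2L,
                                         words_mean = 40, words_sd = 60), res)
  expect_false(identical(c1$docs[[1]]$text, c2$docs[[1]]$text))
})

test_that("singleton surfaces are unique in the corpus", {
  corpus <- small_corpus()
  led <- corpus$ledger
  surf <- tolower(led$surface)
  singles <- surf[led$singleton]
  expect_true(all(table(singles) == 1L))
  expect_true(all(!(singles %in% surf[!led$singleton])))
})

test_that("ledger core spans carry the lexicon base term", {
  corpus <- small_corpus()
  led <- corpus$ledger
  led <- led[!is.na(led$core_start), , drop = FALSE]
  expect_gt(nrow(led), 0)
  for (i in seq_len(nrow(led))) {
    core <- substring(corpus$docs[[led$doc_id[i]]]$text,
                      led$core_start[i] + 1L, led$core_end[i])
    expect_identical(tolower(core), led$base_term[i])
  }
  # punctuation-attached mentions end with the absorbed period
  pa <- corpus$ledger[corpus$ledger$punct_attached, , drop = FALSE]
  if (nrow(pa) > 0)
    expect_true(all(endsWith(pa$surface, ".")))
})

test_that("class mix of a generated corpus tracks the configured weights", {
  corpus <- default_corpus()
  counts <- table(factor(corpus$ledger$entity_class,
                         levels = entity_classes()))
  wts <- generator_config()$class_weights
  obs <- as.numeric(counts) / sum(counts)
  expected <- as.numeric(wts / sum(wts))
  expect_lt(max(abs(obs - expected)), 0.05)
  # the two majority classes dominate, in order
  expect_identical(names(which.max(counts)), "AdverseEvent")
  expect_gt(counts[["Medication"]], max(counts[entity_classes()[-c(1, 7)]]))
})

test_that("zero-rate perturbation is the identity; full miss empties", {
  corpus <- small_corpus()
  same <- perturb_annotations(corpus, perturb_config(0, 0, 0, seed = 5))
  for (id in names(corpus$docs))
    expect_identical(same$mentions[[id]], corpus$gold$mentions[[id]])
  gone <- perturb_annotations(corpus, perturb_config(0, 1, 0, seed = 5))
  expect_identical(sum(vapply(gone$mentions, nrow, 0L)), 0L)
})

test_that("perturbation events have the advertised shapes", {
  corpus <- small_corpus()
  # boundary only: same mention count, same classes, spans shift by one token
  b <- perturb_annotations(corpus, perturb_config(1, 0, 0, seed = 3))
  for (id in names(corpus$docs)) {
    g <- corpus$gold$mentions[[id]]; p <- b$mentions[[id]]
    expect_identical(nrow(p), nrow(g))
    expect_identical(p$entity_class, g$entity_class)
    expect_true(all(p$start != g$start | p$end != g$end))
  }
  # confusion only: same spans, different classes
  cfg <- perturb_config(0, 0, 1, seed = 3)
  cc <- perturb_annotations(corpus, cfg)
  for (id in names(corpus$docs)) {
    g <- corpus$gold$mentions[[id]]; p <- cc$mentions[[id]]
    expect_identical(p$start, g$start)
    expect_identical(p$end, g$end)
    expect_true(all(p$entity_class != g$entity_class))
  }
})

test_that("calibration converts token shares into per-mention rates", {
  corpus <- small_corpus()
  cfg <- calibrate_perturb_rates(corpus, total = 0.3, seed = 1)
  expect_s3_class(cfg, "aet_perturb_config")
  expect_equal(cfg$boundary_rate + cfg$miss_rate + cfg$confusion_rate, 0.3)
  # boundary affects one token, the others whole mentions: the
  # boundary rate must exceed its raw token share after rescaling
  expect_gt(cfg$boundary_rate / 0.3, 0.1394)
  expect_error(perturb_config(0.5, 0.5, 0.2), "<= 1")
})

test_that("write_corpus produces the standard layout and round-trips", {
  dir <- withr::local_tempdir()
  corpus <- small_corpus()
  sim <- perturb_annotations(corpus, perturb_config(seed = 1))
  write_corpus(corpus, dir, list(sim))
  expect_true(dir.exists(file.path(dir, "texts")))
  expect_true(dir.exists(file.path(dir, "ann", "gold")))
  expect_true(dir.exists(file.path(dir, "ann", "simulated")))
  expect_true(file.exists(file.path(dir, "ledger.tsv")))
  id <- names(corpus$docs)[1]
  back <- read_standoff(file.path(dir, "texts", paste0(id, ".txt")),
                        file.path(dir, "ann", "gold", paste0(id, ".ann")))
  expect_identical(back$mentions$surface, corpus$gold$mentions[[id]]$surface)
  expect_identical(back$mentions$start, corpus$gold$mentions[[id]]$start)
})
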