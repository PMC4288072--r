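# Matching, P/R/F1, kappa, folds, tests, correlation, disagreements.

make_ann <- function(id, docs, ...) {
  annotation_set(id, docs)
}

test_that("strict and unstrict mention matching follow their definitions", {
  gold <- mentions(c("AdverseEvent", "Medication"), c(0L, 20L), c(13L, 30L),
                   c("severe nausea", "paclitaxel"))
  # prediction 1 gets the AE boundary wrong but overlaps; prediction 2 exact
  pred <- mentions(c("AdverseEvent", "Medication"), c(7L, 20L), c(13L, 30L),
                   c("nausea", "paclitaxel"))
  strict <- match_mentions(gold, pred, "strict")
  expect_identical(c(strict$tp, strict$fp, strict$fn), c(1L, 1L, 1L))
  unstrict <- match_mentions(gold, pred, "unstrict")
  expect_identical(c(unstrict$tp, unstrict$fp, unstrict$fn), c(2L, 0L, 0L))
  # class must match even with overlap
  pred2 <- mentions("OSSD", 0L, 13L, "severe nausea")
  expect_identical(match_mentions(gold, pred2, "unstrict")$tp, 0L)
  # one-to-one: two predictions cannot both match one gold mention
  pred3 <- mentions(c("AdverseEvent", "AdverseEvent"), c(0L, 7L),
                    c(6L, 13L), c("severe", "nausea"))
  u3 <- match_mentions(gold[1, ], pred3, "unstrict")
  expect_identical(c(u3$tp, u3$fp, u3$fn), c(1L, 1L, 0L))
})

test_that("prf computes per-class and pooled scores with the F1 identity", {
  doc <- document("d", "severe nausea after paclitaxel infusion")
  gold <- annotation_set("gold", list(
    d = mentions(c("AdverseEvent", "Medication"), c(0L, 20L), c(13L, 30L),
                 c("severe nausea", "paclitaxel"))))
  pred <- annotation_set("sys", list(
    d = mentions(c("AdverseEvent", "Medication", "Medication"),
                 c(7L, 20L, 31L), c(13L, 30L, 39L),
                 c("nausea", "paclitaxel", "infusion"))))
  sc <- prf(gold, pred, "strict")
  med <- sc[sc$class == "Medication", ]
  expect_identical(c(med$tp, med$fp, med$fn), c(1, 1, 0))
  expect_equal(med$precision, 0.5)
  expect_equal(med$recall, 1)
  mic <- sc[sc$class == "overall_micro", ]
  expect_identical(c(mic$tp, mic$fp, mic$fn), c(1, 2, 1))
  # F1 is the harmonic mean of the printed precision and recall
  for (i in seq_len(nrow(sc))) {
    p <- sc$precision[i]; r <- sc$recall[i]
    expect_equal(sc$f1[i], if (p + r == 0) 0 else 2 * p * r / (p + r))
  }
  # macro averages only classes present in gold or prediction
  mac <- sc[sc$class == "overall_macro", ]
  expect_equal(mac$precision, mean(c(0.5, 0)))
})

test_that("kappa matches the closed form on a hand-built example", {
  doc <- document("d", "a b c d e f g h i j")
  # A marks tokens 1-4 as AE (chars 0..7), B marks tokens 3-6 (4..11)
  annA <- annotation_set("A", list(d = mentions("AdverseEvent", 0L, 7L, "a b c d")))
  annB <- annotation_set("B", list(d = mentions("AdverseEvent", 4L, 11L, "c d e f")))
  k <- cohens_kappa(annA, annB, list(d = doc), "AdverseEvent", "strict")
  # po = 6/10 agreements; pe = .4*.4 + .6*.6
  po <- 0.6; pe <- 0.4 * 0.4 + 0.6 * 0.6
  expect_equal(k, (po - pe) / (1 - pe))
  # unstrict forgives the boundary difference entirely here
  expect_equal(cohens_kappa(annA, annB, list(d = doc), "AdverseEvent",
                            "unstrict"), 1)
  # self-agreement is perfect
  expect_equal(cohens_kappa(annA, annA, list(d = doc), "AdverseEvent",
                            "strict"), 1)
  # degenerate marginals: no mentions on either side
  none <- annotation_set("n", list(d = mentions()))
  expect_message(
    k0 <- cohens_kappa(none, none, list(d = doc), "Medication", "strict"),
    "degenerate")
  expect_identical(k0, 1)
})

test_that("kfold_split shuffles deterministically into near-equal folds", {
  ids <- sprintf("doc%03d", 1:122)
  f <- kfold_split(ids, 10, seed = 0)
  expect_setequal(names(f$fold), ids)
  sizes <- as.integer(table(f$fold))
  expect_identical(sort(sizes), c(rep(12L, 8), 13L, 13L))
  f2 <- kfold_split(ids, 10, seed = 0)
  expect_identical(f$fold, f2$fold)
  f3 <- kfold_split(ids, 10, seed = 1)
  expect_false(identical(f$fold, f3$fold))
  expect_error(kfold_split(ids[1:3], 5), "k")
})

test_that("paired t-test agrees with its closed form and handles degeneracy", {
  set.seed(9)
  a <- rnorm(10); b <- rnorm(10)
  r <- paired_t_test(a, b)
  d <- a - b
  expect_equal(r$t, mean(d) / (sd(d) / sqrt(10)))
  expect_equal(r$df, 9)
  expect_equal(r$p, 2 * pt(-abs(r$t), 9))
  expect_identical(paired_t_test(a, a), list(t = 0, p = 1, df = 9L))
  r2 <- paired_t_test(a + 1, a)
  expect_identical(r2$t, Inf)
  expect_identical(r2$p, 0)
})

test_that("pearson_r agrees with its closed form", {
  set.seed(10)
  x <- rnorm(12); y <- rnorm(12)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), num / den)
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("disagreement_report categorizes one token per cause", {
  doc <- document("d", "nausea vomiting paclitaxel infusion fever rash")
  # tokens: nausea(0,6) vomiting(7,15) paclitaxel(16,26) infusion(27,35)
  #         fever(36,41) rash(42,46)
  annA <- annotation_set("A", list(d = mentions(
    c("AdverseEvent", "Medication", "AdverseEvent"),
    c(0L, 16L, 36L), c(15L, 26L, 41L),
    c("nausea vomiting", "paclitaxel", "fever"))))
  annB <- annotation_set("B", list(d = mentions(
    c("AdverseEvent", "Medication", "OSSD"),
    c(0L, 16L, 36L), c(6L, 26L, 41L),
    c("nausea", "paclitaxel", "fever"))))
  rep_ <- disagreement_report(annA, annB, list(d = doc))
  # "vomiting": A's mention overlaps B's same-class mention -> boundary
  expect_identical(rep_$boundary, 1L)
  # "fever": both annotate, different classes -> category
  expect_identical(rep_$category, 1L)
  expect_identical(rep_$missed, 0L)
  expect_identical(rep_$total, 2L)
  # adding an unmatched mention produces missed tokens
  annC <- annotation_set("C", list(d = mentions(
    c("AdverseEvent", "Medication", "AdverseEvent", "Treatment"),
    c(0L, 16L, 36L, 27L), c(15L, 26L, 41L, 35L),
    c("nausea vomiting", "paclitaxel", "fever", "infusion"))))
  rep2 <- disagreement_report(annC, annB, list(d = doc))
  expect_identical(rep2$missed, 1L)
  # identical annotations disagree nowhere
  rep3 <- disagreement_report(annA, annA, list(d = doc))
  expect_identical(rep3$total, 0L)
})
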