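# Feature extraction: the seven families and their exact-ablation
# property.

test_that("affix features give lowercased 3/4-char prefixes and suffixes", {
  expect_identical(affix_features("paclitaxel"),
                   c("affix:pre3=pac", "affix:pre4=pacl",
                     "affix:suf3=xel", "affix:suf4=axel"))
  # short tokens contribute the whole token
  expect_identical(affix_features("mg"),
                   c("affix:pre3=mg", "affix:pre4=mg",
                     "affix:suf3=mg", "affix:suf4=mg"))
})

test_that("morphological features follow the character patterns", {
  expect_true("morph:is_capitalized" %in% morphological_features("Taxol"))
  expect_true("morph:is_digit" %in% morphological_features("280"))
  expect_true("morph:is_digit" %in% morphological_features("0.9%"))
  expect_true("morph:all_caps" %in% morphological_features("FAERS"))
  expect_true("morph:alnum=letters_digits" %in% morphological_features("T200"))
  expect_true("morph:alnum=digits_letters" %in% morphological_features("5mg"))
  expect_true("morph:has_hyphen" %in% morphological_features("G-CSF"))
  expect_true("morph:is_punct" %in% morphological_features(","))
  expect_identical(morphological_features("saline"), character(0))
})

test_that("default features carry word, shape and window context", {
  doc <- document("d", "Taxol 280 mg")
  f <- default_features(doc, window = 1L)
  expect_true(all(c("default:w=taxol", "default:shape=Xxxxx",
                    "default:w[+1]=280", "default:shape[+1]=ddd") %in% f[[1]]))
  expect_true(all(c("default:w[-1]=taxol", "default:w[+1]=mg") %in% f[[2]]))
  # window truncates at document edges: first token has no left context
  expect_false(any(startsWith(f[[1]], "default:w[-")))
})

test_that("semantic features mark match position B/I with the type code", {
  res <- test_resources()
  doc <- document("d", "history of bone marrow suppression today")
  f <- semantic_features(doc, res$lexicon)
  idx <- which(doc$tokens$surface == "bone")
  expect_true("sem:type=T047" %in% f[[idx]])
  expect_true("sem:match_position=B" %in% f[[idx]])
  expect_true("sem:match_position=I" %in% f[[idx + 1L]])
  expect_identical(f[[1]], character(0))
})

test_that("negation scope runs forward to terminator, cap, or sentence end", {
  res <- test_resources()
  doc <- document("d", "Patient denies nausea but reported fever. Vomiting occurred.")
  f <- neghedge_features(doc, res$negation, res$hedge)
  toks <- doc$tokens$surface
  expect_true("neg:cue" %in% f[[which(toks == "denies")]])
  expect_true("neg:in_scope" %in% f[[which(toks == "nausea")]])
  # "but" is a terminator: scope stops before it
  expect_false("neg:in_scope" %in% f[[which(toks == "but")]])
  expect_false("neg:in_scope" %in% f[[which(toks == "fever")]])
  # scope never crosses a sentence boundary
  expect_false("neg:in_scope" %in% f[[which(toks == "Vomiting")]])
  # six-token cap
  doc2 <- document("d2", "no a b c d e f g h")
  f2 <- neghedge_features(doc2, res$negation, res$hedge)
  in_scope <- vapply(f2, function(x) "neg:in_scope" %in% x, logical(1))
  expect_identical(sum(in_scope), 6L)
})

test_that("connective features mark the cue token and its sentence", {
  res <- test_resources()
  doc <- document("d", "He was hospitalized due to nausea. Recovery followed.")
  f <- connective_features(doc, res$connective)
  toks <- doc$tokens$surface
  expect_true("conn:cue=due_to" %in% f[[which(toks == "due")]])
  expect_true("conn:present" %in% f[[which(toks == "hospitalized")]])
  expect_false("conn:present" %in% f[[which(toks == "Recovery")]])
})

test_that("syntactic features expose POS, phrase and left POS", {
  res <- test_resources()
  doc <- document("d", "A female patient died. She recovered.")
  f <- syntactic_features(doc, res$pos_annotator)
  expect_true("pos:pos=DT" %in% f[[1]])
  expect_true("pos:left_pos=NONE" %in% f[[1]])
  expect_true("pos:pos=JJ" %in% f[[2]])
  expect_true("pos:left_pos=DT" %in% f[[2]])
  expect_true("pos:phrase=NP" %in% f[[3]])
  # sentence start resets left POS
  she <- which(doc$tokens$surface == "She")
  expect_true("pos:left_pos=NONE" %in% f[[she]])
})

test_that("disabling a family removes exactly its features", {
  res <- test_resources()
  doc <- document("d", "Patient denies nausea after Taxol 280 mg due to cancer.")
  all_f <- extract_features(doc, all_features_config(), res)
  no_affix <- extract_features(doc,
    feature_config(c("default", "connective", "morphological", "neghedge",
                     "semantic", "syntactic")), res)
  for (t in seq_along(all_f)) {
    expect_setequal(setdiff(all_f[[t]], no_affix[[t]]),
                    all_f[[t]][startsWith(all_f[[t]], "affix:")])
    expect_true(all(no_affix[[t]] %in% all_f[[t]]))
  }
  # default family is always present
  cfg <- feature_config("semantic")
  expect_true("default" %in% cfg$families)
  only_def <- extract_features(doc, feature_config(), res)
  expect_true(all(vapply(only_def, function(f)
    all(startsWith(f, "default:")), logical(1))))
})

test_that("feature vectors are sorted and duplicate-free; resources checked", {
  res <- test_resources()
  doc <- document("d", "no nausea no nausea")
  f <- extract_features(doc, all_features_config(), res)
  for (t in seq_along(f)) {
    expect_identical(f[[t]], sort(unique(f[[t]])))
  }
  expect_error(extract_features(doc, feature_config(c("default", "semantic")),
                                resources = NULL), "resource missing")
  expect_error(feature_config("bogus"), "unknown feature family")
})
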