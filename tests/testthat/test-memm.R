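ng_fix <- default_ngram_model()

test_that("feature extraction is deterministic and covers the templates", {
  seq <- tokenise("benzene", 0)
  f <- extract_features(seq, 1, ng_fix)
  expect_true("s3=ene" %in% f)
  expect_true("prev:w=BOS" %in% f)
  expect_true("next:w=EOS" %in% f)
  expect_true("w=benzene" %in% f)
  expect_identical(f, extract_features(seq, 1, ng_fix))
  expect_error(extract_features(seq, 2, ng_fix))

  seq <- tokenise("C-H", 0)
  expect_true("shape=A-A" %in% extract_features(seq, 1, ng_fix))

  seq <- tokenise("one two three", 0)
  f2 <- extract_features(seq, 2, ng_fix)
  expect_true("prev:w=one" %in% f2)
  expect_true("next:w=three" %in% f2)
  expect_true(any(grepl("^ngb=", f2)))
})

test_that("gold spans must align with token boundaries", {
  expect_error(annotated_document("benzene here",
                                  list(named_entity("enz", "CM", 1, 4))),
               "align")
  doc <- annotated_document("benzene here",
                            list(named_entity("benzene", "CM", 0, 7)))
  expect_equal(chemtext:::bio_labels(doc$sequences[[1]], doc$entities),
               c("B-CM", "O"))
  expect_error(annotated_document("aa bb cc",
                                  list(named_entity("aa bb", "CM", 0, 5),
                                       named_entity("bb", "RN", 3, 5))),
               "overlap")
})

test_that("an all-outside corpus decodes everything as outside", {
  set.seed(61)
  spec <- corpus_spec(n_sentences = 40, entity_rate = 0, seed = 3)
  corpus <- generate_corpus(spec)
  expect_true(all(vapply(corpus, function(d)
    length(d$entities) == 0, logical(1))))
  model <- memm_train(corpus, ng_fix, max_iter = 50)
  for (d in corpus[1:10]) {
    for (s in d$sequences) {
      expect_equal(memm_decode(s, model, ng_fix), list())
    }
  }
})

test_that("training reaches a better objective than the zero model", {
  spec <- corpus_spec(n_sentences = 60, seed = 4)
  corpus <- generate_corpus(spec)
  model <- memm_train(corpus, ng_fix, max_iter = 80)
  n_inst <- sum(vapply(corpus, function(d)
    sum(vapply(d$sequences, function(s) length(s$tokens), integer(1))),
    integer(1)))
  # objective at w = 0 is n log 9; the optimum of the convex problem is
  # below it, and the optimiser must not end above its own start
  expect_lt(model$value, n_inst * log(9))
})

test_that("Viterbi equals exhaustive enumeration on short sequences", {
  set.seed(62)
  words <- c("benzene", "house", "ethanol", "methylase", "oxidation",
             "acidic", "the", "C-H")
  for (rep in 1:25) {
    L <- sample(2:5, 1)
    seq <- random_sentence_seq(words, L)
    L <- length(seq$tokens)
    model <- random_memm_model(list(seq), ng_fix)
    logP <- chemtext:::memm_conditionals(seq, model, ng_fix)
    enum <- enumerate_paths(logP, L)
    best <- enum$paths[which.max(enum$logp), ]
    expect_equal(unname(chemtext:::viterbi_path(logP, L)), unname(best))
    # every decoded I label follows a same-class B or I
    labs <- memm_labels()[chemtext:::viterbi_path(logP, L)]
    for (i in seq_along(labs)) {
      if (startsWith(labs[i], "I-")) {
        cls <- sub("I-", "", labs[i])
        expect_true(i > 1 && labs[i - 1] %in% paste0(c("B-", "I-"), cls))
      }
    }
  }
})

test_that("entity confidences equal the enumeration-based constrained ratio", {
  set.seed(63)
  words <- c("benzene", "house", "ethanol", "methylase", "oxidation")
  checked <- 0
  for (rep in 1:25) {
    seq <- random_sentence_seq(words, sample(2:5, 1))
    L <- length(seq$tokens)
    model <- random_memm_model(list(seq), ng_fix)
    logP <- chemtext:::memm_conditionals(seq, model, ng_fix)
    enum <- enumerate_paths(logP, L)
    total <- sum(exp(enum$logp))
    starts <- vapply(seq$tokens, `[[`, integer(1), "start")
    ends <- vapply(seq$tokens, `[[`, integer(1), "end")
    for (e in memm_decode(seq, model, ng_fix)) {
      i <- match(e$start, starts); j <- match(e$end, ends)
      span_labels <- match(c(paste0("B-", e$type),
                             rep(paste0("I-", e$type), j - i)),
                           memm_labels())
      keep <- rep(TRUE, nrow(enum$paths))
      for (k in i:j) keep <- keep & enum$paths[, k] == span_labels[k - i + 1]
      expect_equal(e$confidence, sum(exp(enum$logp[keep])) / total,
                   tolerance = 1e-9)
      expect_gte(e$confidence, 0)
      expect_lte(e$confidence, 1)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 10)
})

test_that("the tagger recovers a single-suffix entity rule perfectly", {
  spec <- corpus_spec(n_sentences = 150, suffixes = "ol",
                      class_mix = c(CM = 1, RN = 0, CJ = 0, ASE = 0),
                      multi_rate = 0, seed = 5)
  corpus <- generate_corpus(spec)
  ng <- ngram_train(generate_word_lists(spec))
  model <- memm_train(corpus[1:120], ng)
  pred <- list(); gold <- list()
  for (d in corpus[121:150]) {
    for (s in d$sequences) pred <- c(pred, memm_decode(s, model, ng))
    gold <- c(gold, d$entities)
  }
  expect_equal(unname(entity_scores(pred, gold)["f1"]), 1.0)
})

test_that("models persist through JSON and refuse mismatched templates", {
  spec <- corpus_spec(n_sentences = 30, seed = 6)
  corpus <- generate_corpus(spec)
  model <- memm_train(corpus, ng_fix, max_iter = 60)
  path <- withr::local_tempfile(fileext = ".json")
  write_memm_model(model, path)
  model2 <- read_memm_model(path)
  for (d in corpus[1:5]) {
    for (s in d$sequences) {
      a <- memm_decode(s, model, ng_fix)
      b <- memm_decode(s, model2, ng_fix)
      expect_equal(to_standoff(a), to_standoff(b), tolerance = 1e-8)
    }
  }
  model2$template_version <- "ft0"
  expect_error(memm_decode(corpus[[1]]$sequences[[1]], model2, ng_fix),
               "template")
})
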