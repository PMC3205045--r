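pl_fix <- chem_pipeline()

test_that("the default pipeline finds the worked multi-token chemical", {
  expect_equal(findNamedEntities(pl_fix, ""), list())
  ents <- findNamedEntities(pl_fix, "Stirred in ethyl acetate overnight.")
  cms <- Filter(function(e) e$type == "CM", ents)
  expect_length(cms, 1)
  expect_equal(cms[[1]]$surface, "ethyl acetate")
  expect_equal(c(cms[[1]]$start, cms[[1]]$end), c(11L, 24L))
})

test_that("resolvable entities are exactly the dictionary hits", {
  rs <- findResolvableEntities(pl_fix, "benzene and the methyl ester")
  expect_length(rs, 1)
  expect_equal(rs[[1]]$entity$surface, "benzene")
  expect_gte(length(rs[[1]]$structures), 1)

  empty_reg <- set_component(pl_fix, "registry", dictionary_registry())
  expect_equal(findResolvableEntities(empty_reg,
                                      "benzene and the methyl ester"),
               list())
})

test_that("resolution preserves spans and partitions the entity list", {
  texts <- c("Stirred in ethyl acetate overnight.",
             "benzene and the methyl ester",
             "toluene, water and unknownol",
             "the melting point of 2,5-dichlorobenzylamine")
  for (text in texts) {
    plain <- findNamedEntities(pl_fix, text)
    both <- findAndResolveNamedEntities(pl_fix, text)
    spans <- function(es) vapply(es, function(e)
      paste(e$start, e$end), character(1))
    got <- c(spans(lapply(both$resolved, `[[`, "entity")),
             spans(both$unresolved))
    expect_setequal(got, spans(plain))
    resolvable <- findResolvableEntities(pl_fix, text)
    expect_equal(spans(lapply(resolvable, `[[`, "entity")),
                 spans(lapply(both$resolved, `[[`, "entity")))
  }
})

test_that("overlap policy: longer span, then type priority, then confidence", {
  e <- function(type, s, en, conf = NA) named_entity(
    strrep("x", en - s), type, s, en, conf)
  # longer span wins
  m <- merge_entities(list(e("CM", 0, 13), e("ONT", 6, 13)))
  expect_length(m, 1)
  expect_equal(m[[1]]$type, "CM")
  m <- merge_entities(list(e("ONT", 0, 13), e("CM", 6, 13)))
  expect_equal(m[[1]]$type, "ONT")
  # CM beats ONT on equal spans
  m <- merge_entities(list(e("ONT", 0, 13), e("CM", 0, 13)))
  expect_equal(vapply(m, `[[`, character(1), "type"), "CM")
  # confidence breaks remaining ties
  m <- merge_entities(list(e("CM", 0, 5, 0.4), e("CM", 0, 5, 0.9)))
  expect_equal(m[[1]]$confidence, 0.9)
  # non-overlapping candidates all survive, sorted by start
  m <- merge_entities(list(e("CM", 10, 15), e("ONT", 0, 5)))
  expect_equal(vapply(m, `[[`, integer(1), "start"), c(0L, 10L))
})

test_that("prefixes abutting or inside chemicals are suppressed", {
  e <- function(type, s, en) named_entity(strrep("x", en - s), type, s, en)
  m <- merge_entities(list(e("CM", 0, 23), e("CPR", 0, 4)))
  expect_equal(vapply(m, `[[`, character(1), "type"), "CM")
  m <- merge_entities(list(e("CM", 4, 10), e("CPR", 0, 4)))
  expect_equal(vapply(m, `[[`, character(1), "type"), "CM")
  m <- merge_entities(list(e("CM", 6, 10), e("CPR", 0, 4)))
  expect_setequal(vapply(m, `[[`, character(1), "type"), c("CM", "CPR"))
})

test_that("merging is idempotent and deterministic", {
  set.seed(81)
  for (rep in 1:25) {
    cand <- random_entities(sample(2:10, 1), text_len = 60)
    once <- merge_entities(cand)
    expect_equal(merge_entities(once), once)
    expect_equal(merge_entities(cand), once)
    if (length(once) > 1) {
      for (i in 2:length(once)) {
        expect_false(entities_overlap(once[[i - 1]], once[[i]]))
      }
    }
  }
})

test_that("component swaps are local and validated", {
  text <- "treated with NSC-2648 overnight"
  # a conservative pattern pipeline does not flag the serial number ...
  strict <- set_component(pl_fix, "patterns",
                          pattern_config(threshold = 0.95))
  before <- findNamedEntities(strict, text)
  expect_false("NSC-2648" %in% vapply(before, `[[`, character(1),
                                      "surface"))
  # ... the regex recogniser, swapped in, does
  swapped <- set_component(strict, "recogniser", "regex")
  after <- findNamedEntities(swapped, text)
  expect_true("NSC-2648" %in% vapply(after, `[[`, character(1), "surface"))
  # the original pipeline is untouched
  expect_equal(to_standoff(findNamedEntities(strict, text)),
               to_standoff(before))

  expect_error(set_component(pl_fix, "recogniser", "bogus"),
               "configuration")
  expect_error(set_component(pl_fix, "registry", "not a registry"),
               "configuration")
  bad_memm <- structure(list(template_version = "ft0"),
                        class = "memm_model")
  expect_error(set_component(pl_fix, "memm_model", bad_memm), "templates")
  expect_error(findNamedEntities(set_component(pl_fix, "recogniser",
                                               "memm"), "benzene"),
               "model")
})

test_that("two differently configured pipelines give independent results", {
  d_a <- chem_name_dict("benzene",
                        list(chemical_structure("SMILES", "c1ccccc1")), "a")
  d_b <- chem_name_dict("toluene",
                        list(chemical_structure("SMILES", "Cc1ccccc1")),
                        "b")
  p_a <- set_component(pl_fix, "registry",
                       dictionary_registry(list(d_a)))
  p_b <- set_component(pl_fix, "registry",
                       dictionary_registry(list(d_b)))
  text <- "benzene and toluene"
  # interleaved use: results match what each pipeline gives in isolation
  ra1 <- findResolvableEntities(p_a, text)
  rb1 <- findResolvableEntities(p_b, text)
  ra2 <- findResolvableEntities(p_a, text)
  rb2 <- findResolvableEntities(p_b, text)
  surf <- function(rs) vapply(rs, function(r) r$entity$surface,
                              character(1))
  expect_equal(surf(ra1), "benzene")
  expect_equal(surf(rb1), "toluene")
  expect_equal(surf(ra2), surf(ra1))
  expect_equal(surf(rb2), surf(rb1))
})

test_that("identical text and configuration give identical output", {
  text <- paste("Stirred in ethyl acetate overnight.",
                "The melting point of 2,5-dichlorobenzylamine rose.",
                sep = "\n\n")
  a <- to_standoff(findNamedEntities(pl_fix, text))
  b <- to_standoff(findNamedEntities(chem_pipeline(), text))
  expect_identical(a, b)
})

test_that("data annotations flow through the standoff channel as DATA", {
  text <- "benzene was pure. 1H NMR (400 MHz) δ 7.26 (s, 6H)."
  anns <- findData(pl_fix, text)
  expect_length(anns, 1)
  des <- data_annotation_entities(anns)
  expect_equal(des[[1]]$type, "DATA")
  expect_identical(substr(normalize_text(text), des[[1]]$start + 1,
                          des[[1]]$end), des[[1]]$surface)
})
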