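test_that("formula parsing and monoisotopic masses match hand sums", {
  f <- parse_formula("C7H8")
  expect_equal(unclass(f)[c("C", "H")], c(C = 7L, H = 8L))
  expect_error(parse_formula("C7Qq8"))
  expect_error(parse_formula(""))
  # 6 x 12 exactly plus 6 x 1.0078250 (lightest-isotope masses)
  expect_equal(monoisotopic_mass("C6H6"), 78.0470, tolerance = 1e-4)
  expect_equal(monoisotopic_mass("H2O"), 18.0106, tolerance = 1e-4)
  expect_error(monoisotopic_mass(structure(integer(),
                                           class = "chem_formula")))
})

test_that("mass is additive over formula union", {
  set.seed(71)
  els <- c("C", "H", "N", "O", "S", "Cl")
  for (rep in 1:20) {
    f1 <- setNames(sample.int(9, 4), sample(els, 4))
    f2 <- setNames(sample.int(9, 4), sample(els, 4))
    joint <- tapply(c(f1, f2), names(c(f1, f2)), sum)
    m12 <- monoisotopic_mass(structure(as.integer(joint),
                                       names = names(joint),
                                       class = "chem_formula"))
    m1 <- monoisotopic_mass(structure(f1, class = "chem_formula"))
    m2 <- monoisotopic_mass(structure(f2, class = "chem_formula"))
    expect_equal(m12, m1 + m2, tolerance = 1e-9)
  }
})

test_that("stylised NMR strings parse into peaks with offsets intact", {
  txt <- "1H NMR (400 MHz, CDCl3) δ 7.26 (s, 1H)."
  anns <- find_data(txt)
  expect_length(anns, 1)
  a <- anns[[1]]
  expect_equal(a$kind, "HNMR")
  expect_length(a$payload$peaks, 1)
  p <- a$payload$peaks[[1]]
  expect_equal(p$shift, 7.26)
  expect_equal(p$multiplicity, "s")
  expect_equal(p$integration, 1L)
  expect_identical(substr(normalize_text(txt), a$start + 1, a$end),
                   a$surface)

  expect_equal(find_data("no spectra here at all"), list())

  anns <- find_data("δ 2.36 (s, 3H), 7.26–7.17 (m, 5H)")
  peaks <- anns[[1]]$payload$peaks
  expect_length(peaks, 2)
  expect_equal(peaks[[1]]$shift, 2.36)
  expect_equal(peaks[[2]]$shift, c(7.26, 7.17))
  expect_equal(peaks[[2]]$multiplicity, "m")
  expect_equal(vapply(peaks, `[[`, integer(1), "integration"), c(3L, 5L))

  anns <- find_data("1H NMR (300 MHz) δ 3.71 (q, J = 7.1 Hz, 2H)")
  expect_equal(anns[[1]]$payload$peaks[[1]]$couplings, 7.1)
})

test_that("13C, HRMS and elemental strings are located and parsed", {
  txt <- paste("13C NMR (101 MHz, CDCl3) δ 137.8 (s), 21.4 (s).",
               "HRMS (EI) m/z calcd for C7H8 92.0626, found 92.0629.",
               "Anal. Calcd for C7H8: C, 91.25; H, 8.75.",
               "Found: C, 91.20; H, 8.80.")
  anns <- find_data(txt)
  kinds <- vapply(anns, `[[`, character(1), "kind")
  expect_setequal(kinds, c("CNMR", "HRMS", "ELEMENTAL"))
  hrms <- anns[[which(kinds == "HRMS")]]
  expect_equal(hrms$payload$formula, "C7H8")
  expect_equal(hrms$payload$calcd, 92.0626)
  expect_equal(hrms$payload$found, 92.0629)
  elem <- anns[[which(kinds == "ELEMENTAL")]]
  expect_equal(elem$payload$calcd, c(C = 91.25, H = 8.75))
  expect_equal(elem$payload$found, c(C = 91.20, H = 8.80))
  starts <- vapply(anns, `[[`, integer(1), "start")
  ends <- vapply(anns, `[[`, integer(1), "end")
  ord <- order(starts)
  expect_true(all(starts[ord][-1] >= ends[ord][-length(ends)]))
})

test_that("random peak lists round-trip through render and parse", {
  set.seed(72)
  mults <- c("s", "d", "t", "q", "m", "dd", "br")
  for (rep in 1:60) {
    k <- sample(1:5, 1)
    peaks <- lapply(seq_len(k), function(i) {
      shift <- sample.int(1200, 1) / 100
      if (runif(1) < 0.25) shift <- c(shift + 0.10, shift)
      nmr_peak(shift, sample(mults, 1),
               integration = sample.int(9, 1),
               couplings = if (runif(1) < 0.3)
                 sample.int(150, sample(1:2, 1)) / 10 else numeric())
    })
    text <- paste0("1H NMR (400 MHz, CDCl3) δ ", render_peaks(peaks), ".")
    anns <- find_data(text)
    expect_length(anns, 1)
    expect_equal(anns[[1]]$payload$peaks, peaks, info = text)
  }
})

test_that("integral consistency checks count protons exactly", {
  good <- find_data("1H NMR (400 MHz) δ 7.20 (m, 5H), 2.34 (s, 3H)")[[1]]
  rep <- check_consistency(good, "C7H8")
  expect_true(rep[[1]]$passed)
  expect_equal(rep[[1]]$observed, 8L)

  bad <- find_data("1H NMR (400 MHz) δ 7.20 (m, 5H), 2.34 (s, 2H)")[[1]]
  rep <- check_consistency(bad, "C7H8")
  expect_false(rep[[1]]$passed)
  expect_equal(rep[[1]]$observed, 7L)
  expect_equal(rep[[1]]$expected, 8L)
})

test_that("HRMS checks compare printed values against computed masses", {
  ann <- find_data("HRMS calcd for C6H6 78.0470, found 78.0473")[[1]]
  reps <- check_consistency(ann, "C6H6")
  expect_true(reps[[1]]$passed)   # printed calcd vs monoisotopic, 5 mDa
  expect_true(reps[[2]]$passed)   # found vs calcd, 5 ppm

  ann <- find_data("HRMS calcd for C6H6 78.0570, found 78.0473")[[1]]
  reps <- check_consistency(ann, "C6H6")
  expect_false(reps[[1]]$passed)

  ann <- find_data("HRMS calcd for C6H6 78.0470, found 78.0480")[[1]]
  reps <- check_consistency(ann, "C6H6")
  expect_false(reps[[2]]$passed)  # 12.8 ppm off
})

test_that("elemental analysis percents check against average weights", {
  ann <- find_data(
    "Anal. Calcd for C7H8: C, 91.25; H, 8.75. Found: C, 91.02; H, 8.70.")[[1]]
  reps <- check_consistency(ann, "C7H8")
  expect_true(all(vapply(reps, `[[`, logical(1), "passed")))

  ann <- find_data(
    "Anal. Calcd for C7H8: C, 90.00; H, 8.75. Found: C, 91.20; H, 8.70.")[[1]]
  reps <- check_consistency(ann, "C7H8")
  fails <- vapply(reps, function(r) !r$passed, logical(1))
  expect_equal(sum(fails), 1)  # only the misprinted calcd C value
})

test_that("unparsed spans are skipped, not failed", {
  anns <- find_data("1H NMR (400 MHz, CDCl3) δ nothing useful follows")
  expect_length(anns, 1)
  expect_false(anns[[1]]$parsed)
  reps <- check_consistency(anns[[1]], "C7H8")
  expect_true(is.na(reps[[1]]$passed))
})
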