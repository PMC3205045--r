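DATA_KINDS <- c("HNMR", "CNMR", "HRMS", "ELEMENTAL")

atomic_mass_env <- new.env(parent = emptyenv())

atomic_masses <- function() {
  if (is.null(atomic_mass_env$tab)) {
    path <- system.file("extdata", "atomic_masses.csv", package = "chemtext",
                        mustWork = TRUE)
    atomic_mass_env$tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  atomic_mass_env$tab
}

#' Parse a Hill-order molecular formula
#'
#' @param formula Formula string such as \code{"C7H8"} or \code{"C7H7NaO2"};
#'   element symbols from the packaged atomic-mass table, counts default 1.
#' @return Named integer vector of element counts (class
#'   \code{"chem_formula"}).
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  pieces <- regmatches(formula, list(m))[[1]]
  if (!length(pieces) || sum(nchar(pieces)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  counts <- integer()
  for (p in pieces) {
    el <- gsub("[0-9]", "", p)
    k <- gsub("[^0-9]", "", p)
    k <- if (nzchar(k)) as.integer(k) else 1L
    if (!el %in% atomic_masses()$element)
      stop("unknown element in formula: ", el)
    counts[el] <- (if (is.na(counts[el])) 0L else counts[el]) + k
  }
  structure(counts, class = "chem_formula")
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times the exact mass of the most abundant
#' isotope, from the packaged mass table.
#'
#' @param f A \code{\link{parse_formula}} result (or a formula string).
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  if (!length(f)) stop("empty formula")
  tab <- atomic_masses()
  masses <- tab$monoisotopic[match(names(f), tab$element)]
  if (anyNA(masses)) stop("unknown element: ",
                          paste(names(f)[is.na(masses)], collapse = ", "))
  sum(unclass(f) * masses)
}

# Average (relative atomic weight) mass, used for elemental-analysis percents.
average_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  tab <- atomic_masses()
  masses <- tab$average[match(names(f), tab$element)]
  if (anyNA(masses)) stop("unknown element: ",
                          paste(names(f)[is.na(masses)], collapse = ", "))
  sum(unclass(f) * masses)
}

#' Construct an NMR peak
#'
#' @param shift Chemical shift in ppm: a single value or a length-2
#'   decreasing range.
#' @param multiplicity Multiplicity token (s, d, t, q, m, dd, ...).
#' @param integration Proton count (1H spectra) or \code{NA}.
#' @param couplings Numeric vector of J values in Hz.
#' @return An object of class \code{"nmr_peak"}.
#' @export
nmr_peak <- function(shift, multiplicity = "m", integration = NA_integer_,
                     couplings = numeric()) {
  stopifnot(length(shift) %in% 1:2, all(is.finite(shift)),
            is.na(integration) || integration >= 1)
  structure(list(shift = as.numeric(shift), multiplicity = multiplicity,
                 integration = as.integer(integration),
                 couplings = as.numeric(couplings)),
            class = "nmr_peak")
}

data_annotation <- function(kind, start, end, surface, payload,
                            parsed = TRUE) {
  kind <- match.arg(kind, DATA_KINDS)
  structure(list(kind = kind, start = as.integer(start),
                 end = as.integer(end), surface = surface,
                 payload = payload, parsed = parsed),
            class = "chem_data_annotation")
}

#' @export
print.chem_data_annotation <- function(x, ...) {
  cat(sprintf("<%s annotation [%d,%d)%s>\n  %s\n", x$kind, x$start, x$end,
              if (x$parsed) "" else " (unparsed)", x$surface))
  invisible(x)
}

NUM_RX <- "\\d+(?:\\.\\d+)?"
PEAK_RX <- paste0(
  "(", NUM_RX, ")(?:\\s*[–-]\\s*(", NUM_RX, "))?\\s*",
  "\\(\\s*([a-z]+)",
  "(?:,\\s*J\\s*=\\s*(", NUM_RX, "(?:,\\s*", NUM_RX, ")*)\\s*Hz)?",
  "(?:,\\s*(\\d+)\\s*H)?\\s*\\)")

HNMR_CUE_RX <- "(?:¹H|1\\s*H)\\s*NMR(?:\\s*\\([^)]*\\))?\\s*:?\\s*δ"
CNMR_CUE_RX <- "(?:¹³C|13\\s*C)\\s*NMR(?:\\s*\\([^)]*\\))?\\s*:?\\s*δ"
HRMS_RX <- paste0(
  "HRMS[^.;]*?[Cc]alcd\\.?\\s+for\\s+([A-Za-z0-9]+)",
  "\\s*((?:\\[[^\\]]+\\])?[+−-]?)[:,]?\\s+(", NUM_RX, ")[,;]?\\s+",
  "[Ff]ound:?\\s*(", NUM_RX, ")")
ELEM_PAIR_RX <- "([A-Z][a-z]?),\\s*(\\d+\\.\\d+)"
ELEM_RX <- paste0(
  "Anal\\.?\\s+[Cc]alcd\\.?\\s+for\\s+([A-Za-z0-9]+)\\s*:\\s*",
  "((?:[A-Z][a-z]?,\\s*\\d+\\.\\d+[;,]\\s*)*[A-Z][a-z]?,\\s*\\d+\\.\\d+)",
  "\\.?\\s+[Ff]ound:?\\s*",
  "((?:[A-Z][a-z]?,\\s*\\d+\\.\\d+[;,]\\s*)*[A-Z][a-z]?,\\s*\\d+\\.\\d+)")

parse_peak_match <- function(g, with_integration = TRUE) {
  shift <- as.numeric(g[1])
  if (!is.na(g[2]) && nzchar(g[2])) shift <- c(shift, as.numeric(g[2]))
  couplings <- if (!is.na(g[4]) && nzchar(g[4]))
    as.numeric(strsplit(g[4], ",\\s*")[[1]]) else numeric()
  integ <- if (with_integration && !is.na(g[5]) && nzchar(g[5]))
    as.integer(g[5]) else NA_integer_
  nmr_peak(shift, g[3], integ, couplings)
}

# Match a comma-separated peak list starting at 1-based position `at` in
# `text`; returns list(peaks=, end=) with `end` the 1-based index of the
# last consumed character (0 when nothing matched).
match_peak_list <- function(text, at) {
  peaks <- list()
  pos <- at
  last_end <- 0L
  repeat {
    rest <- substr(text, pos, nchar(text))
    m <- regexpr(paste0("^\\s*", PEAK_RX), rest, perl = TRUE)
    if (m == -1L) break
    g <- peak_groups(rest, m)
    peaks[[length(peaks) + 1L]] <- parse_peak_match(g)
    pos <- pos + attr(m, "match.length")
    last_end <- pos - 1L
    sep <- regexpr("^,", substr(text, pos, nchar(text)))
    if (sep == -1L) break
    pos <- pos + 1L
  }
  list(peaks = peaks, end = last_end)
}

peak_groups <- function(s, m) {
  st <- attr(m, "capture.start"); len <- attr(m, "capture.length")
  vapply(seq_along(st), function(k)
    if (st[k] > 0) substr(s, st[k], st[k] + len[k] - 1L) else "",
    character(1))
}

regexpr_groups <- function(rx, s) {
  m <- regexpr(rx, s, perl = TRUE)
  if (m == -1L) return(NULL)
  st <- attr(m, "capture.start"); len <- attr(m, "capture.length")
  list(start = as.integer(m), end = as.integer(m) +
         attr(m, "match.length") - 1L,
       groups = vapply(seq_along(st), function(k)
         if (st[k] > 0) substr(s, st[k], st[k] + len[k] - 1L) else "",
         character(1)))
}

parse_elem_pairs <- function(s) {
  ms <- gregexpr(ELEM_PAIR_RX, s, perl = TRUE)[[1]]
  hits <- regmatches(s, list(ms))[[1]]
  out <- numeric()
  for (h in hits) {
    el <- sub(ELEM_PAIR_RX, "\\1", h, perl = TRUE)
    out[el] <- as.numeric(sub(ELEM_PAIR_RX, "\\2", h, perl = TRUE))
  }
  out
}

find_nmr_annotations <- function(text, cue_rx, kind) {
  out <- list()
  offset <- 0L
  repeat {
    rest <- substr(text, offset + 1L, nchar(text))
    m <- regexpr(cue_rx, rest, perl = TRUE)
    if (m == -1L) break
    cue_start <- offset + as.integer(m)              # 1-based in text
    cue_end <- cue_start + attr(m, "match.length") - 1L
    pl <- match_peak_list(text, cue_end + 1L)
    if (length(pl$peaks)) {
      if (kind == "CNMR") {
        pl$peaks <- lapply(pl$peaks, function(p) {
          p$integration <- NA_integer_; p
        })
      }
      out[[length(out) + 1L]] <- data_annotation(
        kind, cue_start - 1L, pl$end,
        substr(text, cue_start, pl$end), list(peaks = pl$peaks))
      offset <- pl$end
    } else {
      out[[length(out) + 1L]] <- data_annotation(
        kind, cue_start - 1L, cue_end,
        substr(text, cue_start, cue_end), NULL, parsed = FALSE)
      offset <- cue_end
    }
  }
  out
}

#' Locate and parse stylised experimental data
#'
#' Scans plain text for journal-style experimental-data strings — 1H NMR
#' and 13C NMR peak lists, HRMS "calcd for ... found ..." lines and
#' elemental analyses ("Anal. Calcd for ...: ... Found: ...") — using
#' data-driven grammars. Located spans whose interior fails to parse are
#' returned flagged \code{parsed = FALSE} rather than raising an error.
#' Returned annotations are non-overlapping and sorted by start offset.
#'
#' @param text Document text.
#' @return List of \code{"chem_data_annotation"} objects. NMR payloads hold
#'   \code{peaks} (a list of \code{\link{nmr_peak}}); HRMS payloads hold
#'   \code{formula}, \code{ion}, \code{calcd}, \code{found}; elemental
#'   payloads hold \code{formula}, \code{calcd}, \code{found} element-to-
#'   percent maps.
#' @export
find_data <- function(text) {
  text <- normalize_text(text)
  anns <- list()
  anns <- c(anns, find_nmr_annotations(text, HNMR_CUE_RX, "HNMR"))
  anns <- c(anns, find_nmr_annotations(text, CNMR_CUE_RX, "CNMR"))
  g <- regexpr_groups(HRMS_RX, text)
  if (!is.null(g)) {
    anns[[length(anns) + 1L]] <- data_annotation(
      "HRMS", g$start - 1L, g$end, substr(text, g$start, g$end),
      list(formula = g$groups[1], ion = g$groups[2],
           calcd = as.numeric(g$groups[3]),
           found = as.numeric(g$groups[4])))
  }
  g <- regexpr_groups(ELEM_RX, text)
  if (!is.null(g)) {
    anns[[length(anns) + 1L]] <- data_annotation(
      "ELEMENTAL", g$start - 1L, g$end, substr(text, g$start, g$end),
      list(formula = g$groups[1],
           calcd = parse_elem_pairs(g$groups[2]),
           found = parse_elem_pairs(g$groups[3])))
  }
  # bare delta peak lists (no explicit nucleus cue) count as 1H
  taken <- lapply(anns, function(a) c(a$start, a$end))
  covered <- function(s, e) any(vapply(taken, function(iv)
    max(iv[1], s) < min(iv[2], e), logical(1)))
  ds <- gregexpr("δ", text, fixed = TRUE)[[1]]
  if (ds[1] != -1L) for (d in ds) {
    pl <- match_peak_list(text, d + 1L)
    if (length(pl$peaks) && !covered(d - 1L, pl$end)) {
      anns[[length(anns) + 1L]] <- data_annotation(
        "HNMR", d - 1L, pl$end, substr(text, d, pl$end),
        list(peaks = pl$peaks))
      taken[[length(taken) + 1L]] <- c(d - 1L, pl$end)
    }
  }
  anns <- anns[order(vapply(anns, `[[`, integer(1), "start"))]
  keep <- rep(TRUE, length(anns))
  if (length(anns) > 1) for (i in 2:length(anns)) {
    prev_kept <- max(which(keep[1:(i - 1)]))
    if (anns[[i]]$start < anns[[prev_kept]]$end) keep[i] <- FALSE
  }
  anns[keep]
}

#' Render a peak list in journal style
#'
#' The inverse of the 1H NMR peak grammar: shifts to two decimals, ranges
#' with an en dash, couplings as \code{"J = x, y Hz"}, integrations as
#' \code{"nH"}. Rendering then re-parsing reproduces the peaks exactly.
#'
#' @param peaks List of \code{\link{nmr_peak}} objects.
#' @return Single string such as \code{"2.36 (s, 3H), 7.26–7.17 (m, 5H)"}.
#' @export
render_peaks <- function(peaks) {
  paste(vapply(peaks, function(p) {
    shift <- paste(sprintf("%.2f", p$shift), collapse = "–")
    inner <- p$multiplicity
    if (length(p$couplings))
      inner <- paste0(inner, ", J = ",
                      paste(sprintf("%.1f", p$couplings), collapse = ", "),
                      " Hz")
    if (!is.na(p$integration))
      inner <- paste0(inner, ", ", p$integration, "H")
    paste0(shift, " (", inner, ")")
  }, character(1)), collapse = ", ")
}

consistency_report <- function(check, passed, observed, expected,
                               tolerance) {
  structure(list(check = check, passed = passed, observed = observed,
                 expected = expected, tolerance = tolerance),
            class = "chem_consistency_report")
}

#' @export
print.chem_consistency_report <- function(x, ...) {
  verdict <- if (is.na(x$passed)) "SKIPPED"
             else if (x$passed) "PASS" else "FAIL"
  cat(sprintf("%-28s %s (observed %s, expected %s, tol %s)\n", x$check,
              verdict, format(x$observed), format(x$expected),
              format(x$tolerance)))
  invisible(x)
}

#' Check experimental data against a molecular formula
#'
#' 1H NMR: the sum of peak integrations must equal the formula's hydrogen
#' count exactly. HRMS: the printed calculated mass must agree with the
#' monoisotopic mass of the stated ion formula within \code{mass_da} Da, and
#' the found mass with the printed calculated mass within \code{ppm} parts
#' per million. Elemental analysis: mass percents computed from the stated
#' formula (average atomic weights) must agree with each printed value
#' within \code{percent} points. Unparsed annotations yield a single skipped
#' report, never a failure.
#'
#' @param ann A \code{"chem_data_annotation"} from \code{\link{find_data}}.
#' @param f A \code{\link{parse_formula}} result (or formula string) for the
#'   compound; HRMS and elemental checks prefer the formula printed in the
#'   data string itself.
#' @param tolerances List with elements \code{mass_da} (default 0.005),
#'   \code{ppm} (default 5), \code{percent} (default 0.4).
#' @return List of \code{"chem_consistency_report"} objects.
#' @export
check_consistency <- function(ann, f,
                              tolerances = list(mass_da = 0.005, ppm = 5,
                                                percent = 0.4)) {
  stopifnot(inherits(ann, "chem_data_annotation"))
  if (is.character(f)) f <- parse_formula(f)
  if (!ann$parsed) {
    return(list(consistency_report("skipped_unparsed", NA, NA, NA, NA)))
  }
  out <- list()
  if (ann$kind == "HNMR") {
    integ <- vapply(ann$payload$peaks, `[[`, integer(1), "integration")
    observed <- sum(integ, na.rm = TRUE)
    expected <- if (!is.na(f["H"])) unname(f["H"]) else 0L
    out[[1]] <- consistency_report("hnmr_integration",
                                   observed == expected, observed, expected,
                                   0)
  } else if (ann$kind == "HRMS") {
    ion <- parse_formula(ann$payload$formula)
    calc <- monoisotopic_mass(ion)
    d1 <- abs(ann$payload$calcd - calc)
    out[[1]] <- consistency_report("hrms_calcd_mass",
                                   d1 <= tolerances$mass_da,
                                   ann$payload$calcd, calc,
                                   tolerances$mass_da)
    ppm <- abs(ann$payload$found - ann$payload$calcd) /
      ann$payload$calcd * 1e6
    out[[2]] <- consistency_report("hrms_found_ppm", ppm <= tolerances$ppm,
                                   ann$payload$found, ann$payload$calcd,
                                   tolerances$ppm)
  } else if (ann$kind == "ELEMENTAL") {
    ef <- tryCatch(parse_formula(ann$payload$formula), error = function(e) f)
    total <- average_mass(ef)
    tab <- atomic_masses()
    for (side in c("calcd", "found")) {
      printed <- ann$payload[[side]]
      for (el in names(printed)) {
        cnt <- if (!is.na(ef[el])) unname(ef[el]) else 0L
        expct <- cnt * tab$average[match(el, tab$element)] / total * 100
        out[[length(out) + 1L]] <- consistency_report(
          paste0("elemental_", side, "_", el),
          abs(printed[[el]] - expct) <= tolerances$percent,
          printed[[el]], round(expct, 2), tolerances$percent)
      }
    }
  } else {
    out[[1]] <- consistency_report("no_check_for_kind", NA, NA, NA, NA)
  }
  out
}
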