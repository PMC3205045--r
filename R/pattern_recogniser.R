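DEFAULT_PATTERNS <- list(c("*yl", "*ate"), c("*yl", "*ide"),
                         c("*ic", "acid"), c("*ium", "*ide"))

#' Pattern recogniser configuration
#'
#' A token counts as chemical when its \code{\link{p_chemical}} reaches
#' \code{threshold}; runs of consecutive chemical tokens are then scanned
#' against multi-token glob patterns such as \code{"*yl *ate"} (matching
#' e.g. "ethyl acetate").
#'
#' @param threshold Probability cutoff in (0,1); default 0.5.
#' @param patterns List of character vectors, one glob per token position;
#'   globs lower-case, \code{"*"} matches any (possibly empty) run.
#' @return An object of class \code{"pattern_config"}.
#' @export
pattern_config <- function(threshold = 0.5, patterns = DEFAULT_PATTERNS) {
  stopifnot(threshold > 0, threshold < 1, length(patterns) > 0)
  patterns <- lapply(patterns, function(p) {
    stopifnot(length(p) >= 1, all(nzchar(p)))
    tolower(p)
  })
  structure(list(threshold = threshold, patterns = patterns),
            class = "pattern_config")
}

#' Read a pattern file
#'
#' One pattern per line, token globs space-separated, e.g.
#' \code{"*yl *ate"}.
#'
#' @param path Path to a pattern file.
#' @param threshold Passed to \code{\link{pattern_config}}.
#' @return A \code{"pattern_config"}.
#' @export
read_patterns <- function(path, threshold = 0.5) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pattern_config(threshold, lapply(lines, function(l)
    strsplit(trimws(l), "\\s+")[[1]]))
}

#' Match a token surface against a glob
#'
#' \code{"*"} is the sole wildcard and matches any (possibly empty) character
#' run; matching is whole-token and case-folded.
#'
#' @param pattern Non-empty glob string.
#' @param surface Token text.
#' @return Logical.
#' @export
glob_matches <- function(pattern, surface) {
  stopifnot(nzchar(pattern))
  rx <- paste0("^", gsub("\\*", ".*", rx_escape_noglob(pattern)), "$")
  grepl(rx, tolower(surface), perl = TRUE)
}

# Escape regex metacharacters except "*", which stays for glob translation.
rx_escape_noglob <- function(s) {
  gsub("([.\\\\+?^$(){}\\[\\]|])", "\\\\\\1", s, perl = TRUE)
}

pattern_matches_at <- function(pattern, surfaces, j) {
  k <- length(pattern)
  if (j + k - 1L > length(surfaces)) return(FALSE)
  all(mapply(glob_matches, pattern, surfaces[j:(j + k - 1L)]))
}

#' Find chemical entities with the pattern recogniser
#'
#' Tokens scoring \code{p_chemical >= threshold} are marked chemical; within
#' each maximal run of consecutive chemical tokens, multi-token glob patterns
#' are matched leftmost-first, longest pattern winning at each position, and
#' each match becomes one CM entity. Chemical tokens not consumed by a
#' pattern become single-token CM entities. Entity confidence is the
#' geometric mean of member token probabilities; emitted entities never
#' overlap.
#'
#' @param seq A \code{\link{token_sequence}}.
#' @param model A trained \code{\link{ngram_train}} model.
#' @param config A \code{\link{pattern_config}}.
#' @return List of CM \code{\link{named_entity}} objects.
#' @export
pattern_find_entities <- function(seq, model, config = pattern_config()) {
  toks <- seq$tokens
  if (!length(toks)) return(list())
  surfaces <- token_surfaces(seq)
  p <- vapply(surfaces, function(s) p_chemical(model, s), numeric(1),
              USE.NAMES = FALSE)
  # pure punctuation can never head or join a chemical run
  chem <- p >= config$threshold & !vapply(surfaces, is_punct_token,
                                          logical(1), USE.NAMES = FALSE)
  pats <- config$patterns[order(-lengths(config$patterns))]
  out <- list()
  emit <- function(i, j) {
    conf <- exp(mean(log(p[i:j])))
    out[[length(out) + 1L]] <<-
      named_entity(slice_text(seq$text,
                              toks[[i]]$start - seq$offset,
                              toks[[j]]$end - seq$offset),
                   "CM", toks[[i]]$start, toks[[j]]$end, conf)
  }
  n <- length(toks)
  i <- 1L
  while (i <= n) {
    if (!chem[i]) { i <- i + 1L; next }
    run_end <- i
    while (run_end < n && chem[run_end + 1L]) run_end <- run_end + 1L
    j <- i
    while (j <= run_end) {
      matched <- FALSE
      for (pat in pats) {
        k <- length(pat)
        if (k > 1L && j + k - 1L <= run_end &&
            pattern_matches_at(pat, surfaces, j)) {
          emit(j, j + k - 1L)
          j <- j + k
          matched <- TRUE
          break
        }
      }
      if (!matched) {
        emit(j, j)
        j <- j + 1L
      }
    }
    i <- run_end + 1L
  }
  out
}
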