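#' Build chemical / non-chemical word lists
#'
#' The chemical list is the (lower-cased) chemical lexicon; the non-chemical
#' list is a standard English word list with every chemical word removed,
#' matching case-insensitively. Both lists must be non-empty after the
#' removal.
#'
#' @param chemical_lexicon Character vector of chemical words.
#' @param english_dictionary Character vector of English words.
#' @return An object of class \code{"word_lists"} with components
#'   \code{chemical} and \code{nonchemical} (disjoint sets).
#' @export
build_word_lists <- function(chemical_lexicon, english_dictionary) {
  stopifnot(length(chemical_lexicon) > 0, length(english_dictionary) > 0)
  chem <- unique(tolower(chemical_lexicon))
  nonchem <- setdiff(unique(tolower(english_dictionary)), chem)
  if (!length(chem)) stop("chemical word list is empty")
  if (!length(nonchem))
    stop("non-chemical word list is empty after removing chemical words")
  structure(list(chemical = chem, nonchemical = nonchem),
            class = "word_lists")
}

# Classifier-facing normalisation: case-fold, map subscript digits to ASCII,
# then map every digit to "0" so n-grams capture digit shape, not value.
ngram_normalise <- function(word) {
  gsub("[0-9]", "0", tolower(normalize_surface(word)))
}

# Pad with n-1 leading "^" and one trailing "$", return all length-n windows.
ngram_windows <- function(word, n) {
  padded <- paste0(strrep("^", n - 1L), word, "$")
  m <- nchar(padded)
  if (m < n) return(character())
  substring(padded, 1:(m - n + 1L), n:m)
}

count_windows <- function(words, n) {
  grams <- unlist(lapply(ngram_normalise(words), ngram_windows, n = n))
  if (!length(grams)) return(integer())
  tab <- table(grams)
  setNames(as.integer(tab), names(tab))
}

#' Train a character n-gram naive Bayes model
#'
#' Every word in each list is padded with \code{n-1} leading \code{"^"}
#' markers and one trailing \code{"$"} marker; each length-\code{n} window of
#' the padded word increments that class's count table. Scoring applies
#' additive smoothing with a shared unseen bucket.
#'
#' @param lists A \code{\link{build_word_lists}} result.
#' @param n N-gram order (default 4).
#' @param alpha Additive smoothing constant (> 0).
#' @param prior_chem Prior probability that a token is chemical, in (0,1).
#' @return An object of class \code{"ngram_model"}.
#' @export
ngram_train <- function(lists, n = 4L, alpha = 1.0, prior_chem = 0.5) {
  stopifnot(inherits(lists, "word_lists"), n >= 1, alpha > 0,
            prior_chem > 0, prior_chem < 1)
  chem_counts <- count_windows(lists$chemical, n)
  nonchem_counts <- count_windows(lists$nonchemical, n)
  structure(list(n = as.integer(n), alpha = alpha, prior_chem = prior_chem,
                 chem_counts = chem_counts, nonchem_counts = nonchem_counts,
                 chem_total = sum(chem_counts),
                 nonchem_total = sum(nonchem_counts),
                 vocab = length(union(names(chem_counts),
                                      names(nonchem_counts))) + 1L),
            class = "ngram_model")
}

#' @export
print.ngram_model <- function(x, ...) {
  cat(sprintf(
    "<ngram model: n=%d, %d chem / %d nonchem grams, alpha=%g, prior=%g>\n",
    x$n, length(x$chem_counts), length(x$nonchem_counts), x$alpha,
    x$prior_chem))
  invisible(x)
}

lookup_counts <- function(tab, grams) {
  v <- tab[grams]
  v[is.na(v)] <- 0L
  unname(v)
}

#' Log-likelihood-ratio score of a token
#'
#' Sums, over the token's padded n-gram windows, the difference of smoothed
#' class log-probabilities
#' \eqn{\log \hat P(g \mid chem) - \log \hat P(g \mid nonchem)} with
#' \eqn{\hat P(g \mid c) = (count_c(g)+\alpha) / (total_c+\alpha V)}, where
#' \eqn{V} counts the distinct n-grams seen in either class plus one unseen
#' bucket. Positive scores favour "chemical".
#'
#' @param model A trained \code{\link{ngram_train}} model.
#' @param token Non-empty token string.
#' @return Numeric log-likelihood ratio.
#' @export
ngram_score <- function(model, token) {
  stopifnot(inherits(model, "ngram_model"), nzchar(token))
  grams <- ngram_windows(ngram_normalise(token), model$n)
  cc <- lookup_counts(model$chem_counts, grams)
  nc <- lookup_counts(model$nonchem_counts, grams)
  V <- model$vocab
  sum(log((cc + model$alpha) / (model$chem_total + model$alpha * V)) -
      log((nc + model$alpha) / (model$nonchem_total + model$alpha * V)))
}

#' Probability that a token is chemical
#'
#' Logistic transform of the log-likelihood-ratio score offset by the prior
#' log-odds: \eqn{\sigma(score + logit(prior))}. Strictly increasing in the
#' score; equals the prior when the score is zero.
#'
#' @inheritParams ngram_score
#' @return Probability in (0,1).
#' @export
p_chemical <- function(model, token) {
  stats::plogis(ngram_score(model, token) + stats::qlogis(model$prior_chem))
}

#' Persist an n-gram model as JSON
#'
#' @param model A \code{\link{ngram_train}} model.
#' @param path Output path.
#' @export
write_ngram_model <- function(model, path) {
  jsonlite::write_json(
    list(n = model$n, alpha = model$alpha, prior_chem = model$prior_chem,
         chem_counts = as.list(model$chem_counts),
         nonchem_counts = as.list(model$nonchem_counts)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an n-gram model written by \code{\link{write_ngram_model}}
#'
#' @param path Input path.
#' @return An \code{"ngram_model"} object.
#' @export
read_ngram_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  chem <- setNames(as.integer(obj$chem_counts), names(obj$chem_counts))
  nonchem <- setNames(as.integer(obj$nonchem_counts),
                      names(obj$nonchem_counts))
  structure(list(n = as.integer(obj$n), alpha = obj$alpha,
                 prior_chem = obj$prior_chem,
                 chem_counts = chem, nonchem_counts = nonchem,
                 chem_total = sum(chem), nonchem_total = sum(nonchem),
                 vocab = length(union(names(chem), names(nonchem))) + 1L),
            class = "ngram_model")
}

#' Read a one-word-per-line word list file
#'
#' @param path Path to a plain text file, one word per line.
#' @return Character vector of words (blank lines dropped).
#' @export
read_word_list <- function(path) {
  w <- readLines(path, encoding = "UTF-8", warn = FALSE)
  w[nzchar(trimws(w))]
}
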