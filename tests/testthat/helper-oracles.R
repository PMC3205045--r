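# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths: plain loops, hash environments and
# enumeration instead of tables, vectorisation and dynamic programming.

# --- n-gram naive Bayes, direct-count ---------------------------------------

oracle_windows <- function(word, n) {
  w <- gsub("[0-9]", "0", tolower(word))
  padded <- paste0(paste(rep("^", n - 1), collapse = ""), w, "$")
  out <- character()
  for (i in seq_len(nchar(padded) - n + 1)) {
    out <- c(out, substr(padded, i, i + n - 1))
  }
  out
}

oracle_count_table <- function(words, n) {
  env <- new.env(parent = emptyenv())
  for (w in words) {
    for (g in oracle_windows(w, n)) {
      env[[g]] <- (if (is.null(env[[g]])) 0 else env[[g]]) + 1
    }
  }
  env
}

oracle_ngram_score <- function(chem_words, nonchem_words, token, n = 4,
                               alpha = 1) {
  ce <- oracle_count_table(chem_words, n)
  ne <- oracle_count_table(nonchem_words, n)
  V <- length(unique(c(ls(ce), ls(ne)))) + 1
  tc <- sum(unlist(as.list(ce)))
  tn <- sum(unlist(as.list(ne)))
  s <- 0
  for (g in oracle_windows(token, n)) {
    cc <- if (is.null(ce[[g]])) 0 else ce[[g]]
    nc <- if (is.null(ne[[g]])) 0 else ne[[g]]
    s <- s + log((cc + alpha) / (tc + alpha * V)) -
      log((nc + alpha) / (tn + alpha * V))
  }
  s
}

# --- ontology longest-leftmost, all-substring scan --------------------------

oracle_ontology_scan <- function(surfaces, lexicon) {
  norm <- function(x) gsub("\\s+", " ", trimws(tolower(x)))
  n <- length(surfaces)
  hits <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      key <- norm(paste(surfaces[i:j], collapse = " "))
      if (key %in% names(lexicon)) {
        hits[[length(hits) + 1]] <- list(i = i, j = j, key = key)
      }
    }
  }
  if (!length(hits)) return(list())
  ord <- order(vapply(hits, `[[`, numeric(1), "i"),
               -vapply(hits, `[[`, numeric(1), "j"))
  hits <- hits[ord]
  taken <- rep(FALSE, n)
  out <- list()
  for (h in hits) {
    if (!any(taken[h$i:h$j])) {
      taken[h$i:h$j] <- TRUE
      out[[length(out) + 1]] <- h
    }
  }
  out[order(vapply(out, `[[`, numeric(1), "i"))]
}

# --- locant-prefix reference regex ------------------------------------------

oracle_prefix_regex <- function(items, digits = TRUE) {
  esc <- function(s) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s)
  alts <- vapply(items[order(-nchar(items))], esc, character(1))
  if (digits) alts <- c(alts, "[0-9]+")
  item <- paste0("(?:", paste(alts, collapse = "|"), ")")
  paste0("^", item, "(?:,", item, ")*-")
}

oracle_prefix_accept_len <- function(rx, s) {
  m <- regexpr(rx, s, perl = TRUE)
  if (m == -1L) 0L else attr(m, "match.length")
}

# --- MEMM enumeration over all label paths ----------------------------------

# Builds a random MEMM model whose feature space covers the given sequences.
random_memm_model <- function(seqs, ngram_model, sd = 0.7) {
  labels <- memm_labels()
  feats <- unique(c(
    unlist(lapply(seqs, function(s)
      lapply(seq_along(s$tokens), function(i)
        extract_features(s, i, ngram_model)))),
    paste0("prev=", c("START", labels))))
  W <- matrix(rnorm(length(feats) * length(labels), sd = sd),
              length(feats), length(labels),
              dimnames = list(feats, labels))
  structure(list(weights = W,
                 feature_index = setNames(seq_along(feats), feats),
                 labels = labels, template_version = "ft1", l2 = 1),
            class = "memm_model")
}

# Log-probability of every label path, by exhaustive enumeration over the
# per-position conditional tables (paths: L-column matrix of label indices).
enumerate_paths <- function(logP, L, K = 9) {
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
  lp <- logP[cbind(1, 1, paths[, 1])]
  if (L > 1) {
    for (i in 2:L) {
      lp <- lp + logP[cbind(i, 1 + paths[, i - 1], paths[, i])]
    }
  }
  list(paths = paths, logp = lp)
}

# --- misc -------------------------------------------------------------------

random_sentence_seq <- function(words, L) {
  tokenise(paste(sample(words, L, replace = TRUE), collapse = " "), 0)
}

random_entities <- function(k, text_len = 200) {
  lapply(seq_len(k), function(i) {
    start <- sample.int(text_len, 1) - 1
    len <- sample.int(12, 1)
    named_entity(
      paste(sample(c(letters, LETTERS, 0:9), len, replace = TRUE),
            collapse = ""),
      sample(c("CM", "ONT", "RN", "CJ", "ASE", "CPR"), 1),
      start, start + len,
      if (runif(1) < 0.5) runif(1) else NA_real_,
      if (runif(1) < 0.3) paste0("ID:", sample.int(99, sample.int(3, 1)))
      else character())
  })
}

fixture_file <- function(name) {
  system.file("extdata", name, package = "chemtext", mustWork = TRUE)
}
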