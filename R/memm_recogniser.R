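MEMM_CLASSES <- c("CM", "RN", "CJ", "ASE")

MEMM_LABELS <- c("O",
                 as.vector(rbind(paste0("B-", MEMM_CLASSES),
                                 paste0("I-", MEMM_CLASSES))))

MEMM_TEMPLATE_VERSION <- "ft1"

#' Label alphabet of the sequence tagger
#'
#' Nine labels: \code{O} plus \code{B-t}/\code{I-t} for each of the four
#' entity classes CM, RN, CJ and ASE. \code{I-t} may only follow \code{B-t}
#' or \code{I-t}.
#'
#' @return Character vector of 9 labels.
#' @export
memm_labels <- function() MEMM_LABELS

word_shape <- function(w) {
  s <- gsub("[A-Z]", "A", w)
  s <- gsub("[a-z]", "a", s)
  s <- gsub("[0-9]", "0", s)
  gsub("(.)\\1+", "\\1", s)   # compress runs
}

is_punct_token <- function(w) {
  grepl("^[[:punct:]]+$", w)
}

char_trigrams <- function(w) {
  padded <- paste0("^", w, "$")
  m <- nchar(padded)
  if (m < 3) return(padded)
  substring(padded, 1:(m - 2), 3:m)
}

token_features <- function(surface, model) {
  lc <- tolower(normalize_surface(surface))
  n <- nchar(surface)
  f <- c(paste0("w=", surface),
         paste0("lc=", lc),
         paste0("shape=", word_shape(surface)))
  for (k in 1:4) {
    if (n >= k) {
      f <- c(f, paste0("p", k, "=", substr(lc, 1, k)),
             paste0("s", k, "=", substr(lc, n - k + 1, n)))
    }
  }
  f <- c(f, paste0("cg=", char_trigrams(lc)))
  p <- p_chemical(model, surface)
  f <- c(f, paste0("ngb=", min(floor(p * 10), 9)))
  if (is_punct_token(surface)) f <- c(f, "punct")
  f
}

#' Extract the feature set for one token position
#'
#' Features describe the token itself (exact and case-folded surface, word
#' shape with compressed A/a/0 runs, prefixes and suffixes of length 1-4,
#' character trigrams of the padded surface, the decile bucket of its
#' n-gram-model chemical probability, a punctuation flag) and its immediate
#' neighbours, whose features are prefixed \code{"prev:"} / \code{"next:"};
#' boundary positions use \code{BOS}/\code{EOS} pseudo-tokens that
#' contribute only their surface feature. Deterministic for a given
#' (sequence, position, model).
#'
#' @param seq A \code{\link{token_sequence}}.
#' @param i Token position (1-based).
#' @param ngram_model A trained \code{\link{ngram_train}} model.
#' @return Character vector of indicator feature names.
#' @export
extract_features <- function(seq, i, ngram_model) {
  toks <- seq$tokens
  if (i < 1L || i > length(toks)) stop("position out of range")
  f <- token_features(toks[[i]]$surface, ngram_model)
  prev <- if (i > 1L) paste0("prev:", token_features(toks[[i - 1L]]$surface,
                                                     ngram_model))
          else "prev:w=BOS"
  nxt <- if (i < length(toks))
           paste0("next:", token_features(toks[[i + 1L]]$surface,
                                          ngram_model))
         else "next:w=EOS"
  c(f, prev, nxt)
}

#' Assemble an annotated document
#'
#' Tokenises the text and checks that every gold span aligns with token
#' boundaries (a data error names the offending span otherwise) and that no
#' two gold spans overlap.
#'
#' @param text Document text.
#' @param entities List of gold \code{\link{named_entity}} spans (classes
#'   CM/RN/CJ/ASE).
#' @param config A \code{\link{tokeniser_config}}.
#' @return An object of class \code{"annotated_document"} with components
#'   \code{text}, \code{sequences}, \code{entities}.
#' @export
annotated_document <- function(text, entities,
                               config = tokeniser_config()) {
  text <- normalize_text(text)
  seqs <- tokenise_document(text, config)
  if (length(entities) > 1) {
    ivl <- cbind(vapply(entities, `[[`, integer(1), "start"),
                 vapply(entities, `[[`, integer(1), "end"))
    ivl <- ivl[order(ivl[, 1]), , drop = FALSE]
    if (any(ivl[-1, 1] < ivl[-nrow(ivl), 2]))
      stop("gold spans overlap")
  }
  for (e in entities) {
    aligned <- FALSE
    for (s in seqs) {
      starts <- vapply(s$tokens, `[[`, integer(1), "start")
      ends <- vapply(s$tokens, `[[`, integer(1), "end")
      if (e$start %in% starts && e$end %in% ends) { aligned <- TRUE; break }
    }
    if (!aligned)
      stop(sprintf("gold span [%d,%d) \"%s\" does not align with tokens",
                   e$start, e$end, e$surface))
  }
  structure(list(text = text, sequences = seqs, entities = entities),
            class = "annotated_document")
}

# BIO labels for one token sequence given gold entities.
bio_labels <- function(seq, entities) {
  starts <- vapply(seq$tokens, `[[`, integer(1), "start")
  ends <- vapply(seq$tokens, `[[`, integer(1), "end")
  lab <- rep("O", length(starts))
  for (e in entities) {
    if (e$start >= min(starts) && e$end <= max(ends)) {
      i <- match(e$start, starts)
      j <- match(e$end, ends)
      if (is.na(i) || is.na(j) || j < i) next
      lab[i] <- paste0("B-", e$type)
      if (j > i) lab[(i + 1L):j] <- paste0("I-", e$type)
    }
  }
  lab
}

# labels valid as successors of `prev` ("START" or a label).
allowed_next <- function(prev) {
  ok <- !startsWith(MEMM_LABELS, "I-")
  if (prev != "START" && prev != "O") {
    cls <- sub("^[BI]-", "", prev)
    ok[MEMM_LABELS == paste0("I-", cls)] <- TRUE
  }
  ok
}

#' Train a Maximum Entropy Markov Model
#'
#' Gold spans are converted to per-class B/I/O labels; each token position
#' yields one training instance whose features are the local features of
#' \code{\link{extract_features}} plus an indicator of the previous gold
#' label (\code{"prev=START"} at sequence start). A single multinomial
#' maximum-entropy classifier over the nine labels is fitted by maximising
#' the L2-regularised conditional log-likelihood with L-BFGS; the objective
#' is convex and optimisation starts from zero weights, so training is
#' deterministic.
#'
#' @param corpus List of \code{\link{annotated_document}} objects.
#' @param ngram_model A trained \code{\link{ngram_train}} model.
#' @param l2 L2 regularisation strength (default 1).
#' @param max_iter Maximum optimiser iterations (default 200).
#' @param seed Retained for API stability; training itself is deterministic.
#' @return An object of class \code{"memm_model"}.
#' @export
memm_train <- function(corpus, ngram_model, l2 = 1.0, max_iter = 200L,
                       seed = 1L) {
  stopifnot(length(corpus) > 0, l2 >= 0)
  feats <- list(); labs <- character()
  for (doc in corpus) {
    for (s in doc$sequences) {
      lab <- bio_labels(s, doc$entities)
      for (i in seq_along(s$tokens)) {
        prev <- if (i == 1L) "START" else lab[i - 1L]
        feats[[length(feats) + 1L]] <-
          unique(c(extract_features(s, i, ngram_model),
                   paste0("prev=", prev)))
        labs <- c(labs, lab[i])
      }
    }
  }
  all_feats <- sort(unique(c(unlist(feats),
                             paste0("prev=", c("START", MEMM_LABELS)))))
  fidx <- setNames(seq_along(all_feats), all_feats)
  N <- length(feats); F <- length(all_feats); L <- length(MEMM_LABELS)
  ii <- rep.int(seq_len(N), lengths(feats))
  jj <- fidx[unlist(feats)]
  X <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(N, F))
  y <- match(labs, MEMM_LABELS)
  Y <- Matrix::sparseMatrix(i = seq_len(N), j = y, x = 1, dims = c(N, L))
  objective <- function(w) {
    W <- matrix(w, F, L)
    S <- as.matrix(X %*% W)
    m <- apply(S, 1, max)
    lse <- m + log(rowSums(exp(S - m)))
    -sum(S[cbind(seq_len(N), y)] - lse) + l2 / 2 * sum(w^2)
  }
  gradient <- function(w) {
    W <- matrix(w, F, L)
    S <- as.matrix(X %*% W)
    m <- apply(S, 1, max)
    P <- exp(S - m)
    P <- P / rowSums(P)
    as.vector(as.matrix(Matrix::crossprod(X, P - Y))) + l2 * w
  }
  fit <- stats::optim(rep(0, F * L), objective, gradient,
                      method = "L-BFGS-B",
                      control = list(maxit = as.integer(max_iter)))
  structure(list(weights = matrix(fit$par, F, L,
                                  dimnames = list(all_feats, MEMM_LABELS)),
                 feature_index = fidx, labels = MEMM_LABELS,
                 template_version = MEMM_TEMPLATE_VERSION, l2 = l2,
                 converged = fit$convergence == 0, value = fit$value),
            class = "memm_model")
}

#' @export
print.memm_model <- function(x, ...) {
  cat(sprintf("<MEMM model: %d features x %d labels, templates %s, l2=%g>\n",
              nrow(x$weights), ncol(x$weights), x$template_version, x$l2))
  invisible(x)
}

# Conditional probability array for a sequence:
# logP[i, p, l] = log P(y_i = l | y_{i-1} = p, x_i), with the I-follows-B/I
# constraint applied as hard zeros (no renormalisation). prev index 1 is
# START (used only at i = 1), 2..10 are the labels.
memm_conditionals <- function(seq, model, ngram_model) {
  L <- length(seq$tokens); K <- length(MEMM_LABELS)
  W <- model$weights
  prevs <- c("START", MEMM_LABELS)
  logP <- array(-Inf, dim = c(max(L, 1L), K + 1L, K))
  for (i in seq_len(L)) {
    f <- unique(extract_features(seq, i, ngram_model))
    rows <- model$feature_index[f]
    rows <- rows[!is.na(rows)]
    base <- if (length(rows)) colSums(W[rows, , drop = FALSE]) else
      rep(0, K)
    for (p in seq_along(prevs)) {
      prow <- model$feature_index[paste0("prev=", prevs[p])]
      s <- base + if (!is.na(prow)) W[prow, ] else 0
      lp <- s - (max(s) + log(sum(exp(s - max(s)))))
      lp[!allowed_next(prevs[p])] <- -Inf
      logP[i, p, ] <- lp
    }
  }
  logP
}

# Viterbi over a conditional array; returns label index path.
viterbi_path <- function(logP, L) {
  K <- dim(logP)[3]
  if (L == 0L) return(integer())
  delta <- matrix(-Inf, L, K)
  back <- matrix(0L, L, K)
  delta[1, ] <- logP[1, 1, ]
  if (L > 1) for (i in 2:L) {
    for (l in seq_len(K)) {
      cand <- delta[i - 1, ] + logP[i, 1 + seq_len(K), l]
      back[i, l] <- which.max(cand)
      delta[i, l] <- cand[back[i, l]]
    }
  }
  path <- integer(L)
  path[L] <- which.max(delta[L, ])
  if (L > 1) for (i in L:2) path[i - 1] <- back[i, path[i]]
  path
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# Forward log-probability mass of all valid paths whose label at position i
# lies in allowed[[i]] (a set of label indices).
forward_log_mass <- function(logP, L, allowed = NULL) {
  K <- dim(logP)[3]
  if (L == 0L) return(0)
  a <- logP[1, 1, ]
  if (!is.null(allowed)) a[-allowed[[1]]] <- -Inf
  if (L > 1) for (i in 2:L) {
    nxt <- vapply(seq_len(K), function(l)
      log_sum_exp(a + logP[i, 1 + seq_len(K), l]), numeric(1))
    if (!is.null(allowed)) nxt[-allowed[[i]]] <- -Inf
    a <- nxt
  }
  log_sum_exp(a)
}

#' Decode a token sequence with a trained MEMM
#'
#' Viterbi decoding over the nine-label alphabet, honouring the constraint
#' that \code{I-t} may only follow \code{B-t} or \code{I-t}, returns the
#' maximum-probability label path; maximal \code{B-t (I-t)*} runs become
#' entities of class \code{t}. Each entity's confidence is the constrained
#' marginal probability of its labelled span: the probability mass of all
#' valid label paths agreeing with the span's labels, divided by the mass of
#' all valid paths, computed by constrained forward passes.
#'
#' @param seq A \code{\link{token_sequence}}.
#' @param model A \code{\link{memm_train}} model.
#' @param ngram_model The n-gram model used at training time.
#' @return List of \code{\link{named_entity}} objects with confidences.
#' @export
memm_decode <- function(seq, model, ngram_model) {
  stopifnot(inherits(model, "memm_model"))
  if (model$template_version != MEMM_TEMPLATE_VERSION)
    stop("feature-template version mismatch: model has ",
         model$template_version)
  L <- length(seq$tokens)
  if (L == 0L) return(list())
  logP <- memm_conditionals(seq, model, ngram_model)
  path <- viterbi_path(logP, L)
  labs <- MEMM_LABELS[path]
  logZ <- forward_log_mass(logP, L)
  out <- list()
  i <- 1L
  while (i <= L) {
    if (startsWith(labs[i], "B-")) {
      cls <- sub("^B-", "", labs[i])
      j <- i
      while (j < L && labs[j + 1L] == paste0("I-", cls)) j <- j + 1L
      allowed <- rep(list(seq_along(MEMM_LABELS)), L)
      for (k in i:j) allowed[[k]] <- match(labs[k], MEMM_LABELS)
      conf <- exp(forward_log_mass(logP, L, allowed) - logZ)
      toks <- seq$tokens
      out[[length(out) + 1L]] <- named_entity(
        slice_text(seq$text, toks[[i]]$start - seq$offset,
                   toks[[j]]$end - seq$offset),
        cls, toks[[i]]$start, toks[[j]]$end, min(max(conf, 0), 1))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

#' Write a trained MEMM model to JSON
#'
#' Weights are stored sparsely (only features with a non-zero weight for
#' some label), alongside the label alphabet, template version and
#' regularisation strength.
#'
#' @param model A \code{"memm_model"}.
#' @param path Output path.
#' @export
write_memm_model <- function(model, path) {
  nz <- which(rowSums(model$weights != 0) > 0)
  jsonlite::write_json(
    list(labels = model$labels, template_version = model$template_version,
         l2 = model$l2,
         features = rownames(model$weights)[nz],
         weights = unname(lapply(nz, function(r)
           unname(model$weights[r, ])))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a MEMM model written by \code{\link{write_memm_model}}
#'
#' @param path Input path.
#' @return A \code{"memm_model"}.
#' @export
read_memm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- if (is.matrix(obj$weights)) obj$weights
       else do.call(rbind, lapply(obj$weights, as.numeric))
  if (is.null(W)) W <- matrix(0, 0, length(obj$labels))
  dimnames(W) <- list(obj$features, obj$labels)
  structure(list(weights = W,
                 feature_index = setNames(seq_along(obj$features),
                                          obj$features),
                 labels = obj$labels,
                 template_version = obj$template_version, l2 = obj$l2,
                 converged = NA, value = NA_real_),
            class = "memm_model")
}

#' Entity-level precision, recall and F1
#'
#' An entity counts as correct when its type, start and end all match a gold
#' entity exactly.
#'
#' @param predicted,gold Lists of \code{\link{named_entity}} objects.
#' @return Named numeric vector \code{c(precision, recall, f1)}.
#' @export
entity_scores <- function(predicted, gold) {
  key <- function(es) vapply(es, function(e)
    paste(e$type, e$start, e$end), character(1))
  pk <- key(predicted); gk <- key(gold)
  tp <- sum(pk %in% gk)
  prec <- if (length(pk)) tp / length(pk) else 1
  rec <- if (length(gk)) tp / length(gk) else 1
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(precision = prec, recall = rec, f1 = f1)
}
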