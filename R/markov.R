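#' Markov score: a word / word-pair probability classifier
#'
#' The Markov matcher treats the words and adjacent word pairs of an address
#' as predictors of a known training flag. Training estimates, separately
#' per health board (care homes in different regions often share similar
#' names), a smoothed log-likelihood ratio for every unigram and bigram:
#' \deqn{w(t) = \log\frac{c_+(t)+\alpha}{M_+ + \alpha V}
#'            - \log\frac{c_-(t)+\alpha}{M_- + \alpha V}}
#' with \eqn{c_\pm(t)} the feature count in positive/negative training
#' addresses of that board, \eqn{M_\pm} the total feature mass per class,
#' and \eqn{V} the board's class-shared vocabulary size for that feature
#' family. Scoring sums the weights of the record's features (unknown
#' features, and unknown boards, contribute 0), adds the prior log-odds
#' \eqn{\log(n_+/n_-)}, and maps through the logistic function onto 0-100.
#'
#' @name markov
NULL

bigrams_of <- function(tokens) {
  if (length(tokens) < 2L) return(character(0))
  paste(tokens[-length(tokens)], tokens[-1])
}

.family_weights <- function(feats_pos, feats_neg, alpha) {
  cp <- table(feats_pos)
  cn <- table(feats_neg)
  vocab <- union(names(cp), names(cn))
  V <- length(vocab)
  if (V == 0L) return(numeric(0))
  Mp <- length(feats_pos)
  Mn <- length(feats_neg)
  kp <- as.numeric(cp[match(vocab, names(cp))]); kp[is.na(kp)] <- 0
  kn <- as.numeric(cn[match(vocab, names(cn))]); kn[is.na(kn)] <- 0
  w <- (log(kp + alpha) - log(Mp + alpha * V)) -
       (log(kn + alpha) - log(Mn + alpha * V))
  names(w) <- vocab
  w
}

#' Train a Markov model
#'
#' @param records population address data.frame (tokens are taken from the
#'   normalized concatenated address including postcode).
#' @param labels logical (or 0/1) training flags, one per record. In the
#'   intended pipeline this is a routinely available proxy flag such as the
#'   institution flag, not the reference standard.
#' @param alpha additive smoothing pseudo-count, `> 0` (default 1).
#' @return object of class `markov_model`: per-board unigram and bigram
#'   weight maps, `prior_logodds`, `alpha` and vocabulary sizes.
#' @export
train_markov <- function(records, labels, alpha = 1) {
  labels <- as.logical(labels)
  if (length(labels) != nrow(records)) {
    cm_alignment_error("labels must have one entry per record")
  }
  if (alpha <= 0) cm_config_error("alpha must be > 0")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    cm_validation_error("training needs at least one positive and one negative record")
  }
  toks <- tokenize(concat_address(record_lines(records), records$postcode))
  boards <- as.character(records$board)
  model_boards <- list()
  for (b in sort(unique(boards))) {
    sel <- boards == b
    tp <- toks[sel & labels]; tn <- toks[sel & !labels]
    uni <- .family_weights(unlist(tp), unlist(tn), alpha)
    bi <- .family_weights(unlist(lapply(tp, bigrams_of)),
                          unlist(lapply(tn, bigrams_of)), alpha)
    model_boards[[b]] <- list(
      unigram = uni, bigram = bi,
      vocab_sizes = c(unigram = length(uni), bigram = length(bi)))
  }
  structure(
    list(boards = model_boards, prior_logodds = log(n_pos / n_neg),
         alpha = alpha, n_pos = n_pos, n_neg = n_neg),
    class = "markov_model"
  )
}

#' @export
print.markov_model <- function(x, ...) {
  cat("<markov_model> prior log-odds ", round(x$prior_logodds, 3),
      ", alpha ", x$alpha, ", ", length(x$boards), " board(s)\n", sep = "")
  for (b in names(x$boards)) {
    vs <- x$boards[[b]]$vocab_sizes
    cat("  ", b, ": ", vs["unigram"], " unigrams, ", vs["bigram"],
        " bigrams\n", sep = "")
  }
  invisible(x)
}

#' Score records with a trained Markov model
#'
#' @param model a `markov_model`.
#' @param records population address data.frame.
#' @return data.frame with columns `record_id`, `method` (`"markov"`),
#'   `score` (0-100, one decimal place) and `best_service` (`NA`: the score
#'   does not itself consult the registry; linking positives to a service is
#'   a separate reporting join).
#' @export
score_markov <- function(model, records) {
  toks <- tokenize(concat_address(record_lines(records), records$postcode))
  boards <- as.character(records$board)
  lo <- rep(model$prior_logodds, nrow(records))
  for (b in unique(boards)) {
    bm <- model$boards[[b]]
    if (is.null(bm)) next  # unknown board: features contribute 0
    sel <- which(boards == b)
    lo[sel] <- lo[sel] + vapply(toks[sel], function(t) {
      s <- sum(bm$unigram[match(t, names(bm$unigram))], na.rm = TRUE)
      bg <- bigrams_of(t)
      s + sum(bm$bigram[match(bg, names(bm$bigram))], na.rm = TRUE)
    }, numeric(1))
  }
  data.frame(record_id = records$record_id, method = "markov",
             score = round(100 * plogis(lo), 1),
             best_service = NA_character_, stringsAsFactors = FALSE)
}

#' Persist / restore a Markov model as JSON
#'
#' @param model a `markov_model`.
#' @param path JSON file path.
#' @export
write_markov_json <- function(model, path) {
  doc <- list(
    alpha = model$alpha, prior_logodds = model$prior_logodds,
    n_pos = model$n_pos, n_neg = model$n_neg,
    boards = lapply(model$boards, function(bm) {
      list(unigram = as.list(bm$unigram), bigram = as.list(bm$bigram))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_markov_json
#' @return `read_markov_json()` returns the restored `markov_model`.
#' @export
read_markov_json <- function(path) {
  doc <- jsonlite::read_json(path)
  boards <- lapply(doc$boards, function(bm) {
    uni <- unlist(bm$unigram); bi <- unlist(bm$bigram)
    if (is.null(uni)) uni <- numeric(0)
    if (is.null(bi)) bi <- numeric(0)
    list(unigram = uni, bigram = bi,
         vocab_sizes = c(unigram = length(uni), bigram = length(bi)))
  })
  structure(
    list(boards = boards, prior_logodds = doc$prior_logodds,
         alpha = doc$alpha, n_pos = doc$n_pos %||% NA_integer_,
         n_neg = doc$n_neg %||% NA_integer_),
    class = "markov_model"
  )
}
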