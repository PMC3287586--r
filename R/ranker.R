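#' Tokenize abstract text
#'
#' Lowercases, strips punctuation, keeps alphabetic/alphanumeric tokens and
#' removes packaged stop words. Deterministic; empty text yields an empty
#' token vector.
#'
#' @param text Character vector.
#' @param stopwords Character vector of words to drop.
#' @return A list of character vectors, one per input element.
#' @export
lit_tokenize <- function(text, stopwords = litpath_stopwords()) {
  toks <- stringr::str_extract_all(stringr::str_to_lower(text),
                                   "[a-z0-9][a-z0-9-]*")
  lapply(toks, function(x) x[!x %in% stopwords])
}

#' Fit discriminating-word weights from training vs background abstracts
#'
#' Implements a smoothed log-odds (naive-Bayes presence) model over document
#' frequencies: for each vocabulary word `w`,
#' `weight(w) = log((df_train(w) + s) / (n_train + 2s)) -
#'              log((df_bg(w) + s) / (n_bg + 2s))`,
#' with vocabulary the union of both sets. A word with equal smoothed
#' document frequency in both sets gets weight 0; `s > 0` keeps all weights
#' finite. The fitted object also retains the background unigram distribution
#' and abstract-length distribution, which parameterize the resampling null
#' used by [rank_abstracts()].
#'
#' @param training,background Data frames with `pmid`, `title`, `abstract`
#'   columns (title and body are pooled per document).
#' @param smoothing Pseudo-count `s` (> 0).
#' @param stopwords Stop-word list passed to [lit_tokenize()].
#' @return A `word_weights` object.
#' @export
fit_weights <- function(training, background, smoothing = 1,
                        stopwords = litpath_stopwords()) {
  if (!is.data.frame(training) || nrow(training) == 0) {
    lp_usage_error("training set must be a non-empty data frame")
  }
  if (!is.data.frame(background) || nrow(background) == 0) {
    lp_usage_error("background set must be a non-empty data frame")
  }
  if (smoothing <= 0) lp_usage_error("smoothing must be > 0")

  doc_text <- function(d) paste(d$title, d$abstract)
  tok_tr <- lit_tokenize(doc_text(training), stopwords)
  tok_bg <- lit_tokenize(doc_text(background), stopwords)

  df_of <- function(toks) table(unlist(lapply(toks, unique)))
  df_tr <- df_of(tok_tr)
  df_bg <- df_of(tok_bg)
  vocab <- sort(union(names(df_tr), names(df_bg)))

  n_tr <- length(tok_tr)
  n_bg <- length(tok_bg)
  s <- smoothing
  dtr <- as.numeric(df_tr[vocab]); dtr[is.na(dtr)] <- 0
  dbg <- as.numeric(df_bg[vocab]); dbg[is.na(dbg)] <- 0
  w <- log((dtr + s) / (n_tr + 2 * s)) - log((dbg + s) / (n_bg + 2 * s))

  bg_tokens <- unlist(tok_bg)
  structure(
    list(weights = tibble(word = vocab, df_train = dtr, df_bg = dbg,
                          weight = w),
         n_train = n_tr, n_bg = n_bg, smoothing = s,
         train_pmids = training$pmid,
         bg_word_freq = table(bg_tokens),
         bg_lengths = lengths(tok_bg),
         stopwords = stopwords),
    class = "word_weights")
}

#' @export
print.word_weights <- function(x, ...) {
  cat(sprintf(
    "<word_weights> vocabulary %d words, %d training vs %d background docs, smoothing %g\n",
    nrow(x$weights), x$n_train, x$n_bg, x$smoothing))
  invisible(x)
}

#' @export
tidy.word_weights <- function(x, ...) x$weights

#' @export
glance.word_weights <- function(x, ...) {
  tibble(vocab_size = nrow(x$weights), n_train = x$n_train, n_bg = x$n_bg,
         smoothing = x$smoothing)
}

score_tokens <- function(tokens, weights) {
  idx <- match(unique(tokens), weights$word)
  sum(weights$weight[idx[!is.na(idx)]])
}

#' Score abstracts by discriminating-word content
#'
#' The score of an abstract is the sum of the weights of its *distinct*
#' vocabulary words (presence-based, matching the document-frequency model);
#' out-of-vocabulary words contribute 0.
#'
#' @param corpus Data frame with `pmid`, `title`, `abstract`.
#' @param ww A `word_weights` object from [fit_weights()].
#' @return `corpus` with a `score` column added.
#' @export
score_abstracts <- function(corpus, ww) {
  stopifnot(inherits(ww, "word_weights"))
  toks <- lit_tokenize(paste(corpus$title, corpus$abstract), ww$stopwords)
  corpus |>
    mutate(score = vapply(toks, score_tokens, numeric(1), ww$weights))
}

#' @rdname score_abstracts
#' @param text A single text string.
#' @return For `score_text()`: a single numeric score.
#' @export
score_text <- function(text, ww) {
  stopifnot(inherits(ww, "word_weights"))
  score_tokens(lit_tokenize(text, ww$stopwords)[[1]], ww$weights)
}

#' Rank abstracts and select the working corpus
#'
#' Scores every abstract, attaches an empirical p-value against a resampling
#' null (abstracts resampled word-wise from the background unigram
#' distribution, lengths drawn from the background length distribution):
#' `p = (1 + #\{null scores >= score\}) / (null_size + 1)`. Training
#' abstracts are excluded from the ranked output. Returns the top `n_top`
#' abstracts that also satisfy `p < p_threshold`, in rank order; the defaults
#' (top 1000 at p < 0.01) are the conventional working-corpus cut.
#'
#' @param corpus Data frame with `pmid`, `title`, `abstract`.
#' @param ww A `word_weights` object.
#' @param n_top Maximum number of abstracts returned.
#' @param p_threshold Empirical p-value cutoff.
#' @param null_size Number of null resamples (>= 1).
#' @param seed Integer seed for the null resampling.
#' @return A tibble `rank`, `pmid`, `score`, `p_value`, ordered by
#'   non-increasing score with ties broken by ascending PMID.
#' @export
rank_abstracts <- function(corpus, ww, n_top = 1000L, p_threshold = 0.01,
                           null_size = 10000L, seed = 1L) {
  stopifnot(inherits(ww, "word_weights"))
  if (null_size < 1) lp_usage_error("null_size must be at least 1")
  withr::local_seed(seed)

  scored <- score_abstracts(corpus, ww) |>
    filter(!.data$pmid %in% ww$train_pmids)

  null_scores <- null_score_sample(ww, null_size)
  # p(a) = (1 + #{null >= score}) / (null_size + 1), via the sorted null
  sorted_null <- sort(null_scores)
  n_ge <- length(sorted_null) -
    findInterval(scored$score, sorted_null, left.open = TRUE)
  scored$p_value <- (1 + n_ge) / (null_size + 1)

  ranked <- scored |>
    arrange(dplyr::desc(.data$score), .data$pmid) |>
    mutate(rank = row_number()) |>
    select("rank", "pmid", "score", "p_value")

  ranked |>
    filter(.data$rank <= n_top, .data$p_value < p_threshold)
}

# Score distribution under the null: word-wise resampling from the
# background unigram distribution at background abstract lengths.
null_score_sample <- function(ww, null_size) {
  freq <- ww$bg_word_freq
  words <- names(freq)
  prob <- as.numeric(freq)
  lens <- sample_vec(ww$bg_lengths, null_size, replace = TRUE)
  res <- numeric(null_size)
  nz <- which(lens > 0)
  if (length(nz) > 0) {
    draws <- sample(words, sum(lens[nz]), replace = TRUE, prob = prob)
    grp <- rep.int(nz, lens[nz])
    s <- vapply(split(draws, grp), score_tokens, numeric(1), ww$weights)
    res[as.integer(names(s))] <- s
  }
  res
}
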