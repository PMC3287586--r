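ABBREVIATIONS <- c("e.g.", "i.e.", "et al.", "cf.", "vs.", "Fig.", "fig.",
                   "approx.", "ca.", "resp.", "No.", "no.")

#' Split text into sentences
#'
#' Rule-based segmentation: a sentence boundary is sentence-final punctuation
#' (`.`, `!`, `?`) followed by whitespace and a capital letter or digit;
#' known abbreviations (e.g., "e.g.", "et al.") are protected. Concatenating
#' `paste0(sentence, sep)` over the rows reconstructs the input exactly.
#'
#' @param text A single character string.
#' @return A tibble `sentence_index`, `sentence`, `sep` (the separator that
#'   followed the sentence; `""` for the last). Empty text gives zero rows.
#' @export
segment_sentences <- function(text) {
  stopifnot(length(text) == 1, !is.na(text))
  empty <- tibble(sentence_index = integer(), sentence = character(),
                  sep = character())
  if (!nzchar(text)) return(empty)

  # mask dots inside protected abbreviations so they cannot split
  masked <- text
  for (ab in ABBREVIATIONS) {
    masked_ab <- gsub(".", "\x01", ab, fixed = TRUE)
    masked <- gsub(ab, masked_ab, masked, fixed = TRUE)
  }
  m <- gregexpr("(?<=[.!?])[ \t\r\n]+(?=[A-Z0-9])", masked, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(tibble(sentence_index = 1L, sentence = text, sep = ""))
  }
  sep_start <- as.integer(m)
  sep_len <- attr(m, "match.length")
  starts <- c(1L, sep_start + sep_len)
  ends <- c(sep_start - 1L, nchar(text))
  tibble(
    sentence_index = seq_along(starts),
    sentence = substring(text, starts, ends),
    sep = c(substring(text, sep_start, sep_start + sep_len - 1L), ""))
}

# Compile a dictionary (symbol, synonym) into a match table with
# case-sensitivity per synonym (synonyms of <= 3 characters match
# case-sensitively, longer ones case-insensitively).
compile_dictionary <- function(dictionary) {
  d <- as_tibble(dictionary)
  stopifnot(all(c("symbol", "synonym") %in% names(d)))
  d |>
    distinct(.data$symbol, .data$synonym) |>
    mutate(case_sensitive = nchar(.data$synonym) <= 3)
}

# All token-boundary matches of `pattern_word` in `sentence`; returns
# half-open [start, end) character offsets (1-based start).
word_matches <- function(sentence, word, ignore_case) {
  pat <- paste0("(?<![A-Za-z0-9])", stringr::str_escape(word),
                "(?![A-Za-z0-9])")
  loc <- stringr::str_locate_all(
    sentence, stringr::regex(pat, ignore_case = ignore_case))[[1]]
  if (nrow(loc) == 0) return(NULL)
  tibble(start = loc[, 1], end = loc[, 2] + 1L)
}

#' Tag gene mentions in a sentence
#'
#' Dictionary matching: token-boundary anchored, longest match wins,
#' scanning left to right; overlapping shorter/later candidates are dropped.
#' Matching is case-insensitive except for synonyms of three characters or
#' fewer, which match case-sensitively (limits false tagging of short
#' symbols against common words).
#'
#' @param sentence A single string.
#' @param dictionary Data frame `symbol`, `synonym`.
#' @return A tibble `symbol`, `surface`, `start`, `end` (half-open span,
#'   1-based start) in span order.
#' @export
tag_genes <- function(sentence, dictionary) {
  d <- compile_dictionary(dictionary)
  # cheap vectorized presence screen before anchored regex matching
  lower <- stringr::str_to_lower(sentence)
  d <- d[stringr::str_detect(
    lower, stringr::fixed(stringr::str_to_lower(d$synonym))), ]
  cands <- purrr::pmap_dfr(d, function(symbol, synonym, case_sensitive) {
    m <- word_matches(sentence, synonym, ignore_case = !case_sensitive)
    if (is.null(m)) return(NULL)
    tibble(symbol = symbol, surface = substring(sentence, m$start, m$end - 1L),
           start = m$start, end = m$end)
  })
  resolve_overlaps(cands)
}

# Left-to-right greedy overlap resolution, longest match first at each
# position; ties broken by symbol for determinism.
resolve_overlaps <- function(cands) {
  empty <- tibble(symbol = character(), surface = character(),
                  start = integer(), end = integer())
  if (is.null(cands) || nrow(cands) == 0) return(empty)
  cands <- cands |>
    arrange(.data$start, dplyr::desc(.data$end - .data$start), .data$symbol)
  kept <- list()
  last_end <- 0L
  for (i in seq_len(nrow(cands))) {
    if (cands$start[i] >= last_end) {
      kept[[length(kept) + 1]] <- cands[i, ]
      last_end <- cands$end[i]
    }
  }
  bind_rows(kept)
}

#' Tag interaction words in a sentence
#'
#' Token-boundary, case-insensitive matches of lexicon words, in span order.
#'
#' @param sentence A single string.
#' @param lexicon Data frame `word`, `polarity`.
#' @return A tibble `word`, `polarity`, `start`, `end` in span order.
#' @export
tag_interaction_words <- function(sentence, lexicon) {
  lx <- as_tibble(lexicon)
  lower <- stringr::str_to_lower(sentence)
  lx <- lx[stringr::str_detect(
    lower, stringr::fixed(stringr::str_to_lower(lx$word))), ]
  out <- purrr::pmap_dfr(lx[, c("word", "polarity")],
                         function(word, polarity) {
    m <- word_matches(sentence, word, ignore_case = TRUE)
    if (is.null(m)) return(NULL)
    tibble(word = word, polarity = polarity, start = m$start, end = m$end)
  })
  if (nrow(out) == 0) {
    return(tibble(word = character(), polarity = character(),
                  start = integer(), end = integer()))
  }
  # keep the longest word at a position (e.g. "down-regulates" over "regulates")
  out <- resolve_word_overlaps(out)
  arrange(out, .data$start)
}

resolve_word_overlaps <- function(cands) {
  cands <- cands |>
    arrange(.data$start, dplyr::desc(.data$end - .data$start), .data$word)
  kept <- list()
  last_end <- 0L
  for (i in seq_len(nrow(cands))) {
    if (cands$start[i] >= last_end) {
      kept[[length(kept) + 1]] <- cands[i, ]
      last_end <- cands$end[i]
    }
  }
  bind_rows(kept)
}

#' Classify gene co-mentions of one sentence into biointeraction types
#'
#' For every ordered pair of gene mentions (A's span strictly before B's)
#' with distinct symbols:
#' * **type 1** — at least one interaction word lies strictly between them
#'   (the word nearest to A is attributed);
#' * **type 2** — the sentence contains an interaction word, but none between
#'   the pair (the first word in span order is attributed);
#' * **type 3** — no interaction word in the sentence (no word attributed).
#'
#' Polarity derives from the attributed word's lexicon entry and is
#' `"unknown"` when no word is attributed. Same-symbol pairs are suppressed.
#'
#' @param genes Gene-mention tibble from [tag_genes()].
#' @param words Word-mention tibble from [tag_interaction_words()].
#' @return A tibble `gene_a`, `word`, `gene_b`, `type`, `polarity`.
#' @export
classify_sentence <- function(genes, words) {
  empty <- tibble(gene_a = character(), word = character(),
                  gene_b = character(), type = integer(),
                  polarity = character())
  if (nrow(genes) < 2) return(empty)
  out <- list()
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(genes))) {
      if (i == j) next
      a <- genes[i, ]; b <- genes[j, ]
      if (a$end > b$start) next            # A must end before B starts
      if (a$symbol == b$symbol) next       # self-pairs suppressed
      between <- words |>
        filter(.data$start >= a$end, .data$end <= b$start)
      if (nrow(between) > 0) {
        w <- between |> arrange(.data$start) |> slice(1)
        out[[length(out) + 1]] <- tibble(
          gene_a = a$symbol, word = w$word, gene_b = b$symbol,
          type = 1L, polarity = w$polarity)
      } else if (nrow(words) > 0) {
        w <- words |> arrange(.data$start) |> slice(1)
        out[[length(out) + 1]] <- tibble(
          gene_a = a$symbol, word = w$word, gene_b = b$symbol,
          type = 2L, polarity = w$polarity)
      } else {
        out[[length(out) + 1]] <- tibble(
          gene_a = a$symbol, word = NA_character_, gene_b = b$symbol,
          type = 3L, polarity = "unknown")
      }
    }
  }
  if (length(out) == 0) return(empty)
  bind_rows(out)
}

#' Extract biointeractions from one abstract
#'
#' Segments title and body into sentences, tags genes and interaction words,
#' classifies each sentence with [classify_sentence()], and adds a **type 4**
#' interaction (word `NA`, symbols in alphabetical order, sentence index
#' `NA`) for every unordered gene pair co-mentioned in the abstract but never
#' within one sentence. Results are deduplicated per
#' (pmid, gene pair, word, type).
#'
#' @param pmid Abstract identifier.
#' @param title,abstract Text fields.
#' @param dictionary Gene dictionary (`symbol`, `synonym`).
#' @param lexicon Interaction lexicon (`word`, `polarity`).
#' @return A tibble `pmid`, `sentence_index`, `gene_a`, `word`, `gene_b`,
#'   `type`, `polarity`.
#' @export
extract_abstract <- function(pmid, title, abstract, dictionary,
                             lexicon = litpath_lexicon()) {
  sents <- bind_rows(segment_sentences(title), segment_sentences(abstract))
  empty <- tibble(pmid = pmid[0], sentence_index = integer(),
                  gene_a = character(), word = character(),
                  gene_b = character(), type = integer(),
                  polarity = character())
  if (nrow(sents) == 0) return(empty)
  sents$sentence_index <- seq_len(nrow(sents))

  per_sentence <- list()
  genes_by_sentence <- vector("list", nrow(sents))
  for (k in seq_len(nrow(sents))) {
    g <- tag_genes(sents$sentence[k], dictionary)
    genes_by_sentence[[k]] <- unique(g$symbol)
    if (nrow(g) == 0) next
    w <- tag_interaction_words(sents$sentence[k], lexicon)
    cl <- classify_sentence(g, w)
    if (nrow(cl) > 0) {
      cl$pmid <- pmid
      cl$sentence_index <- k
      per_sentence[[length(per_sentence) + 1]] <- cl
    }
  }
  res <- bind_rows(per_sentence)

  # abstract-level co-mentions never sharing a sentence -> type 4
  all_syms <- sort(unique(unlist(genes_by_sentence)))
  t4 <- list()
  if (length(all_syms) >= 2) {
    for (i in seq_len(length(all_syms) - 1)) {
      for (j in (i + 1):length(all_syms)) {
        a <- all_syms[i]; b <- all_syms[j]
        shared <- any(vapply(genes_by_sentence,
                             function(s) a %in% s && b %in% s, logical(1)))
        if (!shared) {
          t4[[length(t4) + 1]] <- tibble(
            gene_a = a, word = NA_character_, gene_b = b, type = 4L,
            polarity = "unknown", pmid = pmid,
            sentence_index = NA_integer_)
        }
      }
    }
  }
  res <- bind_rows(res, bind_rows(t4))
  if (nrow(res) == 0) return(empty)
  res |>
    distinct(.data$pmid, .data$gene_a, .data$word, .data$gene_b, .data$type,
             .keep_all = TRUE) |>
    select("pmid", "sentence_index", "gene_a", "word", "gene_b", "type",
           "polarity")
}

#' Extract biointeractions from a corpus
#'
#' Applies [extract_abstract()] to every record and filters to the requested
#' type codes. Output order is by PMID, so the result is invariant to the
#' input row order.
#'
#' @param corpus Data frame with `pmid`, `title`, `abstract`.
#' @param dictionary Gene dictionary (`symbol`, `synonym`).
#' @param lexicon Interaction lexicon (`word`, `polarity`).
#' @param types Integer type codes to keep (subset of 1:4).
#' @return A tibble `pmid`, `sentence_index`, `gene_a`, `word`, `gene_b`,
#'   `type`, `polarity`.
#' @export
extract_interactions <- function(corpus, dictionary,
                                 lexicon = litpath_lexicon(),
                                 types = 1:4) {
  stopifnot(all(types %in% 1:4))
  res <- purrr::pmap_dfr(
    corpus[, c("pmid", "title", "abstract")],
    function(pmid, title, abstract) {
      extract_abstract(pmid, title, abstract, dictionary, lexicon)
    })
  if (nrow(res) == 0) {
    return(tibble(pmid = integer(), sentence_index = integer(),
                  gene_a = character(), word = character(),
                  gene_b = character(), type = integer(),
                  polarity = character()))
  }
  res |>
    filter(.data$type %in% types) |>
    arrange(.data$pmid, .data$sentence_index, .data$gene_a, .data$gene_b)
}
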