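#' Synthetic corpus configuration
#'
#' Builds and validates the configuration for [make_corpus()]. The generator
#' emulates a literature search: `n_relevant` abstracts are drawn from a
#' topic-enriched word distribution and `n_background` abstracts from a
#' background distribution, and each planted interaction is realized as a
#' sentence matching its biointeraction type's syntactic pattern (type 1:
#' gene A, interaction word, gene B, in that order, within one sentence).
#'
#' The default word tables put `n_topic_words` words at `enrichment`-fold
#' their background probability in the relevant distribution (20 words at
#' 5-fold by default), which gives a clear but imperfect topic separation —
#' the regime a relevance ranker is meant to resolve.
#'
#' @param n_relevant,n_background Number of relevant / background abstracts.
#' @param topic_words Named numeric vector: word probabilities for the
#'   relevant topic (must sum to 1). Built from `vocab_size`,
#'   `n_topic_words` and `enrichment` when `NULL`.
#' @param background_words Named numeric vector: background word
#'   probabilities (must sum to 1). Uniform over `vocab_size` words when
#'   `NULL`.
#' @param planted_interactions Data frame with columns `gene_a`, `word`,
#'   `gene_b`, `type` (1-4) and `multiplicity` (number of abstracts the
#'   interaction is planted in). May have zero rows.
#' @param gene_dictionary Data frame with columns `symbol`, `synonym`; every
#'   planted gene symbol must appear in it.
#' @param lexicon Data frame with columns `word`, `polarity`
#'   (activation/repression/neutral).
#' @param vocab_size,n_topic_words,enrichment Used only to build default word
#'   tables.
#' @param sentences_per_abstract,words_per_sentence Integer ranges (length-2)
#'   for abstract shape.
#' @param seed Integer seed; fixed seed gives byte-identical corpora.
#' @return A `corpus_config` list, validated.
#' @export
corpus_config <- function(n_relevant = 50,
                          n_background = 500,
                          topic_words = NULL,
                          background_words = NULL,
                          planted_interactions = NULL,
                          gene_dictionary = litpath_gene_dictionary(),
                          lexicon = litpath_lexicon(),
                          vocab_size = 200,
                          n_topic_words = 20,
                          enrichment = 5,
                          sentences_per_abstract = c(4L, 7L),
                          words_per_sentence = c(8L, 14L),
                          seed = 1L) {
  vocab <- sprintf("kw%03d", seq_len(vocab_size))
  if (is.null(background_words)) {
    background_words <- setNames(rep(1 / vocab_size, vocab_size), vocab)
  }
  if (is.null(topic_words)) {
    w <- background_words
    w[seq_len(min(n_topic_words, length(w)))] <-
      w[seq_len(min(n_topic_words, length(w)))] * enrichment
    topic_words <- w / sum(w)
  }
  if (is.null(planted_interactions)) {
    planted_interactions <- tibble(gene_a = character(), word = character(),
                                   gene_b = character(), type = integer(),
                                   multiplicity = integer())
  }
  cfg <- structure(
    list(n_relevant = as.integer(n_relevant),
         n_background = as.integer(n_background),
         topic_words = topic_words,
         background_words = background_words,
         planted_interactions = as_tibble(planted_interactions),
         gene_dictionary = as_tibble(gene_dictionary),
         lexicon = as_tibble(lexicon),
         sentences_per_abstract = as.integer(sentences_per_abstract),
         words_per_sentence = as.integer(words_per_sentence),
         seed = as.integer(seed)),
    class = "corpus_config")
  validate_corpus_config(cfg)
}

validate_corpus_config <- function(cfg) {
  for (fld in c("topic_words", "background_words")) {
    p <- cfg[[fld]]
    if (is.null(names(p)) || any(!nzchar(names(p)))) {
      lp_config_error(fld, "word probabilities must be a named vector")
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      lp_config_error(fld, "probabilities must be non-negative and sum to 1")
    }
  }
  pl <- cfg$planted_interactions
  need <- c("gene_a", "word", "gene_b", "type", "multiplicity")
  if (!all(need %in% names(pl))) {
    lp_config_error("planted_interactions",
                    paste("missing columns:",
                          paste(setdiff(need, names(pl)), collapse = ", ")))
  }
  if (nrow(pl) > 0) {
    if (!all(pl$type %in% 1:4)) {
      lp_config_error("planted_interactions", "type codes must be in 1..4")
    }
    genes <- unique(c(pl$gene_a, pl$gene_b))
    known <- unique(cfg$gene_dictionary$symbol)
    missing <- setdiff(genes, known)
    if (length(missing) > 0) {
      lp_config_error("gene_dictionary",
                      paste("planted symbols absent from dictionary:",
                            paste(missing, collapse = ", ")))
    }
    lex_words <- cfg$lexicon$word
    bad <- setdiff(stats::na.omit(pl$word[pl$type %in% 1:2]), lex_words)
    if (length(bad) > 0) {
      lp_config_error("lexicon",
                      paste("planted interaction words absent from lexicon:",
                            paste(bad, collapse = ", ")))
    }
  }
  if (cfg$n_relevant < 1 && nrow(pl) > 0) {
    lp_config_error("n_relevant",
                    "must be at least 1 when interactions are planted")
  }
  cfg
}

sample_words <- function(dist, n) {
  sample(names(dist), n, replace = TRUE, prob = unname(dist))
}

make_sentence <- function(dist, n_words) {
  paste0(cap_first(paste(sample_words(dist, n_words), collapse = " ")), ".")
}

cap_first <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

# Sentence realizing one planted interaction of the given type. Filler words
# come from the word table so they can never collide with gene symbols or
# lexicon entries. Types 1/2/3 are single-sentence patterns; type 4 returns
# two sentences placed apart by the caller.
plant_sentences <- function(gene_a, word, gene_b, type, dist) {
  fill <- function(n) if (n == 0) character() else sample_words(dist, n)
  gap <- function() fill(sample(0:2, 1))
  if (type == 1L) {
    s <- paste(c(gene_a, gap(), word, gap(), gene_b), collapse = " ")
    paste0(s, ".")
  } else if (type == 2L) {
    s <- paste(c(word, gene_a, gap(), gene_b), collapse = " ")
    paste0(cap_first(s), ".")
  } else if (type == 3L) {
    s <- paste(c(gene_a, gap(), gene_b), collapse = " ")
    paste0(s, ".")
  } else {
    c(paste0(paste(c(gene_a, fill(3)), collapse = " "), "."),
      paste0(paste(c(gene_b, fill(3)), collapse = " "), "."))
  }
}

#' Generate a synthetic abstract corpus with planted interactions
#'
#' Emits `n_relevant + n_background` abstracts (bag-of-sentences from the
#' class word tables), realizes every planted interaction as sentences
#' matching its type's pattern inside randomly chosen relevant abstracts, and
#' returns the full ground truth. Deterministic for a fixed `cfg$seed`.
#'
#' @param cfg A [corpus_config()].
#' @return A list with elements `abstracts` (tibble `pmid`, `title`,
#'   `abstract`, `relevant`), `truth` (tibble `pmid`, `gene_a`, `word`,
#'   `gene_b`, `type`), and `relevant_pmids` (integer vector).
#' @export
make_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "corpus_config"))
  validate_corpus_config(cfg)
  withr::local_seed(cfg$seed)

  n_total <- cfg$n_relevant + cfg$n_background
  pmids <- 10000000L + seq_len(n_total)
  relevant <- c(rep(TRUE, cfg$n_relevant), rep(FALSE, cfg$n_background))

  spa <- cfg$sentences_per_abstract
  wps <- cfg$words_per_sentence
  gen_abstract <- function(dist) {
    ns <- sample(spa[1]:spa[2], 1)
    vapply(seq_len(ns),
           function(i) make_sentence(dist, sample(wps[1]:wps[2], 1)),
           character(1))
  }

  sentences <- lapply(relevant, function(r) {
    gen_abstract(if (r) cfg$topic_words else cfg$background_words)
  })
  titles <- vapply(relevant, function(r) {
    dist <- if (r) cfg$topic_words else cfg$background_words
    cap_first(paste(sample_words(dist, sample(4:8, 1)), collapse = " "))
  }, character(1))

  # Plant interactions into relevant abstracts.
  truth <- tibble(pmid = integer(), gene_a = character(), word = character(),
                  gene_b = character(), type = integer())
  pl <- cfg$planted_interactions
  if (nrow(pl) > 0) {
    for (i in seq_len(nrow(pl))) {
      row <- pl[i, ]
      hosts <- sample(seq_len(cfg$n_relevant), row$multiplicity,
                      replace = row$multiplicity > cfg$n_relevant)
      for (h in hosts) {
        planted <- plant_sentences(row$gene_a, row$word, row$gene_b,
                                   row$type, cfg$topic_words)
        cur <- sentences[[h]]
        if (row$type == 4L) {
          # two sentences, never adjacent-merged; keep both orders apart
          pos <- sort(sample(seq_len(length(cur) + 1), 2))
          cur <- append(cur, planted[1], after = pos[1] - 1)
          cur <- append(cur, planted[2], after = pos[2])
        } else {
          pos <- sample(seq_len(length(cur) + 1), 1)
          cur <- append(cur, planted, after = pos - 1)
        }
        sentences[[h]] <- cur
        truth <- bind_rows(truth,
                           tibble(pmid = pmids[h], gene_a = row$gene_a,
                                  word = if (row$type %in% 1:2) row$word
                                         else NA_character_,
                                  gene_b = row$gene_b,
                                  type = as.integer(row$type)))
      }
    }
  }

  abstracts <- tibble(
    pmid = pmids,
    title = titles,
    abstract = vapply(sentences, paste, character(1), collapse = " "),
    relevant = relevant)

  list(abstracts = abstracts,
       truth = arrange(truth, .data$pmid, .data$gene_a, .data$gene_b),
       relevant_pmids = pmids[relevant])
}

#' Write / read a corpus as Medline-like TSV
#'
#' Format: `pmid<TAB>title<TAB>abstract`, UTF-8, one record per line, with a
#' header. Ground truth (if given) is written next to it as
#' `pmid gene_a word gene_b type`.
#'
#' @param corpus Result of [make_corpus()], or any tibble with `pmid`,
#'   `title`, `abstract`.
#' @param path Output TSV path.
#' @param truth_path Optional path for the ground-truth TSV.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, truth_path = NULL) {
  abst <- if (is.data.frame(corpus)) corpus else corpus$abstracts
  readr::write_tsv(abst[, c("pmid", "title", "abstract")], path,
                   progress = FALSE)
  if (!is.null(truth_path) && !is.data.frame(corpus)) {
    readr::write_tsv(corpus$truth, truth_path, progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    pmid = readr::col_integer(), title = readr::col_character(),
    abstract = readr::col_character()), progress = FALSE)
}

#' Synthetic proteome configuration
#'
#' Configuration for [make_proteome()]. Each protein family starts from a
#' random ancestor sequence; the member for the i-th chosen taxon is derived
#' from the previous member by one round of i.i.d. substitution at
#' `mutation_rate` per site, so sequence divergence accumulates along the
#' taxon list. Decoys are unrelated i.i.d. random sequences mixed in at
#' `decoy_rate` of the final record set.
#'
#' @param taxa Integer taxon IDs (labels only; defaults reuse familiar NCBI
#'   numerals), ordered by increasing divergence from the focal taxon, which
#'   comes first. A family of size k spans the first k taxa, so family size
#'   maps to gene age.
#' @param families Number of families.
#' @param family_size_range Length-2 integer range of members per family,
#'   within `[2, length(taxa)]`.
#' @param mutation_rate Per-site substitution probability per taxon step, in
#'   `[0, 0.5]`.
#' @param decoy_rate Fraction of all records that are decoys, in `[0, 1)`.
#' @param complete_genome_taxa Taxa flagged as having a complete genome.
#' @param seq_length Ancestor sequence length.
#' @param family_names Optional character names for the families (defaults to
#'   FAM1, FAM2, ...); used to key seed proteins to pathway genes.
#' @param sp_fraction Probability that a non-focal member is Swiss-Prot
#'   (`sp`) rather than TrEMBL (`tr`); focal-taxon members are always `sp`
#'   (they serve as curated seeds).
#' @param seed Integer seed.
#' @return A validated `proteome_config` list.
#' @export
proteome_config <- function(taxa = c(9606L, 10090L, 7955L, 7227L, 6239L, 4932L),
                            families = 5L,
                            family_size_range = c(2L, 6L),
                            mutation_rate = 0.05,
                            decoy_rate = 0.1,
                            complete_genome_taxa = c(9606L, 10090L, 7227L),
                            seq_length = 200L,
                            family_names = NULL,
                            sp_fraction = 0.25,
                            seed = 1L) {
  cfg <- structure(
    list(taxa = as.integer(taxa), families = as.integer(families),
         family_size_range = as.integer(family_size_range),
         mutation_rate = mutation_rate, decoy_rate = decoy_rate,
         complete_genome_taxa = as.integer(complete_genome_taxa),
         seq_length = as.integer(seq_length),
         family_names = family_names, sp_fraction = sp_fraction,
         seed = as.integer(seed)),
    class = "proteome_config")
  validate_proteome_config(cfg)
}

validate_proteome_config <- function(cfg) {
  if (cfg$mutation_rate < 0 || cfg$mutation_rate > 0.5) {
    lp_config_error("mutation_rate", "must lie in [0, 0.5]")
  }
  if (cfg$decoy_rate < 0 || cfg$decoy_rate >= 1) {
    lp_config_error("decoy_rate", "must lie in [0, 1)")
  }
  r <- cfg$family_size_range
  if (length(r) != 2 || r[1] < 2 || r[2] > length(cfg$taxa) || r[1] > r[2]) {
    lp_config_error("family_size_range",
                    sprintf("must be within [2, %d]", length(cfg$taxa)))
  }
  if (!is.null(cfg$family_names) &&
      length(cfg$family_names) != cfg$families) {
    lp_config_error("family_names", "length must equal `families`")
  }
  cfg
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# sample() without the scalar-x surprise
sample_vec <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

mutate_seq <- function(chars, rate) {
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    # substitute to a uniformly chosen *different* residue
    repl <- vapply(chars[hit],
                   function(a) sample(setdiff(AA20, a), 1), character(1))
    chars[hit] <- repl
  }
  chars
}

#' Generate a synthetic proteome with known ortholog families
#'
#' @param cfg A [proteome_config()].
#' @return A list with `records` (tibble `seq_id`, `taxid`, `sequence`,
#'   `source_db`, `complete_genome`, `family`; `family` is `NA` for decoys)
#'   and `truth` (tibble `seq_id`, `family` covering every non-decoy record).
#' @export
make_proteome <- function(cfg) {
  stopifnot(inherits(cfg, "proteome_config"))
  validate_proteome_config(cfg)
  withr::local_seed(cfg$seed)

  fam_names <- cfg$family_names %||% sprintf("FAM%d", seq_len(cfg$families))
  r <- cfg$family_size_range
  recs <- list()
  for (f in seq_len(cfg$families)) {
    k <- if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1)
    # a family of size k spans the first k taxa: the focal taxon plus its
    # k-1 nearest relatives, so family size maps to gene age (young
    # families span few, close taxa; old families reach the outgroups)
    members <- cfg$taxa[seq_len(k)]
    chars <- sample(AA20, cfg$seq_length, replace = TRUE)
    for (tx in members) {
      chars <- mutate_seq(chars, cfg$mutation_rate)
      recs[[length(recs) + 1]] <- tibble(
        seq_id = sprintf("%s_%d", fam_names[f], tx),
        taxid = tx,
        sequence = paste(chars, collapse = ""),
        source_db = if (tx == cfg$taxa[1]) "sp" else
          if (runif(1) < cfg$sp_fraction) "sp" else "tr",
        complete_genome = tx %in% cfg$complete_genome_taxa,
        family = fam_names[f])
    }
  }
  records <- bind_rows(recs)

  n_fam <- nrow(records)
  n_decoy <- round(cfg$decoy_rate * n_fam / (1 - cfg$decoy_rate))
  if (n_decoy > 0) {
    decoy_tax <- sample_vec(cfg$taxa, n_decoy, replace = TRUE)
    decoys <- tibble(
      seq_id = sprintf("DECOY%02d_%d", seq_len(n_decoy), decoy_tax),
      taxid = decoy_tax,
      sequence = vapply(seq_len(n_decoy), function(i) {
        paste(sample(AA20, cfg$seq_length, replace = TRUE), collapse = "")
      }, character(1)),
      source_db = "tr",
      complete_genome = decoy_tax %in% cfg$complete_genome_taxa,
      family = NA_character_)
    records <- bind_rows(records, decoys)
  }

  list(records = records,
       truth = records |>
         filter(!is.na(.data$family)) |>
         select("seq_id", "family"))
}

#' Write / read a proteome as FASTA plus sidecar metadata TSV
#'
#' FASTA is wrapped at 60 columns; the sidecar TSV has columns
#' `seq_id taxid source_db complete_genome` with `source_db` in `{sp, tr}`
#' and `complete_genome` in `{0, 1}`.
#'
#' @param records Tibble as produced by [make_proteome()].
#' @param fasta_path,meta_path Output paths.
#' @return `fasta_path`, invisibly.
#' @export
write_proteome <- function(records, fasta_path, meta_path) {
  seqs <- Biostrings::AAStringSet(setNames(records$sequence, records$seq_id))
  Biostrings::writeXStringSet(seqs, fasta_path, width = 60L)
  meta <- records |>
    mutate(complete_genome = as.integer(.data$complete_genome)) |>
    select("seq_id", "taxid", "source_db", "complete_genome")
  readr::write_tsv(meta, meta_path, progress = FALSE)
  invisible(fasta_path)
}

#' @rdname write_proteome
#' @export
read_proteome <- function(fasta_path, meta_path) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  meta <- readr::read_tsv(meta_path, col_types = "cici", progress = FALSE)
  tibble(seq_id = names(seqs),
         sequence = unname(as.character(seqs))) |>
    left_join(meta, by = "seq_id") |>
    mutate(complete_genome = .data$complete_genome == 1L) |>
    select("seq_id", "taxid", "sequence", "source_db", "complete_genome")
}

#' Mini-taxonomy fixture spanning the human lineage
#'
#' A rooted taxonomy containing, in root-to-tip order on the human lineage:
#' cellular root, Eukaryota, Metazoa, Eumetazoa, Coelomata, Chordata,
#' Euteleostomi, Mammalia, Eutheria, Homo sapiens; with Mus musculus under
#' Eutheria, Danio rerio under Euteleostomi, Drosophila melanogaster
#' branching under Coelomata (outside Chordata), Caenorhabditis elegans under
#' Eumetazoa and Saccharomyces cerevisiae under Eukaryota. "Coelomata" is
#' retained deliberately: the fixture is version-pinned data in the style of
#' older NCBI taxonomies, in which gene-age bins such as Coelomata exist.
#'
#' @return A `taxonomy` object (see [load_taxonomy()]).
#' @export
make_taxonomy <- function() {
  nodes <- tibble(
    taxid  = c(131567L, 2759L, 33208L, 6072L, 33316L, 7711L, 117571L,
               40674L, 9347L, 9606L, 10090L, 7955L, 7227L, 6239L, 4932L),
    parent = c(131567L, 131567L, 2759L, 33208L, 6072L, 33316L, 7711L,
               117571L, 40674L, 9347L, 9347L, 117571L, 33316L, 6072L, 2759L),
    rank = c("no rank", "superkingdom", "kingdom", "no rank", "no rank",
             "phylum", "no rank", "class", "no rank", "species", "species",
             "species", "species", "species", "species"),
    name = c("cellular organisms", "Eukaryota", "Metazoa", "Eumetazoa",
             "Coelomata", "Chordata", "Euteleostomi", "Mammalia", "Eutheria",
             "Homo sapiens", "Mus musculus", "Danio rerio",
             "Drosophila melanogaster", "Caenorhabditis elegans",
             "Saccharomyces cerevisiae"))
  new_taxonomy(nodes)
}

#' Write a taxonomy as NCBI taxdump dialect or JSON
#'
#' `write_taxdump()` emits `nodes.dmp` / `names.dmp` in the pipe-tab dialect
#' of the NCBI taxdump (`taxid\t|\tparent\t|\trank\t|` and
#' `taxid\t|\tname\t|\t\t|\tscientific name\t|`). `write_taxonomy_json()`
#' emits an equivalent JSON encoding.
#'
#' @param tax A `taxonomy` object.
#' @param dir Output directory for the dmp pair.
#' @param path Output path for the JSON encoding.
#' @return The directory or path written, invisibly.
#' @export
write_taxdump <- function(tax, dir) {
  stopifnot(inherits(tax, "taxonomy"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- tax$nodes
  writeLines(sprintf("%d\t|\t%d\t|\t%s\t|", n$taxid, n$parent, n$rank),
             file.path(dir, "nodes.dmp"))
  writeLines(sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|",
                     n$taxid, n$name),
             file.path(dir, "names.dmp"))
  invisible(dir)
}

#' @rdname write_taxdump
#' @export
write_taxonomy_json <- function(tax, path) {
  stopifnot(inherits(tax, "taxonomy"))
  jsonlite::write_json(
    list(root = tax$root,
         nodes = tax$nodes[, c("taxid", "parent", "rank", "name")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
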