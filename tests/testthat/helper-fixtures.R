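# Shared fixtures, built in code.

tiny_dictionary <- function() {
  tibble::tibble(
    symbol  = c("CDX2", "NANOG", "POU5F1", "POU5F1", "SOX2", "GATA4",
                "SOX7"),
    synonym = c("CDX2", "NANOG", "POU5F1", "Oct4", "SOX2", "GATA4",
                "SOX7"))
}

tiny_lexicon <- function() {
  tibble::tibble(
    word = c("activates", "downregulates", "represses", "binds",
             "phosphorylates"),
    polarity = c("activation", "repression", "repression", "neutral",
                 "neutral"))
}

# Independent brute-force oracle for sentence classification: enumerate all
# ordered gene-mention pairs and apply the stated between-word rule directly.
brute_classify <- function(genes, words) {
  out <- list()
  if (nrow(genes) < 2) {
    return(tibble::tibble(gene_a = character(), word = character(),
                          gene_b = character(), type = integer(),
                          polarity = character()))
  }
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(genes))) {
      if (i == j) next
      if (!(genes$end[i] <= genes$start[j])) next
      if (genes$symbol[i] == genes$symbol[j]) next
      between <- words[words$start >= genes$end[i] &
                         words$end <= genes$start[j], , drop = FALSE]
      if (nrow(between) > 0) {
        k <- which.min(between$start)
        out[[length(out) + 1]] <- tibble::tibble(
          gene_a = genes$symbol[i], word = between$word[k],
          gene_b = genes$symbol[j], type = 1L,
          polarity = between$polarity[k])
      } else if (nrow(words) > 0) {
        k <- which.min(words$start)
        out[[length(out) + 1]] <- tibble::tibble(
          gene_a = genes$symbol[i], word = words$word[k],
          gene_b = genes$symbol[j], type = 2L,
          polarity = words$polarity[k])
      } else {
        out[[length(out) + 1]] <- tibble::tibble(
          gene_a = genes$symbol[i], word = NA_character_,
          gene_b = genes$symbol[j], type = 3L, polarity = "unknown")
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(gene_a = character(), word = character(),
                          gene_b = character(), type = integer(),
                          polarity = character()))
  }
  dplyr::bind_rows(out)
}

# Independent brute-force lineage LCA: intersect full ancestor chains,
# restrict to the lineage, take the deepest element.
brute_lca <- function(taxa, tax, lineage) {
  parent_of <- stats::setNames(tax$nodes$parent, tax$nodes$taxid)
  chain <- function(tx) {
    out <- tx
    while (tx != tax$root) {
      tx <- parent_of[[as.character(tx)]]
      out <- c(out, tx)
    }
    out
  }
  common <- Reduce(intersect, lapply(taxa, chain))
  cand <- lineage$taxid[lineage$taxid %in% common]
  cand[length(cand)]
}

# Random pathway graph for round-trip tests.
random_pathway_graph <- function(n_nodes = 5, n_edges = 7) {
  syms <- sort(sample(paste0("G", sprintf("%02d", 1:40)), n_nodes))
  subtypes <- c("activation", "inhibition", "expression", "repression",
                "binding/association", "phosphorylation", "indirect")
  e <- tibble::tibble(
    source = sample(syms, n_edges, replace = TRUE),
    target = sample(syms, n_edges, replace = TRUE),
    subtype = sample(subtypes, n_edges, replace = TRUE))
  e <- dplyr::distinct(e, source, target, subtype)
  e$evidence <- lapply(seq_len(nrow(e)), function(i) {
    sort(unique(as.character(sample(100:999, sample(1:3, 1)))))
  })
  nodes <- tibble::tibble(
    symbol = syms,
    ancestry = sample(c("ancient", "recent", "unassigned"), n_nodes,
                      replace = TRUE),
    fly_ortholog = sample(c(TRUE, FALSE), n_nodes, replace = TRUE))
  pathway_graph(nodes, e)
}

small_corpus_config <- function(seed = 1L, planted = NULL,
                                n_relevant = 20L, n_background = 60L) {
  corpus_config(n_relevant = n_relevant, n_background = n_background,
                planted_interactions = planted, seed = seed)
}
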