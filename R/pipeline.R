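default_planted <- function() {
  tibble(
    gene_a = c("CDX2", "LATS2", "TEAD4", "POU5F1", "SOX2", "NANOG"),
    word   = c("downregulates", "phosphorylates", "activates",
               "activates", "activates", "represses"),
    gene_b = c("NANOG", "YAP1", "CDX2", "NANOG", "POU5F1", "SMAD1"),
    type   = rep(1L, 6),
    multiplicity = c(3L, 2L, 2L, 2L, 2L, 2L))
}

#' End-to-end pipeline configuration
#'
#' One configuration object driving the whole pipeline: synthetic corpus ->
#' ranking -> biointeraction extraction -> curation -> KGML, plus synthetic
#' proteome -> ortholog clusters -> lineage LCA -> annotated pathway. All
#' randomness derives from `seed`; two runs with the same configuration are
#' bitwise identical.
#'
#' @param seed Master integer seed.
#' @param n_relevant,n_background Corpus sizes.
#' @param planted Planted-interaction table (see [corpus_config()]); the
#'   planted gene set also defines the synthetic protein families.
#' @param n_train Number of relevant abstracts used as the training set.
#' @param n_top,p_threshold,null_size Ranking parameters.
#' @param accepted_types Curation: accepted biointeraction types.
#' @param taxa,mutation_rate,decoy_rate Proteome parameters.
#' @param reference,outgroup Ancestry parameters.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            n_relevant = 50L, n_background = 300L,
                            planted = default_planted(),
                            n_train = 10L,
                            n_top = 1000L, p_threshold = 0.01,
                            null_size = 2000L,
                            accepted_types = 1L,
                            taxa = c(9606L, 10090L, 7955L, 7227L, 6239L,
                                     4932L),
                            mutation_rate = 0.05, decoy_rate = 0.1,
                            reference = "Euteleostomi", outgroup = 7227L) {
  seed <- as.integer(seed)
  genes <- sort(unique(c(planted$gene_a, planted$gene_b)))
  structure(
    list(seed = seed,
         corpus = corpus_config(n_relevant = n_relevant,
                                n_background = n_background,
                                planted_interactions = planted,
                                seed = seed),
         n_train = as.integer(n_train),
         rank = list(n_top = as.integer(n_top), p_threshold = p_threshold,
                     null_size = as.integer(null_size),
                     seed = (seed + 1009L) %% .Machine$integer.max),
         accepted_types = as.integer(accepted_types),
         proteome = proteome_config(
           taxa = taxa, families = length(genes),
           family_size_range = c(2L, length(taxa)),
           mutation_rate = mutation_rate, decoy_rate = decoy_rate,
           family_names = genes,
           seed = (seed + 2003L) %% .Machine$integer.max),
         reference = reference, outgroup = as.integer(outgroup)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields mirror the arguments of [pipeline_config()]; a `planted`
#' field is a list of records with `gene_a`, `word`, `gene_b`, `type`,
#' `multiplicity`.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y),
                      setdiff(names(formals(pipeline_config)), "planted"))]
  if (!is.null(y$planted)) {
    args$planted <- purrr::map_dfr(y$planted, as_tibble) |>
      mutate(type = as.integer(.data$type),
             multiplicity = as.integer(.data$multiplicity))
  }
  do.call(pipeline_config, args)
}

#' Run the full literature-to-ancestry pipeline
#'
#' Generates the synthetic corpus, fits discriminating-word weights on the
#' first `n_train` relevant abstracts against the rest, ranks and selects
#' the working corpus, extracts biointeractions, curates them into a pathway
#' graph, generates the synthetic proteome keyed to the planted genes,
#' calibrates similarity thresholds, builds per-gene BBH clusters, assigns
#' each gene a lineage LCA and age label, annotates the graph, and
#' serializes it as KGML.
#'
#' @param config A [pipeline_config()], or the path to a YAML file for
#'   [read_pipeline_config()].
#' @param out_dir Optional directory; when given, all artifacts are written
#'   (corpus.tsv, ranked.tsv, interactions.tsv, pathway.kgml, clusters/,
#'   lca.tsv, origin_bins.tsv).
#' @return A list with elements `corpus`, `ranked`, `interactions`, `graph`
#'   (annotated `pathway_graph`), `kgml` (string), `clusters`, `thresholds`,
#'   `lca`, `bins`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))

  corpus <- make_corpus(config$corpus)
  abst <- corpus$abstracts
  train_pmids <- head(corpus$relevant_pmids, config$n_train)
  training <- abst |> filter(.data$pmid %in% train_pmids)
  background <- abst |> filter(!.data$pmid %in% train_pmids)

  ww <- fit_weights(training, background)
  ranked <- rank_abstracts(abst, ww,
                           n_top = config$rank$n_top,
                           p_threshold = config$rank$p_threshold,
                           null_size = config$rank$null_size,
                           seed = config$rank$seed)
  selected <- abst |> filter(.data$pmid %in% ranked$pmid)

  interactions <- extract_interactions(
    selected, config$corpus$gene_dictionary, config$corpus$lexicon)
  graph <- curate(interactions,
                  curation_rules(accepted_types = config$accepted_types))

  proteome <- make_proteome(config$proteome)
  records <- proteome$records
  calib <- calibrate_thresholds(records)
  seed_map <- records |>
    filter(!is.na(.data$family), .data$taxid == config$proteome$taxa[1],
           .data$family %in% graph$nodes$symbol) |>
    select(gene_symbol = "family", "seq_id")
  clusters <- cluster_genes(seed_map, records,
                            min_score = calib$min_score,
                            min_verify_score = calib$min_verify_score)

  tax <- make_taxonomy()
  lineage <- focal_lineage(tax)
  lca <- gene_ancestry(clusters, records, tax,
                       reference = config$reference,
                       outgroup = config$outgroup)
  graph <- annotate_ancestry(graph, lca)
  kgml <- write_kgml(graph)
  bins <- bin_by_clade(lca, lineage)

  res <- list(corpus = corpus, ranked = ranked,
              interactions = interactions, graph = graph, kgml = kgml,
              clusters = clusters, thresholds = calib, lca = lca,
              bins = bins, config = config)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_corpus(corpus, file.path(out_dir, "corpus.tsv"),
                 file.path(out_dir, "ground_truth.tsv"))
    readr::write_tsv(ranked, file.path(out_dir, "ranked.tsv"),
                     progress = FALSE)
    readr::write_tsv(interactions,
                     file.path(out_dir, "interactions.tsv"),
                     progress = FALSE)
    con <- file(file.path(out_dir, "pathway.kgml"), open = "wb")
    writeChar(kgml, con, eos = NULL)
    close(con)
    write_clusters(clusters, records, file.path(out_dir, "clusters"))
    readr::write_tsv(lca |> select(-"cluster_taxa"),
                     file.path(out_dir, "lca.tsv"), progress = FALSE)
    readr::write_tsv(bins, file.path(out_dir, "origin_bins.tsv"),
                     progress = FALSE)
  }
  res
}
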