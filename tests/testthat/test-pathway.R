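demo_interaction <- function(pmid = 101L) {
  tibble::tibble(pmid = pmid, sentence_index = 1L, gene_a = "CDX2",
                 word = "downregulates", gene_b = "NANOG", type = 1L,
                 polarity = "repression")
}

test_that("curation maps a repression type-1 interaction to one inhibition edge", {
  g <- curate(demo_interaction())
  expect_equal(nrow(g$nodes), 2L)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$source, "CDX2")
  expect_equal(g$edges$target, "NANOG")
  expect_equal(g$edges$subtype, "inhibition")
  expect_equal(g$edges$evidence[[1]], "101")
})

test_that("curation merges duplicate assertions and accumulates evidence", {
  ia <- dplyr::bind_rows(demo_interaction(101L), demo_interaction(202L))
  g <- curate(ia)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$evidence[[1]], c("101", "202"))
  # idempotence: curating the list concatenated with itself changes nothing
  g2 <- curate(dplyr::bind_rows(ia, ia))
  expect_identical(g, g2)
  # empty input -> empty graph
  e <- curate(demo_interaction()[0, ])
  expect_equal(nrow(e$nodes), 0L)
  expect_equal(nrow(e$edges), 0L)
})

test_that("curation respects accepted types, word overrides and strict mode", {
  ia <- tibble::tibble(
    pmid = 1:3, sentence_index = 1L,
    gene_a = c("LATS2", "YAP1", "GATA4"),
    word = c("phosphorylates", "binds", NA),
    gene_b = c("YAP1", "TEAD4", "SOX7"),
    type = c(1L, 1L, 3L),
    polarity = c("neutral", "neutral", "unknown"))
  g <- curate(ia)   # default: type 1 only
  expect_equal(sort(g$edges$subtype),
               c("binding/association", "phosphorylation"))
  g34 <- curate(ia, curation_rules(accepted_types = c(1L, 3L)))
  expect_true("indirect" %in% g34$edges$subtype)
  expect_error(curate(ia, curation_rules(accepted_types = 1:4,
                                         strict = TRUE)),
               "unknown polarity")
  # deny list removes the gene entirely
  gd <- curate(ia, curation_rules(accepted_types = 1L, deny = "TEAD4"))
  expect_false("TEAD4" %in% gd$nodes$symbol)
})

test_that("pathway graph invariants are enforced", {
  expect_error(pathway_graph(
    tibble::tibble(symbol = "A"),
    tibble::tibble(source = "A", target = "B", subtype = "activation",
                   evidence = list("1"))), "endpoint")
  expect_error(pathway_graph(
    tibble::tibble(symbol = c("A", "B")),
    tibble::tibble(source = "A", target = "B", subtype = "activation",
                   evidence = list(character()))), "evidence")
  expect_error(pathway_graph(
    tibble::tibble(symbol = c("A", "B")),
    tibble::tibble(source = c("A", "A"), target = c("B", "B"),
                   subtype = "activation",
                   evidence = list("1", "2"))), "duplicate")
})

test_that("KGML serialization writes the expected relation and validates", {
  g <- curate(demo_interaction())
  kg <- write_kgml(g)
  expect_equal(length(gregexpr("<relation ", kg)[[1]]), 1L)
  expect_match(kg, "<subtype name=\"inhibition\" value=\"--|\"",
               fixed = TRUE)
  v <- kgml_validate(kg)
  expect_true(v$valid)
  # empty graph is a valid document with zero entries
  kg0 <- write_kgml(pathway_graph())
  expect_false(grepl("<entry", kg0))
  expect_true(kgml_validate(kg0)$valid)
})

test_that("KGML write-read-write is byte-identical on 50 random graphs", {
  withr::with_seed(7, {
    for (i in 1:50) {
      g <- random_pathway_graph(n_nodes = sample(2:8, 1),
                                n_edges = sample(1:10, 1))
      k1 <- write_kgml(g)
      g2 <- read_kgml(k1)
      k2 <- write_kgml(g2)
      expect_identical(k1, k2)
      expect_true(kgml_validate(k1)$valid)
      # the graph itself round-trips too (nodes, edges, annotations)
      expect_equal(g2$nodes, g$nodes)
      expect_equal(g2$edges, g$edges)
    }
  })
})

test_that("KGML reading handles edge cases per contract", {
  # document without relations -> edgeless graph
  g <- read_kgml(write_kgml(pathway_graph(tibble::tibble(symbol = "A"))))
  expect_equal(nrow(g$edges), 0L)
  expect_equal(g$nodes$symbol, "A")
  # relation referencing a missing entry id -> error with element path
  bad <- paste0(
    "<?xml version=\"1.0\"?><pathway name=\"x\" org=\"hsa\">",
    "<entry id=\"1\" name=\"A\" type=\"gene\"/>",
    "<relation entry1=\"1\" entry2=\"99\" type=\"PPrel\">",
    "<subtype name=\"activation\" value=\"--&gt;\"/></relation></pathway>")
  expect_error(read_kgml(bad), "relation\\[1\\].*99")
  # unknown subtype is preserved as indirect, with a warning
  odd <- paste0(
    "<?xml version=\"1.0\"?><pathway name=\"x\" org=\"hsa\">",
    "<entry id=\"1\" name=\"A\" type=\"gene\"/>",
    "<entry id=\"2\" name=\"B\" type=\"gene\"/>",
    "<relation entry1=\"1\" entry2=\"2\" type=\"PPrel\">",
    "<subtype name=\"mystery\" value=\"?\"/></relation></pathway>")
  expect_warning(g2 <- read_kgml(odd), "mystery")
  expect_equal(g2$edges$subtype, "indirect")
})

test_that("ancestry annotation labels nodes without touching topology", {
  g <- curate(demo_interaction())
  lca <- tibble::tibble(gene_symbol = "CDX2", age_label = "ancient",
                        fly_ortholog = TRUE)
  a <- annotate_ancestry(g, lca)
  expect_equal(a$nodes$ancestry[a$nodes$symbol == "CDX2"], "ancient")
  expect_true(a$nodes$fly_ortholog[a$nodes$symbol == "CDX2"])
  # absent symbol stays unassigned (genes lacking a seed product)
  expect_equal(a$nodes$ancestry[a$nodes$symbol == "NANOG"], "unassigned")
  expect_identical(a$edges, g$edges)
  expect_identical(a$nodes$symbol, g$nodes$symbol)
})

test_that("evidence conservation: every edge PMID occurs in the input", {
  planted <- tibble::tibble(gene_a = c("CDX2", "SOX2"),
                            word = c("downregulates", "activates"),
                            gene_b = c("NANOG", "POU5F1"),
                            type = 1L, multiplicity = 2L)
  corp <- make_corpus(small_corpus_config(seed = 51L, planted = planted))
  ia <- extract_interactions(corp$abstracts, litpath_gene_dictionary())
  g <- curate(ia)
  for (i in seq_len(nrow(g$edges))) {
    ev <- g$edges$evidence[[i]]
    sub <- ia[ia$gene_a == g$edges$source[i] &
                ia$gene_b == g$edges$target[i], ]
    expect_true(all(ev %in% as.character(sub$pmid)))
  }
})

test_that("demo edge list loads into a valid annotated-ready graph", {
  g <- as_pathway_graph(litpath_demo_edges())
  expect_gt(nrow(g$nodes), 15)
  expect_gt(nrow(g$edges), 25)
  expect_true(kgml_validate(write_kgml(g))$valid)
  td <- tidy(g)
  expect_true(all(td$n_evidence >= 1))
  gl <- glance(g)
  expect_equal(gl$n_genes, nrow(g$nodes))
})

test_that("GraphML export writes a parseable graph", {
  skip_if_not_installed("igraph")
  g <- as_pathway_graph(litpath_demo_edges())
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, f)
  ig <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(ig), nrow(g$nodes))
  expect_equal(igraph::ecount(ig), nrow(g$edges))
})
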