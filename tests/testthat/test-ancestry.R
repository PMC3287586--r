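test_that("taxdump and JSON encodings load to identical trees", {
  tax <- make_taxonomy()
  dir <- withr::local_tempdir()
  write_taxdump(tax, dir)
  jf <- file.path(dir, "taxonomy.json")
  write_taxonomy_json(tax, jf)
  t_dmp <- load_taxonomy(dir)
  t_json <- load_taxonomy(jf)
  expect_equal(t_dmp$nodes, t_json$nodes)
  expect_equal(t_dmp$root, tax$root)
  expect_equal(t_dmp$checksum, tax$checksum)
  expect_true(9606L %in% t_dmp$nodes$taxid)
})

test_that("malformed taxonomies are rejected with the offending taxid", {
  dir <- withr::local_tempdir()
  # a 2-cycle
  writeLines(c("1\t|\t1\t|\tno rank\t|",
               "2\t|\t3\t|\tno rank\t|",
               "3\t|\t2\t|\tno rank\t|"),
             file.path(dir, "nodes.dmp"))
  writeLines(c("1\t|\troot\t|\t\t|\tscientific name\t|",
               "2\t|\ta\t|\t\t|\tscientific name\t|",
               "3\t|\tb\t|\t\t|\tscientific name\t|"),
             file.path(dir, "names.dmp"))
  expect_error(load_taxonomy(dir), "cycle")
  # orphan parent
  writeLines(c("1\t|\t1\t|\tno rank\t|",
               "2\t|\t99\t|\tno rank\t|"),
             file.path(dir, "nodes.dmp"))
  writeLines(c("1\t|\troot\t|\t\t|\tscientific name\t|",
               "2\t|\ta\t|\t\t|\tscientific name\t|"),
             file.path(dir, "names.dmp"))
  expect_error(load_taxonomy(dir), "99")
})

test_that("focal lineage is the ancestor-ordered root-to-focal chain", {
  tax <- make_taxonomy()
  lin <- focal_lineage(tax, 9606L)
  expect_equal(lin$name[1], "cellular organisms")
  expect_equal(lin$name[nrow(lin)], "Homo sapiens")
  # each element is the parent of the next
  parent_of <- stats::setNames(tax$nodes$parent, tax$nodes$taxid)
  for (i in 2:nrow(lin)) {
    expect_equal(parent_of[[as.character(lin$taxid[i])]], lin$taxid[i - 1])
  }
  expect_equal(focal_lineage(tax, tax$root)$taxid, tax$root)
  expect_error(focal_lineage(tax, 424242L), "424242")
})

test_that("lineage LCA matches expectations on the fixture", {
  tax <- make_taxonomy()
  lin <- focal_lineage(tax)
  expect_equal(lca_on_lineage(9606L, tax, lin),
               9606L)                                  # single leaf
  eutheria <- tax$nodes$taxid[tax$nodes$name == "Eutheria"]
  expect_equal(lca_on_lineage(c(9606L, 10090L), tax, lin), eutheria)
  coelomata <- tax$nodes$taxid[tax$nodes$name == "Coelomata"]
  lca_fly <- lca_on_lineage(c(9606L, 7227L), tax, lin)
  expect_equal(lca_fly, coelomata)
  # rootward of Euteleostomi -> ancient
  expect_equal(classify_age(lca_fly, lin), "ancient")
  expect_error(lca_on_lineage(integer(), tax, lin), "non-empty")
  expect_error(lca_on_lineage(31337L, tax, lin), "31337")
})

test_that("lineage LCA equals brute-force intersection for all small leaf subsets", {
  tax <- make_taxonomy()
  lin <- focal_lineage(tax)
  leaves <- setdiff(tax$nodes$taxid, tax$nodes$parent)
  for (k in 1:4) {
    combos <- utils::combn(leaves, k)
    for (j in seq_len(ncol(combos))) {
      taxa <- combos[, j]
      expect_equal(lca_on_lineage(taxa, tax, lin),
                   brute_lca(taxa, tax, lin))
    }
  }
})

test_that("adding a taxon never moves the LCA tipward", {
  tax <- make_taxonomy()
  lin <- focal_lineage(tax)
  leaves <- setdiff(tax$nodes$taxid, tax$nodes$parent)
  withr::with_seed(8, {
    for (i in 1:50) {
      base <- sample(leaves, sample(1:3, 1))
      extra <- sample(setdiff(tax$nodes$taxid, base), 1)
      d0 <- match(lca_on_lineage(base, tax, lin), lin$taxid)
      d1 <- match(lca_on_lineage(c(base, extra), tax, lin), lin$taxid)
      expect_lte(d1, d0)
    }
  })
})

test_that("age classification follows the reference-clade rule", {
  tax <- make_taxonomy()
  lin <- focal_lineage(tax)
  id <- function(nm) tax$nodes$taxid[tax$nodes$name == nm]
  expect_equal(classify_age(id("Eutheria"), lin), "recent")
  expect_equal(classify_age(id("Euteleostomi"), lin), "recent")
  expect_equal(classify_age(id("Eumetazoa"), lin), "ancient")
  # the cutoff is a parameter
  expect_equal(classify_age(id("Eutheria"), lin, reference = "Chordata"),
               "recent")
  expect_equal(classify_age(id("Coelomata"), lin, reference = "Chordata"),
               "ancient")
  expect_error(classify_age(id("Eutheria"), lin, reference = "Nonclade"),
               "reference")
  # order consistency: rootward of an ancient LCA is ancient
  labels <- vapply(lin$taxid, classify_age, character(1), lin)
  first_recent <- match("recent", labels)
  expect_true(all(labels[seq_len(first_recent - 1)] == "ancient"))
  expect_true(all(labels[first_recent:length(labels)] == "recent"))
})

test_that("outgroup-ortholog flag implies an ancient label on this fixture", {
  tax <- make_taxonomy()
  lin <- focal_lineage(tax)
  expect_true(flag_outgroup_ortholog(c(9606L, 7227L)))
  expect_false(flag_outgroup_ortholog(c(9606L, 10090L)))
  leaves <- setdiff(tax$nodes$taxid, tax$nodes$parent)
  withr::with_seed(21, {
    for (i in 1:50) {
      taxa <- unique(c(9606L, sample(leaves, sample(1:3, 1))))
      if (flag_outgroup_ortholog(taxa)) {
        lca <- lca_on_lineage(taxa, tax, lin)
        expect_equal(classify_age(lca, lin), "ancient")
      }
    }
  })
})

test_that("clade binning conserves totals and keeps zero-count clades", {
  tax <- make_taxonomy()
  lin <- focal_lineage(tax)
  eutheria <- tax$nodes$taxid[tax$nodes$name == "Eutheria"]
  lca <- tibble::tibble(gene_symbol = c("A", "B", "C"),
                        lca_taxid = eutheria)
  bins <- bin_by_clade(lca, lin)
  expect_equal(nrow(bins), nrow(lin))
  expect_equal(bins$n_genes[bins$taxid == eutheria], 3L)
  expect_equal(sum(bins$n_genes), 3L)
  # empty input -> all-zero histogram
  bins0 <- bin_by_clade(lca[0, ], lin)
  expect_equal(sum(bins0$n_genes), 0L)
  # conservation on random result sets
  withr::with_seed(31, {
    for (i in 1:100) {
      k <- sample(0:20, 1)
      rand <- tibble::tibble(
        gene_symbol = as.character(seq_len(k)),
        lca_taxid = sample(lin$taxid, k, replace = TRUE))
      expect_equal(sum(bin_by_clade(rand, lin)$n_genes), k)
    }
  })
  p <- plot_origin_histogram(bins)
  expect_s3_class(p, "ggplot")
})

test_that("gene_ancestry assembles per-gene results with the taxonomy pin", {
  tax <- make_taxonomy()
  memb <- tibble::tibble(
    gene_symbol = c("G1", "G1", "G2", "G2", "G2"),
    taxid = c(9606L, 10090L, 9606L, 7227L, 7955L))
  res <- gene_ancestry(memb, tax = tax)
  expect_equal(res$age_label[res$gene_symbol == "G1"], "recent")
  expect_equal(res$age_label[res$gene_symbol == "G2"], "ancient")
  expect_true(res$fly_ortholog[res$gene_symbol == "G2"])
  expect_false(res$fly_ortholog[res$gene_symbol == "G1"])
  expect_equal(attr(res, "taxonomy_checksum"), tax$checksum)
})
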