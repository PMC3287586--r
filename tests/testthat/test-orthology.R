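# One shared labelled proteome for the module: 5 families x 6 taxa with
# decoys at the stated mutation rate.
ortho_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pr <- make_proteome(proteome_config(
        families = 5L, family_size_range = c(6L, 6L),
        mutation_rate = 0.05, decoy_rate = 0.1, seq_length = 150L,
        seed = 42L))
      sc <- similarity_matrix(pr$records)
      cal <- calibrate_thresholds(pr$records, sc)
      cache <<- list(pr = pr, sc = sc, cal = cal)
    }
    cache
  }
})

test_that("self-alignment score equals the BLOSUM62 diagonal sum", {
  seqs <- c("MKTAYIAKQR", "ACDEFGHIKLMNPQRSTVWY")
  b62 <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings",
                                envir = e); e$BLOSUM62
  })
  for (s in seqs) {
    chars <- strsplit(s, "")[[1]]
    expect_equal(similarity(s, s), sum(diag(b62[chars, chars])))
  }
  expect_error(similarity("MKT!", "MKT"), "invalid")
})

test_that("similarity is symmetric on 100 random pairs", {
  withr::with_seed(5, {
    aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
            "P", "Q", "R", "S", "T", "V", "W", "Y")
    for (i in 1:100) {
      a <- paste(sample(aa, 30, replace = TRUE), collapse = "")
      b <- paste(sample(aa, 30, replace = TRUE), collapse = "")
      expect_identical(similarity(a, b), similarity(b, a))
    }
  })
})

test_that("decoys score below family members in exhaustive comparison", {
  fx <- ortho_fixture()
  expect_true(fx$cal$separable)
  expect_gt(fx$cal$within_min, fx$cal$between_max)
})

test_that("best_hit agrees with an exhaustive scan over every (query, taxon) pair", {
  fx <- ortho_fixture()
  rec <- fx$pr$records
  sc <- fx$sc
  for (q in rec$seq_id) {
    for (tx in unique(rec$taxid)) {
      got <- best_hit(q, tx, rec, sc, min_score = 0)
      targets <- setdiff(rec$seq_id[rec$taxid == tx], q)
      if (length(targets) == 0) {
        expect_true(is.na(got))
      } else {
        best <- max(sc[q, targets])
        exp <- sort(targets[sc[q, targets] == best])[1]
        expect_identical(got, exp)
      }
    }
  }
  # exact copy of the query is its own best hit
  copy_rec <- tibble::tibble(
    seq_id = c("q", "copy"), taxid = c(1L, 2L),
    sequence = rep(rec$sequence[1], 2))
  expect_identical(best_hit("q", 2L, copy_rec), "copy")
  # nothing above the floor -> NA
  expect_true(is.na(best_hit(rec$seq_id[1], rec$taxid[2], rec, sc,
                             min_score = 1e6)))
})

test_that("BBH closure is a fixed point containing the seeds", {
  fx <- ortho_fixture()
  rec <- fx$pr$records
  # database of seeds only -> members = seeds
  seeds_only <- rec[rec$seq_id %in% c("FAM1_9606", "FAM1_10090"), ]
  expect_setequal(
    seedlinkage_expand(c("FAM1_9606", "FAM1_10090"), seeds_only),
    c("FAM1_9606", "FAM1_10090"))
  # full database: closure recovers the family; re-running adds nothing
  m1 <- seedlinkage_expand("FAM1_9606", rec,
                           min_score = fx$cal$min_score, scores = fx$sc)
  expect_setequal(m1, rec$seq_id[!is.na(rec$family) & rec$family == "FAM1"])
  m2 <- seedlinkage_expand(m1, rec, min_score = fx$cal$min_score,
                           scores = fx$sc)
  expect_setequal(m2, m1)
})

test_that("zero-mutation family of identical sequences is fully recruited", {
  pr0 <- make_proteome(proteome_config(
    taxa = c(1L, 2L, 3L, 4L, 5L), families = 1L,
    family_size_range = c(5L, 5L), mutation_rate = 0, decoy_rate = 0,
    seed = 3L))
  m <- seedlinkage_expand(pr0$records$seq_id[1], pr0$records)
  expect_setequal(m, pr0$records$seq_id)
})

test_that("ortholog-group union adds seed-sharing groups and is idempotent", {
  members <- c("s1", "a")
  groups <- tibble::tibble(group_id = c("g1", "g1", "g2", "g2"),
                           seq_id = c("s1", "x", "y", "z"))
  u1 <- ko_union(members, seeds = "s1", groups)
  expect_setequal(u1$seq_id, c("s1", "a", "x"))
  expect_equal(u1$provenance[u1$seq_id == "x"], "ko_union")
  # no group contains a seed -> unchanged
  u0 <- ko_union(members, seeds = "none", groups)
  expect_setequal(u0$seq_id, members)
  # idempotent
  expect_identical(ko_union(u1, "s1", groups), u1)
  # overlapping groups rejected
  bad <- tibble::tibble(group_id = c("g1", "g2"), seq_id = c("s1", "s1"))
  expect_error(ko_union(members, "s1", bad), "overlap")
  # property check on random partitions
  withr::with_seed(11, {
    for (i in 1:20) {
      ids <- paste0("p", 1:12)
      grp <- tibble::tibble(group_id = sample(paste0("g", 1:4), 12,
                                              replace = TRUE),
                            seq_id = ids)
      mem <- sample(ids, 3)
      once <- ko_union(mem, mem[1], grp)
      twice <- ko_union(once, mem[1], grp)
      expect_identical(once, twice)
    }
  })
})

test_that("verification removes planted decoys but never seeds", {
  fx <- ortho_fixture()
  rec <- fx$pr$records
  decoys <- rec$seq_id[is.na(rec$family)]
  cl <- structure(list(
    gene_symbol = "FAM1", seeds = "FAM1_9606",
    members = tibble::tibble(
      seq_id = c(rec$seq_id[rec$family %in% "FAM1"], decoys),
      provenance = "seedlinkage"),
    removed = character(), removed_fraction = 0),
    class = "seed_cluster")
  cl$members$provenance[cl$members$seq_id == "FAM1_9606"] <- "seed"
  v <- verify_cluster(cl, rec, fx$cal$min_verify_score, fx$sc)
  expect_setequal(v$removed, decoys)                 # all decoys removed
  expect_true("FAM1_9606" %in% v$members$seq_id)     # seed kept
  expect_equal(v$removed_fraction,
               length(decoys) / (length(decoys) + 5))
  # all-identical members: nothing removed
  pr0 <- make_proteome(proteome_config(
    taxa = 1:3, families = 1L, family_size_range = c(3L, 3L),
    mutation_rate = 0, decoy_rate = 0, seed = 2L))
  cl0 <- build_cluster("F", pr0$records$seq_id[1], pr0$records,
                       min_score = 1)
  expect_length(cl0$removed, 0)
  expect_equal(cl0$removed_fraction, 0)
})

test_that("planted families are recovered for at least 95% of seeds", {
  fx <- ortho_fixture()
  rec <- fx$pr$records
  seeds <- rec[!is.na(rec$family) & rec$taxid == 9606L, ]
  clusters <- cluster_genes(
    tibble::tibble(gene_symbol = seeds$family, seq_id = seeds$seq_id),
    rec, min_score = fx$cal$min_score,
    min_verify_score = fx$cal$min_verify_score)
  ok <- vapply(clusters, function(cl) {
    truth <- rec$seq_id[!is.na(rec$family) & rec$family == cl$gene_symbol]
    setequal(cl$members$seq_id, truth)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
  # verification conservation: members + removed = pre-verification members
  for (cl in clusters) {
    expect_length(intersect(cl$members$seq_id, cl$removed), 0)
    expect_true(all(cl$seeds %in% cl$members$seq_id))
  }
})

test_that("cluster statistics pool correctly over clusters", {
  fx <- ortho_fixture()
  rec <- fx$pr$records
  seeds <- rec[!is.na(rec$family) & rec$taxid == 9606L, ]
  clusters <- cluster_genes(
    tibble::tibble(gene_symbol = seeds$family, seq_id = seeds$seq_id),
    rec, min_score = fx$cal$min_score)
  st <- cluster_stats(clusters, rec)
  pooled <- cluster_pooled_stats(clusters, rec)
  # pooled fraction equals the size-weighted mean of per-cluster fractions
  expect_equal(pooled$frac_sp,
               sum(st$frac_sp * st$size) / sum(st$size))
  expect_equal(pooled$frac_complete,
               sum(st$frac_complete * st$size) / sum(st$size))
  expect_equal(pooled$size_min, min(st$size))
  expect_equal(pooled$size_max, max(st$size))
  # single 2-member sp/complete cluster -> fractions 1
  rec2 <- tibble::tibble(seq_id = c("a", "b"), taxid = c(1L, 2L),
                         sequence = "MKT", source_db = "sp",
                         complete_genome = TRUE, family = "F")
  cl2 <- structure(list(gene_symbol = "F", seeds = "a",
                        members = tibble::tibble(
                          seq_id = c("a", "b"),
                          provenance = c("seed", "seedlinkage")),
                        removed = character(), removed_fraction = 0),
                   class = "seed_cluster")
  st2 <- cluster_stats(list(cl2), rec2)
  expect_equal(st2$frac_sp, 1)
  expect_equal(st2$frac_complete, 1)
  expect_equal(nrow(cluster_stats(list(), rec2)), 0L)
})
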