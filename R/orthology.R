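AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

check_aa <- function(seq) {
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), AA_ALPHABET)
  if (length(bad) > 0) {
    lp_input_error(paste("invalid amino-acid letters:",
                         paste(bad, collapse = ", ")))
  }
  invisible(seq)
}

#' Local-alignment similarity between two protein sequences
#'
#' Deterministic, symmetric Smith-Waterman score (BLOSUM62, gap open 11,
#' gap extend 1), computed with `Biostrings::pairwiseAlignment`. This is the
#' pluggable similarity oracle standing behind best-hit searches and cluster
#' verification; any function with the same signature can replace it.
#'
#' @param a,b Amino-acid sequences (strings over the 20 residues plus X).
#' @return A single numeric alignment score.
#' @export
similarity <- function(a, b) {
  check_aa(a); check_aa(b)
  blosum62 <- get_blosum62()
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "local", substitutionMatrix = blosum62,
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' All-pairs similarity matrix for a proteome
#'
#' @param records Tibble with `seq_id`, `sequence`.
#' @return A symmetric numeric matrix with seq_ids as dimnames.
#' @export
similarity_matrix <- function(records) {
  for (s in records$sequence) check_aa(s)
  blosum62 <- get_blosum62()
  seqs <- Biostrings::AAStringSet(setNames(records$sequence,
                                           records$seq_id))
  n <- length(seqs)
  m <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n)) {
    sc <- Biostrings::pairwiseAlignment(
      seqs[i:n], seqs[[i]], type = "local",
      substitutionMatrix = blosum62, gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    m[i, i:n] <- sc
    m[i:n, i] <- sc
  }
  m
}

#' Best hit of a query within one target taxon
#'
#' Highest-scoring record of the target taxon (the query record itself
#' excluded), subject to `score >= min_score`; ties broken by ascending
#' seq_id; `NA` when no record qualifies.
#'
#' @param query_id A seq_id present in `records`.
#' @param taxid Target taxon.
#' @param records Proteome tibble (`seq_id`, `taxid`, `sequence`).
#' @param scores Optional precomputed [similarity_matrix()].
#' @param min_score Score floor.
#' @return A seq_id or `NA_character_`.
#' @export
best_hit <- function(query_id, taxid, records, scores = NULL,
                     min_score = 0) {
  targets <- records$seq_id[records$taxid == taxid &
                              records$seq_id != query_id]
  if (length(targets) == 0) return(NA_character_)
  targets <- sort(targets)
  sc <- if (!is.null(scores)) {
    scores[query_id, targets]
  } else {
    q <- records$sequence[records$seq_id == query_id]
    vapply(targets, function(t) {
      similarity(q, records$sequence[records$seq_id == t])
    }, numeric(1))
  }
  best <- which(sc == max(sc))[1]   # targets sorted: first max = lowest id
  if (sc[best] < min_score) return(NA_character_)
  targets[best]
}

#' Expand a seed set by bidirectional-best-hit closure
#'
#' Starting from the seeds, for each current member and each other taxon the
#' member's best hit `h` is recruited iff the best hit of `h` back into the
#' member's taxon is itself a current member; iterated to a fixed point.
#' Deterministic under the stated tie rules, and a fixed point: re-running
#' on the result adds nothing.
#'
#' @param seeds Character seq_ids, present in `records`.
#' @param records Proteome tibble.
#' @param taxa Taxa to search (default: all taxa in `records`).
#' @param min_score Score floor for best hits.
#' @param scores Optional precomputed [similarity_matrix()].
#' @return Character vector of member seq_ids (sorted; includes seeds).
#' @export
seedlinkage_expand <- function(seeds, records, taxa = NULL, min_score = 0,
                               scores = NULL) {
  stopifnot(all(seeds %in% records$seq_id))
  taxa <- taxa %||% sort(unique(records$taxid))
  taxid_of_seq <- setNames(records$taxid, records$seq_id)
  members <- sort(unique(seeds))
  repeat {
    added <- character()
    for (m in members) {
      for (tx in setdiff(taxa, taxid_of_seq[[m]])) {
        h <- best_hit(m, tx, records, scores, min_score)
        if (is.na(h) || h %in% members || h %in% added) next
        back <- best_hit(h, taxid_of_seq[[m]], records, scores, min_score)
        if (!is.na(back) && back %in% members) {
          added <- c(added, h)
        }
      }
    }
    if (length(added) == 0) break
    members <- sort(unique(c(members, added)))
  }
  members
}

#' Union cluster members with seed-containing ortholog groups
#'
#' Adds every record belonging to an ortholog group that contains a seed.
#' `groups` must be a (possibly partial) partition: a sequence may belong to
#' at most one group. Idempotent.
#'
#' @param members Tibble `seq_id`, `provenance`, or character seq_ids
#'   (provenance then assumed `seedlinkage`).
#' @param seeds Character seed seq_ids.
#' @param groups Tibble `group_id`, `seq_id`.
#' @return Tibble `seq_id`, `provenance` with recruited members labelled
#'   `ko_union`.
#' @export
ko_union <- function(members, seeds, groups) {
  if (!is.data.frame(members)) {
    members <- tibble(seq_id = members,
                      provenance = ifelse(members %in% seeds, "seed",
                                          "seedlinkage"))
  }
  groups <- as_tibble(groups)
  if (anyDuplicated(groups$seq_id)) {
    lp_input_error("ortholog groups overlap: a seq_id occurs in two groups")
  }
  hit_groups <- unique(groups$group_id[groups$seq_id %in% seeds])
  new_ids <- setdiff(groups$seq_id[groups$group_id %in% hit_groups],
                     members$seq_id)
  bind_rows(members,
            tibble(seq_id = new_ids,
                   provenance = rep("ko_union", length(new_ids)))) |>
    arrange(.data$seq_id)
}

#' Verify a cluster against its seeds and discard false positives
#'
#' Every non-seed member must reach `similarity >= min_verify_score` against
#' at least one seed; failures are moved to the removed set. Seeds are never
#' removed. Mirrors the verification step in which recruited proteins are
#' searched against the seeds and false positives discarded.
#'
#' @param cluster A `seed_cluster` (see [build_cluster()]).
#' @param records Proteome tibble.
#' @param min_verify_score Verification score floor.
#' @param scores Optional precomputed [similarity_matrix()].
#' @return The cluster with `removed` filled and `removed_fraction` set
#'   (removed / non-seed members before verification).
#' @export
verify_cluster <- function(cluster, records, min_verify_score,
                           scores = NULL) {
  stopifnot(inherits(cluster, "seed_cluster"))
  mem <- cluster$members
  non_seed <- mem$seq_id[!mem$seq_id %in% cluster$seeds]
  if (length(non_seed) == 0) {
    cluster$removed <- character()
    cluster$removed_fraction <- 0
    return(cluster)
  }
  seq_of <- setNames(records$sequence, records$seq_id)
  ok <- vapply(non_seed, function(id) {
    best <- max(vapply(cluster$seeds, function(s) {
      if (!is.null(scores)) scores[id, s] else
        similarity(seq_of[[id]], seq_of[[s]])
    }, numeric(1)))
    best >= min_verify_score
  }, logical(1))
  removed <- non_seed[!ok]
  cluster$members <- mem |> filter(!.data$seq_id %in% removed)
  cluster$removed <- sort(removed)
  cluster$removed_fraction <- length(removed) / length(non_seed)
  cluster
}

#' Build one per-gene homolog cluster
#'
#' Seed expansion by bidirectional best hits, then one pass of ortholog-
#' group union, then verification against the seeds.
#'
#' @param gene_symbol Gene the cluster belongs to.
#' @param seeds Seed seq_ids (curated products of the gene).
#' @param records Proteome tibble.
#' @param groups Optional ortholog groups (`group_id`, `seq_id`).
#' @param min_score Best-hit score floor (see [calibrate_thresholds()]).
#' @param min_verify_score Verification floor.
#' @param scores Optional precomputed [similarity_matrix()].
#' @return A `seed_cluster`: list with `gene_symbol`, `seeds`, `members`
#'   (tibble `seq_id`, `provenance` in `{seed, seedlinkage, ko_union}`),
#'   `removed`, `removed_fraction`.
#' @export
build_cluster <- function(gene_symbol, seeds, records, groups = NULL,
                          min_score = 0, min_verify_score = min_score,
                          scores = NULL) {
  ids <- seedlinkage_expand(seeds, records, min_score = min_score,
                            scores = scores)
  members <- tibble(seq_id = ids,
                    provenance = ifelse(ids %in% seeds, "seed",
                                        "seedlinkage"))
  if (!is.null(groups)) {
    members <- ko_union(members, seeds, groups)
  }
  cl <- structure(list(gene_symbol = gene_symbol, seeds = sort(seeds),
                       members = members, removed = character(),
                       removed_fraction = 0),
                  class = "seed_cluster")
  verify_cluster(cl, records, min_verify_score, scores)
}

#' @export
print.seed_cluster <- function(x, ...) {
  cat(sprintf("<seed_cluster> %s: %d members (%d removed at verification)\n",
              x$gene_symbol, nrow(x$members), length(x$removed)))
  invisible(x)
}

#' @export
tidy.seed_cluster <- function(x, ...) {
  x$members |> mutate(gene_symbol = x$gene_symbol, .before = 1)
}

#' Build clusters for a table of genes and seeds
#'
#' @param seed_map Tibble `gene_symbol`, `seq_id` (one row per seed).
#' @param records Proteome tibble.
#' @param groups Optional ortholog groups.
#' @param min_score,min_verify_score Score floors.
#' @return A named list of `seed_cluster` objects.
#' @export
cluster_genes <- function(seed_map, records, groups = NULL,
                          min_score = 0, min_verify_score = min_score) {
  scores <- similarity_matrix(records)
  genes <- sort(unique(seed_map$gene_symbol))
  setNames(lapply(genes, function(g) {
    build_cluster(g, seed_map$seq_id[seed_map$gene_symbol == g],
                  records, groups, min_score, min_verify_score, scores)
  }), genes)
}

#' Calibrate similarity thresholds on a proteome with known families
#'
#' Computes the within-family score distribution and the cross-family (and
#' decoy) score distribution on a labelled proteome, and returns the
#' midpoint between the lowest within-family and the highest cross-family
#' score as the best-hit and verification floor. Thresholds are data-derived
#' configuration, never hard-coded constants.
#'
#' @param records Proteome tibble with a `family` column (`NA` for decoys).
#' @param scores Optional precomputed [similarity_matrix()].
#' @return List `min_score`, `min_verify_score`, `within_min`,
#'   `between_max`, `separable` (whether the distributions do not overlap).
#' @export
calibrate_thresholds <- function(records, scores = NULL) {
  scores <- scores %||% similarity_matrix(records)
  fam <- setNames(records$family, records$seq_id)
  ids <- records$seq_id
  within <- c(); between <- c()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      same <- !is.na(fam[[ids[i]]]) && !is.na(fam[[ids[j]]]) &&
        fam[[ids[i]]] == fam[[ids[j]]]
      if (same) within <- c(within, scores[ids[i], ids[j]])
      else between <- c(between, scores[ids[i], ids[j]])
    }
  }
  wmin <- min(within); bmax <- max(between)
  mid <- (wmin + bmax) / 2
  list(min_score = mid, min_verify_score = mid,
       within_min = wmin, between_max = bmax, separable = wmin > bmax)
}

#' Per-cluster and pooled cluster statistics
#'
#' @param clusters List of `seed_cluster` objects.
#' @param records Proteome tibble with `source_db`, `complete_genome`.
#' @return Tibble `gene_symbol`, `size`, `n_sp`, `n_complete`, `frac_sp`,
#'   `frac_complete`, `removed_fraction`.
#' @export
cluster_stats <- function(clusters, records) {
  if (length(clusters) == 0) {
    return(tibble(gene_symbol = character(), size = integer(),
                  n_sp = integer(), n_complete = integer(),
                  frac_sp = numeric(), frac_complete = numeric(),
                  removed_fraction = numeric()))
  }
  purrr::map_dfr(clusters, function(cl) {
    idx <- match(cl$members$seq_id, records$seq_id)
    size <- nrow(cl$members)
    n_sp <- sum(records$source_db[idx] == "sp")
    n_complete <- sum(records$complete_genome[idx])
    tibble(gene_symbol = cl$gene_symbol, size = size,
           n_sp = n_sp, n_complete = n_complete,
           frac_sp = n_sp / size, frac_complete = n_complete / size,
           removed_fraction = cl$removed_fraction)
  })
}

#' @rdname cluster_stats
#' @return For `cluster_pooled_stats()`: a one-row tibble with `n_clusters`,
#'   `size_min`, `size_max`, pooled `frac_sp` and `frac_complete`, and the
#'   pooled `removed_fraction`.
#' @export
cluster_pooled_stats <- function(clusters, records) {
  st <- cluster_stats(clusters, records)
  n_removed <- sum(vapply(clusters, function(cl) length(cl$removed),
                          integer(1)))
  n_nonseed <- sum(vapply(clusters, function(cl) {
    length(cl$removed) + sum(cl$members$provenance != "seed")
  }, integer(1)))
  tibble(n_clusters = nrow(st),
         size_min = min(st$size), size_max = max(st$size),
         frac_sp = sum(st$n_sp) / sum(st$size),
         frac_complete = sum(st$n_complete) / sum(st$size),
         removed_fraction = if (n_nonseed == 0) 0 else
           n_removed / n_nonseed)
}

#' Write per-cluster membership TSVs
#'
#' One `<gene>.tsv` per cluster with columns `seq_id`, `taxid`,
#' `provenance` (mirrors a two-column identifier/taxon listing plus
#' provenance).
#'
#' @param clusters List of `seed_cluster`s.
#' @param records Proteome tibble.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_clusters <- function(clusters, records, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (cl in clusters) {
    out <- cl$members |>
      mutate(taxid = records$taxid[match(.data$seq_id, records$seq_id)]) |>
      select("seq_id", "taxid", "provenance")
    readr::write_tsv(out, file.path(dir, paste0(cl$gene_symbol, ".tsv")),
                     progress = FALSE)
  }
  invisible(dir)
}
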