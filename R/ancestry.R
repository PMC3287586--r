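#' Taxonomy trees and lineage-constrained last-common-ancestor assignment
#'
#' A `taxonomy` is a rooted tree of taxa: a tibble of nodes
#' (`taxid`, `parent`, `rank`, `name`) where the root is its own parent.
#' Gene age is determined by placing each gene's ortholog-cluster taxa on the
#' tree and finding the most recent clade of the focal (root-to-human)
#' lineage that subtends them all.
#'
#' @name taxonomy
NULL

new_taxonomy <- function(nodes) {
  nodes <- as_tibble(nodes)[, c("taxid", "parent", "rank", "name")]
  nodes$taxid <- as.integer(nodes$taxid)
  nodes$parent <- as.integer(nodes$parent)
  tax <- structure(
    list(nodes = arrange(nodes, .data$taxid),
         root = NA_integer_, checksum = NA_character_),
    class = "taxonomy")
  tax <- validate_taxonomy(tax)
  tax$checksum <- taxonomy_checksum(tax)
  tax
}

validate_taxonomy <- function(tax) {
  n <- tax$nodes
  if (anyDuplicated(n$taxid)) {
    lp_input_error(sprintf("duplicated taxid: %d",
                           n$taxid[duplicated(n$taxid)][1]))
  }
  is_root <- n$parent == n$taxid | is.na(n$parent)
  if (sum(is_root) != 1) {
    lp_input_error(sprintf("taxonomy must have exactly one root, found %d",
                           sum(is_root)))
  }
  root <- n$taxid[is_root]
  orphans <- setdiff(n$parent[!is_root], n$taxid)
  if (length(orphans) > 0) {
    lp_input_error(sprintf("parent taxid %d not present in taxonomy",
                           orphans[1]))
  }
  # parent-chase from every node must reach the root without revisiting
  parent_of <- setNames(n$parent, n$taxid)
  for (tx in n$taxid) {
    seen <- integer()
    cur <- tx
    while (cur != root) {
      if (cur %in% seen) {
        lp_input_error(sprintf("cycle in taxonomy involving taxid %d", cur))
      }
      seen <- c(seen, cur)
      cur <- parent_of[[as.character(cur)]]
    }
  }
  tax$root <- root
  tax
}

# Version pin: md5 of the canonical node table, carried into results.
taxonomy_checksum <- function(tax) {
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  readr::write_tsv(tax$nodes, f, progress = FALSE)
  unname(tools::md5sum(f))
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("<taxonomy> %d taxa, root %d (%s), checksum %s\n",
              nrow(x$nodes), x$root,
              x$nodes$name[x$nodes$taxid == x$root],
              substr(x$checksum, 1, 8)))
  invisible(x)
}

#' @export
tidy.taxonomy <- function(x, ...) x$nodes

parse_dmp <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("\t\\|$", "", lines)
  strsplit(lines, "\t\\|\t")
}

#' Load a taxonomy from NCBI taxdump files or JSON
#'
#' Accepts the pipe-tab `nodes.dmp`/`names.dmp` dialect of the NCBI taxdump,
#' or the JSON encoding written by [write_taxonomy_json()]. The tree is
#' validated: exactly one root (its own parent), no cycles, no orphan
#' parents; violations raise an error naming the offending taxid.
#'
#' @param nodes Path to `nodes.dmp`, to a JSON file, or a directory
#'   containing `nodes.dmp` and `names.dmp`.
#' @param names Path to `names.dmp` (ignored for JSON input).
#' @return A `taxonomy` object with a content checksum for version pinning.
#' @export
load_taxonomy <- function(nodes, names = NULL) {
  if (dir.exists(nodes)) {
    names <- file.path(nodes, "names.dmp")
    nodes <- file.path(nodes, "nodes.dmp")
  }
  if (grepl("\\.json$", nodes, ignore.case = TRUE)) {
    j <- jsonlite::read_json(nodes, simplifyVector = TRUE)
    return(new_taxonomy(as_tibble(j$nodes)))
  }
  if (is.null(names)) {
    lp_input_error("`names` (names.dmp) is required for dmp input")
  }
  nd <- parse_dmp(nodes)
  node_tbl <- tibble(
    taxid = as.integer(vapply(nd, `[`, character(1), 1)),
    parent = as.integer(vapply(nd, `[`, character(1), 2)),
    rank = vapply(nd, `[`, character(1), 3))
  nm <- parse_dmp(names)
  cls <- vapply(nm, function(x) if (length(x) >= 4) x[4] else "", character(1))
  nm <- nm[cls == "scientific name"]
  name_tbl <- tibble(
    taxid = as.integer(vapply(nm, `[`, character(1), 1)),
    name = vapply(nm, `[`, character(1), 2))
  new_taxonomy(left_join(node_tbl, name_tbl, by = "taxid"))
}

taxid_of <- function(tax, x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (!x %in% tax$nodes$taxid) {
      lp_input_error(sprintf("taxid %d not in taxonomy", x))
    }
    return(x)
  }
  hit <- tax$nodes$taxid[tax$nodes$name == x]
  if (length(hit) != 1) {
    lp_input_error(sprintf("clade name '%s' not uniquely in taxonomy", x))
  }
  hit
}

# Ancestor chain, self first, root last.
ancestor_chain <- function(tax, taxid) {
  parent_of <- setNames(tax$nodes$parent, tax$nodes$taxid)
  chain <- integer()
  cur <- taxid
  repeat {
    chain <- c(chain, cur)
    if (cur == tax$root) break
    cur <- parent_of[[as.character(cur)]]
  }
  chain
}

#' Focal lineage: the root-to-focal clade chain
#'
#' @param tax A `taxonomy`.
#' @param focal Focal taxon (taxid or scientific name; default Homo sapiens).
#' @return A tibble `taxid`, `name`, `depth` ordered root first, focal last.
#' @export
focal_lineage <- function(tax, focal = 9606L) {
  stopifnot(inherits(tax, "taxonomy"))
  focal <- taxid_of(tax, focal)
  chain <- rev(ancestor_chain(tax, focal))
  tibble(taxid = chain,
         name = tax$nodes$name[match(chain, tax$nodes$taxid)],
         depth = seq_along(chain))
}

#' Last common ancestor of a taxon set, constrained to the focal lineage
#'
#' Returns the tip-most (most recent) clade of the focal lineage that is an
#' ancestor-or-self of every taxid in `taxa` — equivalently, the deepest
#' element of the intersection of all members' ancestor chains restricted to
#' the lineage. A taxid that is itself a lineage node counts as subtended by
#' itself.
#'
#' @param taxa Integer taxon IDs (an ortholog cluster's taxa); non-empty.
#' @param tax A `taxonomy`.
#' @param lineage A lineage tibble from [focal_lineage()].
#' @return A single taxid on the lineage.
#' @export
lca_on_lineage <- function(taxa, tax, lineage) {
  stopifnot(inherits(tax, "taxonomy"))
  taxa <- unique(as.integer(taxa))
  if (length(taxa) == 0) lp_input_error("`taxa` must be non-empty")
  chains <- lapply(taxa, function(tx) ancestor_chain(tax, taxid_of(tax, tx)))
  common <- Reduce(intersect, chains)
  on_lineage <- lineage$taxid[lineage$taxid %in% common]
  if (length(on_lineage) == 0) {
    lp_input_error("no lineage clade subtends all cluster taxa")
  }
  on_lineage[length(on_lineage)]
}

#' Classify a lineage LCA as ancient or recent
#'
#' A gene is `ancient` when its LCA clade lies strictly rootward of the
#' reference clade on the focal lineage; the reference clade itself and every
#' clade tipward of it yield `recent`. The default reference, Euteleostomi
#' (bony vertebrates), is the conventional cutoff for this classification.
#'
#' @param lca_taxid Taxid on the lineage.
#' @param lineage Lineage tibble from [focal_lineage()].
#' @param reference Reference clade (name or taxid); must be on the lineage.
#' @return `"ancient"` or `"recent"`.
#' @export
classify_age <- function(lca_taxid, lineage, reference = "Euteleostomi") {
  ref_pos <- if (is.numeric(reference)) {
    match(as.integer(reference), lineage$taxid)
  } else {
    match(reference, lineage$name)
  }
  if (is.na(ref_pos)) {
    lp_config_error("reference",
                    "reference clade is not on the focal lineage")
  }
  pos <- match(as.integer(lca_taxid), lineage$taxid)
  if (is.na(pos)) lp_input_error("lca_taxid is not on the focal lineage")
  if (pos < ref_pos) "ancient" else "recent"
}

#' Flag presence of an outgroup ortholog in a cluster
#'
#' @param taxa Cluster taxon IDs.
#' @param outgroup Outgroup taxid (default 7227, Drosophila melanogaster).
#' @return Logical.
#' @export
flag_outgroup_ortholog <- function(taxa, outgroup = 7227L) {
  as.integer(outgroup) %in% as.integer(taxa)
}

#' Per-gene ancestry from ortholog clusters
#'
#' Maps each cluster to the LCA clade of its member taxa on the focal
#' lineage, labels it ancient/recent relative to the reference clade, and
#' flags outgroup orthologs. Genes with no cluster produce no row and
#' propagate as "unassigned" in pathway annotation.
#'
#' @param clusters A list of `seed_cluster` objects (see [build_cluster()]),
#'   or a data frame with columns `gene_symbol` and `taxid` (one row per
#'   cluster member).
#' @param records Proteome record tibble (`seq_id`, `taxid`) used to resolve
#'   member taxa; ignored when `clusters` is already a gene/taxid table.
#' @param tax A `taxonomy`.
#' @param focal,reference,outgroup See [focal_lineage()], [classify_age()],
#'   [flag_outgroup_ortholog()].
#' @return A tibble `gene_symbol`, `lca_taxid`, `lca_name`, `age_label`,
#'   `fly_ortholog`, `n_taxa`, `cluster_taxa` (list-column), with the
#'   taxonomy checksum in attribute `"taxonomy_checksum"`.
#' @export
gene_ancestry <- function(clusters, records = NULL, tax,
                          focal = 9606L, reference = "Euteleostomi",
                          outgroup = 7227L) {
  lineage <- focal_lineage(tax, focal)
  if (is.data.frame(clusters)) {
    per_gene <- clusters |>
      group_by(.data$gene_symbol) |>
      summarise(taxa = list(unique(.data$taxid)), .groups = "drop")
  } else {
    per_gene <- purrr::map_dfr(clusters, function(cl) {
      ids <- cl$members$seq_id
      tibble(gene_symbol = cl$gene_symbol,
             taxa = list(unique(records$taxid[match(ids, records$seq_id)])))
    })
  }
  out <- per_gene |>
    mutate(
      lca_taxid = purrr::map_int(.data$taxa,
                                 ~ lca_on_lineage(.x, tax, lineage)),
      lca_name = lineage$name[match(.data$lca_taxid, lineage$taxid)],
      age_label = purrr::map_chr(.data$lca_taxid,
                                 ~ classify_age(.x, lineage, reference)),
      fly_ortholog = purrr::map_lgl(.data$taxa,
                                    ~ flag_outgroup_ortholog(.x, outgroup)),
      n_taxa = lengths(.data$taxa)) |>
    rename(cluster_taxa = "taxa") |>
    select("gene_symbol", "lca_taxid", "lca_name", "age_label",
           "fly_ortholog", "n_taxa", "cluster_taxa") |>
    arrange(.data$gene_symbol)
  attr(out, "taxonomy_checksum") <- tax$checksum
  out
}

#' Bin genes by origin clade along the focal lineage
#'
#' Counts genes per lineage clade of origin; clades with zero genes are
#' retained with count 0, and the counts total the number of genes supplied.
#'
#' @param lca Tibble from [gene_ancestry()] (needs `lca_taxid`).
#' @param lineage Lineage tibble from [focal_lineage()].
#' @return A tibble `taxid`, `name`, `depth`, `n_genes` in root-first order.
#' @export
bin_by_clade <- function(lca, lineage) {
  counts <- table(factor(lca$lca_taxid, levels = lineage$taxid))
  lineage |>
    mutate(n_genes = as.integer(counts[as.character(.data$taxid)]))
}

#' Bar chart of gene origins along the focal lineage
#'
#' @param bins Tibble from [bin_by_clade()].
#' @return A ggplot object (genes per clade of origin, root-first order).
#' @export
plot_origin_histogram <- function(bins) {
  ggplot2::ggplot(bins, ggplot2::aes(
    x = factor(.data$name, levels = bins$name), y = .data$n_genes)) +
    ggplot2::geom_col(fill = "#4477AA") +
    ggplot2::labs(x = "clade of origin (rootward to tipward)",
                  y = "number of genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
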