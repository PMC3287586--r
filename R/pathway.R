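PATHWAY_SUBTYPES <- c("activation", "inhibition", "expression", "repression",
                      "binding/association", "phosphorylation", "indirect")

# KGML relation type per subtype, and arrow glyph used as the subtype value.
KGML_RELTYPE <- c(activation = "PPrel", inhibition = "PPrel",
                  expression = "GErel", repression = "GErel",
                  `binding/association` = "PPrel",
                  phosphorylation = "PPrel", indirect = "PPrel")
KGML_VALUE <- c(activation = "-->", inhibition = "--|",
                expression = "-->", repression = "--|",
                `binding/association` = "---",
                phosphorylation = "+p", indirect = "..>")
# subtype name as serialized in KGML (graph keeps the short label)
KGML_SUBTYPE_OUT <- c(activation = "activation", inhibition = "inhibition",
                      expression = "expression", repression = "repression",
                      `binding/association` = "binding/association",
                      phosphorylation = "phosphorylation",
                      indirect = "indirect effect")
# ancestry label <-> node fill color (the field's conventional figure colors)
ANCESTRY_BGCOLOR <- c(ancient = "#D8BFD8", recent = "#BFFFBF",
                      unassigned = "#D3D3D3")

#' Pathway graphs
#'
#' A `pathway_graph` holds genes as nodes and directed, typed, evidence-
#' carrying edges. Nodes are a tibble (`symbol`, `ancestry`, `fly_ortholog`),
#' edges a tibble (`source`, `target`, `subtype`, `evidence` list-column of
#' PMIDs). Invariants: edge endpoints exist as nodes; evidence lists are
#' non-empty and duplicate-free; at most one edge per (source, target,
#' subtype) — re-assertions merge evidence.
#'
#' @param nodes Data frame with at least `symbol`; `ancestry` and
#'   `fly_ortholog` are added (default `"unassigned"`, `FALSE`).
#' @param edges Data frame with `source`, `target`, `subtype`, `evidence`
#'   (list-column, or character vector of single PMIDs).
#' @return A validated `pathway_graph`.
#' @export
pathway_graph <- function(nodes = NULL, edges = NULL) {
  nodes <- if (is.null(nodes)) {
    tibble(symbol = character())
  } else {
    as_tibble(nodes)
  }
  if (!"ancestry" %in% names(nodes)) nodes$ancestry <- "unassigned"
  if (!"fly_ortholog" %in% names(nodes)) nodes$fly_ortholog <- FALSE
  edges <- if (is.null(edges)) {
    tibble(source = character(), target = character(),
           subtype = character(), evidence = list())
  } else {
    as_tibble(edges)
  }
  if (!is.list(edges$evidence)) {
    edges$evidence <- as.list(as.character(edges$evidence))
  }
  g <- structure(
    list(nodes = arrange(nodes[, c("symbol", "ancestry", "fly_ortholog")],
                         .data$symbol),
         edges = arrange(edges[, c("source", "target", "subtype",
                                   "evidence")],
                         .data$source, .data$target, .data$subtype)),
    class = "pathway_graph")
  validate_pathway_graph(g)
}

validate_pathway_graph <- function(g) {
  n <- g$nodes; e <- g$edges
  if (anyDuplicated(n$symbol)) {
    lp_input_error("duplicated node symbol in pathway graph")
  }
  if (!all(n$ancestry %in% c("ancient", "recent", "unassigned"))) {
    lp_input_error("node ancestry must be ancient/recent/unassigned")
  }
  if (nrow(e) > 0) {
    missing <- setdiff(c(e$source, e$target), n$symbol)
    if (length(missing) > 0) {
      lp_input_error(paste("edge endpoint not a node:",
                           paste(missing, collapse = ", ")))
    }
    if (!all(e$subtype %in% PATHWAY_SUBTYPES)) {
      lp_input_error(paste("unknown relation subtype:",
                           paste(setdiff(e$subtype, PATHWAY_SUBTYPES),
                                 collapse = ", ")))
    }
    bad_ev <- vapply(e$evidence, function(x) {
      length(x) == 0 || anyDuplicated(x) > 0
    }, logical(1))
    if (any(bad_ev)) {
      lp_input_error("edge evidence must be non-empty and duplicate-free")
    }
    key <- paste(e$source, e$target, e$subtype, sep = "\r")
    if (anyDuplicated(key)) {
      lp_input_error("duplicate (source, target, subtype) edge")
    }
  }
  g
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph> %d genes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$edges) > 0) {
    tab <- table(x$edges$subtype)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.pathway_graph <- function(x, ...) {
  x$edges |>
    mutate(n_evidence = lengths(.data$evidence))
}

#' @export
glance.pathway_graph <- function(x, ...) {
  tibble(n_genes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_evidence = length(unique(unlist(x$edges$evidence))),
         n_ancient = sum(x$nodes$ancestry == "ancient"),
         n_recent = sum(x$nodes$ancestry == "recent"),
         n_unassigned = sum(x$nodes$ancestry == "unassigned"))
}

#' Curation rules for pathway construction
#'
#' Declarative stand-in for manual curation: which biointeraction types are
#' accepted (type 1 — gene, word, gene in order within a sentence — by
#' default, the strongest evidence class), how word polarity maps to a
#' relation subtype, word-specific subtype overrides for neutral verbs, and
#' optional symbol allow/deny lists.
#'
#' @param accepted_types Integer type codes kept (default 1).
#' @param polarity_map Named map polarity -> subtype.
#' @param word_subtypes Named map word -> subtype, overriding `polarity_map`
#'   (defaults route binding verbs to binding/association and
#'   phosphorylation verbs to phosphorylation).
#' @param allow,deny Optional symbol allow/deny lists.
#' @param strict Error (rather than keep as "indirect") when an interaction
#'   has unknown polarity.
#' @return A `curation_rules` list.
#' @export
curation_rules <- function(accepted_types = 1L,
                           polarity_map = c(activation = "activation",
                                            repression = "inhibition",
                                            neutral = "binding/association",
                                            unknown = "indirect"),
                           word_subtypes = c(
                             binds = "binding/association",
                             bind = "binding/association",
                             bound = "binding/association",
                             interacts = "binding/association",
                             interact = "binding/association",
                             associates = "binding/association",
                             associate = "binding/association",
                             phosphorylates = "phosphorylation",
                             phosphorylate = "phosphorylation",
                             phosphorylated = "phosphorylation"),
                           allow = NULL, deny = NULL, strict = FALSE) {
  structure(list(accepted_types = as.integer(accepted_types),
                 polarity_map = polarity_map,
                 word_subtypes = word_subtypes,
                 allow = allow, deny = deny, strict = strict),
            class = "curation_rules")
}

#' Build a pathway graph from extracted interactions
#'
#' Keeps interactions whose type is accepted by the rules, applies symbol
#' allow/deny lists, maps each interaction to a relation subtype (word
#' override first, then polarity), directs the edge by textual order (A acts
#' on B), and merges duplicate assertions across abstracts by accumulating
#' their evidence PMIDs. Curation is idempotent: re-curating a concatenated
#' interaction list yields the same graph.
#'
#' @param interactions Tibble from [extract_interactions()].
#' @param rules A [curation_rules()] object.
#' @return A `pathway_graph`.
#' @export
curate <- function(interactions, rules = curation_rules()) {
  stopifnot(inherits(rules, "curation_rules"))
  x <- as_tibble(interactions) |>
    filter(.data$type %in% rules$accepted_types)
  if (!is.null(rules$allow)) {
    x <- filter(x, .data$gene_a %in% rules$allow,
                .data$gene_b %in% rules$allow)
  }
  if (!is.null(rules$deny)) {
    x <- filter(x, !.data$gene_a %in% rules$deny,
                !.data$gene_b %in% rules$deny)
  }
  if (nrow(x) == 0) return(pathway_graph())

  if (rules$strict && any(x$polarity == "unknown")) {
    bad <- unique(x$word[x$polarity == "unknown"])
    bad[is.na(bad)] <- "<none>"
    abort(sprintf("interactions with unknown polarity under strict curation: %s",
                  paste(unique(bad), collapse = ", ")),
          class = "litpath_curation_error")
  }

  subtype <- ifelse(
    !is.na(x$word) & x$word %in% names(rules$word_subtypes),
    unname(rules$word_subtypes[x$word]),
    unname(rules$polarity_map[x$polarity]))
  if (any(is.na(subtype))) {
    lp_input_error(paste("no subtype mapping for polarity:",
                         paste(unique(x$polarity[is.na(subtype)]),
                               collapse = ", ")))
  }
  x$subtype <- subtype

  edges <- x |>
    group_by(.data$gene_a, .data$gene_b, .data$subtype) |>
    summarise(evidence = list(sort(unique(as.character(.data$pmid)))),
              .groups = "drop") |>
    rename(source = "gene_a", target = "gene_b")
  nodes <- tibble(symbol = sort(unique(c(edges$source, edges$target))))
  pathway_graph(nodes, edges)
}

#' Annotate pathway nodes with ancestry results
#'
#' Nodes gain an ancestry label (`ancient`/`recent`/`unassigned`) and an
#' outgroup(fly)-ortholog flag from a [gene_ancestry()] table. Symbols absent
#' from the table — genes that produced no ortholog cluster — stay
#' `unassigned`. Annotation never adds or removes nodes or edges.
#'
#' @param graph A `pathway_graph`.
#' @param lca Tibble with `gene_symbol`, `age_label`, `fly_ortholog`.
#' @return The annotated `pathway_graph`.
#' @export
annotate_ancestry <- function(graph, lca) {
  stopifnot(inherits(graph, "pathway_graph"))
  idx <- match(graph$nodes$symbol, lca$gene_symbol)
  graph$nodes$ancestry <- ifelse(is.na(idx), "unassigned",
                                 lca$age_label[idx])
  graph$nodes$fly_ortholog <- ifelse(is.na(idx), FALSE,
                                     lca$fly_ortholog[idx])
  validate_pathway_graph(graph)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

# Deterministic grid layout in lexicographic node order (layered rows of 6).
kgml_layout <- function(n) {
  i <- seq_len(n) - 1L
  tibble(x = 70L + 110L * (i %% 6L), y = 45L + 65L * (i %/% 6L))
}

#' Serialize a pathway graph as KGML
#'
#' Writes KGML (KEGG Markup Language): one `entry` per gene (stable integer
#' ids in lexicographic symbol order from 1, `name` = gene symbol) with
#' deterministic grid graphics, and one `relation` per edge with a `subtype`
#' child naming the relation subtype. Two dialect extensions make the
#' serialization lossless: evidence PMIDs travel in an extra
#' `<subtype name="evidence">` child, node ancestry in the graphics
#' `bgcolor` (lilac = ancient, green = recent, grey = unassigned) and the
#' fly-ortholog marker as a trailing `*` on the graphics display name.
#' Output is byte-stable for a fixed graph and validates against the
#' packaged KGML v0.7.2 DTD.
#'
#' @param graph A `pathway_graph`.
#' @param path Optional output path; when `NULL` the KGML string is
#'   returned.
#' @param name Pathway name attribute.
#' @param org Organism tag attribute.
#' @param title Pathway title attribute.
#' @return The KGML document as a single string (invisibly when `path` is
#'   given).
#' @export
write_kgml <- function(graph, path = NULL, name = "litpath:custom",
                       org = "hsa", title = "literature-mined pathway") {
  stopifnot(inherits(graph, "pathway_graph"))
  validate_pathway_graph(graph)
  n <- arrange(graph$nodes, .data$symbol)
  ids <- setNames(seq_len(nrow(n)), n$symbol)
  lay <- kgml_layout(nrow(n))

  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<!DOCTYPE pathway SYSTEM \"KGML_v0.7.2_.dtd\">",
    sprintf("<pathway name=\"%s\" org=\"%s\" title=\"%s\">",
            xml_escape(name), xml_escape(org), xml_escape(title)))
  for (k in seq_len(nrow(n))) {
    label <- paste0(n$symbol[k], if (n$fly_ortholog[k]) "*" else "")
    lines <- c(lines,
      sprintf("  <entry id=\"%d\" name=\"%s\" type=\"gene\">",
              ids[[n$symbol[k]]], xml_escape(n$symbol[k])),
      sprintf(paste0("    <graphics name=\"%s\" type=\"rectangle\" ",
                     "x=\"%d\" y=\"%d\" width=\"46\" height=\"17\" ",
                     "fgcolor=\"#000000\" bgcolor=\"%s\"/>"),
              xml_escape(label), lay$x[k], lay$y[k],
              ANCESTRY_BGCOLOR[[n$ancestry[k]]]),
      "  </entry>")
  }
  e <- arrange(graph$edges, .data$source, .data$target, .data$subtype)
  for (k in seq_len(nrow(e))) {
    lines <- c(lines,
      sprintf("  <relation entry1=\"%d\" entry2=\"%d\" type=\"%s\">",
              ids[[e$source[k]]], ids[[e$target[k]]],
              KGML_RELTYPE[[e$subtype[k]]]),
      sprintf("    <subtype name=\"%s\" value=\"%s\"/>",
              KGML_SUBTYPE_OUT[[e$subtype[k]]],
              xml_escape(KGML_VALUE[[e$subtype[k]]])),
      sprintf("    <subtype name=\"evidence\" value=\"%s\"/>",
              xml_escape(paste(e$evidence[[k]], collapse = " "))),
      "  </relation>")
  }
  lines <- c(lines, "</pathway>")
  doc <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeChar(doc, con, eos = NULL)
    return(invisible(doc))
  }
  doc
}

#' Validate a KGML document against the packaged DTD
#'
#' Runs real libxml2 DTD validation: the document is parsed next to the
#' packaged KGML v0.7.2 DTD with DTD loading and validation enabled, and any
#' validity complaints are collected.
#'
#' @param kgml A KGML string or a path to a KGML file.
#' @return A list with `valid` (logical) and `messages` (character).
#' @export
kgml_validate <- function(kgml) {
  dir <- tempfile("kgml")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  file.copy(lp_extdata("KGML_v0.7.2_.dtd"),
            file.path(dir, "KGML_v0.7.2_.dtd"))
  doc_path <- file.path(dir, "doc.xml")
  if (length(kgml) == 1 && !grepl("^\\s*<", kgml) && file.exists(kgml)) {
    file.copy(kgml, doc_path)
  } else {
    writeLines(kgml, doc_path, useBytes = TRUE)
  }
  msgs <- character()
  ok <- withCallingHandlers(
    tryCatch({
      xml2::read_xml(doc_path, options = c("DTDLOAD", "DTDVALID"))
      TRUE
    }, error = function(e) {
      msgs <<- c(msgs, conditionMessage(e))
      FALSE
    }),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  list(valid = ok && length(msgs) == 0, messages = msgs)
}

#' Read a KGML document into a pathway graph
#'
#' Inverse of [write_kgml()] on its image. Entries of type `gene` become
#' nodes (ancestry decoded from the graphics `bgcolor`, fly-ortholog flag
#' from a trailing `*` on the graphics name); relations become edges, with
#' the `evidence` subtype child restoring PMIDs. Unknown relation subtypes
#' are preserved as `"indirect"` with a warning. A relation referencing a
#' missing entry id is an error reporting the element path.
#'
#' @param kgml A KGML string, or a path to a KGML file.
#' @return A `pathway_graph`.
#' @export
read_kgml <- function(kgml) {
  doc <- xml2::read_xml(kgml)
  entries <- xml2::xml_find_all(doc, "/pathway/entry")
  sym_of <- character()
  nodes <- list()
  for (en in entries) {
    id <- xml2::xml_attr(en, "id")
    sym <- xml2::xml_attr(en, "name")
    gr <- xml2::xml_find_first(en, "graphics")
    bg <- if (inherits(gr, "xml_missing")) NA_character_ else
      xml2::xml_attr(gr, "bgcolor")
    gname <- if (inherits(gr, "xml_missing")) sym else
      xml2::xml_attr(gr, "name")
    anc_idx <- match(bg, ANCESTRY_BGCOLOR)
    sym_of[[id]] <- sym
    nodes[[length(nodes) + 1]] <- tibble(
      symbol = sym,
      ancestry = if (is.na(anc_idx)) "unassigned" else
        names(ANCESTRY_BGCOLOR)[anc_idx],
      fly_ortholog = grepl("\\*$", gname %||% sym))
  }
  rels <- xml2::xml_find_all(doc, "/pathway/relation")
  edges <- list()
  in_subtypes <- setNames(names(KGML_SUBTYPE_OUT), KGML_SUBTYPE_OUT)
  for (i in seq_along(rels)) {
    rel <- rels[[i]]
    e1 <- xml2::xml_attr(rel, "entry1")
    e2 <- xml2::xml_attr(rel, "entry2")
    for (ed in c(e1, e2)) {
      if (!ed %in% names(sym_of)) {
        lp_input_error(sprintf(
          "relation at /pathway/relation[%d] references missing entry id %s",
          i, ed))
      }
    }
    subs <- xml2::xml_find_all(rel, "subtype")
    sub_names <- xml2::xml_attr(subs, "name")
    ev <- character()
    subtype <- NA_character_
    for (k in seq_along(sub_names)) {
      if (sub_names[k] == "evidence") {
        ev <- strsplit(xml2::xml_attr(subs[[k]], "value"), " ",
                       fixed = TRUE)[[1]]
      } else if (is.na(subtype)) {
        if (sub_names[k] %in% names(in_subtypes)) {
          subtype <- unname(in_subtypes[sub_names[k]])
        } else {
          warn(sprintf("unknown relation subtype '%s'; kept as 'indirect'",
                       sub_names[k]))
          subtype <- "indirect"
        }
      }
    }
    if (is.na(subtype)) subtype <- "indirect"
    if (length(ev) == 0) ev <- "unspecified"
    edges[[length(edges) + 1]] <- tibble(
      source = sym_of[[e1]], target = sym_of[[e2]], subtype = subtype,
      evidence = list(sort(unique(ev))))
  }
  pathway_graph(bind_rows(nodes),
                if (length(edges) > 0) bind_rows(edges) else NULL)
}

#' Convert a curated edge table to a pathway graph
#'
#' Convenience for hand-curated edge lists such as [litpath_demo_edges()]:
#' columns `source`, `target`, `subtype`, `evidence` (semicolon- or
#' space-separated PMIDs per row; duplicate rows merge their evidence).
#'
#' @param edges A data frame of curated edges.
#' @return A `pathway_graph`.
#' @export
as_pathway_graph <- function(edges) {
  e <- as_tibble(edges) |>
    mutate(evidence_split = strsplit(as.character(.data$evidence),
                                     "[; ]+")) |>
    tidyr::unnest("evidence_split") |>
    group_by(.data$source, .data$target, .data$subtype) |>
    summarise(evidence = list(sort(unique(.data$evidence_split))),
              .groups = "drop")
  nodes <- tibble(symbol = sort(unique(c(e$source, e$target))))
  pathway_graph(nodes, e)
}

#' Export a pathway graph as GraphML
#'
#' @param graph A `pathway_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    lp_usage_error("GraphML export requires the igraph package")
  }
  e <- graph$edges |>
    mutate(evidence = vapply(.data$evidence, paste, character(1),
                             collapse = ";"))
  ig <- igraph::graph_from_data_frame(
    e, directed = TRUE,
    vertices = graph$nodes |> rename(name = "symbol"))
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Plot a pathway graph
#'
#' Nodes on the deterministic KGML grid layout, filled by ancestry label
#' (with the fly-ortholog marker appended to the symbol), edges colored by
#' relation subtype.
#'
#' @param object A `pathway_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.pathway_graph <- function(object, ...) {
  n <- arrange(object$nodes, .data$symbol)
  lay <- kgml_layout(nrow(n))
  nd <- dplyr::bind_cols(n, lay) |>
    mutate(label = paste0(.data$symbol,
                          ifelse(.data$fly_ortholog, "*", "")))
  ed <- object$edges |>
    left_join(nd |> select("symbol", x0 = "x", y0 = "y"),
              by = c(source = "symbol")) |>
    left_join(nd |> select("symbol", x1 = "x", y1 = "y"),
              by = c(target = "symbol"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, color = .data$subtype),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      alpha = 0.7) +
    ggplot2::geom_label(
      data = nd,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label,
                   fill = .data$ancestry),
      size = 3) +
    ggplot2::scale_fill_manual(
      values = c(ancient = "#D8BFD8", recent = "#BFFFBF",
                 unassigned = "#D3D3D3")) +
    ggplot2::scale_y_reverse() +
    ggplot2::theme_void()
}

#' @rdname autoplot.pathway_graph
#' @param graph A `pathway_graph`.
#' @export
plot_pathway <- function(graph, ...) autoplot.pathway_graph(graph, ...)
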