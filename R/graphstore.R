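# Property-graph export (graph-database bulk-import CSV convention plus a
# JSON dump), pathway search scored by classifier confidence, neighborhood
# extraction, and expression overlays.

REL_TYPES <- c("INTERACT_WITH", "PREDICTED_INTERACT_WITH", "HOMOLOG_OF",
               "HAS_DOMAIN", "HAS_GO")

fmt_prop <- function(x) {
  if (is.numeric(x)) {
    vapply(x, function(v) {
      if (is.na(v)) "" else format(v, digits = 12, trim = TRUE,
                                   scientific = v != 0 && abs(v) < 1e-4)
    }, character(1))
  } else {
    y <- as.character(x); y[is.na(y)] <- ""; y
  }
}

#' Assemble the multi-network property graph
#'
#' Builds the property graph connecting one or more predicted networks to
#' the reference human interactome: Human-labelled nodes joined by
#' `INTERACT_WITH`, dataset-labelled contig nodes joined by
#' `PREDICTED_INTERACT_WITH` (property `votes`), `HOMOLOG_OF` from each
#' contig to its human protein (properties `blast_evalue`, `coverage`,
#' `rule`), `HAS_DOMAIN` from sequences to PFAM domain nodes (coordinates
#' and E-value), and `HAS_GO` from human proteins to GO-term nodes. Only
#' `HOMOLOG_OF` is part of the original schema description; the other four
#' relationship types are this package's concrete schema.
#'
#' @param networks Named list of `predicted_network` objects (names become
#'   node labels), or a single network.
#' @param assignments Named list (parallel to `networks`) of assignment
#'   data frames, or a single data frame.
#' @param reference Reference interactome (`igraph`).
#' @param domain_annotations Optional data frame of merged domain
#'   annotations (`seq_id`, `domain_id`, `seq_start`, `seq_end`, `evalue`).
#' @param go_annotations Optional data frame (`symbol`, `go_id`).
#' @return Object of class `property_graph`: `nodes` (data frame `id`,
#'   `label`) and `rels` (named list of per-type data frames, all
#'   properties held as character).
#' @export
build_property_graph <- function(networks, assignments, reference,
                                 domain_annotations = NULL,
                                 go_annotations = NULL) {
  if (inherits(networks, "predicted_network")) {
    networks <- stats::setNames(list(networks), networks$dataset)
  }
  if (is.data.frame(assignments)) {
    assignments <- stats::setNames(rep(list(assignments), length(networks)),
                                   names(networks))
  }
  ref_nodes <- data.frame(id = igraph::V(reference)$name, label = "Human",
                          stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(reference)
  rel_int <- data.frame(start_id = pmin(el[, 1L], el[, 2L]),
                        end_id = pmax(el[, 1L], el[, 2L]),
                        stringsAsFactors = FALSE)
  contig_nodes <- list(); rel_pred <- list(); rel_hom <- list()
  for (ds in names(networks)) {
    net <- networks[[ds]]; asg <- assignments[[ds]]
    used <- sort(unique(c(net$nodes, asg$transcript_id)))
    contig_nodes[[ds]] <- data.frame(id = used, label = ds,
                                     stringsAsFactors = FALSE)
    e <- net$edges
    rel_pred[[ds]] <- data.frame(
      start_id = e$contig_a, end_id = e$contig_b,
      votes = fmt_prop(e$votes), stringsAsFactors = FALSE)
    rel_hom[[ds]] <- data.frame(
      start_id = asg$transcript_id, end_id = asg$human_symbol,
      blast_evalue = fmt_prop(asg$blast_evalue %||% rep(NA_real_, nrow(asg))),
      coverage = fmt_prop(asg$blast_coverage %||% rep(NA_real_, nrow(asg))),
      rule = fmt_prop(asg$rule), stringsAsFactors = FALSE)
  }
  nodes <- rbind(ref_nodes, do.call(rbind, contig_nodes))
  rels <- list(INTERACT_WITH = rel_int,
               PREDICTED_INTERACT_WITH = do.call(rbind, rel_pred),
               HOMOLOG_OF = do.call(rbind, rel_hom))
  if (!is.null(domain_annotations) && nrow(domain_annotations) > 0L) {
    da <- domain_annotations
    nodes <- rbind(nodes, data.frame(id = sort(unique(da$domain_id)),
                                     label = "Domain", stringsAsFactors = FALSE))
    rels$HAS_DOMAIN <- data.frame(
      start_id = da$seq_id, end_id = da$domain_id,
      seq_start = fmt_prop(da$seq_start), seq_end = fmt_prop(da$seq_end),
      evalue = fmt_prop(da$evalue), stringsAsFactors = FALSE)
  }
  if (!is.null(go_annotations) && nrow(go_annotations) > 0L) {
    ga <- go_annotations
    nodes <- rbind(nodes, data.frame(id = sort(unique(ga$go_id)),
                                     label = "GO", stringsAsFactors = FALSE))
    rels$HAS_GO <- data.frame(start_id = ga$symbol, end_id = ga$go_id,
                              stringsAsFactors = FALSE)
  }
  nodes <- unique(nodes)
  nodes <- nodes[order(nodes$label, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  pg <- structure(list(nodes = nodes, rels = rels), class = "property_graph")
  validate_property_graph(pg)
  pg
}

validate_property_graph <- function(pg) {
  ids <- pg$nodes$id
  for (type in names(pg$rels)) {
    r <- pg$rels[[type]]
    dangling <- unique(c(setdiff(r$start_id, ids), setdiff(r$end_id, ids)))
    if (length(dangling) > 0L) {
      stop("dangling ", type, " endpoint(s): ",
           paste(utils::head(dangling, 10L), collapse = ", "))
    }
  }
  invisible(pg)
}

#' Export a property graph as bulk-import files
#'
#' Writes one `nodes_<label>.csv` per node label (`id:ID`, `:LABEL`
#' headers) and one `rels_<TYPE>.csv` per relationship type (`:START_ID`,
#' `:END_ID`, `:TYPE` plus property columns), in the bulk-import CSV
#' convention of graph databases, together with a single-file `graph.json`
#' dump. Rows are written in a canonical sort order so that an
#' export/import/export round trip is byte-identical.
#'
#' @param pg A `property_graph` (or the arguments of
#'   [build_property_graph()] via `...`).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
export_graph <- function(pg, dir) {
  validate_property_graph(pg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (lab in sort(unique(pg$nodes$label))) {
    sub <- pg$nodes[pg$nodes$label == lab, , drop = FALSE]
    sub <- sub[order(sub$id), , drop = FALSE]
    f <- file.path(dir, paste0("nodes_", gsub("[^A-Za-z0-9_]", "_", lab), ".csv"))
    lines <- c("id:ID,:LABEL", paste0(csv_quote(sub$id), ",", csv_quote(lab)))
    writeLines(lines, f)
    files <- c(files, f)
  }
  for (type in intersect(REL_TYPES, names(pg$rels))) {
    r <- pg$rels[[type]]
    props <- setdiff(names(r), c("start_id", "end_id"))
    ord <- do.call(order, r[c("start_id", "end_id", props)])
    r <- r[ord, , drop = FALSE]
    f <- file.path(dir, paste0("rels_", type, ".csv"))
    header <- paste(c(":START_ID", ":END_ID", ":TYPE", props), collapse = ",")
    body <- paste(csv_quote(r$start_id), csv_quote(r$end_id), type, sep = ",")
    for (p in props) body <- paste(body, csv_quote(r[[p]]), sep = ",")
    writeLines(c(header, body), f)
    files <- c(files, f)
  }
  json <- file.path(dir, "graph.json")
  dump <- list(nodes = pg$nodes,
               relationships = lapply(pg$rels, function(r) r))
  jsonlite::write_json(dump, json, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, json)
  invisible(files)
}

csv_quote <- function(x) {
  needs <- grepl('[",\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

#' Import a property graph from bulk-import files
#'
#' Inverse of [export_graph()]; properties stay character, so re-exporting
#' the result is lossless.
#'
#' @param dir Directory holding `nodes_*.csv` and `rels_*.csv`.
#' @return A `property_graph`.
#' @export
import_graph <- function(dir) {
  node_files <- sort(list.files(dir, "^nodes_.*\\.csv$", full.names = TRUE))
  rel_files <- sort(list.files(dir, "^rels_.*\\.csv$", full.names = TRUE))
  stopifnot(length(node_files) > 0L)
  nodes <- do.call(rbind, lapply(node_files, function(f) {
    d <- utils::read.csv(f, colClasses = "character", check.names = FALSE)
    data.frame(id = d[["id:ID"]], label = d[[":LABEL"]],
               stringsAsFactors = FALSE)
  }))
  nodes <- nodes[order(nodes$label, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  rels <- list()
  for (f in rel_files) {
    d <- utils::read.csv(f, colClasses = "character", check.names = FALSE)
    type <- d[[":TYPE"]][1L]
    props <- setdiff(names(d), c(":START_ID", ":END_ID", ":TYPE"))
    r <- data.frame(start_id = d[[":START_ID"]], end_id = d[[":END_ID"]],
                    stringsAsFactors = FALSE)
    for (p in props) r[[p]] <- d[[p]]
    rels[[type]] <- r
  }
  rels <- rels[intersect(REL_TYPES, names(rels))]
  structure(list(nodes = nodes, rels = rels), class = "property_graph")
}

net_igraph <- function(network) {
  e <- network$edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$contig_a, to = e$contig_b, votes = e$votes,
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE))
  g
}

#' Confidence-scored paths between two nodes
#'
#' Enumerates all simple paths of length at most `max_len` between two
#' contigs of a predicted network and scores each by the mean of its edge
#' vote fractions. Results are sorted by score (descending), then by
#' length, then by the lexicographic node sequence.
#'
#' @param network A `predicted_network`.
#' @param src,dst Distinct node identifiers present in the network.
#' @param max_len Maximum path length in edges (default 4).
#' @return List of `scored_path` objects: `nodes` (ordered), `votes` (per
#'   edge), `score` (mean vote).
#' @export
find_paths <- function(network, src, dst, max_len = 4L) {
  stopifnot(max_len >= 1L)
  if (src == dst) stop("src and dst must differ")
  missing <- setdiff(c(src, dst), network$nodes)
  if (length(missing) > 0L) stop("node(s) not in network: ",
                                 paste(missing, collapse = ", "))
  g <- net_igraph(network)
  paths <- igraph::all_simple_paths(g, from = src, to = dst, cutoff = max_len)
  scored <- lapply(paths, function(p) {
    nm <- igraph::V(g)$name[as.integer(p)]
    eid <- igraph::get_edge_ids(g, rep(nm, each = 2L)[-c(1L, 2L * length(nm))])
    v <- igraph::E(g)$votes[eid]
    structure(list(nodes = nm, votes = v, score = mean(v)),
              class = "scored_path")
  })
  ord <- order(-vapply(scored, `[[`, numeric(1), "score"),
               vapply(scored, function(p) length(p$nodes), integer(1)),
               vapply(scored, function(p) paste(p$nodes, collapse = "\r"),
                      character(1)))
  scored[ord]
}

#' Neighborhood subgraph of a node
#'
#' Induced subgraph of all nodes within `depth` hops of `node`, votes
#' preserved.
#'
#' @param network A `predicted_network`.
#' @param node Node identifier.
#' @param depth Hop limit (0 returns the node alone).
#' @return A `predicted_network` restricted to the neighborhood.
#' @export
neighborhood <- function(network, node, depth) {
  if (!(node %in% network$nodes)) stop("node not in network: ", node)
  g <- net_igraph(network)
  keep <- igraph::V(g)$name[as.integer(
    igraph::ego(g, order = depth, nodes = node)[[1L]])]
  e <- network$edges
  sel <- e$contig_a %in% keep & e$contig_b %in% keep
  structure(list(dataset = network$dataset,
                 edges = e[sel, , drop = FALSE],
                 nodes = sort(keep), cutoff = network$cutoff),
            class = "predicted_network")
}

#' Map expression values onto network nodes
#'
#' Single-sample mode bins each node's absolute expression into percentile
#' deciles; fold-change mode colors by `log2((a + pc) / (b + pc))` with a
#' pseudocount `pc` (zeros are common in digital expression counts).
#' Contigs absent from the matrix are flagged missing.
#'
#' @param network A `predicted_network`.
#' @param expr Numeric matrix, samples in rows, contigs in columns,
#'   values >= 0.
#' @param mode `"single"` or `"fold_change"`.
#' @param sample_a First (or only) sample name.
#' @param sample_b Second sample (required for fold change).
#' @param pseudocount Added to both counts in fold-change mode (default 1).
#' @return List with `value` (named numeric per node), `bin` (decile 1-10
#'   in single mode, sign bin in fold-change mode), `missing` (nodes not in
#'   the matrix).
#' @export
expression_overlay <- function(network, expr, mode = c("single", "fold_change"),
                               sample_a, sample_b = NULL, pseudocount = 1) {
  mode <- match.arg(mode)
  stopifnot(sample_a %in% rownames(expr))
  if (mode == "fold_change" && is.null(sample_b)) {
    stop("fold_change mode requires sample_b")
  }
  if (any(expr < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  nodes <- network$nodes
  present <- nodes[nodes %in% colnames(expr)]
  missing <- setdiff(nodes, present)
  if (mode == "single") {
    v <- expr[sample_a, present]
    # percentile decile: average ranks put all-equal values in one bin
    bin <- ceiling(rank(v) / length(v) * 10)
    out_bin <- stats::setNames(as.integer(bin), present)
  } else {
    stopifnot(sample_b %in% rownames(expr))
    a <- expr[sample_a, present]; b <- expr[sample_b, present]
    v <- log2((a + pseudocount) / (b + pseudocount))
    out_bin <- stats::setNames(as.integer(sign(round(v, 10))), present)
  }
  list(value = stats::setNames(as.numeric(v), present), bin = out_bin,
       missing = missing)
}
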