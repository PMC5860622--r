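# Candidate-pair generation, many-to-one pruning, network prediction and
# summary statistics.

#' Prune many-to-one contig homologies
#'
#' When more contigs than `max_per_protein` resolve to the same human
#' protein, only the contig with the lowest EggNOG E-value is kept (ties
#' broken by lexicographically smaller contig id; contigs with no EggNOG
#' E-value fall back to the BLAST E-value with a warning). The cap
#' generalizes to a parameter what was originally an ad-hoc intervention
#' on two extreme cases.
#'
#' @param assignments Assignment data frame (needs `transcript_id`,
#'   `human_symbol`, and `eggnog_evalue` / `blast_evalue` columns).
#' @param max_per_protein Maximum contigs allowed per human protein before
#'   pruning kicks in (default 100).
#' @return The pruned assignment data frame; number of removed contigs in
#'   attribute `n_pruned`.
#' @export
prune_many_to_one <- function(assignments, max_per_protein = 100L) {
  counts <- table(assignments$human_symbol)
  crowded <- names(counts)[counts > max_per_protein]
  if (length(crowded) == 0L) {
    attr(assignments, "n_pruned") <- 0L
    return(assignments)
  }
  drop <- character(0)
  for (sym in crowded) {
    sub <- assignments[assignments$human_symbol == sym, , drop = FALSE]
    ev <- sub$eggnog_evalue
    if (anyNA(ev)) {
      warning("contig(s) for ", sym,
              " lack an EggNOG E-value; falling back to BLAST E-value")
      ev[is.na(ev)] <- sub$blast_evalue[is.na(ev)]
    }
    ev[is.na(ev)] <- Inf
    keep <- sub$transcript_id[order(ev, sub$transcript_id)][1L]
    drop <- c(drop, setdiff(sub$transcript_id, keep))
  }
  message(length(drop), " contig(s) pruned from crowded homologies")
  out <- assignments[!(assignments$transcript_id %in% drop), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_pruned") <- length(drop)
  out
}

#' Candidate transcript pairs within the path-length horizon
#'
#' All unordered pairs of assigned contigs whose homologs lie at shortest
#' path 1..`max_path` in the reference interactome. Pairs at path 0
#' (both contigs resolving to the same protein: would be self-interactions
#' at the protein level) and disconnected pairs (path -1) are excluded.
#'
#' @param assignments Assignment data frame.
#' @param dist A `distance_store` (or `igraph` reference graph).
#' @param max_path Path-length horizon (default 2).
#' @return Data frame (`contig_a`, `contig_b`, `human_a`, `human_b`,
#'   `path_length`), pairs in canonical order.
#' @export
candidate_pairs <- function(assignments, dist, max_path = 2L) {
  if (inherits(dist, "igraph")) dist <- precompute_distances(dist)
  empty <- data.frame(contig_a = character(), contig_b = character(),
                      human_a = character(), human_b = character(),
                      path_length = integer(), stringsAsFactors = FALSE)
  n <- nrow(assignments)
  if (n < 2L) return(empty)
  ord <- order(assignments$transcript_id)
  tid <- assignments$transcript_id[ord]
  sym <- assignments$human_symbol[ord]
  idx <- match(sym, dist$nodes)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pairs[, 1L]; j <- pairs[, 2L]
  d <- rep(-1, length(i))
  ok <- !is.na(idx[i]) & !is.na(idx[j])
  d[ok] <- dist$d[cbind(idx[i][ok], idx[j][ok])]
  keep <- ok & d >= 1 & d <= max_path
  out <- data.frame(contig_a = tid[i[keep]], contig_b = tid[j[keep]],
                    human_a = sym[i[keep]], human_b = sym[j[keep]],
                    path_length = as.integer(d[keep]),
                    stringsAsFactors = FALSE)
  out[order(out$contig_a, out$contig_b), , drop = FALSE]
}

#' Predict an interaction network from candidate features
#'
#' Scores every candidate pair with the forest and keeps pairs whose vote
#' fraction reaches the cutoff.
#'
#' @param features Candidate feature data frame (from
#'   [compute_pair_features()], carrying `contig_a`/`contig_b`/`human_a`/
#'   `human_b`/`path_length` id columns).
#' @param model An `interolog_model`, or `NULL` when `votes` are supplied
#'   directly.
#' @param cutoff Vote threshold (default 0.6); a pair is kept iff
#'   `vote >= cutoff`.
#' @param dataset Name of the network.
#' @param votes Optional precomputed vote fractions (bypasses the model).
#' @return Object of class `predicted_network`: `dataset`, `edges` (data
#'   frame with `contig_a`, `contig_b`, `human_a`, `human_b`,
#'   `path_length`, `votes`), `nodes` (contigs in >= 1 edge), `cutoff`.
#' @export
predict_network <- function(features, model = NULL, cutoff = 0.6,
                            dataset = "network", votes = NULL) {
  if (is.null(votes)) {
    stopifnot(!is.null(model))
    votes <- predict_votes(model, features)
  }
  stopifnot(length(votes) == nrow(features))
  keep <- votes >= cutoff
  edges <- features[keep, c("contig_a", "contig_b", "human_a", "human_b",
                            "path_length"), drop = FALSE]
  edges$votes <- votes[keep]
  edges <- edges[edges$contig_a != edges$contig_b, , drop = FALSE]  # no self-edges
  edges <- edges[!duplicated(paste(edges$contig_a, edges$contig_b, sep = "\r")),
                 , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(dataset = dataset, edges = edges,
                 nodes = sort(unique(c(edges$contig_a, edges$contig_b))),
                 cutoff = cutoff),
            class = "predicted_network")
}

#' Summary statistics of a predicted network
#'
#' The summary-table row for one dataset. `average_degree` follows the
#' interactions/nodes definition (not the graph-theoretic 2E/N), and
#' `pct_plen1` is the fraction of predicted interactions whose human pair
#' is itself an edge of the reference interactome.
#'
#' @param network A `predicted_network`.
#' @param assignments Assignment data frame used for the prediction.
#' @param graph Reference interactome (`igraph`).
#' @param total_contigs Total number of contigs in the dataset before
#'   homology resolution (defaults to the number of assignments when
#'   unknown).
#' @return List of class `network_summary` with fields `dataset`,
#'   `total_contigs`, `contigs_with_homolog`, `human_homologs`,
#'   `contigs_in_interactome`, `n_interactions`, `average_degree`,
#'   `pct_plen1`, and `empty` flag.
#' @export
summarize_network <- function(network, assignments, graph,
                              total_contigs = NULL) {
  e <- network$edges
  n_nodes <- length(network$nodes)
  n_int <- nrow(e)
  if (n_int == 0L) {
    avg <- 0; p1 <- 0; empty <- TRUE
  } else {
    empty <- FALSE
    avg <- n_int / n_nodes
    ref_keys <- apply(igraph::as_edgelist(graph), 1L,
                      function(r) paste(min(r), max(r), sep = "\r"))
    edge_keys <- paste(pmin(e$human_a, e$human_b),
                       pmax(e$human_a, e$human_b), sep = "\r")
    p1 <- mean(edge_keys %in% ref_keys)
  }
  structure(list(
    dataset = network$dataset,
    total_contigs = total_contigs %||% nrow(assignments),
    contigs_with_homolog = nrow(assignments),
    human_homologs = length(unique(assignments$human_symbol)),
    contigs_in_interactome = n_nodes,
    n_interactions = n_int,
    average_degree = avg,
    pct_plen1 = p1,
    empty = empty), class = "network_summary")
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, as used to relate the
#' summary-table columns across datasets.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Spearman's rho.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("constant vector: rank correlation undefined")
  }
  stats::cor(x, y, method = "spearman")
}

#' Histogram of predicted-edge votes per dataset
#'
#' @param networks A `predicted_network` or list of them.
#' @param breaks Bin edges over the vote range (default width 0.05 over
#'   \[0.6, 1\]; the last bin is closed on the right).
#' @return Data frame (`dataset`, `bin_lo`, `bin_hi`, `count`); counts per
#'   dataset sum to that network's edge count.
#' @export
vote_distribution <- function(networks, breaks = seq(0.6, 1, by = 0.05)) {
  if (inherits(networks, "predicted_network")) networks <- list(networks)
  rows <- lapply(networks, function(net) {
    v <- net$edges$votes
    bin <- findInterval(v, breaks, rightmost.closed = TRUE)
    # clamp out-of-range votes into the boundary bins so counts conserve
    bin <- pmin(pmax(bin, 1L), length(breaks) - 1L)
    counts <- tabulate(bin, nbins = length(breaks) - 1L)
    data.frame(dataset = net$dataset,
               bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
               count = counts, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
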