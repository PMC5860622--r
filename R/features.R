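# The 19-feature vector per candidate transcript pair: interactome path
# length, domain-domain interaction score, three GO normalized term
# overlaps, and per-transcript alignment measures for the two members.

FEATURE_ROSTER <- c(
  "path_length", "dom_int_score", "nto_mf", "nto_bp", "nto_cc",
  "blast_evalue_a", "blast_evalue_b", "eggnog_evalue_a", "eggnog_evalue_b",
  "blast_qcov_a", "blast_qcov_b", "pfam_metascore_a", "pfam_metascore_b",
  "blast_brh_a", "blast_brh_b", "eggnog_brh_a", "eggnog_brh_b",
  "pfam_brh_a", "pfam_brh_b")

#' The 19-feature roster
#' @return Character vector of feature names in canonical order.
#' @export
feature_roster <- function() FEATURE_ROSTER

#' Parse a Gene Ontology OBO 1.2 flat file
#'
#' Minimal parser for the OBO 1.2 stanza format: keeps term id, name,
#' namespace, `is_a` parents and `part_of` relationships; obsolete terms
#' and non-Term stanzas are skipped. `alt_id`s resolve to their primary
#' term.
#'
#' @param path OBO file.
#' @return Object of class `go_dag`: list with `terms` (data frame `id`,
#'   `name`, `aspect`), `parents` (named list id -> parent ids via is_a and
#'   part_of) and `alt` (named character vector alt_id -> id).
#' @export
read_obo <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  term_starts <- which(lines == "[Term]")
  ids <- character(0); names_ <- character(0); aspects <- character(0)
  parents <- list(); alt <- character(0)
  bounds <- c(term_starts, length(lines) + 1L)
  for (k in seq_along(term_starts)) {
    block <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    block <- block[nzchar(block) & !startsWith(block, "[")]
    field <- function(key) sub(paste0("^", key, ": "), "",
                               grep(paste0("^", key, ": "), block, value = TRUE))
    if (length(field("is_obsolete")) > 0L && field("is_obsolete")[1L] == "true")
      next
    id <- field("id")[1L]
    par <- sub(" !.*$", "", field("is_a"))
    rel <- field("relationship")
    po <- sub(" !.*$", "", sub("^part_of ", "", grep("^part_of ", rel, value = TRUE)))
    ids <- c(ids, id)
    nm <- field("name"); names_ <- c(names_, if (length(nm)) nm[1L] else id)
    ns <- field("namespace")
    aspects <- c(aspects, if (length(ns)) ns[1L] else NA_character_)
    parents[[id]] <- c(par, po)
    for (a in field("alt_id")) alt[a] <- id
  }
  structure(list(terms = data.frame(id = ids, name = names_, aspect = aspects,
                                    stringsAsFactors = FALSE),
                 parents = parents, alt = alt),
            class = "go_dag")
}

#' Reflexive ancestor closure of GO terms
#'
#' Every term is its own ancestor; closure follows `is_a` and `part_of`
#' edges. Unknown ids are ignored with a warning.
#'
#' @param dag A `go_dag`.
#' @param terms Character vector of GO ids.
#' @return Character vector: the union of the terms and all their
#'   ancestors.
#' @export
go_ancestors <- function(dag, terms) {
  terms <- unique(ifelse(terms %in% names(dag$alt),
                         unname(dag$alt[terms]), terms))
  unknown <- setdiff(terms, dag$terms$id)
  if (length(unknown) > 0L) {
    warning("unknown GO id(s) ignored: ", paste(unknown, collapse = ", "))
    terms <- setdiff(terms, unknown)
  }
  seen <- character(0); frontier <- terms
  while (length(frontier) > 0L) {
    seen <- c(seen, frontier)
    nxt <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
  }
  sort(unique(seen))
}

#' GO normalized term overlap (NTO)
#'
#' For one GO aspect, the size of the intersection of the two reflexive
#' ancestor closures divided by the size of the smaller closure. 1 when
#' the annotations coincide, 0 when they share nothing; if either protein
#' has no annotation in the aspect the score is 0 (absence of evidence for
#' similarity, not undefined).
#'
#' @param dag A `go_dag`.
#' @param terms_a,terms_b GO ids annotated on the two proteins.
#' @param aspect One of `"molecular_function"`, `"biological_process"`,
#'   `"cellular_component"`; terms of other aspects are filtered out.
#' @return Numeric in \[0, 1\].
#' @export
go_nto <- function(dag, terms_a, terms_b, aspect) {
  stopifnot(aspect %in% c("molecular_function", "biological_process",
                          "cellular_component"))
  in_aspect <- dag$terms$id[!is.na(dag$terms$aspect) &
                              dag$terms$aspect == aspect]
  unknown <- setdiff(c(terms_a, terms_b),
                     c(dag$terms$id, names(dag$alt)))
  if (length(unknown) > 0L) {
    warning("unknown GO id(s) ignored: ", paste(unknown, collapse = ", "))
  }
  ca <- go_ancestors(dag, intersect(terms_a, in_aspect))
  cb <- go_ancestors(dag, intersect(terms_b, in_aspect))
  ca <- intersect(ca, in_aspect); cb <- intersect(cb, in_aspect)
  if (length(ca) == 0L || length(cb) == 0L) return(0)
  length(intersect(ca, cb)) / min(length(ca), length(cb))
}

# Per-symbol closures for all three aspects, computed once per analysis.
go_closure_index <- function(dag, annotations) {
  aspects <- c(mf = "molecular_function", bp = "biological_process",
               cc = "cellular_component")
  asp_of <- stats::setNames(dag$terms$aspect, dag$terms$id)
  by_sym <- split(annotations$go_id, annotations$symbol)
  lapply(by_sym, function(terms) {
    lapply(aspects, function(aspect) {
      t_asp <- terms[!is.na(asp_of[terms]) & asp_of[terms] == aspect]
      if (length(t_asp) == 0L) return(character(0))
      cl <- suppressWarnings(go_ancestors(dag, t_asp))
      cl[!is.na(asp_of[cl]) & asp_of[cl] == aspect]
    })
  })
}

nto_from_closures <- function(ca, cb) {
  if (length(ca) == 0L || length(cb) == 0L) return(0)
  length(intersect(ca, cb)) / min(length(ca), length(cb))
}

#' Precompute all-pairs shortest-path distances
#'
#' Unweighted breadth-first distances between every pair of reference
#' proteins, stored densely so that [path_length()] answers in constant
#' time.
#'
#' @param graph Reference interactome (`igraph`).
#' @return Object of class `distance_store`.
#' @export
precompute_distances <- function(graph) {
  d <- igraph::distances(graph)
  structure(list(d = d, nodes = rownames(d)), class = "distance_store")
}

#' Shortest-path length between two reference proteins
#'
#' @param x A `distance_store` from [precompute_distances()] or an
#'   `igraph` graph.
#' @param a,b Protein symbols. 0 iff `a == b`; -1 when the two proteins
#'   are disconnected or either symbol is absent from the graph (with a
#'   warning, mirroring the no-path semantics).
#' @return Integer path length.
#' @export
path_length <- function(x, a, b) {
  if (inherits(x, "distance_store")) {
    if (!(a %in% x$nodes) || !(b %in% x$nodes)) {
      warning("symbol absent from reference graph: ",
              paste(setdiff(c(a, b), x$nodes), collapse = ", "))
      return(-1L)
    }
    d <- x$d[a, b]
  } else {
    nodes <- igraph::V(x)$name
    if (!(a %in% nodes) || !(b %in% nodes)) {
      warning("symbol absent from reference graph: ",
              paste(setdiff(c(a, b), nodes), collapse = ", "))
      return(-1L)
    }
    d <- suppressWarnings(igraph::distances(x, v = a, to = b)[1L, 1L])
  }
  if (is.infinite(d)) -1L else as.integer(d)
}

#' Build a domain-domain interaction catalog
#'
#' @param pairs Data frame or two-column matrix of interacting domain
#'   pairs (3did-style); homotypic pairs allowed. Membership is symmetric.
#' @return Object of class `ddi_catalog`.
#' @export
ddi_catalog <- function(pairs) {
  if (is.character(pairs) && length(pairs) == 1L) pairs <- read_edge_tsv(pairs)
  a <- as.character(pairs[[1L]]); b <- as.character(pairs[[2L]])
  keys <- unique(paste(pmin(a, b), pmax(a, b), sep = "\r"))
  structure(list(keys = keys), class = "ddi_catalog")
}

#' Domain interaction score of a transcript pair
#'
#' Number of distinct unordered domain pairs, one from each transcript,
#' annotated as interacting in the catalog.
#'
#' @param domains_a,domains_b Character vectors of PFAM domain ids
#'   (deduplicated internally).
#' @param catalog A [ddi_catalog()].
#' @return Non-negative integer count.
#' @export
domain_interaction_score <- function(domains_a, domains_b, catalog) {
  domains_a <- unique(domains_a); domains_b <- unique(domains_b)
  if (length(domains_a) == 0L || length(domains_b) == 0L) return(0L)
  grid <- expand.grid(a = domains_a, b = domains_b,
                      stringsAsFactors = FALSE)
  keys <- unique(paste(pmin(grid$a, grid$b), pmax(grid$a, grid$b), sep = "\r"))
  sum(keys %in% catalog$keys)
}

#' Feature vectors for candidate transcript pairs
#'
#' Computes the 19 features for each pair of transcripts with resolved
#' homologs: shortest path between the homologs in the reference
#' interactome, domain interaction score, NTO per GO aspect, and the
#' per-transcript alignment measures (E-values, BLAST query coverage, PFAM
#' meta-alignment score, reciprocal-hit booleans) carried on the homology
#' assignments. Pairs are stored in canonical order (lexicographic contig
#' ids); missing alignment measures stay `NA` and fall into the
#' discretization scheme's sentinel bin.
#'
#' @param pairs Data frame with columns `contig_a`, `contig_b`.
#' @param assignments Assignment data frame from [resolve_homologs()]
#'   (columns `transcript_id`, `human_symbol`, `rule` and per-method
#'   evidence columns).
#' @param dist A `distance_store` (or `igraph` reference graph).
#' @param catalog A [ddi_catalog()].
#' @param dag A `go_dag`.
#' @param go_annotations Data frame (`symbol`, `go_id`) for the reference
#'   proteins.
#' @param contig_domains Named list contig id -> character vector of PFAM
#'   domain ids annotated on the transcript.
#' @return Data frame: `contig_a`, `contig_b`, `human_a`, `human_b` plus
#'   the 19 feature columns of [feature_roster()].
#' @export
compute_pair_features <- function(pairs, assignments, dist, catalog, dag,
                                  go_annotations, contig_domains) {
  if (inherits(dist, "igraph")) dist <- precompute_distances(dist)
  stopifnot(all(c("contig_a", "contig_b") %in% names(pairs)))
  # canonical pair order
  a <- pmin(pairs$contig_a, pairs$contig_b)
  b <- pmax(pairs$contig_a, pairs$contig_b)
  ia <- match(a, assignments$transcript_id)
  ib <- match(b, assignments$transcript_id)
  if (anyNA(ia) || anyNA(ib)) {
    stop("pair member(s) without a resolved homolog: ",
         paste(unique(c(a[is.na(ia)], b[is.na(ib)])), collapse = ", "))
  }
  ha <- assignments$human_symbol[ia]; hb <- assignments$human_symbol[ib]
  # path length via the dense store, -1 for absent/disconnected
  pl <- rep(-1L, length(a))
  known <- ha %in% dist$nodes & hb %in% dist$nodes
  if (any(!known)) warning(sum(!known),
                           " pair(s) with homolog absent from reference graph")
  if (any(known)) {
    dv <- dist$d[cbind(match(ha[known], dist$nodes),
                       match(hb[known], dist$nodes))]
    pl[known] <- ifelse(is.infinite(dv), -1L, as.integer(dv))
  }
  closures <- go_closure_index(dag, go_annotations)
  nto3 <- function(sa, sb) {
    ca <- closures[[sa]]; cb <- closures[[sb]]
    if (is.null(ca) || is.null(cb)) return(c(0, 0, 0))
    c(nto_from_closures(ca$mf, cb$mf),
      nto_from_closures(ca$bp, cb$bp),
      nto_from_closures(ca$cc, cb$cc))
  }
  ntos <- t(mapply(nto3, ha, hb))
  dis <- mapply(function(ca, cb) domain_interaction_score(
    contig_domains[[ca]], contig_domains[[cb]], catalog), a, b)
  evcol <- function(col, idx) {
    if (col %in% names(assignments)) assignments[[col]][idx] else NA_real_
  }
  out <- data.frame(
    contig_a = a, contig_b = b, human_a = ha, human_b = hb,
    path_length = pl,
    dom_int_score = as.integer(dis),
    nto_mf = ntos[, 1L], nto_bp = ntos[, 2L], nto_cc = ntos[, 3L],
    blast_evalue_a = evcol("blast_evalue", ia),
    blast_evalue_b = evcol("blast_evalue", ib),
    eggnog_evalue_a = evcol("eggnog_evalue", ia),
    eggnog_evalue_b = evcol("eggnog_evalue", ib),
    blast_qcov_a = evcol("blast_coverage", ia),
    blast_qcov_b = evcol("blast_coverage", ib),
    pfam_metascore_a = evcol("pfam_score", ia),
    pfam_metascore_b = evcol("pfam_score", ib),
    blast_brh_a = as.logical(evcol("blast_brh", ia)),
    blast_brh_b = as.logical(evcol("blast_brh", ib)),
    eggnog_brh_a = as.logical(evcol("eggnog_brh", ia)),
    eggnog_brh_b = as.logical(evcol("eggnog_brh", ib)),
    pfam_brh_a = as.logical(evcol("pfam_brh", ia)),
    pfam_brh_b = as.logical(evcol("pfam_brh", ib)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Feature vector for a single candidate pair
#'
#' Convenience wrapper over [compute_pair_features()] for one pair.
#'
#' @param pair Character vector of two contig ids.
#' @inheritParams compute_pair_features
#' @return One-row feature data frame.
#' @export
build_pair_features <- function(pair, assignments, dist, catalog, dag,
                                go_annotations, contig_domains) {
  compute_pair_features(
    data.frame(contig_a = pair[1L], contig_b = pair[2L],
               stringsAsFactors = FALSE),
    assignments, dist, catalog, dag, go_annotations, contig_domains)
}
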