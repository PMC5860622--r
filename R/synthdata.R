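# Seeded synthetic worlds with planted ground truth. The generator writes
# every input file the pipeline consumes (evidence tables, OBO ontology,
# annotations, edge lists, domain-pair catalog, training labels) plus the
# truth tables, so every stage is testable end to end without downloads.

#' Default synthetic-world configuration
#'
#' The default world: a scale-free reference interactome of 300 proteins
#' (preferential attachment, m = 2, matching the heavy-tailed degree
#' distributions of real interactomes), 120 PFAM-like domains, a
#' three-aspect layered GO DAG, and two species -- a training species
#' standing in for the fly data and a query species -- each with contigs
#' for 220 sampled proteins, a 10% fragmentation rate and a 10% spurious-
#' hit rate. True-mapping E-values are drawn log-uniform from
#' \[1e-180, 1e-20\] and spurious ones from \[1e-15, 1e-10\]; both pass
#' the 1e-10 gate, so the best-homolog cascade is genuinely exercised.
#'
#' @param ... Overrides for individual entries.
#' @return Named configuration list.
#' @export
world_config <- function(...) {
  cfg <- list(
    n_proteins = 300L, m = 2L,
    n_domains = 120L, max_domains_per_protein = 3L,
    p_ddi = 0.35, n_ddi_noise = 30L,
    go_layer_sizes = c(5L, 30L), terms_per_protein = 3L, p_go_share = 0.5,
    n_contig_proteins = 220L, fragmentation = 0.1, frag_k = 2L,
    noise = 0.1, p_drop_eggnog = 0.15, p_drop_blast = 0.05,
    true_evalue_exp = c(20, 180), spurious_evalue_exp = c(10, 15),
    n_expr_samples = 2L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) stop("unknown world_config key(s): ",
                                 paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

rle10 <- function(n, lo, hi) signif(10^(-stats::runif(n, lo, hi)), 6)

#' Generate a synthetic world with planted ground truth
#'
#' Builds the reference graph, per-protein domain architectures, the
#' domain-interaction catalog (seeded from reference edges plus noise
#' pairs), a layered GO DAG with neighbor-sharing annotations, and two
#' species of contigs with BLAST/EggNOG/PFAM evidence tables whose
#' E-values are conditioned on whether the mapping is true. Planted
#' positive pairs are the contig pairs whose proteins form a reference
#' edge. Every file the pipeline consumes is written to `dir`;
#' regeneration with the same seed is byte-identical.
#'
#' @param config A [world_config()].
#' @param seed Integer seed.
#' @param dir Output directory for the fixture file set.
#' @return Object of class `synthetic_world`: `seed`, `config`, `dir`,
#'   `files` (named paths), `graph`, `protein_domains`, `domain_len`,
#'   `species` (contig tables with true proteins), `planted` (canonical
#'   contig-pair truth per species).
#' @export
make_world <- function(config = world_config(), seed = 1L,
                       dir = tempfile("world")) {
  stopifnot(config$n_proteins >= 20L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  n <- config$n_proteins
  syms <- sprintf("HP%04d", seq_len(n))
  g <- igraph::sample_pa(n, power = 1, m = config$m, directed = FALSE)
  igraph::V(g)$name <- syms
  el <- igraph::as_edgelist(g)
  el <- data.frame(a = pmin(el[, 1L], el[, 2L]), b = pmax(el[, 1L], el[, 2L]),
                   stringsAsFactors = FALSE)
  el <- unique(el[el$a != el$b, , drop = FALSE])
  el <- el[order(el$a, el$b), , drop = FALSE]
  if (nrow(el) < 1L) stop("infeasible config: reference graph has no edges")

  doms <- sprintf("PF%05d", seq_len(config$n_domains))
  domain_len <- stats::setNames(sample(50:300, config$n_domains, replace = TRUE),
                                doms)
  protein_domains <- lapply(syms, function(s)
    sample(doms, sample.int(config$max_domains_per_protein, 1L)))
  names(protein_domains) <- syms
  protein_len <- stats::setNames(
    vapply(protein_domains, function(d)
      sum(domain_len[d]) + sample(50:200, 1L), numeric(1)), syms)

  # domain-interaction catalog: seeded by reference edges, plus noise
  ddi <- list()
  for (i in seq_len(nrow(el))) {
    if (stats::runif(1) < config$p_ddi) {
      da <- sample(protein_domains[[el$a[i]]], 1L)
      db <- sample(protein_domains[[el$b[i]]], 1L)
      ddi[[length(ddi) + 1L]] <- c(min(da, db), max(da, db))
    }
  }
  for (i in seq_len(config$n_ddi_noise)) {
    p <- sample(doms, 2L, replace = TRUE)
    ddi[[length(ddi) + 1L]] <- c(min(p), max(p))
  }
  ddi <- unique(do.call(rbind, ddi))
  ddi <- data.frame(a = ddi[, 1L], b = ddi[, 2L], stringsAsFactors = FALSE)
  ddi <- ddi[order(ddi$a, ddi$b), , drop = FALSE]

  go <- make_go(config, el, syms)

  species <- list(); planted <- list()
  prefixes <- c(training = "tr", query = "qy")
  for (sp in names(prefixes)) {
    species[[sp]] <- make_species(prefixes[[sp]], config, syms,
                                  protein_domains, domain_len, protein_len)
    contigs <- species[[sp]]$contigs
    planted[[sp]] <- plant_pairs(contigs, el)
  }

  files <- list(
    reference_edges = file.path(dir, "reference_edges.tsv"),
    ddi = file.path(dir, "ddi_pairs.tsv"),
    obo = file.path(dir, "ontology.obo"),
    go_annotations = file.path(dir, "go_annotations.tsv"),
    pfam_human = file.path(dir, "human_pfam.domtblout"),
    training_pairs = file.path(dir, "training_positive_pairs.tsv"),
    expression = file.path(dir, "query_expression.tsv"))
  for (sp in names(prefixes)) {
    files[[paste0(sp, "_blast_fwd")]] <- file.path(dir, paste0(sp, "_blast_fwd.tsv"))
    files[[paste0(sp, "_blast_rev")]] <- file.path(dir, paste0(sp, "_blast_rev.tsv"))
    files[[paste0(sp, "_eggnog")]] <- file.path(dir, paste0(sp, "_eggnog.domtblout"))
    files[[paste0(sp, "_pfam")]] <- file.path(dir, paste0(sp, "_pfam.domtblout"))
    files[[paste0(sp, "_truth")]] <- file.path(dir, paste0(sp, "_truth.tsv"))
    files[[paste0(sp, "_planted")]] <- file.path(dir, paste0(sp, "_planted.tsv"))
  }

  writeLines(paste(el$a, el$b, sep = "\t"), files$reference_edges)
  writeLines(paste(ddi$a, ddi$b, sep = "\t"), files$ddi)
  writeLines(go$obo, files$obo)
  writeLines(paste(go$annotations$symbol, go$annotations$go_id, sep = "\t"),
             files$go_annotations)
  write_evidence_table(human_pfam_hits(syms, protein_domains, domain_len,
                                       protein_len), files$pfam_human)
  for (sp in names(prefixes)) {
    s <- species[[sp]]
    write_evidence_table(s$blast_fwd, files[[paste0(sp, "_blast_fwd")]])
    write_evidence_table(s$blast_rev, files[[paste0(sp, "_blast_rev")]])
    write_evidence_table(s$eggnog, files[[paste0(sp, "_eggnog")]])
    write_evidence_table(s$pfam, files[[paste0(sp, "_pfam")]])
    writeLines(paste(s$contigs$contig_id, s$contigs$protein,
                     s$contigs$fragment, sep = "\t"),
               files[[paste0(sp, "_truth")]])
    writeLines(if (nrow(planted[[sp]]) > 0L)
      paste(planted[[sp]]$contig_a, planted[[sp]]$contig_b, sep = "\t")
      else character(0), files[[paste0(sp, "_planted")]])
  }
  writeLines(paste(planted$training$contig_a, planted$training$contig_b,
                   sep = "\t"), files$training_pairs)
  # expression for the query species
  qc <- species$query$contigs$contig_id
  expr <- matrix(stats::rnbinom(config$n_expr_samples * length(qc),
                                mu = 100, size = 2),
                 nrow = config$n_expr_samples,
                 dimnames = list(sprintf("S%d", seq_len(config$n_expr_samples)),
                                 qc))
  writeLines(c(paste(c("sample", qc), collapse = "\t"),
               vapply(seq_len(nrow(expr)), function(i)
                 paste(c(rownames(expr)[i], expr[i, ]), collapse = "\t"),
                 character(1))), files$expression)

  structure(list(seed = seed, config = config, dir = dir, files = files,
                 graph = g, protein_domains = protein_domains,
                 domain_len = domain_len, ddi = ddi,
                 species = species, planted = planted),
            class = "synthetic_world")
}

plant_pairs <- function(contigs, el) {
  edge_keys <- paste(el$a, el$b, sep = "\r")
  n <- nrow(contigs)
  if (n < 2L) {
    return(data.frame(contig_a = character(), contig_b = character()))
  }
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pa <- contigs$protein[idx[, 1L]]; pb <- contigs$protein[idx[, 2L]]
  keys <- paste(pmin(pa, pb), pmax(pa, pb), sep = "\r")
  keep <- pa != pb & keys %in% edge_keys
  ca <- contigs$contig_id[idx[, 1L]][keep]
  cb <- contigs$contig_id[idx[, 2L]][keep]
  out <- data.frame(contig_a = pmin(ca, cb), contig_b = pmax(ca, cb),
                    stringsAsFactors = FALSE)
  out[order(out$contig_a, out$contig_b), , drop = FALSE]
}

make_go <- function(config, el, syms) {
  aspects <- c("molecular_function", "biological_process",
               "cellular_component")
  counter <- 0L
  next_id <- function() { counter <<- counter + 1L; sprintf("GO:%07d", counter) }
  obo <- c("format-version: 1.2", "")
  ann_sym <- character(0); ann_go <- character(0)
  leaf_terms <- list()
  for (asp in aspects) {
    root <- next_id()
    l1 <- vapply(seq_len(config$go_layer_sizes[1L]), function(i) next_id(),
                 character(1))
    l2 <- vapply(seq_len(config$go_layer_sizes[2L]), function(i) next_id(),
                 character(1))
    obo <- c(obo, "[Term]", paste0("id: ", root),
             paste0("name: ", asp, " root"), paste0("namespace: ", asp), "")
    for (t in l1) {
      obo <- c(obo, "[Term]", paste0("id: ", t), paste0("name: node ", t),
               paste0("namespace: ", asp), paste0("is_a: ", root), "")
    }
    for (t in l2) {
      parents <- sample(l1, sample.int(2L, 1L))
      lines <- c("[Term]", paste0("id: ", t), paste0("name: leaf ", t),
                 paste0("namespace: ", asp))
      for (p in parents) {
        lines <- c(lines, if (stats::runif(1) < 0.2)
          paste0("relationship: part_of ", p) else paste0("is_a: ", p))
      }
      obo <- c(obo, lines, "")
    }
    leaf_terms[[asp]] <- l2
    # base annotations
    ann <- lapply(syms, function(s)
      sample(l2, min(config$terms_per_protein, length(l2))))
    names(ann) <- syms
    # interacting neighbors share terms
    for (i in seq_len(nrow(el))) {
      if (stats::runif(1) < config$p_go_share) {
        shared <- sample(ann[[el$a[i]]], 1L)
        ann[[el$b[i]]] <- unique(c(ann[[el$b[i]]], shared))
      }
    }
    ann_sym <- c(ann_sym, rep(syms, lengths(ann)))
    ann_go <- c(ann_go, unlist(ann, use.names = FALSE))
  }
  ord <- order(ann_sym, ann_go)
  list(obo = obo,
       annotations = data.frame(symbol = ann_sym[ord], go_id = ann_go[ord],
                                stringsAsFactors = FALSE),
       leaf_terms = leaf_terms)
}

domtbl_row <- function(seq_id, dom, domain_len, seq_len, model_start,
                       model_end, seq_start, seq_end, evalue) {
  data.frame(query_id = seq_id, target_id = dom, method = "pfam",
             evalue = evalue, score = round(stats::runif(1, 20, 300), 1),
             query_coverage = NA_real_, model_len = unname(domain_len[dom]),
             model_start = model_start, model_end = model_end,
             seq_start = seq_start, seq_end = seq_end,
             seq_len = seq_len, stringsAsFactors = FALSE)
}

human_pfam_hits <- function(syms, protein_domains, domain_len, protein_len) {
  rows <- list()
  for (s in syms) {
    pos <- 10L
    for (d in protein_domains[[s]]) {
      ml <- domain_len[[d]]
      cov <- stats::runif(1, 0.9, 1.0)
      cl <- max(1L, round(cov * ml))
      ms <- sample.int(ml - cl + 1L, 1L) - 1L
      rows[[length(rows) + 1L]] <- domtbl_row(
        s, d, domain_len, round(protein_len[[s]]), ms, ms + cl,
        pos, pos + cl, rle10(1, 20, 100))
      pos <- pos + cl + sample(5:40, 1L)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

make_species <- function(prefix, config, syms, protein_domains, domain_len,
                         protein_len) {
  chosen <- sort(sample(syms, config$n_contig_proteins))
  contig_id <- character(0); protein <- character(0); fragment <- logical(0)
  dom_slices <- list()
  counter <- 0L
  for (p in chosen) {
    k <- if (stats::runif(1) < config$fragmentation) config$frag_k else 1L
    pd <- protein_domains[[p]]
    for (j in seq_len(k)) {
      counter <- counter + 1L
      cid <- sprintf("%s%04d", prefix, counter)
      contig_id <- c(contig_id, cid); protein <- c(protein, p)
      fragment <- c(fragment, k > 1L)
      if (k > 1L) {
        # fragments keep a contiguous slice of the domain architecture
        frac <- stats::runif(1, 0.3, 0.8)
        nk <- max(1L, ceiling(frac * length(pd)))
        st <- sample.int(length(pd) - nk + 1L, 1L)
        dom_slices[[cid]] <- pd[st:(st + nk - 1L)]
      } else {
        dom_slices[[cid]] <- pd
      }
    }
  }
  contigs <- data.frame(contig_id = contig_id, protein = protein,
                        fragment = fragment, stringsAsFactors = FALSE)
  contigs$nt_len <- round(3 * protein_len[contigs$protein] *
                            ifelse(contigs$fragment,
                                   stats::runif(nrow(contigs), 0.35, 0.8), 1))

  te <- config$true_evalue_exp; se <- config$spurious_evalue_exp
  bf <- list(); brv <- list(); eg <- list(); pf <- list()
  blast_row <- function(q, t, ev, cov, qlen, slen) {
    alen <- min(qlen, max(30L, round(cov * qlen)))
    data.frame(query_id = q, target_id = t, method = "blast", evalue = ev,
               score = round(stats::runif(1, 80, 2000), 1),
               query_coverage = alen / qlen,
               pident = round(stats::runif(1, 40, 95), 2), aln_length = alen,
               q_start = 0L, q_end = alen,
               s_start = 0L, s_end = min(slen, alen %/% 3L + 1L),
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(contigs))) {
    cid <- contigs$contig_id[i]; p <- contigs$protein[i]
    qlen <- contigs$nt_len[i]; plen <- round(protein_len[[p]])
    cov <- if (contigs$fragment[i]) stats::runif(1, 0.35, 0.7) else
      stats::runif(1, 0.7, 0.98)
    # some contigs lack a channel entirely, so the lower cascade rules and
    # the missing-value sentinel bins are genuinely exercised
    have_blast <- stats::runif(1) >= config$p_drop_blast
    have_eggnog <- stats::runif(1) >= config$p_drop_eggnog
    ev <- rle10(1, te[1L], te[2L])
    if (have_blast) {
      bf[[length(bf) + 1L]] <- blast_row(cid, p, ev, cov, qlen, plen)
      brv[[length(brv) + 1L]] <- blast_row(
        p, cid, signif(min(1e-11, ev * 10^stats::runif(1, -3, 3)), 6),
        stats::runif(1, 0.5, 0.95), plen, qlen)
    }
    if (have_eggnog) {
      eg[[length(eg) + 1L]] <- domtbl_row(
        cid, p, stats::setNames(plen, p), qlen %/% 3L,
        0L, plen, 0L, round(cov * plen), rle10(1, te[1L], te[2L]))
    }
    # spurious extra hits
    if (stats::runif(1) < config$noise) {
      p2 <- sample(setdiff(syms, p), 1L)
      bf[[length(bf) + 1L]] <- blast_row(cid, p2, rle10(1, se[1L], se[2L]),
                                         stats::runif(1, 0.15, 0.45), qlen,
                                         round(protein_len[[p2]]))
    }
    if (stats::runif(1) < config$noise) {
      p2 <- sample(setdiff(syms, p), 1L)
      eg[[length(eg) + 1L]] <- domtbl_row(
        cid, p2, stats::setNames(round(protein_len[[p2]]), p2), qlen %/% 3L,
        0L, round(protein_len[[p2]]) %/% 2L, 0L, plen %/% 2L,
        rle10(1, se[1L], se[2L]))
    }
    # PFAM hits along the ORF for the contig's (possibly sliced) domains
    pos <- 5L
    for (d in dom_slices[[cid]]) {
      ml <- domain_len[[d]]
      mcov <- if (contigs$fragment[i]) stats::runif(1, 0.4, 0.9) else
        stats::runif(1, 0.75, 1.0)
      cl <- max(1L, round(mcov * ml))
      ms <- sample.int(ml - cl + 1L, 1L) - 1L
      pf[[length(pf) + 1L]] <- domtbl_row(
        cid, d, domain_len, qlen %/% 3L, ms, ms + cl, pos, pos + cl,
        rle10(1, 10, 60))
      pos <- pos + cl + sample(5:40, 1L)
    }
  }
  rbind_all <- function(lst) {
    out <- do.call(rbind, lst); rownames(out) <- NULL; out
  }
  list(contigs = contigs, dom_slices = dom_slices,
       blast_fwd = rbind_all(bf), blast_rev = rbind_all(brv),
       eggnog = rbind_all(eg), pfam = rbind_all(pf))
}

#' Precision/recall of a predicted network against planted truth
#'
#' Compares predicted contig pairs with the world's planted interolog
#' pairs and reports the enrichment of the prediction over a random edge
#' set of equal size drawn from all contig pairs of the species
#' (`enrichment = precision / planted-pair density`).
#'
#' @param predicted A `predicted_network`.
#' @param world A `synthetic_world`.
#' @param species `"query"` (default) or `"training"`.
#' @return List (`precision`, `recall`, `enrichment`, `n_predicted`,
#'   `n_planted`, `n_true_positive`).
#' @export
truth_recovery_report <- function(predicted, world, species = "query") {
  planted <- world$planted[[species]]
  pk <- paste(planted$contig_a, planted$contig_b, sep = "\r")
  e <- predicted$edges
  ek <- paste(pmin(e$contig_a, e$contig_b), pmax(e$contig_a, e$contig_b),
              sep = "\r")
  tp <- sum(ek %in% pk)
  n_contigs <- nrow(world$species[[species]]$contigs)
  density <- nrow(planted) / choose(n_contigs, 2)
  precision <- if (length(ek) == 0L) 0 else tp / length(ek)
  list(precision = precision,
       recall = if (nrow(planted) == 0L) 0 else tp / nrow(planted),
       enrichment = if (density == 0) 0 else precision / density,
       n_predicted = length(ek), n_planted = nrow(planted),
       n_true_positive = tp)
}

#' End-to-end benchmark on one synthetic world
#'
#' Generates a world, runs the full pipeline from the written fixture
#' files (readers included), trains the forest on the training species'
#' planted pairs plus sampled negatives, evaluates OOB performance (full
#' model and with the path-length feature ablated), predicts the query
#' species' network at the vote cutoff, and scores it against the planted
#' truth.
#'
#' @param seed Integer seed driving both the world and the forest.
#' @param config A [world_config()].
#' @param n_trees Trees per forest (default 1000).
#' @param train_neg_ratio Sampled negatives per positive in the training
#'   table (default 6; per-tree downsampling then enforces the 5:1 ratio).
#' @param pipeline_config See [default_config()].
#' @param dir World directory (temporary by default, removed afterwards).
#' @return List with `auc_full`, `auc_without_path`, `report`
#'   (OOB metrics at the vote cutoff), `network`, `recovery`
#'   (truth-recovery list), `summary` (network summary), and sizes.
#' @export
synthetic_benchmark <- function(seed, config = world_config(),
                                n_trees = 1000L, train_neg_ratio = 6L,
                                pipeline_config = default_config(),
                                dir = NULL) {
  cleanup <- is.null(dir)
  if (is.null(dir)) dir <- tempfile("bench_world")
  world <- make_world(config, seed, dir)
  on.exit(if (cleanup) unlink(dir, recursive = TRUE), add = TRUE)
  files <- world$files
  reference <- build_reference_network(files$reference_edges)
  dist <- precompute_distances(reference)
  dag <- read_obo(files$obo)
  goa <- read_go_annotations(files$go_annotations)
  catalog <- ddi_catalog(read_edge_tsv(files$ddi))
  human_pfam <- read_evidence_table(files$pfam_human, "pfam")
  resolve <- function(sp) {
    resolve_homologs(
      read_evidence_table(files[[paste0(sp, "_blast_fwd")]], "blast"),
      read_evidence_table(files[[paste0(sp, "_blast_rev")]], "blast"),
      read_evidence_table(files[[paste0(sp, "_eggnog")]], "eggnog"),
      read_evidence_table(files[[paste0(sp, "_pfam")]], "pfam"),
      human_pfam, pipeline_config)
  }
  tr <- resolve("training")
  positives <- read_edge_tsv(files$training_pairs)
  names(positives) <- c("contig_a", "contig_b")
  assigned <- tr$assignments$transcript_id
  positives <- positives[positives$contig_a %in% assigned &
                           positives$contig_b %in% assigned, , drop = FALSE]
  n_pos <- nrow(positives)
  if (n_pos < 10L) stop("infeasible world: too few recoverable planted pairs")
  # sampled negatives: random assigned-contig pairs that are not planted
  set.seed(seed + 100003L)
  pool_n <- length(assigned)
  idx <- which(upper.tri(matrix(0, pool_n, pool_n)), arr.ind = TRUE)
  aa <- sort(assigned)
  all_a <- aa[idx[, 1L]]; all_b <- aa[idx[, 2L]]
  pos_keys <- paste(pmin(positives$contig_a, positives$contig_b),
                    pmax(positives$contig_a, positives$contig_b), sep = "\r")
  neg_ok <- which(!(paste(all_a, all_b, sep = "\r") %in% pos_keys))
  take <- sample(neg_ok, min(train_neg_ratio * n_pos, length(neg_ok)))
  pairs_train <- data.frame(
    contig_a = c(positives$contig_a, all_a[take]),
    contig_b = c(positives$contig_b, all_b[take]),
    stringsAsFactors = FALSE)
  labels <- rep(c(TRUE, FALSE), c(n_pos, length(take)))
  feats <- compute_pair_features(pairs_train, tr$assignments, dist, catalog,
                                 dag, goa, tr$contig_domains)
  model <- train_classifier(feats, labels, n_trees = n_trees,
                            neg_pos_ratio = pipeline_config$neg_pos_ratio,
                            seed = seed)
  model_np <- train_classifier(feats, labels, n_trees = n_trees,
                               neg_pos_ratio = pipeline_config$neg_pos_ratio,
                               seed = seed, exclude = "path_length")
  auc_full <- roc_auc(model$oob_votes, labels)
  auc_np <- roc_auc(model_np$oob_votes, labels)
  report <- oob_metrics(model$oob_votes, labels,
                        pipeline_config$vote_cutoff)
  qr <- resolve("query")
  pruned <- prune_many_to_one(qr$assignments,
                              pipeline_config$max_contigs_per_protein)
  cand <- candidate_pairs(pruned, dist, pipeline_config$max_path_length)
  qfeats <- compute_pair_features(cand[c("contig_a", "contig_b")], pruned,
                                  dist, catalog, dag, goa, qr$contig_domains)
  network <- predict_network(qfeats, model,
                             cutoff = pipeline_config$vote_cutoff,
                             dataset = "query")
  recovery <- truth_recovery_report(network, world, "query")
  summary <- summarize_network(network, pruned, reference,
                               total_contigs = nrow(world$species$query$contigs))
  list(seed = seed, auc_full = auc_full, auc_without_path = auc_np,
       report = report, model = model, network = network,
       recovery = recovery, summary = summary,
       n_train_pos = n_pos, n_train_neg = length(take),
       n_candidates = nrow(cand))
}
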