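# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive and separate from the package's own code paths.

# --- fixture builders -------------------------------------------------------

ann_row <- function(seq_id, domain_id, model_len, model_start, model_end,
                    seq_start, seq_end, evalue = 1e-20) {
  data.frame(seq_id = seq_id, domain_id = domain_id, model_len = model_len,
             model_start = model_start, model_end = model_end,
             seq_start = seq_start, seq_end = seq_end, evalue = evalue,
             stringsAsFactors = FALSE)
}

mk_meta <- function(domains, coverages, seq_id = "m") {
  structure(list(seq_id = seq_id, domain = domains, coverage = coverages),
            class = "meta_sequence")
}

mk_hit <- function(query, target, method, evalue = NA_real_, score = 0,
                   is_brh = FALSE) {
  data.frame(query_id = query, target_id = target, method = method,
             evalue = evalue, score = score, query_coverage = NA_real_,
             is_brh = is_brh, stringsAsFactors = FALSE)
}

# a tiny OBO file: per-aspect root R with children A, B; C is_a A and B
write_toy_obo <- function(path = tempfile(fileext = ".obo")) {
  lines <- c("format-version: 1.2", "")
  for (asp in c("molecular_function", "biological_process",
                "cellular_component")) {
    tag <- switch(asp, molecular_function = "1", biological_process = "2",
                  cellular_component = "3")
    id <- function(x) sprintf("GO:%s00000%s", tag, x)
    lines <- c(lines,
      "[Term]", paste0("id: ", id(0)), "name: root",
      paste0("namespace: ", asp), "",
      "[Term]", paste0("id: ", id(1)), "name: A",
      paste0("namespace: ", asp), paste0("is_a: ", id(0)), "",
      "[Term]", paste0("id: ", id(2)), "name: B",
      paste0("namespace: ", asp), paste0("is_a: ", id(0)), "",
      "[Term]", paste0("id: ", id(3)), "name: C",
      paste0("namespace: ", asp), paste0("is_a: ", id(1)),
      paste0("relationship: part_of ", id(2)), "")
  }
  writeLines(lines, path)
  path
}

small_world_config <- function(...) {
  world_config(n_proteins = 50L, n_domains = 30L, n_contig_proteins = 30L,
               n_ddi_noise = 10L, ...)
}

# --- oracles ----------------------------------------------------------------

# six-frame translation by direct codon lookup, longest stop-free stretch
orf_oracle <- function(seq) {
  code <- Biostrings::GENETIC_CODE
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
  best_len <- -1L; best <- NULL
  for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    s <- if (frame > 0) seq else rc
    off <- abs(frame)
    codons <- substring(s, seq(off, nchar(s) - 2L, by = 3L),
                        seq(off + 2L, nchar(s), by = 3L))
    if (length(codons) == 0L) next
    aa <- vapply(codons, function(cd)
      if (cd %in% names(code)) code[[cd]] else "X", character(1))
    run <- 0L; start <- 1L
    for (i in seq_along(aa)) {
      if (aa[i] == "*") { run <- 0L; start <- i + 1L }
      else {
        run <- run + 1L
        if (run > best_len) {
          best_len <- run
          best <- list(frame = frame, aa = paste(aa[start:i], collapse = ""))
        }
      }
    }
  }
  best
}

# exhaustive mutual-best enumeration
brh_oracle <- function(forward, reverse = NULL) {
  if (is.null(reverse)) {
    reverse <- forward[, c("target_id", "query_id", "method", "evalue",
                           "score", "query_coverage")]
    names(reverse)[1:2] <- c("query_id", "target_id")
  }
  better <- function(e1, s1, e2, s2) {
    e1 <- ifelse(is.na(e1), Inf, e1); e2 <- ifelse(is.na(e2), Inf, e2)
    e1 < e2 | (e1 == e2 & s1 > s2)
  }
  is_best <- function(tab, q, t) {
    rows <- which(tab$query_id == q)
    mine <- rows[tab$target_id[rows] == t]
    others <- rows[tab$target_id[rows] != t]
    for (i in mine) {
      if (all(better(tab$evalue[i], tab$score[i],
                     tab$evalue[others], tab$score[others]))) return(TRUE)
    }
    FALSE
  }
  pairs <- unique(forward[, c("query_id", "target_id")])
  keep <- vapply(seq_len(nrow(pairs)), function(i) {
    q <- pairs$query_id[i]; t <- pairs$target_id[i]
    is_best(forward, q, t) && t %in% reverse$query_id &&
      is_best(reverse, t, q)
  }, logical(1))
  out <- pairs[keep, , drop = FALSE]
  out[order(out$query_id, out$target_id), , drop = FALSE]
}

# brute-force global alignment: enumerate every alignment recursively
meta_align_oracle <- function(a, b, match = 30, mismatch = -30, gap = -5) {
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) {
      s <- if (a$domain[i] == b$domain[j])
        match * min(a$coverage[i], b$coverage[j]) else mismatch
      best <- max(best, rec(i - 1L, j - 1L) + s)
    }
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(length(a$domain), length(b$domain))
}

# plain queue BFS distances from one source over an edge list
bfs_oracle <- function(edges, nodes, src) {
  adj <- lapply(stats::setNames(nodes, nodes), function(n)
    c(edges$b[edges$a == n], edges$a[edges$b == n]))
  dist <- stats::setNames(rep(-1L, length(nodes)), nodes)
  dist[src] <- 0L
  queue <- src
  while (length(queue) > 0L) {
    u <- queue[1L]; queue <- queue[-1L]
    for (v in adj[[u]]) if (dist[v] < 0L) {
      dist[v] <- dist[u] + 1L
      queue <- c(queue, v)
    }
  }
  dist
}

# transitive ancestor closure by adjacency-matrix reachability
closure_oracle <- function(dag, terms, aspect) {
  ids <- dag$terms$id[dag$terms$aspect == aspect]
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (id in ids) for (p in dag$parents[[id]])
    if (p %in% ids) A[id, p] <- TRUE
  R <- A | diag(n) > 0
  repeat {
    R2 <- R | (R %*% R) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  terms <- intersect(terms, ids)
  if (length(terms) == 0L) return(character(0))
  sort(ids[colSums(R[terms, , drop = FALSE]) > 0])
}

# all simple paths by plain recursive DFS over an edge data frame
simple_paths_oracle <- function(edges, src, dst, max_len) {
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    adj[[edges$contig_a[i]]] <- c(adj[[edges$contig_a[i]]], edges$contig_b[i])
    adj[[edges$contig_b[i]]] <- c(adj[[edges$contig_b[i]]], edges$contig_a[i])
  }
  out <- list()
  walk <- function(path) {
    u <- path[length(path)]
    if (u == dst) { out[[length(out) + 1L]] <<- path; return(invisible()) }
    if (length(path) > max_len) return(invisible())
    for (v in adj[[u]]) if (!(v %in% path)) walk(c(path, v))
  }
  walk(src)
  out
}

# pairwise concordance count with ties as 1/2
auc_oracle <- function(votes, labels) {
  pos <- votes[labels]; neg <- votes[!labels]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  total / (length(pos) * length(neg))
}

# rank-then-Pearson
spearman_oracle <- function(x, y) stats::cor(rank(x), rank(y))
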