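# Path lengths, GO term overlap, domain-interaction score and the
# assembled 19-feature vector.

test_that("path length answers adjacency, disconnection and missing nodes", {
  g <- build_reference_network(data.frame(a = c("P", "B"), b = c("Q", "C")))
  d <- precompute_distances(g)
  expect_equal(path_length(d, "P", "Q"), 1L)
  expect_equal(path_length(d, "P", "P"), 0L)
  expect_equal(path_length(d, "P", "B"), -1L)   # different components
  expect_warning(expect_equal(path_length(d, "P", "ZZZ"), -1L), "absent")
  expect_equal(path_length(g, "P", "Q"), 1L)    # direct-graph dispatch
})

test_that("precomputed distances equal per-pair BFS on random graphs", {
  set.seed(19)
  for (trial in 1:4) {
    nodes <- paste0("n", 1:20)
    edges <- unique(data.frame(
      a = sample(nodes, 30, replace = TRUE),
      b = sample(nodes, 30, replace = TRUE), stringsAsFactors = FALSE))
    edges <- edges[edges$a != edges$b, ]
    g <- build_reference_network(edges)
    d <- precompute_distances(g)
    present <- igraph::V(g)$name
    for (src in present) {
      want <- bfs_oracle(edges, present, src)
      for (dst in present) {
        expect_equal(path_length(d, src, dst), unname(want[dst]),
                     info = paste(src, dst))
      }
    }
  }
})

test_that("domain interaction score counts catalog pairs", {
  cat13 <- ddi_catalog(data.frame(a = "PF1", b = "PF3"))
  expect_equal(domain_interaction_score(c("PF1", "PF2"), "PF3", cat13), 1L)
  cat2 <- ddi_catalog(data.frame(a = c("PF1", "PF2"), b = c("PF3", "PF3")))
  expect_equal(domain_interaction_score(c("PF1", "PF2"), "PF3", cat2), 2L)
  expect_equal(domain_interaction_score(character(0), "PF3", cat2), 0L)
  # symmetric membership: (PF3, PF1) hits the (PF1, PF3) entry
  expect_equal(domain_interaction_score("PF3", "PF1", cat13), 1L)
})

test_that("domain interaction score equals exhaustive enumeration", {
  set.seed(8)
  doms <- paste0("PF", 1:8)
  for (trial in 1:15) {
    da <- sample(doms, 5, replace = TRUE)
    db <- sample(doms, 5, replace = TRUE)
    cat_pairs <- unique(data.frame(a = sample(doms, 10, replace = TRUE),
                                   b = sample(doms, 10, replace = TRUE),
                                   stringsAsFactors = FALSE))
    catalog <- ddi_catalog(cat_pairs)
    keys <- unique(paste(pmin(cat_pairs$a, cat_pairs$b),
                         pmax(cat_pairs$a, cat_pairs$b)))
    seen <- character(0)
    for (x in unique(da)) for (y in unique(db)) {
      k <- paste(min(x, y), max(x, y))
      if (k %in% keys) seen <- union(seen, k)
    }
    got <- domain_interaction_score(da, db, catalog)
    expect_equal(got, length(seen))
    expect_lte(got, length(unique(da)) * length(unique(db)))
  }
})

test_that("GO NTO matches hand-computed closures on the toy DAG", {
  dag <- read_obo(write_toy_obo())
  # molecular_function: root GO:1000000, A GO:1000001, B GO:1000002
  expect_equal(go_nto(dag, "GO:1000001", "GO:1000001", "molecular_function"), 1)
  # closures {A, R} and {B, R}: overlap {R}, min size 2 -> 0.5
  expect_equal(go_nto(dag, "GO:1000001", "GO:1000002", "molecular_function"), 0.5)
  # C is_a A, part_of B: closure {C, A, B, R}; vs {A}: overlap {A} -> 1/2... but
  # min(|{C,A,B,R}|, |{A,R}|) = 2 and intersection {A,R} -> 1
  expect_equal(go_nto(dag, "GO:1000003", "GO:1000001", "molecular_function"), 1)
  expect_equal(go_nto(dag, "GO:1000001", character(0), "molecular_function"), 0)
  expect_warning(
    expect_equal(go_nto(dag, "GO:9999999", "GO:1000001", "molecular_function"), 0),
    "unknown GO id")
  # aspect filtering: a biological_process term contributes nothing to MF
  expect_equal(go_nto(dag, c("GO:1000001", "GO:2000001"), "GO:1000002",
                      "molecular_function"), 0.5)
})

test_that("ancestor closures equal matrix-reachability oracle", {
  dag <- read_obo(write_toy_obo())
  for (asp in c("molecular_function", "biological_process",
                "cellular_component")) {
    ids <- dag$terms$id[dag$terms$aspect == asp]
    for (t in ids) {
      got <- go_ancestors(dag, t)
      expect_equal(got, closure_oracle(dag, t, asp), info = t)
    }
  }
})

make_feature_fixture <- function() {
  g <- build_reference_network(data.frame(
    a = c("H1", "H2", "H1"), b = c("H2", "H3", "H4")))
  dag <- read_obo(write_toy_obo())
  goa <- data.frame(
    symbol = c("H1", "H1", "H2", "H3"),
    go_id = c("GO:1000001", "GO:2000001", "GO:1000001", "GO:1000002"),
    stringsAsFactors = FALSE)
  assignments <- data.frame(
    transcript_id = c("c1", "c2", "c3"),
    human_symbol = c("H1", "H2", "H3"),
    rule = c(1L, 1L, 2L),
    blast_evalue = c(1e-60, 1e-40, NA),
    blast_coverage = c(0.9, 0.5, NA),
    blast_brh = c(TRUE, FALSE, FALSE),
    eggnog_evalue = c(1e-80, NA, 1e-30),
    eggnog_brh = c(TRUE, FALSE, FALSE),
    pfam_score = c(55, NA, 28),
    pfam_brh = c(FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  catalog <- ddi_catalog(data.frame(a = "PFA", b = "PFB"))
  contig_domains <- list(c1 = c("PFA"), c2 = c("PFB", "PFC"), c3 = "PFC")
  list(g = g, dist = precompute_distances(g), dag = dag, goa = goa,
       assignments = assignments, catalog = catalog,
       contig_domains = contig_domains)
}

test_that("pair features compose the individual operations", {
  fx <- make_feature_fixture()
  row <- build_pair_features(c("c1", "c2"), fx$assignments, fx$dist,
                             fx$catalog, fx$dag, fx$goa, fx$contig_domains)
  expect_equal(names(row)[-(1:4)], feature_roster())
  expect_equal(row$path_length,
               path_length(fx$dist, "H1", "H2"))
  expect_equal(row$dom_int_score,
               domain_interaction_score(fx$contig_domains$c1,
                                        fx$contig_domains$c2, fx$catalog))
  expect_equal(row$nto_mf,
               go_nto(fx$dag, "GO:1000001", "GO:1000001", "molecular_function"))
  expect_equal(row$nto_bp,
               go_nto(fx$dag, "GO:2000001", character(0), "biological_process"))
  expect_equal(row$blast_evalue_a, 1e-60)
  expect_equal(row$blast_brh_a, TRUE)
  # c2 has no EggNOG evidence: sentinel NA, boolean FALSE
  expect_true(is.na(row$eggnog_evalue_b))
  expect_false(row$eggnog_brh_b)

  # a pair member without an assignment is a contract violation
  expect_error(build_pair_features(c("c1", "nope"), fx$assignments, fx$dist,
                                   fx$catalog, fx$dag, fx$goa,
                                   fx$contig_domains), "resolved homolog")
})

test_that("pair features are canonical under member swap", {
  fx <- make_feature_fixture()
  fwd <- build_pair_features(c("c1", "c2"), fx$assignments, fx$dist,
                             fx$catalog, fx$dag, fx$goa, fx$contig_domains)
  swp <- build_pair_features(c("c2", "c1"), fx$assignments, fx$dist,
                             fx$catalog, fx$dag, fx$goa, fx$contig_domains)
  expect_equal(fwd, swp)
  expect_equal(fwd$contig_a, "c1")  # lexicographic canonical order
})

test_that("NTO stays within [0,1] and is 1 on identical annotation", {
  fx <- make_feature_fixture()
  set.seed(4)
  terms <- fx$dag$terms$id[fx$dag$terms$aspect == "molecular_function"]
  for (i in 1:20) {
    ta <- sample(terms, sample(0:3, 1))
    tb <- sample(terms, sample(0:3, 1))
    v <- go_nto(fx$dag, ta, tb, "molecular_function")
    expect_gte(v, 0); expect_lte(v, 1)
    if (length(ta) > 0) {
      expect_equal(go_nto(fx$dag, ta, ta, "molecular_function"), 1)
    }
  }
})
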