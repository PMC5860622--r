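# All internal coordinates are 0-based half-open. BLAST tabular and HMMER
# domtblout are 1-based inclusive; conversion happens here, at the format
# boundary, and nowhere else.

#' Read a tabular homology-evidence file
#'
#' Parses BLAST tabular output (`-outfmt 6`, optionally with a 13th `qlen`
#' column as produced by `-outfmt "6 std qlen"`) or HMMER per-domain tables
#' (`--domtblout`) into a uniform evidence-hit data frame. For HMMER tables
#' the searched sequence (domtblout "target") becomes `query_id` and the
#' profile model (domtblout "query") becomes `target_id`, so that `query_id`
#' is always the transcript/protein being annotated.
#'
#' @param path Path to the file.
#' @param method One of `"blast"`, `"eggnog"`, `"pfam"`. EggNOG and PFAM
#'   share the domtblout dialect; the method tag is carried through so that
#'   downstream evidence can be told apart.
#' @param query_lengths Optional named integer vector of query sequence
#'   lengths, used to compute BLAST query coverage when the table has no
#'   `qlen` column.
#' @return A data frame with one row per hit: `query_id`, `target_id`,
#'   `method`, `evalue`, `score`, `query_coverage` (BLAST only, `NA`
#'   otherwise) plus coordinate columns in 0-based half-open convention
#'   (`q_start`/`q_end`/`s_start`/`s_end` for BLAST;
#'   `model_len`/`model_start`/`model_end`/`seq_start`/`seq_end`/`seq_len`
#'   for HMMER).
#' @export
read_evidence_table <- function(path, method = c("blast", "eggnog", "pfam"),
                                query_lengths = NULL) {
  method <- match.arg(method)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty evidence table: ", path)
    return(empty_evidence(method))
  }
  if (method == "blast") parse_blast_lines(lines, path, query_lengths)
  else parse_domtbl_lines(lines, path, method)
}

empty_evidence <- function(method) {
  base <- data.frame(query_id = character(), target_id = character(),
                     method = character(), evalue = numeric(),
                     score = numeric(), query_coverage = numeric(),
                     stringsAsFactors = FALSE)
  if (method == "blast") {
    cbind(base, data.frame(pident = numeric(), aln_length = integer(),
                           q_start = integer(), q_end = integer(),
                           s_start = integer(), s_end = integer()))
  } else {
    cbind(base, data.frame(model_len = integer(), model_start = integer(),
                           model_end = integer(), seq_start = integer(),
                           seq_end = integer(), seq_len = integer()))
  }
}

parse_blast_lines <- function(lines, path, query_lengths) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(!(ncols %in% c(12L, 13L)))
  if (length(bad) > 0L) {
    stop("malformed BLAST tabular row (expected 12 or 13 columns) at line ",
         bad[1L], " of ", path)
  }
  m <- do.call(rbind, lapply(fields, function(f) f[seq_len(12L)]))
  qlen <- if (all(ncols == 13L)) {
    as.integer(vapply(fields, `[`, character(1), 13L))
  } else if (!is.null(query_lengths)) {
    unname(query_lengths[m[, 1L]])
  } else NA_integer_
  qstart <- as.integer(m[, 7L]); qend <- as.integer(m[, 8L])
  cov <- (qend - qstart + 1L) / qlen
  out <- data.frame(
    query_id = m[, 1L], target_id = m[, 2L], method = "blast",
    evalue = as.numeric(m[, 11L]), score = as.numeric(m[, 12L]),
    query_coverage = as.numeric(cov),
    pident = as.numeric(m[, 3L]), aln_length = as.integer(m[, 4L]),
    q_start = qstart - 1L, q_end = qend,
    s_start = as.integer(m[, 9L]) - 1L, s_end = as.integer(m[, 10L]),
    stringsAsFactors = FALSE)
  if (anyNA(out$evalue)) {
    stop("malformed E-value at line ", which(is.na(out$evalue))[1L],
         " of ", path)
  }
  out
}

parse_domtbl_lines <- function(lines, path, method) {
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(lengths(fields) < 22L)
  if (length(bad) > 0L) {
    stop("malformed domtblout row (expected >= 22 columns) at line ",
         bad[1L], " of ", path)
  }
  col <- function(i, as = as.character) as(vapply(fields, `[`, character(1), i))
  out <- data.frame(
    query_id = col(1L),                       # searched sequence
    target_id = col(4L),                      # profile model
    method = method,
    evalue = col(13L, as.numeric),            # i-Evalue (per-domain)
    score = col(14L, as.numeric),             # per-domain bit score
    query_coverage = NA_real_,
    model_len = col(6L, as.integer),
    model_start = col(16L, as.integer) - 1L,  # hmm from/to
    model_end = col(17L, as.integer),
    seq_start = col(18L, as.integer) - 1L,    # ali from/to
    seq_end = col(19L, as.integer),
    seq_len = col(3L, as.integer),
    stringsAsFactors = FALSE)
  if (anyNA(out$evalue) || anyNA(out$model_start)) {
    stop("malformed numeric field in domtblout ", path)
  }
  out
}

#' Write evidence hits back to their on-disk dialect
#'
#' Inverse of [read_evidence_table()]: BLAST hits go out as 13-column
#' tabular (`std` + `qlen`), HMMER hits as a minimal domtblout. Coordinates
#' are converted back to 1-based inclusive.
#'
#' @param hits Evidence data frame as returned by [read_evidence_table()].
#' @param path Output path.
#' @export
write_evidence_table <- function(hits, path) {
  if (nrow(hits) == 0L) { writeLines(character(), path); return(invisible(path)) }
  if (hits$method[1L] == "blast") {
    qlen <- as.integer(round((hits$q_end - hits$q_start) / hits$query_coverage))
    lines <- sprintf("%s\t%s\t%s\t%d\t0\t0\t%d\t%d\t%d\t%d\t%s\t%s\t%d",
                     hits$query_id, hits$target_id, num_chr(hits$pident),
                     as.integer(hits$aln_length), as.integer(hits$q_start) + 1L,
                     as.integer(hits$q_end), as.integer(hits$s_start) + 1L,
                     as.integer(hits$s_end),
                     num_chr(hits$evalue), num_chr(hits$score), qlen)
  } else {
    lines <- sprintf(
      "%s - %d %s - %d %s %s 0.0 1 1 %s %s %s 0.0 %d %d %d %d %d %d 0.90 -",
      hits$query_id, as.integer(hits$seq_len), hits$target_id,
      as.integer(hits$model_len),
      num_chr(hits$evalue), num_chr(hits$score), num_chr(hits$evalue),
      num_chr(hits$evalue), num_chr(hits$score),
      as.integer(hits$model_start) + 1L, as.integer(hits$model_end),
      as.integer(hits$seq_start) + 1L, as.integer(hits$seq_end),
      as.integer(hits$seq_start) + 1L, as.integer(hits$seq_end))
  }
  writeLines(lines, path)
  invisible(path)
}

# Compact, parse-stable number formatting for writers.
num_chr <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == 0) return("0.0")
    format(v, digits = 7, trim = TRUE, scientific = abs(log10(abs(v))) > 5)
  }, character(1))
}

#' Build a synonym table
#'
#' @param canonical Character vector of canonical symbols.
#' @param synonyms List (parallel to `canonical`) of character vectors of
#'   synonyms. Each canonical symbol is implicitly its own synonym.
#' @return A data frame (`synonym`, `canonical`); a synonym may map to only
#'   one canonical symbol (violations are an error).
#' @export
synonym_table <- function(canonical, synonyms = vector("list", length(canonical))) {
  stopifnot(length(canonical) == length(synonyms), !anyDuplicated(canonical))
  tab <- data.frame(
    synonym = c(canonical, unlist(synonyms, use.names = FALSE)),
    canonical = c(canonical, rep(canonical, lengths(synonyms))),
    stringsAsFactors = FALSE)
  tab <- unique(tab)
  dup <- tab$synonym[duplicated(tab$synonym)]
  if (length(dup) > 0L) {
    stop("synonym(s) mapping to more than one canonical symbol: ",
         paste(unique(dup), collapse = ", "))
  }
  class(tab) <- c("synonym_table", class(tab))
  tab
}

#' Resolve an identifier through a synonym table
#'
#' @param ids Character vector of identifiers.
#' @param synonyms A [synonym_table()], or `NULL` (identity mapping).
#' @return Canonical symbols where resolvable, the input identifier
#'   otherwise.
#' @export
resolve_symbols <- function(ids, synonyms) {
  if (is.null(synonyms)) return(ids)
  i <- match(ids, synonyms$synonym)
  out <- synonyms$canonical[i]
  out[is.na(i)] <- ids[is.na(i)]
  out
}

#' Assign one sequence record per symbol with database priority
#'
#' Walks the databases in priority order; a symbol is looked up in the next
#' database only if it is still unassigned by every higher-priority
#' database. Duplicate records for one symbol within one database are
#' resolved deterministically (longest sequence, then lexicographically
#' smallest id) with a warning.
#'
#' @param records Data frame with columns `id`, `sequence`, `source_db`.
#' @param synonyms A [synonym_table()] mapping record ids to canonical
#'   symbols, or `NULL`.
#' @param priority Character vector of database tags, highest priority
#'   first; must cover every `source_db` present.
#' @return Data frame (`symbol`, `id`, `sequence`, `source_db`), one row per
#'   assigned symbol. Records whose id resolves to no known symbol are
#'   dropped (count in attribute `n_unmapped`).
#' @export
map_symbols <- function(records, synonyms = NULL, priority) {
  stopifnot(all(c("id", "sequence", "source_db") %in% names(records)))
  missing_db <- setdiff(unique(records$source_db), priority)
  if (length(missing_db) > 0L) {
    stop("priority list does not cover database(s): ",
         paste(missing_db, collapse = ", "))
  }
  n_unmapped <- 0L
  assigned <- list()
  for (db in priority) {
    sub <- records[records$source_db == db, , drop = FALSE]
    if (nrow(sub) == 0L) next
    sym <- resolve_symbols(sub$id, synonyms)
    if (!is.null(synonyms)) {
      known <- sym %in% synonyms$canonical
      n_unmapped <- n_unmapped + sum(!known)
      sub <- sub[known, , drop = FALSE]; sym <- sym[known]
    }
    # deterministic tie-break within one database
    ord <- order(sym, -nchar(sub$sequence), sub$id)
    sub <- sub[ord, , drop = FALSE]; sym <- sym[ord]
    if (anyDuplicated(sym)) {
      warning("duplicate records within database '", db,
              "' resolved by longest sequence then id")
    }
    keep <- !duplicated(sym) & !(sym %in% names(assigned))
    for (k in which(keep)) {
      assigned[[sym[k]]] <- data.frame(
        symbol = sym[k], id = sub$id[k], sequence = sub$sequence[k],
        source_db = db, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, assigned[order(names(assigned))])
  if (is.null(out)) out <- data.frame(symbol = character(), id = character(),
                                      sequence = character(),
                                      source_db = character())
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Read a two-column edge list
#'
#' @param path TSV with two identifier columns (no header, `#` comments
#'   allowed).
#' @return Data frame with columns `a`, `b`.
#' @export
read_edge_tsv <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(a = character(), b = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad) > 0L) stop("edge row with fewer than two columns at line ",
                             bad[1L], " of ", path)
  data.frame(a = vapply(parts, `[`, character(1), 1L),
             b = vapply(parts, `[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Assemble the reference interactome from edge lists
#'
#' Concatenates one or more two-column edge lists, renames every endpoint to
#' its canonical symbol where the synonym table resolves it (identifiers
#' with no synonym are kept verbatim), drops self-loops arising before or
#' after renaming, and deduplicates undirected edges.
#'
#' @param edge_lists A data frame, a path, or a list of either.
#' @param synonyms A [synonym_table()] or `NULL`.
#' @return An undirected simple `igraph` graph; the number of dropped
#'   self-loops is stored in graph attribute `selfloops_dropped`.
#' @export
build_reference_network <- function(edge_lists, synonyms = NULL) {
  if (is.data.frame(edge_lists) || is.character(edge_lists)) {
    edge_lists <- list(edge_lists)
  }
  tabs <- lapply(edge_lists, function(e) {
    if (is.character(e)) read_edge_tsv(e) else {
      stopifnot(ncol(e) >= 2L)
      data.frame(a = as.character(e[[1L]]), b = as.character(e[[2L]]),
                 stringsAsFactors = FALSE)
    }
  })
  edges <- do.call(rbind, tabs)
  edges$a <- resolve_symbols(edges$a, synonyms)
  edges$b <- resolve_symbols(edges$b, synonyms)
  loops <- edges$a == edges$b
  if (any(loops)) message(sum(loops), " self-loop(s) dropped")
  edges <- edges[!loops, , drop = FALSE]
  lo <- pmin(edges$a, edges$b); hi <- pmax(edges$a, edges$b)
  keep <- !duplicated(paste(lo, hi, sep = "\r"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo[keep], to = hi[keep], stringsAsFactors = FALSE),
    directed = FALSE)
  g <- igraph::set_graph_attr(g, "selfloops_dropped", sum(loops))
  g
}

#' Write a reference network back to a two-column TSV
#' @param graph An `igraph` graph.
#' @param path Output path.
#' @export
write_edge_tsv <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  lo <- pmin(el[, 1L], el[, 2L]); hi <- pmax(el[, 1L], el[, 2L])
  ord <- order(lo, hi)
  writeLines(paste(lo[ord], hi[ord], sep = "\t"), path)
  invisible(path)
}

#' Read GO annotations
#'
#' @param path TSV mapping protein symbol to GO id, with an optional third
#'   aspect column (ignored if present; the aspect is taken from the
#'   ontology itself).
#' @return Data frame (`symbol`, `go_id`).
#' @export
read_go_annotations <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad) > 0L) stop("annotation row with fewer than two columns at line ",
                             bad[1L], " of ", path)
  data.frame(symbol = vapply(parts, `[`, character(1), 1L),
             go_id = vapply(parts, `[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Read transcript sequences from FASTA
#'
#' @param path FASTA file of nucleotide sequences.
#' @return Data frame (`id`, `sequence`).
#' @export
read_transcripts <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  data.frame(id = sub("\\s.*$", "", names(x)),
             sequence = as.character(x), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Default pipeline configuration
#'
#' All tunable thresholds in one place; [read_config()] overlays a YAML
#' file on these defaults.
#'
#' @return Named list of parameters: per-method E-value cutoffs (1e-10
#'   each), domain-merge overlap fraction (0.25), meta-alignment scores
#'   (+30/-30/-5), forest size (1000) and per-tree negative:positive ratio
#'   (5), vote cutoff (0.6), candidate path-length horizon (2),
#'   many-to-one pruning cap (100), and vote-histogram bin width (0.05).
#' @export
default_config <- function() {
  list(
    evalue_blast = 1e-10,
    evalue_eggnog = 1e-10,
    evalue_pfam = 1e-10,
    merge_overlap_fraction = 0.25,
    meta_match = 30, meta_mismatch = -30, meta_gap = -5,
    n_trees = 1000L, neg_pos_ratio = 5L,
    vote_cutoff = 0.6,
    max_path_length = 2L,
    max_contigs_per_protein = 100L,
    vote_bin_width = 0.05,
    expression_pseudocount = 1
  )
}

#' Read a YAML configuration file
#' @param path YAML file; keys override [default_config()] entries.
#' @return Full configuration list.
#' @export
read_config <- function(path) {
  cfg <- default_config()
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L) warning("unknown config key(s): ",
                                    paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  cfg
}
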