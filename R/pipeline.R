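# Pipeline glue: from raw evidence tables to homology assignments.

#' Resolve best human homologs from the three evidence channels
#'
#' Runs the full homology stage: filters hits by their per-method E-value
#' cutoffs, computes best reciprocal hits for BLAST (forward/reverse
#' tables) and for the EggNOG profile search (table margins), merges split
#' PFAM annotations and builds domain meta-sequences on both sides, scores
#' the meta-alignments, and applies the best-homolog cascade per
#' transcript.
#'
#' @param blast_fwd,blast_rev BLAST evidence data frames
#'   (transcript -> human and human -> transcript) from
#'   [read_evidence_table()].
#' @param eggnog EggNOG domtblout evidence (model names must be the human
#'   symbols they represent; the model set is assumed pre-filtered to
#'   models with an HGNC member).
#' @param pfam_query,pfam_target PFAM domtblout evidence for the
#'   transcripts and for the reference proteins.
#' @param config Configuration list (see [default_config()]).
#' @return Object of class `homology_result`: `assignments` (data frame
#'   `transcript_id`, `human_symbol`, `rule`, `blast_evalue`,
#'   `blast_coverage`, `blast_brh`, `eggnog_evalue`, `eggnog_brh`,
#'   `pfam_score`, `pfam_brh`), `contig_domains` and `target_domains`
#'   (named lists of PFAM ids), `evidence` (the combined filtered hit
#'   table), and `n_discarded`.
#' @export
resolve_homologs <- function(blast_fwd, blast_rev, eggnog,
                             pfam_query, pfam_target,
                             config = default_config()) {
  bf <- blast_fwd[blast_fwd$evalue <= config$evalue_blast, , drop = FALSE]
  br <- blast_rev[blast_rev$evalue <= config$evalue_blast, , drop = FALSE]
  eg <- eggnog[eggnog$evalue <= config$evalue_eggnog, , drop = FALSE]
  pq <- pfam_query[pfam_query$evalue <= config$evalue_pfam, , drop = FALSE]
  pt <- pfam_target[pfam_target$evalue <= config$evalue_pfam, , drop = FALSE]

  brh_key <- function(df) paste(df$query_id, df$target_id, sep = "\r")
  blast_brh <- best_reciprocal_hits(bf, br)
  eggnog_brh <- best_reciprocal_hits(eg)

  sort_ann <- function(h) {
    a <- data.frame(seq_id = h$query_id, domain_id = h$target_id,
                    model_len = h$model_len, model_start = h$model_start,
                    model_end = h$model_end, seq_start = h$seq_start,
                    seq_end = h$seq_end, evalue = h$evalue,
                    stringsAsFactors = FALSE)
    a[order(a$seq_id, a$seq_start), , drop = FALSE]
  }
  q_ann <- merge_domains(sort_ann(pq), config$merge_overlap_fraction)
  t_ann <- merge_domains(sort_ann(pt), config$merge_overlap_fraction)
  metas <- function(ann) {
    lapply(split(ann, ann$seq_id), build_metasequence)
  }
  meta_hits <- meta_alignment_hits(metas(q_ann), metas(t_ann),
                                   match = config$meta_match,
                                   mismatch = config$meta_mismatch,
                                   gap = config$meta_gap)
  pfam_brh <- best_reciprocal_hits(meta_hits)

  ev_cols <- c("query_id", "target_id", "method", "evalue", "score",
               "query_coverage")
  evidence <- rbind(bf[ev_cols], eg[ev_cols], meta_hits[ev_cols])
  brh_keys <- c(brh_key(blast_brh), brh_key(eggnog_brh), brh_key(pfam_brh))
  evidence$is_brh <- brh_key(evidence) %in% brh_keys

  transcripts <- sort(unique(evidence$query_id))
  by_tr <- split(evidence, evidence$query_id)
  rows <- vector("list", length(transcripts)); k <- 0L
  for (tr in transcripts) {
    sel <- select_best_homolog(tr, by_tr[[tr]])
    if (is.null(sel)) next
    ev <- sel$evidence
    measure <- function(m, field) {
      sub <- ev[ev$method == m, , drop = FALSE]
      if (nrow(sub) == 0L) return(NA_real_)
      best <- if (m == "pfam_meta") which.max(sub$score) else which.min(sub$evalue)
      sub[[field]][best]
    }
    k <- k + 1L
    rows[[k]] <- data.frame(
      transcript_id = sel$transcript_id, human_symbol = sel$human_symbol,
      rule = sel$rule,
      blast_evalue = measure("blast", "evalue"),
      blast_coverage = measure("blast", "query_coverage"),
      blast_brh = isTRUE(any(ev$method == "blast" & ev$is_brh)),
      eggnog_evalue = measure("eggnog", "evalue"),
      eggnog_brh = isTRUE(any(ev$method == "eggnog" & ev$is_brh)),
      pfam_score = measure("pfam_meta", "score"),
      pfam_brh = isTRUE(any(ev$method == "pfam_meta" & ev$is_brh)),
      stringsAsFactors = FALSE)
  }
  assignments <- if (k > 0L) do.call(rbind, rows[seq_len(k)]) else
    data.frame(transcript_id = character(), human_symbol = character(),
               rule = integer(), stringsAsFactors = FALSE)
  rownames(assignments) <- NULL
  structure(list(
    assignments = assignments,
    contig_domains = lapply(split(q_ann$domain_id, q_ann$seq_id), unique),
    target_domains = lapply(split(t_ann$domain_id, t_ann$seq_id), unique),
    evidence = evidence,
    n_discarded = length(transcripts) - k), class = "homology_result")
}

#' Read an expression matrix TSV
#'
#' @param path TSV with a leading `sample` column and one column per
#'   contig.
#' @return Numeric matrix, samples in rows, contigs in columns.
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  storage.mode(m) <- "double"
  m
}
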