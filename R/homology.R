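# Homology resolution: each transcript gets at most one best human homolog,
# chosen by a strict cascade over three evidence channels (BLAST, EggNOG
# profile hits, PFAM domain-architecture meta-alignment).

#' Longest open reading frame over six frames
#'
#' Translates the transcript in all six frames and returns the single
#' longest stop-free translated stretch. No start codon is required:
#' assembled contigs are frequently 5'-truncated and demanding an ATG would
#' discard genuine coding fragments. Ties are broken by frame order
#' (+1, +2, +3, -1, -2, -3), then by smaller start position.
#'
#' @param sequence Nucleotide string (or a data frame row with `id` and
#'   `sequence` as returned by [read_transcripts()]).
#' @param id Transcript identifier.
#' @return List with `transcript_id`, `frame` (in \{-3..-1, 1..3\}),
#'   `aa_start`/`aa_end` (0-based half-open coordinates on that frame's
#'   translation) and `aa_sequence`.
#' @export
longest_orf <- function(sequence, id = "transcript") {
  if (is.data.frame(sequence)) { id <- sequence$id; sequence <- sequence$sequence }
  sequence <- toupper(sequence)
  if (nchar(sequence) < 3L) stop("sequence shorter than one codon: ", id)
  fwd <- Biostrings::DNAString(sequence)
  rev <- Biostrings::reverseComplement(fwd)
  frames <- list(`1` = fwd, `2` = fwd, `3` = fwd,
                 `-1` = rev, `-2` = rev, `-3` = rev)
  best <- NULL
  for (k in seq_along(frames)) {
    off <- c(1L, 2L, 3L, 1L, 2L, 3L)[k]
    s <- frames[[k]]
    n <- length(s) - off + 1L
    n <- n - n %% 3L
    if (n < 3L) next
    aa <- as.character(suppressWarnings(
      Biostrings::translate(Biostrings::subseq(s, off, off + n - 1L),
                            if.fuzzy.codon = "X")))
    runs <- gregexpr("[^*]+", aa)[[1L]]
    if (runs[1L] == -1L) next
    lens <- attr(runs, "match.length")
    for (r in seq_along(runs)) {
      # frames are visited in tie-break order (+1,+2,+3,-1,-2,-3) and runs
      # in order of start, so a strict comparison implements the tie rule
      if (is.null(best) || lens[r] > best$len) {
        best <- list(len = lens[r], start = runs[r],
                     frame = as.integer(names(frames)[k]), aa = aa)
      }
    }
  }
  if (is.null(best)) stop("no translatable stretch in ", id)
  list(transcript_id = id, frame = best$frame,
       aa_start = best$start - 1L, aa_end = best$start - 1L + best$len,
       aa_sequence = substr(best$aa, best$start, best$start + best$len - 1L))
}

# Best hit of each query in a hit table: strictly lowest E-value, then
# strictly highest score. Ambiguous bests (exact ties) yield no best hit.
best_hit_per <- function(hits, key_col, other_col) {
  if (nrow(hits) == 0L) return(character(0))
  ev <- hits$evalue
  ev[is.na(ev)] <- Inf          # pfam_meta hits rank by score only
  ord <- order(hits[[key_col]], ev, -hits$score)
  h <- hits[ord, , drop = FALSE]
  first <- !duplicated(h[[key_col]])
  best <- h[first, , drop = FALSE]
  # mark ambiguous keys (runner-up identical in both ranking criteria)
  run_idx <- which(first) + 1L
  ambiguous <- rep(FALSE, nrow(best))
  valid <- run_idx <= nrow(h)
  if (any(valid)) {
    i <- which(valid)
    same_key <- h[[key_col]][run_idx[i]] == best[[key_col]][i]
    ev2 <- ev[ord]
    tie <- same_key & ev2[run_idx[i]] == ev2[which(first)[i]] &
      h$score[run_idx[i]] == best$score[i]
    ambiguous[i] <- tie
  }
  best <- best[!ambiguous, , drop = FALSE]
  stats::setNames(best[[other_col]], best[[key_col]])
}

#' Best reciprocal hits between two hit tables
#'
#' A pair (q, t) is a best reciprocal hit when t is q's unique best hit
#' (lowest E-value, then highest score) in the forward table and q is t's
#' unique best hit in the reverse table. With `reverse = NULL` reciprocity
#' is computed on the two margins of the single forward table, the natural
#' reading for profile searches that have no literal reverse run.
#'
#' @param forward Evidence data frame, queries in `query_id`.
#' @param reverse Evidence data frame with roles swapped (its `query_id`
#'   values are the forward targets), or `NULL`.
#' @return Data frame (`query_id`, `target_id`) of reciprocal pairs.
#' @export
best_reciprocal_hits <- function(forward, reverse = NULL) {
  out0 <- data.frame(query_id = character(), target_id = character(),
                     stringsAsFactors = FALSE)
  if (nrow(forward) == 0L) return(out0)
  fbest <- best_hit_per(forward, "query_id", "target_id")
  rbest <- if (is.null(reverse)) {
    best_hit_per(forward, "target_id", "query_id")
  } else if (nrow(reverse) == 0L) character(0) else {
    best_hit_per(reverse, "query_id", "target_id")
  }
  if (length(fbest) == 0L || length(rbest) == 0L) return(out0)
  q <- names(fbest); t <- unname(fbest)
  ok <- !is.na(rbest[t]) & rbest[t] == q
  ok[is.na(ok)] <- FALSE
  out <- data.frame(query_id = q[ok], target_id = t[ok],
                    stringsAsFactors = FALSE)
  out[order(out$query_id, out$target_id), , drop = FALSE]
}

#' Merge consecutive partial annotations of one PFAM domain
#'
#' Split hits of a single domain model along an ORF are rejoined when all
#' three conditions hold: (1) the two annotations carry the same domain and
#' are consecutive (no other annotation between them on the sequence);
#' (2) they cover different regions of the model -- their model-coordinate
#' overlap is < 25% of the model length; (3) the gap between them on the
#' ORF is at most the unannotated model length plus 25% of the model
#' length. Merging is applied left-to-right and repeated to fixpoint, so a
#' merged annotation may merge again with its right neighbour.
#'
#' @param annots Data frame of domain annotations for one or more
#'   sequences, 0-based half-open coordinates, sorted by `seq_start` within
#'   each `seq_id` (unsorted input is an error).
#' @param overlap_fraction Model-overlap / gap-slack fraction (default
#'   0.25).
#' @return Data frame of merged annotations; a merged row spans the union
#'   of sequence and model coordinates and keeps the smaller E-value.
#' @export
merge_domains <- function(annots, overlap_fraction = 0.25) {
  if (nrow(annots) == 0L) return(annots)
  if (is.null(annots$model_covered)) {
    # residues of the model covered; a merged row tracks the union, which
    # can be smaller than its model-coordinate span
    annots$model_covered <- annots$model_end - annots$model_start
  }
  out <- lapply(split(annots, annots$seq_id), merge_one_seq, overlap_fraction)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

merge_one_seq <- function(a, frac) {
  if (is.unsorted(a$seq_start)) stop("annotations not sorted by seq_start: ",
                                     a$seq_id[1L])
  rows <- split(a, seq_len(nrow(a)))
  repeat {
    merged_any <- FALSE
    i <- 1L
    while (i < length(rows)) {
      x <- rows[[i]]; y <- rows[[i + 1L]]
      if (x$domain_id == y$domain_id && can_merge(x, y, frac)) {
        rows[[i]] <- merge_pair(x, y)
        rows[[i + 1L]] <- NULL
        merged_any <- TRUE            # stay at i: result may merge again
      } else i <- i + 1L
    }
    if (!merged_any) break
  }
  do.call(rbind, rows)
}

can_merge <- function(x, y, frac) {
  ml <- x$model_len
  overlap <- max(0L, min(x$model_end, y$model_end) -
                   max(x$model_start, y$model_start))
  if (overlap >= frac * ml) return(FALSE)
  covered <- x$model_covered + y$model_covered - overlap
  gap <- y$seq_start - x$seq_end
  gap <= (ml - covered) + frac * ml
}

merge_pair <- function(x, y) {
  overlap <- max(0L, min(x$model_end, y$model_end) -
                   max(x$model_start, y$model_start))
  x$model_covered <- x$model_covered + y$model_covered - overlap
  x$model_start <- min(x$model_start, y$model_start)
  x$model_end <- max(x$model_end, y$model_end)
  x$seq_start <- min(x$seq_start, y$seq_start)
  x$seq_end <- max(x$seq_end, y$seq_end)
  x$evalue <- min(x$evalue, y$evalue)
  x
}

#' Build a domain meta-sequence
#'
#' Collapses merged domain annotations into the ordered string of domain
#' symbols used by the meta-alignment, each weighted by the fraction of the
#' domain model it covers.
#'
#' @param merged Merged annotations for one sequence (see
#'   [merge_domains()]), sorted by `seq_start`.
#' @param seq_id Identifier (taken from the annotations when present).
#' @return An object of class `meta_sequence`: list with `seq_id`, `domain`
#'   (character vector) and `coverage` (numeric in (0, 1], clamped).
#' @export
build_metasequence <- function(merged, seq_id = NULL) {
  if (is.null(seq_id)) {
    seq_id <- if (nrow(merged) > 0L) merged$seq_id[1L] else ""
  }
  if (nrow(merged) == 0L) {
    return(structure(list(seq_id = seq_id, domain = character(0),
                          coverage = numeric(0)), class = "meta_sequence"))
  }
  ord <- order(merged$seq_start)
  m <- merged[ord, , drop = FALSE]
  covered <- if (!is.null(m$model_covered)) m$model_covered else
    m$model_end - m$model_start
  structure(list(
    seq_id = seq_id, domain = m$domain_id,
    coverage = pmin(1, covered / m$model_len)),
    class = "meta_sequence")
}

#' Needleman-Wunsch alignment of two domain meta-sequences
#'
#' Global alignment over domain symbols with linear gap penalty. An aligned
#' pair of identical domains scores `match` scaled by the smaller of the
#' two model coverages (the match reward is adjusted to the fraction of the
#' domain actually annotated); different domains score `mismatch`; each
#' gapped symbol scores `gap`. Traceback ties are resolved diagonal > up >
#' left (up consumes a symbol of `a`).
#'
#' @param a,b `meta_sequence` objects.
#' @param match,mismatch,gap Scores (defaults +30, -30, -5).
#' @return List with `score` and `alignment` (data frame of `a_index`,
#'   `b_index`, `NA` marking a gap). Two empty meta-sequences score 0.
#' @export
meta_align <- function(a, b, match = 30, mismatch = -30, gap = -5) {
  na <- length(a$domain); nb <- length(b$domain)
  S <- matrix(0, na + 1L, nb + 1L)
  S[, 1L] <- gap * (0:na)
  S[1L, ] <- gap * (0:nb)
  for (i in seq_len(na)) {
    sub_i <- ifelse(a$domain[i] == b$domain,
                    match * pmin(a$coverage[i], b$coverage), mismatch)
    for (j in seq_len(nb)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + sub_i[j],
                               S[i, j + 1L] + gap,
                               S[i + 1L, j] + gap)
    }
  }
  # traceback, diagonal > up > left
  i <- na; j <- nb; ai <- integer(0); bi <- integer(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L) {
      sub <- if (a$domain[i] == b$domain[j])
        match * min(a$coverage[i], b$coverage[j]) else mismatch
      if (S[i + 1L, j + 1L] == S[i, j] + sub) {
        ai <- c(i, ai); bi <- c(j, bi); i <- i - 1L; j <- j - 1L; next
      }
    }
    if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      ai <- c(i, ai); bi <- c(NA_integer_, bi); i <- i - 1L; next
    }
    ai <- c(NA_integer_, ai); bi <- c(j, bi); j <- j - 1L
  }
  list(score = S[na + 1L, nb + 1L],
       alignment = data.frame(a_index = ai, b_index = bi))
}

#' Score meta-alignments between two sets of meta-sequences
#'
#' Computes [meta_align()] scores for every (query, target) pair sharing at
#' least one domain symbol (pairs with disjoint architectures cannot score
#' above an all-gap alignment and are skipped).
#'
#' @param queries,targets Named lists of `meta_sequence` objects.
#' @param min_score Keep hits scoring strictly above this (default 0).
#' @param match,mismatch,gap Passed to [meta_align()].
#' @return Evidence data frame (`query_id`, `target_id`,
#'   `method = "pfam_meta"`, `evalue = NA`, `score`).
#' @export
meta_alignment_hits <- function(queries, targets, min_score = 0,
                                match = 30, mismatch = -30, gap = -5) {
  # index targets by domain symbol
  dom2t <- list()
  for (tn in names(targets)) {
    for (d in unique(targets[[tn]]$domain)) dom2t[[d]] <- c(dom2t[[d]], tn)
  }
  rows <- vector("list", length(queries)); k <- 0L
  for (qn in names(queries)) {
    q <- queries[[qn]]
    cand <- unique(unlist(dom2t[unique(q$domain)], use.names = FALSE))
    if (length(cand) == 0L) next
    sc <- vapply(cand, function(tn)
      meta_align(q, targets[[tn]], match, mismatch, gap)$score, numeric(1))
    keep <- sc > min_score
    if (!any(keep)) next
    k <- k + 1L
    rows[[k]] <- data.frame(query_id = qn, target_id = cand[keep],
                            method = "pfam_meta", evalue = NA_real_,
                            score = sc[keep], query_coverage = NA_real_,
                            stringsAsFactors = FALSE)
  }
  if (k == 0L) {
    return(data.frame(query_id = character(), target_id = character(),
                      method = character(), evalue = numeric(),
                      score = numeric(), query_coverage = numeric()))
  }
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Select the best human homolog for one transcript
#'
#' Evaluates the decision cascade strictly in order: (1) unique EggNOG best
#' reciprocal hit; (2) unique protein with the largest number of supporting
#' evidence channels across the three methods; (3) unique lowest-E-value
#' EggNOG hit; (4) unique lowest-E-value BLAST hit; (5) best-scoring PFAM
#' meta-alignment hit (ties go to the lexicographically smallest symbol);
#' otherwise the transcript is discarded. Any hit passing its method's
#' E-value cutoff counts as supporting evidence in rule 2, reciprocal or
#' not.
#'
#' @param transcript_id Transcript identifier.
#' @param hits Evidence data frame for this transcript: columns `query_id`,
#'   `target_id`, `method` (`blast`/`eggnog`/`pfam_meta`), `evalue`,
#'   `score`, `is_brh` (logical).
#' @return List (`transcript_id`, `human_symbol`, `rule`, `evidence`) or
#'   `NULL` when no rule fires.
#' @export
select_best_homolog <- function(transcript_id, hits) {
  hits <- hits[hits$query_id == transcript_id, , drop = FALSE]
  if (nrow(hits) == 0L) return(NULL)
  pick <- function(symbol, rule) {
    list(transcript_id = transcript_id, human_symbol = symbol, rule = rule,
         evidence = hits[hits$target_id == symbol, , drop = FALSE])
  }
  egg <- hits[hits$method == "eggnog", , drop = FALSE]
  # rule 1: unique EggNOG BRH
  eb <- unique(egg$target_id[egg$is_brh])
  if (length(eb) == 1L) return(pick(eb, 1L))
  # rule 2: unique protein with the most supporting evidence channels
  support <- tapply(hits$method, hits$target_id,
                    function(m) length(unique(m)))
  top <- names(support)[support == max(support)]
  if (length(top) == 1L) return(pick(top, 2L))
  # rules 3 and 4: unique lowest-E-value hit, EggNOG first, then BLAST
  unique_lowest <- function(sub) {
    if (nrow(sub) == 0L) return(NULL)
    cand <- unique(sub$target_id[sub$evalue == min(sub$evalue)])
    if (length(cand) == 1L) cand else NULL
  }
  r3 <- unique_lowest(egg)
  if (!is.null(r3)) return(pick(r3, 3L))
  r4 <- unique_lowest(hits[hits$method == "blast", , drop = FALSE])
  if (!is.null(r4)) return(pick(r4, 4L))
  # rule 5: best-scoring meta-alignment hit, lexicographic tie-break
  pf <- hits[hits$method == "pfam_meta", , drop = FALSE]
  if (nrow(pf) > 0L) {
    hi <- max(pf$score)
    cand <- sort(unique(pf$target_id[pf$score == hi]))
    return(pick(cand[1L], 5L))
  }
  NULL
}
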