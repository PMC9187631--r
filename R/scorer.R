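#' Scoring parameters for the similarity-based pair scorer
#'
#' The scorer accumulates evidence for an interaction between query
#' proteins Q1 and Q2 from every known interacting pair (P1, P2) in which
#' P1 is locally similar to Q1 and P2 to Q2 (and vice versa). Similarity is
#' assessed over sliding windows of `w` residues under a substitution
#' matrix; a window pair is a hit when its similarity reaches a fraction
#' `tau` of the smaller of the two windows' self-scores, making the
#' threshold matrix-agnostic. Overlapping hits on one diagonal are merged
#' into regions so a single long similar segment counts once.
#'
#' @param w Window length in residues. Default 20, about the length of a
#'   therapeutic peptide — the scale at which local similarity carries
#'   interaction evidence.
#' @param tau Relative similarity threshold in (0, 1]; default 0.75.
#' @param matrix A [substitution_matrix][sub_matrix]; default PAM120.
#' @param merge_gap Maximum gap (in residues) between window spans on the
#'   same diagonal that still merges them into one region; default 0
#'   (overlapping or abutting windows merge).
#' @param exclude_query_pair When `TRUE`, a database record equal to the
#'   query pair itself is skipped (leave-one-out for self-evaluation).
#'   Default `FALSE`: a screened peptide is never in the database.
#' @return A list of class `scoring_params`.
#' @export
scoring_params <- function(w = 20L, tau = 0.75, matrix = sub_matrix("PAM120"),
                           merge_gap = 0L, exclude_query_pair = FALSE) {
  w <- as.integer(w)
  if (w < 1L) stop("`w` must be >= 1")
  if (!(tau > 0 && tau <= 1)) stop("`tau` must be in (0, 1]")
  if (merge_gap < 0) stop("`merge_gap` must be >= 0")
  stopifnot(inherits(matrix, "substitution_matrix"))
  structure(list(w = w, tau = tau, matrix = matrix,
                 merge_gap = as.integer(merge_gap),
                 exclude_query_pair = isTRUE(exclude_query_pair)),
            class = "scoring_params")
}

#' Window similarity and self-score
#'
#' `window_similarity()` scores two equal-length residue strings as the sum
#' of per-position substitution-matrix entries; `self_score()` scores a
#' string against itself (the window's maximum attainable similarity under
#' a diagonally dominant matrix).
#'
#' @param a,b Residue strings of equal length.
#' @param matrix A [substitution_matrix][sub_matrix].
#' @return Integer score.
#' @examples
#' window_similarity("ACD", "ACE", sub_matrix("BLOSUM62"))  # 15
#' self_score("ACD", sub_matrix("BLOSUM62"))                # 19
#' @export
window_similarity <- function(a, b, matrix) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  if (length(av) != length(bv)) stop("windows must have equal length")
  sum(matrix[cbind(av, bv)])
}

#' @rdname window_similarity
#' @export
self_score <- function(a, matrix) window_similarity(a, a, matrix)

#' Enumerate similar window pairs between two proteins
#'
#' All window-start pairs (i, j) whose window similarity reaches
#' `tau * min(self_score(Q window), self_score(P window))`. Starts are
#' 1-based; `diagonal = p_start - q_start`. Output is sorted by
#' `(q_start, p_start)` and fully deterministic.
#'
#' @param q,p Protein records; both sequences must be at least `w` long.
#' @param params A [scoring_params()].
#' @return Data frame with columns `q_start`, `p_start`, `sim`, `diagonal`.
#' @export
similar_windows <- function(q, p, params = scoring_params()) {
  q <- as_protein(q); p <- as_protein(p)
  if (nchar(q$sequence) < params$w || nchar(p$sequence) < params$w)
    stop("sequence shorter than the window length w = ", params$w)
  h <- cpp_window_hits(encode_seq(q$sequence, params$matrix),
                       encode_seq(p$sequence, params$matrix),
                       params$matrix, params$w, params$tau)
  data.frame(q_start = h$q_start + 1L, p_start = h$p_start + 1L,
             sim = h$sim, diagonal = h$p_start - h$q_start)
}

#' Merge window hits into similarity regions
#'
#' Hits sharing a diagonal whose window spans overlap or abut (within
#' `merge_gap`) merge into one region; the region weight is the maximum
#' normalized similarity `sim / min(self scores)` over its hits.
#'
#' @param hits Output of [similar_windows()] for one (Q, P) comparison.
#' @param q,p The same protein records (needed for window self-scores).
#' @param params A [scoring_params()].
#' @return Data frame with columns `diagonal`, `q_start`, `q_end` (1-based
#'   closed span over the query) and `weight`.
#' @export
merge_hits_to_regions <- function(hits, q, p, params = scoring_params()) {
  q <- as_protein(q); p <- as_protein(p)
  w <- params$w
  m <- params$matrix
  out <- data.frame(diagonal = integer(), q_start = integer(),
                    q_end = integer(), weight = numeric())
  if (nrow(hits) == 0L) return(out)
  selfq <- cpp_self_scores(encode_seq(q$sequence, m), m, w)
  selfp <- cpp_self_scores(encode_seq(p$sequence, m), m, w)
  norm <- hits$sim / pmin(selfq[hits$q_start], selfp[hits$p_start])
  o <- order(hits$diagonal, hits$q_start)
  hits <- hits[o, ]; norm <- norm[o]
  res <- list()
  cur <- list(d = hits$diagonal[1], s = hits$q_start[1],
              e = hits$q_start[1] + w - 1L, w = norm[1])
  for (k in seq_len(nrow(hits))[-1]) {
    if (hits$diagonal[k] == cur$d &&
        hits$q_start[k] <= cur$e + 1L + params$merge_gap) {
      cur$e <- max(cur$e, hits$q_start[k] + w - 1L)
      cur$w <- max(cur$w, norm[k])
    } else {
      res[[length(res) + 1L]] <- cur
      cur <- list(d = hits$diagonal[k], s = hits$q_start[k],
                  e = hits$q_start[k] + w - 1L, w = norm[k])
    }
  }
  res[[length(res) + 1L]] <- cur
  data.frame(diagonal = vapply(res, `[[`, 0, "d"),
             q_start = vapply(res, `[[`, 0, "s"),
             q_end = vapply(res, `[[`, 0, "e"),
             weight = vapply(res, `[[`, 0, "w"))
}

#' Evidence weight between a query and a database protein
#'
#' Sum over merged similarity regions of the region weight; 0 when no
#' window pair reaches the threshold. A sequence shorter than the window
#' length contributes weight 0 with a warning rather than erroring, so
#' short mutant peptides degrade gracefully.
#'
#' @inheritParams similar_windows
#' @return Non-negative numeric scalar.
#' @export
evidence_weight <- function(q, p, params = scoring_params()) {
  q <- as_protein(q); p <- as_protein(p)
  if (nchar(q$sequence) < params$w || nchar(p$sequence) < params$w) {
    warning("sequence shorter than w = ", params$w, "; evidence weight 0")
    return(0)
  }
  cpp_evidence_weight(encode_seq(q$sequence, params$matrix),
                      encode_seq(p$sequence, params$matrix),
                      params$matrix, params$w, params$tau, params$merge_gap)
}

# Evidence weights of one query against a set of encoded db sequences.
# enc: list of integer vectors (NULL for unresolvable/short); returns numeric.
ev_vector <- function(qenc, enc, params) {
  vapply(enc, function(e) {
    if (is.null(e) || length(e) < params$w) return(0)
    cpp_evidence_weight(qenc, e, params$matrix, params$w, params$tau,
                        params$merge_gap)
  }, numeric(1))
}

# Encode registry sequences named by the ids in `ids`; unresolvable ids get
# NULL and are counted.
encode_registry <- function(ids, registry, params) {
  reg <- as_registry(registry)
  enc <- setNames(vector("list", length(ids)), ids)
  n_missing <- 0L
  for (i in seq_along(ids)) {
    s <- reg[[ids[i]]]
    if (is.null(s) || is.na(s)) n_missing <- n_missing + 1L
    else enc[[i]] <- encode_seq(s, params$matrix)
  }
  if (n_missing > 0L)
    message(n_missing, " database protein id(s) not resolvable in the ",
            "registry; their records contribute no evidence")
  enc
}

#' Score one query pair against the interaction database
#'
#' The pair score is the sum over unordered database records \{P1, P2\} of
#' `ev(Q1,P1)*ev(Q2,P2) + ev(Q1,P2)*ev(Q2,P1)`, where `ev` is
#' [evidence_weight()]; self-records (P, P) contribute `ev(Q1,P)*ev(Q2,P)`
#' once. The score is a raw, unbounded evidence sum — it is never converted
#' to a probability, and rank on the one-to-all curve is the primary
#' readout. Symmetric in (Q1, Q2); zero iff no record contributes.
#'
#' @param q1,q2 Protein records.
#' @param db An [interaction_db].
#' @param registry Protein records (or named character vector) resolving the
#'   database protein ids; unresolvable ids are skipped with a message.
#' @param params A [scoring_params()]. With `exclude_query_pair = TRUE`, a
#'   database record equal to \{q1, q2\} (by id) is skipped.
#' @return A list of class `pair_score`: `q1_id`, `q2_id`, `score`,
#'   `n_supporting_pairs`.
#' @export
score_pair <- function(q1, q2, db, registry, params = scoring_params()) {
  q1 <- as_protein(q1); q2 <- as_protein(q2)
  recs <- db$records
  if (nrow(recs) > 0L && length(as_registry(registry)) == 0L)
    stop("empty registry with a non-empty interaction database")
  if (params$exclude_query_pair && nrow(recs) > 0L) {
    qa <- min(q1$id, q2$id); qb <- max(q1$id, q2$id)
    recs <- recs[!(recs$id_a == qa & recs$id_b == qb), , drop = FALSE]
  }
  if (nrow(recs) == 0L)
    return(structure(list(q1_id = q1$id, q2_id = q2$id, score = 0,
                          n_supporting_pairs = 0L), class = "pair_score"))
  ids <- unique(c(recs$id_a, recs$id_b))
  enc <- encode_registry(ids, registry, params)
  e1 <- ev_vector(encode_seq(q1$sequence, params$matrix), enc, params)
  e2 <- ev_vector(encode_seq(q2$sequence, params$matrix), enc, params)
  contrib <- ifelse(recs$id_a == recs$id_b,
                    e1[recs$id_a] * e2[recs$id_a],
                    e1[recs$id_a] * e2[recs$id_b] +
                      e1[recs$id_b] * e2[recs$id_a])
  structure(list(q1_id = q1$id, q2_id = q2$id, score = sum(contrib),
                 n_supporting_pairs = sum(contrib > 0)),
            class = "pair_score")
}

#' Score one peptide against every protein in a proteome
#'
#' Equivalent to calling [score_pair()] for the peptide against each
#' proteome protein, but evidence weights are computed once per database
#' protein and records that cannot contribute (both sides have zero
#' peptide-side evidence) are pruned before the per-target loop — results
#' are identical to the naive per-pair loop.
#'
#' @param q The query peptide (protein record).
#' @param proteome `protein_records` to score against.
#' @param db An [interaction_db].
#' @param registry Resolves database protein ids to sequences.
#' @param params A [scoring_params()].
#' @return Data frame with columns `query_id`, `protein_id`, `score`,
#'   `n_supporting_pairs`, one row per proteome protein (input order).
#' @export
score_one_vs_all <- function(q, proteome, db, registry,
                             params = scoring_params()) {
  q <- as_protein(q)
  if (nrow(proteome) == 0L) stop("empty proteome")
  recs <- db$records
  if (params$exclude_query_pair && nrow(recs) > 0L) {
    # exclusion is per-target; handled below by masking the matching record
    qid <- q$id
  }
  empty <- data.frame(query_id = character(), protein_id = character(),
                      score = numeric(), n_supporting_pairs = integer())
  if (nrow(recs) == 0L)
    return(rbind(empty, data.frame(query_id = q$id,
                                   protein_id = proteome$id, score = 0,
                                   n_supporting_pairs = 0L)))
  ids <- unique(c(recs$id_a, recs$id_b))
  enc <- encode_registry(ids, registry, params)
  eq <- ev_vector(encode_seq(q$sequence, params$matrix), enc, params)
  # locality: a record contributes only if the peptide has evidence on at
  # least one side
  active <- eq[recs$id_a] > 0 | eq[recs$id_b] > 0
  arecs <- recs[active, , drop = FALSE]
  aids <- unique(c(arecs$id_a, arecs$id_b))
  qmat <- params$matrix
  rows <- vector("list", nrow(proteome))
  for (t in seq_len(nrow(proteome))) {
    tid <- proteome$id[t]
    trecs <- arecs
    if (params$exclude_query_pair && nrow(trecs) > 0L) {
      qa <- min(q$id, tid); qb <- max(q$id, tid)
      trecs <- trecs[!(trecs$id_a == qa & trecs$id_b == qb), , drop = FALSE]
    }
    if (nrow(trecs) == 0L) {
      rows[[t]] <- data.frame(query_id = q$id, protein_id = tid, score = 0,
                              n_supporting_pairs = 0L)
      next
    }
    et <- ev_vector(encode_seq(proteome$sequence[t], qmat), enc[aids], params)
    contrib <- ifelse(trecs$id_a == trecs$id_b,
                      eq[trecs$id_a] * et[trecs$id_a],
                      eq[trecs$id_a] * et[trecs$id_b] +
                        eq[trecs$id_b] * et[trecs$id_a])
    rows[[t]] <- data.frame(query_id = q$id, protein_id = tid,
                            score = sum(contrib),
                            n_supporting_pairs = sum(contrib > 0))
  }
  do.call(rbind, rows)
}

#' Write a score table to TSV
#'
#' @param scores Data frame from [score_one_vs_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
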