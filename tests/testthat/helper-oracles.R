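# Independent, deliberately naive reference implementations used to verify
# the package's fast paths. None of these call the package's C++ kernels.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_prot <- function(id, len) {
  protein_records(id, paste(sample(AA, len, replace = TRUE), collapse = ""))
}

# window score by direct per-position matrix lookup
o_win <- function(a, b, m) {
  sum(m[cbind(strsplit(a, "")[[1]], strsplit(b, "")[[1]])])
}

# exhaustive double loop over all window-start pairs (1-based starts)
oracle_window_hits <- function(qs, ps, m, w, tau) {
  nq <- nchar(qs) - w + 1; np <- nchar(ps) - w + 1
  qv <- strsplit(qs, "")[[1]]; pv <- strsplit(ps, "")[[1]]
  qwin <- lapply(seq_len(nq), function(i) qv[i:(i + w - 1)])
  pwin <- lapply(seq_len(np), function(j) pv[j:(j + w - 1)])
  sq <- vapply(qwin, function(x) sum(m[cbind(x, x)]), numeric(1))
  sp <- vapply(pwin, function(x) sum(m[cbind(x, x)]), numeric(1))
  rows <- list()
  for (i in seq_len(nq)) {
    for (j in seq_len(np)) {
      lo <- min(sq[i], sp[j])
      s <- sum(m[cbind(qwin[[i]], pwin[[j]])])
      if (lo > 0 && s >= tau * lo)
        rows[[length(rows) + 1]] <- data.frame(
          q_start = i, p_start = j, sim = s, norm = s / lo)
    }
  }
  if (length(rows) == 0)
    return(data.frame(q_start = integer(), p_start = integer(),
                      sim = numeric(), norm = numeric()))
  do.call(rbind, rows)
}

# interval-union merging per diagonal; returns total evidence weight
oracle_evidence <- function(qs, ps, m, w, tau, merge_gap = 0) {
  h <- oracle_window_hits(qs, ps, m, w, tau)
  if (nrow(h) == 0) return(0)
  h$diag <- h$p_start - h$q_start
  total <- 0
  for (d in unique(h$diag)) {
    hd <- h[h$diag == d, ]
    hd <- hd[order(hd$q_start), ]
    end <- hd$q_start[1] + w - 1
    wt <- hd$norm[1]
    for (k in seq_len(nrow(hd))[-1]) {
      if (hd$q_start[k] <= end + 1 + merge_gap) {
        end <- max(end, hd$q_start[k] + w - 1)
        wt <- max(wt, hd$norm[k])
      } else {
        total <- total + wt
        end <- hd$q_start[k] + w - 1
        wt <- hd$norm[k]
      }
    }
    total <- total + wt
  }
  total
}

# exhaustive pair score: every db record, both orientations
oracle_score_pair <- function(s1, s2, records, reg, m, w, tau) {
  ev <- function(a, b) oracle_evidence(a, b, m, w, tau)
  total <- 0
  for (k in seq_len(nrow(records))) {
    pa <- reg[[records$id_a[k]]]; pb <- reg[[records$id_b[k]]]
    if (is.null(pa) || is.null(pb)) next
    total <- total +
      if (records$id_a[k] == records$id_b[k]) ev(s1, pa) * ev(s2, pa)
      else ev(s1, pa) * ev(s2, pb) + ev(s1, pb) * ev(s2, pa)
  }
  total
}

# Biostrings local alignment as the alignment oracle (same gap convention)
oracle_sw_score <- function(a, b, mname = "BLOSUM62", go = 11, ge = 1) {
  e <- new.env()
  utils::data(list = mname, package = "Biostrings", envir = e)
  Biostrings::pairwiseAlignment(
    a, b, substitutionMatrix = get(mname, envir = e),
    gapOpening = go, gapExtension = ge, type = "local",
    scoreOnly = TRUE)
}

# exact two-sided rank-sum p by enumeration of all C(n+m, n) labelings
oracle_ranksum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  labs <- utils::combn(n + m, n)
  us <- apply(labs, 2, function(ix) sum(r[ix]) - n * (n + 1) / 2)
  mu <- n * m / 2
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# small fixed test world: registry + db used across scorer tests
make_world <- function(n_prot = 6, len = c(30, 60), n_rec = 5, seed = 42) {
  set.seed(seed)
  ids <- sprintf("P%02d", seq_len(n_prot))
  seqs <- vapply(ids, function(i)
    paste(sample(AA, sample(seq(len[1], len[2]), 1), replace = TRUE),
          collapse = ""), "")
  pairs <- t(replicate(n_rec, sort(sample(ids, 2))))
  recs <- unique(data.frame(id_a = pairs[, 1], id_b = pairs[, 2],
                            stringsAsFactors = FALSE))
  list(registry = protein_records(ids, seqs),
       reg_list = as.list(setNames(seqs, ids)),
       db = interaction_db(recs, provenance = "test world"))
}
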