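#' Build a one-to-all curve
#'
#' Scores the peptide against every protein in `proteome` (plus any
#' `extras`, e.g. a known off-surface target added to every screen) and
#' orders the scores non-increasingly. Tied scores all receive the worst
#' (largest) rank of their tied block — the conservative choice when
#' claiming that a target ranks highly. Within a tied block, entries are
#' ordered by protein id so the curve is fully deterministic.
#'
#' @param peptide A protein record.
#' @param proteome `protein_records`; the screening universe (non-empty).
#' @param extras Optional additional `protein_records` appended to the
#'   universe; ids must not clash with the proteome.
#' @param db An [interaction_db].
#' @param registry Resolves database protein ids to sequences.
#' @param params A [scoring_params()].
#' @return A list of class `one_to_all_curve`: `peptide_id`, `entries`
#'   (data frame `protein_id`, `score`, `rank`, sorted by non-increasing
#'   score) and `proteome_size` (the curve length).
#' @export
build_curve <- function(peptide, proteome, extras = NULL, db, registry,
                        params = scoring_params()) {
  if (is.null(proteome) || nrow(proteome) == 0L) stop("empty proteome")
  universe <- if (!is.null(extras) && nrow(extras) > 0L)
    rbind(proteome[, c("id", "sequence")], extras[, c("id", "sequence")])
  else proteome[, c("id", "sequence")]
  if (anyDuplicated(universe$id))
    stop("proteome and extras ids must be unique")
  sc <- score_one_vs_all(peptide, universe, db, registry, params)
  o <- order(-sc$score, sc$protein_id)
  entries <- data.frame(protein_id = sc$protein_id[o], score = sc$score[o])
  entries$rank <- rank(-entries$score, ties.method = "max")
  rownames(entries) <- NULL
  structure(list(peptide_id = as_protein(peptide)$id, entries = entries,
                 proteome_size = nrow(entries)),
            class = "one_to_all_curve")
}

#' @export
print.one_to_all_curve <- function(x, ...) {
  cat(sprintf("one-to-all curve for '%s' over %d proteins; top score %.4g\n",
              x$peptide_id, x$proteome_size, x$entries$score[1]))
  invisible(x)
}

#' Rank of a target on a one-to-all curve
#'
#' Under the worst-rank tie policy: 1 + (number of entries scoring strictly
#' higher) + (number of entries tied with the target, excluding itself).
#'
#' @param curve A [one_to_all_curve][build_curve].
#' @param target_id Protein id present on the curve.
#' @return Integer rank in `[1, proteome_size]`.
#' @export
rank_of <- function(curve, target_id) {
  i <- match(target_id, curve$entries$protein_id)
  if (is.na(i)) stop("target '", target_id, "' not on the curve")
  curve$entries$rank[i]
}

#' Does the target rank in the top fraction of the curve?
#'
#' The cutoff is `ceiling(fraction * proteome_size)`; e.g. rank 29 of
#' 2,886 proteins is inside the top 1% (cutoff 29) and rank 30 is not.
#'
#' @inheritParams rank_of
#' @param fraction Fraction in (0, 1]; default 0.01.
#' @return Logical scalar.
#' @export
in_top_fraction <- function(curve, target_id, fraction = 0.01) {
  if (!(fraction > 0 && fraction <= 1)) stop("`fraction` must be in (0, 1]")
  rank_of(curve, target_id) <= ceiling(fraction * curve$proteome_size)
}

#' Detect the elbow of a one-to-all curve
#'
#' Returns the rank position maximizing the perpendicular distance from the
#' point (rank, score) to the chord joining the first and last curve
#' points. Ranks and scores are min-max normalized before the geometry, so
#' the result is invariant to affine rescaling of the (unbounded) scores.
#' Ties break toward the smaller rank; flat curves return 1.
#'
#' @param curve A [one_to_all_curve][build_curve] with at least 3 entries.
#' @return Integer elbow position (index into the sorted curve).
#' @export
detect_elbow <- function(curve) {
  s <- curve$entries$score
  n <- length(s)
  if (n < 3L) stop("elbow detection needs a curve of length >= 3")
  if (s[1] == s[n]) return(1L)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[n]) / (s[1] - s[n])
  # chord from (0, 1) to (1, 0); distance proportional to |x + y - 1|
  which.max(abs(x + y - 1))
}

#' Classify the morphology of a one-to-all curve
#'
#' Operationalizes the three qualitative curve shapes: `no_interaction`
#' (flat baseline, targets not above it), `non_specific` (many proteins
#' above the elbow) and `specific` (a target above the elbow among few
#' high scorers). The numeric thresholds are explicit operational choices,
#' exposed as arguments and echoed in the result.
#'
#' @param curve A [one_to_all_curve][build_curve].
#' @param target_ids Character vector of intended target ids on the curve.
#' @param spec_max Maximum number of above-elbow proteins compatible with a
#'   "specific" call; default 10.
#' @param nonspec_frac Fraction of the curve above the elbow beyond which
#'   the interaction is called non-specific; default 0.05.
#' @return A list of class `morphology_call`: `label`, `elbow_rank` (rank
#'   of the entry at the elbow position), `n_above_elbow` (entries with
#'   rank < elbow_rank), `spec_max`, `nonspec_frac`.
#' @export
classify_morphology <- function(curve, target_ids, spec_max = 10L,
                                nonspec_frac = 0.05) {
  if (spec_max <= 0 || nonspec_frac <= 0) stop("thresholds must be positive")
  s <- curve$entries$score
  n <- curve$proteome_size
  ek <- detect_elbow(curve)
  elbow_rank <- curve$entries$rank[ek]
  n_above <- sum(curve$entries$rank < elbow_rank)
  tr <- vapply(target_ids, function(t) rank_of(curve, t), integer(1))
  ts <- s[match(target_ids, curve$entries$protein_id)]
  label <- if (s[1] == s[n]) "no_interaction"
  else if (n_above > nonspec_frac * n) "non_specific"
  else if (any(tr < elbow_rank) && n_above <= spec_max) "specific"
  else if (any(tr < elbow_rank)) "non_specific"
  else "no_interaction"
  structure(list(label = label, elbow_rank = elbow_rank,
                 n_above_elbow = n_above, spec_max = spec_max,
                 nonspec_frac = nonspec_frac),
            class = "morphology_call")
}

#' Glycine mutational scan of a peptide
#'
#' Rebuilds the one-to-all curve for every single-position glycine mutant
#' of the peptide (glycine positions are skipped) and reports the change in
#' the target's score and rank relative to the unmutated curve. Near a flat
#' zero baseline, small score changes can produce very large rank changes —
#' an artifact of rank, not of the scan.
#'
#' @inheritParams build_curve
#' @param target_id Protein id of the intended target; must be on the
#'   curve.
#' @return Data frame with one row per non-glycine position: `position`
#'   (1-based), `original_aa`, `score`, `rank` (mutant curve), `delta_score`,
#'   `delta_rank` (mutant minus original) and `abs_delta_rank`.
#' @export
glycine_scan <- function(peptide, target_id, proteome, extras = NULL, db,
                         registry, params = scoring_params()) {
  pep <- as_protein(peptide)
  base <- build_curve(pep, proteome, extras, db, registry, params)
  if (!target_id %in% base$entries$protein_id)
    stop("target '", target_id, "' absent from proteome and extras")
  s0 <- base$entries$score[match(target_id, base$entries$protein_id)]
  r0 <- rank_of(base, target_id)
  aas <- strsplit(pep$sequence, "")[[1]]
  pos <- which(aas != "G")
  rows <- lapply(pos, function(i) {
    mut <- aas; mut[i] <- "G"
    mrec <- list(id = pep$id, sequence = paste(mut, collapse = ""))
    cur <- build_curve(mrec, proteome, extras, db, registry, params)
    s1 <- cur$entries$score[match(target_id, cur$entries$protein_id)]
    r1 <- rank_of(cur, target_id)
    data.frame(position = i, original_aa = aas[i], score = s1, rank = r1,
               delta_score = s1 - s0, delta_rank = r1 - r0,
               abs_delta_rank = abs(r1 - r0))
  })
  if (length(rows) == 0L)
    return(data.frame(position = integer(), original_aa = character(),
                      score = numeric(), rank = integer(),
                      delta_score = numeric(), delta_rank = integer(),
                      abs_delta_rank = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a one-to-all curve to TSV
#'
#' Columns: `rank`, `protein_id`, `score`, `is_target`, `above_elbow`.
#'
#' @param curve A [one_to_all_curve][build_curve].
#' @param path Output path.
#' @param target_ids Ids flagged in the `is_target` column.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, target_ids = character()) {
  ek <- if (curve$proteome_size >= 3L) detect_elbow(curve) else 1L
  elbow_rank <- curve$entries$rank[ek]
  out <- data.frame(rank = curve$entries$rank,
                    protein_id = curve$entries$protein_id,
                    score = curve$entries$score,
                    is_target = curve$entries$protein_id %in% target_ids,
                    above_elbow = curve$entries$rank < elbow_rank)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a one-to-all curve
#'
#' Score against rank, targets highlighted. Requires ggplot2.
#'
#' @inheritParams write_curve
#' @return A ggplot object.
#' @export
plot_curve <- function(curve, target_ids = character()) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  d <- curve$entries
  d$position <- seq_len(nrow(d))
  d$is_target <- d$protein_id %in% target_ids
  ggplot2::ggplot(d, ggplot2::aes(x = position, y = score)) +
    ggplot2::geom_point(ggplot2::aes(colour = is_target),
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "Rank", y = "Interaction score",
                  title = paste("One-to-all curve:", curve$peptide_id)) +
    ggplot2::theme_minimal()
}
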