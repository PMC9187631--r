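#' Summarize screening outcomes across peptide-target pairs
#'
#' Aggregates per-pair one-to-all outcomes into per-scenario summaries:
#' the median target rank (lower-median convention for even counts — ranks
#' are integers, an interpolated median would be misleading) and the count
#' of pairs ranking inside the top fraction of their curve.
#'
#' @param per_pair Data frame with columns `peptide_id`, `target_id`,
#'   `scenario`, `rank`, `proteome_size`; an `in_top_1pct` logical column is
#'   recomputed from `rank` and `proteome_size` when absent.
#' @param fraction Top-fraction cutoff; default 0.01.
#' @return A list of class `evaluation_report`: `per_pair` (with
#'   `in_top_1pct` filled in), `median_rank` and `top_1pct_count` (named by
#'   scenario), and `comparisons` (empty data frame; see
#'   [compare_scenarios()]).
#' @export
summarize_screen <- function(per_pair, fraction = 0.01) {
  if (is.null(per_pair) || nrow(per_pair) == 0L) stop("empty results")
  need <- c("peptide_id", "target_id", "scenario", "rank", "proteome_size")
  if (!all(need %in% names(per_pair)))
    stop("per_pair requires columns: ", paste(need, collapse = ", "))
  per_pair$in_top_1pct <-
    per_pair$rank <= ceiling(fraction * per_pair$proteome_size)
  sc <- split(per_pair, per_pair$scenario)
  structure(list(
    per_pair = per_pair,
    median_rank = vapply(sc, function(d) lower_median(d$rank), numeric(1)),
    top_1pct_count = vapply(sc, function(d) sum(d$in_top_1pct), integer(1)),
    comparisons = data.frame(group_a = character(), group_b = character(),
                             n_a = integer(), n_b = integer(),
                             statistic = numeric(), p_value = numeric(),
                             mode = character())
  ), class = "evaluation_report")
}

# lower median: for even n, the n/2-th order statistic
lower_median <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

#' Compare rank distributions between two scenarios or predictors
#'
#' Appends a Wilcoxon rank-sum comparison row to an evaluation report.
#'
#' @param report An [evaluation_report][summarize_screen].
#' @param group_a,group_b Scenario labels present in `report$per_pair`.
#' @param mode Passed to [rank_sum_test()].
#' @return The report with one more `comparisons` row.
#' @export
compare_scenarios <- function(report, group_a, group_b, mode = "auto") {
  pa <- report$per_pair$rank[report$per_pair$scenario == group_a]
  pb <- report$per_pair$rank[report$per_pair$scenario == group_b]
  t <- rank_sum_test(pa, pb, mode = mode)
  report$comparisons <- rbind(report$comparisons, data.frame(
    group_a = group_a, group_b = group_b, n_a = length(pa),
    n_b = length(pb), statistic = t$statistic, p_value = t$p_value,
    mode = t$mode))
  report
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' The statistic is the Mann-Whitney U of the first sample, computed from
#' midranks. `mode = "exact"` uses the exact null distribution (ties not
#' supported there); `"normal_approx"` uses the normal approximation with
#' tie correction and continuity correction; `"auto"` picks exact when
#' `n + m <= 12` and there are no ties.
#'
#' @param x,y Non-empty numeric samples (e.g. target ranks per scenario).
#' @param mode `"exact"`, `"normal_approx"` or `"auto"`.
#' @return A list: `statistic` (U of `x`), `p_value` (two-sided, in
#'   `[0, 1]`) and `mode` (the mode actually used).
#' @export
rank_sum_test <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  n <- length(x); m <- length(y)
  all_ranks <- rank(c(x, y))  # midranks
  U <- sum(all_ranks[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (mode == "auto") mode <- if (n + m <= 12L && !ties) "exact"
  else "normal_approx"
  if (mode == "exact") {
    if (ties) stop("exact mode does not support ties")
    p <- 2 * min(pwilcox(U, n, m), 1 - pwilcox(U - 1, n, m))
  } else {
    tab <- table(c(x, y))
    N <- n + m
    mu <- n * m / 2
    sig2 <- n * m / 12 * ((N + 1) - sum(tab^3 - tab) / (N * (N - 1)))
    if (sig2 <= 0) return(list(statistic = U, p_value = 1, mode = mode))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
  }
  list(statistic = U, p_value = min(1, p), mode = mode)
}

#' Write an evaluation report
#'
#' Emits `per_pair.tsv`, `comparisons.tsv` and `summary.json` into a
#' directory.
#'
#' @param report An [evaluation_report][summarize_screen].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$per_pair, file.path(dir, "per_pair.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$comparisons, file.path(dir, "comparisons.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(median_rank = as.list(report$median_rank),
         top_1pct_count = as.list(report$top_1pct_count)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
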