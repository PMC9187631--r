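pm <- sub_matrix("PAM120")

# tiny planted benchmark shared by several blocks
small_bench <- function(seed = 5, mu = 0) {
  generate_benchmark(synthetic_params(
    n_proteome = 25, n_db_proteins = 8, n_decoy_interactions = 10,
    protein_length_range = c(60, 120), core_length = 30,
    mutation_rate = mu, seed = seed))
}

test_that("curve construction: ties, extras, and planted-target recovery", {
  params <- scoring_params(matrix = pm)
  b <- small_bench()
  # empty database: total tie, every rank equals the proteome size
  cur0 <- build_curve(b$peptide, b$proteome, NULL, interaction_db(NULL),
                      b$registry, params)
  expect_true(all(cur0$entries$rank == cur0$proteome_size))

  cur <- build_curve(b$peptide, b$proteome, NULL, b$db_optimistic,
                     b$registry, params)
  expect_equal(rank_of(cur, b$target_id), 1L)
  # the receptor's evidence comes from the planted pair; decoys are zero
  expect_equal(sum(cur$entries$score > 0), 1L)

  extra <- protein_records("THRM", b$registry$sequence[1])
  cur2 <- build_curve(b$peptide, b$proteome, extra, b$db_optimistic,
                      b$registry, params)
  expect_equal(cur2$proteome_size, nrow(b$proteome) + 1L)
  expect_error(build_curve(b$peptide, b$proteome,
                           protein_records("RCPT", "ACDEF"),
                           b$db_optimistic, b$registry, params), "unique")
  expect_error(build_curve(b$peptide, b$proteome[0, ], NULL,
                           b$db_optimistic, b$registry, params), "empty")
})

test_that("rank_of follows the worst-rank tie policy and a counting oracle", {
  mk <- function(scores) {
    ids <- sprintf("p%02d", seq_along(scores))
    o <- order(-scores, ids)
    e <- data.frame(protein_id = ids[o], score = scores[o])
    e$rank <- rank(-e$score, ties.method = "max")
    structure(list(peptide_id = "q", entries = e,
                   proteome_size = length(scores)),
              class = "one_to_all_curve")
  }
  cur <- mk(c(10, 5, 5, 5, 1))
  expect_equal(rank_of(cur, "p01"), 1L)
  expect_equal(rank_of(cur, "p03"), 4L)  # tied with 2 others: rank k+1 = 4
  expect_error(rank_of(cur, "nope"), "not on the curve")

  set.seed(61)
  for (rep in 1:10) {
    scores <- sample(0:5, 30, replace = TRUE)
    cur <- mk(scores)
    for (t in sample(cur$entries$protein_id, 5)) {
      s <- cur$entries$score[match(t, cur$entries$protein_id)]
      want <- 1 + sum(cur$entries$score > s) +
        sum(cur$entries$score == s) - 1
      expect_equal(rank_of(cur, t), want)
    }
    # ranks consistent with scores
    expect_true(all(diff(cur$entries$score) <= 0))
    expect_true(all(diff(cur$entries$rank) >= 0))
  }
})

test_that("top-fraction membership uses the ceiling cutoff and is monotone", {
  mk_rank <- function(r, n) {
    e <- data.frame(protein_id = c("t", sprintf("x%04d", seq_len(n - 1))),
                    score = 0, rank = c(r, rep(n, n - 1)))
    structure(list(peptide_id = "q", entries = e, proteome_size = n),
              class = "one_to_all_curve")
  }
  expect_true(in_top_fraction(mk_rank(1, 50), "t", 0.01))
  expect_true(in_top_fraction(mk_rank(29, 2886), "t", 0.01))   # cutoff 29
  expect_false(in_top_fraction(mk_rank(30, 2886), "t", 0.01))
  for (f in c(0.02, 0.05, 0.2, 1))
    expect_true(in_top_fraction(mk_rank(29, 2886), "t", f))
  expect_error(in_top_fraction(mk_rank(1, 10), "t", 0), "fraction")
})

test_that("elbow detection: hand geometry, flat and linear degenerate cases", {
  mk <- function(scores) {
    e <- data.frame(protein_id = sprintf("p%d", seq_along(scores)),
                    score = scores)
    e$rank <- rank(-e$score, ties.method = "max")
    structure(list(peptide_id = "q", entries = e,
                   proteome_size = length(scores)),
              class = "one_to_all_curve")
  }
  expect_equal(detect_elbow(mk(c(10, 0, 0, 0, 0))), 2L)
  expect_equal(detect_elbow(mk(rep(3, 6))), 1L)
  expect_equal(detect_elbow(mk(c(10, 8, 6, 4, 2, 0))), 1L)
  # invariance under affine rescaling of scores
  s <- c(50, 20, 5, 4, 3, 2, 1, 0)
  expect_equal(detect_elbow(mk(s)), detect_elbow(mk(7 * s + 100)))
})

test_that("morphology classification covers the three curve shapes", {
  mk <- function(scores, ids = sprintf("p%d", seq_along(scores))) {
    o <- order(-scores, ids)
    e <- data.frame(protein_id = ids[o], score = scores[o])
    e$rank <- rank(-e$score, ties.method = "max")
    structure(list(peptide_id = "q", entries = e,
                   proteome_size = length(scores)),
              class = "one_to_all_curve")
  }
  expect_equal(classify_morphology(mk(rep(0, 20)), "p1")$label,
               "no_interaction")
  spec <- mk(c(100, rep(0, 49)))
  expect_equal(classify_morphology(spec, "p1")$label, "specific")
  # 40% of a 500-protein curve above the elbow: non-specific
  ns <- mk(c(seq(500, 301, length.out = 200), rep(0, 300)))
  call <- classify_morphology(ns, "p1")
  expect_equal(call$label, "non_specific")
  expect_gt(call$n_above_elbow, 0.05 * 500)
  # target stuck on the baseline of an otherwise specific curve
  base <- mk(c(100, rep(0, 49)))
  expect_equal(classify_morphology(base, "p50")$label, "no_interaction")
})

test_that("glycine scan counts positions, skips Gly, restores bit-for-bit", {
  params <- scoring_params(matrix = pm)
  b <- small_bench(seed = 9)
  allg <- protein_records("g", paste(rep("G", 30), collapse = ""))
  expect_equal(nrow(glycine_scan(allg, b$target_id, b$proteome, NULL,
                                 b$db_optimistic, b$registry, params)), 0L)

  scan <- glycine_scan(b$peptide, b$target_id, b$proteome, NULL,
                       b$db_optimistic, b$registry, params)
  ng <- sum(strsplit(b$peptide$sequence, "")[[1]] != "G")
  expect_equal(nrow(scan), ng)
  expect_true(all(scan$original_aa != "G"))
  expect_equal(scan$abs_delta_rank, abs(scan$delta_rank))
  # scanning leaves the original curve untouched
  before <- build_curve(b$peptide, b$proteome, NULL, b$db_optimistic,
                        b$registry, params)
  after <- build_curve(b$peptide, b$proteome, NULL, b$db_optimistic,
                       b$registry, params)
  expect_identical(before, after)
  expect_error(glycine_scan(b$peptide, "missing", b$proteome, NULL,
                            b$db_optimistic, b$registry, params), "absent")
})

test_that("near-flat curves turn small score changes into large rank swings", {
  # a regression guard for the rank-artifact regime: target sits on a zero
  # baseline; an epsilon score lifts it from worst rank to rank 1
  mk <- function(tscore) {
    scores <- c(tscore, rep(0, 499))
    ids <- c("t", sprintf("x%03d", 1:499))
    o <- order(-scores, ids)
    e <- data.frame(protein_id = ids[o], score = scores[o])
    e$rank <- rank(-e$score, ties.method = "max")
    structure(list(peptide_id = "q", entries = e, proteome_size = 500),
              class = "one_to_all_curve")
  }
  expect_equal(rank_of(mk(0), "t"), 500L)
  expect_equal(rank_of(mk(1e-9), "t"), 1L)
})

test_that("curve TSV round-trips ranks, targets and elbow annotation", {
  params <- scoring_params(matrix = pm)
  b <- small_bench(seed = 5)
  cur <- build_curve(b$peptide, b$proteome, NULL, b$db_optimistic,
                     b$registry, params)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_curve(cur, f, target_ids = b$target_id)
  tab <- read.delim(f)
  expect_equal(nrow(tab), cur$proteome_size)
  expect_equal(tab$protein_id[tab$is_target], b$target_id)
  expect_equal(tab$rank, cur$entries$rank)
})
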