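pm <- sub_matrix("PAM120")

test_that("hit merging matches interval-union over diagonals", {
  params <- scoring_params(w = 20, tau = 0.75, matrix = pm)
  set.seed(3)
  q <- random_prot("q", 80)
  # single synthetic hit -> single region carrying its normalized weight
  h1 <- data.frame(q_start = 5L, p_start = 11L, sim = 90L, diagonal = 6L)
  r1 <- merge_hits_to_regions(h1, q, q, params)
  expect_equal(nrow(r1), 1L)
  selfs <- vapply(1:(80 - 19), function(i)
    self_score(substr(q$sequence, i, i + 19), pm), numeric(1))
  expect_equal(r1$weight, 90 / min(selfs[5], selfs[11]))

  # same diagonal, overlapping spans -> one region
  h2 <- data.frame(q_start = c(1L, 2L), p_start = c(6L, 7L),
                   sim = c(80L, 85L), diagonal = 5L)
  expect_equal(nrow(merge_hits_to_regions(h2, q, q, params)), 1L)
  # different diagonals never merge
  h3 <- data.frame(q_start = c(1L, 1L), p_start = c(6L, 7L),
                   sim = c(80L, 85L), diagonal = c(5L, 6L))
  expect_equal(nrow(merge_hits_to_regions(h3, q, q, params)), 2L)
})

test_that("evidence weight: identity gives 1, dissimilarity 0, oracle agrees", {
  set.seed(13)
  q <- random_prot("q", 50)
  params <- scoring_params(w = 20, tau = 0.6, matrix = pm)
  expect_equal(evidence_weight(q, q, params), 1.0)

  p2 <- random_prot("p", 50)
  expect_equal(evidence_weight(q, p2, scoring_params(w = 20, tau = 1,
                                                     matrix = pm)),
               oracle_evidence(q$sequence, p2$sequence, pm, 20, 1))

  for (rep in 1:8) {
    a <- random_prot("a", sample(25:55, 1))
    b <- random_prot("b", sample(25:55, 1))
    w <- sample(c(5, 8), 1); tau <- sample(c(0.5, 0.7), 1)
    params <- scoring_params(w = w, tau = tau, matrix = pm)
    expect_equal(evidence_weight(a, b, params),
                 oracle_evidence(a$sequence, b$sequence, pm, w, tau),
                 tolerance = 1e-12)
  }
  expect_warning(
    expect_equal(evidence_weight(random_prot("s", 10), q,
                                 scoring_params(w = 20, matrix = pm)), 0),
    "shorter")
})

test_that("score_pair handles empty evidence, leave-one-out and twins", {
  params <- scoring_params(matrix = pm)
  set.seed(17)
  q1 <- random_prot("Q1", 60); q2 <- random_prot("Q2", 60)
  empty <- interaction_db(NULL)
  s <- score_pair(q1, q2, empty, protein_records("x", "ACDEFGHIKLMNPQRSTVWY"),
                  params)
  expect_equal(s$score, 0)
  expect_equal(s$n_supporting_pairs, 0L)

  db_self <- interaction_db(data.frame(id_a = "Q1", id_b = "Q2"))
  reg <- protein_records(c("Q1", "Q2"), c(q1$sequence, q2$sequence))
  loo <- scoring_params(matrix = pm, exclude_query_pair = TRUE)
  expect_equal(score_pair(q1, q2, db_self, reg, loo)$score, 0)
  # same record with exclusion off scores (two identity sides) = 1
  expect_equal(score_pair(q1, q2, db_self, reg, params)$score, 1.0)

  # twin database pair with distinct ids, identical sequences
  db <- interaction_db(data.frame(id_a = "P1", id_b = "P2"))
  reg2 <- protein_records(c("P1", "P2"), c(q1$sequence, q2$sequence))
  got <- score_pair(q1, q2, db, reg2, params)
  expect_equal(got$score,
               oracle_score_pair(q1$sequence, q2$sequence, db$records,
                                 list(P1 = q1$sequence, P2 = q2$sequence),
                                 pm, params$w, params$tau))
  expect_equal(got$score, 1.0)
  expect_equal(got$n_supporting_pairs, 1L)
})

test_that("score_pair equals the exhaustive oracle on random worlds", {
  set.seed(29)
  params <- scoring_params(w = 8, tau = 0.7, matrix = pm)
  for (rep in 1:6) {
    wd <- make_world(n_prot = 5, len = c(20, 50), n_rec = 4,
                     seed = 100 + rep)
    q1 <- random_prot("QA", sample(20:50, 1))
    q2 <- random_prot("QB", sample(20:50, 1))
    got <- score_pair(q1, q2, wd$db, wd$registry, params)
    want <- oracle_score_pair(q1$sequence, q2$sequence, wd$db$records,
                              wd$reg_list, pm, 8, 0.7)
    expect_equal(got$score, want, tolerance = 1e-9)
    # symmetry and non-negativity
    expect_equal(score_pair(q2, q1, wd$db, wd$registry, params)$score,
                 got$score)
    expect_gte(got$score, 0)
  }
})

test_that("score_pair is monotone under added records and local in evidence", {
  set.seed(41)
  params <- scoring_params(w = 8, tau = 0.7, matrix = pm)
  for (rep in 1:10) {
    wd <- make_world(n_prot = 6, len = c(20, 45), n_rec = 4,
                     seed = 200 + rep)
    q1 <- random_prot("QA", 30); q2 <- random_prot("QB", 30)
    base <- score_pair(q1, q2, wd$db, wd$registry, params)$score
    # add one more record: score never decreases
    ids <- wd$registry$id
    extra <- sort(sample(ids, 2))
    db2 <- interaction_db(rbind(wd$db$records[c("id_a", "id_b")],
                                data.frame(id_a = extra[1],
                                           id_b = extra[2])))
    expect_gte(score_pair(q1, q2, db2, wd$registry, params)$score,
               base - 1e-12)
    # locality: delete every record with no evidence on either query side
    ev1 <- vapply(ids, function(i) evidence_weight(
      q1, wd$registry[wd$registry$id == i, ], params), numeric(1))
    ev2 <- vapply(ids, function(i) evidence_weight(
      q2, wd$registry[wd$registry$id == i, ], params), numeric(1))
    live <- ids[ev1 > 0 | ev2 > 0]
    keep <- wd$db$records$id_a %in% live | wd$db$records$id_b %in% live
    db3 <- interaction_db(wd$db$records[keep, c("id_a", "id_b")])
    expect_equal(score_pair(q1, q2, db3, wd$registry, params)$score, base)
  }
})

test_that("one-vs-all scoring equals the naive per-pair loop bitwise", {
  set.seed(53)
  params <- scoring_params(w = 8, tau = 0.7, matrix = pm)
  wd <- make_world(n_prot = 8, len = c(20, 45), n_rec = 6, seed = 301)
  pep <- random_prot("PEP", 25)
  proteome <- do.call(rbind, lapply(1:12, function(i)
    random_prot(sprintf("T%02d", i), sample(20:45, 1))))
  got <- score_one_vs_all(pep, proteome, wd$db, wd$registry, params)
  expect_equal(got$protein_id, proteome$id)
  for (i in seq_len(nrow(proteome))) {
    naive <- score_pair(pep, proteome[i, ], wd$db, wd$registry, params)
    expect_identical(got$score[i], naive$score)
    expect_equal(got$n_supporting_pairs[i], naive$n_supporting_pairs)
  }
  # empty database: all-zero scores
  z <- score_one_vs_all(pep, proteome, interaction_db(NULL), wd$registry,
                        params)
  expect_true(all(z$score == 0))
  # determinism: bitwise-identical on repeat
  expect_identical(score_one_vs_all(pep, proteome, wd$db, wd$registry,
                                    params), got)
})
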