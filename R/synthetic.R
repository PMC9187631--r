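#' Parameters for the synthetic screening benchmark
#'
#' The generator emulates the statistical structure the screening analysis
#' relies on: a decoy surfaceome of random proteins, a decoy interaction
#' network over a separate pool of database proteins, and one planted
#' endogenous ligand-receptor interaction. The query peptide is a mutated
#' copy of a local core region of the ligand — a peptide analog of an
#' endogenous protein — so in the optimistic scenario the planted record
#' supplies the only systematic evidence linking the peptide to its
#' receptor, while every decoy is evidence-free by construction.
#'
#' @param n_proteome Decoy surfaceome size (includes the receptor);
#'   default 300.
#' @param n_db_proteins Decoy database-protein pool size; default 50.
#' @param n_decoy_interactions Decoy interaction count, drawn uniformly
#'   over distinct db-protein pairs; default 200.
#' @param protein_length_range Length range (min, max) for all generated
#'   proteins; default c(200, 600).
#' @param core_length Planted-core (and peptide) length; default 30.
#'   Should be at least the scorer window length for a meaningful
#'   benchmark (warned otherwise at generation time).
#' @param mutation_rate Per-residue substitution probability applied to the
#'   peptide copy of the core, in `[0, 1)`; default 0.1.
#' @param residue_background Length-20 frequency vector over
#'   [aa_alphabet()]; default uniform (keeps the null analytically
#'   predictable).
#' @param n_confounders Number of additional ligand-like decoys planted in
#'   the database (each carries a copy of the core and one interaction to a
#'   random decoy surfaceome protein) — used to provoke non-specific curve
#'   morphologies; default 0.
#' @param seed Integer seed; one global stream consumed in documented
#'   order (db proteins, ligand, core offset, proteome, decoy network,
#'   peptide mutations, confounders).
#' @return A list of class `synthetic_params`.
#' @export
synthetic_params <- function(n_proteome = 300L, n_db_proteins = 50L,
                             n_decoy_interactions = 200L,
                             protein_length_range = c(200L, 600L),
                             core_length = 30L, mutation_rate = 0.1,
                             residue_background = NULL,
                             n_confounders = 0L, seed = 1L) {
  if (!(mutation_rate >= 0 && mutation_rate < 1))
    stop("`mutation_rate` must be in [0, 1)")
  if (n_proteome < 1L) stop("`n_proteome` must be >= 1")
  if (n_db_proteins < 1L) stop("`n_db_proteins` must be >= 1")
  if (length(protein_length_range) != 2L ||
      protein_length_range[1] > protein_length_range[2] ||
      protein_length_range[1] < 1L)
    stop("`protein_length_range` must be (min, max) with 1 <= min <= max")
  if (core_length < 1L || core_length > protein_length_range[1])
    stop("`core_length` must be in [1, min protein length]")
  maxpairs <- choose(n_db_proteins, 2)
  if (n_decoy_interactions > maxpairs)
    stop("`n_decoy_interactions` exceeds the number of distinct pairs")
  if (is.null(residue_background))
    residue_background <- rep(1 / 20, 20)
  if (length(residue_background) != 20L || any(residue_background < 0))
    stop("`residue_background` must be 20 non-negative frequencies")
  residue_background <- residue_background / sum(residue_background)
  structure(list(n_proteome = as.integer(n_proteome),
                 n_db_proteins = as.integer(n_db_proteins),
                 n_decoy_interactions = as.integer(n_decoy_interactions),
                 protein_length_range = as.integer(protein_length_range),
                 core_length = as.integer(core_length),
                 mutation_rate = mutation_rate,
                 residue_background = residue_background,
                 n_confounders = as.integer(n_confounders),
                 seed = as.integer(seed)),
            class = "synthetic_params")
}

rand_seq <- function(len, bg) {
  paste(sample(.aa_alphabet, len, replace = TRUE, prob = bg), collapse = "")
}

#' Generate a synthetic screening benchmark
#'
#' Fully deterministic given `params$seed` (the caller's RNG state is left
#' untouched). The decoy proteome contains the receptor `RCPT`; the ligand
#' `LIG` is deliberately absent from the proteome (an endogenous, non-
#' surface protein). The optimistic database holds the decoy network plus
#' the planted `(LIG, RCPT)` record; the peptide `PEP` is a copy of a
#' random `core_length` window of the ligand with each position substituted
#' with probability `mutation_rate` (to a background residue other than the
#' original).
#'
#' @param params A [synthetic_params()].
#' @param w Scorer window length used only to warn when
#'   `core_length < w` (such benchmarks carry no plantable signal).
#' @return A list of class `synthetic_benchmark`: `proteome`, `registry`
#'   (all sequences: db proteins, ligand, receptor), `db_optimistic`,
#'   `peptide`, `target_id` (`"RCPT"`), `ligand_id` (`"LIG"`),
#'   `core_offset` (1-based start of the core in the ligand), `params`,
#'   `seed`.
#' @export
generate_benchmark <- function(params = synthetic_params(), w = 20L) {
  if (params$core_length < w)
    warning("core_length < w: the planted signal cannot produce window hits")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(params$seed)
  bg <- params$residue_background
  lr <- params$protein_length_range
  rlen <- function(n) sample(seq(lr[1], lr[2]), n, replace = TRUE)

  db_ids <- sprintf("DBP%04d", seq_len(params$n_db_proteins))
  db_seqs <- vapply(rlen(params$n_db_proteins),
                    function(l) rand_seq(l, bg), "")
  ligand <- rand_seq(rlen(1), bg)
  core_offset <- sample(nchar(ligand) - params$core_length + 1L, 1L)
  core <- substr(ligand, core_offset, core_offset + params$core_length - 1L)

  prot_ids <- c("RCPT", sprintf("SRF%04d", seq_len(params$n_proteome - 1L)))
  prot_seqs <- vapply(rlen(params$n_proteome),
                      function(l) rand_seq(l, bg), "")
  proteome <- protein_records(prot_ids, prot_seqs, validate = "none")

  # decoy network: sample distinct unordered db-protein pairs
  npairs <- choose(params$n_db_proteins, 2)
  picked <- sample(npairs, params$n_decoy_interactions)
  pairidx <- utils::combn(params$n_db_proteins, 2)
  rec <- data.frame(id_a = db_ids[pairidx[1, picked]],
                    id_b = db_ids[pairidx[2, picked]],
                    n_publications = rep(2L, length(picked)),
                    stringsAsFactors = FALSE)
  rec$methods <- rep(list("synthetic-benchmark"), nrow(rec))
  rec <- rbind(rec, data.frame(id_a = "LIG", id_b = "RCPT",
                               n_publications = 2L,
                               methods = I(list("synthetic-benchmark"))))

  # peptide: mutated copy of the ligand core
  aas <- strsplit(core, "")[[1]]
  flip <- runif(length(aas)) < params$mutation_rate
  for (i in which(flip)) {
    others <- setdiff(.aa_alphabet, aas[i])
    p <- bg[match(others, .aa_alphabet)]
    aas[i] <- sample(others, 1L, prob = p / sum(p))
  }
  peptide <- protein_records("PEP", paste(aas, collapse = ""),
                             validate = "none")

  conf_ids <- character(); conf_seqs <- character()
  if (params$n_confounders > 0L) {
    for (k in seq_len(params$n_confounders)) {
      cid <- sprintf("CONF%02d", k)
      cseq <- rand_seq(rlen(1), bg)
      off <- sample(nchar(cseq) - params$core_length + 1L, 1L)
      substr(cseq, off, off + params$core_length - 1L) <- core
      partner <- sample(prot_ids, 1L)
      rec <- rbind(rec, data.frame(id_a = cid, id_b = partner,
                                   n_publications = 2L,
                                   methods = I(list("synthetic-benchmark"))))
      conf_ids <- c(conf_ids, cid); conf_seqs <- c(conf_seqs, cseq)
    }
  }

  registry <- protein_records(
    c(db_ids, "LIG", "RCPT", conf_ids,
      if (params$n_confounders > 0L) prot_ids[-1L] else character()),
    c(db_seqs, ligand, prot_seqs[1], conf_seqs,
      if (params$n_confounders > 0L) prot_seqs[-1L] else character()),
    validate = "none")

  db <- interaction_db(rec, provenance = sprintf("synthetic seed=%d",
                                                 params$seed))
  structure(list(proteome = proteome, registry = registry,
                 db_optimistic = db, peptide = peptide,
                 target_id = "RCPT", ligand_id = "LIG",
                 core_offset = core_offset, params = params,
                 seed = params$seed),
            class = "synthetic_benchmark")
}

#' Derive the pessimistic scenario from a benchmark
#'
#' Runs the leakage filter: aligns the peptide against every protein in the
#' database, then removes all interactions touching the hits. With a small
#' mutation rate and `min_score` below the planted-core alignment score,
#' the ligand is always hit, taking the planted ligand-receptor record (and
#' the receptor's only evidence) with it.
#'
#' @param bench A [synthetic_benchmark][generate_benchmark].
#' @param min_score Alignment-score hit threshold; default 50.
#' @param ... Further arguments to [find_similar_proteins()].
#' @return A `scenario_split` (see [pessimistic_split()]).
#' @export
derive_pessimistic <- function(bench, min_score = 50L, ...) {
  ids <- db_proteins(bench$db_optimistic)
  reg <- bench$registry
  pool <- reg[reg$id %in% ids, , drop = FALSE]
  hits <- find_similar_proteins(bench$peptide, pool,
                                min_score = min_score, ...)
  pessimistic_split(bench$db_optimistic, hits)
}

#' Write a benchmark directory
#'
#' Emits `proteome.fasta`, `registry.fasta`, `peptide.fasta`,
#' `interactions.tsv` and `truth.json` (target id, ligand id, core offset,
#' parameters, seed). Contents are byte-identical across runs with the
#' same parameters.
#'
#' @param bench A [synthetic_benchmark][generate_benchmark].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bench$proteome, file.path(dir, "proteome.fasta"))
  write_fasta(bench$registry, file.path(dir, "registry.fasta"))
  write_fasta(bench$peptide, file.path(dir, "peptide.fasta"))
  write_interactions(bench$db_optimistic, file.path(dir, "interactions.tsv"))
  jsonlite::write_json(
    list(target_id = bench$target_id, ligand_id = bench$ligand_id,
         core_offset = bench$core_offset, seed = bench$seed,
         params = bench$params[setdiff(names(bench$params),
                                       "residue_background")]),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Read a benchmark directory back
#'
#' @param dir A directory written by [write_benchmark()].
#' @return A list with `proteome`, `registry`, `peptide`, `db_optimistic`,
#'   `target_id`, `ligand_id`.
#' @export
read_benchmark <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  list(proteome = read_fasta(file.path(dir, "proteome.fasta"), "none"),
       registry = read_fasta(file.path(dir, "registry.fasta"), "none"),
       peptide = read_fasta(file.path(dir, "peptide.fasta"), "none"),
       db_optimistic = read_interactions(file.path(dir, "interactions.tsv")),
       target_id = truth$target_id, ligand_id = truth$ligand_id)
}
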