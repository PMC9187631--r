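#' Interaction databases
#'
#' The evidence database of known interacting protein pairs. Pairs are
#' unordered and stored once with `id_a <= id_b`; self-pairs are permitted
#' and flagged. Each record carries the number of distinct supporting
#' publications (the proxy for independent reporting groups) and a set of
#' detection-method labels.
#'
#' @param records Data frame with columns `id_a`, `id_b`, and optionally
#'   `n_publications` (default 1) and `methods` (list column of character
#'   vectors, or a character column of `;`-separated labels). Duplicate
#'   unordered pairs are merged by summing publications and unioning
#'   methods.
#' @param provenance Free-text label describing where the records came from.
#' @return A list of class `interaction_db` with elements `records` (the
#'   canonicalized data frame, including a `self_pair` flag), `index`
#'   (named list: protein id -> character vector of partners) and
#'   `provenance`.
#' @export
interaction_db <- function(records = NULL, provenance = "unspecified") {
  if (is.null(records) || nrow(records) == 0L) {
    records <- data.frame(id_a = character(), id_b = character(),
                          n_publications = integer(), self_pair = logical())
    records$methods <- list()
    return(structure(list(records = records, index = list(),
                          provenance = provenance),
                     class = "interaction_db"))
  }
  stopifnot(all(c("id_a", "id_b") %in% names(records)))
  id_a <- as.character(records$id_a)
  id_b <- as.character(records$id_b)
  npub <- if ("n_publications" %in% names(records))
    as.integer(records$n_publications) else rep(1L, length(id_a))
  if (any(npub < 0)) stop("n_publications must be non-negative")
  meth <- if ("methods" %in% names(records)) {
    if (is.list(records$methods)) records$methods
    else strsplit(as.character(records$methods), ";", fixed = TRUE)
  } else rep(list(character()), length(id_a))
  lo <- pmin(id_a, id_b); hi <- pmax(id_a, id_b)
  key <- paste(lo, hi, sep = "\r")
  ukey <- unique(key)
  idx <- split(seq_along(key), factor(key, levels = ukey))
  rec <- data.frame(
    id_a = vapply(idx, function(i) lo[i[1]], ""),
    id_b = vapply(idx, function(i) hi[i[1]], ""),
    n_publications = vapply(idx, function(i) sum(npub[i]), 0L),
    stringsAsFactors = FALSE)
  rec$methods <- lapply(idx, function(i) sort(unique(unlist(meth[i]))))
  rec$self_pair <- rec$id_a == rec$id_b
  rownames(rec) <- NULL
  structure(list(records = rec, index = build_index(rec),
                 provenance = provenance),
            class = "interaction_db")
}

build_index <- function(rec) {
  if (nrow(rec) == 0L) return(list())
  prot <- c(rec$id_a, rec$id_b)
  part <- c(rec$id_b, rec$id_a)
  lapply(split(part, prot), function(x) sort(unique(x)))
}

#' @param db An `interaction_db`.
#' @rdname interaction_db
#' @export
db_size <- function(db) nrow(db$records)

#' @rdname interaction_db
#' @export
db_proteins <- function(db) sort(unique(c(db$records$id_a, db$records$id_b)))

#' Audit an interaction database
#'
#' Verifies the structural invariants: canonical ordering (`id_a <= id_b`),
#' no duplicate unordered pairs, and exact consistency of the
#' partner index with the records. Errors on violation.
#'
#' @param db An [interaction_db].
#' @return `TRUE`, invisibly.
#' @export
db_audit <- function(db) {
  rec <- db$records
  if (any(rec$id_a > rec$id_b)) stop("audit: non-canonical pair ordering")
  if (anyDuplicated(paste(rec$id_a, rec$id_b, sep = "\r")))
    stop("audit: duplicate unordered pairs")
  if (!identical(db$index, build_index(rec)))
    stop("audit: index inconsistent with records")
  invisible(TRUE)
}

#' @export
print.interaction_db <- function(x, ...) {
  cat(sprintf("interaction_db: %d record(s), %d protein(s) [%s]\n",
              db_size(x), length(db_proteins(x)), x$provenance))
  invisible(x)
}

#' Read an interaction database from a tabular file
#'
#' Two dialects are supported. `"simple"` is a TSV with header columns
#' `id_a`, `id_b` and optionally `n_publications` and `methods`
#' (`;`-separated labels). `"biogrid_tab3"` accepts the BioGRID tab3
#' export: pairs come from the official-symbol interactor columns, the
#' experimental-system column supplies method labels, and the number of
#' distinct publication sources per pair becomes `n_publications`.
#'
#' @param path Path to the tabular file. An empty file (header only or zero
#'   bytes) yields an empty database.
#' @param dialect `"simple"` or `"biogrid_tab3"`.
#' @return An [interaction_db].
#' @export
read_interactions <- function(path, dialect = c("simple", "biogrid_tab3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L)
    return(interaction_db(NULL, provenance = basename(path)))
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0L)
    return(interaction_db(NULL, provenance = basename(path)))
  if (dialect == "simple") {
    need <- c("id_a", "id_b")
    if (!all(need %in% names(tab)))
      stop("simple dialect requires columns: ", paste(need, collapse = ", "))
    interaction_db(tab, provenance = basename(path))
  } else {
    ca <- "Official Symbol Interactor A"
    cb <- "Official Symbol Interactor B"
    cm <- "Experimental System"
    cp <- "Publication Source"
    if (!all(c(ca, cb, cm) %in% names(tab)))
      stop("biogrid_tab3 dialect requires columns: ",
           paste(c(ca, cb, cm), collapse = ", "))
    lo <- pmin(tab[[ca]], tab[[cb]]); hi <- pmax(tab[[ca]], tab[[cb]])
    key <- paste(lo, hi, sep = "\r")
    pubs <- if (cp %in% names(tab)) tab[[cp]] else seq_along(key)
    agg <- lapply(split(seq_along(key), key), function(i) {
      list(a = lo[i[1]], b = hi[i[1]],
           n = length(unique(pubs[i])),
           m = sort(unique(tab[[cm]][i])))
    })
    rec <- data.frame(id_a = vapply(agg, `[[`, "", "a"),
                      id_b = vapply(agg, `[[`, "", "b"),
                      n_publications = vapply(agg, `[[`, 0L, "n"),
                      stringsAsFactors = FALSE)
    rec$methods <- lapply(agg, `[[`, "m")
    interaction_db(rec, provenance = paste0("biogrid:", basename(path)))
  }
}

#' Write an interaction database to the simple TSV dialect
#'
#' @param db An [interaction_db].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(db, path) {
  rec <- db$records
  out <- data.frame(id_a = rec$id_a, id_b = rec$id_b,
                    n_publications = rec$n_publications,
                    methods = vapply(rec$methods, paste, "", collapse = ";"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default stringent detection-method labels
#'
#' The quality filter retains only interactions detected with stringent
#' experimental methods. The reference list is a curation choice; this
#' package ships a default set (direct physical-evidence assays) in
#' `inst/extdata/stringent_methods.txt`, which users should review and
#' override for their own database export.
#'
#' @return Character vector of method labels.
#' @export
default_stringent_methods <- function() {
  readLines(system.file("extdata", "stringent_methods.txt",
                        package = "pepscreen"))
}

#' Quality-filter an interaction database
#'
#' Retains records reported by at least `min_publications` distinct
#' publications AND detected with at least one stringent method. Passing an
#' empty or missing stringent set while stringency is enabled is an error —
#' silent vacuous filtering is forbidden; supply
#' [default_stringent_methods()] explicitly or set
#' `require_stringent = FALSE`.
#'
#' @param db An [interaction_db].
#' @param min_publications Minimum distinct publications; default 2
#'   (interactions reported by at least two groups).
#' @param stringent_methods Character vector of acceptable method labels.
#' @param require_stringent Apply the method criterion (default `TRUE`).
#' @return A filtered [interaction_db] with annotated provenance.
#' @export
quality_filter <- function(db, min_publications = 2L,
                           stringent_methods = NULL,
                           require_stringent = TRUE) {
  if (min_publications < 1L) stop("`min_publications` must be >= 1")
  if (require_stringent && length(stringent_methods) == 0L)
    stop("stringency enabled but no stringent methods supplied; pass ",
         "default_stringent_methods() or set require_stringent = FALSE")
  rec <- db$records
  keep <- rec$n_publications >= min_publications
  if (require_stringent)
    keep <- keep & vapply(rec$methods, function(m)
      length(intersect(m, stringent_methods)) > 0L, logical(1))
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(records = out, index = build_index(out),
                 provenance = sprintf(
                   "%s | quality_filter(min_pubs=%d, stringent=%s)",
                   db$provenance, min_publications, require_stringent)),
            class = "interaction_db")
}

#' Curate a therapeutic-peptide table
#'
#' Retains peptides of at least `min_length` residues whose sequences (when
#' supplied) contain only the 20 standard amino acids — the inclusion rule
#' used for assembling an FDA-approved evaluation panel. The length bound
#' is inclusive so a 20-mer such as bivalirudin is retained.
#'
#' @param entries Data frame with columns `compound_name`, `chemical_basis`
#'   (`"Native"` or `"Analog"`), `length`, `target_accessions`
#'   (`;`-separated), and optionally `sequence`.
#' @param min_length Minimum peptide length, inclusive; default 20.
#' @return The retained rows of `entries`.
#' @export
curate_peptides <- function(entries, min_length = 20L) {
  keep <- entries$length >= min_length
  if ("sequence" %in% names(entries)) {
    has <- !is.na(entries$sequence) & nzchar(entries$sequence)
    std <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", toupper(entries$sequence))
    keep <- keep & (!has | std)
  }
  out <- entries[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' The packaged FDA-approved peptide panel
#'
#' @return Data frame mirroring the curated panel of FDA-approved
#'   therapeutic peptides with their molecular targets, chemical basis
#'   (native fragment vs analog), length, and target accession ids.
#' @export
fda_peptide_table <- function() {
  read.delim(system.file("extdata", "fda_peptides.tsv",
                         package = "pepscreen"),
             stringsAsFactors = FALSE)
}

#' Find database proteins similar to a peptide
#'
#' The leakage filter: identifies proteins sharing a region of high local
#' similarity with the peptide, by Smith-Waterman alignment (default
#' BLOSUM62, gaps 11/1 — the blastp-like setting) or from a precomputed
#' external hit file in 12-column tabular alignment format (only the
#' query, subject and bitscore columns are consumed).
#'
#' @param peptide A protein record.
#' @param proteins `protein_records` to scan (non-empty), ignored when
#'   `hits_file` is given.
#' @param min_score Minimum alignment score (or bitscore, for external
#'   files) to call a hit; must be positive. Default 50.
#' @param matrix,gap_open,gap_extend Alignment parameters.
#' @param hits_file Optional path to an external tabular hit file.
#' @return Character vector of hit protein ids (possibly empty).
#' @export
find_similar_proteins <- function(peptide, proteins, min_score = 50L,
                                  matrix = sub_matrix("BLOSUM62"),
                                  gap_open = 11L, gap_extend = 1L,
                                  hits_file = NULL) {
  if (min_score <= 0) stop("`min_score` must be positive")
  if (!is.null(hits_file)) {
    tab <- read.delim(hits_file, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 12L)
      stop("external hit file must be 12-column tabular alignment format")
    return(sort(unique(tab[[2]][tab[[12]] >= min_score])))
  }
  if (nrow(proteins) == 0L) stop("`proteins` must be non-empty")
  pep <- as_protein(peptide)
  hit <- vapply(seq_len(nrow(proteins)), function(i) {
    smith_waterman(pep, list(id = proteins$id[i],
                             sequence = proteins$sequence[i]),
                   matrix = matrix, gap_open = gap_open,
                   gap_extend = gap_extend)$score >= min_score
  }, logical(1))
  sort(proteins$id[hit])
}

#' Split the database into an evidence scenario
#'
#' `pessimistic_split()` removes every record touching a hit protein,
#' emulating the de novo design case where no interactor similar to the
#' peptide is known; `optimistic_split()` keeps the database unchanged
#' (the analog design case).
#'
#' @param db An [interaction_db].
#' @param hits Character vector of protein ids to purge.
#' @return A list of class `scenario_split`: `scenario`
#'   (`"pessimistic"`/`"optimistic"`), `removed_proteins` (hits actually
#'   present in the database) and `retained` (the filtered
#'   [interaction_db]).
#' @export
pessimistic_split <- function(db, hits) {
  hits <- as.character(hits)
  rec <- db$records
  keep <- !(rec$id_a %in% hits | rec$id_b %in% hits)
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  retained <- structure(
    list(records = out, index = build_index(out),
         provenance = sprintf("%s | pessimistic(-): removed %d protein(s)",
                              db$provenance,
                              length(intersect(hits, db_proteins(db))))),
    class = "interaction_db")
  structure(list(scenario = "pessimistic",
                 removed_proteins = intersect(hits, db_proteins(db)),
                 retained = retained),
            class = "scenario_split")
}

#' @rdname pessimistic_split
#' @export
optimistic_split <- function(db) {
  structure(list(scenario = "optimistic", removed_proteins = character(),
                 retained = db),
            class = "scenario_split")
}
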