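#' Substitution matrices
#'
#' A substitution matrix is a symmetric integer matrix over an ordered
#' residue alphabet, carrying a `name` attribute. `sub_matrix()` returns one
#' of the shipped standards (taken from Biostrings' data, restricted to the
#' 20 standard residues); `read_matrix()` parses the conventional square
#' text dialect with `#` comment lines and a header row of residues, as
#' distributed with NCBI BLAST.
#'
#' PAM120 is the default for the similarity scorer; BLOSUM62 (the blastp
#' default) for the leakage-control aligner. "BLOSUM64" occasionally seen in
#' the literature is taken to mean BLOSUM62.
#'
#' @param name One of `"PAM120"`, `"BLOSUM62"`.
#' @return An integer matrix of class `substitution_matrix` with residue
#'   dimnames and a `name` attribute.
#' @examples
#' m <- sub_matrix("BLOSUM62")
#' m["D", "E"]
#' @export
sub_matrix <- function(name = c("PAM120", "BLOSUM62")) {
  name <- match.arg(name)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  m <- get(name, envir = e)[.aa_alphabet, .aa_alphabet]
  substitution_matrix(m, name = name)
}

#' @param scores A square numeric matrix with identical row/column residue
#'   names; validated for symmetry and coerced to integer storage.
#' @rdname sub_matrix
#' @export
substitution_matrix <- function(scores, name = "custom") {
  scores <- as.matrix(scores)
  if (nrow(scores) != ncol(scores) ||
      is.null(rownames(scores)) || is.null(colnames(scores)) ||
      !identical(rownames(scores), colnames(scores)))
    stop("substitution matrix must be square with matching residue dimnames")
  if (any(scores != round(scores))) stop("scores must be integers")
  if (!isSymmetric(unname(scores)))
    stop("substitution matrix must be symmetric")
  storage.mode(scores) <- "integer"
  structure(scores, name = name,
            class = c("substitution_matrix", class(scores)))
}

#' @param path Path to a matrix file in the square text dialect.
#' @rdname sub_matrix
#' @export
read_matrix <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("no matrix content in ", path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  res <- vapply(rows, `[`, "", 1L)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]),
                   numeric(length(header))))
  dimnames(vals) <- list(res, header)
  # restrict to residues present both ways (drops B, Z, X, * columns)
  keep <- intersect(res, header)
  substitution_matrix(vals[keep, keep], name = name)
}

#' Is a substitution matrix diagonally dominant?
#'
#' True when every off-diagonal score is at most the smaller of the two
#' diagonal self-scores, `m[a,b] <= min(m[a,a], m[b,b])`. Under a dominant
#' matrix, normalized window similarities lie in (0, 1]. Holds for the
#' shipped PAM120 and BLOSUM62; recorded, not required.
#'
#' @param m A `substitution_matrix`.
#' @return Logical scalar.
#' @export
is_diagonal_dominant <- function(m) {
  d <- diag(m)
  all(m <= outer(d, d, pmin))
}
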