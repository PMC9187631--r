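#' Construct a set of protein records
#'
#' A protein record is an identifier (no whitespace) plus an amino-acid
#' sequence over the 20 standard one-letter codes. Records are carried as a
#' data frame with columns `id` and `sequence`; every sequence-consuming
#' function in the package accepts this form.
#'
#' @param id Character vector of identifiers; must be non-empty, unique and
#'   contain no whitespace.
#' @param sequence Character vector of amino-acid sequences (upper-cased on
#'   construction).
#' @param validate Alphabet policy: `"reject"` errors on any non-standard
#'   residue, `"drop"` removes the offending records with a warning,
#'   `"none"` skips the check.
#' @return A `protein_records` data frame with columns `id`, `sequence`.
#' @examples
#' protein_records(c("a", "b"), c("PEPTIDE", "ACDEFGHIKLMNPQRSTVWY"))
#' @export
protein_records <- function(id, sequence,
                            validate = c("reject", "drop", "none")) {
  validate <- match.arg(validate)
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence))
    stop("`id` and `sequence` must have the same length")
  if (any(!nzchar(id)) || any(grepl("[[:space:]]", id)))
    stop("identifiers must be non-empty and contain no whitespace")
  if (anyDuplicated(id))
    stop("duplicate identifiers: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!nzchar(sequence))) stop("empty sequence for record(s): ",
                                   paste(id[!nzchar(sequence)], collapse = ", "))
  if (validate != "none") {
    bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", sequence)
    if (any(bad)) {
      if (validate == "reject") {
        first <- which(bad)[1]
        pos <- regexpr("[^ACDEFGHIKLMNPQRSTVWY]", sequence[first])
        stop(sprintf("non-standard residue '%s' at position %d in record '%s'",
                     substr(sequence[first], pos, pos), pos, id[first]))
      }
      warning(sprintf("dropping %d record(s) with non-standard residues: %s",
                      sum(bad), paste(id[bad], collapse = ", ")))
      id <- id[!bad]; sequence <- sequence[!bad]
    }
  }
  structure(data.frame(id = id, sequence = sequence,
                       stringsAsFactors = FALSE),
            class = c("protein_records", "data.frame"))
}

#' @rdname protein_records
#' @export
protein_record <- function(id, sequence, validate = "reject") {
  protein_records(id, sequence, validate = validate)
}

# Normalize any single-protein argument to list(id=, sequence=).
as_protein <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop("expected exactly one protein record")
    list(id = x$id, sequence = x$sequence)
  } else if (is.list(x) && !is.null(x$id) && !is.null(x$sequence)) {
    list(id = x$id, sequence = x$sequence)
  } else stop("cannot interpret object as a protein record")
}

# Named character vector id -> sequence.
as_registry <- function(x) {
  if (is.character(x) && !is.null(names(x))) return(x)
  if (is.data.frame(x)) return(setNames(x$sequence, x$id))
  stop("registry must be protein records or a named character vector")
}

#' Read protein records from a FASTA file
#'
#' Identifiers are the token before the first whitespace in the header;
#' sequences are upper-cased. Duplicate identifiers are rejected.
#'
#' @param path Path to a FASTA file.
#' @param validate Alphabet policy, see [protein_records()]. The default
#'   `"reject"` suits curated peptides; use `"drop"` for bulk proteomes so a
#'   single odd database protein does not abort a screen.
#' @return A `protein_records` data frame.
#' @export
read_fasta <- function(path, validate = c("reject", "drop", "none")) {
  validate <- match.arg(validate)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("[[:space:]].*$", "", names(set))
  protein_records(ids, as.character(set), validate = validate)
}

#' Write protein records to a FASTA file
#'
#' @param records A `protein_records` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

# Encode a sequence as 0-based indices into a matrix alphabet.
encode_seq <- function(sequence, matrix) {
  codes <- match(strsplit(sequence, "")[[1]], rownames(matrix)) - 1L
  if (anyNA(codes))
    stop("sequence contains residues absent from the substitution matrix")
  codes
}
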