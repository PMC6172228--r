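#' Read a gapped, pre-aligned FASTA file
#'
#' Reads fixed-length, AHo-style aligned amino-acid sequences. Gaps are `-`.
#' The alignment itself must be produced externally (e.g. ANARCI with the
#' AHo numbering scheme); this reader only validates it.
#'
#' @param path Path to a FASTA file.
#' @param chain One of `"VH"`, `"VL"`, `"VHVL"`.
#' @param L Alignment length. Defaults to 149 for a single chain and 298
#'   for the combined VHVL alignment.
#' @param species Optional species label attached to every record.
#' @return A tibble with columns `id`, `chain`, `residues`, `species`,
#'   record order preserved.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACDEF-GHIK", ">b", "ACDEFWGHIK"), f)
#' read_aligned_fasta(f, chain = "VH", L = 10)
read_aligned_fasta <- function(path, chain = c("VH", "VL", "VHVL"),
                               L = NULL, species = NA_character_) {
  chain <- match.arg(chain)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(L)) L <- default_chain_length(chain)
  set <- tryCatch(
    Biostrings::readAAStringSet(path, format = "fasta"),
    error = function(e) abort(sprintf("malformed FASTA '%s': %s",
                                      path, conditionMessage(e))))
  if (length(set) == 0) abort(sprintf("no FASTA records in '%s'", path))
  db <- tibble(
    id = names(set),
    chain = chain,
    residues = unname(as.character(set)),
    species = species
  )
  validate_seq_db(db, L = L, chain = chain)
}

#' Write a sequence database as gapped FASTA
#'
#' @param db A validated sequence database tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(db, path) {
  db <- validate_seq_db(db)
  set <- Biostrings::AAStringSet(setNames(db$residues, db$id))
  Biostrings::writeXStringSet(set, filepath = path, format = "fasta")
  invisible(path)
}

#' Hamming distance between two aligned sequences
#'
#' Counts positions at which the two sequences differ. The gap `-` is an
#' ordinary 21st symbol: a gap aligned against an amino acid (or a
#' different gap placement) counts as one mismatch.
#'
#' @param a,b Residue strings (or one-row sequence tibbles) of equal length.
#' @return Integer mismatch count.
#' @export
#' @examples
#' hamming_distance("AC-D", "ACWD")  # 1
hamming_distance <- function(a, b) {
  a <- as_residues(a); b <- as_residues(b)
  if (nchar(a) != nchar(b))
    abort(sprintf("length mismatch: %d vs %d", nchar(a), nchar(b)))
  sa <- strsplit(a, "", fixed = TRUE)[[1]]
  sb <- strsplit(b, "", fixed = TRUE)[[1]]
  sum(sa != sb)
}

# integer state matrix (M x L) for a database; rows follow db order
db_state_matrix <- function(db) {
  t(vapply(db$residues, state_index, integer(nchar(db$residues[1])),
           USE.NAMES = FALSE))
}
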