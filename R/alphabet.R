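# Fixed residue alphabet. One-hot blocks use the 20 amino acids in
# alphabetical one-letter order; the gap '-' is the 21st categorical state
# and carries no bit (all-zero block), so N = 20 * L exactly.

#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard amino acids in alphabetical one-letter-code order. This
#' ordering defines the layout of one-hot encodings and is serialized with
#' every fitted model.
#'
#' @format Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

.AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.GAP <- "-"
.STATES <- c(.AA, .GAP)   # 21 categorical states; gap is state 21
.Q <- 20L

# residue string -> integer states in 1..21
state_index <- function(residues) {
  match(strsplit(residues, "", fixed = TRUE)[[1]], .STATES)
}

states_to_residues <- function(states) {
  paste(.STATES[states], collapse = "")
}

default_chain_length <- function(chain) {
  switch(chain, VH = 149L, VL = 149L, VHVL = 298L,
         abort(sprintf("unknown chain '%s' (expected VH, VL or VHVL)", chain)))
}

#' Validate an aligned-sequence database
#'
#' A sequence database is a tibble with columns `id`, `chain`, `residues`
#' and optionally `species`. All sequences must share one chain label and
#' one alignment length, every residue must be one of the 20 amino-acid
#' one-letter codes or `-`, and ids must be unique.
#'
#' @param db A data frame with columns `id`, `chain`, `residues`.
#' @param L Expected alignment length; if `NULL`, taken from the first row.
#' @param chain Expected chain label; if `NULL`, taken from the first row.
#' @return The validated database, invisibly usable downstream (a tibble).
#' @export
validate_seq_db <- function(db, L = NULL, chain = NULL) {
  db <- as_tibble(db)
  need <- c("id", "chain", "residues")
  miss <- setdiff(need, names(db))
  if (length(miss) > 0)
    abort(paste0("sequence database lacks column(s): ",
                 paste(miss, collapse = ", ")))
  if (nrow(db) == 0) abort("sequence database is empty")
  if (anyDuplicated(db$id))
    abort(sprintf("duplicate sequence id '%s'",
                  db$id[duplicated(db$id)][1]))
  if (is.null(chain)) chain <- db$chain[1]
  if (!all(db$chain == chain))
    abort("all sequences in a database must share one chain label")
  if (!chain %in% c("VH", "VL", "VHVL"))
    abort(sprintf("unknown chain '%s' (expected VH, VL or VHVL)", chain))
  if (is.null(L)) L <- nchar(db$residues[1])
  for (i in seq_len(nrow(db))) {
    check_residues(db$residues[i], L, db$id[i])
  }
  db
}

check_residues <- function(residues, L, id) {
  if (nchar(residues) != L)
    abort(sprintf("sequence '%s' has length %d, expected %d",
                  id, nchar(residues), L))
  st <- match(strsplit(residues, "", fixed = TRUE)[[1]], .STATES)
  if (anyNA(st)) {
    pos <- which(is.na(st))[1]
    abort(sprintf(
      "sequence '%s' has illegal character '%s' at position %d",
      id, substr(residues, pos, pos), pos))
  }
  invisible(residues)
}

# Accept a residue string, or a one-row database tibble, as a single sequence.
as_residues <- function(x) {
  if (is.character(x) && length(x) == 1) return(x)
  if (is.data.frame(x) && nrow(x) == 1 && "residues" %in% names(x))
    return(x$residues[1])
  abort("expected a single residue string or a one-row sequence tibble")
}
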