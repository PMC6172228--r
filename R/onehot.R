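#' One-hot encode an aligned sequence
#'
#' Maps an L-residue gapped sequence to a binary vector of N = 20L bits.
#' Block i (bits 20(i-1)+1 .. 20i) carries the indicator of the amino acid
#' at position i in the fixed alphabetical ordering ([aa_alphabet()]); a
#' gap leaves its whole block at zero, so every block sums to 0 or 1.
#'
#' @param seq Residue string (or one-row sequence tibble).
#' @return Numeric 0/1 vector of length `20 * nchar(seq)`.
#' @export
#' @examples
#' encode_onehot("A")[1:3]  # 1 0 0
#' sum(encode_onehot("-"))  # 0
encode_onehot <- function(seq) {
  residues <- as_residues(seq)
  check_residues(residues, nchar(residues), "<query>")
  st <- state_index(residues)
  L <- length(st)
  y <- numeric(.Q * L)
  keep <- st <= .Q
  y[(which(keep) - 1L) * .Q + st[keep]] <- 1
  y
}

#' Decode a one-hot vector back to a residue string
#'
#' Inverse of [encode_onehot()]. An all-zero block decodes to a gap.
#'
#' @param v Numeric 0/1 vector of length `20 * L`.
#' @param L Alignment length.
#' @return Residue string.
#' @export
decode_onehot <- function(v, L) {
  if (length(v) != .Q * L)
    abort(sprintf("expected %d bits, got %d", .Q * L, length(v)))
  if (!all(v %in% c(0, 1))) abort("one-hot vector must be binary")
  m <- matrix(v, nrow = .Q, ncol = L)
  sums <- colSums(m)
  if (any(sums > 1)) {
    abort(sprintf("block %d has sum %d > 1", which(sums > 1)[1],
                  max(sums)))
  }
  st <- vapply(seq_len(L), function(i) {
    if (sums[i] == 0) 21L else which(m[, i] == 1)
  }, integer(1))
  states_to_residues(st)
}

# M x N one-hot matrix for a database (rows in db order)
encode_db <- function(db) {
  L <- nchar(db$residues[1])
  t(vapply(db$residues, encode_onehot, numeric(.Q * L), USE.NAMES = FALSE))
}
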