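# Distance-based humanness scores: average Hamming distance from a query
# to its k nearest reference sequences (T_k), to the whole reference
# ensemble (T_all), and the two-reference difference score.

#' Nearest-neighbour distance score T_k
#'
#' For each query, the mean of the k smallest Hamming distances to the
#' reference database; `k = "all"` averages over the whole ensemble
#' (the T_all score). Lower values mean more reference-like (for a human
#' reference: more human). Ties at the k-th distance are resolved on
#' distance values (smallest-k multiset), so the score is independent of
#' reference ordering.
#'
#' @param queries Query sequence database tibble.
#' @param ref Reference database tibble (same chain and length).
#' @param k Integer in `[1, nrow(ref)]`, or `"all"`.
#' @param exclude Optional [cdr_mask()] (or integer positions) removed
#'   from the Hamming sum — the framework-only ("FR") variant.
#' @param reference_label Label recorded in the output.
#' @return Tibble `id`, `k`, `score`, `reference_label`.
#' @export
t_k_score <- function(queries, ref, k = 1, exclude = NULL,
                      reference_label = "reference") {
  queries <- validate_seq_db(queries)
  ref <- validate_seq_db(ref)
  check_same_frame(queries, ref)
  M <- nrow(ref)
  k_all <- identical(k, "all")
  if (!k_all) {
    k <- as.integer(k)
    if (k < 1 || k > M)
      abort(sprintf("k = %d out of range [1, %d]", k, M))
  }
  D <- distance_matrix(queries, ref, exclude)
  score <- apply(D, 1, function(d) {
    if (k_all) mean(d) else mean(sort(d, partial = k)[seq_len(k)])
  })
  tibble(id = queries$id, k = if (k_all) "all" else as.character(k),
         score = as.numeric(score), reference_label = reference_label)
}

#' Two-reference distance score
#'
#' The difference of average distances to a murine and a human reference
#' ensemble, oriented so that positive values indicate the query is closer
#' to the human ensemble: `s = dbar_murine - dbar_human`. A sequence with
#' `s > 0` is classified human, `s <= 0` murine.
#'
#' @param queries Query database tibble.
#' @param ref_h,ref_m Human and murine reference databases.
#' @param exclude Optional mask excluded from distances.
#' @return Tibble `id`, `score` (positive = human-like).
#' @export
two_reference_score <- function(queries, ref_h, ref_m, exclude = NULL) {
  th <- t_k_score(queries, ref_h, k = "all", exclude = exclude,
                  reference_label = "human")
  tm <- t_k_score(queries, ref_m, k = "all", exclude = exclude,
                  reference_label = "murine")
  tibble(id = th$id, score = tm$score - th$score)
}

check_same_frame <- function(a, b) {
  if (nchar(a$residues[1]) != nchar(b$residues[1]))
    abort("query and reference alignment lengths differ")
  if (a$chain[1] != b$chain[1])
    abort(sprintf("chain mismatch: %s vs %s", a$chain[1], b$chain[1]))
  invisible(TRUE)
}

# pairwise Hamming distances, queries in rows, refs in columns
distance_matrix <- function(queries, ref, exclude = NULL) {
  L <- nchar(queries$residues[1])
  keep <- setdiff(seq_len(L), mask_positions(exclude, L))
  Qm <- db_state_matrix(queries)[, keep, drop = FALSE]
  Rm <- db_state_matrix(ref)[, keep, drop = FALSE]
  nq <- nrow(Qm)
  D <- matrix(0L, nq, nrow(Rm))
  for (i in seq_len(nq)) {
    D[i, ] <- colSums(t(Rm) != Qm[i, ])
  }
  D
}
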