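# Fast single-mutation score updates. A point mutation flips at most two
# bits of the one-hot encoding, so with S^{-1} materialized and
# v = S^{-1} (y - mu) cached, the change of the Mahalanobis form is O(1)
# per proposal and the cache update on acceptance is O(N).

#' Cached scoring context for single-mutation updates
#'
#' Precomputes the dense inverse scale matrix and the residual state of a
#' sequence so that [mg_score_delta()] evaluates a point mutation in O(1)
#' and [mg_apply_mutation()] commits it in O(N). The context is an
#' environment and is modified in place by [mg_apply_mutation()].
#'
#' @param model An `mg_model`.
#' @param seq Residue string (or one-row tibble) matching the model.
#' @return An environment of class `mg_context` with fields `states`,
#'   `q` (Mahalanobis form), `score`, and internals.
#' @export
mg_score_context <- function(model, seq) {
  residues <- as_residues(seq)
  check_residues(residues, model$meta$L, "<query>")
  ctx <- new.env(parent = emptyenv())
  ctx$Sinv <- chol2inv(model$chol_scale)
  ctx$Sdiag <- diag(ctx$Sinv)
  ctx$states <- state_index(residues)
  y <- encode_onehot(residues)
  r <- y - model$mu_post
  ctx$v <- drop(ctx$Sinv %*% r)
  ctx$q <- sum(r * ctx$v)
  ctx$score <- score_from_q(model, ctx$q)
  class(ctx) <- "mg_context"
  ctx
}

score_from_q <- function(model, q) {
  N <- length(model$mu_post)
  nu <- model$dof
  if (is.finite(nu)) {
    model$log_norm - ((nu + N) / 2) * log1p(q / nu)
  } else {
    model$log_norm - q / 2
  }
}

# change of the Mahalanobis form q for mutating position pos from state a
# to state b (states in 1..21; 21 = gap carries no bit)
delta_q <- function(ctx, pos, a, b) {
  dq <- 0
  j1 <- if (a <= .Q) (pos - 1L) * .Q + a else 0L
  j2 <- if (b <= .Q) (pos - 1L) * .Q + b else 0L
  if (j1 > 0L) dq <- dq - 2 * ctx$v[j1] + ctx$Sdiag[j1]
  if (j2 > 0L) dq <- dq + 2 * ctx$v[j2] + ctx$Sdiag[j2]
  if (j1 > 0L && j2 > 0L) dq <- dq - 2 * ctx$Sinv[j1, j2]
  dq
}

#' Score change of a single point mutation
#'
#' Returns `mg_score(mutated) - mg_score(current)` for replacing the
#' residue at `pos` by `new_aa`, via a sparse update of the quadratic
#' form. Masking of CDR positions is the caller's responsibility.
#'
#' @param model The `mg_model` used to build `ctx`.
#' @param ctx Context from [mg_score_context()].
#' @param pos 1-based alignment position.
#' @param new_aa Replacement residue (one of the 20 letters or `-`).
#' @return Numeric score difference; exactly 0 when `new_aa` equals the
#'   current residue.
#' @export
mg_score_delta <- function(model, ctx, pos, new_aa) {
  L <- model$meta$L
  if (pos < 1 || pos > L) abort(sprintf("position %d out of range", pos))
  b <- match(new_aa, .STATES)
  if (is.na(b)) abort(sprintf("illegal residue '%s'", new_aa))
  a <- ctx$states[pos]
  if (a == b) return(0)
  dq <- delta_q(ctx, pos, a, b)
  score_from_q(model, ctx$q + dq) - score_from_q(model, ctx$q)
}

#' Commit a point mutation into a scoring context
#'
#' Updates the cached residual, Mahalanobis form and score in O(N). The
#' context environment is modified in place and returned invisibly.
#'
#' @inheritParams mg_score_delta
#' @export
mg_apply_mutation <- function(model, ctx, pos, new_aa) {
  b <- match(new_aa, .STATES)
  if (is.na(b)) abort(sprintf("illegal residue '%s'", new_aa))
  apply_state(model, ctx, pos, b)
  invisible(ctx)
}

apply_state <- function(model, ctx, pos, b) {
  a <- ctx$states[pos]
  if (a == b) return(invisible(ctx))
  dq <- delta_q(ctx, pos, a, b)
  if (a <= .Q) {
    j1 <- (pos - 1L) * .Q + a
    ctx$v <- ctx$v - ctx$Sinv[, j1]
  }
  if (b <= .Q) {
    j2 <- (pos - 1L) * .Q + b
    ctx$v <- ctx$v + ctx$Sinv[, j2]
  }
  ctx$q <- ctx$q + dq
  ctx$states[pos] <- b
  ctx$score <- score_from_q(model, ctx$q)
  invisible(ctx)
}

# exact refresh of the cached residual state (used at temperature changes
# to stop incremental rounding drift)
refresh_context <- function(model, ctx) {
  y <- encode_onehot(states_to_residues(ctx$states))
  r <- y - model$mu_post
  ctx$v <- drop(ctx$Sinv %*% r)
  ctx$q <- sum(r * ctx$v)
  ctx$score <- score_from_q(model, ctx$q)
  invisible(ctx)
}
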