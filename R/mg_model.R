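# Multivariate Gaussian sequence model with Normal-Inverse-Wishart prior.
#
# Sequences are one-hot encoded to y in {0,1}^N, N = 20L, and treated as
# draws from N(mu, Sigma) with a NIW prior on (mu, Sigma). The posterior
# predictive of a new sequence is the multivariate Student-t
#
#   p(y | X) = t_N( nu, <mu>_post, S ),  nu = M/(1-lambda) + 2,
#   S = (1 + (1-lambda)/M) <Sigma>_post,
#   <mu>_post    = lambda eta + (1-lambda) xbar,
#   <Sigma>_post = lambda U + (1-lambda) Cbar
#                  + lambda (1-lambda) (xbar-eta)(xbar-eta)^T,
#
# with (eta, U) the moments of a uniform categorical sample and lambda in
# (0, 1] the single regularization knob. The MG humanness score of y is
# log p(y | X); it is a log *density* and routinely exceeds 0.

#' Moments of a uniformly distributed one-hot sample
#'
#' The prior location `eta` and scale `U` are the exact first and second
#' central moments of the one-hot encoding of a sequence whose every
#' position is uniform over the 21 states (20 amino acids + gap):
#' `eta = 1/21` everywhere; `U` is block diagonal with within-position
#' blocks `(1/21) I - (1/441) J`. Including the gap state keeps `U`
#' positive definite (smallest eigenvalue 1/441); uniform over 20 amino
#' acids alone would make block sums constant and `U` singular.
#'
#' @param L Alignment length (positions).
#' @return List with fields `eta` (length `20L`) and `U` (`20L x 20L`).
#' @export
uniform_prior_moments <- function(L) {
  stopifnot(L >= 1)
  N <- .Q * L
  eta <- rep(1 / 21, N)
  block <- diag(1 / 21, .Q) - matrix(1 / 441, .Q, .Q)
  U <- matrix(0, N, N)
  for (i in seq_len(L)) {
    idx <- (i - 1L) * .Q + seq_len(.Q)
    U[idx, idx] <- block
  }
  list(eta = eta, U = U)
}

# ---- constructor from moments (any N; used by fit_mg and by toy tests) ----

#' Build a fitted model directly from moment statistics
#'
#' Low-level constructor taking empirical moments `(xbar, Cbar)` of `M`
#' observations and prior moments `(eta, U)`; computes the posterior
#' location/scale, the Student-t degrees of freedom and the cached
#' Cholesky factor and log normalizing constant. [fit_mg()] is the
#' data-facing wrapper; this constructor also serves arbitrary-dimension
#' toy problems.
#'
#' @param xbar,Cbar Empirical mean vector and (1/M-normalized) covariance.
#' @param M Number of observations behind `xbar`, `Cbar`.
#' @param lam Regularization weight lambda in (0, 1].
#' @param eta,U Prior moments (defaults: uniform-sample moments when the
#'   dimension is a multiple of 20 — supply both explicitly otherwise).
#' @param meta List of metadata (chain, L, Q, alphabet, ...).
#' @return An object of class `mg_model`.
#' @export
mg_model_from_moments <- function(xbar, Cbar, M, lam, eta = NULL, U = NULL,
                                  meta = list()) {
  N <- length(xbar)
  if (lam <= 0 || lam > 1) abort("lambda must lie in (0, 1]")
  if (M < 1) abort("M must be >= 1")
  if (is.null(eta) || is.null(U)) {
    if (N %% .Q != 0)
      abort("default prior needs dimension divisible by 20; supply eta and U")
    pr <- uniform_prior_moments(N %/% .Q)
    if (is.null(eta)) eta <- pr$eta
    if (is.null(U)) U <- pr$U
  }
  d <- xbar - eta
  mu_post <- lam * eta + (1 - lam) * xbar
  Sigma_post <- lam * U + (1 - lam) * Cbar +
    lam * (1 - lam) * tcrossprod(d)
  Sigma_post <- (Sigma_post + t(Sigma_post)) / 2
  dof <- if (lam < 1) M / (1 - lam) + 2 else Inf
  scale <- (1 + (1 - lam) / M) * Sigma_post
  model <- structure(list(
    M = M, xbar = xbar, Cbar = Cbar,
    prior = list(eta = eta, U = U, lam = lam),
    mu_post = mu_post, Sigma_post = Sigma_post,
    dof = dof, scale = scale,
    chol_scale = NULL, log_norm = NULL,
    meta = utils::modifyList(
      list(chain = NA_character_, L = N / .Q, Q = .Q,
           alphabet = paste(.STATES, collapse = ""),
           ablation = "none", model_id = "mg", version = 1L),
      meta)
  ), class = "mg_model")
  refactorize(model)
}

# (re)compute chol_scale and log_norm from scale/dof
refactorize <- function(model) {
  N <- length(model$mu_post)
  ch <- tryCatch(chol(model$scale), error = function(e) {
    piv <- min(eigen(model$scale, symmetric = TRUE,
                     only.values = TRUE)$values)
    abort(sprintf(
      "scale matrix is not positive definite (smallest eigenvalue %.3e)",
      piv))
  })
  logdet <- 2 * sum(log(diag(ch)))
  nu <- model$dof
  log_norm <- if (is.finite(nu)) {
    lgamma((nu + N) / 2) - lgamma(nu / 2) -
      (N / 2) * log(nu * pi) - logdet / 2
  } else {
    -(N / 2) * log(2 * pi) - logdet / 2
  }
  model$chol_scale <- ch
  model$log_norm <- log_norm
  model
}

#' Fit the multivariate Gaussian humanness model
#'
#' Computes the empirical mean and (biased, 1/M-normalized) covariance of
#' the one-hot encodings of a learning database and combines them with the
#' uniform-sample prior moments under regularization weight `lam`.
#'
#' @param db Learning database tibble (see [validate_seq_db()]).
#' @param lam Regularization lambda in (0, 1]. `lam = 0` is rejected: the
#'   empirical covariance alone is singular whenever M < N.
#' @param prior Optional list with fields `eta`, `U` overriding the
#'   uniform-sample prior.
#' @param engine `"batch"` (BLAS crossproduct) or `"streaming"`
#'   (one-sequence-at-a-time accumulation); both give the same moments.
#' @param model_id Label stored in the model metadata.
#' @return An `mg_model`.
#' @export
fit_mg <- function(db, lam, prior = NULL, engine = c("batch", "streaming"),
                   model_id = "mg") {
  engine <- match.arg(engine)
  db <- validate_seq_db(db)
  L <- nchar(db$residues[1])
  M <- nrow(db)
  if (engine == "batch") {
    X <- encode_db(db)
    xbar <- colMeans(X)
    Cbar <- crossprod(X) / M - tcrossprod(xbar)
  } else {
    N <- .Q * L
    s1 <- numeric(N)
    S2 <- matrix(0, N, N)
    for (i in seq_len(M)) {
      y <- encode_onehot(db$residues[i])
      s1 <- s1 + y
      S2 <- S2 + tcrossprod(y)
    }
    xbar <- s1 / M
    Cbar <- S2 / M - tcrossprod(xbar)
  }
  Cbar <- (Cbar + t(Cbar)) / 2
  mg_model_from_moments(
    xbar, Cbar, M, lam,
    eta = prior$eta, U = prior$U,
    meta = list(chain = db$chain[1], L = L, model_id = model_id))
}

#' Log posterior-predictive density at an arbitrary point
#'
#' Evaluates the log multivariate Student-t density (or its Gaussian limit
#' at `lam = 1`) at a numeric vector `y` of the model's dimension. Used by
#' [mg_score()] on encoded sequences and directly on toy problems.
#'
#' @param model An `mg_model`.
#' @param y Numeric vector of length N.
#' @return Log density (may exceed 0).
#' @export
mg_logdensity <- function(model, y) {
  N <- length(model$mu_post)
  if (length(y) != N)
    abort(sprintf("dimension mismatch: y has length %d, model N = %d",
                  length(y), N))
  r <- y - model$mu_post
  z <- backsolve(model$chol_scale, r, transpose = TRUE)
  q <- sum(z * z)
  nu <- model$dof
  if (is.finite(nu)) {
    model$log_norm - ((nu + N) / 2) * log1p(q / nu)
  } else {
    model$log_norm - q / 2
  }
}

#' MG humanness score of aligned sequences
#'
#' Scores every sequence in `db` with the log posterior-predictive
#' Student-t density of `model`. Higher scores mean more human-like (when
#' the model was learned on human sequences). Scores are log densities,
#' not log probabilities, and typically exceed 0 by a large margin.
#'
#' @param db Sequence database tibble to score.
#' @param model A fitted `mg_model` of matching chain and length.
#' @return A tibble `id`, `chain`, `mg_score`, `model_id`.
#' @export
mg_score <- function(db, model) {
  db <- validate_seq_db(db)
  check_model_compat(model, db)
  scores <- vapply(db$residues, function(s)
    mg_logdensity(model, encode_onehot(s)), numeric(1), USE.NAMES = FALSE)
  tibble(id = db$id, chain = db$chain, mg_score = scores,
         model_id = model$meta$model_id)
}

check_model_compat <- function(model, db) {
  L <- nchar(db$residues[1])
  if (L != model$meta$L)
    abort(sprintf("sequence length %d does not match model L = %d",
                  L, model$meta$L))
  mc <- model$meta$chain
  if (!is.na(mc) && !all(db$chain == mc))
    abort(sprintf("chain mismatch: model is %s, database is %s",
                  mc, db$chain[1]))
  invisible(TRUE)
}

#' Maximum attainable MG score
#'
#' The log density at the posterior-predictive mode `y = <mu>_post`
#' (Mahalanobis term zero), an upper bound on [mg_score()] over all
#' inputs. Note the mode is generally not a valid one-hot vector, so the
#' bound need not be attained by any sequence.
#'
#' @param model An `mg_model`.
#' @return Numeric upper bound (equals the model's log normalizing term).
#' @export
mg_max <- function(model) {
  model$log_norm
}

#' Zero out pair correlations in a fitted model
#'
#' `all_off` zeroes every cross-position block of the posterior covariance
#' (keeping the within-position 20x20 blocks), removing all inter-residue
#' interactions. `interchain_off` zeroes only the blocks coupling VH
#' positions with VL positions of a combined VHVL model. The scale,
#' Cholesky factor and normalizing constant are recomputed; lambda is kept
#' (re-selecting lambda for the ablated model is the caller's job).
#'
#' @param model An `mg_model`.
#' @param mode `"all_off"` or `"interchain_off"`.
#' @param boundary For `interchain_off`, the last VH position (default 149
#'   for L = 298, otherwise L/2).
#' @return A new `mg_model` with the ablation tag recorded.
#' @export
ablate_correlations <- function(model, mode = c("all_off", "interchain_off"),
                                boundary = NULL) {
  mode <- match.arg(mode)
  L <- model$meta$L
  pos <- rep(seq_len(L), each = .Q)
  Sig <- model$Sigma_post
  if (mode == "all_off") {
    keep <- outer(pos, pos, "==")
    Sig[!keep] <- 0
  } else {
    if (!identical(model$meta$chain, "VHVL"))
      abort("interchain_off requires a combined VHVL model")
    if (is.null(boundary)) boundary <- if (L == 298) 149L else L %/% 2L
    half <- pos <= boundary
    cross <- outer(half, half, "!=")
    Sig[cross] <- 0
  }
  model$Sigma_post <- Sig
  model$scale <- (1 + (1 - model$prior$lam) / model$M) * Sig
  model$meta$ablation <- mode
  refactorize(model)
}

#' @export
print.mg_model <- function(x, ...) {
  N <- length(x$mu_post)
  cat(sprintf(
    "<mg_model> %s  L=%d  N=%d  M=%d  lambda=%.4g  dof=%.4g  ablation=%s\n",
    x$meta$model_id,
    x$meta$L, N, x$M, x$prior$lam, x$dof, x$meta$ablation))
  cat(sprintf("  mg_max = %.4f\n", mg_max(x)))
  invisible(x)
}

#' @export
glance.mg_model <- function(x, ...) {
  tibble(model_id = x$meta$model_id, chain = x$meta$chain,
         L = x$meta$L, N = length(x$mu_post), M = x$M,
         lambda = x$prior$lam, dof = x$dof, ablation = x$meta$ablation,
         mg_max = mg_max(x))
}

#' @export
tidy.mg_model <- function(x, ...) {
  L <- x$meta$L
  tibble(
    position = rep(seq_len(L), each = .Q),
    residue = rep(.AA, L),
    mean_post = x$mu_post,
    mean_empirical = x$xbar
  )
}

#' Serialize / restore a fitted model
#'
#' Models are written as a versioned native R serialization; scores of a
#' reloaded model are bit-identical to the original.
#'
#' @param model An `mg_model`.
#' @param path File path.
#' @return `path` (write) or the restored `mg_model` (read).
#' @export
write_mg_model <- function(model, path) {
  stopifnot(inherits(model, "mg_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_mg_model
#' @export
read_mg_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mg_model")) abort("file does not contain an mg_model")
  model
}

#' Write scores as TSV
#'
#' @param scores Score tibble from [mg_score()] or the distance scores.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
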