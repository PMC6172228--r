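# Independent oracles and small fixture builders. These deliberately use
# different code paths from the package internals (solve()/determinant()
# instead of Cholesky solves, full re-scoring instead of sparse deltas).

# textbook multivariate Student-t log-density
dmvt_log_oracle <- function(y, nu, mu, S) {
  N <- length(mu)
  r <- y - mu
  q <- drop(t(r) %*% solve(S) %*% r)
  lgamma((nu + N) / 2) - lgamma(nu / 2) - (N / 2) * log(nu * pi) -
    0.5 * as.numeric(determinant(S, logarithm = TRUE)$modulus) -
    ((nu + N) / 2) * log(1 + q / nu)
}

dmvnorm_log_oracle <- function(y, mu, S) {
  N <- length(mu)
  r <- y - mu
  -0.5 * (N * log(2 * pi) +
            as.numeric(determinant(S, logarithm = TRUE)$modulus) +
            drop(t(r) %*% solve(S) %*% r))
}

# random small-dimension fitted model (arbitrary N, explicit prior)
random_toy_model <- function(N, seed) {
  withr::with_seed(seed, {
    M <- sample(20:200, 1)
    lam <- runif(1, 0.05, 0.95)
    xbar <- runif(N)
    A <- matrix(rnorm(N * N), N)
    Cbar <- crossprod(A) / N
    eta <- runif(N)
    B <- matrix(rnorm(N * N), N)
    U <- crossprod(B) / N + diag(0.5, N)
    mg_model_from_moments(xbar, Cbar, M, lam, eta = eta, U = U)
  })
}

# small sequence model fitted on profile samples; with `letters`, the
# profiles are supported on that alphabet only, so every search state of
# a restricted toy landscape is actually observed (no exactly-degenerate
# unobserved states)
toy_seq_model <- function(L = 4, M = 40, lam = 0.3, seed = 7,
                          letters = NULL) {
  pm <- if (is.null(letters)) {
    profile_model(L, seed = seed)
  } else {
    idx <- match(letters, c(humab::aa_alphabet(), "-"))
    probs <- withr::with_seed(seed, {
      vapply(seq_len(L), function(i) {
        p <- numeric(21)
        g <- stats::rgamma(length(idx), shape = 1)
        p[idx] <- g / sum(g)
        p
      }, numeric(21))
    })
    profile_model(L, probs = probs)
  }
  db <- sample_profile_db(pm, M, label = "toy", seed = seed + 1)
  fit_mg(db, lam = lam)
}

random_residues <- function(L, seed = NULL, gap_prob = 0.1) {
  draw <- function() {
    st <- sample(21, L, replace = TRUE,
                 prob = c(rep((1 - gap_prob) / 20, 20), gap_prob))
    paste(c(humab::aa_alphabet(), "-")[st], collapse = "")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# every sequence obtained by varying `free` positions of `origin` over
# `letters`, with its MG score
enumerate_landscape <- function(model, origin, free, letters) {
  grids <- rep(list(letters), length(free))
  combos <- expand.grid(grids, stringsAsFactors = FALSE)
  seqs <- apply(combos, 1, function(row) {
    s <- origin
    for (k in seq_along(free)) substr(s, free[k], free[k]) <- row[k]
    s
  })
  scores <- vapply(seqs, function(s)
    mg_logdensity(model, encode_onehot(s)), numeric(1), USE.NAMES = FALSE)
  data.frame(residues = seqs, score = scores, stringsAsFactors = FALSE)
}

# full-rescore greedy hill climb with the same tie-break as the package
# (lowest position, then alphabetical residue; strict improvement)
greedy_oracle <- function(model, origin, free, letters) {
  cur <- origin
  score <- mg_logdensity(model, encode_onehot(cur))
  path <- list()
  repeat {
    best <- NULL
    for (pos in free) {
      for (aa in letters) {
        if (substr(cur, pos, pos) == aa) next
        cand <- cur
        substr(cand, pos, pos) <- aa
        s <- mg_logdensity(model, encode_onehot(cand))
        if (s > score + 1e-9 && (is.null(best) || s > best$score + 1e-9)) {
          best <- list(seq = cand, score = s, pos = pos, aa = aa)
        }
      }
    }
    if (is.null(best)) break
    cur <- best$seq
    score <- best$score
    path[[length(path) + 1]] <- best
  }
  list(final = cur, score = score, path = path)
}

# chi-square statistic with cells of small expectation pooled
chisq_pooled <- function(obs, expected, min_expected = 5) {
  obs <- as.numeric(obs); expected <- as.numeric(expected)
  pool <- expected >= min_expected
  o <- obs[pool]; e <- expected[pool]
  if (any(!pool)) {
    o <- c(o, sum(obs[!pool]))
    e <- c(e, sum(expected[!pool]))
  }
  list(stat = sum((o - e)^2 / e), df = length(o) - 1)
}

# state visited after every SAMC proposal, reconstructed from the
# accepted-move record
samc_state_sequence <- function(traj, n_proposals) {
  steps <- traj$steps
  seqs <- character(n_proposals)
  cur <- traj$origin
  last <- 0L
  if (nrow(steps) > 0) {
    for (r in seq_len(nrow(steps))) {
      t <- steps$step[r]
      if (t > last + 1L) seqs[(last + 1L):(t - 1L)] <- cur
      substr(cur, steps$position[r], steps$position[r]) <- steps$to[r]
      seqs[t] <- cur
      last <- t
    }
  }
  if (last < n_proposals) seqs[(last + 1L):n_proposals] <- cur
  seqs
}
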