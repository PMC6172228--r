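# Seeded generators of aligned ensembles with controlled statistics:
# independent per-site profiles, and Potts-like pairwise-coupled models
# sampled by Gibbs sweeps. These emulate the statistical structure of the
# immunoglobulin learning ensembles (site preferences, within- and
# cross-chain residue couplings, species divergence) without any claim of
# germline realism.

#' Independent per-site profile model
#'
#' Each alignment position has its own categorical distribution over the
#' 21 states (20 amino acids + gap). With `probs = NULL`, profiles are
#' drawn from a symmetric Dirichlet over the amino acids, with a fixed
#' per-site gap probability so that gap-handling code paths are exercised.
#'
#' @param L Alignment length.
#' @param probs Optional 21 x L column-stochastic matrix (rows in the
#'   [aa_alphabet()] order, gap last).
#' @param seed Seed for the random profile draw.
#' @param concentration Dirichlet concentration of random profiles. The
#'   default 0.1 gives strongly conserved columns (median dominant-residue
#'   mass around 0.5), emulating the conservation of immunoglobulin
#'   framework positions.
#' @param gap_prob Per-site gap probability of random profiles.
#' @return Object of class `profile_model`.
#' @export
profile_model <- function(L, probs = NULL, seed = 1,
                          concentration = 0.1, gap_prob = 0.02) {
  if (is.null(probs)) {
    probs <- withr::with_seed(seed, {
      vapply(seq_len(L), function(i) {
        g <- stats::rgamma(.Q, shape = concentration)
        c(g / sum(g) * (1 - gap_prob), gap_prob)
      }, numeric(21))
    })
  }
  probs <- as.matrix(probs)
  if (nrow(probs) != 21 || ncol(probs) != L)
    abort("probs must be a 21 x L matrix")
  if (any(probs < 0) || any(abs(colSums(probs) - 1) > 1e-12))
    abort("each per-position probability vector must be >= 0 and sum to 1")
  structure(list(L = L, probs = probs, seed = seed),
            class = "profile_model")
}

#' Sample an i.i.d. database from a profile model
#'
#' @param model A [profile_model()].
#' @param M Number of sequences.
#' @param label Database label (used for ids and the species column).
#' @param seed RNG seed; identical seeds give identical databases.
#' @param chain Chain tag for the output tibble.
#' @return Sequence database tibble.
#' @export
sample_profile_db <- function(model, M, label = "synthetic", seed = 1,
                              chain = "VHVL") {
  stopifnot(inherits(model, "profile_model"), M >= 1)
  states <- withr::with_seed(seed, {
    vapply(seq_len(model$L), function(i) {
      sample.int(21L, M, replace = TRUE, prob = model$probs[, i])
    }, integer(M))
  })
  states <- matrix(states, nrow = M)
  tibble(
    id = sprintf("%s_%05d", label, seq_len(M)),
    chain = chain,
    residues = apply(states, 1, states_to_residues),
    species = label
  )
}

#' Pairwise-coupled sequence model
#'
#' A Boltzmann distribution over aligned sequences with per-site fields
#' and sparse pairwise couplings:
#' `P(s) ~ exp( sum_i fields[s_i, i] + sum_(i<j) table_ij[s_i, s_j] )`.
#'
#' @param L Alignment length.
#' @param fields 21 x L matrix of log-preferences.
#' @param couplings List of `list(i, j, table)` with `i < j` and `table` a
#'   finite 21 x 21 matrix.
#' @param gibbs_burnin Burn-in sweeps per chain before the first draw.
#' @param gibbs_thin Sweeps between consecutive draws from one chain.
#' @param seed Seed recorded with the model.
#' @return Object of class `coupled_model`.
#' @export
coupled_model <- function(L, fields, couplings = list(),
                          gibbs_burnin = 100, gibbs_thin = 10, seed = 1) {
  fields <- as.matrix(fields)
  if (nrow(fields) != 21 || ncol(fields) != L)
    abort("fields must be a 21 x L matrix")
  for (cp in couplings) {
    if (!(cp$i < cp$j && cp$i >= 1 && cp$j <= L))
      abort("coupling positions must satisfy 1 <= i < j <= L")
    if (!all(is.finite(cp$table)) || !all(dim(cp$table) == c(21, 21)))
      abort("coupling tables must be finite 21 x 21 matrices")
  }
  structure(list(L = L, fields = fields, couplings = couplings,
                 gibbs_burnin = gibbs_burnin, gibbs_thin = gibbs_thin,
                 seed = seed),
            class = "coupled_model")
}

# neighbour lists: for site i, couplings touching i with the table
# oriented so rows index the state of i
coupling_neighbours <- function(model) {
  nb <- vector("list", model$L)
  for (cp in model$couplings) {
    nb[[cp$i]] <- c(nb[[cp$i]], list(list(j = cp$j, table = cp$table)))
    nb[[cp$j]] <- c(nb[[cp$j]], list(list(j = cp$i, table = t(cp$table))))
  }
  nb
}

#' Sample a database from a coupled model by Gibbs sampling
#'
#' Runs vectorized parallel single-site Gibbs chains: each chain is
#' burned in for `gibbs_burnin` full sweeps, then one sequence is drawn
#' every `gibbs_thin` sweeps, round-robin across chains, until `M`
#' sequences are collected. Exactness of the sampler is certified against
#' full enumeration at L = 2 in the test suite.
#'
#' @inheritParams sample_profile_db
#' @param model A [coupled_model()].
#' @param n_chains Number of parallel chains (default `min(M, 64)`).
#' @return Sequence database tibble.
#' @export
sample_coupled_db <- function(model, M, label = "synthetic", seed = 1,
                              chain = "VHVL", n_chains = NULL) {
  stopifnot(inherits(model, "coupled_model"), M >= 1)
  if (is.null(n_chains)) n_chains <- min(M, 64L)
  nb <- coupling_neighbours(model)
  L <- model$L
  per_chain <- ceiling(M / n_chains)
  states <- withr::with_seed(seed, {
    # init from the fields-only marginals
    st <- vapply(seq_len(L), function(i) {
      p <- exp(model$fields[, i] - max(model$fields[, i]))
      sample.int(21L, n_chains, replace = TRUE, prob = p / sum(p))
    }, integer(n_chains))
    st <- matrix(st, nrow = n_chains)
    out <- matrix(0L, n_chains * per_chain, L)
    got <- 0L
    sweeps_to_next <- model$gibbs_burnin
    for (round in seq_len(per_chain)) {
      for (sw in seq_len(sweeps_to_next)) {
        for (i in seq_len(L)) {
          logits <- matrix(model$fields[, i], 21L, n_chains)
          for (e in nb[[i]]) {
            logits <- logits + e$table[, st[, e$j], drop = FALSE]
          }
          gumb <- -log(-log(matrix(runif(21L * n_chains), n_chains, 21L)))
          st[, i] <- max.col(t(logits) + gumb)
        }
      }
      out[got + seq_len(n_chains), ] <- st
      got <- got + n_chains
      sweeps_to_next <- model$gibbs_thin
    }
    out[seq_len(M), , drop = FALSE]
  })
  tibble(
    id = sprintf("%s_%05d", label, seq_len(M)),
    chain = chain,
    residues = apply(states, 1, states_to_residues),
    species = label
  )
}

#' Paired "human-like" / "murine-like" coupled models
#'
#' Builds two coupled models sharing a random base profile. A fraction
#' `divergence` of positions receives an independent field perturbation
#' in the murine model (species-divergent site preferences). Couplings
#' are placed at shared position pairs within the first half (VH-like
#' block), within the second half (VL-like block) and — when
#' `cross_chain` — across the two blocks; each species draws its own
#' random 20 x 20 permutation table scaled by `coupling_strength`, so the
#' two ensembles differ in their covariation structure, not only in their
#' marginals.
#'
#' @param L Alignment length (even).
#' @param divergence Fraction of positions with species-shifted fields.
#' @param coupling_strength Log-scale magnitude of the coupling tables.
#' @param cross_chain Place couplings across the half-way boundary too.
#' @param seed RNG seed; deterministic per seed.
#' @param n_pairs_per_block Coupled position pairs per block
#'   (default `max(1, round(L/6))`).
#' @return List with elements `human` and `murine`, both
#'   [coupled_model()] objects.
#' @export
make_species_pair <- function(L = 30, divergence = 0.2,
                              coupling_strength = 3, cross_chain = TRUE,
                              seed = 1, n_pairs_per_block = NULL) {
  stopifnot(divergence >= 0, divergence <= 1, L >= 4)
  if (is.null(n_pairs_per_block)) n_pairs_per_block <- max(1L, round(L / 6))
  half <- L %/% 2L
  gap_prob <- 0.02
  withr::with_seed(seed, {
    base <- vapply(seq_len(L), function(i) {
      aa <- rnorm(.Q, sd = 1.2)
      lse <- log(sum(exp(aa)))
      c(aa, log(gap_prob / (1 - gap_prob)) + lse)  # exact 2% gap marginal
    }, numeric(21))
    fields_h <- base
    fields_m <- base
    ndiv <- round(divergence * L)
    if (ndiv > 0) {
      div_pos <- sample.int(L, ndiv)
      fields_m[seq_len(.Q), div_pos] <-
        fields_m[seq_len(.Q), div_pos] + rnorm(.Q * ndiv, sd = 1.5)
    }
    pick_pairs <- function(range_i, range_j, n) {
      pairs <- list()
      for (k in seq_len(n)) {
        i <- sample(range_i, 1); j <- sample(range_j, 1)
        while (j == i) j <- sample(range_j, 1)
        pairs[[k]] <- sort(c(i, j))
      }
      unique(pairs)
    }
    blocks <- c(
      pick_pairs(seq_len(half), seq_len(half), n_pairs_per_block),
      pick_pairs(half + seq_len(L - half), half + seq_len(L - half),
                 n_pairs_per_block),
      if (cross_chain)
        pick_pairs(seq_len(half), half + seq_len(L - half),
                   n_pairs_per_block)
    )
    perm_table <- function() {
      tab <- matrix(0, 21, 21)
      tab[seq_len(.Q), seq_len(.Q)] <-
        coupling_strength * diag(.Q)[sample.int(.Q), ]
      tab
    }
    cp_h <- lapply(blocks, function(p)
      list(i = p[1], j = p[2], table = perm_table()))
    cp_m <- lapply(blocks, function(p)
      list(i = p[1], j = p[2], table = perm_table()))
    list(
      human = coupled_model(L, fields_h, cp_h, seed = seed),
      murine = coupled_model(L, fields_m, cp_m, seed = seed)
    )
  })
}

# fields-only (couplings ignored) per-site marginals of a coupled model
softmax_marginals <- function(fields) {
  apply(fields, 2, function(f) {
    p <- exp(f - max(f)); p / sum(p)
  })
}
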