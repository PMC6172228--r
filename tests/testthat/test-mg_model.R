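test_that("uniform-sample prior moments have the closed form", {
  pr <- uniform_prior_moments(1)
  expect_equal(pr$eta, rep(1 / 21, 20))
  expect_equal(diag(pr$U), rep((1 / 21) * (1 - 1 / 21), 20))
  expect_equal(pr$U[1, 2], -1 / 441)
  ev <- eigen(pr$U, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(min(ev), 1 / 441, tolerance = 1e-12)

  pr2 <- uniform_prior_moments(2)
  expect_equal(pr2$U[1:20, 21:40], matrix(0, 20, 20))
})

test_that("fit_mg produces the documented posterior moments", {
  db <- sample_profile_db(profile_model(5, seed = 1), 30, seed = 2)
  lam <- 0.3
  m <- fit_mg(db, lam)
  pr <- uniform_prior_moments(5)
  d <- m$xbar - pr$eta
  expect_equal(m$mu_post, lam * pr$eta + (1 - lam) * m$xbar)
  expect_equal(m$Sigma_post,
               lam * pr$U + (1 - lam) * m$Cbar +
                 lam * (1 - lam) * tcrossprod(d),
               tolerance = 1e-12)
  expect_equal(m$dof, 30 / 0.7 + 2)
  expect_equal(m$scale, (1 + 0.7 / 30) * m$Sigma_post)
  expect_gt(m$dof, 2)

  # identical sequences: zero empirical covariance
  db1 <- db[rep(1, 10), ]
  db1$id <- paste0("s", 1:10)
  m1 <- fit_mg(db1, lam)
  expect_equal(m1$Cbar, matrix(0, 100, 100))

  # order invariance is bit-exact
  perm <- db[rev(seq_len(nrow(db))), ]
  expect_identical(fit_mg(perm, lam)$Sigma_post, m$Sigma_post)

  expect_error(fit_mg(db, 0), "lambda")
  expect_error(fit_mg(db[0, ], 0.5), "empty")
})

test_that("streaming and batch moment accumulation agree", {
  db <- sample_profile_db(profile_model(6, seed = 4), 40, seed = 5)
  mb <- fit_mg(db, 0.2, engine = "batch")
  ms <- fit_mg(db, 0.2, engine = "streaming")
  expect_lt(max(abs(mb$xbar - ms$xbar)), 1e-13)
  expect_lt(max(abs(mb$Cbar - ms$Cbar)), 1e-12)
  expect_lt(max(abs(mb$Sigma_post - ms$Sigma_post)), 1e-12)
})

test_that("lambda = 1 collapses the posterior onto the prior", {
  db <- sample_profile_db(profile_model(3, seed = 6), 15, seed = 7)
  m <- fit_mg(db, 1)
  pr <- uniform_prior_moments(3)
  expect_identical(m$mu_post, pr$eta)
  expect_equal(m$Sigma_post, pr$U, tolerance = 1e-15)
  expect_true(is.infinite(m$dof))
  # the Gaussian-limit score matches the closed-form normal log-pdf
  y <- encode_onehot(db$residues[1])
  expect_equal(mg_logdensity(m, y),
               dmvnorm_log_oracle(y, pr$eta, pr$U), tolerance = 1e-8)
})

test_that("mg scores equal an independent multivariate-t oracle", {
  for (seed in 1:20) {
    N <- sample(2:12, 1)
    m <- random_toy_model(N, seed)
    y <- withr::with_seed(seed + 1000, rnorm(N))
    expect_equal(mg_logdensity(m, y),
                 dmvt_log_oracle(y, m$dof, m$mu_post, m$scale),
                 tolerance = 1e-10)
  }
})

test_that("scoring a database is deterministic and validates shape", {
  db <- sample_profile_db(profile_model(5, seed = 8), 25, seed = 9)
  m <- fit_mg(db, 0.2)
  s1 <- mg_score(db, m)
  s2 <- mg_score(db, m)
  expect_identical(s1$mg_score, s2$mg_score)
  # byte-identical sequences get identical scores
  expect_equal(s1$mg_score[1],
               mg_score(db[rep(1, 2), ] |>
                          dplyr::mutate(id = c("a", "b")), m)$mg_score[2])
  longer <- db; longer$residues <- paste0(db$residues, "A")
  expect_error(mg_score(longer, m), "does not match model")
})

test_that("mg_max bounds every score and sits at the mode", {
  m <- toy_seq_model(L = 4, M = 30, lam = 0.3, seed = 12)
  expect_equal(mg_max(m), m$log_norm)
  expect_equal(mg_logdensity(m, m$mu_post), mg_max(m))
  withr::with_seed(13, {
    for (rep in 1:200) {
      s <- random_residues(4)
      expect_lte(mg_logdensity(m, encode_onehot(s)), mg_max(m))
    }
  })
})

test_that("single-mutation deltas match full recomputation", {
  m <- toy_seq_model(L = 6, M = 40, lam = 0.25, seed = 20)
  letters21 <- c(aa_alphabet(), "-")
  withr::with_seed(21, {
    for (rep in 1:200) {
      s <- random_residues(6)
      ctx <- mg_score_context(m, s)
      pos <- sample(6, 1)
      aa <- sample(letters21, 1)
      d <- mg_score_delta(m, ctx, pos, aa)
      mut <- s; substr(mut, pos, pos) <- aa
      full <- mg_logdensity(m, encode_onehot(mut)) -
        mg_logdensity(m, encode_onehot(s))
      expect_equal(d, full, tolerance = 1e-9)
      if (substr(s, pos, pos) == aa) expect_identical(d, 0)
    }
  })
  # reversibility: apply then revert returns to the starting score
  s <- random_residues(6, seed = 22)
  ctx <- mg_score_context(m, s)
  s0 <- ctx$score
  old <- substr(s, 3, 3)
  mg_apply_mutation(m, ctx, 3, if (old == "W") "Y" else "W")
  mg_apply_mutation(m, ctx, 3, old)
  expect_equal(ctx$score, s0, tolerance = 1e-9)
  expect_error(mg_score_delta(m, ctx, 99, "A"), "out of range")
})

test_that("correlation ablations zero the documented blocks", {
  db <- sample_coupled_db(
    make_species_pair(L = 6, seed = 3)$human, 50, seed = 4)
  m <- fit_mg(db, 0.3)
  off <- ablate_correlations(m, "all_off")
  pos <- rep(1:6, each = 20)
  cross <- outer(pos, pos, "!=")
  expect_true(all(off$Sigma_post[cross] == 0))
  diag_kept <- !cross
  expect_equal(off$Sigma_post[diag_kept], m$Sigma_post[diag_kept])
  expect_equal(off$meta$ablation, "all_off")

  inter <- ablate_correlations(m, "interchain_off")
  half <- pos <= 3
  between <- outer(half, half, "!=")
  expect_true(all(inter$Sigma_post[between] == 0))
  within <- !between & cross
  expect_equal(inter$Sigma_post[within], m$Sigma_post[within])

  # all_off is a fixed point of further ablation
  expect_equal(ablate_correlations(off, "interchain_off")$Sigma_post,
               off$Sigma_post)

  single <- fit_mg(dplyr::mutate(db, chain = "VH"), 0.3)
  expect_error(ablate_correlations(single, "interchain_off"), "VHVL")
})

test_that("model serialization round-trips scores bit-exactly", {
  m <- toy_seq_model(L = 5, M = 30, lam = 0.2, seed = 30)
  path <- tempfile(fileext = ".rds")
  write_mg_model(m, path)
  m2 <- read_mg_model(path)
  s <- random_residues(5, seed = 31)
  expect_identical(mg_logdensity(m, encode_onehot(s)),
                   mg_logdensity(m2, encode_onehot(s)))
})

test_that("tidy and glance summarize a fitted model", {
  m <- toy_seq_model(L = 3, M = 20, lam = 0.4, seed = 40)
  td <- tidy(m)
  expect_equal(nrow(td), 3 * 20)
  expect_equal(unique(td$position), 1:3)
  gl <- glance(m)
  expect_equal(gl$lambda, 0.4)
  expect_equal(gl$mg_max, mg_max(m))
})
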