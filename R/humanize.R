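# CDR-preserving optimization of the MG energy E = -mg_score by greedy
# steepest descent (SD) and simulated-annealing Metropolis Monte Carlo
# (SAMC). CDR positions are frozen; by default gaps are neither proposed
# nor removed (allow_gaps = FALSE), keeping the fixed-length framework
# free of indel artifacts.

#' Annealing schedule for SAMC humanization
#'
#' The default "desk" preset keeps the published temperature ladder
#' (start T = 25.1, cool by 0.5 down to 0.1) at 20,000 proposals per
#' level; the `"full"` preset uses the complete 3,740,000 proposals per
#' level (~1.9e8 total — cluster scale).
#'
#' @param t_init,t_final,dt Temperature ladder: start, floor, decrement.
#' @param steps_per_t Proposals per temperature level.
#' @param preset `"desk"` or `"full"` (sets `steps_per_t`).
#' @return List of class `anneal_schedule`.
#' @export
anneal_schedule <- function(t_init = 25.1, t_final = 0.1, dt = 0.5,
                            steps_per_t = NULL,
                            preset = c("desk", "full")) {
  preset <- match.arg(preset)
  if (is.null(steps_per_t))
    steps_per_t <- if (preset == "full") 3740000L else 20000L
  if (!(t_init >= t_final && t_final > 0 && dt > 0))
    abort("invalid schedule: need t_init >= t_final > 0 and dt > 0")
  structure(list(t_init = t_init, t_final = t_final, dt = dt,
                 steps_per_t = as.integer(steps_per_t), preset = preset),
            class = "anneal_schedule")
}

schedule_temperatures <- function(s) {
  n <- floor((s$t_init - s$t_final) / s$dt + 1e-9) + 1
  s$t_init - s$dt * (seq_len(n) - 1)
}

# allowed mutation target states (ranks into .STATES)
allowed_states <- function(allow_gaps, alphabet = NULL) {
  letters20 <- if (is.null(alphabet)) .AA else {
    bad <- setdiff(alphabet, .AA)
    if (length(bad) > 0)
      abort(sprintf("alphabet contains non-amino-acid letters: %s",
                    paste(bad, collapse = ",")))
    sort(unique(alphabet))
  }
  st <- match(letters20, .STATES)
  if (allow_gaps) st <- c(st, 21L)
  st
}

new_humanization <- function(origin, method, seed, steps, final_states,
                             best_states, best_score, mask, model,
                             schedule = NULL) {
  structure(list(
    origin = origin, method = method, seed = seed, steps = steps,
    final = states_to_residues(final_states),
    best = states_to_residues(best_states),
    best_score = best_score,
    mask = mask, model_id = model$meta$model_id, schedule = schedule
  ), class = "humanization")
}

#' Steepest-descent humanization
#'
#' At every step, evaluates all single mutations at all non-CDR positions
#' and applies the one with the largest strict score increase; stops when
#' no mutation improves the score (a local optimum of the MG energy).
#' Deterministic; ties broken toward the lowest position, then the
#' alphabetically first residue.
#'
#' @param model Fitted `mg_model` (typically learned on human sequences).
#' @param origin Starting (murine) sequence: residue string or one-row
#'   tibble matching the model.
#' @param mask [cdr_mask()] (or integer positions) held fixed. `NULL`
#'   leaves every position free.
#' @param allow_gaps Allow proposing/removing gaps (default `FALSE`).
#' @param alphabet Optional restricted set of target amino acids.
#' @param max_steps Safety cap on accepted mutations.
#' @return A `humanization` object; `$steps` records every accepted
#'   mutation with its score and Hamming distance from the origin.
#' @export
humanize_sd <- function(model, origin, mask = NULL, allow_gaps = FALSE,
                        alphabet = NULL, max_steps = Inf) {
  origin <- as_residues(origin)
  L <- model$meta$L
  check_residues(origin, L, "<origin>")
  fixed <- mask_positions(mask, L)
  free <- setdiff(seq_len(L), fixed)
  if (length(free) == 0) abort("mask freezes every position")
  allowed <- allowed_states(allow_gaps, alphabet)
  ctx <- mg_score_context(model, origin)
  origin_states <- ctx$states
  hd <- 0L
  rec <- list(step = integer(), position = integer(),
              from = character(), to = character(),
              score_after = numeric(), hd_to_origin = integer())
  step <- 0L
  repeat {
    mv <- sd_best_move(ctx, free, allowed)
    if (is.null(mv) || step >= max_steps) break
    step <- step + 1L
    a <- ctx$states[mv$pos]
    apply_state(model, ctx, mv$pos, mv$state)
    hd <- hd + (mv$state != origin_states[mv$pos]) -
      (a != origin_states[mv$pos])
    rec$step <- c(rec$step, step)
    rec$position <- c(rec$position, mv$pos)
    rec$from <- c(rec$from, .STATES[a])
    rec$to <- c(rec$to, .STATES[mv$state])
    rec$score_after <- c(rec$score_after, ctx$score)
    rec$hd_to_origin <- c(rec$hd_to_origin, hd)
  }
  steps <- as_tibble(rec)
  new_humanization(origin, "SD", NA_integer_, steps,
                   ctx$states, ctx$states, ctx$score, fixed, model)
}

# best strictly-improving single mutation: minimal delta-q < 0
sd_best_move <- function(ctx, free, allowed) {
  best <- NULL
  best_dq <- -1e-12   # strict improvement required
  for (pos in free) {
    a <- ctx$states[pos]
    cand <- allowed[allowed != a]
    if (length(cand) == 0) next
    base <- if (a <= .Q) {
      j1 <- (pos - 1L) * .Q + a
      -2 * ctx$v[j1] + ctx$Sdiag[j1]
    } else 0
    c20 <- cand[cand <= .Q]
    dq <- rep(base, length(cand))
    if (length(c20) > 0) {
      j2 <- (pos - 1L) * .Q + c20
      term <- 2 * ctx$v[j2] + ctx$Sdiag[j2]
      if (a <= .Q) term <- term - 2 * ctx$Sinv[(pos - 1L) * .Q + a, j2]
      dq[cand <= .Q] <- base + term
    }
    k <- which.min(dq)
    if (dq[k] < best_dq) {
      best_dq <- dq[k]
      best <- list(pos = pos, state = cand[k], dq = dq[k])
    }
  }
  best
}

#' Simulated-annealing Monte Carlo humanization
#'
#' Metropolis sampling of the MG energy `E = -mg_score`: each proposal
#' mutates a uniformly drawn non-CDR position to a uniformly drawn
#' alternative residue and is accepted with probability
#' `min(1, exp(delta_score / T))`. The temperature drops by `dt` after
#' `steps_per_t` proposals until it falls below `t_final`. The best-ever
#' sequence (not the final one) is the headline output, since low-T
#' trapping can end off-optimum. Identical seeds give byte-identical
#' trajectories.
#'
#' @inheritParams humanize_sd
#' @param schedule An [anneal_schedule()].
#' @param seed Mandatory RNG seed.
#' @return A `humanization` object; `$steps` records accepted proposals
#'   with their global proposal index and temperature.
#' @export
humanize_samc <- function(model, origin, mask = NULL,
                          schedule = anneal_schedule(), seed,
                          allow_gaps = FALSE, alphabet = NULL) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    abort("SAMC requires an explicit seed")
  stopifnot(inherits(schedule, "anneal_schedule"))
  origin <- as_residues(origin)
  L <- model$meta$L
  check_residues(origin, L, "<origin>")
  fixed <- mask_positions(mask, L)
  free <- setdiff(seq_len(L), fixed)
  if (length(free) == 0) abort("mask freezes every position")
  allowed <- allowed_states(allow_gaps, alphabet)
  K <- length(allowed)
  if (K < 2) abort("need at least two allowed residue states")
  rank_of <- rep(NA_integer_, 21L)
  rank_of[allowed] <- seq_len(K)

  ctx <- mg_score_context(model, origin)
  origin_states <- ctx$states
  hd <- 0L
  best_score <- ctx$score
  best_states <- ctx$states
  temps <- schedule_temperatures(schedule)
  spt <- schedule$steps_per_t
  nfree <- length(free)

  cap <- 1024L
  r_step <- integer(cap); r_temp <- numeric(cap); r_pos <- integer(cap)
  r_from <- integer(cap); r_to <- integer(cap)
  r_score <- numeric(cap); r_hd <- integer(cap)
  nrec <- 0L

  withr::with_seed(seed, {
    gstep <- 0L
    for (Tcur in temps) {
      refresh_context(model, ctx)   # stop incremental rounding drift
      upos <- runif(spt); ures <- runif(spt); uacc <- runif(spt)
      for (s in seq_len(spt)) {
        gstep <- gstep + 1L
        pos <- free[1L + floor(upos[s] * nfree)]
        a <- ctx$states[pos]
        ar <- rank_of[a]
        idx <- if (is.na(ar)) {
          1L + floor(ures[s] * K)
        } else {
          i0 <- 1L + floor(ures[s] * (K - 1L))
          i0 + (i0 >= ar)
        }
        b <- allowed[idx]
        dq <- delta_q(ctx, pos, a, b)
        dscore <- score_from_q(model, ctx$q + dq) - ctx$score
        if (dscore >= 0 || uacc[s] < exp(dscore / Tcur)) {
          apply_state(model, ctx, pos, b)
          hd <- hd + (b != origin_states[pos]) - (a != origin_states[pos])
          nrec <- nrec + 1L
          if (nrec > cap) {
            cap <- cap * 2L
            length(r_step) <- cap; length(r_temp) <- cap
            length(r_pos) <- cap; length(r_from) <- cap
            length(r_to) <- cap; length(r_score) <- cap
            length(r_hd) <- cap
          }
          r_step[nrec] <- gstep; r_temp[nrec] <- Tcur
          r_pos[nrec] <- pos; r_from[nrec] <- a; r_to[nrec] <- b
          r_score[nrec] <- ctx$score; r_hd[nrec] <- hd
          if (ctx$score > best_score) {
            best_score <- ctx$score
            best_states <- ctx$states
          }
        }
      }
    }
  })
  idx <- seq_len(nrec)
  steps <- tibble(
    step = r_step[idx], temperature = r_temp[idx], position = r_pos[idx],
    from = .STATES[r_from[idx]], to = .STATES[r_to[idx]],
    score_after = r_score[idx], hd_to_origin = r_hd[idx])
  out <- new_humanization(origin, "SAMC", seed, steps,
                          ctx$states, best_states, best_score, fixed,
                          model, schedule)
  out$n_proposals <- length(temps) * spt
  out
}

#' @export
print.humanization <- function(x, ...) {
  cat(sprintf(
    "<humanization> %s: %d accepted mutations, best score %.4f, final HD %d\n",
    x$method, nrow(x$steps), x$best_score,
    hamming_distance(x$origin, x$final)))
  invisible(x)
}

#' @export
tidy.humanization <- function(x, ...) x$steps

#' @export
glance.humanization <- function(x, ...) {
  tibble(method = x$method, seed = x$seed, n_accepted = nrow(x$steps),
         best_score = x$best_score,
         hd_final = hamming_distance(x$origin, x$final),
         hd_best = hamming_distance(x$origin, x$best),
         model_id = x$model_id)
}

#' Triple comparison of original, humanized and predicted sequences
#'
#' Classifies every compared (non-CDR) position of the triple
#' (original murine `o`, experimentally humanized `h`, predicted `p`) by
#' the residue pattern: `(A,A,A)` TN; `(A,A,B)` and `(A,B,C)` FP;
#' `(A,B,A)` FN; `(A,B,B)` TP — i.e. a "positive" is a predicted mutation
#' away from the original, true when the experimental humanization made
#' the same change. `HD(p,h) = FP + FN` follows.
#'
#' @param original,humanized,predicted Equal-length residue strings (or
#'   one-row tibbles).
#' @param mask Optional [cdr_mask()] excluded from the comparison.
#' @return One-row tibble `tp, fp, tn, fn, tpr, fpr, youden, hd_po,
#'   hd_ho`.
#' @export
compare_to_reference <- function(original, humanized, predicted,
                                 mask = NULL) {
  o <- as_residues(original); h <- as_residues(humanized)
  p <- as_residues(predicted)
  L <- nchar(o)
  if (nchar(h) != L || nchar(p) != L)
    abort("the three sequences must have equal length")
  keep <- setdiff(seq_len(L), mask_positions(mask, L))
  so <- strsplit(o, "")[[1]][keep]
  sh <- strsplit(h, "")[[1]][keep]
  sp <- strsplit(p, "")[[1]][keep]
  tn <- sum(so == sh & so == sp)
  fp <- sum((so == sh & sp != so) | (so != sh & sp != so & sp != sh))
  fn <- sum(so != sh & sp == so)
  tp <- sum(so != sh & sp == sh)
  cs <- confusion_stats(tp = tp, fp = fp, tn = tn, fn = fn)
  dplyr::mutate(cs, hd_po = sum(sp != so), hd_ho = sum(sh != so))
}

#' Write a humanization trajectory to disk
#'
#' Emits the accepted-move TSV, a FASTA with the origin/final/best
#' sequences, and a JSON run manifest (seed, schedule, model id, mask).
#'
#' @param traj A `humanization` object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return The manifest path, invisibly.
#' @export
write_humanization <- function(traj, dir, prefix = "humanization") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, paste0(prefix, "_steps.tsv"))
  write.table(traj$steps, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  fa <- file.path(dir, paste0(prefix, ".fasta"))
  db <- tibble(id = c("origin", "final", "best"), chain = "VHVL",
               residues = c(traj$origin, traj$final, traj$best))
  set <- Biostrings::AAStringSet(setNames(db$residues, db$id))
  Biostrings::writeXStringSet(set, fa)
  manifest <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(list(
    method = traj$method, seed = traj$seed, model_id = traj$model_id,
    mask = traj$mask, schedule = unclass(traj$schedule),
    best_score = traj$best_score, n_accepted = nrow(traj$steps)
  ), manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
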