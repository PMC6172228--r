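# ROC construction, Youden/MCC diagnostics, threshold and lambda
# selection, and one-/two-reference classification.

#' Confusion-matrix statistics
#'
#' Youden's index (default: sensitivity + specificity - 1 = TPR - FPR),
#' the Matthews Correlation Coefficient, TPR and FPR. A variant Youden
#' formula `TPR + TN/(TN+FN) - 1` is available behind
#' `formula = "printed"` for comparison; the standard definition is the
#' default because published threshold diagnostics for this scheme are
#' consistent with TPR - FPR. MCC with a zero denominator is defined as 0.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @param formula `"standard"` or `"printed"` Youden variant.
#' @return One-row tibble `tp, fp, tn, fn, tpr, fpr, youden, mcc`.
#' @export
#' @examples
#' confusion_stats(tp = 90, fn = 10, fp = 7, tn = 93)$youden  # 0.83
confusion_stats <- function(tp, fp, tn, fn,
                            formula = c("standard", "printed")) {
  formula <- match.arg(formula)
  if (any(c(tp, fp, tn, fn) < 0)) abort("counts must be non-negative")
  if (tp + fp + tn + fn == 0) abort("all confusion counts are zero")
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  fpr <- if (tn + fp > 0) fp / (tn + fp) else NA_real_
  youden <- if (formula == "standard") {
    tpr - fpr
  } else {
    tpr + (if (tn + fn > 0) tn / (tn + fn) else NA_real_) - 1
  }
  denom <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc <- if (denom == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / denom
  tibble(tp = tp, fp = fp, tn = tn, fn = fn,
         tpr = tpr, fpr = fpr, youden = youden, mcc = mcc)
}

#' ROC curve over a threshold sweep
#'
#' Sweeps every distinct score value plus infinities as thresholds,
#' classifying positive at `score >= t` (`higher_is_positive`, e.g. MG
#' scores) or `score <= t` (`lower_is_positive`, e.g. distances). AUC is
#' the trapezoid area, equal to the Mann-Whitney concordance
#' (ties counted 1/2).
#'
#' @param scores_pos Scores of the positive (human) class.
#' @param scores_neg Scores of the negative (murine) class.
#' @param direction Which way the score points at the positive class.
#' @return An object of class `mg_roc`: sweep tibble plus `auc`,
#'   `best_threshold`, `best_youden`, `best_mcc`, `direction`.
#' @export
roc_curve <- function(scores_pos, scores_neg,
                      direction = c("higher_is_positive",
                                    "lower_is_positive")) {
  direction <- match.arg(direction)
  if (length(scores_pos) == 0 || length(scores_neg) == 0)
    abort("score arrays must be non-empty")
  P <- length(scores_pos); N <- length(scores_neg)
  thr <- sort(unique(c(-Inf, scores_pos, scores_neg, Inf)))
  cmp <- if (direction == "higher_is_positive") `>=` else `<=`
  stats <- purrr::map_dfr(thr, function(t) {
    tp <- sum(cmp(scores_pos, t)); fp <- sum(cmp(scores_neg, t))
    cbind(threshold = t,
          confusion_stats(tp = tp, fp = fp, tn = N - fp, fn = P - tp))
  })
  ord <- order(stats$fpr, stats$tpr)
  auc <- sum(diff(stats$fpr[ord]) *
               (head(stats$tpr[ord], -1) + tail(stats$tpr[ord], -1)) / 2)
  best <- best_sweep_row(stats, "youden")
  structure(list(
    sweep = stats, auc = auc, direction = direction,
    n_pos = P, n_neg = N,
    best_threshold = stats$threshold[best],
    best_youden = stats$youden[best],
    best_mcc = max(stats$mcc)
  ), class = "mg_roc")
}

# index of the sweep row maximizing a criterion; ties broken toward the
# threshold classifying fewer positives, then first occurrence
best_sweep_row <- function(sweep, criterion) {
  val <- sweep[[criterion]]
  cand <- which(val == max(val))
  if (length(cand) > 1) {
    npos <- sweep$tp[cand] + sweep$fp[cand]
    cand <- cand[npos == min(npos)]
  }
  cand[1]
}

#' Pick the operating threshold from a ROC sweep
#'
#' Returns the threshold maximizing Youden's index (or MCC). The chosen
#' threshold is meant to be frozen and reused on later data (therapeutic
#' antibodies, humanization), never re-optimized per query set.
#'
#' @param roc An `mg_roc` from [roc_curve()].
#' @param criterion `"youden"` or `"mcc"`.
#' @return The selected threshold (numeric scalar).
#' @export
select_threshold <- function(roc, criterion = c("youden", "mcc")) {
  criterion <- match.arg(criterion)
  roc$sweep$threshold[best_sweep_row(roc$sweep, criterion)]
}

#' @export
print.mg_roc <- function(x, ...) {
  cat(sprintf(
    "<mg_roc> %d pos / %d neg, %s\n  AUC = %.4f  best threshold = %.6g  Youden = %.4f  MCC = %.4f\n",
    x$n_pos, x$n_neg, x$direction, x$auc, x$best_threshold,
    x$best_youden, x$best_mcc))
  invisible(x)
}

#' @export
tidy.mg_roc <- function(x, ...) as_tibble(x$sweep)

#' @export
glance.mg_roc <- function(x, ...) {
  tibble(auc = x$auc, best_threshold = x$best_threshold,
         best_youden = x$best_youden, best_mcc = x$best_mcc,
         n_pos = x$n_pos, n_neg = x$n_neg, direction = x$direction)
}

#' Write a ROC sweep and its summary to disk
#'
#' @param roc An `mg_roc`.
#' @param tsv_path Path for the threshold/tpr/fpr TSV.
#' @param json_path Optional path for the summary JSON.
#' @return `tsv_path`, invisibly.
#' @export
write_roc <- function(roc, tsv_path, json_path = NULL) {
  write.table(roc$sweep[, c("threshold", "tpr", "fpr")], tsv_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(as.list(glance(roc)), json_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(tsv_path)
}

#' Select the regularization lambda by validation AUC
#'
#' Fits one model per grid value on the learning database (optionally
#' ablated), scores a positive and a negative validation database, and
#' returns the lambda with maximal ROC AUC. Validation sets must be
#' explicit — the learning or final test sets are never silently reused.
#' Ties go to the smaller lambda.
#'
#' @param learn Learning database.
#' @param val_pos,val_neg Validation databases (positive = same species
#'   as `learn`).
#' @param grid Numeric vector of candidate lambdas in (0, 1]. Default: 21
#'   log-spaced values in `[0.005, 0.5]`.
#' @param ablation Optional [ablate_correlations()] mode applied to every
#'   fitted model before scoring.
#' @return List with `lambda` (selected value) and `auc_by_lambda`
#'   (tibble `lambda`, `auc`).
#' @export
select_lambda <- function(learn, val_pos, val_neg,
                          grid = default_lambda_grid(), ablation = NULL) {
  if (length(grid) == 0) abort("lambda grid is empty")
  if (any(grid <= 0 | grid > 1)) abort("lambda grid must lie in (0, 1]")
  grid <- sort(grid)
  aucs <- vapply(grid, function(lam) {
    model <- fit_mg(learn, lam)
    if (!is.null(ablation)) model <- ablate_correlations(model, ablation)
    sp <- mg_score(val_pos, model)$mg_score
    sn <- mg_score(val_neg, model)$mg_score
    roc_curve(sp, sn, "higher_is_positive")$auc
  }, numeric(1))
  tab <- tibble(lambda = grid, auc = aucs)
  list(lambda = grid[which.max(aucs)], auc_by_lambda = tab)
}

#' @rdname select_lambda
#' @export
default_lambda_grid <- function() {
  exp(seq(log(0.005), log(0.5), length.out = 21))
}

#' Classify query sequences as human or non-human
#'
#' One-reference modes score against a single (human) model or ensemble
#' and compare with a frozen threshold; two-reference modes compare the
#' human and murine scores directly. Exact ties in two-reference modes are
#' labelled non-human (conservative for humanization use).
#'
#' @param queries Query database tibble.
#' @param mode One of `"mg_one_ref"`, `"mg_two_ref"`, `"t_k_one_ref"`,
#'   `"t_k_two_ref"`.
#' @param model,model_m Human / murine `mg_model` (MG modes).
#' @param ref,ref_m Human / murine reference databases (distance modes).
#' @param k Neighbourhood size for distance modes (or `"all"`).
#' @param threshold Frozen threshold (required for one-reference modes;
#'   MG: human at `score >= threshold`; distance: human at
#'   `score <= threshold`).
#' @param exclude Optional mask for distance modes.
#' @return Tibble `id`, `score`, `label` (`"human"`/`"non-human"`).
#' @export
classify_sequences <- function(queries,
                               mode = c("mg_one_ref", "mg_two_ref",
                                        "t_k_one_ref", "t_k_two_ref"),
                               model = NULL, model_m = NULL,
                               ref = NULL, ref_m = NULL, k = 1,
                               threshold = NULL, exclude = NULL) {
  mode <- match.arg(mode)
  queries <- validate_seq_db(queries)
  if (mode %in% c("mg_one_ref", "t_k_one_ref") && is.null(threshold))
    abort(sprintf("mode '%s' requires a frozen threshold", mode))
  out <- switch(mode,
    mg_one_ref = {
      s <- mg_score(queries, model)$mg_score
      tibble(id = queries$id, score = s,
             label = ifelse(s >= threshold, "human", "non-human"))
    },
    mg_two_ref = {
      sh <- mg_score(queries, model)$mg_score
      sm <- mg_score(queries, model_m)$mg_score
      tibble(id = queries$id, score = sh - sm,
             label = ifelse(sh > sm, "human", "non-human"))
    },
    t_k_one_ref = {
      s <- t_k_score(queries, ref, k = k, exclude = exclude)$score
      tibble(id = queries$id, score = s,
             label = ifelse(s <= threshold, "human", "non-human"))
    },
    t_k_two_ref = {
      s <- two_reference_score(queries, ref, ref_m, exclude = exclude)$score
      tibble(id = queries$id, score = s,
             label = ifelse(s > 0, "human", "non-human"))
    })
  out
}
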