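# Evaluation suite: protein-centric Fmax over a 100-point threshold grid,
# term-centric F1 / AUPR / AUC / MCC, the true-path-rule conflict score, the
# term co-occurrence heatmap and its MSE against the training ground truth,
# and the per-height / per-sample-count F1 breakdowns.
#
# Conventions (documented, configurable where noted): a prediction is
# positive when score >= t; 0/0 precision is 0 and the protein still counts
# in the protein average (the CAFA refinement that averages precision over
# proteins with at least one prediction is available via `protein_average`);
# terms without a positive (or, for AUC, without both classes) are undefined
# and excluded from macro averages.

#' Evaluation threshold grid
#'
#' 100 evenly spaced thresholds spanning `[0, 1]` (0 and 1 included).
#'
#' @export
threshold_grid <- function() seq(0, 1, length.out = 100L)

.check_pair <- function(truth, scores) {
  truth <- as.matrix(truth); scores <- as.matrix(scores)
  if (!all(dim(truth) == dim(scores)))
    stop("truth and scores must have identical shapes")
  if (nrow(truth) == 0L) stop("empty protein set")
  if (!all(truth %in% c(0, 1))) stop("truth must be binary")
  list(truth = truth, scores = scores)
}

#' Per-protein precision and recall at a threshold
#'
#' @param truth binary vector for one protein.
#' @param scores score vector for the same protein.
#' @param t threshold; predicted positive iff `score >= t`.
#' @return Named vector with `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
protein_prf <- function(truth, scores, t) {
  pred <- scores >= t
  tp <- sum(pred & truth == 1)
  fp <- sum(pred & truth == 0)
  fn <- sum(!pred & truth == 1)
  c(precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    recall = if (tp + fn > 0) tp / (tp + fn) else 0,
    tp = tp, fp = fp, fn = fn)
}

#' Protein-centric Fmax
#'
#' For each threshold in the grid, precision and recall are computed per
#' protein and averaged over all proteins; Fmax is the maximum over the grid
#' of the harmonic mean of the two averages.
#'
#' @param truth binary annotation matrix (proteins x terms).
#' @param scores score matrix of the same shape.
#' @param grid threshold vector (default [threshold_grid()]).
#' @param protein_average `"plain"` counts every protein in the precision
#'   average (0/0 precision = 0); `"cafa"` averages precision only over
#'   proteins with at least one prediction above the threshold.
#' @return List with `fmax`, `threshold` (first maximising threshold) and
#'   `curve` (per-threshold average precision/recall/F).
#' @export
fmax <- function(truth, scores, grid = threshold_grid(),
                 protein_average = c("plain", "cafa")) {
  protein_average <- match.arg(protein_average)
  ck <- .check_pair(truth, scores)
  truth <- ck$truth; scores <- ck$scores
  curve <- vapply(grid, function(t) {
    pred <- scores >= t
    tp <- rowSums(pred & truth == 1)
    fp <- rowSums(pred & truth == 0)
    fn <- rowSums(!pred & truth == 1)
    prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
    rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
    ap <- if (protein_average == "cafa") {
      covered <- tp + fp > 0
      if (any(covered)) mean(prec[covered]) else 0
    } else mean(prec)
    ar <- mean(rec)
    f <- if (ap + ar > 0) 2 * ap * ar / (ap + ar) else 0
    c(precision = ap, recall = ar, f = f)
  }, c(precision = 0, recall = 0, f = 0))
  i <- which.max(curve["f", ])
  list(fmax = unname(curve["f", i]), threshold = grid[i],
       curve = data.frame(threshold = grid, t(curve)))
}

#' Term-centric F1
#'
#' Maximum over the threshold grid of the F1 of one term's column, with
#' tp/fp/fn counted over proteins.  Terms with no positive protein are
#' undefined (NA).
#'
#' @param truth binary vector over proteins for one term.
#' @param scores score vector for the same term.
#' @param grid threshold vector.
#' @return F1 in `[0, 1]`, or NA for an all-negative column.
#' @export
term_f1 <- function(truth, scores, grid = threshold_grid()) {
  if (sum(truth == 1) == 0L) return(NA_real_)
  f <- vapply(grid, function(t) {
    pred <- scores >= t
    tp <- sum(pred & truth == 1)
    fp <- sum(pred & truth == 0)
    fn <- sum(!pred & truth == 1)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- tp / (tp + fn)
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }, 0)
  max(f)
}

#' Term-centric area under the precision-recall curve
#'
#' Trapezoidal integration over the PR points at the unique score cut
#' points (thresholding at `score >= cut`), with the curve anchored at
#' recall 0 using the precision of the first point.
#'
#' @inheritParams term_f1
#' @return AUPR in `[0, 1]`, or NA for an all-negative column.
#' @export
term_aupr <- function(truth, scores) {
  npos <- sum(truth == 1)
  if (npos == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  ts <- truth[ord]; ss <- scores[ord]
  cum_tp <- cumsum(ts == 1)
  n_pred <- seq_along(ss)
  last <- !duplicated(ss, fromLast = TRUE) # last index of each distinct score
  tp <- cum_tp[last]
  np <- n_pred[last]
  prec <- tp / np
  rec <- tp / npos
  sum(diff(c(0, rec)) * (prec + c(prec[1], prec[-length(prec)])) / 2)
}

#' Term-centric AUC and MCC
#'
#' AUC is the rank statistic (probability that a positive outscores a
#' negative, ties counted one half); MCC is computed from the confusion
#' matrix at `mcc_threshold`, with the convention MCC = 0 when any marginal
#' is zero.
#'
#' @inheritParams term_f1
#' @param mcc_threshold binarisation threshold for the MCC (default 0.5 on
#'   the `[0, 1]` score scale).
#' @return Named vector `c(auc, mcc)`; `auc` is NA unless the column has at
#'   least one positive and one negative.
#' @export
term_auc_mcc <- function(truth, scores, mcc_threshold = 0.5) {
  npos <- sum(truth == 1)
  nneg <- sum(truth == 0)
  auc <- if (npos == 0L || nneg == 0L) NA_real_
  else (sum(rank(scores)[truth == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  pred <- scores >= mcc_threshold
  tp <- as.numeric(sum(pred & truth == 1))
  fp <- as.numeric(sum(pred & truth == 0))
  fn <- as.numeric(sum(!pred & truth == 1))
  tn <- as.numeric(sum(!pred & truth == 0))
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  c(auc = auc, mcc = mcc)
}

#' True-path-rule conflict score
#'
#' Expected number of conflicts per protein: for every annotated term, the
#' number of its ancestors (restricted to the evaluated term set) that are
#' missing from the protein's annotation, summed over terms and averaged
#' over proteins.  Exactly 0 on any true-path propagated matrix.
#'
#' @param dag an [ontology_dag].
#' @param predicted binary (thresholded) annotation matrix, proteins x terms.
#' @return Non-negative scalar.
#' @export
tpr_score <- function(dag, predicted) {
  predicted <- .check_annotation_matrix(predicted)
  terms <- colnames(predicted)
  missing <- setdiff(terms, dag$terms)
  if (length(missing)) stop("unknown terms: ", paste(missing, collapse = ", "))
  A <- .ancestor_matrix(dag, terms)
  anc_count <- rowSums(A)
  # per protein: sum_t y_t * |anc(t)| - y' A y
  covered <- rowSums((predicted %*% t(A)) * predicted)
  mean(as.numeric(predicted %*% anc_count) - covered)
}

#' Term co-occurrence heatmap
#'
#' Binary c x c matrix whose (i, j) entry is 1 iff at least one protein
#' carries both terms; the diagonal marks terms annotated at least once.
#'
#' @param assignments binary matrix, proteins x terms.
#' @return Symmetric binary matrix with the terms as dimnames.
#' @export
cooccurrence_heatmap <- function(assignments) {
  M <- as.matrix(assignments)
  if (!all(M %in% c(0, 1))) stop("assignments must be binary")
  H <- (crossprod(M) > 0) + 0
  dimnames(H) <- list(colnames(M), colnames(M))
  H
}

#' Mean squared error between two binary heatmaps
#'
#' For binary inputs this equals the fraction of disagreeing entries over
#' all c^2 cells.
#'
#' @param predicted,truth binary c x c matrices of identical shape.
#' @return MSE in `[0, 1]`.
#' @export
heatmap_mse <- function(predicted, truth) {
  predicted <- as.matrix(predicted); truth <- as.matrix(truth)
  if (!all(dim(predicted) == dim(truth)))
    stop("heatmaps must have identical shapes")
  mean((predicted - truth)^2)
}

#' Mean term F1 per DAG height
#'
#' @param dag an [ontology_dag].
#' @param f1 named vector of per-term F1 values (NA = undefined, excluded).
#' @return `data.frame` with `height`, `mean_f1` and `n_terms`.
#' @export
f1_by_height <- function(dag, f1) {
  h <- term_heights(dag)[names(f1)]
  ok <- !is.na(f1)
  agg <- tapply(f1[ok], h[ok], mean)
  data.frame(height = as.integer(names(agg)), mean_f1 = as.numeric(agg),
             n_terms = as.integer(table(h[ok])[names(agg)]))
}

#' Term F1 against positive-sample count
#'
#' @param truth binary annotation matrix (proteins x terms).
#' @param f1 named per-term F1 vector (NA excluded).
#' @return `data.frame` with `term`, `n_pos`, `f1`.
#' @export
f1_by_sample_count <- function(truth, f1) {
  truth <- as.matrix(truth)
  n_pos <- colSums(truth == 1)[names(f1)]
  ok <- !is.na(f1)
  data.frame(term = names(f1)[ok], n_pos = as.integer(n_pos[ok]),
             f1 = as.numeric(f1[ok]), row.names = NULL)
}

#' Full evaluation report
#'
#' Computes every metric of the suite for one truth/score pair: Fmax (with
#' its maximising threshold), per-term F1/AUPR/AUC/MCC and their macro
#' averages (undefined terms excluded, exclusion counted), the
#' true-path-rule conflict score and the co-occurrence heatmap MSE of the
#' predictions binarised at the Fmax-maximising threshold, and the
#' per-height / per-sample-count F1 breakdowns when a DAG is supplied.
#'
#' @param truth binary annotation matrix (proteins x terms, named columns).
#' @param scores score matrix of the same shape.
#' @param dag optional [ontology_dag] for TPR score and height breakdown.
#' @param grid threshold grid.
#' @param mcc_threshold threshold for the MCC.
#' @param binarize_threshold threshold used for the heatmap and TPR score;
#'   defaults to the Fmax-maximising threshold of this very evaluation.
#' @return Object of class `pfp_eval`.
#' @export
evaluate_predictions <- function(truth, scores, dag = NULL,
                                 grid = threshold_grid(),
                                 mcc_threshold = 0.5,
                                 binarize_threshold = NULL) {
  ck <- .check_pair(truth, scores)
  truth <- ck$truth; scores <- ck$scores
  fm <- fmax(truth, scores, grid)
  c <- ncol(truth)
  terms <- colnames(truth)
  f1 <- vapply(seq_len(c), function(j) term_f1(truth[, j], scores[, j], grid), 0)
  aupr <- vapply(seq_len(c), function(j) term_aupr(truth[, j], scores[, j]), 0)
  aucmcc <- vapply(seq_len(c), function(j)
    term_auc_mcc(truth[, j], scores[, j], mcc_threshold), c(auc = 0, mcc = 0))
  names(f1) <- names(aupr) <- terms
  auc <- setNames(aucmcc["auc", ], terms)
  mcc <- setNames(aucmcc["mcc", ], terms)
  thr <- if (is.null(binarize_threshold)) fm$threshold else binarize_threshold
  pred_bin <- (scores >= thr) + 0
  colnames(pred_bin) <- terms
  out <- list(
    fmax = fm$fmax, fmax_threshold = fm$threshold, curve = fm$curve,
    per_term = data.frame(term = terms, n_pos = as.integer(colSums(truth)),
                          f1 = f1, aupr = aupr, auc = auc, mcc = mcc,
                          row.names = NULL),
    macro_f1 = mean(f1, na.rm = TRUE),
    macro_aupr = mean(aupr, na.rm = TRUE),
    macro_auc = mean(auc, na.rm = TRUE),
    macro_mcc = mean(mcc, na.rm = TRUE),
    n_undefined = sum(is.na(f1)),
    binarize_threshold = thr,
    pred_heatmap = cooccurrence_heatmap(pred_bin),
    truth_heatmap = cooccurrence_heatmap(truth))
  out$heatmap_mse <- heatmap_mse(out$pred_heatmap, out$truth_heatmap)
  if (!is.null(dag)) {
    out$tpr_score <- tpr_score(dag, pred_bin)
    out$by_height <- f1_by_height(dag, f1)
    out$by_sample_count <- f1_by_sample_count(truth, f1)
    out$per_term$height <- term_heights(dag)[terms]
  }
  structure(out, class = "pfp_eval")
}

#' @export
print.pfp_eval <- function(x, ...) {
  cat("Protein function prediction evaluation\n")
  cat(sprintf("  Fmax        %.4f  (threshold %.3f)\n", x$fmax,
              x$fmax_threshold))
  cat(sprintf("  macro F1    %.4f\n", x$macro_f1))
  cat(sprintf("  macro AUPR  %.4f\n", x$macro_aupr))
  cat(sprintf("  macro AUC   %.4f\n", x$macro_auc))
  cat(sprintf("  macro MCC   %.4f\n", x$macro_mcc))
  if (x$n_undefined > 0)
    cat("  (", x$n_undefined, "terms undefined, excluded from macros )\n")
  cat(sprintf("  heatmap MSE %.4f  (binarised at %.3f)\n", x$heatmap_mse,
              x$binarize_threshold))
  if (!is.null(x$tpr_score))
    cat(sprintf("  TPR score   %.4f conflicts/protein\n", x$tpr_score))
  invisible(x)
}

#' Micro-averaged F1 at a threshold
#'
#' F1 over the confusion counts pooled across every protein-term cell.
#'
#' @param truth binary annotation matrix.
#' @param scores score matrix of the same shape.
#' @param t threshold (prediction positive iff score >= t).
#' @export
micro_f1 <- function(truth, scores, t) {
  ck <- .check_pair(truth, scores)
  pred <- ck$scores >= t
  tp <- sum(pred & ck$truth == 1)
  fp <- sum(pred & ck$truth == 0)
  fn <- sum(!pred & ck$truth == 1)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
}
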