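test_that("the threshold grid spans [0, 1] with 100 sorted values", {
  g <- threshold_grid()
  expect_length(g, 100L)
  expect_equal(g[1], 0)
  expect_equal(g[100], 1)
  expect_true(!is.unsorted(g))
})

test_that("per-protein precision/recall follow the counting definitions", {
  truth <- c(1, 1, 0, 1, 0)
  scores <- c(0.9, 0.8, 0.7, 0.1, 0.2)
  out <- protein_prf(truth, scores, 0.5)
  expect_equal(unname(out[c("tp", "fp", "fn")]), c(2, 1, 1))
  expect_equal(unname(out["precision"]), 2 / 3)
  expect_equal(unname(out["recall"]), 2 / 3)
  # no predictions above threshold: 0/0 precision defined as 0
  out2 <- protein_prf(truth, scores, 0.95)
  expect_equal(unname(out2["precision"]), 0)
  expect_equal(unname(out2["recall"]), 0)
  # perfect prediction
  out3 <- protein_prf(truth, truth, 0.5)
  expect_equal(unname(out3[c("precision", "recall")]), c(1, 1))
})

test_that("Fmax is 1 for a perfect predictor and handles one-protein cases", {
  truth <- matrix(c(1, 0, 1, 1, 0, 0, 1, 0), 2, 4)
  fm <- fmax(truth, truth)
  expect_equal(fm$fmax, 1)
  one <- fmax(matrix(c(1, 0), 1, 2), matrix(c(0.9, 0.4), 1, 2))
  expect_equal(one$fmax, 1)
  expect_true(one$threshold > 0.4 && one$threshold <= 0.9)
  expect_error(fmax(truth[0, , drop = FALSE], truth[0, , drop = FALSE]),
               "empty")
})

test_that("fmax, term F1, AUPR and TPR match brute force on random cases", {
  set.seed(61)
  for (rep in 1:50) {
    pair <- random_eval_pair(20, 15)
    expect_equal(fmax(pair$truth, pair$scores)$fmax,
                 bf_fmax(pair$truth, pair$scores), tolerance = 1e-9)
    j <- sample(15, 1)
    expect_equal(term_f1(pair$truth[, j], pair$scores[, j]),
                 bf_term_f1(pair$truth[, j], pair$scores[, j]),
                 tolerance = 1e-9)
    expect_equal(term_aupr(pair$truth[, j], pair$scores[, j]),
                 bf_term_aupr(pair$truth[, j], pair$scores[, j]),
                 tolerance = 1e-9)
  }
  for (rep in 1:10) {
    dag <- random_dag(sample(8:50, 1))
    M <- matrix(rbinom(10 * length(dag$terms), 1, 0.25), 10,
                dimnames = list(NULL, dag$terms))
    expect_equal(tpr_score(dag, M), bf_tpr_score(dag, M), tolerance = 1e-9)
  }
})

test_that("anti-perfect scores still yield a grid maximum (degenerate case)", {
  set.seed(62)
  truth <- matrix(rbinom(12, 1, 0.5), 3, 4)
  scores <- 1 - truth
  expect_equal(fmax(truth, scores)$fmax, bf_fmax(truth, scores),
               tolerance = 1e-12)
})

test_that("term F1 closed form at the all-positive threshold", {
  # constant scores 0.5, prevalence 1/2: the all-positive prediction has
  # precision 1/2 and recall 1, so F1 = 2*(1/2)/(3/2) = 2/3
  truth <- rep(c(1, 0), 10)
  scores <- rep(0.5, 20)
  expect_equal(term_f1(truth, scores), 2 / 3)
  expect_true(is.na(term_f1(rep(0, 20), scores)))
})

test_that("AUPR is 1 for perfect ranking and near prevalence for noise", {
  truth <- c(1, 1, 0, 0, 0)
  expect_equal(term_aupr(truth, c(0.9, 0.8, 0.3, 0.2, 0.1)), 1)
  set.seed(63)
  n <- 10000
  tr <- rbinom(n, 1, 0.15)
  expect_equal(term_aupr(tr, runif(n)), 0.15, tolerance = 0.02)
  expect_true(is.na(term_aupr(rep(0, 5), runif(5))))
})

test_that("AUC is the rank statistic and MCC follows the confusion matrix", {
  truth <- c(1, 1, 0, 0)
  perfect <- c(0.9, 0.8, 0.2, 0.1)
  out <- term_auc_mcc(truth, perfect, mcc_threshold = 0.5)
  expect_equal(unname(out["auc"]), 1)
  expect_equal(unname(out["mcc"]), 1)
  # tp = fp = fn = tn = 1 has no association: MCC 0
  out2 <- term_auc_mcc(c(1, 0, 1, 0), c(0.9, 0.9, 0.1, 0.1), 0.5)
  expect_equal(unname(out2["mcc"]), 0)
  set.seed(64)
  tr <- rbinom(5000, 1, 0.4)
  out3 <- term_auc_mcc(tr, runif(5000), 0.5)
  expect_equal(unname(out3["auc"]), 0.5, tolerance = 0.03)
  expect_true(is.na(term_auc_mcc(rep(1, 4), runif(4), 0.5)["auc"]))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(65)
  truth <- rbinom(200, 1, 0.3)
  scores <- runif(200) + truth * 0.3
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(unname(term_auc_mcc(truth, scores)["auc"]), ref,
               tolerance = 1e-9)
})

test_that("TPR score counts missing ancestors on the worked chain examples", {
  dag <- chain_dag()
  terms <- dag$terms
  m <- function(v) matrix(v, 1, 3, dimnames = list("p", terms))
  expect_equal(tpr_score(dag, m(c(0, 0, 1))), 2) # {b}: misses a and r
  expect_equal(tpr_score(dag, m(c(0, 1, 1))), 2) # {a,b}: each misses r
  expect_equal(tpr_score(dag, m(c(1, 1, 1))), 0) # closed set
  # one protein of N with a height-h term alone raises the score by h/N
  M <- rbind(m(c(1, 1, 1)), m(c(1, 1, 1)), m(c(1, 1, 1)), m(c(0, 0, 1)))
  expect_equal(tpr_score(dag, M), term_height(dag, "GO:0000003") / 4)
})

test_that("co-occurrence heatmaps mark pairs seen in at least one protein", {
  M <- matrix(c(1, 0, 1, 1, 0, 1), 2, 3,
              dimnames = list(NULL, c("t1", "t2", "t3")))
  H <- cooccurrence_heatmap(M)
  expect_equal(H["t1", "t2"], 1)
  expect_equal(H["t2", "t3"], 1)
  expect_equal(H["t1", "t3"], 0)
  expect_equal(H, t(H))
  expect_equal(diag(H), c(t1 = 1, t2 = 1, t3 = 1))
  expect_equal(cooccurrence_heatmap(M[c(1, 1, 2, 2), ]), H)
  empty <- matrix(0, 2, 3, dimnames = list(NULL, c("t1", "t2", "t3")))
  expect_true(all(cooccurrence_heatmap(empty) == 0))
})

test_that("heatmap MSE is the binary disagreement fraction", {
  A <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(heatmap_mse(A, A), 0)
  expect_equal(heatmap_mse(A, 1 - A), 1)
  B <- matrix(0, 3, 3); C <- B; C[1, 2] <- 1; C[2, 1] <- 1
  expect_equal(heatmap_mse(B, C), 2 / 9)
  expect_equal(heatmap_mse(B, C), heatmap_mse(C, B))
  expect_error(heatmap_mse(A, B), "shapes")
})

test_that("per-height and per-sample-count breakdowns group correctly", {
  dag <- chain_dag()
  f1 <- setNames(c(0.9, 0.6, NA), dag$terms)
  bh <- f1_by_height(dag, f1)
  expect_equal(bh$height, c(0L, 1L))
  expect_equal(bh$mean_f1, c(0.9, 0.6))
  truth <- matrix(c(1, 1, 1, 1, 0, 1, 0, 0, 0), 3, 3,
                  dimnames = list(NULL, dag$terms))
  bs <- f1_by_sample_count(truth, f1)
  expect_equal(bs$term, dag$terms[1:2])
  expect_equal(bs$n_pos, c(3L, 2L))
  # grouped means equal a naive loop
  set.seed(66)
  dag2 <- random_dag(20)
  f1r <- setNames(runif(20), dag2$terms)
  bh2 <- f1_by_height(dag2, f1r)
  h <- term_heights(dag2)
  for (i in seq_len(nrow(bh2)))
    expect_equal(bh2$mean_f1[i], mean(f1r[h[names(f1r)] == bh2$height[i]]))
})

test_that("the evaluation report assembles all measures coherently", {
  set.seed(67)
  dag <- random_dag(12)
  pair <- random_eval_pair(15, 12)
  colnames(pair$truth) <- colnames(pair$scores) <- dag$terms
  ev <- evaluate_predictions(pair$truth, pair$scores, dag = dag)
  expect_s3_class(ev, "pfp_eval")
  expect_equal(ev$fmax, bf_fmax(pair$truth, pair$scores), tolerance = 1e-9)
  expect_equal(nrow(ev$per_term), 12L)
  expect_true(all(ev$per_term$f1 >= 0 & ev$per_term$f1 <= 1, na.rm = TRUE))
  expect_true(all(ev$per_term$mcc >= -1 & ev$per_term$mcc <= 1, na.rm = TRUE))
  expect_true(ev$heatmap_mse >= 0 && ev$heatmap_mse <= 1)
  expect_true(ev$tpr_score >= 0)
  expect_output(print(ev), "Fmax")
})

test_that("micro F1 pools confusion counts over all cells", {
  truth <- matrix(c(1, 0, 0, 1), 2, 2)
  scores <- matrix(c(0.9, 0.2, 0.8, 0.3), 2, 2)
  # at t = 0.5: tp = 1 (cell 1), fp = 1 (cell 3), fn = 1 (cell 4)
  expect_equal(micro_f1(truth, scores, 0.5), 2 * 0.5 * 0.5 / 1)
})
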