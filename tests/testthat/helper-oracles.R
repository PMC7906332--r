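# Shared fixtures and independent brute-force oracles.  The oracles are
# deliberately naive (explicit loops, reachability searches) so they share no
# code with the implementations they check.

# chain root <- a <- b
chain_dag <- function() {
  ontology_dag(c("GO:0000001", "GO:0000002", "GO:0000003"),
               rep("BP", 3),
               list(`GO:0000002` = "GO:0000001",
                    `GO:0000003` = "GO:0000002"))
}

# diamond: root <- a, root <- b, a <- c, b <- c
diamond_dag <- function() {
  ontology_dag(c("r", "a", "b", "c"), rep("MF", 4),
               list(a = "r", b = "r", c = c("a", "b")))
}

# random layered DAG of at most `n` nodes (single namespace, single root)
random_dag <- function(n, depth = 4L) {
  ids <- sprintf("T%03d", seq_len(n))
  level <- c(0L, sample(depth, n - 1L, replace = TRUE))
  level[2:min(n, depth + 1L)] <- seq_len(min(n - 1L, depth))
  parents <- list()
  for (i in seq_len(n)[-1]) {
    cand <- ids[level < level[i]]
    npar <- min(length(cand), sample(1:2, 1))
    parents[[ids[i]]] <- sample(cand, npar)
  }
  ontology_dag(ids, rep("BP", n), parents)
}

# brute-force ancestor set by graph walking
bf_ancestors <- function(dag, term) {
  seen <- character(0)
  frontier <- dag$parents[[term]]
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- unique(unlist(dag$parents[frontier]))
    frontier <- setdiff(frontier, seen)
  }
  seen
}

# brute-force longest path to a root by recursion
bf_height <- function(dag, term) {
  p <- dag$parents[[term]]
  if (!length(p)) return(0L)
  1L + max(vapply(p, function(q) bf_height(dag, q), 0L))
}

# naive Fmax: double loop over proteins and thresholds
bf_fmax <- function(truth, scores, grid = threshold_grid()) {
  best <- 0
  for (t in grid) {
    precs <- recs <- numeric(nrow(truth))
    for (i in seq_len(nrow(truth))) {
      pred <- scores[i, ] >= t
      tp <- sum(pred & truth[i, ] == 1)
      fp <- sum(pred & truth[i, ] == 0)
      fn <- sum(!pred & truth[i, ] == 1)
      precs[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
      recs[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    }
    ap <- mean(precs); ar <- mean(recs)
    f <- if (ap + ar > 0) 2 * ap * ar / (ap + ar) else 0
    if (f > best) best <- f
  }
  best
}

bf_term_f1 <- function(truth, scores, grid = threshold_grid()) {
  if (sum(truth) == 0) return(NA_real_)
  best <- 0
  for (t in grid) {
    pred <- scores >= t
    tp <- sum(pred & truth == 1); fp <- sum(pred & truth == 0)
    fn <- sum(!pred & truth == 1)
    pr <- if (tp + fp > 0) tp / (tp + fp) else 0
    re <- tp / (tp + fn)
    f <- if (pr + re > 0) 2 * pr * re / (pr + re) else 0
    if (f > best) best <- f
  }
  best
}

# naive AUPR: walk the distinct cut points explicitly and integrate
bf_term_aupr <- function(truth, scores) {
  npos <- sum(truth)
  if (npos == 0) return(NA_real_)
  cuts <- sort(unique(scores), decreasing = TRUE)
  rec <- prec <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    pred <- scores >= cuts[i]
    prec[i] <- sum(truth[pred]) / sum(pred)
    rec[i] <- sum(truth[pred]) / npos
  }
  area <- rec[1] * prec[1]
  if (length(cuts) > 1)
    for (i in 2:length(cuts))
      area <- area + (rec[i] - rec[i - 1]) * (prec[i] + prec[i - 1]) / 2
  area
}

# naive TPR score: set arithmetic per protein and term
bf_tpr_score <- function(dag, M) {
  terms <- colnames(M)
  total <- 0
  for (i in seq_len(nrow(M))) {
    annot <- terms[M[i, ] == 1]
    for (t in annot) {
      anc <- intersect(bf_ancestors(dag, t), terms)
      total <- total + length(setdiff(anc, annot))
    }
  }
  total / nrow(M)
}

# random truth/score matrix pair
random_eval_pair <- function(n = 20, c = 15) {
  truth <- matrix(rbinom(n * c, 1, 0.3), n, c,
                  dimnames = list(NULL, sprintf("T%03d", seq_len(c))))
  scores <- matrix(runif(n * c), n, c)
  list(truth = truth, scores = scores)
}

# tiny trained-model fixture shared by model/training tests
tiny_gen_config <- function(n_terms = 4L) {
  generator_config("sequence", n_terms = n_terms, max_positions = 28L,
                   embed_dim = 8L, n_filters = 4L, kernel_size = 5L,
                   pool_size = 8L, pool_stride = 4L, dense_sizes = c(16L, 8L))
}

tiny_disc_config <- function(gen) {
  discriminator_config(gen, label_branch_size = 8L, cond_size = 8L,
                       trunk_sizes = c(16L, 12L, 10L, 8L, 6L))
}

random_idx_batch <- function(n, L = 28L, lens = NULL) {
  idx <- matrix(0L, L, n)
  if (is.null(lens)) lens <- sample(5:L, n, replace = TRUE)
  for (s in seq_len(n)) idx[seq_len(lens[s]), s] <- sample(8000L, lens[s], TRUE)
  idx
}
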