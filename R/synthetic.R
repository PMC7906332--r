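# Desk-scale synthetic benchmark with the statistical structure the
# adversarial annotator exploits: DAG-organised labels, term membership
# determined by exact sequence motifs, true-path-closed annotation matrices,
# and planted leaf-level co-occurrence / mutual-exclusion pairs (internal
#-node correlations then arise from propagation, the way real GO
# co-occurrence exceeds what the DAG alone implies).

#' Synthetic benchmark specification
#'
#' @param n_terms total number of GO-style terms (default 40).
#' @param dag_depth depth of the label DAG (default 4).
#' @param n_proteins number of proteins (default 2000).
#' @param seq_len length range of the background sequences (default 50-400).
#' @param motif_len length of each leaf's planted motif (default 6).
#' @param motifs_per_leaf motifs per leaf term (1; exposed for clarity).
#' @param n_co_pairs,n_excl_pairs number of forced-co-occurrence (rho = 1)
#'   and mutual-exclusion (rho = -1) leaf pairs planted when `co_pairs` is
#'   NULL (defaults 3 and 3).
#' @param co_pairs optional explicit `data.frame(term_a, term_b, rho)` with
#'   `rho` 1 (always together) or -1 (never together); leaf terms only, each
#'   leaf in at most one pair.
#' @param leaf_range range of the number of (pre-closure) leaf terms drawn
#'   per protein (default 1-3).
#' @param noise post-propagation label-flip probability (default 0; nonzero
#'   values break true-path closure and are meant for robustness tests only).
#' @param feature_dim,feature_noise_sd dimension and noise of the
#'   feature-vector variant (defaults 64 and 0.1).
#' @param namespace single namespace for all terms (default `"BP"`).
#' @param seed master seed.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_terms = 40L, dag_depth = 4L, n_proteins = 2000L,
                       seq_len = c(50L, 400L), motif_len = 6L,
                       motifs_per_leaf = 1L, n_co_pairs = 3L,
                       n_excl_pairs = 3L, co_pairs = NULL,
                       leaf_range = c(1L, 3L), noise = 0,
                       feature_dim = 64L, feature_noise_sd = 0.1,
                       namespace = "BP", seed = 1L) {
  if (n_terms < dag_depth + 1L) stop("n_terms must exceed dag_depth")
  if (noise < 0 || noise > 1) stop("noise must be a probability")
  if (motifs_per_leaf != 1L) stop("one motif per leaf is supported")
  structure(list(n_terms = as.integer(n_terms),
                 dag_depth = as.integer(dag_depth),
                 n_proteins = as.integer(n_proteins),
                 seq_len = as.integer(seq_len),
                 motif_len = as.integer(motif_len),
                 motifs_per_leaf = 1L,
                 n_co_pairs = as.integer(n_co_pairs),
                 n_excl_pairs = as.integer(n_excl_pairs),
                 co_pairs = co_pairs,
                 leaf_range = as.integer(leaf_range), noise = noise,
                 feature_dim = as.integer(feature_dim),
                 feature_noise_sd = feature_noise_sd,
                 namespace = namespace, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Sample a random term DAG
#'
#' Single root; every non-root term sits on a level 1..`dag_depth`, takes one
#' parent from the level immediately above (so its height equals its level)
#' and, with probability 0.3, a second parent from any shallower level
#' (creating diamonds).  Reproducible under the spec's seed.
#'
#' @param spec a [synth_spec()].
#' @return An [ontology_dag].
#' @export
sample_dag <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_terms
  depth <- spec$dag_depth
  ids <- sprintf("GO:%07d", seq_len(n))
  level <- c(0L, seq_len(depth),
             if (n > depth + 1L) sample(depth, n - depth - 1L, replace = TRUE))
  parents <- list()
  for (i in seq_len(n)[-1]) {
    l <- level[i]
    above <- ids[level == l - 1L]
    p <- if (length(above) == 1L) above else sample(above, 1L)
    if (l > 1L && runif(1) < 0.3) {
      shallower <- setdiff(ids[level < l], p)
      if (length(shallower))
        p <- c(p, if (length(shallower) == 1L) shallower
               else sample(shallower, 1L))
    }
    parents[[ids[i]]] <- p
  }
  dag <- ontology_dag(ids, rep(spec$namespace, n), parents)
  dag$term_names <- setNames(paste0("synthetic term ", seq_len(n)), ids)
  dag
}

.dag_leaves <- function(dag) {
  has_child <- unique(unlist(dag$parents))
  setdiff(dag$terms, has_child)
}

.resolve_co_pairs <- function(spec, leaves) {
  if (!is.null(spec$co_pairs)) {
    cp <- spec$co_pairs
    if (!all(c(cp$term_a, cp$term_b) %in% leaves))
      stop("co_pairs must reference leaf terms only")
    if (anyDuplicated(c(cp$term_a, cp$term_b)))
      stop("each leaf may appear in at most one pair")
    if (!all(cp$rho %in% c(-1, 1)))
      stop("only rho = 1 (co-occurrence) and rho = -1 (exclusion) supported")
    return(cp)
  }
  need <- 2L * (spec$n_co_pairs + spec$n_excl_pairs)
  if (length(leaves) < need)
    stop("DAG has ", length(leaves), " leaves; ", need,
         " are needed for the requested pairs")
  picked <- sample(leaves, need)
  data.frame(
    term_a = picked[seq_len(spec$n_co_pairs + spec$n_excl_pairs) * 2L - 1L],
    term_b = picked[seq_len(spec$n_co_pairs + spec$n_excl_pairs) * 2L],
    rho = c(rep(1, spec$n_co_pairs), rep(-1, spec$n_excl_pairs)))
}

# leaf set honoring the planted pairs: rho = 1 partners always join,
# rho = -1 partners are banned once the other is chosen
.draw_leaf_set <- function(leaves, co, excl, k) {
  chosen <- character(0)
  avail <- leaves
  while (length(chosen) < k && length(avail)) {
    pick <- if (length(avail) == 1L) avail else sample(avail, 1L)
    add <- pick
    repeat {
      partners <- unique(c(co$term_b[co$term_a %in% add],
                           co$term_a[co$term_b %in% add]))
      new <- setdiff(partners, add)
      if (!length(new)) break
      add <- c(add, new)
    }
    chosen <- c(chosen, add)
    banned <- unique(c(excl$term_b[excl$term_a %in% chosen],
                       excl$term_a[excl$term_b %in% chosen]))
    avail <- setdiff(avail, c(chosen, banned))
  }
  chosen
}

.random_motifs <- function(n, len) {
  repeat {
    motifs <- vapply(seq_len(n), function(i)
      paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = ""), "")
    if (!anyDuplicated(motifs)) return(motifs)
  }
}

#' Sample the motif-annotated sequence benchmark
#'
#' Per protein: a set of leaf terms is drawn honouring the planted
#' co-occurrence/exclusion pairs, one exact motif per drawn leaf is planted
#' at a random non-overlapping position in a uniform-background sequence
#' (sequences accidentally containing another leaf's motif are resampled),
#' the annotation is the true-path closure of the drawn leaves, and optional
#' label noise is applied after closure.
#'
#' @param spec a [synth_spec()].
#' @param dag the DAG from [sample_dag()] (regenerated when NULL).
#' @return Object of class `synth_dataset`: `dag`, `records` (id/sequence
#'   data frame), `annotations` (binary matrix over all DAG terms, true-path
#'   closed when `noise = 0`), `truth_heatmap`, `motifs` (named by leaf),
#'   `co_pairs`, and a per-protein `ledger` of planted leaves and motif
#'   positions.
#' @export
sample_proteins <- function(spec, dag = NULL) {
  if (is.null(dag)) dag <- sample_dag(spec)
  set.seed(spec$seed + 1L)
  leaves <- .dag_leaves(dag)
  pairs <- .resolve_co_pairs(spec, leaves)
  co <- pairs[pairs$rho == 1, , drop = FALSE]
  excl <- pairs[pairs$rho == -1, , drop = FALSE]
  motifs <- setNames(.random_motifs(length(leaves), spec$motif_len), leaves)
  n <- spec$n_proteins
  ids <- sprintf("P%05d", seq_len(n))
  seqs <- character(n)
  leaf_sets <- vector("list", n)
  positions <- vector("list", n)
  mlen <- spec$motif_len
  for (i in seq_len(n)) {
    k <- sample(seq(spec$leaf_range[1], spec$leaf_range[2]), 1L)
    ls <- .draw_leaf_set(leaves, co, excl, k)
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      if (attempt > 100L)
        stop("could not place ", length(ls), " motifs in a sequence of the ",
             "requested length range after 100 attempts")
      L <- sample(seq(spec$seq_len[1], spec$seq_len[2]), 1L)
      if (L < length(ls) * mlen) next
      bg <- sample(AA_ALPHABET, L, replace = TRUE)
      # non-overlapping placements
      pos <- integer(0)
      ok <- TRUE
      for (m in seq_along(ls)) {
        free <- setdiff(seq_len(L - mlen + 1L),
                        unlist(lapply(pos, function(p) (p - mlen + 1L):(p + mlen - 1L))))
        if (!length(free)) { ok <- FALSE; break }
        pos <- c(pos, if (length(free) == 1L) free else sample(free, 1L))
      }
      if (!ok) next
      for (m in seq_along(ls)) {
        at <- pos[m]
        bg[at:(at + mlen - 1L)] <- strsplit(motifs[[ls[m]]], "")[[1]]
      }
      s <- paste(bg, collapse = "")
      # no spurious occurrence of any other leaf's motif
      others <- motifs[setdiff(leaves, ls)]
      if (length(others) && any(vapply(others, grepl, TRUE, x = s, fixed = TRUE)))
        next
      seqs[i] <- s
      leaf_sets[[i]] <- ls
      positions[[i]] <- setNames(pos, ls)
      break
    }
  }
  ann <- matrix(0, n, length(dag$terms), dimnames = list(ids, dag$terms))
  for (i in seq_len(n)) ann[i, leaf_sets[[i]]] <- 1
  ann <- propagate_true_path(dag, ann)
  if (spec$noise > 0) {
    flip <- matrix(runif(length(ann)) < spec$noise, nrow(ann))
    ann <- (ann + flip) %% 2
  }
  structure(list(
    dag = dag,
    records = data.frame(id = ids, sequence = seqs),
    annotations = ann,
    truth_heatmap = cooccurrence_heatmap(ann),
    motifs = motifs, co_pairs = pairs,
    ledger = list(leaves = setNames(leaf_sets, ids),
                  motif_positions = setNames(positions, ids)),
    spec = spec), class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat("synth_dataset:", nrow(x$records), "proteins,",
      length(x$dag$terms), "terms,",
      sum(x$co_pairs$rho == 1), "co-occurrence and",
      sum(x$co_pairs$rho == -1), "exclusion pairs\n")
  invisible(x)
}

#' Sample the feature-vector benchmark variant
#'
#' Per protein the feature vector is the sum of term-specific prototype
#' vectors over its drawn leaves plus isotropic Gaussian noise; annotations
#' follow the same leaf-drawing and closure logic as [sample_proteins()].
#'
#' @param spec a [synth_spec()].
#' @param dag the DAG from [sample_dag()] (regenerated when NULL).
#' @return List with `features` (n x d matrix), `annotations`,
#'   `truth_heatmap`, `prototypes`, `co_pairs` and the leaf `ledger`.
#' @export
sample_feature_dataset <- function(spec, dag = NULL) {
  if (is.null(dag)) dag <- sample_dag(spec)
  set.seed(spec$seed + 2L)
  leaves <- .dag_leaves(dag)
  pairs <- .resolve_co_pairs(spec, leaves)
  co <- pairs[pairs$rho == 1, , drop = FALSE]
  excl <- pairs[pairs$rho == -1, , drop = FALSE]
  d <- spec$feature_dim
  proto <- matrix(rnorm(length(leaves) * d), length(leaves), d,
                  dimnames = list(leaves, NULL))
  n <- spec$n_proteins
  ids <- sprintf("P%05d", seq_len(n))
  X <- matrix(0, n, d, dimnames = list(ids, NULL))
  leaf_sets <- vector("list", n)
  for (i in seq_len(n)) {
    k <- sample(seq(spec$leaf_range[1], spec$leaf_range[2]), 1L)
    ls <- .draw_leaf_set(leaves, co, excl, k)
    leaf_sets[[i]] <- ls
    X[i, ] <- colSums(proto[ls, , drop = FALSE]) +
      rnorm(d, sd = spec$feature_noise_sd)
  }
  ann <- matrix(0, n, length(dag$terms), dimnames = list(ids, dag$terms))
  for (i in seq_len(n)) ann[i, leaf_sets[[i]]] <- 1
  ann <- propagate_true_path(dag, ann)
  list(dag = dag, features = X, annotations = ann,
       truth_heatmap = cooccurrence_heatmap(ann), prototypes = proto,
       co_pairs = pairs, ledger = list(leaves = setNames(leaf_sets, ids)),
       spec = spec)
}

#' Write a synthetic dataset to disk
#'
#' Emits `seqs.fa`, `ontology.obo`, `annotations.tsv`,
#' `truth_heatmap.tsv` and `ledger.json` into `dir`.
#'
#' @param dataset a `synth_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_synth_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(dataset$records, file.path(dir, "seqs.fa"))
  write_obo(dataset$dag, file.path(dir, "ontology.obo"))
  write_annotations(dataset$annotations, file.path(dir, "annotations.tsv"))
  write.table(dataset$truth_heatmap, file.path(dir, "truth_heatmap.tsv"),
              sep = "\t", quote = FALSE)
  jsonlite::write_json(
    list(motifs = as.list(dataset$motifs),
         co_pairs = dataset$co_pairs,
         leaves = lapply(dataset$ledger$leaves, as.list),
         motif_positions = lapply(dataset$ledger$motif_positions, as.list)),
    file.path(dir, "ledger.json"), auto_unbox = TRUE)
  invisible(dir)
}
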