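#' @useDynLib pfpwgan, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rnorm median setNames
#' @importFrom utils read.delim write.table head
NULL

NAMESPACE_LEVELS <- c("BP", "MF", "CC")

.canon_namespace <- function(x) {
  map <- c(biological_process = "BP", molecular_function = "MF",
           cellular_component = "CC", BP = "BP", MF = "MF", CC = "CC")
  out <- unname(map[x])
  if (anyNA(out)) stop("unknown namespace: ", paste(x[is.na(out)], collapse = ", "))
  out
}

#' Construct an ontology DAG
#'
#' Holds a Gene Ontology-style hierarchy restricted to `is_a` edges: a set of
#' term identifiers, the namespace of each term (`BP`, `MF` or `CC`), and the
#' parent sets.  Acyclicity and namespace consistency (a term's parents live
#' in the same namespace) are verified on construction; a topological order is
#' computed once and reused for true-path propagation and term heights.
#'
#' @param terms character vector of term identifiers.
#' @param namespace character vector (same length) of namespaces; either the
#'   long OBO names or the abbreviations `BP`/`MF`/`CC`.
#' @param parents named list mapping a term to the character vector of its
#'   `is_a` parents; terms without an entry are roots.
#' @return An object of class `ontology_dag`.
#' @export
ontology_dag <- function(terms, namespace, parents = list()) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop("duplicated term ids")
  namespace <- setNames(.canon_namespace(as.character(namespace)), terms)
  par <- setNames(vector("list", length(terms)), terms)
  for (t in names(parents)) {
    if (!t %in% terms) stop("parent entry for unknown term: ", t)
    p <- unique(as.character(parents[[t]]))
    p <- setdiff(p, t)
    missing <- setdiff(p, terms)
    if (length(missing))
      stop("term ", t, " has is_a parents outside the ontology: ",
           paste(missing, collapse = ", "))
    bad <- p[namespace[p] != namespace[t]]
    if (length(bad))
      stop("term ", t, " has parents in a different namespace: ",
           paste(bad, collapse = ", "))
    par[[t]] <- p
  }
  dag <- structure(
    list(terms = terms, namespace = namespace, parents = par,
         cache = new.env(parent = emptyenv())),
    class = "ontology_dag")
  dag$topo <- .topo_sort(dag) # errors on cycles
  dag$roots <- terms[vapply(par, length, 1L) == 0L]
  dag
}

# Kahn's algorithm; on failure report one cycle found by walking parents.
.topo_sort <- function(dag) {
  terms <- dag$terms
  n <- length(terms)
  idx <- setNames(seq_len(n), terms)
  npar <- vapply(dag$parents, length, 1L)
  children <- setNames(vector("list", n), terms)
  for (t in terms) for (p in dag$parents[[t]])
    children[[p]] <- c(children[[p]], t)
  queue <- terms[npar == 0L]
  order <- character(0)
  remaining <- npar
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]
    order <- c(order, t)
    for (ch in children[[t]]) {
      remaining[[ch]] <- remaining[[ch]] - 1L
      if (remaining[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    left <- setdiff(terms, order)
    cyc <- left[[1]]; seen <- cyc; cur <- cyc
    repeat {
      nxt <- intersect(dag$parents[[cur]], left)[1]
      if (is.na(nxt)) break
      if (nxt %in% seen) {
        cyc <- c(seen[which(seen == nxt):length(seen)], nxt)
        stop("ontology contains a cycle: ", paste(cyc, collapse = " -> "))
      }
      seen <- c(seen, nxt); cur <- nxt
    }
    stop("ontology contains a cycle among: ", paste(left, collapse = ", "))
  }
  order
}

#' Parse a minimal OBO file
#'
#' Reads `[Term]` stanzas from an OBO 1.2-style flat file and returns the
#' `is_a` hierarchy.  Only the `id`, `name`, `namespace`, `is_a` and
#' `is_obsolete` tags are honoured; obsolete terms are dropped (together with
#' edges that point at them) and every other tag or stanza type is skipped.
#'
#' @param path path to the OBO file.
#' @return An [ontology_dag] with a `names` attribute carrying term names.
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\[", lines)
  if (!length(starts)) stop("no stanzas found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  ids <- nsp <- nms <- character(0)
  parents <- list()
  for (i in seq_along(starts)) {
    if (lines[starts[i]] != "[Term]") next
    body <- lines[seq(starts[i] + 1L, ends[i])]
    body <- body[nzchar(body)]
    tagm <- regmatches(body, regexec("^([a-z_]+):\\s*(.*)$", body))
    bad <- which(vapply(tagm, length, 1L) != 3L)
    if (length(bad))
      stop("malformed OBO line ", starts[i] + bad[1],
           ": ", body[bad[1]])
    tags <- vapply(tagm, `[`, "", 2L)
    vals <- vapply(tagm, `[`, "", 3L)
    id <- vals[tags == "id"][1]
    if (is.na(id)) stop("[Term] stanza at line ", starts[i], " has no id")
    if (any(tags == "is_obsolete" & grepl("^true", vals))) next
    ns <- vals[tags == "namespace"][1]
    if (is.na(ns)) stop("term ", id, " has no namespace tag")
    nm <- vals[tags == "name"][1]
    isa <- sub("\\s*!.*$", "", vals[tags == "is_a"])
    ids <- c(ids, id); nsp <- c(nsp, ns)
    nms <- c(nms, if (is.na(nm)) id else nm)
    parents[[id]] <- isa
  }
  if (!length(ids)) stop("no non-obsolete [Term] stanzas in ", path)
  # drop edges to terms that are absent (e.g. obsolete parents)
  parents <- lapply(parents, function(p) intersect(p, ids))
  dag <- ontology_dag(ids, .canon_namespace(nsp), parents)
  dag$term_names <- setNames(nms, ids)
  dag
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("ontology_dag:", length(x$terms), "terms,",
      sum(lengths(x$parents)), "is_a edges\n")
  tab <- table(x$namespace)
  cat("  namespaces:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n  roots:", paste(x$roots, collapse = ", "), "\n")
  invisible(x)
}

#' Ancestors of a term
#'
#' Transitive closure of the `is_a` parent relation, excluding the term
#' itself.  Results are memoised inside the DAG object, so repeated lookups
#' are amortised O(1).
#'
#' @param dag an [ontology_dag].
#' @param term a term identifier present in `dag`.
#' @return Character vector of ancestor term ids (empty for a root).
#' @export
ancestors <- function(dag, term) {
  if (!term %in% dag$terms) stop("unknown term: ", term)
  cache <- dag$cache
  key <- paste0("anc.", term)
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  anc <- character(0)
  for (p in dag$parents[[term]])
    anc <- union(anc, c(p, ancestors(dag, p)))
  cache[[key]] <- anc
  anc
}

# c x c indicator with A[t, u] = 1 iff u is an ancestor of t,
# restricted to the given term subset.
.ancestor_matrix <- function(dag, terms) {
  c <- length(terms)
  A <- matrix(0, c, c, dimnames = list(terms, terms))
  for (t in terms) {
    a <- intersect(ancestors(dag, t), terms)
    if (length(a)) A[t, a] <- 1
  }
  A
}

#' True-path-rule propagation of an annotation matrix
#'
#' Closes every protein's annotation set under ancestors: whenever a term
#' annotates a protein, all of its ancestors that are present among the
#' matrix's columns become annotated as well.  Idempotent.
#'
#' @param dag an [ontology_dag].
#' @param assignments binary matrix, proteins in rows, terms in columns
#'   (column names must be term ids present in `dag`).
#' @return A binary matrix of the same shape, closed under the true-path rule.
#' @export
propagate_true_path <- function(dag, assignments) {
  assignments <- .check_annotation_matrix(assignments)
  terms <- colnames(assignments)
  missing <- setdiff(terms, dag$terms)
  if (length(missing))
    stop("annotation columns not in the ontology: ",
         paste(missing, collapse = ", "))
  R <- .ancestor_matrix(dag, terms)
  diag(R) <- 1
  out <- (assignments %*% R > 0) + 0
  dimnames(out) <- dimnames(assignments)
  out
}

.check_annotation_matrix <- function(M) {
  M <- as.matrix(M)
  if (is.null(colnames(M))) stop("annotation matrix needs term column names")
  if (!all(M %in% c(0, 1))) stop("annotation matrix must be binary")
  storage.mode(M) <- "double"
  M
}

#' Term heights
#'
#' Height of a term is the length of the longest `is_a` path from the term up
#' to its namespace root; roots have height 0.
#'
#' @param dag an [ontology_dag].
#' @return Named integer vector over all terms.
#' @export
term_heights <- function(dag) {
  hit <- dag$cache[["heights"]]
  if (!is.null(hit)) return(hit)
  h <- setNames(integer(length(dag$terms)), dag$terms)
  for (t in dag$topo) {
    p <- dag$parents[[t]]
    h[[t]] <- if (length(p)) max(h[p]) + 1L else 0L
  }
  dag$cache[["heights"]] <- h
  h
}

#' @rdname term_heights
#' @param term a single term identifier.
#' @export
term_height <- function(dag, term) {
  if (!term %in% dag$terms) stop("unknown term: ", term)
  unname(term_heights(dag)[[term]])
}

#' Frequency thresholds for term filtering
#'
#' Minimum number of annotated proteins a term must reach to be kept, per
#' namespace.  The defaults (250 for BP, 50 for MF, 50 for CC) follow the
#' DeepGO-style preprocessing of SwissProt-scale corpora; set all three to 1
#' to keep every annotated term.
#'
#' @param min_count_bp,min_count_mf,min_count_cc positive integers.
#' @export
term_filter_spec <- function(min_count_bp = 250L, min_count_mf = 50L,
                             min_count_cc = 50L) {
  spec <- list(BP = as.integer(min_count_bp), MF = as.integer(min_count_mf),
               CC = as.integer(min_count_cc))
  if (any(unlist(spec) < 1L)) stop("all minimum counts must be >= 1")
  structure(spec, class = "term_filter_spec")
}

#' Drop rarely annotated terms
#'
#' Keeps a term iff its positive-protein count in the (already true-path
#' propagated) annotation matrix reaches the namespace threshold.  Counting
#' on the propagated matrix means a parent's count includes the proteins of
#' all of its descendants, as the true-path rule implies.
#'
#' @param dag an [ontology_dag].
#' @param assignments propagated binary annotation matrix (proteins x terms).
#' @param spec a [term_filter_spec].
#' @return List with `kept` (term ids per namespace), `counts` (named positive
#'   counts over all input terms) and `matrix` (the reduced annotation matrix).
#' @export
filter_terms <- function(dag, assignments, spec = term_filter_spec()) {
  assignments <- .check_annotation_matrix(assignments)
  terms <- colnames(assignments)
  missing <- setdiff(terms, dag$terms)
  if (length(missing))
    stop("annotation columns not in the ontology: ",
         paste(missing, collapse = ", "))
  counts <- colSums(assignments)
  ns <- dag$namespace[terms]
  keep <- counts >= unlist(spec)[ns]
  kept <- split(terms[keep], ns[keep])
  for (level in intersect(NAMESPACE_LEVELS, unique(ns)))
    if (!length(kept[[level]]))
      warning("no ", level, " terms pass the frequency threshold")
  list(kept = kept, counts = counts,
       matrix = assignments[, terms[keep], drop = FALSE])
}

#' Write the reduced term list as TSV
#'
#' @param dag an [ontology_dag].
#' @param terms character vector of term ids to write.
#' @param path output path; columns are `term_id` and `namespace`.
#' @export
write_term_table <- function(dag, terms, path) {
  df <- data.frame(term_id = terms, namespace = dag$namespace[terms])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an ontology as a minimal OBO file
#'
#' @param dag an [ontology_dag].
#' @param path output path.
#' @export
write_obo <- function(dag, path) {
  long <- c(BP = "biological_process", MF = "molecular_function",
            CC = "cellular_component")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in dag$terms) {
    nm <- if (!is.null(dag$term_names)) dag$term_names[[t]] else t
    block <- c("[Term]", paste0("id: ", t), paste0("name: ", nm),
               paste0("namespace: ", long[[dag$namespace[[t]]]]),
               paste0("is_a: ", dag$parents[[t]]), "")
    writeLines(block, con)
  }
  invisible(path)
}
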