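#' Similarity matrices
#'
#' A `similarity_matrix` is a square symmetric numeric matrix with entries in
#' \[0, 1\], unit diagonal, and an id ordering stored in its dimnames.  It is
#' the common container for the three drug feature similarities, their fused
#' version, and the disease semantic similarity.
#'
#' @param values square numeric matrix.
#' @param ids character vector of entity identifiers, one per row.
#' @return A `similarity_matrix` object.
#' @export
similarity_matrix <- function(values, ids) {
  values <- as.matrix(values)
  ids <- as.character(ids)
  check_no_duplicates(ids)
  if (nrow(values) != length(ids) || ncol(values) != length(ids)) {
    abort(sprintf(
      "matrix is %dx%d but %d ids were given",
      nrow(values), ncol(values), length(ids)
    ))
  }
  dimnames(values) <- list(ids, ids)
  out <- structure(values, class = c("similarity_matrix", "matrix", "array"))
  validate_similarity_matrix(out)
  out
}

validate_similarity_matrix <- function(x, tol = 1e-12) {
  if (nrow(x) > 0) {
    if (max(abs(x - t(x))) > tol) abort("similarity matrix is not symmetric")
    if (any(x < -tol) || any(x > 1 + tol)) {
      abort("similarity values must lie in [0, 1]")
    }
    if (max(abs(diag(x) - 1)) > tol) abort("similarity diagonal must be 1")
  }
  invisible(x)
}

sim_ids <- function(x) rownames(x)

#' Jaccard similarity of two feature sets
#'
#' \eqn{|a \cap b| / |a \cup b|}; two empty sets score 0 (absence of shared
#' features is not evidence of similarity).
#'
#' @param a,b character vectors treated as sets (duplicates ignored).
#' @return A similarity score in \[0, 1\].
#' @export
#' @examples
#' jaccard_similarity(c("f1", "f2", "f3"), c("f2", "f3", "f4")) # 0.5
jaccard_similarity <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

# Tidy feature table (drug_id, feature_id) -> named list of character sets.
feature_sets <- function(features) {
  stopifnot(all(c("drug_id", "feature_id") %in% names(features)))
  split(as.character(features$feature_id), as.character(features$drug_id))
}

#' Drug similarity matrix from feature sets
#'
#' Computes pairwise Jaccard similarity over one kind of drug feature
#' (chemical substructures, target-protein domains, or gene annotations).
#' Drugs absent from `features` get an empty feature set; the diagonal is
#' forced to 1.
#'
#' @param features a tibble/data frame with columns `drug_id`, `feature_id`,
#'   or a named list of character feature sets.
#' @param drug_order character vector fixing the row/column ordering.
#' @return A [similarity_matrix()] over `drug_order`.
#' @export
drug_similarity_matrix <- function(features, drug_order) {
  drug_order <- as.character(drug_order)
  check_no_duplicates(drug_order, "drug id")
  sets <- if (is.data.frame(features)) feature_sets(features) else features
  sets <- lapply(sets, function(s) unique(as.character(s)))
  n <- length(drug_order)
  m <- diag(1, n)
  if (n > 1) {
    # sparse incidence trick: |a intersect b| via crossprod of indicator matrix
    feats <- lapply(drug_order, function(d) sets[[d]] %||% character())
    sizes <- lengths(feats)
    all_f <- unique(unlist(feats))
    if (length(all_f) > 0) {
      inc <- matrix(0L, n, length(all_f), dimnames = list(NULL, all_f))
      for (i in seq_len(n)) inc[i, feats[[i]]] <- 1L
      inter <- tcrossprod(inc)
      uni <- outer(sizes, sizes, `+`) - inter
      m <- ifelse(uni > 0, inter / uni, 0)
      diag(m) <- 1
    }
  }
  similarity_matrix(m, drug_order)
}

#' Disease DAG
#'
#' The ancestor graph of one disease term: nodes are the disease and all of
#' its ancestors, edges point child -> parent.  Used by the semantic
#' similarity of the disease network.
#'
#' @param disease_id the root disease term.
#' @param edges two-column data frame / tibble (`child`, `parent`), possibly
#'   empty for a singleton DAG.
#' @param delta semantic contribution decay per edge, in (0, 1\]; 0.5 by
#'   convention.
#' @return A `disease_dag` object.
#' @export
disease_dag <- function(disease_id, edges = NULL, delta = 0.5) {
  disease_id <- as.character(disease_id)
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble(child = character(), parent = character())
  } else {
    edges <- tibble(
      child = as.character(edges[[1]]),
      parent = as.character(edges[[2]])
    )
    edges <- dplyr::distinct(edges)
    edges <- edges[!(edges$child == disease_id & edges$parent == disease_id), ]
  }
  if (!is.numeric(delta) || delta <= 0 || delta > 1) {
    abort("`delta` must lie in (0, 1]")
  }
  nodes <- union(disease_id, union(edges$child, edges$parent))
  structure(
    list(disease_id = disease_id, nodes = nodes, edges = edges, delta = delta),
    class = "disease_dag"
  )
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf(
    "<disease_dag> %s: %d node(s), %d edge(s), delta = %g\n",
    x$disease_id, length(x$nodes), nrow(x$edges), x$delta
  ))
  invisible(x)
}

#' Semantic contribution profile of a disease DAG
#'
#' Assigns every ancestor term `s` its semantic contribution to the disease
#' `d`: the disease itself contributes 1 and each other term contributes
#' `max(delta * contribution(child))` over its children inside the DAG, so
#' contributions decay by `delta` per edge along the best (shortest) path
#' from the disease.  The semantic value DV(d) is the sum of all
#' contributions.
#'
#' @param dag a [disease_dag()].
#' @return A list with `disease_id`, `contributions` (named numeric vector),
#'   and `semantic_value`, of class `semantic_profile`.
#' @export
semantic_profile <- function(dag) {
  stopifnot(inherits(dag, "disease_dag"))
  d <- dag$disease_id
  contrib <- setNames(rep(NA_real_, length(dag$nodes)), dag$nodes)
  contrib[d] <- 1
  # children within the DAG, indexed by parent
  kids <- split(dag$edges$child, dag$edges$parent)
  visiting <- character()
  eval_node <- function(s) {
    if (!is.na(contrib[[s]])) return(contrib[[s]])
    if (s %in% visiting) {
      i <- which(dag$edges$parent == s)[1]
      abort(sprintf(
        "cycle detected in DAG of '%s' through edge %s -> %s",
        d, dag$edges$child[i], dag$edges$parent[i]
      ))
    }
    visiting <<- c(visiting, s)
    ch <- kids[[s]]
    if (is.null(ch) || length(ch) == 0) {
      abort(sprintf(
        "node '%s' in DAG of '%s' is not reachable from the disease", s, d
      ))
    }
    v <- max(vapply(ch, eval_node, numeric(1))) * dag$delta
    visiting <<- setdiff(visiting, s)
    contrib[[s]] <<- v
    v
  }
  for (s in dag$nodes) eval_node(s)
  structure(
    list(
      disease_id = d,
      contributions = contrib,
      semantic_value = sum(contrib)
    ),
    class = "semantic_profile"
  )
}

#' Semantic similarity of two diseases
#'
#' Shared-ancestor similarity: the contributions of terms present in both
#' DAGs, summed from both sides, normalised by the two semantic values.
#' Identical profiles score 1; disjoint term sets score 0.
#'
#' @param p1,p2 [semantic_profile()] objects computed with the same `delta`.
#' @return A similarity score in \[0, 1\].
#' @export
disease_semantic_similarity <- function(p1, p2) {
  stopifnot(inherits(p1, "semantic_profile"), inherits(p2, "semantic_profile"))
  shared <- intersect(names(p1$contributions), names(p2$contributions))
  if (length(shared) == 0) return(0)
  num <- sum(p1$contributions[shared]) + sum(p2$contributions[shared])
  num / (p1$semantic_value + p2$semantic_value)
}

#' Disease semantic similarity matrix
#'
#' Pairwise [disease_semantic_similarity()] over an ordered disease list.
#' Diseases with no DAG keep an identity row (self-similarity 1, 0
#' elsewhere) so the matrix stays aligned with the association table.
#'
#' @param dags named list of [disease_dag()] objects (names are disease ids).
#' @param order character vector fixing the row/column ordering.
#' @return A [similarity_matrix()] over `order`.
#' @export
disease_similarity_matrix <- function(dags, order) {
  order <- as.character(order)
  check_no_duplicates(order, "disease id")
  deltas <- unique(vapply(dags, function(d) d$delta, numeric(1)))
  if (length(deltas) > 1) {
    abort("all disease DAGs must share the same `delta`")
  }
  profiles <- lapply(dags, semantic_profile)
  n <- length(order)
  m <- diag(1, n)
  have <- order %in% names(profiles)
  idx <- which(have)
  if (length(idx) > 1) {
    for (a in seq_along(idx)[-1]) {
      for (b in seq_len(a - 1)) {
        i <- idx[a]; j <- idx[b]
        s <- disease_semantic_similarity(
          profiles[[order[i]]], profiles[[order[j]]]
        )
        m[i, j] <- s
        m[j, i] <- s
      }
    }
  }
  similarity_matrix(m, order)
}

#' Fuse drug similarity matrices
#'
#' Combines the per-feature-kind drug similarity matrices into the drug
#' block of the heterogeneous network.  `mode = "mean"` takes the
#' element-wise arithmetic mean (diagonal re-forced to 1); `mode =
#' "per_network"` returns the list unchanged for the pathway that builds one
#' heterogeneous network per feature kind.
#'
#' @param mats list of [similarity_matrix()] objects sharing one id ordering
#'   (1 to 3 of them; feature-kind ablations pass fewer than three).
#' @param mode `"mean"` (default) or `"per_network"`.
#' @return A [similarity_matrix()], or the input list for `"per_network"`.
#' @export
fuse_drug_similarities <- function(mats, mode = c("mean", "per_network")) {
  mode <- match.arg(mode)
  if (inherits(mats, "similarity_matrix")) mats <- list(mats)
  if (length(mats) < 1) abort("need at least one similarity matrix")
  ids <- sim_ids(mats[[1]])
  for (k in seq_along(mats)) {
    other <- sim_ids(mats[[k]])
    if (!identical(other, ids)) {
      bad <- which(other != ids)[1] %||% (min(length(other), length(ids)) + 1)
      abort(sprintf(
        "id orderings differ between matrices 1 and %d at position %d", k, bad
      ))
    }
  }
  if (mode == "per_network") return(mats)
  m <- Reduce(`+`, lapply(mats, unclass)) / length(mats)
  diag(m) <- 1
  similarity_matrix(m, ids)
}
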