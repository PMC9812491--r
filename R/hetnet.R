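#' Drug-disease association matrix
#'
#' Binary matrix with drugs as rows and diseases as columns; entry (i, j) is
#' 1 when the pair appears in `pairs`.  Duplicate pairs collapse to a single
#' 1.
#'
#' @param pairs tibble/data frame with columns `drug_id`, `disease_id`.
#' @param drug_ids,disease_ids ordered id vectors fixing the matrix layout.
#' @return An `association_matrix` (binary matrix with id dimnames).
#' @export
build_association_matrix <- function(pairs, drug_ids, disease_ids) {
  drug_ids <- as.character(drug_ids)
  disease_ids <- as.character(disease_ids)
  check_no_duplicates(drug_ids, "drug id")
  check_no_duplicates(disease_ids, "disease id")
  m <- matrix(0, length(drug_ids), length(disease_ids),
    dimnames = list(drug_ids, disease_ids)
  )
  if (!is.null(pairs) && nrow(pairs) > 0) {
    rid <- as.character(pairs$drug_id)
    did <- as.character(pairs$disease_id)
    bad <- setdiff(rid, drug_ids)
    if (length(bad)) abort(sprintf("unknown drug id: '%s'", bad[[1]]))
    bad <- setdiff(did, disease_ids)
    if (length(bad)) abort(sprintf("unknown disease id: '%s'", bad[[1]]))
    m[cbind(match(rid, drug_ids), match(did, disease_ids))] <- 1
  }
  structure(m, class = c("association_matrix", "matrix", "array"))
}

assoc_pairs <- function(m_rd) {
  idx <- which(unclass(m_rd) == 1, arr.ind = TRUE)
  tibble(
    drug_id = rownames(m_rd)[idx[, 1]],
    disease_id = colnames(m_rd)[idx[, 2]]
  )
}

#' Mask held-out associations
#'
#' Returns a copy of the association matrix with the held-out pairs zeroed,
#' used to keep test-fold associations out of the network the model trains
#' on.  Masking an entry that is already 0 errors, as that signals a fold
#' bookkeeping bug.
#'
#' @param m_rd an [build_association_matrix()] result.
#' @param held_out tibble with columns `drug_id`, `disease_id` (may be empty).
#' @return The masked association matrix.
#' @export
mask_test_edges <- function(m_rd, held_out) {
  out <- m_rd
  if (is.null(held_out) || nrow(held_out) == 0) return(out)
  i <- match(as.character(held_out$drug_id), rownames(m_rd))
  j <- match(as.character(held_out$disease_id), colnames(m_rd))
  if (anyNA(i) || anyNA(j)) abort("held-out pair references an unknown id")
  cur <- out[cbind(i, j)]
  if (any(cur != 1)) {
    k <- which(cur != 1)[1]
    abort(sprintf(
      "cannot mask (%s, %s): entry is not a known association",
      held_out$drug_id[k], held_out$disease_id[k]
    ))
  }
  out[cbind(i, j)] <- 0
  out
}

#' Assemble the drug-disease heterogeneous network
#'
#' Builds the block adjacency `M_h = [[M_r, M_rd], [M_rd', M_d]]`, adds a
#' self-loop to every node (`A = M_h + I`), computes the weighted degree
#' matrix and the symmetric normalisation `D^{-1/2} A D^{-1/2}` used by the
#' graph-convolutional encoder, and the initial feature matrix
#' `X0 = [[0, M_rd], [M_rd', 0]]`.  Drugs occupy the first `N_r` rows,
#' diseases the remaining `N_d`.
#'
#' @param m_r drug [similarity_matrix()].
#' @param m_d disease [similarity_matrix()].
#' @param m_rd [build_association_matrix()] result with matching orderings.
#' @return A `het_network` list with elements `m_h`, `a`, `degree`
#'   (vector of weighted degrees), `a_norm`, `x0`, `drug_ids`, `disease_ids`.
#' @export
build_heterogeneous_network <- function(m_r, m_d, m_rd) {
  drug_ids <- rownames(m_rd)
  disease_ids <- colnames(m_rd)
  if (!identical(sim_ids(m_r), drug_ids)) {
    abort("drug id ordering of `m_r` does not match `m_rd` rows")
  }
  if (!identical(sim_ids(m_d), disease_ids)) {
    abort("disease id ordering of `m_d` does not match `m_rd` columns")
  }
  mr <- unclass(m_r); md <- unclass(m_d); mrd <- unclass(m_rd)
  m_h <- rbind(cbind(mr, mrd), cbind(t(mrd), md))
  n <- nrow(m_h)
  node_ids <- c(drug_ids, disease_ids)
  dimnames(m_h) <- list(node_ids, node_ids)
  a <- m_h + diag(n)
  deg <- rowSums(a)
  stopifnot(all(deg >= 1)) # self-loop guarantees positivity
  dinv <- 1 / sqrt(deg)
  a_norm <- a * (dinv %o% dinv)
  zero_r <- matrix(0, length(drug_ids), length(drug_ids))
  zero_d <- matrix(0, length(disease_ids), length(disease_ids))
  x0 <- rbind(cbind(zero_r, mrd), cbind(t(mrd), zero_d))
  dimnames(x0) <- dimnames(m_h)
  structure(
    list(
      m_h = m_h, a = a, degree = deg, a_norm = a_norm, x0 = x0,
      drug_ids = drug_ids, disease_ids = disease_ids
    ),
    class = "het_network"
  )
}

#' @export
print.het_network <- function(x, ...) {
  cat(sprintf(
    "<het_network> %d drugs + %d diseases, %d association edge(s)\n",
    length(x$drug_ids), length(x$disease_ids),
    sum(x$x0[seq_along(x$drug_ids), -seq_along(x$drug_ids), drop = FALSE])
  ))
  invisible(x)
}

#' Heterogeneous network as a tidy edge list
#'
#' @param net a [build_heterogeneous_network()] result.
#' @return Tibble with `node_u`, `node_v`, `weight`, `edge_type` (one of
#'   drug-drug, disease-disease, drug-disease); upper triangle only, zero
#'   weights dropped.
#' @export
hetnet_edge_list <- function(net) {
  m <- net$m_h
  nr <- length(net$drug_ids)
  idx <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
  type <- ifelse(
    idx[, 1] <= nr & idx[, 2] <= nr, "drug-drug",
    ifelse(idx[, 1] > nr & idx[, 2] > nr, "disease-disease", "drug-disease")
  )
  tibble(
    node_u = rownames(m)[idx[, 1]],
    node_v = colnames(m)[idx[, 2]],
    weight = m[idx],
    edge_type = type
  )
}
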