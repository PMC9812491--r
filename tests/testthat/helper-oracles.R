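# Independent brute-force oracles used across the suite.  These deliberately
# re-derive quantities by enumeration so they share no code with the package
# implementations they check.

# Semantic contribution by exhaustive path enumeration: D_d(s) is the max of
# delta^(path length) over every directed child->parent path from d to s.
oracle_semantic_profile <- function(dag) {
  edges <- dag$edges
  contrib <- setNames(rep(-Inf, length(dag$nodes)), dag$nodes)
  walk <- function(node, depth) {
    v <- dag$delta^depth
    if (v > contrib[[node]]) contrib[[node]] <<- v
    parents <- edges$parent[edges$child == node]
    for (p in parents) walk(p, depth + 1)
  }
  walk(dag$disease_id, 0)
  contrib
}

# AUC by exhaustive pair counting with ties worth 0.5.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# AUPR by walking the full precision-recall step curve threshold by
# threshold (distinct scores descending, ties grouped).
oracle_aupr <- function(labels, scores) {
  np <- sum(labels == 1)
  if (np == 0 || sum(labels == 0) == 0) return(NA_real_)
  cuts <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  area <- 0
  for (ct in cuts) {
    sel <- scores >= ct
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / np
    area <- area + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  area
}

# Direct nested-loop evaluation of one conv layer (stride 1, valid
# placement, ReLU), input and filters as plain arrays.
oracle_conv <- function(x, w, b) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1)
  if (is.matrix(w)) dim(w) <- c(dim(w), 1, 1)
  dx <- dim(x); dw <- dim(w)
  ho <- dx[1] - dw[1] + 1; wo <- dx[2] - dw[2] + 1
  out <- array(0, c(ho, wo, dw[4]))
  for (k in seq_len(dw[4])) {
    for (i in seq_len(ho)) {
      for (j in seq_len(wo)) {
        acc <- b[k]
        for (di in seq_len(dw[1])) {
          for (dj in seq_len(dw[2])) {
            for (c in seq_len(dx[3])) {
              acc <- acc + x[i + di - 1, j + dj - 1, c] * w[di, dj, c, k]
            }
          }
        }
        out[i, j, k] <- max(acc, 0)
      }
    }
  }
  out
}

# Ceil-mode non-overlapping max pooling by direct loops.
oracle_pool <- function(m, p_l, p_w) {
  ph <- ceiling(nrow(m) / p_l); pw <- ceiling(ncol(m) / p_w)
  out <- matrix(0, ph, pw)
  for (a in seq_len(ph)) {
    for (b in seq_len(pw)) {
      ri <- ((a - 1) * p_l + 1):min(a * p_l, nrow(m))
      ci <- ((b - 1) * p_w + 1):min(b * p_w, ncol(m))
      out[a, b] <- max(m[ri, ci])
    }
  }
  out
}

# Random DAG over <= max_nodes nodes: a chain/merge structure built by
# attaching each new ancestor under one or two existing nodes.
random_dag <- function(max_nodes = 10, delta = 0.5) {
  n <- sample(1:max_nodes, 1)
  nodes <- sprintf("t%02d", seq_len(n))
  d <- nodes[1]
  if (n == 1) return(disease_dag(d, NULL, delta = delta))
  children <- list()
  edges <- NULL
  for (i in 2:n) {
    # parent node i attaches above 1-2 already-reachable nodes
    k <- sample(1:min(2, i - 1), 1)
    kids <- sample(nodes[seq_len(i - 1)], k)
    edges <- rbind(edges, data.frame(child = kids, parent = nodes[i]))
  }
  disease_dag(d, edges, delta = delta)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
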