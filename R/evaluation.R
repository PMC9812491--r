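#' Sample negative drug-disease pairs
#'
#' Uniform seeded sample without replacement from the zero cells of the
#' association matrix — unobserved pairs presumed negative, matched 1:1 to
#' the positives by the evaluation protocol.
#'
#' @param m_rd an association matrix.
#' @param count number of negatives to draw.
#' @param seed integer seed.
#' @return Tibble `drug_id`, `disease_id`.
#' @export
sample_negatives <- function(m_rd, count, seed = 1) {
  zeros <- which(unclass(m_rd) == 0)
  if (count > length(zeros)) {
    abort(sprintf(
      "requested %d negatives but only %d unobserved pairs exist",
      count, length(zeros)
    ))
  }
  if (count == 0) {
    return(tibble(drug_id = character(), disease_id = character()))
  }
  picked <- with_seed(seed, zeros[sample.int(length(zeros), count)])
  nr <- nrow(m_rd)
  tibble(
    drug_id = rownames(m_rd)[(picked - 1) %% nr + 1],
    disease_id = colnames(m_rd)[(picked - 1) %/% nr + 1]
  )
}

#' Labelled pair set
#'
#' @param positives,negatives tibbles of (`drug_id`, `disease_id`) pairs;
#'   the two lists must be disjoint and duplicate-free.
#' @return A `labelled_pair_set` list.
#' @export
labelled_pair_set <- function(positives, negatives) {
  key <- function(p) paste(p$drug_id, p$disease_id, sep = "\r")
  check_no_duplicates(key(positives), "positive pair")
  check_no_duplicates(key(negatives), "negative pair")
  if (length(intersect(key(positives), key(negatives))) > 0) {
    abort("a pair appears in both the positive and negative lists")
  }
  structure(
    list(
      positives = as_tibble(positives),
      negatives = as_tibble(negatives)
    ),
    class = "labelled_pair_set"
  )
}

#' Five-fold split with an independent test fold
#'
#' Shuffles positives and negatives separately (seeded) and deals them
#' round-robin into `k` folds.  Each of the `k` rotations designates one
#' positive and one negative fold as the independent test set and the
#' remaining `k - 1` of each as the cross-validation set.
#'
#' @param pairs a [labelled_pair_set()].
#' @param k number of folds (default 5).
#' @param seed integer seed for the shuffles.
#' @return A `cv_split` with per-pair fold assignments.
#' @export
make_cv_split <- function(pairs, k = 5, seed = 1) {
  stopifnot(inherits(pairs, "labelled_pair_set"))
  np <- nrow(pairs$positives)
  nn <- nrow(pairs$negatives)
  if (np < k || nn < k) {
    abort(sprintf("need at least %d positives and negatives for %d folds", k, k))
  }
  # shuffle, then deal round-robin: fold sizes differ by at most one
  folds <- with_seed(seed, {
    fp <- integer(np)
    fp[sample.int(np)] <- rep_len(seq_len(k), np)
    fn <- integer(nn)
    fn[sample.int(nn)] <- rep_len(seq_len(k), nn)
    list(positive = fp, negative = fn)
  })
  structure(
    list(pairs = pairs, k = k, folds = folds, seed = seed),
    class = "cv_split"
  )
}

#' Extract one rotation of a CV split
#'
#' @param split a [make_cv_split()] result.
#' @param rotation which fold (1..k) acts as the independent test fold.
#' @return List with `cv` and `test`, each a tibble `drug_id`, `disease_id`,
#'   `label`.
#' @export
cv_rotation <- function(split, rotation) {
  stopifnot(rotation >= 1, rotation <= split$k)
  pos <- dplyr::mutate(split$pairs$positives, label = 1)
  neg <- dplyr::mutate(split$pairs$negatives, label = 0)
  fp <- split$folds$positive
  fn <- split$folds$negative
  list(
    cv = dplyr::bind_rows(pos[fp != rotation, ], neg[fn != rotation, ]),
    test = dplyr::bind_rows(pos[fp == rotation, ], neg[fn == rotation, ])
  )
}

# Rank-based AUC (Mann-Whitney with ties counted 0.5).
auc_rank <- function(labels, scores) {
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

# Step-wise area under the precision-recall curve: descending score order,
# tied scores grouped, sum of P(t) * (R(t) - R(t-1)) over distinct cutoffs.
aupr_step <- function(labels, scores) {
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  ctp <- cumsum(l == 1)
  cfp <- cumsum(l == 0)
  last <- c(s[-1] != s[-length(s)], TRUE) # last index of each tie group
  tp <- ctp[last]
  fp <- cfp[last]
  prec <- tp / (tp + fp)
  rec <- tp / np
  sum(prec * diff(c(0, rec)))
}

#' Confusion counts and the seven evaluation metrics
#'
#' Thresholds the scores (prediction positive when score >= threshold) and
#' reports TP/FP/TN/FN, TPR/FPR, precision, recall, specificity, accuracy,
#' F1, plus threshold-free AUC (rank formulation, ties 0.5) and AUPR
#' (step-wise precision-recall integration).
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores, same length.
#' @param threshold decision threshold (default 0.5).
#' @return One-row tibble (class `metrics_report`).
#' @export
confusion_and_metrics <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores))
  labels <- as.numeric(labels)
  stopifnot(all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2) {
    warn("single-class labels: AUC and AUPR are undefined (reported as NA)")
  }
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  out <- tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    tpr = recall,
    fpr = safe_div(fp, tn + fp),
    auc = auc_rank(labels, scores),
    aupr = aupr_step(labels, scores),
    f1 = f1,
    accuracy = (tp + tn) / length(labels),
    specificity = safe_div(tn, tn + fp),
    precision = precision,
    recall = recall,
    threshold = threshold
  )
  class(out) <- c("metrics_report", class(out))
  out
}

#' ROC and PR curve points
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores.
#' @return Tibble with `threshold`, `fpr`, `tpr`, `recall`, `precision` at
#'   every distinct cutoff.
#' @export
roc_pr_points <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  l <- labels[ord]
  s <- scores[ord]
  np <- sum(l == 1)
  nn <- sum(l == 0)
  ctp <- cumsum(l == 1)
  cfp <- cumsum(l == 0)
  last <- c(s[-1] != s[-length(s)], TRUE)
  tibble(
    threshold = s[last],
    fpr = cfp[last] / nn,
    tpr = ctp[last] / np,
    recall = ctp[last] / np,
    precision = ctp[last] / (ctp[last] + cfp[last])
  )
}

#' Rank candidate drugs for a disease
#'
#' Scores every drug against the query disease with the trained classifier
#' and returns them in descending probability order (ties broken by drug
#' id).  With `exclude_known`, drugs already associated with the disease in
#' the supplied association matrix are dropped first.
#'
#' @param emb a `node_embeddings` object.
#' @param fit trained `cnn_fit`.
#' @param query a disease id present in the embeddings.
#' @param m_rd association matrix of known (training) pairs; required when
#'   `exclude_known = TRUE`.
#' @param exclude_known drop drugs already known for the query.
#' @param top_n optionally keep only the first `top_n` rows.
#' @return Tibble `rank`, `drug_id`, `disease_id`, `probability`.
#' @export
rank_candidates <- function(emb, fit, query, m_rd = NULL,
                            exclude_known = FALSE, top_n = NULL) {
  ids <- rownames(emb$x2)
  drugs <- ids[emb$drug_rows]
  diseases <- ids[emb$disease_rows]
  query <- as.character(query)
  if (!query %in% diseases) abort(sprintf("unknown disease: '%s'", query))
  if (exclude_known) {
    if (is.null(m_rd)) abort("`m_rd` is required when `exclude_known = TRUE`")
    known <- rownames(m_rd)[unclass(m_rd)[, query] == 1]
    drugs <- setdiff(drugs, known)
  }
  if (length(drugs) == 0) {
    return(tibble(
      rank = integer(), drug_id = character(),
      disease_id = character(), probability = numeric()
    ))
  }
  preds <- predict_pairs(
    emb, fit, tibble(drug_id = drugs, disease_id = query)
  )
  preds <- preds[order(-preds$probability, preds$drug_id), ]
  preds$rank <- seq_len(nrow(preds))
  if (!is.null(top_n)) preds <- utils::head(preds, top_n)
  preds[, c("rank", "drug_id", "disease_id", "probability")]
}
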