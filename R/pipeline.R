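#' Pipeline configuration
#'
#' Collects every tunable of the pipeline: similarity fusion, encoder
#' dimensions and training settings, classifier geometry and training
#' settings, the evaluation protocol, and the leakage-control flag that
#' masks test-fold associations out of the network before training.
#'
#' @param delta semantic contribution factor of the disease DAGs.
#' @param fusion `"mean"` or `"per_network"` drug-similarity fusion.
#' @param kinds drug feature kinds to use (subset of che/dom/anno).
#' @param mask_test mask test positives out of the network (default TRUE).
#' @param threshold decision threshold for the thresholded metrics.
#' @param k cross-validation folds.
#' @param vgae list of encoder settings (`d0`, `d1`, `lr`, `epochs`,
#'   `head_activation`).
#' @param cnn list of classifier settings (`n_conv`, `filter1`, `filter`,
#'   `pool`, `fc`, `dropout`, `lr`, `epochs`, `batch_size`).
#' @return A `hetvgae_config` list.
#' @export
hetvgae_config <- function(delta = 0.5,
                           fusion = c("mean", "per_network"),
                           kinds = c("che", "dom", "anno"),
                           mask_test = TRUE,
                           threshold = 0.5,
                           k = 5,
                           vgae = list(),
                           cnn = list()) {
  fusion <- match.arg(fusion)
  vgae_defaults <- list(
    d0 = 128, d1 = 64, lr = 0.01, epochs = 200, head_activation = "linear"
  )
  cnn_defaults <- list(
    n_conv = 16, filter1 = c(2, 3), filter = c(1, 3), pool = c(1, 2),
    fc = c(1024, 1024, 512), dropout = 0.1, lr = 0.001, epochs = 30,
    batch_size = 128
  )
  structure(
    list(
      delta = delta, fusion = fusion, kinds = kinds, mask_test = mask_test,
      threshold = threshold, k = k,
      vgae = utils::modifyList(vgae_defaults, vgae),
      cnn = utils::modifyList(cnn_defaults, cnn)
    ),
    class = "hetvgae_config"
  )
}

#' Compact configuration for small networks
#'
#' The package defaults size the model for association networks with
#' hundreds to thousands of nodes.  This profile shrinks the encoder and
#' classifier for networks of a couple of hundred nodes — the scale of the
#' bundled synthetic studies — so a full cross-validated run takes minutes
#' on one CPU while exercising every stage of the pipeline.
#'
#' @param ... overrides forwarded to [hetvgae_config()].
#' @return A `hetvgae_config`.
#' @export
compact_config <- function(...) {
  base <- hetvgae_config(
    vgae = list(d0 = 32, d1 = 16, epochs = 300),
    cnn = list(
      n_conv = 4, fc = c(64, 64, 32), epochs = 30, batch_size = 128
    )
  )
  utils::modifyList(base, list(...))
}

# Similarity matrices + association matrix for a dataset, for one subset of
# feature kinds.
build_dataset_matrices <- function(data, config) {
  kinds <- intersect(config$kinds, names(data$features))
  if (length(kinds) == 0) abort("no usable feature kinds in the dataset")
  drug_sims <- lapply(kinds, function(k) {
    drug_similarity_matrix(data$features[[k]], data$drug_ids)
  })
  if (identical(config$fusion, "per_network")) {
    # the per-network pathway is exposed at the operation level
    # (fuse_drug_similarities); the end-to-end pipeline embeds one fused
    # network and has no learned merge of per-network embeddings
    abort("the pipeline requires fusion = \"mean\"; see fuse_drug_similarities() for the per-network pathway")
  }
  m_r <- fuse_drug_similarities(drug_sims, mode = "mean")
  m_d <- disease_similarity_matrix(data$dags, data$disease_ids)
  m_rd <- build_association_matrix(
    data$associations, data$drug_ids, data$disease_ids
  )
  list(m_r = m_r, m_d = m_d, m_rd = m_rd, kinds = kinds)
}

# Train VGAE + classifier on one cv set and score one test set.
# `mask_pairs` defaults to the test positives; the label-shuffled null
# control passes the true (pre-shuffle) positives explicitly.
fit_and_score <- function(mats, cv, test, config, seed, mask_pairs = NULL) {
  m_rd_train <- if (config$mask_test) {
    mask_test_edges(mats$m_rd, mask_pairs %||% test[test$label == 1, ])
  } else {
    mats$m_rd
  }
  net <- build_heterogeneous_network(mats$m_r, mats$m_d, m_rd_train)
  vfit <- train_vgae(net,
    d0 = config$vgae$d0, d1 = config$vgae$d1, lr = config$vgae$lr,
    epochs = config$vgae$epochs,
    head_activation = config$vgae$head_activation,
    seed = derive_seed(seed, "vgae")
  )
  cfit <- train_classifier(
    vfit$embeddings, cv,
    params = cnn_params(
      d1 = config$vgae$d1, n_conv = config$cnn$n_conv,
      filter1 = config$cnn$filter1, filter = config$cnn$filter,
      pool = config$cnn$pool, fc = config$cnn$fc,
      dropout = config$cnn$dropout, seed = derive_seed(seed, "cnn-init")
    ),
    lr = config$cnn$lr, epochs = config$cnn$epochs,
    batch_size = config$cnn$batch_size, seed = derive_seed(seed, "cnn")
  )
  preds <- predict_pairs(vfit$embeddings, cfit, test)
  metrics <- confusion_and_metrics(
    preds$label, preds$probability, threshold = config$threshold
  )
  list(
    vgae = vfit, cnn = cfit, predictions = preds, metrics = metrics,
    m_rd_train = m_rd_train
  )
}

#' Run the cross-validated evaluation protocol
#'
#' Samples negatives 1:1 with the positives (once per experiment), splits
#' both into `k` folds, and for every rotation trains the encoder and the
#' classifier on the cross-validation set and scores the independent test
#' fold.  Test-fold positives are masked out of the network the encoder
#' sees unless `config$mask_test` is off.  Per-rotation metrics and their
#' unweighted mean are returned.
#'
#' @param data dataset list with `features`, `dags`, `associations`,
#'   `drug_ids`, `disease_ids` (e.g. a [generate_synthetic_dataset()] or
#'   [read_dataset()] result).
#' @param config a [hetvgae_config()].
#' @param seed integer seed governing negative sampling, folding, and every
#'   training run.
#' @param shuffle_labels permute the pair labels before training — a null
#'   control that should score at chance.
#' @return A `cv_result` with `rotations` (per-rotation metrics tibble),
#'   `mean` (one-row tibble), and `predictions`.
#' @export
run_cross_validation <- function(data, config = hetvgae_config(), seed = 1,
                                 shuffle_labels = FALSE) {
  mats <- build_dataset_matrices(data, config)
  positives <- assoc_pairs(mats$m_rd)
  negatives <- sample_negatives(
    mats$m_rd, nrow(positives),
    seed = derive_seed(seed, "negatives")
  )
  pair_set <- labelled_pair_set(positives, negatives)
  split <- make_cv_split(pair_set,
    k = config$k, seed = derive_seed(seed, "folds")
  )
  rotations <- vector("list", config$k)
  all_preds <- vector("list", config$k)
  for (r in seq_len(config$k)) {
    rot <- cv_rotation(split, r)
    mask_pairs <- rot$test[rot$test$label == 1, ]
    if (shuffle_labels) {
      rot <- shuffle_rotation_labels(rot, derive_seed(seed, paste0("shuf", r)))
    }
    res <- tryCatch(
      fit_and_score(mats, rot$cv, rot$test, config,
        seed = derive_seed(seed, paste0("rot", r)),
        mask_pairs = mask_pairs
      ),
      error = function(e) {
        abort(sprintf("rotation %d failed: %s", r, conditionMessage(e)))
      }
    )
    rotations[[r]] <- dplyr::mutate(res$metrics, rotation = r, .before = 1)
    all_preds[[r]] <- dplyr::mutate(res$predictions, rotation = r, .before = 1)
  }
  rot_tbl <- dplyr::bind_rows(rotations)
  mean_tbl <- dplyr::summarise(
    rot_tbl,
    dplyr::across(-"rotation", ~ mean(.x, na.rm = TRUE))
  )
  structure(
    list(
      rotations = rot_tbl,
      mean = mean_tbl,
      predictions = dplyr::bind_rows(all_preds),
      split = split,
      config = config,
      seed = seed
    ),
    class = "cv_result"
  )
}

# Null control: permute labels within the cv and test sets jointly, keeping
# the pair lists and fold sizes intact.
shuffle_rotation_labels <- function(rot, seed) {
  with_seed(seed, {
    rot$cv$label <- sample(rot$cv$label)
    rot$test$label <- sample(rot$test$label)
  })
  rot
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %d rotations | mean AUC %.3f, AUPR %.3f, F1 %.3f\n",
    nrow(x$rotations), x$mean$auc, x$mean$aupr, x$mean$f1
  ))
  invisible(x)
}

#' Feature-kind ablation study
#'
#' Trains and scores the pipeline with different subsets of the drug
#' feature kinds on a single train/test rotation per seed, mirroring the
#' ablation logic of dropping one information source at a time.
#'
#' @param data dataset list (see [run_cross_validation()]).
#' @param kind_sets named list of feature-kind subsets to compare.
#' @param config a [hetvgae_config()]; its `kinds` field is overridden.
#' @param seeds integer seeds.
#' @param rotations how many of the `k` fold rotations to train and score
#'   per seed (default 1; more rotations reduce the variance of the
#'   per-seed estimate at proportional cost).
#' @return Tibble with `setting`, `seed`, `rotation`, and the metric
#'   columns.
#' @export
run_feature_ablation <- function(data,
                                 kind_sets = list(
                                   all = c("che", "dom", "anno"),
                                   che = "che", dom = "dom", anno = "anno"
                                 ),
                                 config = hetvgae_config(),
                                 seeds = 1:5, rotations = 1) {
  out <- list()
  for (setting in names(kind_sets)) {
    cfg <- config
    cfg$kinds <- kind_sets[[setting]]
    mats <- build_dataset_matrices(data, cfg)
    for (seed in seeds) {
      positives <- assoc_pairs(mats$m_rd)
      negatives <- sample_negatives(
        mats$m_rd, nrow(positives),
        seed = derive_seed(seed, "negatives")
      )
      split <- make_cv_split(
        labelled_pair_set(positives, negatives),
        k = cfg$k, seed = derive_seed(seed, "folds")
      )
      for (r in seq_len(rotations)) {
        rot <- cv_rotation(split, r)
        res <- fit_and_score(mats, rot$cv, rot$test, cfg,
          seed = derive_seed(seed, paste0("rot", r))
        )
        out[[length(out) + 1]] <- dplyr::mutate(
          res$metrics,
          setting = setting, seed = seed, rotation = r, .before = 1
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Train the full pipeline once
#'
#' Builds the network from all supplied associations, trains the encoder
#' and the classifier, and returns both fits for downstream prediction and
#' candidate ranking.
#'
#' @inheritParams run_cross_validation
#' @param negatives optional tibble of negative pairs; sampled 1:1 when
#'   missing.
#' @return A `hetvgae_fit` list with `vgae`, `cnn`, `matrices`, `config`.
#' @export
train_pipeline <- function(data, config = hetvgae_config(), seed = 1,
                           negatives = NULL) {
  mats <- build_dataset_matrices(data, config)
  positives <- assoc_pairs(mats$m_rd)
  if (is.null(negatives)) {
    negatives <- sample_negatives(
      mats$m_rd, nrow(positives),
      seed = derive_seed(seed, "negatives")
    )
  }
  train <- dplyr::bind_rows(
    dplyr::mutate(positives, label = 1),
    dplyr::mutate(negatives, label = 0)
  )
  net <- build_heterogeneous_network(mats$m_r, mats$m_d, mats$m_rd)
  vfit <- train_vgae(net,
    d0 = config$vgae$d0, d1 = config$vgae$d1, lr = config$vgae$lr,
    epochs = config$vgae$epochs,
    head_activation = config$vgae$head_activation,
    seed = derive_seed(seed, "vgae")
  )
  cfit <- train_classifier(
    vfit$embeddings, train,
    params = cnn_params(
      d1 = config$vgae$d1, n_conv = config$cnn$n_conv,
      filter1 = config$cnn$filter1, filter = config$cnn$filter,
      pool = config$cnn$pool, fc = config$cnn$fc,
      dropout = config$cnn$dropout, seed = derive_seed(seed, "cnn-init")
    ),
    lr = config$cnn$lr, epochs = config$cnn$epochs,
    batch_size = config$cnn$batch_size, seed = derive_seed(seed, "cnn")
  )
  structure(
    list(
      vgae = vfit, cnn = cfit, matrices = mats, config = config, seed = seed
    ),
    class = "hetvgae_fit"
  )
}

#' @export
print.hetvgae_fit <- function(x, ...) {
  cat(sprintf(
    "<hetvgae_fit> %d drugs x %d diseases; encoder d1=%d; classifier final loss %.4f\n",
    nrow(x$matrices$m_rd), ncol(x$matrices$m_rd),
    ncol(x$vgae$embeddings$x2), x$cnn$losses$loss[nrow(x$cnn$losses)]
  ))
  invisible(x)
}
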