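# Convolutional pair classifier.
#
# A drug-disease pair is represented as a 2 x d1 matrix (drug embedding row
# over disease embedding row), zero-padded by one ring, then pushed through
# three conv+max-pool stages with filter counts n_conv : 2*n_conv : 3*n_conv,
# three fully-connected layers and a 2-unit softmax.  Feature maps of shape
# (h, w, C) are stored flattened column-major, so a batch is a plain
# B x (h*w*C) matrix and convolution becomes an im2col gather followed by one
# matrix product — which also makes the backward pass a single scatter.

conv_geometry <- function(h, w, c_in, l, wd, k, p_l, p_w, stage) {
  if (l > h || wd > w) {
    abort(sprintf(
      "stage %d filter (%dx%d) larger than its input (%dx%d)",
      stage, l, wd, h, w
    ))
  }
  ho <- h - l + 1
  wo <- w - wd + 1
  npos <- ho * wo
  # im2col gather: idx[p, q] = flat input index of offset q at output pos p;
  # offset ordering matches as.vector() of an (l, wd, c_in) weight block
  pos_i <- rep(seq_len(ho), times = wo)
  pos_j <- rep(seq_len(wo), each = ho)
  di <- rep(0:(l - 1), times = wd * c_in)
  dj <- rep(rep(0:(wd - 1), each = l), times = c_in)
  c0 <- rep(0:(c_in - 1), each = l * wd)
  idx <- outer(pos_i, di, `+`) +
    (outer(pos_j, dj, `+`) - 1) * h +
    matrix(c0 * h * w, npos, length(c0), byrow = TRUE)

  # ceil-mode non-overlapping pooling; ragged edge keeps a truncated window
  ph <- ceiling(ho / p_l)
  pw <- ceiling(wo / p_w)
  out_a <- rep(seq_len(ph), times = pw)
  out_b <- rep(seq_len(pw), each = ph)
  da <- rep(0:(p_l - 1), times = p_w)
  db <- rep(rep(0:(p_w - 1), each = p_l), times = 1)
  src_i <- outer((out_a - 1) * p_l + 1, da, `+`)
  src_j <- outer((out_b - 1) * p_w + 1, db, `+`)
  memb <- src_i + (src_j - 1) * ho
  memb[src_i > ho | src_j > wo] <- NA_integer_
  # expand membership across the k output channels
  npo <- ph * pw
  chan_off <- rep((0:(k - 1)) * npos, each = npo)
  srcfull <- memb[rep(seq_len(npo), times = k), , drop = FALSE] + chan_off

  list(
    h = h, w = w, c_in = c_in, l = l, wd = wd, k = k,
    ho = ho, wo = wo, npos = npos, idx = idx,
    p_l = p_l, p_w = p_w, ph = ph, pw = pw, srcfull = srcfull,
    in_len = h * w * c_in, conv_len = npos * k, out_len = npo * k
  )
}

cnn_geometry <- function(d1, n_conv, filter1, filter, pool) {
  h <- 4
  w <- d1 + 2
  c_in <- 1
  stages <- vector("list", 3)
  ks <- c(n_conv, 2L * n_conv, 3L * n_conv)
  fs <- list(filter1, filter, filter)
  for (s in 1:3) {
    g <- conv_geometry(
      h, w, c_in, fs[[s]][1], fs[[s]][2], ks[s], pool[1], pool[2], s
    )
    if (g$ho < 1 || g$wo < 1 || g$ph < 1 || g$pw < 1) {
      abort(sprintf("geometry collapse at conv stage %d", s))
    }
    stages[[s]] <- g
    h <- g$ph
    w <- g$pw
    c_in <- ks[s]
  }
  list(stages = stages, flat = h * w * c_in, d1 = d1)
}

he_init <- function(fan_in, n) rnorm(n, sd = sqrt(2 / fan_in))

#' Initialise the convolutional classifier
#'
#' Three conv+pool stages with filter counts `n_conv`, `2*n_conv`,
#' `3*n_conv`, followed by fully-connected layers (`fc`, defaults 1024,
#' 1024, 512 — the first two each followed by dropout) and a 2-unit softmax.
#' Filter sizes, pooling windows and widths are configurable.
#'
#' @param d1 embedding dimension of the node embeddings being paired.
#' @param n_conv filters in the first conv layer (default 16).
#' @param filter1 (length, width) of first-layer filters; default `c(2, 3)`
#'   spans both embedding rows.
#' @param filter (length, width) of later-layer filters; default `c(1, 3)`.
#' @param pool (length, width) of the max-pool window; default `c(1, 2)`.
#' @param fc sizes of the three fully-connected layers.
#' @param dropout dropout rate after the first two FC layers (default 0.1).
#' @param seed seed for the weight initialisation.
#' @return A `cnn_params` object.
#' @export
cnn_params <- function(d1, n_conv = 16, filter1 = c(2, 3), filter = c(1, 3),
                       pool = c(1, 2), fc = c(1024, 1024, 512),
                       dropout = 0.1, seed = 1) {
  stopifnot(n_conv >= 1, dropout >= 0, dropout < 1, length(fc) == 3)
  geom <- cnn_geometry(d1, n_conv, filter1, filter, pool)
  with_seed(seed, {
    weights <- list()
    for (s in 1:3) {
      g <- geom$stages[[s]]
      fan <- g$l * g$wd * g$c_in
      weights[[paste0("conv", s)]] <- matrix(he_init(fan, fan * g$k), fan, g$k)
      weights[[paste0("cb", s)]] <- rep(0, g$k)
    }
    dims <- c(geom$flat, fc, 2)
    for (s in 1:4) {
      nm <- if (s == 4) "out" else paste0("fc", s)
      weights[[nm]] <- matrix(
        he_init(dims[s], dims[s] * dims[s + 1]), dims[s], dims[s + 1]
      )
      weights[[paste0("b_", nm)]] <- rep(0, dims[s + 1])
    }
    structure(
      list(
        weights = weights, geometry = geom,
        config = list(
          d1 = d1, n_conv = n_conv, filter1 = filter1, filter = filter,
          pool = pool, fc = fc, dropout = dropout
        )
      ),
      class = "cnn_params"
    )
  })
}

#' Pair feature tensor
#'
#' Stacks the drug and disease embedding rows into a 2 x d1 matrix and pads
#' a ring of zeros around it (so the convolution sees the boundary), giving
#' the 4 x (d1+2) input of the classifier.
#'
#' @param emb a `node_embeddings` object with row names.
#' @param drug_id,disease_id identifiers resolving to embedding rows.
#' @return A `pair_tensor` matrix with the ids attached as attributes.
#' @export
build_pair_tensor <- function(emb, drug_id, disease_id) {
  z <- emb$x2
  ids <- rownames(z)
  i <- match(as.character(drug_id), ids[emb$drug_rows])
  j <- match(as.character(disease_id), ids[emb$disease_rows])
  if (is.na(i)) abort(sprintf("unknown drug id: '%s'", drug_id))
  if (is.na(j)) abort(sprintf("unknown disease id: '%s'", disease_id))
  d1 <- ncol(z)
  m <- matrix(0, 4, d1 + 2)
  m[2, 2:(d1 + 1)] <- z[emb$drug_rows[i], ]
  m[3, 2:(d1 + 1)] <- z[emb$disease_rows[j], ]
  structure(m,
    class = c("pair_tensor", "matrix", "array"),
    drug_id = as.character(drug_id), disease_id = as.character(disease_id)
  )
}

# Batch of padded pair tensors as a B x (4*(d1+2)) matrix (flat (h,w) layout).
pair_batch_matrix <- function(emb, drug_id, disease_id) {
  z <- emb$x2
  ids <- rownames(z)
  i <- match(as.character(drug_id), ids[emb$drug_rows])
  j <- match(as.character(disease_id), ids[emb$disease_rows])
  if (anyNA(i)) {
    abort(sprintf("unknown drug id: '%s'", as.character(drug_id)[which(is.na(i))[1]]))
  }
  if (anyNA(j)) {
    abort(sprintf(
      "unknown disease id: '%s'", as.character(disease_id)[which(is.na(j))[1]]
    ))
  }
  d1 <- ncol(z)
  b <- length(i)
  x <- matrix(0, b, 4 * (d1 + 2))
  cols <- 2:(d1 + 1)
  x[, 2 + (cols - 1) * 4] <- z[emb$drug_rows[i], , drop = FALSE]
  x[, 3 + (cols - 1) * 4] <- z[emb$disease_rows[j], , drop = FALSE]
  x
}

#' Single convolution layer (ReLU)
#'
#' `ReLU(W_k * X[i:i+l, j:j+w] + b_k)` at every valid placement, stride 1.
#'
#' @param x input matrix (h x w) or array (h, w, C).
#' @param w filter weights: an (l, wd) matrix for one single-channel filter,
#'   or an (l, wd, C, K) array.
#' @param b bias, one value per filter.
#' @return Feature maps as an (ho, wo, K) array, dropped to a matrix when
#'   K = 1.
#' @export
conv_forward <- function(x, w, b = 0) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (is.matrix(w)) dim(w) <- c(dim(w), 1L, 1L)
  dx <- dim(x)
  dw <- dim(w)
  stopifnot(dw[3] == dx[3])
  g <- conv_geometry(dx[1], dx[2], dx[3], dw[1], dw[2], dw[4], 1, 1, 1)
  wmat <- matrix(w, dw[1] * dw[2] * dw[3], dw[4])
  xv <- matrix(as.vector(x), 1)
  cols <- xv[, as.vector(g$idx), drop = FALSE]
  dim(cols) <- c(g$npos, ncol(g$idx))
  out <- pmax(sweep(cols %*% wmat, 2, rep(b, length.out = dw[4]), `+`), 0)
  dim(out) <- c(g$ho, g$wo, dw[4])
  if (dw[4] == 1) out <- out[, , 1, drop = TRUE]
  if (is.null(dim(out))) out <- matrix(out, g$ho, g$wo)
  out
}

#' Max pooling
#'
#' Non-overlapping max pooling with window (`p_l`, `p_w`); a ragged edge is
#' covered by a truncated final window (ceil mode).
#'
#' @param m feature map matrix (or array with channels last).
#' @param p_l,p_w pooling window length and width.
#' @return Pooled map of shape (ceil(h/p_l), ceil(w/p_w)).
#' @export
max_pool <- function(m, p_l, p_w) {
  if (is.matrix(m)) {
    h <- nrow(m); w <- ncol(m)
    stopifnot(p_l <= h, p_w <= w)
    ph <- ceiling(h / p_l); pw <- ceiling(w / p_w)
    out <- matrix(-Inf, ph, pw)
    for (a in seq_len(ph)) {
      ri <- ((a - 1) * p_l + 1):min(a * p_l, h)
      for (b in seq_len(pw)) {
        ci <- ((b - 1) * p_w + 1):min(b * p_w, w)
        out[a, b] <- max(m[ri, ci])
      }
    }
    out
  } else {
    d <- dim(m)
    res <- lapply(seq_len(d[3]), function(k) max_pool(m[, , k], p_l, p_w))
    array(unlist(res), c(dim(res[[1]]), d[3]))
  }
}

# --- vectorised batch forward / backward ------------------------------------

batch_conv_pool <- function(x, g, wmat, bias) {
  b <- nrow(x)
  cols <- x[, as.vector(g$idx), drop = FALSE]
  dim(cols) <- c(b * g$npos, ncol(g$idx))
  pre <- sweep(cols %*% wmat, 2, bias, `+`)
  act <- pmax(pre, 0)
  conv <- act
  dim(conv) <- c(b, g$conv_len) # (B, npos*k), position fastest

  out <- matrix(-Inf, b, g$out_len)
  argm <- matrix(NA_integer_, b, g$out_len)
  for (o in seq_len(ncol(g$srcfull))) {
    src <- g$srcfull[, o]
    valid <- which(!is.na(src))
    if (length(valid) == 0) next
    vals <- conv[, src[valid], drop = FALSE]
    cur <- out[, valid, drop = FALSE]
    sel <- vals > cur
    cur[sel] <- vals[sel]
    out[, valid] <- cur
    srcrep <- matrix(src[valid], b, length(valid), byrow = TRUE)
    acur <- argm[, valid, drop = FALSE]
    acur[sel] <- srcrep[sel]
    argm[, valid] <- acur
  }
  list(cols = cols, pre_pos = pre > 0, conv = conv, out = out, argm = argm)
}

batch_conv_pool_backward <- function(dout, cache, g, wmat) {
  b <- nrow(dout)
  # route gradient to the argmax cell of each (disjoint) pooling window
  dconv <- matrix(0, b, g$conv_len)
  lin <- rep(seq_len(b), times = ncol(dout)) + (as.vector(cache$argm) - 1) * b
  dconv[lin] <- as.vector(dout)
  dmat <- dconv
  dim(dmat) <- c(b * g$npos, g$k)
  dmat <- dmat * cache$pre_pos
  dw <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- dmat %*% t(wmat)
  dim(dcols) <- c(b, g$npos * ncol(g$idx))
  dx <- matrix(0, b, g$in_len)
  for (q in seq_len(ncol(g$idx))) {
    cols_q <- ((q - 1) * g$npos + 1):(q * g$npos)
    dx[, g$idx[, q]] <- dx[, g$idx[, q], drop = FALSE] +
      dcols[, cols_q, drop = FALSE]
  }
  list(dx = dx, dw = dw, db = db)
}

cnn_batch_forward <- function(x, params, train_mode = FALSE,
                              drop_masks = NULL) {
  w <- params$weights
  geom <- params$geometry
  caches <- vector("list", 3)
  cur <- x
  for (s in 1:3) {
    g <- geom$stages[[s]]
    caches[[s]] <- batch_conv_pool(
      cur, g, w[[paste0("conv", s)]], w[[paste0("cb", s)]]
    )
    caches[[s]]$input <- cur
    cur <- caches[[s]]$out
  }
  y <- cur # flattened latent, B x flat
  p_drop <- params$config$dropout
  b <- nrow(x)
  if (train_mode && p_drop > 0 && is.null(drop_masks)) {
    drop_masks <- list(
      (matrix(runif(b * ncol(w$fc1)), b) >= p_drop) / (1 - p_drop),
      (matrix(runif(b * ncol(w$fc2)), b) >= p_drop) / (1 - p_drop)
    )
  }
  a1_pre <- sweep(y %*% w$fc1, 2, w$b_fc1, `+`)
  a1 <- pmax(a1_pre, 0)
  d1 <- if (train_mode && p_drop > 0) a1 * drop_masks[[1]] else a1
  a2_pre <- sweep(d1 %*% w$fc2, 2, w$b_fc2, `+`)
  a2 <- pmax(a2_pre, 0)
  d2 <- if (train_mode && p_drop > 0) a2 * drop_masks[[2]] else a2
  a3_pre <- sweep(d2 %*% w$fc3, 2, w$b_fc3, `+`)
  a3 <- pmax(a3_pre, 0)
  logits <- sweep(a3 %*% w$out, 2, w$b_out, `+`)
  mx <- pmax(logits[, 1], logits[, 2])
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  list(
    prob = probs[, 2], probs = probs, logits = logits,
    caches = caches, y = y,
    a1_pre = a1_pre, d1 = d1, a2_pre = a2_pre, d2 = d2, a3_pre = a3_pre,
    a3 = a3, drop_masks = drop_masks, train_mode = train_mode
  )
}

cnn_batch_backward <- function(fwd, labels, params) {
  w <- params$weights
  b <- length(labels)
  target <- cbind(1 - labels, labels)
  dlogits <- (fwd$probs - target) / b
  grads <- list()
  grads$out <- crossprod(fwd$a3, dlogits)
  grads$b_out <- colSums(dlogits)
  da3 <- (dlogits %*% t(w$out)) * (fwd$a3_pre > 0)
  grads$fc3 <- crossprod(fwd$d2, da3)
  grads$b_fc3 <- colSums(da3)
  dd2 <- da3 %*% t(w$fc3)
  if (fwd$train_mode && !is.null(fwd$drop_masks)) {
    dd2 <- dd2 * fwd$drop_masks[[2]]
  }
  da2 <- dd2 * (fwd$a2_pre > 0)
  grads$fc2 <- crossprod(fwd$d1, da2)
  grads$b_fc2 <- colSums(da2)
  dd1 <- da2 %*% t(w$fc2)
  if (fwd$train_mode && !is.null(fwd$drop_masks)) {
    dd1 <- dd1 * fwd$drop_masks[[1]]
  }
  da1 <- dd1 * (fwd$a1_pre > 0)
  grads$fc1 <- crossprod(fwd$y, da1)
  grads$b_fc1 <- colSums(da1)
  dcur <- da1 %*% t(w$fc1)
  for (s in 3:1) {
    g <- params$geometry$stages[[s]]
    bk <- batch_conv_pool_backward(
      dcur, fwd$caches[[s]], g, w[[paste0("conv", s)]]
    )
    grads[[paste0("conv", s)]] <- bk$dw
    grads[[paste0("cb", s)]] <- bk$db
    dcur <- bk$dx
  }
  grads
}

#' Forward pass of the pair classifier
#'
#' Runs one padded pair tensor through the three conv+pool stages, the
#' fully-connected layers and the softmax, returning every intermediate for
#' inspection.  Dropout is active only in `train_mode` and is seeded.
#'
#' @param pair a [build_pair_tensor()] result (padded 4 x (d1+2) matrix).
#' @param params a [cnn_params()] object.
#' @param train_mode enable (seeded) dropout.
#' @param seed seed for dropout masks.
#' @return A `cnn_forward_trace` list: `feature_maps`, `pooled_maps`,
#'   `latent`, `flattened`, `probability`.
#' @export
cnn_forward <- function(pair, params, train_mode = FALSE, seed = 1) {
  x <- matrix(as.vector(unclass(pair)), 1)
  fwd <- if (train_mode) {
    with_seed(seed, cnn_batch_forward(x, params, train_mode = TRUE))
  } else {
    cnn_batch_forward(x, params, train_mode = FALSE)
  }
  fmaps <- list()
  pmaps <- list()
  for (s in 1:3) {
    g <- params$geometry$stages[[s]]
    fm <- fwd$caches[[s]]$conv
    dim(fm) <- c(g$ho, g$wo, g$k)
    pm <- fwd$caches[[s]]$out
    dim(pm) <- c(g$ph, g$pw, g$k)
    fmaps[[s]] <- fm
    pmaps[[s]] <- pm
  }
  structure(
    list(
      feature_maps = fmaps, pooled_maps = pmaps,
      latent = pmaps[[3]], flattened = as.vector(fwd$y),
      probability = fwd$prob[1]
    ),
    class = "cnn_forward_trace"
  )
}

#' Binary cross-entropy of pair predictions
#'
#' Mean of `-(Z log Zhat + (1 - Z) log(1 - Zhat))` over a labelled batch,
#' probabilities clipped to `[1e-12, 1 - 1e-12]`.
#'
#' @param batch tibble with columns `probability` and `label`.
#' @return Scalar loss.
#' @export
cnn_loss <- function(batch) {
  if (!"label" %in% names(batch) || anyNA(batch$label)) {
    abort("every prediction in the batch needs a 0/1 label")
  }
  p <- pmin(pmax(batch$probability, 1e-12), 1 - 1e-12)
  z <- batch$label
  mean(-(z * log(p) + (1 - z) * log(1 - p)))
}

#' Train the pair classifier
#'
#' Mini-batch Adam training of the convolutional head on labelled
#' drug-disease pairs scored against fixed node embeddings.  Shuffling,
#' dropout and initialisation all derive from `seed`.
#'
#' @param emb a `node_embeddings` object (typically inference-mode output of
#'   [train_vgae()]).
#' @param pairs tibble with columns `drug_id`, `disease_id`, `label`.
#' @param params optional pre-built [cnn_params()]; built from `...` when
#'   missing.
#' @param lr Adam learning rate (default 0.001).
#' @param epochs passes over the training set (default 30).
#' @param batch_size mini-batch size (default 128).
#' @param seed integer seed.
#' @param ... forwarded to [cnn_params()] when `params` is missing.
#' @return A `cnn_fit` with trained `params` and per-epoch `losses`.
#' @export
train_classifier <- function(emb, pairs, params = NULL, lr = 0.001,
                             epochs = 30, batch_size = 128, seed = 1, ...) {
  if (is.null(pairs) || nrow(pairs) == 0) abort("empty training set")
  stopifnot(batch_size >= 1)
  if (is.null(params)) {
    params <- cnn_params(ncol(emb$x2), seed = derive_seed(seed, "cnn-init"), ...)
  }
  x <- pair_batch_matrix(emb, pairs$drug_id, pairs$disease_id)
  z <- as.numeric(pairs$label)
  stopifnot(all(z %in% c(0, 1)))
  n <- nrow(x)
  weights <- params$weights
  state <- adam_init(weights)
  losses <- numeric(epochs)
  with_seed(derive_seed(seed, "cnn-train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        params$weights <- weights
        fwd <- cnn_batch_forward(
          x[idx, , drop = FALSE], params,
          train_mode = params$config$dropout > 0
        )
        p <- pmin(pmax(fwd$prob, 1e-12), 1 - 1e-12)
        ep_loss <- ep_loss + mean(-(z[idx] * log(p) +
          (1 - z[idx]) * log(1 - p)))
        nb <- nb + 1
        grads <- cnn_batch_backward(fwd, z[idx], params)
        upd <- adam_step(weights, grads, state, lr = lr)
        weights <- upd$params
        state <- upd$state
      }
      losses[ep] <- ep_loss / nb
      if (!is.finite(losses[ep])) {
        abort(sprintf("non-finite classifier loss at epoch %d", ep))
      }
    }
  })
  params$weights <- weights
  structure(
    list(
      params = params,
      losses = tibble(epoch = seq_len(epochs), loss = losses),
      config = list(
        lr = lr, epochs = epochs, batch_size = batch_size, seed = seed
      )
    ),
    class = "cnn_fit"
  )
}

#' @export
print.cnn_fit <- function(x, ...) {
  cat(sprintf(
    "<cnn_fit> %d epochs, batch %d, final loss %.4f\n",
    nrow(x$losses), x$config$batch_size, x$losses$loss[nrow(x$losses)]
  ))
  invisible(x)
}

#' Score drug-disease pairs
#'
#' Inference-mode (dropout off) association probabilities for a list of
#' pairs, preserving input order.
#'
#' @param emb a `node_embeddings` object.
#' @param fit a `cnn_fit` (or bare `cnn_params`).
#' @param pairs tibble with columns `drug_id`, `disease_id` and optionally
#'   `label`.
#' @return Tibble `drug_id`, `disease_id`, `probability` (plus `label` when
#'   supplied).
#' @export
predict_pairs <- function(emb, fit, pairs) {
  params <- if (inherits(fit, "cnn_fit")) fit$params else fit
  x <- pair_batch_matrix(emb, pairs$drug_id, pairs$disease_id)
  prob <- numeric(nrow(x))
  # chunked to bound memory on large pair lists
  for (start in seq(1, nrow(x), by = 2048)) {
    idx <- start:min(start + 2047, nrow(x))
    prob[idx] <- cnn_batch_forward(
      x[idx, , drop = FALSE], params,
      train_mode = FALSE
    )$prob
  }
  out <- tibble(
    drug_id = as.character(pairs$drug_id),
    disease_id = as.character(pairs$disease_id),
    probability = prob
  )
  if ("label" %in% names(pairs)) out$label <- pairs$label
  out
}
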