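tiny_emb <- function(d1 = 8, n_r = 3, n_d = 2, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm((n_r + n_d) * d1), n_r + n_d, d1)
  rownames(z) <- c(sprintf("r%d", 1:n_r), sprintf("d%d", 1:n_d))
  node_embeddings(z, n_r, n_d)
}

tiny_params <- function(d1 = 8, seed = 11, dropout = 0) {
  cnn_params(d1,
    n_conv = 1, filter1 = c(2, 3), filter = c(1, 2), pool = c(1, 2),
    fc = c(5, 4, 3), dropout = dropout, seed = seed
  )
}

# weights drawn wide enough that no ReLU stage is fully dead
live_weights <- function(params, seed = 5) {
  set.seed(seed)
  params$weights <- lapply(params$weights, function(w) {
    array(rnorm(length(w), sd = 0.5), dim = dim(w) %||% length(w))
  })
  params
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("pair tensors centre the two embedding rows in a zero ring", {
  emb <- node_embeddings(
    matrix(c(1, 2, 3, 4), 2, byrow = TRUE,
      dimnames = list(c("r1", "d1"), NULL)
    ), 1, 1
  )
  pt <- build_pair_tensor(emb, "r1", "d1")
  expect_equal(dim(pt), c(4, 4))
  expect_equal(unclass(pt)[2:3, 2:3], matrix(c(1, 3, 2, 4), 2))
  ring <- unclass(pt)
  ring[2:3, 2:3] <- 0
  expect_equal(ring, matrix(0, 4, 4), ignore_attr = TRUE)
  expect_error(build_pair_tensor(emb, "nope", "d1"), "nope")
  expect_error(build_pair_tensor(emb, "r1", "nope"), "nope")

  zero <- node_embeddings(
    matrix(0, 2, 3, dimnames = list(c("r1", "d1"), NULL)), 1, 1
  )
  expect_equal(
    unclass(build_pair_tensor(zero, "r1", "d1")), matrix(0, 4, 5),
    ignore_attr = TRUE
  )
})

test_that("conv layer matches hand arithmetic and the loop oracle", {
  x <- matrix(c(1, 3, 2, 4), 2)
  expect_equal(conv_forward(x, matrix(1, 1, 1), 0), pmax(x, 0))
  expect_equal(conv_forward(x, matrix(1, 2, 2), 0), matrix(10, 1, 1))
  expect_equal(conv_forward(x, matrix(1, 2, 2), -100), matrix(0, 1, 1))
  expect_error(conv_forward(x, matrix(1, 3, 3), 0), "larger than")

  set.seed(407)
  for (i in 1:10) {
    h <- sample(3:5, 1)
    w <- sample(3:6, 1)
    cin <- sample(1:2, 1)
    k <- sample(1:3, 1)
    l <- sample(1:2, 1)
    wd <- sample(1:3, 1)
    x <- array(rnorm(h * w * cin), c(h, w, cin))
    wt <- array(rnorm(l * wd * cin * k), c(l, wd, cin, k))
    b <- rnorm(k)
    got <- conv_forward(x, wt, b)
    want <- oracle_conv(x, wt, b)
    if (k == 1) want <- want[, , 1, drop = TRUE]
    if (is.null(dim(want))) want <- matrix(want, h - l + 1, w - wd + 1)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("max pooling matches the windowed oracle including ragged edges", {
  expect_equal(max_pool(matrix(c(1, 2, 3, 0), 2), 2, 2), matrix(3, 1, 1))
  expect_equal(max_pool(matrix(c(1, 4, 2, 8), 1), 1, 2), matrix(c(4, 8), 1))
  expect_equal(max_pool(matrix(7, 3, 4), 1, 2), matrix(7, 3, 2))
  set.seed(408)
  for (i in 1:10) {
    m <- matrix(rnorm(35), 5, 7)
    pl <- sample(1:3, 1)
    pw <- sample(1:3, 1)
    expect_equal(max_pool(m, pl, pw), oracle_pool(m, pl, pw))
  }
})

test_that("full forward pass equals a stage-by-stage oracle evaluation", {
  set.seed(409)
  params <- live_weights(tiny_params(), seed = 9)
  emb <- tiny_emb()
  pt <- build_pair_tensor(emb, "r1", "d1")
  trace <- cnn_forward(pt, params)

  # oracle: naive conv/pool per stage, then FC chain
  w <- params$weights
  g <- params$geometry
  cur <- array(unclass(pt), c(4, ncol(pt), 1))
  for (s in 1:3) {
    gs <- g$stages[[s]]
    wt <- array(w[[paste0("conv", s)]], c(gs$l, gs$wd, gs$c_in, gs$k))
    conv <- oracle_conv(cur, wt, w[[paste0("cb", s)]])
    expect_equal(trace$feature_maps[[s]], conv, tolerance = 1e-10)
    pooled <- array(0, c(gs$ph, gs$pw, gs$k))
    for (k in seq_len(gs$k)) {
      pooled[, , k] <- oracle_pool(matrix(conv[, , k], gs$ho, gs$wo),
        gs$p_l, gs$p_w
      )
    }
    expect_equal(trace$pooled_maps[[s]], pooled, tolerance = 1e-10)
    cur <- pooled
  }
  y <- as.vector(cur)
  expect_equal(trace$flattened, y, tolerance = 1e-10)
  a1 <- pmax(y %*% w$fc1 + as.vector(w$b_fc1), 0)
  a2 <- pmax(a1 %*% w$fc2 + as.vector(w$b_fc2), 0)
  a3 <- pmax(a2 %*% w$fc3 + as.vector(w$b_fc3), 0)
  logits <- a3 %*% w$out + as.vector(w$b_out)
  expect_equal(
    trace$probability,
    exp(logits[2]) / sum(exp(logits)),
    tolerance = 1e-10
  )
})

test_that("softmax head reproduces closed-form probabilities", {
  params <- tiny_params()
  # zero everything: equal logits, probability one half
  params$weights <- lapply(params$weights, function(w) w * 0)
  emb <- tiny_emb()
  pt <- build_pair_tensor(emb, "r1", "d1")
  expect_equal(cnn_forward(pt, params)$probability, 0.5, tolerance = 1e-9)

  # bias-only logits (0, log 3) -> positive-class probability 3/4
  params$weights$b_out <- c(0, log(3))
  expect_equal(cnn_forward(pt, params)$probability, 0.75, tolerance = 1e-9)

  # two-class softmax sums to one
  params2 <- live_weights(tiny_params(), seed = 13)
  x <- matrix(as.vector(unclass(pt)), 1)
  fwd <- hetvgae:::cnn_batch_forward(x, params2)
  expect_equal(rowSums(fwd$probs), 1, tolerance = 1e-12)

  # inference is deterministic even with dropout configured
  params3 <- live_weights(tiny_params(dropout = 0.1), seed = 13)
  expect_identical(
    cnn_forward(pt, params3)$probability,
    cnn_forward(pt, params3)$probability
  )
})

test_that("geometry collapse and undersized inputs raise errors", {
  expect_error(
    cnn_params(4,
      n_conv = 1, filter1 = c(2, 3), filter = c(1, 2), pool = c(1, 2),
      fc = c(5, 4, 3)
    ),
    "stage"
  )
})

test_that("classifier cross-entropy matches direct evaluation", {
  batch <- tibble::tibble(probability = c(1 - 1e-13, 0.5, 0.5), label = c(1, 1, 0))
  expect_equal(
    cnn_loss(batch),
    mean(c(-log(1 - 1e-12), log(2), log(2))),
    tolerance = 1e-9
  )
  expect_equal(
    cnn_loss(tibble::tibble(probability = 0.5, label = 1)), log(2),
    tolerance = 1e-12
  )
  expect_error(
    cnn_loss(tibble::tibble(probability = 0.5)), "label"
  )
})

test_that("classifier gradients match central finite differences", {
  params <- live_weights(tiny_params(), seed = 5)
  set.seed(410)
  x <- matrix(rnorm(3 * 4 * 10), 3)
  z <- c(1, 0, 1)
  loss_of <- function(w) {
    p <- params
    p$weights <- w
    fwd <- hetvgae:::cnn_batch_forward(x, p)
    pr <- pmin(pmax(fwd$prob, 1e-12), 1 - 1e-12)
    mean(-(z * log(pr) + (1 - z) * log(1 - pr)))
  }
  fwd <- hetvgae:::cnn_batch_forward(x, params)
  grads <- hetvgae:::cnn_batch_backward(fwd, z, params)
  h <- 1e-5
  for (nm in names(params$weights)) {
    w0 <- params$weights
    ng <- array(0, dim = dim(w0[[nm]]) %||% length(w0[[nm]]))
    for (i in seq_along(w0[[nm]])) {
      wp <- w0
      wp[[nm]][i] <- wp[[nm]][i] + h
      wm <- w0
      wm[[nm]][i] <- wm[[nm]][i] - h
      ng[i] <- (loss_of(wp) - loss_of(wm)) / (2 * h)
    }
    rel <- max(abs(ng - as.vector(grads[[nm]]))) / max(max(abs(ng)), 1e-6)
    expect_lt(rel, 1e-4)
  }
})

test_that("training on separable pairs reduces the loss deterministically", {
  set.seed(411)
  d1 <- 8
  n_r <- 10
  n_d <- 10
  z <- rbind(
    matrix(rnorm(n_r * d1, mean = rep(c(2, -2), each = n_r / 2)), n_r, d1),
    matrix(rnorm(n_d * d1, mean = rep(c(2, -2), each = n_d / 2)), n_d, d1)
  )
  rownames(z) <- c(sprintf("r%d", 1:n_r), sprintf("d%d", 1:n_d))
  emb <- node_embeddings(z, n_r, n_d)
  pairs <- tidyr::expand_grid(
    drug_id = sprintf("r%d", 1:n_r), disease_id = sprintf("d%d", 1:n_d)
  )
  match_block <- function(r, d) {
    (as.integer(sub("r", "", r)) <= n_r / 2) ==
      (as.integer(sub("d", "", d)) <= n_d / 2)
  }
  pairs$label <- as.numeric(mapply(match_block, pairs$drug_id, pairs$disease_id))

  fit <- train_classifier(emb, pairs,
    params = tiny_params(d1 = 8, dropout = 0.1),
    epochs = 50, batch_size = 16, seed = 21
  )
  expect_lt(fit$losses$loss[50], fit$losses$loss[1])
  fit2 <- train_classifier(emb, pairs,
    params = tiny_params(d1 = 8, dropout = 0.1),
    epochs = 50, batch_size = 16, seed = 21
  )
  expect_identical(fit$losses, fit2$losses)

  expect_error(train_classifier(emb, pairs[0, ]), "empty")
})

test_that("all-positive labels drift predictions toward one", {
  emb <- tiny_emb(d1 = 8, n_r = 4, n_d = 4, seed = 3)
  pairs <- tidyr::expand_grid(
    drug_id = sprintf("r%d", 1:4), disease_id = sprintf("d%d", 1:4)
  )
  pairs$label <- 1
  params <- tiny_params(d1 = 8)
  before <- mean(predict_pairs(emb, params, pairs)$probability)
  fit <- train_classifier(emb, pairs, params = params, epochs = 30, seed = 4)
  after <- mean(predict_pairs(emb, fit, pairs)$probability)
  expect_gt(after, before)
})

test_that("pair prediction preserves order, range and duplicates", {
  emb <- tiny_emb()
  params <- live_weights(tiny_params(), seed = 19)
  pairs <- tibble::tibble(
    drug_id = c("r1", "r2", "r1"), disease_id = c("d1", "d2", "d1")
  )
  preds <- predict_pairs(emb, params, pairs)
  expect_equal(nrow(preds), 3)
  expect_identical(preds$drug_id, pairs$drug_id)
  expect_equal(preds$probability[1], preds$probability[3])
  expect_true(all(preds$probability > 0 & preds$probability < 1))
  expect_error(
    predict_pairs(emb, params, tibble::tibble(drug_id = "zz", disease_id = "d1")),
    "zz"
  )
})
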