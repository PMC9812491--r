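tiny_net <- function() {
  m_r <- similarity_matrix(matrix(c(1, .3, .3, 1), 2), c("r1", "r2"))
  m_d <- similarity_matrix(matrix(c(1, .6, .6, 1), 2), c("d1", "d2"))
  m_rd <- build_association_matrix(
    tibble::tibble(drug_id = c("r1", "r2"), disease_id = c("d1", "d2")),
    c("r1", "r2"), c("d1", "d2")
  )
  build_heterogeneous_network(m_r, m_d, m_rd)
}

two_block_net <- function(seed = 2, n_half = 10, p_in = 0.8, p_out = 0.05) {
  set.seed(seed)
  n <- 2 * n_half
  blk <- rep(1:2, each = n_half)
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- if (blk[i] == blk[j]) p_in else p_out
      if (runif(1) < p) a[i, j] <- a[j, i] <- 1
    }
  }
  ids <- sprintf("n%02d", seq_len(n))
  dimnames(a) <- list(ids, ids)
  deg <- rowSums(a) + 1
  dinv <- 1 / sqrt(deg)
  structure(
    list(
      m_h = a, a = a + diag(n), degree = deg,
      a_norm = (a + diag(n)) * (dinv %o% dinv), x0 = a,
      drug_ids = ids[blk == 1], disease_ids = ids[blk == 2]
    ),
    class = "het_network"
  )
}

test_that("gcn layer applies normalized propagation and optional ReLU", {
  x <- matrix(c(-1, 2, 3, -4), 2)
  expect_equal(gcn_layer(diag(2), x, diag(2), activate = TRUE), pmax(x, 0))
  expect_equal(
    gcn_layer(matrix(0.5, 2, 2), matrix(c(2, 0), 2), matrix(1), TRUE),
    matrix(c(1, 1), 2)
  )
  expect_equal(
    gcn_layer(diag(2), x, matrix(0, 2, 2), TRUE), matrix(0, 2, 2)
  )
  expect_error(gcn_layer(diag(2), x, matrix(1, 3, 1)), "shape mismatch")
})

test_that("encode produces finite heads and responds linearly to weights", {
  net <- tiny_net()
  params <- vgae_params(4, d0 = 3, d1 = 2, seed = 9)
  zero <- params
  zero$w1 <- zero$w1 * 0
  zero$w2 <- zero$w2 * 0
  enc0 <- encode(net, zero)
  expect_equal(enc0$mu, matrix(0, 4, 2), ignore_attr = TRUE)
  expect_equal(enc0$log_sigma, matrix(0, 4, 2), ignore_attr = TRUE)

  enc <- encode(net, params)
  doubled <- params
  doubled$w1 <- 2 * params$w1
  expect_equal(encode(net, doubled)$mu, 2 * enc$mu)

  # hand-evaluated forward pass with 1-dim weights
  p1 <- list(
    w0 = matrix(1, 4, 1), w1 = matrix(1, 1, 1), w2 = matrix(0.5, 1, 1)
  )
  hidden <- pmax(net$a_norm %*% net$x0 %*% p1$w0, 0)
  expect_equal(
    encode(net, p1)$mu, net$a_norm %*% hidden %*% p1$w1
  )
  expect_equal(
    encode(net, p1)$log_sigma, net$a_norm %*% hidden %*% p1$w2
  )
})

test_that("relu head mode clips the second-layer outputs at zero", {
  net <- tiny_net()
  params <- vgae_params(4, d0 = 3, d1 = 2, seed = 9)
  enc <- encode(net, params, head_activation = "relu")
  expect_true(all(enc$mu >= 0))
  expect_true(all(enc$log_sigma >= 0))
})

test_that("reparameterization is seeded, unbiased, and exact in inference", {
  dist <- structure(
    list(
      mu = matrix(c(1, -2), 1), log_sigma = matrix(c(0, 0.5), 1)
    ),
    class = "encoded_distribution"
  )
  expect_equal(reparameterize(dist, inference = TRUE)$x2, dist$mu)
  a <- reparameterize(dist, seed = 77)$x2
  b <- reparameterize(dist, seed = 77)$x2
  expect_identical(a, b)
  expect_false(identical(a, reparameterize(dist, seed = 78)$x2))

  draws <- vapply(
    1:4000, function(s) reparameterize(dist, seed = s)$x2[1, 1], numeric(1)
  )
  se <- exp(dist$log_sigma[1, 1]) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - dist$mu[1, 1]), 3 * se)
})

test_that("decoder is a symmetric sigmoid of row inner products", {
  z <- node_embeddings(matrix(0, 3, 2), 2, 1)
  expect_equal(decode(z), matrix(0.5, 3, 3))

  z2 <- matrix(c(2, 2, 0, 0), 2)
  expect_equal(decode(z2)[1, 2], plogis(4))
  orth <- matrix(c(1, 0, 0, 1), 2)
  expect_equal(decode(orth)[1, 2], 0.5)

  set.seed(405)
  zz <- matrix(rnorm(20), 5)
  ah <- decode(zz)
  expect_identical(ah, t(ah))
  expect_true(all(ah > 0 & ah < 1))
})

test_that("variational loss matches closed forms", {
  dist0 <- structure(
    list(mu = matrix(0, 1, 1), log_sigma = matrix(0, 1, 1)),
    class = "encoded_distribution"
  )
  expect_equal(
    vgae_loss(matrix(1, 1, 1), matrix(0.5, 1, 1), dist0, 1)$kl, 0
  )
  expect_equal(
    vgae_loss(matrix(1, 1, 1), matrix(0.5, 1, 1), dist0, 1)$reconstruction,
    log(2),
    tolerance = 1e-9
  )
  dist1 <- structure(
    list(mu = matrix(1, 1, 1), log_sigma = matrix(0, 1, 1)),
    class = "encoded_distribution"
  )
  rep1 <- vgae_loss(matrix(1, 1, 1), matrix(0.5, 1, 1), dist1, 1)
  expect_equal(rep1$kl, 0.5, tolerance = 1e-9)
  expect_equal(rep1$total, rep1$reconstruction + rep1$kl)
  expect_gte(rep1$kl, 0)
})

test_that("analytic KL matches a Monte-Carlo estimate", {
  set.seed(406)
  for (i in 1:3) {
    mu <- rnorm(1)
    ls <- rnorm(1, sd = 0.4)
    dist <- structure(
      list(mu = matrix(mu, 1, 1), log_sigma = matrix(ls, 1, 1)),
      class = "encoded_distribution"
    )
    analytic <- vgae_loss(matrix(1, 1, 1), matrix(0.5, 1, 1), dist, 1)$kl
    z <- rnorm(1e6, mu, exp(ls))
    mc <- mean(
      dnorm(z, mu, exp(ls), log = TRUE) - dnorm(z, 0, 1, log = TRUE)
    )
    expect_equal(analytic, mc, tolerance = 0.02)
  }
})

test_that("loss gradients match central finite differences", {
  net <- tiny_net()
  params <- vgae_params(4, d0 = 3, d1 = 2, seed = 7)
  set.seed(42)
  eps_mat <- matrix(rnorm(8), 4, 2)
  fb <- hetvgae:::vgae_forward_backward(net, params, eps_mat, 1.7)
  h <- 1e-5
  for (nm in c("w0", "w1", "w2")) {
    ng <- array(0, dim = dim(params[[nm]]))
    for (i in seq_along(params[[nm]])) {
      pp <- params
      pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- params
      pm[[nm]][i] <- pm[[nm]][i] - h
      lp <- hetvgae:::vgae_forward_backward(
        net, pp, eps_mat, 1.7, want_grads = FALSE
      )$report$total
      lm <- hetvgae:::vgae_forward_backward(
        net, pm, eps_mat, 1.7, want_grads = FALSE
      )$report$total
      ng[i] <- (lp - lm) / (2 * h)
    }
    rel <- max(abs(ng - fb$grads[[nm]])) / max(max(abs(ng)), 1e-8)
    expect_lt(rel, 1e-4)
  }
})

test_that("encoder is permutation-equivariant", {
  net <- two_block_net(seed = 11, n_half = 4)
  params <- vgae_params(8, d0 = 5, d1 = 3, seed = 3)
  enc <- encode(net, params)
  perm <- sample(8)
  pnet <- net
  pnet$a_norm <- net$a_norm[perm, perm]
  pnet$x0 <- net$x0[perm, perm]
  # weights of the first layer act on node-indexed features: permute rows
  pparams <- params
  pparams$w0 <- params$w0[perm, , drop = FALSE]
  penc <- encode(pnet, pparams)
  expect_equal(penc$mu, enc$mu[perm, , drop = FALSE], ignore_attr = TRUE)
  expect_equal(
    penc$log_sigma, enc$log_sigma[perm, , drop = FALSE],
    ignore_attr = TRUE
  )
})

test_that("training reduces the loss deterministically", {
  net <- tiny_net()
  fit <- train_vgae(net, d0 = 4, d1 = 2, epochs = 100, seed = 8)
  # single-sample losses are noisy on a 4-node graph; compare running means
  expect_lt(
    mean(fit$losses$total[91:100]), mean(fit$losses$total[1:5])
  )
  fit2 <- train_vgae(net, d0 = 4, d1 = 2, epochs = 100, seed = 8)
  expect_identical(fit$losses, fit2$losses)
  expect_identical(fit$embeddings$x2, fit2$embeddings$x2)
  # inference embeddings equal the encoded means
  expect_equal(fit$embeddings$x2, fit$dist$mu)
})

test_that("trained decoder separates a planted two-block network", {
  net <- two_block_net(seed = 2)
  fit <- train_vgae(net, d0 = 16, d1 = 8, epochs = 200, seed = 5)
  ah <- decode(fit$embeddings)
  blk <- rep(1:2, each = 10)
  same <- outer(blk, blk, `==`) & upper.tri(ah)
  diff <- outer(blk, blk, `!=`) & upper.tri(ah)
  expect_gt(mean(ah[same]), mean(ah[diff]))
})
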