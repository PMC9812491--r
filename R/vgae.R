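#' Graph convolution layer
#'
#' One propagation step `a_norm %*% x %*% w`, optionally passed through
#' ReLU.  `a_norm` is the symmetrically normalised self-looped adjacency of
#' the heterogeneous network.
#'
#' @param a_norm normalised adjacency (N x N).
#' @param x node feature matrix (N x d_in).
#' @param w weight matrix (d_in x d_out).
#' @param activate apply ReLU when `TRUE`.
#' @return N x d_out matrix.
#' @export
gcn_layer <- function(a_norm, x, w, activate = TRUE) {
  if (ncol(a_norm) != nrow(x) || ncol(x) != nrow(w)) {
    abort(sprintf(
      "shape mismatch: a_norm %dx%d, x %dx%d, w %dx%d",
      nrow(a_norm), ncol(a_norm), nrow(x), ncol(x), nrow(w), ncol(w)
    ))
  }
  out <- a_norm %*% x %*% w
  if (activate) out <- pmax(out, 0)
  out
}

#' Initialise encoder parameters
#'
#' Weight matrices of the two-layer GCN variational encoder: `w0` maps the
#' (Nr+Nd)-wide initial features to a `d0`-dimensional hidden layer; `w1`
#' and `w2` map the hidden layer to the latent mean and log standard
#' deviation (both of width `d1`; the two latent heads share dimension).
#'
#' @param n_nodes number of network nodes (Nr + Nd).
#' @param d0 hidden dimension of the first GCN layer (default 128).
#' @param d1 latent dimension (default 64).
#' @param seed integer seed for the initialisation draw.
#' @return A `vgae_params` list with `w0`, `w1`, `w2`, `dims`.
#' @export
vgae_params <- function(n_nodes, d0 = 128, d1 = 64, seed = 1) {
  stopifnot(d0 >= 1, d1 >= 1)
  with_seed(seed, {
    structure(
      list(
        w0 = glorot_init(n_nodes, d0),
        w1 = glorot_init(d0, d1),
        w2 = glorot_init(d0, d1),
        dims = c(d0 = d0, d1 = d1, d2 = d1)
      ),
      class = "vgae_params"
    )
  })
}

#' Encode a heterogeneous network into latent Gaussians
#'
#' The first GCN layer (shared by both heads) produces a ReLU hidden
#' representation; the second layer yields the per-node latent mean and log
#' standard deviation.  The mean/log-sigma heads are linear by default: a
#' ReLU'd log-sigma could never go negative, pinning every variance at 1 or
#' more; `head_activation = "relu"` restores the literal form.
#'
#' @param net a [build_heterogeneous_network()] result.
#' @param params a [vgae_params()] object.
#' @param head_activation `"linear"` (default) or `"relu"` for the second
#'   layer heads.
#' @return List with `mu`, `log_sigma` (both N x d1), class
#'   `encoded_distribution`.
#' @export
encode <- function(net, params, head_activation = c("linear", "relu")) {
  head_activation <- match.arg(head_activation)
  act <- identical(head_activation, "relu")
  hidden <- gcn_layer(net$a_norm, net$x0, params$w0, activate = TRUE)
  if (!all(is.finite(hidden))) abort("non-finite values in the hidden GCN layer")
  mu <- gcn_layer(net$a_norm, hidden, params$w1, activate = act)
  log_sigma <- gcn_layer(net$a_norm, hidden, params$w2, activate = act)
  if (!all(is.finite(mu))) abort("non-finite values in the mean head")
  if (!all(is.finite(log_sigma))) abort("non-finite values in the log-sigma head")
  structure(
    list(mu = mu, log_sigma = log_sigma),
    class = "encoded_distribution"
  )
}

#' Sample node embeddings by reparameterization
#'
#' Draws `x2 = mu + exp(log_sigma) * eps` with standard-normal `eps` from a
#' seeded generator, so gradients flow through `mu` and `log_sigma`.  In
#' inference mode the sample is the mean exactly.
#'
#' @param dist an [encode()] result.
#' @param seed integer seed for the noise draw.
#' @param n_r,n_d drug and disease counts partitioning the rows (drugs
#'   first).
#' @param inference return `mu` without noise when `TRUE`.
#' @return `node_embeddings` list with `x2`, `n_r`, `n_d`.
#' @export
reparameterize <- function(dist, seed = 1, n_r = NULL, n_d = NULL,
                           inference = FALSE) {
  if (inference) {
    x2 <- dist$mu
  } else {
    eps <- with_seed(seed, {
      matrix(rnorm(length(dist$mu)), nrow(dist$mu), ncol(dist$mu))
    })
    x2 <- dist$mu + exp(dist$log_sigma) * eps
  }
  node_embeddings(x2, n_r %||% nrow(x2), n_d %||% 0L,
    node_ids = rownames(dist$mu)
  )
}

#' Node embedding container
#'
#' Latent matrix partitioned into drug rows (first `n_r`) and disease rows
#' (remaining `n_d`), with node ids as row names.
#'
#' @param x2 latent matrix with one row per node.
#' @param n_r,n_d drug and disease counts.
#' @param node_ids optional row names.
#' @return A `node_embeddings` object.
#' @export
node_embeddings <- function(x2, n_r, n_d, node_ids = NULL) {
  stopifnot(nrow(x2) == n_r + n_d)
  if (!is.null(node_ids)) rownames(x2) <- node_ids
  structure(
    list(
      x2 = x2, n_r = n_r, n_d = n_d,
      drug_rows = seq_len(n_r), disease_rows = n_r + seq_len(n_d)
    ),
    class = "node_embeddings"
  )
}

#' Inner-product decoder
#'
#' Reconstructs the adjacency as `sigmoid(z_i . z_j)` over all node pairs;
#' the output is symmetric with entries in (0, 1).
#'
#' @param emb a `node_embeddings` object (or a bare latent matrix).
#' @return N x N matrix of edge probabilities.
#' @export
decode <- function(emb) {
  z <- if (inherits(emb, "node_embeddings")) emb$x2 else emb
  plogis(tcrossprod(z))
}

#' Variational loss of the graph autoencoder
#'
#' Reconstruction term: weighted cross-entropy between the target adjacency
#' and the decoded probabilities, positives weighted by `pos_weight`,
#' averaged over all entries.  By default the target keeps the similarity
#' weights as soft edge probabilities (entries clipped to \[0, 1\], so the
#' self-loop diagonal of 2 becomes 1); `binarize_target = TRUE` instead
#' treats every nonzero entry as a hard edge, which on weighted similarity
#' blocks turns them into complete graphs and discards their structure.  KL term: divergence of the
#' per-node latent Gaussians from the standard normal prior, summed and
#' scaled by `1/N` twice — once per node and once more so the two terms
#' are balanced per adjacency entry, the scaling of the reference
#' graph-autoencoder objective.  The total (minimised) loss is their sum —
#' the negative evidence lower bound.
#'
#' @param target_adjacency matrix of edge weights in \[0, 1\] (values above
#'   1, such as the self-loop diagonal, are clipped).
#' @param a_hat decoded probability matrix.
#' @param dist the [encode()] result used to produce the sample.
#' @param pos_weight weight on positive entries of the reconstruction term.
#' @param binarize_target treat every nonzero target entry as 1.
#' @return List with `reconstruction`, `kl`, `total` (class
#'   `vgae_loss_report`).
#' @export
vgae_loss <- function(target_adjacency, a_hat, dist, pos_weight = 1,
                      binarize_target = FALSE) {
  t_bin <- unclass(target_adjacency)
  t_bin <- if (binarize_target) (t_bin > 0) * 1 else pmin(t_bin, 1)
  if (!all(dim(t_bin) == dim(a_hat))) abort("target and a_hat shapes differ")
  eps <- 1e-12
  p <- pmin(pmax(a_hat, eps), 1 - eps)
  recon <- mean(-pos_weight * t_bin * log(p) - (1 - t_bin) * log(1 - p))
  mu <- dist$mu
  ls <- dist$log_sigma
  kl <- 0.5 * sum(exp(2 * ls) + mu^2 - 1 - 2 * ls) / nrow(mu)^2
  structure(
    list(reconstruction = recon, kl = kl, total = recon + kl),
    class = "vgae_loss_report"
  )
}

# Full forward + analytic backward pass for a fixed noise draw `eps_mat`.
# Returns loss report, gradients w.r.t. w0/w1/w2, and intermediates.
# `kl_weight` scales the KL term (and its gradient) for warm-up annealing;
# the reported loss always uses the full-weight KL.
vgae_forward_backward <- function(net, params, eps_mat, pos_weight,
                                  head_activation = "linear",
                                  want_grads = TRUE, kl_weight = 1,
                                  binarize_target = FALSE) {
  s <- net$a_norm
  x0 <- net$x0
  n <- nrow(x0)
  relu_heads <- identical(head_activation, "relu")

  sx0 <- s %*% x0
  pre0 <- sx0 %*% params$w0
  hidden <- pmax(pre0, 0)
  sh <- s %*% hidden
  pre_mu <- sh %*% params$w1
  pre_ls <- sh %*% params$w2
  mu <- if (relu_heads) pmax(pre_mu, 0) else pre_mu
  ls <- if (relu_heads) pmax(pre_ls, 0) else pre_ls
  dist <- structure(list(mu = mu, log_sigma = ls),
    class = "encoded_distribution"
  )
  sig <- exp(ls)
  z <- mu + sig * eps_mat

  logits <- tcrossprod(z)
  a_hat <- plogis(logits)
  t_bin <- unclass(net$a)
  t_bin <- if (binarize_target) (t_bin > 0) * 1 else pmin(t_bin, 1)
  report <- vgae_loss(net$a, a_hat, dist, pos_weight,
    binarize_target = binarize_target
  )
  if (!want_grads) {
    return(list(report = report, dist = dist, z = z, a_hat = a_hat))
  }

  # d(recon)/d(logits); clipping ignored away from saturation
  g <- ((1 - t_bin) * a_hat - pos_weight * t_bin * (1 - a_hat)) / n^2
  dz <- (g + t(g)) %*% z
  dmu <- dz + kl_weight * mu / n^2
  dls <- dz * eps_mat * sig + kl_weight * (exp(2 * ls) - 1) / n^2
  if (relu_heads) {
    dmu <- dmu * (pre_mu > 0)
    dls <- dls * (pre_ls > 0)
  }
  dw1 <- crossprod(sh, dmu)
  dw2 <- crossprod(sh, dls)
  dhidden <- s %*% (dmu %*% t(params$w1) + dls %*% t(params$w2))
  dpre0 <- dhidden * (pre0 > 0)
  dw0 <- crossprod(sx0, dpre0)

  list(
    report = report, dist = dist, z = z, a_hat = a_hat,
    grads = list(w0 = dw0, w1 = dw1, w2 = dw2)
  )
}

#' Train the variational graph autoencoder
#'
#' Full-graph Adam training of the encoder against the self-looped
#' adjacency, one reparameterized sample per step.  The returned embeddings
#' are inference-mode (the latent means); sampled embeddings remain
#' available through [encode()] + [reparameterize()].
#'
#' @param net a [build_heterogeneous_network()] result.
#' @param d0,d1 hidden and latent dimensions.
#' @param lr Adam learning rate (default 0.01).
#' @param epochs training epochs (default 200).
#' @param head_activation activation of the mean/log-sigma heads.
#' @param pos_weight positive-class weight of the reconstruction term;
#'   `NULL` (default) balances the total negative and positive target mass.
#' @param binarize_target reconstruct the binarised adjacency (every
#'   nonzero entry a hard edge) instead of the weighted one.  Off by
#'   default: similarity edges carry their weights as soft targets, which
#'   preserves the similarity structure the heterogeneous network was built
#'   from.
#' @param kl_warmup fraction of the epochs over which the KL weight ramps
#'   linearly from 0 to 1 (default 0.3).  The all-zero latent matrix is a
#'   saddle point of the inner-product decoder, and on dense targets the KL
#'   pull toward the prior can trap training there; annealing the KL lets
#'   the reconstruction term establish structure first.  Set to 0 for a
#'   constant full-weight KL.
#' @param seed integer seed covering initialisation and every noise draw.
#' @return A `vgae_fit` with `params`, `embeddings` (inference mode),
#'   `dist`, and a per-epoch `losses` tibble.
#' @export
train_vgae <- function(net, d0 = 128, d1 = 64, lr = 0.01, epochs = 200,
                       head_activation = c("linear", "relu"),
                       pos_weight = NULL, binarize_target = FALSE,
                       kl_warmup = 0.3, seed = 1) {
  head_activation <- match.arg(head_activation)
  n <- nrow(net$x0)
  t_mat <- unclass(net$a)
  t_mat <- if (binarize_target) (t_mat > 0) * 1 else pmin(t_mat, 1)
  pos_mass <- sum(t_mat)
  pos_weight <- pos_weight %||% ((n^2 - pos_mass) / max(pos_mass, 1))
  params <- vgae_params(n, d0, d1, seed = derive_seed(seed, "vgae-init"))
  weights <- params[c("w0", "w1", "w2")]
  state <- adam_init(weights)
  losses <- vector("list", epochs)

  with_seed(derive_seed(seed, "vgae-train"), {
    for (ep in seq_len(epochs)) {
      eps_mat <- matrix(rnorm(n * d1), n, d1)
      p_full <- c(weights, list(dims = params$dims))
      klw <- if (kl_warmup > 0) min(1, ep / (kl_warmup * epochs)) else 1
      fb <- vgae_forward_backward(net, p_full, eps_mat, pos_weight,
        head_activation = head_activation, kl_weight = klw,
        binarize_target = binarize_target
      )
      if (!is.finite(fb$report$total)) {
        abort(sprintf("non-finite VGAE loss at epoch %d", ep))
      }
      losses[[ep]] <- tibble(
        epoch = ep,
        reconstruction = fb$report$reconstruction,
        kl = fb$report$kl,
        total = fb$report$total
      )
      upd <- adam_step(weights, fb$grads, state, lr = lr)
      weights <- upd$params
      state <- upd$state
    }
  })

  params$w0 <- weights$w0
  params$w1 <- weights$w1
  params$w2 <- weights$w2
  dist <- encode(net, params, head_activation = head_activation)
  emb <- reparameterize(dist,
    n_r = length(net$drug_ids), n_d = length(net$disease_ids),
    inference = TRUE
  )
  structure(
    list(
      params = params,
      embeddings = emb,
      dist = dist,
      losses = dplyr::bind_rows(losses),
      config = list(
        d0 = d0, d1 = d1, lr = lr, epochs = epochs,
        head_activation = head_activation, pos_weight = pos_weight,
        binarize_target = binarize_target, kl_warmup = kl_warmup,
        seed = seed
      )
    ),
    class = "vgae_fit"
  )
}

#' @export
print.vgae_fit <- function(x, ...) {
  cat(sprintf(
    "<vgae_fit> %d nodes -> %d latent dims, %d epochs, final loss %.4f\n",
    nrow(x$embeddings$x2), ncol(x$embeddings$x2),
    nrow(x$losses), x$losses$total[nrow(x$losses)]
  ))
  invisible(x)
}
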