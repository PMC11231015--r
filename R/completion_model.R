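#' Diagonal-Gaussian latent distribution
#'
#' @param mean,log_var numeric vectors of equal length; `log_var` is clamped
#'   to `[-10, 10]`.
#' @return object of class `latent_dist`.
#' @export
latent_dist <- function(mean, log_var) {
  mean <- as.numeric(mean); log_var <- as.numeric(log_var)
  if (length(mean) != length(log_var)) stop("mean and log_var must match in length")
  if (any(!is.finite(mean)) || any(!is.finite(log_var)))
    stop("latent distribution entries must be finite")
  structure(list(mean = mean, log_var = pmin(10, pmax(-10, log_var))),
            class = "latent_dist")
}

#' Kullback-Leibler divergence between diagonal Gaussians
#'
#' Closed form
#' `KL(q || p) = 1/2 * sum( (s2q + (mq - mp)^2) / s2p - 1 + log s2p - log s2q )`
#' with `s2 = exp(log_var)`.
#'
#' @param q,p [latent_dist()]s of equal dimension.
#' @return non-negative scalar.
#' @export
kl_divergence <- function(q, p) {
  stopifnot(inherits(q, "latent_dist"), inherits(p, "latent_dist"))
  if (length(q$mean) != length(p$mean))
    stop("latent dimensions differ between q and p")
  0.5 * sum(exp(q$log_var - p$log_var) +
              (q$mean - p$mean)^2 / exp(p$log_var) -
              1 + p$log_var - q$log_var)
}

#' Completion-model configuration
#'
#' Two presets are provided: `"smoke"` (tiny clouds and widths for desk-scale
#' training in minutes on one CPU) and `"full"` (full-scale clouds of 2048
#' points, Adam at 1e-4, batch 8, 100 epochs).
#'
#' @param preset `"smoke"` or `"full"`.
#' @param ... named overrides of individual fields (`n_in`, `n_gt`, `n_coarse`,
#'   `n_out`, `latent_dim`, `feature_dim`, `enc_hidden`, `dec_hidden`,
#'   `refine_dim`, `attention_scales`, `kl_weight`, `kl_warmup_frac`,
#'   `epochs`, `batch_size`, `learning_rate`, `split_fractions`, `seed`).
#' @return named list of class `model_config`.
#' @export
model_config <- function(preset = c("smoke", "full"), ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "smoke") {
    list(n_in = 256L, n_gt = 256L, n_coarse = 64L, n_out = 256L, latent_dim = 16L,
         feature_dim = 64L, enc_hidden = 64L, dec_hidden = 128L,
         refine_dim = 32L, attention_scales = c(8L, 16L), kl_weight = 0.5,
         kl_warmup_frac = 0.1, epochs = 30L, batch_size = 8L,
         learning_rate = 1e-3, split_fractions = c(0.6, 0.2, 0.2), seed = 1L)
  } else {
    list(n_in = 2048L, n_gt = 2048L, n_coarse = 512L, n_out = 2048L, latent_dim = 64L,
         feature_dim = 1024L, enc_hidden = 256L, dec_hidden = 512L,
         refine_dim = 128L, attention_scales = c(8L, 16L, 32L), kl_weight = 0.5,
         kl_warmup_frac = 0.1, epochs = 100L, batch_size = 8L,
         learning_rate = 1e-4, split_fractions = c(0.6, 0.2, 0.2), seed = 1L)
  }
  over <- list(...)
  cfg[names(over)] <- over
  if (abs(sum(cfg$split_fractions) - 1) > 1e-9)
    stop("split_fractions must sum to 1")
  counts <- c(cfg$n_in, cfg$n_gt, cfg$n_coarse, cfg$n_out, cfg$latent_dim,
              cfg$feature_dim, cfg$enc_hidden, cfg$dec_hidden, cfg$refine_dim)
  if (any(counts <= 0)) stop("all model dimensions must be positive")
  structure(cfg, class = "model_config")
}

# ---- parameters -------------------------------------------------------------

init_weight <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

init_params <- function(cfg, seed) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  h <- cfg$enc_hidden; f <- cfg$feature_dim; L <- cfg$latent_dim
  hd <- cfg$dec_hidden; r <- cfg$refine_dim; S <- length(cfg$attention_scales)
  enc <- function() list(W1 = init_weight(3L, h), b1 = rep(0, h),
                         W2 = init_weight(h, f), b2 = rep(0, f),
                         Wm = init_weight(f, L), bm = rep(0, L),
                         Wv = init_weight(f, L), bv = rep(0, L))
  list(enc_p = enc(), enc_c = enc(),
       dec = list(V1 = init_weight(L + f, hd), c1 = rep(0, hd),
                  V2 = init_weight(hd, 3L * cfg$n_coarse), c2 = rep(0, 3L * cfg$n_coarse)),
       ref = list(U1 = init_weight(3L, r), d1 = rep(0, r),
                  U2 = init_weight(r * (1L + S), r), d2 = rep(0, r),
                  U3 = init_weight(r, 3L), d3 = rep(0, 3L)))
}

zeros_like <- function(p) rapply(p, function(x) x * 0, how = "replace")

# ---- forward pieces ---------------------------------------------------------

relu <- function(x) x * (x > 0)

encoder_forward <- function(W, X) {
  H1p <- sweep(X %*% W$W1, 2L, W$b1, "+"); H1 <- relu(H1p)
  H2p <- sweep(H1 %*% W$W2, 2L, W$b2, "+"); H2 <- relu(H2p)
  amax <- max.col(t(H2), ties.method = "first")      # argmax row per feature
  g <- H2[cbind(amax, seq_along(amax))]
  mu <- drop(g %*% W$Wm) + W$bm
  lvp <- drop(g %*% W$Wv) + W$bv
  lv <- pmin(10, pmax(-10, lvp))
  list(H1p = H1p, H1 = H1, H2p = H2p, amax = amax, g = g,
       mu = mu, lv_pre = lvp, lv = lv)
}

encoder_backward <- function(W, X, fw, dg, dmu, dlv) {
  dlv_pre <- dlv * (abs(fw$lv_pre) < 10)
  dW <- list()
  dW$Wm <- outer(fw$g, dmu); dW$bm <- dmu
  dW$Wv <- outer(fw$g, dlv_pre); dW$bv <- dlv_pre
  dg_tot <- dg + drop(W$Wm %*% dmu) + drop(W$Wv %*% dlv_pre)
  dH2 <- matrix(0, nrow(X), length(dg_tot))
  dH2[cbind(fw$amax, seq_along(dg_tot))] <- dg_tot
  dH2p <- dH2 * (fw$H2p > 0)
  dW$W2 <- t(fw$H1) %*% dH2p; dW$b2 <- colSums(dH2p)
  dH1 <- dH2p %*% t(W$W2)
  dH1p <- dH1 * (fw$H1p > 0)
  dW$W1 <- t(X) %*% dH1p; dW$b1 <- colSums(dH1p)
  dW
}

decoder_forward <- function(W, z, g, n_coarse) {
  u <- c(z, g)
  D1p <- drop(u %*% W$V1) + W$c1; D1 <- relu(D1p)
  flat <- drop(D1 %*% W$V2) + W$c2
  list(u = u, D1p = D1p, D1 = D1, coarse = matrix(flat, n_coarse, 3L))
}

decoder_backward <- function(W, fw, dcoarse, latent_dim) {
  dflat <- as.vector(dcoarse)
  dW <- list(V2 = outer(fw$D1, dflat), c2 = dflat)
  dD1 <- drop(W$V2 %*% dflat)
  dD1p <- dD1 * (fw$D1p > 0)
  dW$V1 <- outer(fw$u, dD1p); dW$c1 <- dD1p
  du <- drop(W$V1 %*% dD1p)
  list(dW = dW, dz = du[seq_len(latent_dim)], dg = du[-seq_len(latent_dim)])
}

refiner_forward <- function(W, X, coarse, cfg) {
  Yc <- rbind(X, coarse)
  m <- nrow(Yc)
  scales <- pmin(cfg$attention_scales, m)
  F1p <- sweep(Yc %*% W$U1, 2L, W$d1, "+"); F1 <- relu(F1p)
  nbs <- lapply(scales, function(k) cpp_knn(Yc, k))
  pooled <- lapply(nbs, function(nb) {
    k <- ncol(nb)
    acc <- F1[nb[, 1L], , drop = FALSE]
    if (k > 1L) for (j in 2:k) acc <- acc + F1[nb[, j], , drop = FALSE]
    acc / k
  })
  C <- do.call(cbind, c(list(F1), pooled))
  F2p <- sweep(C %*% W$U2, 2L, W$d2, "+"); F2 <- relu(F2p)
  O <- sweep(F2 %*% W$U3, 2L, W$d3, "+")
  idx <- cpp_fps(Yc, cfg$n_out, 1L)
  fine <- Yc[idx, , drop = FALSE] + O[idx, , drop = FALSE]
  list(Yc = Yc, F1p = F1p, F1 = F1, nbs = nbs, C = C, F2p = F2p, F2 = F2,
       O = O, idx = idx, fine = fine)
}

refiner_backward <- function(W, fw, dfine, cfg) {
  m <- nrow(fw$Yc); r <- ncol(fw$F1)
  dO <- matrix(0, m, 3L); dO[fw$idx, ] <- dO[fw$idx, , drop = FALSE] + dfine
  dYc <- matrix(0, m, 3L); dYc[fw$idx, ] <- dYc[fw$idx, , drop = FALSE] + dfine
  dW <- list(U3 = t(fw$F2) %*% dO, d3 = colSums(dO))
  dF2 <- dO %*% t(W$U3)
  dF2p <- dF2 * (fw$F2p > 0)
  dW$U2 <- t(fw$C) %*% dF2p; dW$d2 <- colSums(dF2p)
  dC <- dF2p %*% t(W$U2)
  dF1 <- dC[, seq_len(r), drop = FALSE]
  for (s in seq_along(fw$nbs)) {
    nb <- fw$nbs[[s]]; k <- ncol(nb)
    dA <- dC[, (s * r + 1L):((s + 1L) * r), drop = FALSE] / k
    expanded <- dA[rep(seq_len(m), k), , drop = FALSE]
    rs <- rowsum(expanded, as.vector(nb))
    contrib <- matrix(0, m, r)
    contrib[as.integer(rownames(rs)), ] <- rs
    dF1 <- dF1 + contrib
  }
  dF1p <- dF1 * (fw$F1p > 0)
  dW$U1 <- t(fw$Yc) %*% dF1p; dW$d1 <- colSums(dF1p)
  dYc <- dYc + dF1p %*% t(W$U1)
  list(dW = dW, dcoarse = dYc[(cfg$n_in + 1L):m, , drop = FALSE])
}

# Chamfer loss (squared, mean per direction, scale 1) and its gradient with
# respect to the first cloud.
chamfer_loss_grad <- function(P, G) {
  fw <- cpp_nn(P, G); bw <- cpp_nn(G, P)
  loss <- mean(fw$d2) + mean(bw$d2)
  grad <- 2 * (P - G[fw$idx, , drop = FALSE]) / nrow(P)
  back <- 2 * (P[bw$idx, , drop = FALSE] - G) / nrow(G)
  grad_back <- rowsum(back, bw$idx)
  grad[as.integer(rownames(grad_back)), ] <-
    grad[as.integer(rownames(grad_back)), , drop = FALSE] + grad_back
  list(loss = loss, grad = grad)
}

# Full forward + backward for one training pair. `eps` is the reparameterized
# latent noise (NULL = use the posterior mean, as in validation).
model_step <- function(params, cfg, X, Ygt, eps = NULL, kl_weight = 0.5,
                       with_grad = TRUE) {
  fp <- encoder_forward(params$enc_p, X)
  fc <- encoder_forward(params$enc_c, Ygt)
  if (is.null(eps)) eps <- rep(0, cfg$latent_dim)
  z <- fc$mu + exp(0.5 * fc$lv) * eps
  fd <- decoder_forward(params$dec, z, fp$g, cfg$n_coarse)
  fr <- refiner_forward(params$ref, X, fd$coarse, cfg)
  kl <- 0.5 * sum(exp(fc$lv - fp$lv) + (fc$mu - fp$mu)^2 / exp(fp$lv) -
                    1 + fp$lv - fc$lv)
  cg_c <- chamfer_loss_grad(fd$coarse, Ygt)
  cg_f <- chamfer_loss_grad(fr$fine, Ygt)
  total <- kl_weight * kl + cg_c$loss + cg_f$loss
  out <- list(loss = total, kl = kl, cd_coarse = cg_c$loss, cd_fine = cg_f$loss,
              coarse = fd$coarse, fine = fr$fine)
  if (!with_grad) return(out)

  grads <- list()
  rb <- refiner_backward(params$ref, fr, cg_f$grad, cfg)
  grads$ref <- rb$dW
  dcoarse <- cg_c$grad + rb$dcoarse
  db <- decoder_backward(params$dec, fd, dcoarse, cfg$latent_dim)
  grads$dec <- db$dW
  # KL gradients
  ratio <- exp(fc$lv - fp$lv)
  dmu_q <- kl_weight * (fc$mu - fp$mu) / exp(fp$lv)
  dmu_p <- -dmu_q
  dlv_q <- kl_weight * 0.5 * (ratio - 1)
  dlv_p <- kl_weight * 0.5 * (1 - ratio - (fc$mu - fp$mu)^2 / exp(fp$lv))
  # reparameterization: z = mu_q + exp(lv_q / 2) * eps
  dmu_q <- dmu_q + db$dz
  dlv_q <- dlv_q + db$dz * 0.5 * exp(0.5 * fc$lv) * eps
  grads$enc_c <- encoder_backward(params$enc_c, Ygt, fc,
                                  dg = rep(0, cfg$feature_dim),
                                  dmu = dmu_q, dlv = dlv_q)
  grads$enc_p <- encoder_backward(params$enc_p, X, fp,
                                  dg = db$dg, dmu = dmu_p, dlv = dlv_p)
  out$grads <- grads
  out
}

# ---- public operation wrappers ---------------------------------------------

#' Encode a partial cloud into a global feature and shape prior
#'
#' Permutation-invariant (shared per-point layers followed by feature-wise
#' max pooling): shuffling the input point order leaves the outputs
#' unchanged.
#'
#' @param model a trained or freshly initialized model (see
#'   [train_completion()] / [init_completion_model()]).
#' @param cloud [point_cloud()] or point matrix of exactly `n_in` points
#'   (normalized coordinates).
#' @return list with `global_feature` (length `feature_dim`) and `prior`
#'   (a [latent_dist()]).
#' @export
encode_partial <- function(model, cloud) {
  X <- as_points(cloud)
  if (nrow(X) != model$config$n_in)
    stop(sprintf("expected %d input points, got %d", model$config$n_in, nrow(X)))
  fw <- encoder_forward(model$params$enc_p, X)
  list(global_feature = fw$g, prior = latent_dist(fw$mu, fw$lv))
}

#' Encode a complete cloud into the posterior distribution
#'
#' @param model completion model.
#' @param cloud complete (ground-truth) cloud of `n_gt` points.
#' @return a [latent_dist()] posterior.
#' @export
encode_complete <- function(model, cloud) {
  Y <- as_points(cloud)
  fw <- encoder_forward(model$params$enc_c, Y)
  latent_dist(fw$mu, fw$lv)
}

#' Decode a latent sample into a coarse completion
#'
#' @param model completion model.
#' @param z latent vector (`latent_dim`).
#' @param global_feature conditioning feature from [encode_partial()].
#' @return `n_coarse x 3` point matrix.
#' @export
decode_coarse <- function(model, z, global_feature) {
  decoder_forward(model$params$dec, z, global_feature, model$config$n_coarse)$coarse
}

#' Relational refinement of a coarse completion
#'
#' Operates on the concatenation of the partial input and the coarse
#' completion: per-point features are pooled over k-nearest-neighbor
#' neighborhoods at each configured attention scale, combined, and decoded
#' into per-point displacements; the output is a farthest-point subset of
#' the concatenated cloud moved by its displacement.
#'
#' @param model completion model.
#' @param partial `n_in x 3` partial cloud (normalized).
#' @param coarse `n_coarse x 3` coarse completion.
#' @return `n_out x 3` refined cloud.
#' @export
refine <- function(model, partial, coarse) {
  X <- as_points(partial); Cc <- as_points(coarse)
  if (nrow(X) != model$config$n_in || nrow(Cc) != model$config$n_coarse)
    stop("partial/coarse cardinalities do not match the model configuration")
  refiner_forward(model$params$ref, X, Cc, model$config)$fine
}

#' Composite training loss
#'
#' `loss = kl_weight * KL(q || p) + CD(coarse, gt) + CD(fine, gt)` with the
#' Chamfer distances in the squared-mean convention at scale 1 (the training
#' loss does not carry the 1e4 reporting factor).
#'
#' @param coarse,fine,gt normalized point matrices or clouds.
#' @param q,p posterior and prior [latent_dist()]s.
#' @param kl_weight weight of the KL term.
#' @return list with `total`, `kl`, `cd_coarse`, `cd_fine`.
#' @export
composite_loss <- function(coarse, fine, gt, q, p, kl_weight = 0.5) {
  kl <- kl_divergence(q, p)
  cd_c <- chamfer(coarse, gt, scale = 1, squared = TRUE)
  cd_f <- chamfer(fine, gt, scale = 1, squared = TRUE)
  list(total = kl_weight * kl + cd_c + cd_f,
       kl = kl, cd_coarse = cd_c, cd_fine = cd_f)
}

#' Initialize an untrained completion model
#'
#' @param config a [model_config()].
#' @return model object (list with `params`, `config`).
#' @export
init_completion_model <- function(config = model_config("smoke")) {
  stopifnot(inherits(config, "model_config"))
  list(params = init_params(config, config$seed), config = config)
}

#' Train the completion model
#'
#' Pairs are split 60/20/20 into train/validation/test by subject
#' (`spine_id`), so views of one spine never straddle splits. Optimization is
#' Adam on the composite KL + Chamfer loss with a linear KL warm-up over the
#' first `kl_warmup_frac` of epochs; the parameters with the best validation
#' loss are kept. Fully seeded and deterministic.
#'
#' @param pairs list of `training_pair`s (from [generate_dataset()] or
#'   [make_sphere_cap_pairs()]); at least `3 * batch_size`.
#' @param config a [model_config()].
#' @return model object: `params` (best-validation), `config`, `history`
#'   (per-epoch data frame), `split` (subject ids per split), `best_epoch`,
#'   and `final_params`.
#' @export
train_completion <- function(pairs, config = model_config("smoke")) {
  stopifnot(inherits(config, "model_config"))
  if (length(pairs) < 3L * config$batch_size)
    stop(sprintf("need at least %d pairs (3 batches), got %d",
                 3L * config$batch_size, length(pairs)))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  subjects <- vapply(pairs, function(p) p$spine_id, numeric(1))
  uniq <- sort(unique(subjects))
  set.seed(config$seed)
  uniq <- sample(uniq)
  cuts <- cumsum(config$split_fractions)
  n_s <- length(uniq)
  split_of <- cut(seq_len(n_s) / n_s, breaks = c(0, cuts[1L], cuts[2L], 1 + 1e-9),
                  labels = c("train", "val", "test"))
  split <- split(uniq, split_of)
  idx_train <- which(subjects %in% split$train)
  idx_val <- which(subjects %in% split$val)
  idx_test <- which(subjects %in% split$test)
  if (length(idx_train) == 0L || length(idx_val) == 0L)
    stop("subject split left the train or validation set empty; use more subjects")

  params <- init_params(config, config$seed)
  adam_m <- zeros_like(params); adam_v <- zeros_like(params)
  adam_t <- 0L
  lr <- config$learning_rate; b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
  warm_epochs <- max(1, ceiling(config$kl_warmup_frac * config$epochs))
  history <- list()
  best_val <- Inf; best_params <- params; best_epoch <- NA_integer_

  pair_xy <- lapply(pairs, function(p)
    list(X = resample_points(p$partial$points, config$n_in),
         Y = resample_points(p$complete$points, config$n_gt)))

  for (epoch in seq_len(config$epochs)) {
    klw <- config$kl_weight * min(1, epoch / warm_epochs)
    set.seed((as.numeric(config$seed) * 2654435 + epoch * 97) %% 2147483629)
    order_tr <- sample(idx_train)
    eps_mat <- matrix(rnorm(length(order_tr) * config$latent_dim),
                      length(order_tr), config$latent_dim)
    batches <- split(seq_along(order_tr),
                     ceiling(seq_along(order_tr) / config$batch_size))
    tr_loss <- 0; tr_kl <- 0; tr_cdc <- 0; tr_cdf <- 0
    for (b in batches) {
      gsum <- NULL
      bloss <- 0
      for (j in b) {
        i <- order_tr[j]
        st <- model_step(params, config, pair_xy[[i]]$X, pair_xy[[i]]$Y,
                         eps = eps_mat[j, ], kl_weight = klw)
        bloss <- bloss + st$loss
        tr_loss <- tr_loss + st$loss; tr_kl <- tr_kl + st$kl
        tr_cdc <- tr_cdc + st$cd_coarse; tr_cdf <- tr_cdf + st$cd_fine
        gsum <- if (is.null(gsum)) st$grads else add_params(gsum, st$grads)
      }
      gavg <- scale_params(gsum, 1 / length(b))
      adam_t <- adam_t + 1L
      upd <- adam_update(params, gavg, adam_m, adam_v, adam_t, lr, b1, b2, aeps)
      params <- upd$params; adam_m <- upd$m; adam_v <- upd$v
    }
    n_tr <- length(idx_train)
    val_loss <- mean(vapply(idx_val, function(i)
      model_step(params, config, pair_xy[[i]]$X, pair_xy[[i]]$Y, eps = NULL,
                 kl_weight = klw, with_grad = FALSE)$loss, numeric(1)))
    history[[epoch]] <- data.frame(
      epoch = epoch, kl_weight = klw,
      train_loss = tr_loss / n_tr, train_kl = tr_kl / n_tr,
      train_cd_coarse = tr_cdc / n_tr, train_cd_fine = tr_cdf / n_tr,
      val_loss = val_loss)
    if (val_loss < best_val) {
      best_val <- val_loss; best_params <- params; best_epoch <- epoch
    }
  }
  list(params = best_params, final_params = params, config = config,
       history = do.call(rbind, history), best_epoch = best_epoch,
       split = split,
       split_idx = list(train = idx_train, val = idx_val, test = idx_test))
}

add_params <- function(a, b) {
  for (g in names(a)) for (w in names(a[[g]])) a[[g]][[w]] <- a[[g]][[w]] + b[[g]][[w]]
  a
}
scale_params <- function(a, s) {
  for (g in names(a)) for (w in names(a[[g]])) a[[g]][[w]] <- a[[g]][[w]] * s
  a
}
adam_update <- function(params, grads, m, v, t, lr, b1, b2, eps) {
  for (g in names(params)) for (w in names(params[[g]])) {
    m[[g]][[w]] <- b1 * m[[g]][[w]] + (1 - b1) * grads[[g]][[w]]
    v[[g]][[w]] <- b2 * v[[g]][[w]] + (1 - b2) * grads[[g]][[w]]^2
    mhat <- m[[g]][[w]] / (1 - b1^t)
    vhat <- v[[g]][[w]] / (1 - b2^t)
    params[[g]][[w]] <- params[[g]][[w]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, m = m, v = v)
}

#' Complete a partial cloud (MAP inference)
#'
#' Normalizes the input to the unit sphere, resamples it to `n_in` points,
#' encodes it, decodes the coarse completion from the prior mean (the
#' maximum-a-posteriori point estimate -- no sampling at inference, so
#' repeated calls are identical), refines, and denormalizes both clouds back
#' to millimetres with the input's transform.
#'
#' @param partial a [point_cloud()] in mm (non-empty).
#' @param model trained model from [train_completion()].
#' @return object of class `completion_result`: `coarse` and `fine`
#'   [point_cloud()]s in mm, plus the `transform` used.
#' @export
complete_cloud <- function(partial, model) {
  stopifnot(inherits(partial, "point_cloud"))
  if (nrow(partial$points) == 0L) stop("cannot complete an empty cloud")
  norm <- normalize_cloud(partial)
  X <- resample_points(norm$cloud$points, model$config$n_in)
  enc <- encode_partial(model, X)
  coarse <- decode_coarse(model, enc$prior$mean, enc$global_feature)
  fine <- refine(model, X, coarse)
  structure(list(
    coarse = denormalize_cloud(point_cloud(coarse), norm$transform),
    fine = denormalize_cloud(point_cloud(fine), norm$transform),
    transform = norm$transform), class = "completion_result")
}

#' @export
print.completion_result <- function(x, ...) {
  cat(sprintf("completion_result: coarse %d, fine %d points (mm)\n",
              nrow(x$coarse$points), nrow(x$fine$points)))
  invisible(x)
}

#' Sphere-with-cap-removed smoke benchmark pairs
#'
#' A desk-scale analogue of the vertebra task: the complete shape is a unit
#' sphere (area-uniform samples); the partial view is the sphere with a polar
#' cap removed (everything above `cos(cap_angle_deg)` dropped), mimicking an
#' occluded region, plus slight Gaussian jitter. Each pair is its own
#' subject, so subject-level splitting applies directly.
#'
#' @param n_pairs number of pairs (default 200).
#' @param n_points points per cloud.
#' @param cap_angle_deg half-angle of the removed polar cap.
#' @param noise_sd jitter standard deviation (normalized units).
#' @param seed integer seed.
#' @return list of `training_pair`s.
#' @export
make_sphere_cap_pairs <- function(n_pairs = 200L, n_points = 256L,
                                  cap_angle_deg = 60, noise_sd = 0.01,
                                  seed = 1L) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  zmax <- cos(cap_angle_deg * pi / 180)
  sphere <- function(n) {
    z <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
    r <- sqrt(pmax(0, 1 - z^2))
    cbind(r * cos(phi), r * sin(phi), z)
  }
  lapply(seq_len(n_pairs), function(i) {
    gt <- sphere(n_points)
    part <- sphere(4L * n_points)
    part <- part[part[, 3L] < zmax, , drop = FALSE]
    part <- resample_points(part, n_points)
    part <- part + matrix(rnorm(length(part), sd = noise_sd), nrow(part), 3L)
    gt_norm <- normalize_cloud(point_cloud(gt))
    structure(list(
      partial = point_cloud(apply_norm_transform(part, gt_norm$transform)),
      complete = gt_norm$cloud, transform = gt_norm$transform,
      level = "sphere", spine_id = i, curvature_id = 1L),
      class = "training_pair")
  })
}
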