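tiny_config <- function(...) {
  model_config("smoke", n_in = 24L, n_gt = 24L, n_coarse = 8L, n_out = 24L,
               latent_dim = 4L, feature_dim = 8L, enc_hidden = 6L,
               dec_hidden = 10L, refine_dim = 6L, attention_scales = c(3L, 5L),
               ...)
}

test_that("encoders are permutation invariant and shape-sensitive", {
  model <- init_completion_model(model_config("smoke"))
  set.seed(3)
  X <- matrix(rnorm(256 * 3), 256, 3)
  a <- encode_partial(model, X)
  b <- encode_partial(model, X[sample(256), ])
  expect_lt(max(abs(a$global_feature - b$global_feature)), 1e-5)
  expect_lt(max(abs(a$prior$mean - b$prior$mean)), 1e-5)
  q1 <- encode_complete(model, X)
  q2 <- encode_complete(model, X[sample(256), ])
  expect_lt(max(abs(q1$mean - q2$mean)), 1e-5)
  # two disjoint clouds give distinct features
  Y <- sweep(X, 2L, c(5, 0, 0), "+")
  c2 <- encode_partial(model, Y)
  cosim <- sum(a$global_feature * c2$global_feature) /
    sqrt(sum(a$global_feature^2) * sum(c2$global_feature^2))
  expect_lt(cosim, 0.999)
  # contract: output dimensions
  expect_length(a$global_feature, model$config$feature_dim)
  expect_length(a$prior$mean, model$config$latent_dim)
  expect_length(a$prior$log_var, model$config$latent_dim)
  expect_error(encode_partial(model, X[1:100, ]), "expected")
  # robustness: degenerate all-duplicate cloud still yields finite outputs
  dup <- matrix(0.3, 256, 3)
  qd <- encode_complete(model, dup)
  expect_true(all(is.finite(qd$mean)) && all(is.finite(qd$log_var)))
})

test_that("KL closed form matches identities and a Monte-Carlo oracle", {
  q <- latent_dist(c(0.3, -1), c(0.2, -0.4))
  expect_equal(kl_divergence(q, q), 0)
  expect_equal(kl_divergence(latent_dist(0, 0), latent_dist(1, 0)), 0.5)
  expect_error(kl_divergence(q, latent_dist(0, 0)), "dimensions")
  set.seed(8)
  for (trial in 1:3) {
    mq <- rnorm(3); lq <- runif(3, -1, 1)
    mp <- rnorm(3); lp <- runif(3, -1, 1)
    q <- latent_dist(mq, lq); p <- latent_dist(mp, lp)
    n <- 1e5
    z <- matrix(rnorm(3 * n, mean = rep(mq, each = n),
                      sd = rep(exp(lq / 2), each = n)), n, 3)
    log_ratio <- rowSums(dnorm(z, rep(mq, each = n), rep(exp(lq / 2), each = n), log = TRUE) -
                           dnorm(z, rep(mp, each = n), rep(exp(lp / 2), each = n), log = TRUE))
    mc <- mean(log_ratio)
    se <- sd(log_ratio) / sqrt(n)
    expect_lt(abs(kl_divergence(q, p) - mc), 3 * se)
  }
})

test_that("decoder and refiner honor their output contracts", {
  cfg <- tiny_config()
  model <- init_completion_model(cfg)
  set.seed(5)
  g <- rnorm(cfg$feature_dim); z <- rnorm(cfg$latent_dim)
  coarse <- decode_coarse(model, z, g)
  expect_equal(dim(coarse), c(cfg$n_coarse, 3L))
  expect_identical(coarse, decode_coarse(model, z, g))
  expect_lt(max(sqrt(rowSums(coarse^2))), 10)  # untrained output bounded
  X <- matrix(rnorm(cfg$n_in * 3), cfg$n_in, 3)
  fine <- refine(model, X, coarse)
  expect_equal(dim(fine), c(cfg$n_out, 3L))
  expect_identical(fine, refine(model, X, coarse))
  expect_true(all(is.finite(fine)))
  expect_error(refine(model, X[1:5, ], coarse), "cardinalities")
})

test_that("the composite loss decomposes and vanishes at the optimum", {
  set.seed(2)
  gt <- matrix(rnorm(60), 20, 3)
  q <- latent_dist(rnorm(4), runif(4, -1, 0))
  perfect <- composite_loss(gt, gt, gt, q, q, kl_weight = 0.5)
  expect_equal(perfect$total, 0)
  other <- matrix(rnorm(60), 20, 3)
  p2 <- latent_dist(rnorm(4), runif(4, -1, 0))
  l <- composite_loss(other, gt, gt, q, p2, kl_weight = 0)
  expect_equal(l$total, l$cd_coarse + l$cd_fine)
  lw <- composite_loss(other, other, gt, q, p2, kl_weight = 0.5)
  expect_gte(lw$total, lw$cd_coarse)
  expect_gte(lw$total, lw$cd_fine)
  expect_gte(lw$total, 0.5 * lw$kl)
})

test_that("analytic gradients agree with finite differences everywhere", {
  cfg <- tiny_config()
  params <- sonocomplete:::init_params(cfg, 1L)
  set.seed(42)
  X <- matrix(rnorm(cfg$n_in * 3), cfg$n_in, 3)
  Y <- matrix(rnorm(cfg$n_gt * 3), cfg$n_gt, 3)
  eps <- rnorm(cfg$latent_dim)
  st <- sonocomplete:::model_step(params, cfg, X, Y, eps = eps, kl_weight = 0.5)
  h <- 1e-6
  for (g in names(params)) for (w in names(params[[g]])) {
    i <- sample(length(params[[g]][[w]]), 1L)
    pp <- params; pp[[g]][[w]][i] <- pp[[g]][[w]][i] + h
    pm <- params; pm[[g]][[w]][i] <- pm[[g]][[w]][i] - h
    fd <- (sonocomplete:::model_step(pp, cfg, X, Y, eps, 0.5, with_grad = FALSE)$loss -
             sonocomplete:::model_step(pm, cfg, X, Y, eps, 0.5, with_grad = FALSE)$loss) / (2 * h)
    an <- st$grads[[g]][[w]][i]
    expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), 1e-4)
  }
})

test_that("training is deterministic, split-disjoint, and improves the loss", {
  pairs <- make_sphere_cap_pairs(40L, 24L, seed = 6L)
  cfg <- tiny_config(epochs = 4L, batch_size = 4L, seed = 6L)
  m1 <- train_completion(pairs, cfg)
  m2 <- train_completion(pairs, cfg)
  expect_identical(m1$history, m2$history)
  ids <- list(train = m1$split$train, val = m1$split$val, test = m1$split$test)
  expect_length(intersect(ids$train, ids$val), 0L)
  expect_length(intersect(ids$train, ids$test), 0L)
  expect_length(intersect(ids$val, ids$test), 0L)
  expect_lt(m1$history$train_loss[4L], m1$history$train_loss[1L])
  expect_error(train_completion(pairs[1:5], cfg), "at least")
})

test_that("MAP completion is deterministic and respects the input frame", {
  pairs <- make_sphere_cap_pairs(40L, 24L, seed = 6L)
  cfg <- tiny_config(epochs = 2L, batch_size = 4L, seed = 6L)
  model <- train_completion(pairs, cfg)
  partial_mm <- point_cloud(pairs[[1L]]$partial$points * 30 +
                              matrix(rep(c(100, -50, 20), each = 24L), 24L, 3L))
  r1 <- complete_cloud(partial_mm, model)
  r2 <- complete_cloud(partial_mm, model)
  expect_identical(r1$fine$points, r2$fine$points)
  # denormalized output stays in the input's normalization sphere neighborhood
  cen <- r1$transform$center
  expect_lt(sqrt(sum((colMeans(r1$fine$points) - cen)^2)),
            2 * r1$transform$scale)
  expect_error(complete_cloud(point_cloud(matrix(numeric(0), 0, 3)), model))
})
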