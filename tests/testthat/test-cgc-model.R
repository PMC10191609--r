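make_feats <- function(cfg, B, seed = 1) {
  set.seed(seed)
  L <- cfg$window_size
  list(kmer = array(runif(4^cfg$kmer_order * L * B),
                    c(4^cfg$kmer_order, L, B)),
       shape = array(rnorm(4 * L * B), c(4, L, B)),
       histone = array(runif(8 * L * B), c(8, L, B)))
}

small_cfg <- function(...) {
  tfgate_config(n_cells = 2, kmer_order = 2, n_kernels = 4, motif_width = 5,
                hidden_units = 8, dropout = 0, window_size = 12, ...)
}

test_that("the latent projection sends all three streams to 4 x L", {
  cfg <- small_cfg()
  model <- init_model(cfg, seed = 2)
  feats <- make_feats(cfg, 3)
  fw <- tfgate:::model_forward(model, feats, keep_cache = TRUE)
  for (s in c("kmer", "shape", "histone")) {
    expect_equal(dim(fw$cache$streams[[s]]$cache$pre),
                 c(3 * cfg$n_kernels, 12L, 3L))
  }
  expect_equal(dim(fw$cache$lat$kmer), c(4L, 12L, 3L))
  expect_equal(dim(fw$cache$lat$histone), c(4L, 12L, 3L))
  # identity projection on the shape stream reproduces its input latent
  model$params$proj$shape$W <- diag(4)
  model$params$proj$shape$b <- numeric(4)
  fw2 <- tfgate:::model_forward(model, feats, keep_cache = TRUE)
  expect_equal(fw2$cache$lat$shape, feats$shape, tolerance = 1e-12)
})

test_that("gate weights form a probability simplex for random inputs", {
  cfg <- small_cfg()
  model <- init_model(cfg, seed = 3)
  feats <- make_feats(cfg, 64, seed = 9)
  fw <- tfgate:::model_forward(model, feats)
  for (k in 1:2) {
    wg <- fw$gate_weights[[k]]
    expect_equal(dim(wg), c(6L, 64L))
    expect_true(all(wg >= 0))
    expect_equal(unname(colSums(wg)), rep(1, 64), tolerance = 1e-9)
  }
})

test_that("zero gate logits give uniform 1/6 weights and the mean map", {
  cfg <- small_cfg()
  model <- init_model(cfg, seed = 4)
  for (k in 1:2) {
    model$params$gates[[k]]$W[] <- 0
    model$params$gates[[k]]$b[] <- 0
  }
  feats <- make_feats(cfg, 5)
  fw <- tfgate:::model_forward(model, feats, keep_cache = TRUE)
  expect_equal(fw$gate_weights[[1]], matrix(1 / 6, 6, 5), tolerance = 1e-12)
  E <- fw$cache$gates[[1]]$E
  mix <- tfgate:::cpp_gate_mix(E, matrix(1 / 6, 6, 5))
  expect_equal(mix, Reduce(`+`, E) / 6, tolerance = 1e-12)
})

test_that("a saturated gate logit selects a single expert map", {
  cfg <- small_cfg()
  model <- init_model(cfg, seed = 5)
  model$params$gates[[1]]$W[] <- 0
  model$params$gates[[1]]$b <- c(50, rep(0, 5)) # softmax -> ~1 on expert 1
  feats <- make_feats(cfg, 4)
  fw <- tfgate:::model_forward(model, feats, keep_cache = TRUE)
  wg <- fw$gate_weights[[1]]
  expect_true(all(wg[1, ] > 1 - 1e-15))
  E <- fw$cache$gates[[1]]$E
  mix <- tfgate:::cpp_gate_mix(E, wg)
  expect_equal(mix, E[[1]], tolerance = 1e-10)
})

test_that("prediction heads apply sigma(MLP(g)) with outputs in (0, 1)", {
  cfg <- small_cfg()
  model <- init_model(cfg, seed = 6)
  feats <- make_feats(cfg, 10)
  fw <- tfgate:::model_forward(model, feats)
  expect_true(all(fw$probs > 0 & fw$probs < 1))
  # zero-weight head -> sigma(0) = 0.5
  for (k in 1:2) {
    for (nm in c("W1", "b1", "W2", "b2")) model$params$heads[[k]][[nm]][] <- 0
  }
  fw0 <- tfgate:::model_forward(model, feats)
  expect_equal(fw0$probs, matrix(0.5, 2, 10))
  # 1-tap closed form through a deterministic head
  model$params$heads[[1]]$W2[] <- 1
  model$params$heads[[1]]$b2 <- -0.3
  fw1 <- tfgate:::model_forward(model, feats)
  expect_equal(unname(fw1$probs[1, ]), rep(tfgate:::sigmoid(-0.3), 10))
})

test_that("forward is deterministic in eval mode and sized by n_cells", {
  cfg1 <- tfgate_config(n_cells = 1, n_kernels = 4, motif_width = 5,
                        window_size = 12, hidden_units = 8)
  m1 <- init_model(cfg1, seed = 7)
  f1 <- make_feats(cfg1, 3)
  expect_equal(dim(tfgate:::model_forward(m1, f1)$probs), c(1L, 3L))
  cfg <- small_cfg()
  model <- init_model(cfg, seed = 7)
  feats <- make_feats(cfg, 6)
  a <- tfgate:::model_forward(model, feats)
  b <- tfgate:::model_forward(model, feats)
  expect_identical(a$probs, b$probs)
})

test_that("permuting cell types permutes the outputs", {
  cfg <- small_cfg()
  model <- init_model(cfg, seed = 8)
  feats <- make_feats(cfg, 5)
  base <- tfgate:::model_forward(model, feats)$probs
  swapped <- model
  swapped$params$experts <- model$params$experts[c(2, 1, 3)]
  swapped$params$gates <- model$params$gates[c(2, 1)]
  swapped$params$heads <- model$params$heads[c(2, 1)]
  got <- tfgate:::model_forward(swapped, feats)$probs
  expect_equal(got, base[c(2, 1), ], tolerance = 1e-12)
})

test_that("the parameter count is a deterministic function of the config", {
  cfg <- tfgate_config(n_cells = 3, kmer_order = 2, n_kernels = 16,
                       motif_width = 15, hidden_units = 64,
                       window_size = 101)
  model <- init_model(cfg, seed = 9)
  C <- 16
  h_rows <- c(16, 4, 8)
  proj <- sum(4 * h_rows + 4)
  kappa <- adaptive_kernel_size(C)
  block <- C * 4 * 15 + C + 2 + kappa + 1
  experts <- (3 + 1) * 3 * block
  gates <- 3 * (6 * sum(h_rows) + 6)
  heads <- 3 * (64 * C + 64 + 64 + 1) # pooled head input
  expect_equal(n_parameters(model), proj + experts + gates + heads)
  expect_equal(n_parameters(init_model(cfg, seed = 99)),
               n_parameters(model))
})

test_that("the shared expert receives gradient from every task, specific experts only from their own", {
  cfg <- small_cfg()
  model <- init_model(cfg, seed = 10)
  feats <- make_feats(cfg, 4)
  fw <- tfgate:::model_forward(model, feats, keep_cache = TRUE)
  grad_norm <- function(g) sum(abs(unlist(g)))
  for (k in 1:2) {
    dz <- matrix(0, 2, 4)
    dz[k, ] <- 1
    g <- tfgate:::model_backward(model, fw, dz)
    expect_gt(grad_norm(g$experts[[3]]), 0) # shared expert always learns
    expect_gt(grad_norm(g$experts[[k]]), 0)
    expect_equal(grad_norm(g$experts[[setdiff(1:2, k)]]), 0)
    expect_equal(grad_norm(g$heads[[setdiff(1:2, k)]]), 0)
    expect_equal(grad_norm(g$gates[[setdiff(1:2, k)]]), 0)
  }
})

test_that("analytic gradients match finite differences", {
  cfg <- small_cfg()
  model <- init_model(cfg, seed = 11)
  feats <- make_feats(cfg, 3, seed = 12)
  set.seed(13)
  labels <- matrix(rbinom(6, 1, 0.5), 2, 3)
  theta <- tfgate:::flatten_params(model$params)
  lossfn <- function(th) {
    m2 <- model
    m2$params <- tfgate:::unflatten_params(th, model$params)
    joint_loss(tfgate:::model_forward(m2, feats)$probs, labels)
  }
  fw <- tfgate:::model_forward(model, feats, keep_cache = TRUE)
  dz <- (fw$probs - labels) / 3
  g <- tfgate:::flatten_params(tfgate:::model_backward(model, fw, dz))
  eps <- 1e-6
  idx <- sort(sample(length(theta), 120))
  for (i in idx) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    fd <- (lossfn(tp) - lossfn(tm)) / (2 * eps)
    denom <- max(abs(fd), abs(g[i]), 1e-4)
    expect_lt(abs(fd - g[i]) / denom, 1e-4)
  }
})

test_that("checkpoints restore a model bit-exactly", {
  res <- tiny_trained_fit()
  dir <- withr::local_tempdir()
  save_fit(res$fit, dir)
  fit2 <- load_fit(dir)
  p1 <- predict(res$fit, res$dataset, indices = 1:20)
  p2 <- predict(fit2, res$dataset, indices = 1:20)
  expect_equal(p2, p1, tolerance = 1e-12)
  expect_equal(fit2$cell_types, res$fit$cell_types)
})
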