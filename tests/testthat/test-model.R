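# Model construction, metrics, splits, and the training loop's contracts.

test_that("models output sigmoid probabilities with deterministic init", {
  m <- build_model("tiny3d", c(32, 32, 5), seed = 11)
  x <- array(runif(32 * 32 * 5), c(32, 32, 5))
  p <- predict(m, list(x, x * 0.5))
  expect_length(p, 2L)
  expect_true(all(p > 0 & p < 1))
  m2 <- build_model("tiny3d", c(32, 32, 5), seed = 11)
  expect_identical(m$layers, m2$layers)
  m3 <- build_model("tiny3d", c(32, 32, 5), seed = 12)
  expect_false(identical(m$layers, m3$layers))
})

test_that("the residual architecture builds its published stage layout", {
  r1 <- build_model("resnet34_3d", c(64, 64, 5), seed = 1)
  r2 <- build_model("resnet34_3d", c(64, 64, 5), seed = 2)
  expect_identical(n_params(r1), n_params(r2))       # count depends on arch only
  blocks <- Filter(function(l) l$type == "resblock", r1$layers)
  expect_length(blocks, 16L)                          # 3 + 4 + 6 + 3
  expect_identical(dim(blocks[[1]]$conv1$w), c(3L, 3L, 3L, 64L, 64L))
  expect_identical(dim(blocks[[16]]$conv2$w), c(3L, 3L, 3L, 512L, 512L))
  # depth axis is never strided
  strides <- vapply(blocks, function(b) b$conv1$stride[3], 0L)
  expect_true(all(strides == 1L))
  p <- predict(r1, list(array(runif(32 * 32 * 5), c(32, 32, 5))))
  expect_true(p > 0 && p < 1)
  expect_error(build_model("tiny3d", c(4, 4, 5)), class = "ctsurv_bad_shape")
})

test_that("stratified splits preserve class balance and are reproducible", {
  set.seed(3)
  labels <- rep(c(0, 1), c(251, 122))               # 32.7% positives
  sp <- stratified_split(labels, 0.15, seed = 4)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0L)
  expect_identical(sort(c(sp$train_idx, sp$test_idx)), seq_along(labels))
  tr_frac <- mean(labels[sp$train_idx])
  expect_lt(abs(tr_frac - mean(labels)), 1 / length(sp$train_idx) + 0.01)
  expect_identical(stratified_split(labels, 0.15, seed = 4), sp)
  expect_error(stratified_split(rep(1, 10), 0.15, 1), class = "ctsurv_bad_split")
})

test_that("rank AUC equals brute force and an independent implementation", {
  expect_identical(auc_midrank(c(0.1, 0.9), c(0, 1)), 1)
  expect_identical(auc_midrank(rep(0.4, 6), c(0, 1, 0, 1, 1, 0)), 0.5)
  expect_true(is.na(auc_midrank(runif(5), rep(1, 5))))
  brute <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(19)
  for (i in 1:30) {
    n <- sample(10:200, 1)
    s <- round(runif(n), 2)                          # force ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(auc_midrank(s, y), brute(s, y), tolerance = 1e-12)
    roc <- pROC::roc(response = y, predictor = s, direction = "<",
                     levels = c(0, 1), quiet = TRUE)
    expect_equal(auc_midrank(s, y), as.numeric(pROC::auc(roc)),
                 tolerance = 1e-12)
  }
  # permutation property: random scores hover at 0.5
  aucs <- vapply(1:100, function(i) {
    set.seed(i)
    auc_midrank(runif(1000), rbinom(1000, 1, 0.3))
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("training reduces loss and honours the LR plateau schedule", {
  task <- separable_task(n = 32, seed = 2)
  m <- build_model("tiny3d", c(32, 32, 5), seed = 2)
  cfg <- train_config(lr = 0.08, epochs = 16, folds = 1, seed = 2,
                      batch_size = 8)
  fit <- train(m, task$stacks, task$labels, cfg)
  h <- fit$history
  expect_lt(tail(h$train_loss, 1), 0.5 * h$train_loss[1])
  # plateau: freeze learning (lr ~ 0) so validation never improves
  cfg2 <- train_config(lr = 1e-12, epochs = 6, folds = 1, seed = 2,
                       plateau_patience = 2L, early_stopping_patience = 50L,
                       batch_size = 8)
  fit2 <- train(m, task$stacks, task$labels, cfg2)
  lrs <- fit2$history$lr
  expect_equal(lrs[1:3], rep(1e-12, 3))
  expect_equal(lrs[4], 1e-12 * 0.9, tolerance = 1e-9)  # dropped after 2 stalls
  expect_equal(lrs[6], 1e-12 * 0.9^2, tolerance = 1e-9)
})

test_that("PEN-BCE at zero penalties trains bit-identically to BCE", {
  task <- separable_task(n = 16, seed = 6)
  m <- build_model("tiny3d", c(32, 32, 5), seed = 6)
  cfg_b <- train_config(lr = 0.05, epochs = 4, folds = 1, seed = 9,
                        batch_size = 8, loss = "bce")
  cfg_p <- train_config(lr = 0.05, epochs = 4, folds = 1, seed = 9,
                        batch_size = 8, loss = "pen_bce",
                        loss_params = loss_params(0, 0, 0.5, 0.2))
  fit_b <- train(m, task$stacks, task$labels, cfg_b)
  fit_p <- train(m, task$stacks, task$labels, cfg_p)
  expect_identical(fit_b$history[c("train_loss", "val_loss")],
                   fit_p$history[c("train_loss", "val_loss")])
  expect_identical(fit_b$models[[1]]$layers, fit_p$models[[1]]$layers)
})

test_that("augmentation doubles the training stream with in-range volumes", {
  task <- separable_task(n = 16, seed = 8)
  set.seed(1)
  v <- task$stacks[[1]]
  a <- augment_volume(v)
  expect_identical(dim(a), dim(v))
  expect_true(all(a >= 0 & a <= 1))
  expect_false(identical(a, v))
  m <- build_model("tiny3d", c(32, 32, 5), seed = 8)
  cfg <- train_config(lr = 0.05, epochs = 1, folds = 1, seed = 8,
                      batch_size = 8, augment = TRUE)
  fit <- train(m, task$stacks, task$labels, cfg)
  n_train <- length(task$stacks) -
    length(stratified_split(task$labels, 0.15, seed = 8)$test_idx)
  expect_identical(fit$n_train_effective, 2L * n_train)
})

test_that("evaluation reports per-fold metrics and NA AUC for one-class sets", {
  m <- build_model("tiny3d", c(16, 16, 5), seed = 1)
  xs <- lapply(1:6, function(i) array(runif(16 * 16 * 5), c(16, 16, 5)))
  ev <- evaluate(m, xs, c(0, 1, 0, 1, 0, 1))
  expect_s3_class(ev, "eval_result")
  expect_true(ev$acc >= 0 && ev$acc <= 1)
  ev1 <- evaluate(m, xs, rep(1, 6))
  expect_true(is.na(ev1$auc))
})

test_that("a 2-cell ablation with equivalent losses yields identical rows", {
  task <- separable_task(n = 16, seed = 4)
  grid <- data.frame(loss = c("bce", "pen_bce"),
                     alpha = 0, beta = 0, p_fn = 0.5, p_fp = 0.2)
  cfg <- train_config(lr = 0.05, epochs = 3, folds = 1, seed = 4,
                      batch_size = 8)
  res <- run_ablation(grid, list(main = task), base_config = cfg)
  expect_identical(nrow(res), 2L)
  expect_equal(res$test_loss[1], res$test_loss[2], tolerance = 1e-12)
  expect_identical(res$acc[1], res$acc[2])
  expect_identical(res$auc[1], res$auc[2])
})
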