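# Training recipe: SGD with Nesterov momentum, learning-rate reduction on
# validation-loss plateau, early stopping with best-weight restore, K-fold
# cross-validation over the training split of a stratified 85/15 division.

#' Training configuration
#'
#' Defaults follow the reference recipe: SGD with Nesterov momentum 0.9,
#' initial learning rate 2e-5, weight decay 1e-6, batch size 16, up to 200
#' epochs, learning rate multiplied by 0.9 after 25 epochs without
#' validation-loss improvement (beyond `plateau_min_delta`), early stopping
#' on validation loss (patience 50, best weights restored), and 5-fold
#' cross-validation inside the training split.
#'
#' @param lr initial learning rate.
#' @param weight_decay L2 penalty folded into the gradient.
#' @param momentum,nesterov SGD momentum settings.
#' @param batch_size minibatch size.
#' @param epochs maximum epochs per fold.
#' @param plateau_patience epochs without improvement before the LR drops.
#' @param lr_factor multiplicative LR reduction on plateau.
#' @param plateau_min_delta improvement below this counts as constant.
#' @param early_stopping_patience epochs without improvement before stopping.
#' @param folds cross-validation folds over the training data (1 = single
#'   stratified 85/15 train/validation split).
#' @param loss `"bce"` or `"pen_bce"`.
#' @param loss_params a [loss_params()] object (used by `"pen_bce"`).
#' @param augment add one rotated/shifted copy of every training sample.
#' @param aug_max_rot,aug_max_shift augmentation ranges: rotation in degrees,
#'   shift as a fraction of width/height.
#' @param seed RNG seed for splits, shuffling and augmentation.
#' @param verbose print per-epoch progress.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 2e-5, weight_decay = 1e-6, momentum = 0.9,
                         nesterov = TRUE, batch_size = 16L, epochs = 200L,
                         plateau_patience = 25L, lr_factor = 0.9,
                         plateau_min_delta = 1e-4,
                         early_stopping_patience = 50L, folds = 5L,
                         loss = c("bce", "pen_bce"),
                         loss_params = ctsurv::loss_params(),
                         augment = FALSE, aug_max_rot = 15,
                         aug_max_shift = 0.1, seed = 1L, verbose = FALSE) {
  loss <- match.arg(loss)
  stopifnot(lr > 0, batch_size >= 1, epochs >= 1, folds >= 1,
            lr_factor > 0, lr_factor < 1)
  structure(as.list(environment()), class = "train_config")
}

#' Stratified train/test split
#'
#' Splits indices so each class appears in the training set in (to within
#' one patient) the same proportion as overall; the two index sets are
#' disjoint and exhaustive.
#'
#' @param labels 0/1 vector.
#' @param test_frac held-out fraction (default 0.15).
#' @param seed RNG seed; the same seed reproduces the same split.
#' @return list with `train_idx` and `test_idx`.
#' @export
stratified_split <- function(labels, test_frac = 0.15, seed = 1L) {
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    ctsurv_abort("both classes must be present", "ctsurv_bad_split")
  set.seed(seed)
  test_idx <- integer(0)
  for (cl in classes) {
    idx <- which(labels == cl)
    if (length(idx) < 2L)
      ctsurv_abort("a class has fewer than 2 members", "ctsurv_bad_split")
    n_test <- max(1L, round(test_frac * length(idx)))
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  list(train_idx = setdiff(seq_along(labels), test_idx),
       test_idx = sort(test_idx))
}

.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Rotate/shift augmentation of one input volume
#'
#' Applies a single random in-plane rotation (uniform in
#' `[-max_rot, max_rot]` degrees) and translation (uniform up to
#' `max_shift` of each in-plane dimension) to every slice of the volume,
#' with bilinear resampling and zero fill.
#'
#' @param volume `H x W x D` array in `[0, 1]`.
#' @param max_rot maximum absolute rotation in degrees.
#' @param max_shift maximum shift as a fraction of width/height.
#' @return augmented array, same shape, clipped to `[0, 1]`.
#' @export
augment_volume <- function(volume, max_rot = 15, max_shift = 0.1) {
  d <- dim(volume)
  ang <- stats::runif(1, -max_rot, max_rot)
  sh <- c(stats::runif(1, -max_shift, max_shift) * d[1],
          stats::runif(1, -max_shift, max_shift) * d[2])
  out <- array(0, d)
  for (i in seq_len(d[3])) {
    img <- EBImage::Image(volume[, , i])
    img <- EBImage::rotate(img, ang, filter = "bilinear",
                           output.dim = d[1:2], bg.col = 0)
    img <- EBImage::translate(img, sh, filter = "bilinear", bg.col = 0)
    out[, , i] <- as.matrix(img)
  }
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

.loss_value <- function(probs, labels, config) {
  if (config$loss == "bce") bce(probs, labels)
  else pen_bce(probs, labels, config$loss_params)
}
.loss_grad <- function(probs, labels, config) {
  if (config$loss == "bce") bce_grad(probs, labels)
  else pen_bce_grad(probs, labels, config$loss_params)
}

#' Fit the classifier with cross-validated SGD
#'
#' Runs `config$folds`-fold stratified cross-validation over the supplied
#' training data. Within each fold the model is trained by minibatch SGD
#' (Nesterov momentum, L2 weight decay) on the configured loss; after every
#' epoch the validation loss drives the plateau LR schedule and early
#' stopping, and the best-validation weights are restored at the end.
#'
#' @param model a [build_model()] result (its initial weights seed every
#'   fold).
#' @param stacks list of `H x W x D` arrays or `input_stack` objects.
#' @param labels 0/1 vector aligned with `stacks`.
#' @param config a [train_config()].
#' @return object of class `ctsurv_fit`: `models` (one per fold),
#'   `history` (data.frame: fold, epoch, lr, train_loss, val_loss),
#'   `config`, and `n_train_effective` (per-fold training-set size after
#'   augmentation).
#' @export
train <- function(model, stacks, labels, config = train_config()) {
  stacks <- lapply(stacks, function(x) if (inherits(x, "input_stack")) x$volume else x)
  if (length(stacks) != length(labels))
    ctsurv_abort("stacks and labels differ in length", "ctsurv_bad_batch")
  set.seed(config$seed)
  labels <- as.numeric(labels)
  n <- length(labels)
  fold_of <- if (config$folds > 1L) .stratified_folds(labels, config$folds)
             else {
               v <- rep(0L, n)
               v[stratified_split(labels, 0.15, seed = config$seed)$test_idx] <- 1L
               v + 1L  # fold 1 trains on fold != 1? see below
             }
  k_eff <- max(fold_of)
  models <- vector("list", if (config$folds > 1L) k_eff else 1L)
  history <- NULL
  n_eff <- integer(0)
  for (fold in seq_along(models)) {
    if (config$folds > 1L) {
      tr <- which(fold_of != fold); va <- which(fold_of == fold)
    } else {
      tr <- which(fold_of == 1L); va <- which(fold_of == 2L)
    }
    xs <- stacks[tr]; ys <- labels[tr]
    if (config$augment) {
      aug <- lapply(xs, augment_volume, max_rot = config$aug_max_rot,
                    max_shift = config$aug_max_shift)
      xs <- c(xs, aug); ys <- c(ys, ys)
    }
    n_eff <- c(n_eff, length(xs))
    m <- model
    vel <- .zero_like_grads(m)
    lr <- config$lr
    best_val <- Inf; best_m <- m
    plateau <- 0L; stall <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(length(xs))
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      tr_losses <- numeric(0)
      for (bi in batches) {
        fw <- lapply(xs[bi], function(x) .model_fw(m, x, keep_cache = TRUE))
        p <- vapply(fw, `[[`, 0, "prob")
        y <- ys[bi]
        tr_losses <- c(tr_losses, .loss_value(p, y, config))
        gp <- .loss_grad(p, y, config)
        gz <- gp * p * (1 - p)          # through the sigmoid
        grads <- .zero_like_grads(m)
        for (s in seq_along(bi))
          grads <- .acc_grads(grads, .model_bw(m, fw[[s]]$caches, gz[s]))
        r <- .sgd_step(m, grads, vel, lr, config$momentum, config$nesterov,
                       config$weight_decay)
        m <- r$model; vel <- r$vel
      }
      vp <- vapply(stacks[va], function(x) .model_fw(m, x)$prob, 0)
      val_loss <- .loss_value(vp, labels[va], config)
      history <- rbind(history, data.frame(
        fold = fold, epoch = epoch, lr = lr,
        train_loss = mean(tr_losses), val_loss = val_loss))
      if (is.na(val_loss) || !is.finite(val_loss))
        ctsurv_abort("non-finite validation loss; aborting training",
                     "ctsurv_nan_loss")
      improved <- val_loss < best_val - config$plateau_min_delta
      if (improved) {
        best_val <- val_loss; best_m <- m
        plateau <- 0L; stall <- 0L
      } else {
        plateau <- plateau + 1L; stall <- stall + 1L
        if (plateau >= config$plateau_patience) {
          lr <- lr * config$lr_factor
          plateau <- 0L
        }
        if (stall >= config$early_stopping_patience) break
      }
      if (config$verbose)
        message(sprintf("fold %d epoch %3d lr %.2e train %.4f val %.4f",
                        fold, epoch, lr, mean(tr_losses), val_loss))
    }
    models[[fold]] <- best_m
  }
  structure(list(models = models, history = history, config = config,
                 n_train_effective = n_eff),
            class = "ctsurv_fit")
}

#' Rank-based ROC AUC (Mann-Whitney with midranks)
#'
#' The probability that a random positive scores above a random negative,
#' counting ties as one half -- computed from midranks, so it equals the
#' brute-force average over all (positive, negative) pairs.
#'
#' @param scores numeric scores.
#' @param labels 0/1 vector.
#' @return AUC in `[0, 1]`, or `NA` when only one class is present.
#' @export
auc_midrank <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)  # midranks for ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a fitted classifier on a test set
#'
#' Applies each fold model to the test stacks and reports per-fold test
#' loss, accuracy at the 0.5 threshold, and rank-based AUC, plus their
#' means. An AUC on a single-class test set is reported as `NA`, not 0.
#'
#' @param fit a `ctsurv_fit` (or a bare `ctsurv_model`).
#' @param stacks,labels test data.
#' @param threshold classification threshold for accuracy.
#' @return object of class `eval_result`: `per_fold` data.frame and scalar
#'   `test_loss`, `acc`, `auc` means.
#' @export
evaluate <- function(fit, stacks, labels, threshold = 0.5) {
  stacks <- lapply(stacks, function(x) if (inherits(x, "input_stack")) x$volume else x)
  models <- if (inherits(fit, "ctsurv_fit")) fit$models else list(fit)
  config <- if (inherits(fit, "ctsurv_fit")) fit$config else train_config()
  labels <- as.numeric(labels)
  rows <- lapply(seq_along(models), function(i) {
    p <- vapply(stacks, function(x) .model_fw(models[[i]], x)$prob, 0)
    data.frame(fold = i,
               test_loss = .loss_value(p, labels, config),
               acc = mean((p > threshold) == (labels == 1)),
               auc = auc_midrank(p, labels))
  })
  per_fold <- do.call(rbind, rows)
  structure(list(per_fold = per_fold,
                 test_loss = mean(per_fold$test_loss),
                 acc = mean(per_fold$acc),
                 auc = mean(per_fold$auc)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> loss %.4f  ACC %.4f  AUC %s  (%d fold model(s))\n",
              x$test_loss, x$acc,
              ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc)),
              nrow(x$per_fold)))
  invisible(x)
}

#' Run an ablation grid
#'
#' Trains and evaluates one model per grid row, holding everything but the
#' varied axis fixed (identical seeds and initial weights across cells).
#' Axes: the dataset variant (`dataset`, a name into `datasets`, covering
#' slice depth / input-crop / censoring-policy variants), the loss
#' (`loss`, plus optional `alpha`, `beta`, `p_fn`, `p_fp` columns for
#' `"pen_bce"`), and `augment`.
#'
#' @param grid data.frame; columns among `dataset`, `loss`, `alpha`, `beta`,
#'   `p_fn`, `p_fp`, `augment`.
#' @param datasets named list; each element a list with `stacks`, `labels`.
#' @param arch model architecture for every cell.
#' @param base_config a [train_config()] supplying the common recipe.
#' @param test_frac held-out fraction for the per-dataset stratified split.
#' @return data.frame: grid columns plus `test_loss`, `acc`, `auc`.
#' @export
run_ablation <- function(grid, datasets, arch = "tiny3d",
                         base_config = train_config(), test_frac = 0.15) {
  out <- NULL
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, , drop = FALSE]
    ds_name <- if ("dataset" %in% names(cell)) as.character(cell$dataset)
               else names(datasets)[1]
    ds <- datasets[[ds_name]]
    cfg <- base_config
    if ("loss" %in% names(cell)) cfg$loss <- as.character(cell$loss)
    if (cfg$loss == "pen_bce" && all(c("alpha", "beta", "p_fn", "p_fp") %in%
                                     names(cell)))
      cfg$loss_params <- loss_params(cell$alpha, cell$beta, cell$p_fn,
                                     cell$p_fp)
    if ("augment" %in% names(cell)) cfg$augment <- isTRUE(cell$augment)
    sp <- stratified_split(ds$labels, test_frac, seed = cfg$seed)
    shape <- dim(if (inherits(ds$stacks[[1]], "input_stack"))
                   ds$stacks[[1]]$volume else ds$stacks[[1]])
    model <- build_model(arch, shape, seed = cfg$seed)
    fit <- train(model, ds$stacks[sp$train_idx], ds$labels[sp$train_idx], cfg)
    ev <- evaluate(fit, ds$stacks[sp$test_idx], ds$labels[sp$test_idx])
    out <- rbind(out, cbind(cell, data.frame(
      test_loss = ev$test_loss, acc = ev$acc, auc = ev$auc,
      row.names = NULL)))
  }
  rownames(out) <- NULL
  out
}
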