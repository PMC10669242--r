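# ---------------------------------------------------------------------------
# Fine-tuning: focal losses, stratified splitting, and the repeated-split
# early-stopping protocol.
# ---------------------------------------------------------------------------

#' Focal loss for classification
#'
#' \code{-alpha * (1 - p_t)^gamma * log(p_t)} where \code{p_t} is the
#' predicted probability of the true class. With \code{alpha = 1, gamma = 0}
#' it reduces to cross-entropy.
#'
#' @param probs probability vector over T classes (softmax output), or an
#'   N x T matrix.
#' @param true_class 0-based class index (or length-N vector).
#' @param alpha,gamma focal-loss parameters.
#' @param eps clamp for \code{p_t}.
#' @return scalar loss (mean over the batch when a matrix is given).
#' @export
focal_loss_classification <- function(probs, true_class, alpha = 0.25,
                                      gamma = 2, eps = 1e-7) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  T <- ncol(probs)
  if (any(true_class < 0L) || any(true_class >= T))
    stop(sprintf("true_class must be in [0, %d)", T), call. = FALSE)
  pt <- probs[cbind(seq_len(nrow(probs)), true_class + 1L)]
  pt <- pmin(pmax(pt, eps), 1 - eps)
  mean(-alpha * (1 - pt)^gamma * log(pt))
}

#' Focal loss for segmentation
#'
#' Pixelwise focal loss averaged over all \code{H * W} positions (and the
#' batch): the mean of [focal_loss_classification()] applied at every pixel.
#'
#' @param prob_maps per-pixel class probabilities, dim \code{c(H, W, T)} or
#'   \code{c(H, W, T, N)} (channels sum to 1 at each pixel).
#' @param true_map H x W map of 0-based class indices (or \code{c(H, W, N)}).
#' @param alpha,gamma,eps as in [focal_loss_classification()].
#' @return scalar loss.
#' @export
focal_loss_segmentation <- function(prob_maps, true_map, alpha = 0.25,
                                    gamma = 2, eps = 1e-7) {
  d <- dim(prob_maps)
  if (length(d) == 3L) { dim(prob_maps) <- c(d, 1L); d <- dim(prob_maps) }
  if (length(true_map) != d[1] * d[2] * d[4])
    stop("probability maps and truth shapes do not match", call. = FALSE)
  T <- d[3]
  tm <- as.integer(true_map)
  if (any(tm < 0L) || any(tm >= T))
    stop(sprintf("true_map labels must be in [0, %d)", T), call. = FALSE)
  pm <- matrix(aperm(prob_maps, c(3, 1, 2, 4)), T)   # T x (HWN)
  pt <- pm[cbind(tm + 1L, seq_len(ncol(pm)))]
  pt <- pmin(pmax(pt, eps), 1 - eps)
  mean(-alpha * (1 - pt)^gamma * log(pt))
}

# d(focal)/d(p_t); used to seed the backward pass at the softmax output
focal_grad_pt <- function(pt, alpha, gamma, eps = 1e-7) {
  pt <- pmin(pmax(pt, eps), 1 - eps)
  -alpha * (-gamma * (1 - pt)^(gamma - 1) * log(pt) + (1 - pt)^gamma / pt)
}

# analytic focal gradient with respect to the softmax *logits*: with
# G = alpha (1-pt)^(gamma-1) (gamma pt log pt - (1-pt)), the gradient is
# -G p_j for j != t and G (1 - pt) for the true class.  Bounded for pt in
# [0, 1], so saturated predictions keep a finite restoring force (for
# alpha = 1, gamma = 0 it reduces to the familiar p - onehot).
focal_grad_logits <- function(p, true1, alpha, gamma) {
  # p: T x M probability matrix (columns are samples/pixels);
  # true1: 1-based true-class index per column
  sel <- cbind(true1, seq_len(ncol(p)))
  pt <- p[sel]
  G <- alpha * (1 - pt)^(gamma - 1) *
    (gamma * pt * log(pmax(pt, 1e-12)) - (1 - pt))
  dz <- -sweep(p, 2, G, "*")
  dz[sel] <- dz[sel] + G
  dz
}

#' Fine-tuning configuration
#'
#' @param input_resolution input side length (images are resized to it).
#' @param learning_rate SGD learning rate.
#' @param momentum,weight_decay SGD momentum and L2 coefficient.
#' @param batch_size minibatch size.
#' @param max_epochs training-epoch cap per fold.
#' @param patience early stopping: training stops once the validation loss
#'   has not reached a new minimum for this many consecutive epochs
#'   (0 stops after the first epoch).
#' @param n_folds repeated random splits, each with its own seed
#'   (\code{seed + fold - 1}).
#' @param focal_alpha,focal_gamma focal-loss parameters.
#' @param freeze_positional_encoding exclude PEG parameters from updates.
#' @param clip_norm global gradient-norm clip applied before each update
#'   (\code{Inf} disables clipping).
#' @param head_lr_multiplier learning-rate multiplier for the freshly
#'   initialised head relative to the pretrained backbone (1 trains both at
#'   the same rate; desk-scale runs with few optimisation steps benefit from
#'   a larger value).
#' @param split_ratio train/val/test fractions (must sum to 1).
#' @param seed base seed.
#' @return a named list.
#' @export
finetune_config <- function(input_resolution = 384L, learning_rate = 1e-4,
                            momentum = 0.9, weight_decay = 0,
                            batch_size = 64L, max_epochs = 200L,
                            patience = 20L, n_folds = 5L, focal_alpha = 0.25,
                            focal_gamma = 2,
                            freeze_positional_encoding = TRUE,
                            head_lr_multiplier = 1, clip_norm = 5,
                            split_ratio = c(0.6, 0.2, 0.2), seed = 1L) {
  if (abs(sum(split_ratio) - 1) > 1e-8)
    stop("split fractions must sum to 1", call. = FALSE)
  if (patience > max_epochs)
    stop("patience must not exceed max_epochs", call. = FALSE)
  if (focal_gamma < 0) stop("focal_gamma must be >= 0", call. = FALSE)
  list(input_resolution = as.integer(input_resolution),
       learning_rate = learning_rate, momentum = momentum,
       weight_decay = weight_decay, batch_size = as.integer(batch_size),
       max_epochs = as.integer(max_epochs), patience = as.integer(patience),
       n_folds = as.integer(n_folds), focal_alpha = focal_alpha,
       focal_gamma = focal_gamma,
       freeze_positional_encoding = isTRUE(freeze_positional_encoding),
       head_lr_multiplier = head_lr_multiplier, clip_norm = clip_norm,
       split_ratio = split_ratio, seed = as.integer(seed))
}

#' Stratified train/validation/test split
#'
#' Random split stratified by class at the given fractions; the three index
#' lists partition the input (disjoint, exhaustive) and are deterministic
#' given the seed.
#'
#' @param labels class label per item (any type; used for stratification).
#' @param ratio train/val/test fractions.
#' @param seed integer seed.
#' @return list of integer index vectors \code{train}, \code{val},
#'   \code{test}.
#' @export
split_dataset <- function(labels, ratio = c(0.6, 0.2, 0.2), seed = 1L) {
  if (abs(sum(ratio) - 1) > 1e-8)
    stop("split fractions must sum to 1", call. = FALSE)
  set.seed(seed)
  tr <- c(); va <- c(); te <- c()
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n <- length(idx)
    n_tr <- round(ratio[1] * n)
    n_va <- round((ratio[1] + ratio[2]) * n) - n_tr
    if (n_tr < 1L || n_va < 1L || n - n_tr - n_va < 1L)
      stop(sprintf("class '%s' has too few items (%d) for a %s split",
                   cl, n, paste(ratio, collapse = "/")), call. = FALSE)
    idx <- idx[sample.int(n)]
    tr <- c(tr, idx[seq_len(n_tr)])
    va <- c(va, idx[n_tr + seq_len(n_va)])
    te <- c(te, idx[(n_tr + n_va + 1L):n])
  }
  list(train = sort(tr), val = sort(va), test = sort(te))
}

# resize an item's image (and mask) to the configured resolution and build
# the (H, W, 3) in [0,1] input plus its target
prep_item <- function(item, res, task) {
  if (task == "cls") {
    img <- resize_for_pretraining(item$image, res)
    list(x = img / 255, y = item$label)
  } else {
    pr <- resize_for_pretraining(item$image, res, mask = item$mask)
    list(x = pr$image / 255, y = pr$mask)
  }
}

# model here outputs logits (activation stripped); probabilities are formed
# locally for losses and metrics
logits_to_probs <- function(z, task) {
  if (task == "cls") {
    e <- exp(z - apply(z, 1, max))
    e / rowSums(e)
  } else smch_fwd(z)
}

eval_loss <- function(model, prepped, idx, task, config) {
  ls <- vapply(idx, function(i) {
    it <- prepped[[i]]
    x <- array(it$x, c(dim(it$x), 1L))
    p <- logits_to_probs(nn_forward(model, x), task)
    if (task == "cls")
      focal_loss_classification(p, it$y, config$focal_alpha,
                                config$focal_gamma)
    else
      focal_loss_segmentation(p[, , , 1], it$y, config$focal_alpha,
                              config$focal_gamma)
  }, numeric(1))
  mean(ls)
}

train_one_fold <- function(model, prepped, split, task, config, fold_seed) {
  set.seed(fold_seed)
  model <- strip_output_activation(model)
  state <- list()
  freeze <- if (config$freeze_positional_encoding) "peg" else character()
  best <- list(val = Inf, model = model, epoch = 0L)
  ntr <- length(split$train)
  bs <- min(config$batch_size, ntr)
  epoch <- 0L
  while (epoch < config$max_epochs) {
    epoch <- epoch + 1L
    ord <- split$train[sample.int(ntr)]
    for (start in seq(1L, ntr, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, ntr)]
      it1 <- prepped[[idx[1]]]
      xb <- array(0, c(dim(it1$x), length(idx)))
      for (j in seq_along(idx)) xb[, , , j] <- prepped[[idx[j]]]$x
      o <- fwd(model, xb, keep = TRUE)
      if (task == "cls") {
        yb <- vapply(idx, function(i) prepped[[i]]$y, integer(1))
        p <- logits_to_probs(o$y, "cls")
        dz <- t(focal_grad_logits(t(p), yb + 1L, config$focal_alpha,
                                  config$focal_gamma)) / length(idx)
      } else {
        d <- dim(o$y)
        tm <- array(0L, c(d[1], d[2], d[4]))
        for (j in seq_along(idx)) tm[, , j] <- prepped[[idx[j]]]$y
        p <- logits_to_probs(o$y, "seg")
        pm <- matrix(aperm(p, c(3, 1, 2, 4)), d[3])
        dpm <- focal_grad_logits(pm, as.integer(tm) + 1L,
                                 config$focal_alpha, config$focal_gamma) /
          ncol(pm)
        dz <- aperm(array(dpm, c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
      }
      b <- bwd(model, o$cache, dz)
      b$grads <- clip_grads(b$grads, config$clip_norm)
      st <- sgd_step(model, b$grads, state, lr = config$learning_rate,
                     momentum = config$momentum,
                     weight_decay = config$weight_decay,
                     freeze_tags = freeze,
                     lr_scale_tags = c(head = config$head_lr_multiplier))
      model <- st$mod
      state <- st$state
    }
    vl <- eval_loss(model, prepped, split$val, task, config)
    if (!is.finite(vl)) stop("non-finite validation loss", call. = FALSE)
    if (vl < best$val) best <- list(val = vl, model = model, epoch = epoch)
    if (epoch - best$epoch >= config$patience) break
  }
  list(model = restore_output_activation(best$model), best_val = best$val,
       epochs = epoch)
}

#' Fine-tune a model under the repeated-split early-stopping protocol
#'
#' For each of \code{n_folds} seeds: split the dataset (stratified 6:2:2 by
#' default), train with SGD + momentum minimising the focal loss, stop early
#' when the validation loss has not improved for \code{patience} epochs,
#' restore the best-validation checkpoint, and evaluate on the test split
#' (accuracy for classification, mIoU for segmentation). Reports per-fold
#' results and their mean.
#'
#' @param model a task model (e.g. from [replace_head()]).
#' @param dataset a dataset from [make_downstream_dataset()], or any list
#'   with \code{items}, \code{task} ("cls"/"seg"), \code{n_classes}.
#' @param config a [finetune_config()].
#' @return list with \code{folds} (data.frame: fold, seed, epochs, best_val,
#'   test_metric) and \code{mean_metric}.
#' @export
finetune <- function(model, dataset, config = finetune_config()) {
  task <- dataset$task
  items <- dataset$items
  labels <- if (task == "cls")
    vapply(items, function(it) it$label, integer(1))
  else rep(0L, length(items))   # segmentation: unstratified random split
  prepped <- lapply(items, prep_item, res = config$input_resolution,
                    task = task)
  folds <- data.frame()
  for (fold in seq_len(config$n_folds)) {
    fold_seed <- config$seed + fold - 1L
    split <- split_dataset(labels, config$split_ratio, seed = fold_seed)
    if (length(split$val) == 0L) stop("empty validation split", call. = FALSE)
    r <- train_one_fold(model, prepped, split, task, config, fold_seed)
    metric <- if (task == "cls") {
      preds <- vapply(split$test, function(i) {
        p <- nn_forward(r$model, array(prepped[[i]]$x,
                                       c(dim(prepped[[i]]$x), 1L)))
        which.max(p[1, ]) - 1L
      }, integer(1))
      accuracy(preds, labels[split$test])
    } else {
      pm <- lapply(split$test, function(i) {
        p <- nn_forward(r$model, array(prepped[[i]]$x,
                                       c(dim(prepped[[i]]$x), 1L)))
        apply(p[, , , 1], c(1, 2), which.max) - 1L
      })
      tm <- lapply(split$test, function(i) prepped[[i]]$y)
      as.numeric(mean_iou(pm, tm, dataset$n_classes))
    }
    folds <- rbind(folds, data.frame(fold = fold, seed = fold_seed,
                                     epochs = r$epochs, best_val = r$best_val,
                                     test_metric = metric))
  }
  list(folds = folds, mean_metric = mean(folds$test_metric))
}
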