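# ---------------------------------------------------------------------------
# Response-based cross-task knowledge distillation: a frozen teacher predicts
# per-pixel nuclei probabilities on unlabeled images; thresholding gives
# binary pseudo-labels; the student (backbone + U-Net style decoder) is
# trained to reproduce them with per-pixel binary cross-entropy under LARS.
# ---------------------------------------------------------------------------

#' Threshold a probability map into a binary pseudo-label
#'
#' Entries are 1 where \code{y >= alpha} (inclusive threshold) and 0
#' elsewhere; applying the operation twice with any threshold in (0, 1] is
#' idempotent.
#'
#' @param y probability map (matrix or array), entries in \code{[0, 1]}.
#' @param alpha threshold in (0, 1).
#' @return integer 0/1 map of the same shape.
#' @export
binarize <- function(y, alpha = 0.5) {
  if (any(y < 0) || any(y > 1))
    stop("probability map entries must lie in [0, 1]", call. = FALSE)
  out <- as.integer(y >= alpha)
  dim(out) <- dim(y)
  out
}

#' Pixel-averaged binary cross-entropy distillation loss
#'
#' @param student_probs per-pixel foreground probabilities (any shape).
#' @param pseudo matching binary pseudo-label map.
#' @param eps probability clamp to avoid log(0).
#' @return scalar loss (mean over all pixels).
#' @export
kd_loss <- function(student_probs, pseudo, eps = 1e-7) {
  if (!identical(dim(student_probs), dim(pseudo)) &&
      length(student_probs) != length(pseudo))
    stop("student and pseudo-label shapes do not match", call. = FALSE)
  p <- pmin(pmax(student_probs, eps), 1 - eps)
  l <- -(pseudo * log(p) + (1 - pseudo) * log(1 - p))
  bad <- sum(!is.finite(l))
  if (bad > 0)
    stop(sprintf("non-finite loss at %d pixels", bad), call. = FALSE)
  mean(l)
}

# gradient of kd_loss with respect to the (clamped) probabilities
kd_loss_grad <- function(student_probs, pseudo, eps = 1e-7) {
  p <- pmin(pmax(student_probs, eps), 1 - eps)
  (-(pseudo / p) + (1 - pseudo) / (1 - p)) / length(p)
}

#' Mock teacher: returns the generator's ground-truth nuclei probabilities
#'
#' The teacher contract is a function from an RGB image (values in
#' \code{[0, 255]}) to an H x W probability map in \code{[0, 1]}. The mock
#' teacher reads the \code{"nuclei_prob"} attribute that the synthetic
#' generators attach to their images, standing in for a frozen external
#' nuclei-segmentation model.
#'
#' @return a teacher object: \code{list(predict = function(image) ...)}.
#' @export
teacher_mock <- function() {
  list(name = "mock",
       predict = function(image) {
         p <- attr(image, "nuclei_prob")
         if (is.null(p))
           stop("mock teacher needs images carrying a 'nuclei_prob' attribute",
                call. = FALSE)
         storage.mode(p) <- "double"
         p
       })
}

#' External-command teacher adapter
#'
#' Subprocess contract: the command is invoked as
#' \code{cmd <input.png> <output.png>}; it must write the probability map as
#' a 16-bit single-channel PNG (0..65535 mapped to \code{[0, 1]}).
#'
#' @param cmd path to the executable.
#' @return a teacher object.
#' @export
teacher_external <- function(cmd) {
  list(name = "external",
       predict = function(image) {
         fin <- tempfile(fileext = ".png")
         fout <- tempfile(fileext = ".png")
         on.exit(unlink(c(fin, fout)))
         write_image_rgb(image, fin)
         status <- system2(cmd, c(fin, fout))
         if (status != 0L || !file.exists(fout))
           stop("external teacher command failed", call. = FALSE)
         read_mask_png(fout)
       })
}

#' Distillation (pretraining) configuration
#'
#' @param threshold_alpha pseudo-label probability threshold.
#' @param input_size side length images are resized to for training.
#' @param batch_size minibatch size.
#' @param epochs,warmup_epochs total epochs and linear-warmup epochs; the
#'   global learning rate starts at \code{base_lr}, warms up linearly to
#'   \code{peak_lr}, then follows a cosine decay.
#' @param base_lr initial global learning rate (0; LARS adapts per layer).
#' @param peak_lr global learning rate reached after warmup.
#' @param trust_coefficient LARS trust coefficient.
#' @param momentum,weight_decay,epsilon LARS momentum, L2 coefficient and
#'   trust-ratio floor.
#' @param clip_norm global gradient-norm clip applied before each update.
#' @param seed integer seed controlling initialisation and shuffling.
#' @return a named list.
#' @export
distill_config <- function(threshold_alpha = 0.5, input_size = 512L,
                           batch_size = 64L, epochs = 100L,
                           warmup_epochs = 10L, base_lr = 0, peak_lr = 1,
                           trust_coefficient = 0.001, momentum = 0.9,
                           weight_decay = 1e-4, epsilon = 1e-9,
                           clip_norm = 5, seed = 1L) {
  if (!(threshold_alpha > 0 && threshold_alpha < 1))
    stop("threshold_alpha must be in (0, 1)", call. = FALSE)
  if (warmup_epochs > epochs)
    stop("warmup_epochs must not exceed epochs", call. = FALSE)
  list(threshold_alpha = threshold_alpha, input_size = as.integer(input_size),
       batch_size = as.integer(batch_size), epochs = as.integer(epochs),
       warmup_epochs = as.integer(warmup_epochs), base_lr = base_lr,
       peak_lr = peak_lr, trust_coefficient = trust_coefficient,
       momentum = momentum, weight_decay = weight_decay, epsilon = epsilon,
       clip_norm = clip_norm,
       seed = as.integer(seed))
}

# warmup + cosine schedule for the global LARS learning rate
global_lr_at <- function(epoch, config) {
  if (config$warmup_epochs > 0 && epoch <= config$warmup_epochs) {
    frac <- epoch / config$warmup_epochs
    return(config$base_lr + (config$peak_lr - config$base_lr) * frac)
  }
  rest <- max(config$epochs - config$warmup_epochs, 1L)
  t <- (epoch - config$warmup_epochs) / rest
  config$peak_lr * 0.5 * (1 + cos(pi * t))
}

#' Pretrain a student by response-based knowledge distillation
#'
#' For every unlabeled image the frozen teacher predicts a nuclei probability
#' map, which is thresholded into a binary pseudo-label (generated once;
#' the teacher is frozen, so labels are constant across epochs). Image and
#' label are resized to \code{input_size} (bilinear / nearest-neighbour) and
#' the student -- the backbone plus a U-Net style decoder with a 1-channel
#' sigmoid output -- minimises the pixel-averaged binary cross-entropy
#' against the pseudo-labels with the LARS optimiser.
#'
#' @param student_backbone a CSAT backbone from
#'   \code{build_csat(head = "none")}.
#' @param teacher a teacher object ([teacher_mock()], [teacher_external()],
#'   or any \code{list(predict = ...)}).
#' @param images list of RGB arrays \code{c(H, W, 3)} in \code{[0, 255]}.
#' @param config a [distill_config()].
#' @param seg_head optional prebuilt decoder head (a fresh one is created
#'   otherwise).
#' @return list with \code{backbone} (pretrained, head detached),
#'   \code{head}, \code{model} (the combined student), and \code{log}
#'   (data.frame: epoch, mean_loss, lr, seed).
#' @export
pretrain <- function(student_backbone, teacher, images,
                     config = distill_config(), seg_head = NULL) {
  if (length(images) == 0L) stop("empty image set", call. = FALSE)
  if (student_backbone$kind != "csat_backbone")
    stop("student_backbone must be a CSAT backbone", call. = FALSE)
  set.seed(config$seed)
  cfg <- student_backbone$cfg$config
  if (is.null(seg_head))
    seg_head <- new_unet_head(c(cfg$stem_channels, cfg$stage_channels),
                              out_channels = 1L, out_act = "sigmoid")
  model <- new_module("backbone_with_head",
                      children = list(backbone = student_backbone,
                                      head = seg_head),
                      cfg = list(head = "pretrain"))

  # offline pseudo-label generation: teacher -> threshold -> resize
  pairs <- lapply(images, function(img) {
    y <- teacher$predict(img)
    if (!identical(dim(y), dim(img)[1:2]))
      stop("teacher output shape does not match the image", call. = FALSE)
    nl <- binarize(y, config$threshold_alpha)
    resize_for_pretraining(img, config$input_size, mask = nl)
  })

  log <- data.frame(epoch = integer(), mean_loss = numeric(), lr = numeric(),
                    seed = integer())
  if (config$epochs == 0L)
    return(list(backbone = model$children$backbone, head = model$children$head,
                model = model, log = log))

  # train on logits: the BCE gradient with respect to the pre-sigmoid
  # output is (p - t)/n, bounded even at saturation
  model <- strip_output_activation(model)
  state <- list()
  n <- length(pairs)
  bs <- min(config$batch_size, n)
  for (epoch in seq_len(config$epochs)) {
    lr <- global_lr_at(epoch, config)
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      xb <- array(0, c(config$input_size, config$input_size, 3L, length(idx)))
      tb <- array(0, c(config$input_size, config$input_size, 1L, length(idx)))
      for (j in seq_along(idx)) {
        xb[, , , j] <- pairs[[idx[j]]]$image / 255
        tb[, , 1L, j] <- pairs[[idx[j]]]$mask
      }
      o <- fwd(model, xb, keep = TRUE)
      probs <- 1 / (1 + exp(-o$y))
      losses <- c(losses, kd_loss(probs, tb))
      dy <- (probs - tb) / length(probs)
      b <- bwd(model, o$cache, dy)
      b$grads <- clip_grads(b$grads, config$clip_norm)
      st <- lars_tree_step(model, b$grads, state, global_lr = lr,
                           trust_coefficient = config$trust_coefficient,
                           weight_decay = config$weight_decay,
                           momentum = config$momentum)
      model <- st$mod
      state <- st$state
    }
    log <- rbind(log, data.frame(epoch = epoch, mean_loss = mean(losses),
                                 lr = lr, seed = config$seed))
  }
  model <- restore_output_activation(model)
  list(backbone = model$children$backbone, head = model$children$head,
       model = model, log = log)
}

#' Pixel agreement between a student and the teacher's pseudo-labels
#'
#' Fraction of pixels at which the student's thresholded output equals the
#' teacher's binarized prediction, averaged over a held-out image set.
#'
#' @param model combined student model (backbone + decoder).
#' @param teacher teacher object.
#' @param images held-out RGB images.
#' @param config [distill_config()] (threshold and input size).
#' @return mean pixel agreement in \code{[0, 1]}.
#' @export
pixel_agreement <- function(model, teacher, images,
                            config = distill_config()) {
  agree <- vapply(images, function(img) {
    nl <- binarize(teacher$predict(img), config$threshold_alpha)
    pr <- resize_for_pretraining(img, config$input_size, mask = nl)
    x <- array(pr$image / 255, c(dim(pr$image), 1L))
    p <- nn_forward(model, x)
    mean((p[, , 1, 1] >= 0.5) == (pr$mask == 1))
  }, numeric(1))
  mean(agree)
}
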