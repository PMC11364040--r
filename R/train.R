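#' Training configuration
#'
#' Optimization hyperparameters of the self-supervised training loop:
#' Adam with `beta1 = 0.9`, `beta2 = 0.999`, `epsilon = 1e-8`, an
#' initial learning rate of 3e-4 decayed by a factor 0.7 every ten
#' epochs (staircase), 195 epochs, batch size 6.
#'
#' @param lr0 initial learning rate.
#' @param beta1,beta2,epsilon Adam moment decays and stabilizer.
#' @param decay staircase decay factor applied every `decay_every`
#'   epochs.
#' @param decay_every epochs between decay steps.
#' @param epochs number of training epochs.
#' @param batch patches per optimization step.
#' @param seed RNG seed governing every shuffle of the loop.
#' @param checkpoint_every epochs between saved checkpoints (when a
#'   checkpoint directory is given); 0 disables periodic checkpoints.
#' @param select_best if `TRUE`, return the checkpoint with the lowest
#'   evaluation loss instead of the final epoch. Off by default: the
#'   model is not tuned on held-out data, the evaluation curve is for
#'   monitoring only.
#' @return A `train_config`.
#' @export
train_config <- function(lr0 = 3e-4, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, decay = 0.7, decay_every = 10L,
                         epochs = 195L, batch = 6L, seed = 1L,
                         checkpoint_every = 1L, select_best = FALSE) {
  stopifnot(lr0 > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            epsilon > 0, decay > 0, decay <= 1, decay_every >= 1,
            epochs >= 1, batch >= 1)
  structure(
    list(lr0 = lr0, beta1 = beta1, beta2 = beta2, epsilon = epsilon,
         decay = decay, decay_every = as.integer(decay_every),
         epochs = as.integer(epochs), batch = as.integer(batch),
         seed = as.integer(seed),
         checkpoint_every = as.integer(checkpoint_every),
         select_best = isTRUE(select_best)),
    class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Staircase exponential schedule:
#' `lr0 * decay^floor(epoch / decay_every)`, with `epoch` counted from
#' 0.
#'
#' @param cfg a [train_config()].
#' @param epoch 0-based epoch index.
#' @return The learning rate.
#' @examples
#' lr_at_epoch(train_config(), 0)   # 3e-4
#' lr_at_epoch(train_config(), 10)  # 2.1e-4
#' @export
lr_at_epoch <- function(cfg, epoch) {
  if (any(epoch < 0)) stop("`epoch` must be >= 0")
  cfg$lr0 * cfg$decay^floor(epoch / cfg$decay_every)
}

# the per-patch training objective and its gradient wrt the network
# output: Cref loss on (half-map average -> denoised) with per-patch
# FSC_half
patch_loss_grad <- function(d, pair, p, grad = TRUE) {
  avg <- (pair$p1 + pair$p2) / 2
  fw <- unet_forward(d, avg, keep_cache = grad)
  vs <- pair$voxel_size %||% 1
  ha <- volume_grid(pair$p1, vs); hb <- volume_grid(pair$p2, vs)
  mean_v <- volume_grid(avg, vs)
  den_v <- volume_grid(fw$y, vs)
  loss <- cref_loss(mean_v, den_v, ha, hb, p, grad = grad)
  list(loss = as.numeric(loss), grad = attr(loss, "gradient"),
       cache = fw$cache)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train the denoiser on a patch dataset
#'
#' Self-supervised training: for every patch pair the network input is
#' the half-map average, and the loss drives the FSC between that input
#' and the network output toward the Cref curve computed from the
#' patch's half-map FSC. No clean target is involved anywhere. A batch's
#' loss is the arithmetic mean of per-patch losses; Adam updates use the
#' staircase schedule of [lr_at_epoch()]. Every shuffle is derived from
#' `tcfg$seed`, so repeated runs produce identical histories.
#'
#' @param dataset list of `patch_pair`s (see [tile_patches()]); patch
#'   edge must be a multiple of `2^depth`.
#' @param dcfg a [denoiser_config()].
#' @param tcfg a [train_config()].
#' @param eval_dataset optional held-out patch pairs; their mean loss is
#'   recorded per epoch (monitoring only, unless
#'   `tcfg$select_best`).
#' @param checkpoint_dir optional directory for periodic checkpoints.
#' @param verbose emit a per-epoch summary to stderr.
#' @return List with `denoiser` (trained), `history` (data.frame:
#'   `epoch`, `lr`, `train_loss`, `eval_loss`, `checkpoint`), and
#'   `final`/`best` checkpoint paths when `checkpoint_dir` is set.
#' @export
train_denoiser <- function(dataset, dcfg = denoiser_config(),
                           tcfg = train_config(), eval_dataset = NULL,
                           checkpoint_dir = NULL, verbose = FALSE) {
  if (length(dataset) == 0L) stop("empty training dataset")
  edge <- dim(dataset[[1]]$p1)[1]
  if (edge %% 2L^dcfg$depth != 0L)
    stop("patch edge ", edge, " is not a multiple of 2^depth = ",
         2L^dcfg$depth)
  vs <- dataset[[1]]$voxel_size %||% 1
  p <- build_shell_partition(rep(edge, 3L), vs)
  d <- build_denoiser(dcfg)
  adam_m <- lapply(d$params, function(x) array(0, dim(x) %||% length(x)))
  adam_v <- adam_m
  t_step <- 0L
  n <- length(dataset)
  hist <- data.frame(epoch = integer(0), lr = numeric(0),
                     train_loss = numeric(0), eval_loss = numeric(0),
                     checkpoint = character(0))
  best <- list(loss = Inf, path = NA_character_)
  if (!is.null(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)

  for (epoch in seq_len(tcfg$epochs) - 1L) {
    lr <- lr_at_epoch(tcfg, epoch)
    withr_seed(tcfg$seed + epoch, ord <- sample(n))
    losses <- numeric(0)
    for (start in seq.int(1L, n, by = tcfg$batch)) {
      idx <- ord[seq.int(start, min(start + tcfg$batch - 1L, n))]
      gsum <- NULL
      bl <- 0
      for (i in idx) {
        lg <- patch_loss_grad(d, dataset[[i]], p)
        if (!is.finite(lg$loss))
          stop(sprintf(
            "non-finite loss at epoch %d, patch %d: aborting", epoch, i))
        bl <- bl + lg$loss
        gparams <- unet_backward(d, lg$cache, lg$grad)
        gsum <- if (is.null(gsum)) gparams
                else mapply(`+`, gsum, gparams, SIMPLIFY = FALSE)
      }
      nb <- length(idx)
      losses <- c(losses, bl / nb)
      t_step <- t_step + 1L
      for (nm in names(d$params)) {
        g <- gsum[[nm]] / nb
        adam_m[[nm]] <- tcfg$beta1 * adam_m[[nm]] + (1 - tcfg$beta1) * g
        adam_v[[nm]] <- tcfg$beta2 * adam_v[[nm]] + (1 - tcfg$beta2) * g^2
        mhat <- adam_m[[nm]] / (1 - tcfg$beta1^t_step)
        vhat <- adam_v[[nm]] / (1 - tcfg$beta2^t_step)
        d$params[[nm]] <- d$params[[nm]] -
          lr * mhat / (sqrt(vhat) + tcfg$epsilon)
      }
    }
    eval_loss <- NA_real_
    if (!is.null(eval_dataset) && length(eval_dataset))
      eval_loss <- mean(vapply(eval_dataset, function(pp)
        patch_loss_grad(d, pp, p, grad = FALSE)$loss, numeric(1)))
    ck <- NA_character_
    if (!is.null(checkpoint_dir) && tcfg$checkpoint_every > 0L &&
        ((epoch + 1L) %% tcfg$checkpoint_every == 0L ||
         epoch == tcfg$epochs - 1L)) {
      ck <- file.path(checkpoint_dir, sprintf("epoch_%03d.rds", epoch))
      save_checkpoint(d, ck, meta = list(epoch = epoch, lr = lr,
                                         train_loss = mean(losses),
                                         eval_loss = eval_loss))
      if (is.finite(eval_loss) && eval_loss < best$loss)
        best <- list(loss = eval_loss, path = ck)
    }
    hist <- rbind(hist, data.frame(
      epoch = epoch, lr = lr, train_loss = mean(losses),
      eval_loss = eval_loss, checkpoint = ck))
    if (verbose)
      message(sprintf("epoch %3d  lr %.3g  train %.5f  eval %s",
                      epoch, lr, mean(losses),
                      ifelse(is.na(eval_loss), "-",
                             sprintf("%.5f", eval_loss))))
  }
  out <- list(denoiser = d, history = hist)
  if (!is.null(checkpoint_dir)) {
    out$final <- hist$checkpoint[nrow(hist)]
    out$best <- best$path
    if (tcfg$select_best && !is.na(best$path))
      out$denoiser <- load_checkpoint(best$path)
  }
  out
}

#' Write a training history as TSV
#' @param history the `history` data.frame from [train_denoiser()].
#' @param path output path.
#' @export
write_history_tsv <- function(history, path) {
  utils::write.table(history, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
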