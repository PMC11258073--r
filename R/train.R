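#' Training configuration for the segmentation U-Net
#'
#' Defaults encode the training schedule the pipeline uses: initial
#' learning rate 1e-4, halved (factor 0.5) when the validation loss has not
#' decreased for 5 epochs, early stop after 10 epochs without decrease,
#' cross-entropy loss with an ignore label, Nadam optimizer, L2 weight
#' regularization 1e-3 and dropout 0.5 before the last two convolution
#' layers. An epoch is `iterations_per_epoch` gradient steps (20,000 at
#' full scale; 200 in the toy preset); every `hardmine_every_epochs` the
#' model is run over the entire training set to re-weight patch sampling
#' toward high-loss regions (500 at full scale; 5 in the toy preset).
#'
#' @param initial_lr,lr_factor,lr_patience_epochs,stop_patience_epochs
#'   learning-rate schedule; `0 < lr_factor < 1`, patiences >= 1.
#' @param iterations_per_epoch gradient steps per epoch.
#' @param hardmine_every_epochs period of hard-example mining.
#' @param l2_weight L2 regularization factor on convolution weights.
#' @param dropout_rate dropout probability in `[0, 1)`.
#' @param patch_size (z, y, x) patch extents, each divisible by
#'   `2^(levels - 1)`.
#' @param batch_size patches per gradient step.
#' @param levels,width U-Net depth and base channel width.
#' @param max_epochs hard cap on epochs (early stopping usually fires
#'   first).
#' @param spacing working grid the model expects volumes on.
#' @param aorta_distance_cutoff_mm label preprocessing: LM/RCA voxels
#'   farther than this from the aorta are ignored during training.
#' @param seed RNG seed controlling initialization and sampling.
#' @return A `training_config`.
#' @export
training_config <- function(initial_lr = 1e-4, lr_factor = 0.5,
                            lr_patience_epochs = 5L,
                            stop_patience_epochs = 10L,
                            iterations_per_epoch = 20000L,
                            hardmine_every_epochs = 500L,
                            l2_weight = 1e-3, dropout_rate = 0.5,
                            patch_size = c(16L, 24L, 24L),
                            batch_size = 2L, levels = 4L, width = 32L,
                            max_epochs = 1500L,
                            spacing = c(0.9, 0.66, 0.66),
                            aorta_distance_cutoff_mm = 20,
                            seed = 1L) {
  stopifnot(lr_patience_epochs >= 1L, stop_patience_epochs >= 1L,
            lr_factor > 0, lr_factor < 1,
            dropout_rate >= 0, dropout_rate < 1,
            initial_lr > 0, batch_size >= 1L, iterations_per_epoch >= 1L)
  if (any(patch_size %% 2^(levels - 1L) != 0))
    stop("patch_size extents must be divisible by 2^(levels - 1)")
  structure(list(initial_lr = initial_lr, lr_factor = lr_factor,
                 lr_patience_epochs = as.integer(lr_patience_epochs),
                 stop_patience_epochs = as.integer(stop_patience_epochs),
                 iterations_per_epoch = as.integer(iterations_per_epoch),
                 hardmine_every_epochs = as.integer(hardmine_every_epochs),
                 l2_weight = l2_weight, dropout_rate = dropout_rate,
                 patch_size = as.integer(patch_size),
                 batch_size = as.integer(batch_size),
                 levels = as.integer(levels), width = as.integer(width),
                 max_epochs = as.integer(max_epochs),
                 spacing = spacing,
                 aorta_distance_cutoff_mm = aorta_distance_cutoff_mm,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' @rdname training_config
#' @param ... overrides of the toy preset.
#' @export
toy_training_config <- function(...) {
  base <- list(iterations_per_epoch = 200L, hardmine_every_epochs = 5L,
               levels = 3L, width = 8L, patch_size = c(16L, 24L, 24L),
               batch_size = 2L, max_epochs = 2L, initial_lr = 1e-3)
  do.call(training_config, utils::modifyList(base, list(...)))
}

#' Validation-loss driven learning-rate schedule
#'
#' Tracks the best (strictly smallest) validation loss seen so far. After
#' an epoch without a strict decrease, both patience counters advance; at
#' `lr_patience` epochs without improvement the learning rate is multiplied
#' by `lr_factor` (and the LR counter resets), and at `stop_patience`
#' epochs without improvement training stops. Exposed as a pure state
#' machine so the schedule is testable with injected loss sequences.
#'
#' @param initial_lr,lr_factor,lr_patience,stop_patience schedule
#'   parameters.
#' @return A `scheduler_state`; advance it with [scheduler_step()].
#' @export
scheduler_init <- function(initial_lr, lr_factor = 0.5, lr_patience = 5L,
                           stop_patience = 10L) {
  structure(list(lr = initial_lr, lr_factor = lr_factor,
                 lr_patience = lr_patience, stop_patience = stop_patience,
                 best = Inf, since_best = 0L, since_lr_drop = 0L,
                 stop = FALSE),
            class = "scheduler_state")
}

#' @rdname scheduler_init
#' @param state a `scheduler_state`.
#' @param val_loss the epoch's validation loss.
#' @export
scheduler_step <- function(state, val_loss) {
  if (val_loss < state$best) {
    state$best <- val_loss
    state$since_best <- 0L
    state$since_lr_drop <- 0L
  } else {
    state$since_best <- state$since_best + 1L
    state$since_lr_drop <- state$since_lr_drop + 1L
    if (state$since_lr_drop >= state$lr_patience) {
      state$lr <- state$lr * state$lr_factor
      state$since_lr_drop <- 0L
    }
    if (state$since_best >= state$stop_patience) state$stop <- TRUE
  }
  state
}

# --- Nadam (Adam with Nesterov momentum) ------------------------------------
nadam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

nadam_step <- function(params, grads, state, lr) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    upd <- (b1 * mhat + (1 - b1) * g / bc1) / (sqrt(vhat) + state$eps)
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

# fixed affine intensity normalization: keeps absolute HU information
# (unlike per-patch standardization) while conditioning the optimizer
normalize_hu <- function(values) (values - 200) / 300

# sample one patch (input + labels) from a prepared training case
sample_patch_from_case <- function(case, patch, center_lin = NULL) {
  d <- dim(case$values)
  if (is.null(center_lin)) {
    # foreground-biased: half the draws center on a random labelled voxel
    if (length(case$fg_idx) && runif(1) < 0.5) {
      center_lin <- case$fg_idx[sample.int(length(case$fg_idx), 1L)]
    } else {
      center_lin <- sample.int(prod(d), 1L)
    }
  }
  cz <- arrayInd(center_lin, d)
  lo <- pmin(pmax(as.integer(cz) - patch %/% 2L, 1L), d - patch + 1L)
  hi <- lo + patch - 1L
  list(x = array(case$values_norm[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]],
                 dim = c(patch, 1L)),
       lab = case$labels_pp[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])
}

prepare_case <- function(phantom, config) {
  mask_pp <- preprocess_labels(phantom$labels,
                               config$aorta_distance_cutoff_mm)
  values <- phantom$volume$values
  list(values = values, values_norm = normalize_hu(values),
       labels = phantom$labels$labels, labels_pp = mask_pp$labels,
       spacing = phantom$labels$spacing,
       fg_idx = which(phantom$labels$labels != 0L),
       loss_cum = NULL, case_weight = 1)
}

#' Train the segmentation U-Net on phantoms
#'
#' Runs the configured schedule: per-epoch validation loss drives learning
#' rate halving and early stopping; every `hardmine_every_epochs` epochs
#' per-voxel cross-entropy over the whole training set re-weights patch
#' sampling (cases drawn proportional to mean loss, patch centers within a
#' case proportional to voxel loss); the checkpoint with the highest
#' aorta-class validation Dice is returned. Fully deterministic given the
#' config seed.
#'
#' @param phantoms_train,phantoms_val disjoint non-empty lists of
#'   `ct_phantom` on the working grid.
#' @param config a [training_config()].
#' @param verbose print a per-epoch progress line.
#' @param init optional `trained_unet` whose weights warm-start this run
#'   (optimizer and schedule state start fresh); used by the CLI's
#'   `--resume`.
#' @param epoch_offset first logged epoch is `epoch_offset + 1`, so a
#'   resumed run continues the previous numbering.
#' @return A `trained_unet`: `net` (best checkpoint), `config`,
#'   `best_val_dice` (per class and mean), `training_log` (data.frame:
#'   epoch, train_loss, val_loss, val_dice_aorta, val_dice_mean, lr).
#' @export
train_unet <- function(phantoms_train, phantoms_val, config = toy_training_config(),
                       verbose = FALSE, init = NULL, epoch_offset = 0L) {
  stopifnot(length(phantoms_train) >= 1L, length(phantoms_val) >= 1L)
  set.seed(config$seed)
  net <- unet_init(config$levels, config$width, 4L, seed = config$seed)
  if (!is.null(init)) {
    stopifnot(inherits(init, "trained_unet"))
    if (!identical(lapply(init$net$params, dim), lapply(net$params, dim)))
      stop("checkpoint architecture does not match the configured network")
    net$params <- init$net$params
  }
  opt <- nadam_init(net$params)
  sched <- scheduler_init(config$initial_lr, config$lr_factor,
                          config$lr_patience_epochs,
                          config$stop_patience_epochs)
  train_cases <- lapply(phantoms_train, prepare_case, config = config)
  val_cases <- lapply(phantoms_val, prepare_case, config = config)
  weight_decay_names <- grep("_W$", names(net$params), value = TRUE)

  log <- list()
  best <- list(dice_aorta = -Inf, params = net$params, dice = NULL)
  case_weights <- rep(1, length(train_cases))

  for (epoch in seq_len(config$max_epochs)) {
    if (epoch > 1L && (epoch - 1L) %% config$hardmine_every_epochs == 0L) {
      hm <- hardmine_weights(net, train_cases, config)
      train_cases <- hm$cases
      case_weights <- hm$case_weights
    }
    epoch_loss <- 0
    for (it in seq_len(config$iterations_per_epoch)) {
      grads_acc <- NULL
      loss_acc <- 0
      for (b in seq_len(config$batch_size)) {
        ci <- sample.int(length(train_cases), 1L,
                         prob = case_weights)
        case <- train_cases[[ci]]
        center <- if (is.null(case$loss_cum)) NULL else {
          u <- runif(1) * case$loss_cum[length(case$loss_cum)]
          findInterval(u, case$loss_cum) + 1L
        }
        pt <- sample_patch_from_case(case, config$patch_size, center)
        fwd <- unet_forward(net, pt$x, train = TRUE,
                            dropout_rate = config$dropout_rate)
        ce <- softmax_ce_ignore(fwd$logits, pt$lab, want_grad = TRUE)
        g <- unet_backward(net, fwd$cache, ce$dlogits)
        loss_acc <- loss_acc + ce$loss
        grads_acc <- if (is.null(grads_acc)) g
                     else mapply(`+`, grads_acc, g, SIMPLIFY = FALSE)
      }
      grads_acc <- lapply(grads_acc, `/`, config$batch_size)
      for (nm in weight_decay_names)
        grads_acc[[nm]] <- grads_acc[[nm]] +
          config$l2_weight * net$params[[nm]]
      if (!all(vapply(grads_acc, function(g) all(is.finite(g)), TRUE)))
        stop("training diverged: non-finite gradients at epoch ", epoch,
             ", iteration ", it)
      st <- nadam_step(net$params, grads_acc, opt, sched$lr)
      net$params <- st$params
      opt <- st$state
      epoch_loss <- epoch_loss + loss_acc / config$batch_size
    }
    train_loss <- epoch_loss / config$iterations_per_epoch
    if (!is.finite(train_loss))
      stop("training diverged: non-finite loss at epoch ", epoch)

    ev <- evaluate_on_cases(net, val_cases, config)
    lr_in_effect <- sched$lr
    sched <- scheduler_step(sched, ev$loss)
    log[[epoch]] <- data.frame(epoch = epoch + epoch_offset,
                               train_loss = train_loss,
                               val_loss = ev$loss,
                               val_dice_aorta = ev$dice[["aorta"]],
                               val_dice_mean = mean(ev$dice),
                               lr = sched$lr)
    if (verbose)
      message(sprintf(
        "epoch %3d  train %.4f  val %.4f  dice(aorta) %.3f  lr %.2e",
        epoch, train_loss, ev$loss, ev$dice[["aorta"]], sched$lr))
    if (ev$dice[["aorta"]] > best$dice_aorta) {
      best$dice_aorta <- ev$dice[["aorta"]]
      best$params <- net$params
      best$dice <- ev$dice
    }
    if (sched$stop) break
  }
  net$params <- best$params
  structure(list(net = net, config = config,
                 best_val_dice = c(best$dice,
                                   mean = mean(best$dice)),
                 training_log = do.call(rbind, log)),
            class = "trained_unet")
}

# validation loss + per-class Dice via full sliding-window inference
evaluate_on_cases <- function(net, cases, config) {
  total_loss <- 0; total_n <- 0
  inter <- setNames(numeric(3), c("aorta", "lm", "rca"))
  sizes <- inter
  for (case in cases) {
    logits <- sw_logits(net, case$values_norm, config$patch_size,
                        overlap = 0)
    ce <- softmax_ce_ignore(logits, case$labels_pp)
    total_loss <- total_loss + ce$loss * ce$n_valid
    total_n <- total_n + ce$n_valid
    pred <- argmax_labels(logits)
    for (cls in names(inter)) {
      code <- label_codes[[cls]]
      inter[cls] <- inter[cls] + sum(pred == code & case$labels == code)
      sizes[cls] <- sizes[cls] + sum(pred == code) +
        sum(case$labels == code)
    }
  }
  dice <- ifelse(sizes > 0, 2 * inter / sizes, 1)
  names(dice) <- names(inter)
  list(loss = total_loss / max(total_n, 1L), dice = dice)
}

hardmine_weights <- function(net, cases, config) {
  case_weights <- numeric(length(cases))
  for (i in seq_along(cases)) {
    logits <- sw_logits(net, cases[[i]]$values_norm, config$patch_size,
                        overlap = 0)
    vl <- voxel_ce(logits, cases[[i]]$labels_pp)
    case_weights[i] <- mean(vl[cases[[i]]$labels_pp != 255L])
    cases[[i]]$loss_cum <- cumsum(as.numeric(vl) + 1e-8)
  }
  if (all(case_weights <= 0)) case_weights[] <- 1
  list(cases = cases, case_weights = case_weights)
}

# per-voxel cross entropy (0 at ignored voxels)
voxel_ce <- function(logits, labels) {
  C <- dim(logits)[4]
  m <- matrix(logits, ncol = C)
  mx <- do.call(pmax, lapply(seq_len(C), function(j) m[, j]))
  lse <- mx + log(rowSums(exp(m - mx)))
  lab <- as.vector(labels)
  out <- numeric(length(lab))
  valid <- lab != 255L
  idx <- cbind(which(valid), lab[valid] + 1L)
  out[valid] <- lse[valid] - m[idx]
  array(out, dim = dim(labels))
}

#' @export
print.trained_unet <- function(x, ...) {
  cat(sprintf("<trained_unet> %d levels, width %d; best val Dice (aorta) %.3f over %d epochs\n",
              x$net$meta$levels, x$net$meta$width,
              x$best_val_dice[["aorta"]], nrow(x$training_log)))
  invisible(x)
}

#' Save / load a trained model as a portable JSON checkpoint
#'
#' Weights and the config snapshot are serialized as plain JSON (text
#' format; adequate at toy scale and free of binary-compatibility issues).
#'
#' @param model a `trained_unet`.
#' @param path file path (`.json`).
#' @export
save_model <- function(model, path) {
  payload <- list(
    meta = model$net$meta,
    config = unclass(model$config),
    best_val_dice = as.list(model$best_val_dice),
    training_log = model$training_log,
    params = lapply(model$net$params, function(p)
      list(dim = dim(p) %||% length(p), data = as.numeric(p))))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(payload$params, function(p) {
    if (length(p$dim) > 1L) array(p$data, dim = p$dim) else p$data
  })
  cfg <- payload$config
  config <- do.call(training_config, cfg[names(cfg) %in%
                                           names(formals(training_config))])
  net <- structure(list(meta = payload$meta, params = params),
                   class = "unet_params")
  structure(list(net = net, config = config,
                 best_val_dice = unlist(payload$best_val_dice),
                 training_log = payload$training_log),
            class = "trained_unet")
}
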