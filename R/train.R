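#' Random rotation augmentation
#'
#' With probability `prob`, rotates the volume about one randomly chosen
#' axis by an angle drawn uniformly from `[-max_angle, +max_angle]` degrees
#' (trilinear interpolation, zero background); otherwise returns the input
#' unchanged.  Draws from the current R RNG state.
#'
#' @param vol A `volume3d`.
#' @param prob Probability of applying a rotation.
#' @param max_angle Maximum rotation magnitude in degrees.
#' @return A `volume3d`.
#' @export
augment_rotate <- function(vol, prob = 0.5, max_angle = 15) {
  if (prob <= 0 || runif(1) >= prob) return(vol)
  axis <- sample.int(3L, 1L)
  angle <- runif(1, -max_angle, max_angle)
  rot <- c(0, 0, 0)
  rot[axis] <- angle
  resample(vol, rigid_transform(rotations = rot))
}

#' Training configuration
#'
#' Defaults follow the study protocol: batch size 16, initial learning rate
#' 0.01, Adam, binary cross-entropy, learning rate reduced by a factor of
#' 0.1 after five epochs without validation-loss improvement, 50 epochs,
#' and on-the-fly rotation augmentation of half the scans by up to 15
#' degrees.
#'
#' @param batch_size Mini-batch size.
#' @param lr0 Initial learning rate.
#' @param epochs Number of epochs.
#' @param plateau_factor Multiplicative learning-rate decay on plateau.
#' @param plateau_patience Stagnant epochs before decay.
#' @param aug_prob Probability a training scan is rotated.
#' @param aug_max_angle Maximum augmentation rotation (degrees).
#' @param seed Integer seed for shuffling, dropout and augmentation.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 16L, lr0 = 0.01, epochs = 50L,
                         plateau_factor = 0.1, plateau_patience = 5L,
                         aug_prob = 0.5, aug_max_angle = 15, seed = 1L) {
  stopifnot(batch_size >= 1, lr0 > 0, epochs >= 1, plateau_factor > 0,
            plateau_patience >= 1, aug_prob >= 0, aug_prob <= 1,
            aug_max_angle >= 0)
  structure(list(batch_size = as.integer(batch_size), lr0 = lr0,
                 epochs = as.integer(epochs), plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 aug_prob = aug_prob, aug_max_angle = aug_max_angle,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Reduce-on-plateau learning-rate schedule (min mode, no cooldown, no lower
# bound): after `patience` consecutive epochs without validation-loss
# improvement the rate is multiplied by `factor` and the stagnation counter
# resets.
plateau_state <- function(lr0, factor, patience) {
  list(lr = lr0, best = Inf, stagnant = 0L, factor = factor,
       patience = as.integer(patience))
}

plateau_update <- function(st, val_loss) {
  if (val_loss < st$best - 1e-12) {
    st$best <- val_loss
    st$stagnant <- 0L
  } else {
    st$stagnant <- st$stagnant + 1L
    if (st$stagnant >= st$patience) {
      st$lr <- st$lr * st$factor
      st$stagnant <- 0L
    }
  }
  st
}

# flatten/unflatten the parameter structure for the Adam update
param_leaves <- function(p) {
  leaves <- list()
  for (i in 1:6)
    for (nm in c("W", "b", "gamma", "beta"))
      leaves[[sprintf("b%d.%s", i, nm)]] <- p$blocks[[i]][[nm]]
  leaves[["out.W"]] <- p$out$W
  leaves[["out.b"]] <- p$out$b
  leaves
}

set_param_leaves <- function(p, leaves) {
  for (i in 1:6)
    for (nm in c("W", "b", "gamma", "beta"))
      p$blocks[[i]][[nm]] <- leaves[[sprintf("b%d.%s", i, nm)]]
  p$out$W <- leaves[["out.W"]]
  p$out$b <- leaves[["out.b"]]
  p
}

#' Train the SFCN sex classifier
#'
#' Adam with binary cross-entropy on the single sigmoid output (Male = 1),
#' on-the-fly rotation augmentation, and a reduce-on-plateau learning-rate
#' schedule (min mode on validation loss, no cooldown, no lower bound).  The
#' returned weights are those of the epoch with the lowest validation loss.
#'
#' @param model An initialized `sfcn_model`.
#' @param train_vols,val_vols Lists of volumes.
#' @param train_labels,val_labels 0/1 labels (1 = Male).
#' @param cfg A `train_config`.
#' @param verbose Print per-epoch progress.
#' @return An `sfcn_trained`: `model` (best weights), `history` (per-epoch
#'   train/val loss and learning rate), `selected_epoch`.
#' @export
train_sfcn <- function(model, train_vols, train_labels, val_vols, val_labels,
                       cfg = train_config(), verbose = FALSE) {
  stopifnot(length(train_vols) == length(train_labels),
            length(val_vols) == length(val_labels),
            length(train_vols) > 0, length(val_vols) > 0)
  if (length(unique(train_labels)) < 2L)
    stop("training set must contain both classes")
  set.seed(derive_seed(cfg$seed, "train"))
  n <- length(train_vols)
  sched <- plateau_state(cfg$lr0, cfg$plateau_factor, cfg$plateau_patience)
  adam <- list(m = NULL, v = NULL, t = 0L)
  best_val <- Inf; best_params <- model$params; best_epoch <- NA_integer_
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), lr = numeric(0))
  val_loss_of <- function() {
    tot <- 0; i <- 1L; nv <- length(val_vols)
    while (i <= nv) {
      j <- min(i + cfg$batch_size - 1L, nv)
      fw <- sfcn_forward(model, batch_matrix(val_vols[i:j]), j - i + 1L,
                         training = FALSE)
      tot <- tot + bce_with_logits(fw$logits, val_labels[i:j]) * (j - i + 1L)
      i <- j + 1L
    }
    tot / nv
  }
  for (epoch in seq_len(cfg$epochs)) {
    lr <- sched$lr
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    i <- 1L
    while (i <= n) {
      j <- min(i + cfg$batch_size - 1L, n)
      ix <- ord[i:j]
      B <- length(ix)
      vols <- lapply(train_vols[ix], augment_rotate,
                     prob = cfg$aug_prob, max_angle = cfg$aug_max_angle)
      X <- batch_matrix(vols)
      fw <- sfcn_forward(model, X, B, training = TRUE, keep_cache = TRUE)
      model$params <- fw$params  # batch-norm running stats
      y <- train_labels[ix]
      loss <- bce_with_logits(fw$logits, y)
      dlogit <- (stats::plogis(fw$logits) - y) / B
      bw <- sfcn_backward(model, fw$cache, dlogit, training = TRUE)
      upd <- adam_step(param_leaves(model$params), param_leaves(bw$grads),
                       adam, lr)
      adam <- upd$state
      model$params <- set_param_leaves(model$params, upd$leaves)
      ep_loss <- ep_loss + loss; nb <- nb + 1L
      i <- j + 1L
    }
    vl <- val_loss_of()
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                   val_loss = vl, lr = lr))
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f lr %g",
                      epoch, ep_loss / nb, vl, lr))
    if (vl < best_val - 1e-12) {
      best_val <- vl; best_params <- model$params; best_epoch <- epoch
    }
    sched <- plateau_update(sched, vl)
  }
  model$params <- best_params
  structure(list(model = model, history = hist, selected_epoch = best_epoch),
            class = "sfcn_trained")
}

adam_step <- function(leaves, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.null(state$m)) {
    state$m <- lapply(leaves, function(x) x * 0)
    state$v <- lapply(leaves, function(x) x * 0)
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(leaves)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    leaves[[nm]] <- leaves[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(leaves = leaves, state = state)
}
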