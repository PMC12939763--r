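#' Training configuration
#'
#' Defaults follow the study protocol: batch size 16, Adam with initial
#' learning rate 1e-3 and L2 weight decay 1e-4, cosine annealing over 150
#' epochs, early stopping with patience 20 on the validation loss, fixed
#' seed 42, and a combined loss `lambda_seg * Dice + lambda_cls *
#' cross-entropy` with unit weights.
#'
#' @param batch_size samples per optimization step.
#' @param lr_init initial learning rate.
#' @param epochs maximum training epochs (cosine period).
#' @param lr_min final learning rate of the cosine schedule.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping.
#' @param weight_decay L2 coefficient added to the gradients.
#' @param seed RNG seed controlling shuffling, dropout and augmentation.
#' @param lambda_seg,lambda_cls loss weights.
#' @param folds cross-validation folds.
#' @param augment apply random affine augmentation to training samples.
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 16L, lr_init = 1e-3, epochs = 150L,
                         lr_min = 1e-6, early_stop_patience = 20L,
                         weight_decay = 1e-4, seed = 42L,
                         lambda_seg = 1, lambda_cls = 1, folds = 5L,
                         augment = FALSE) {
  stopifnot(batch_size >= 1, lr_init > 0, epochs >= 1,
            early_stop_patience >= 1, folds >= 2)
  structure(list(batch_size = as.integer(batch_size), lr_init = lr_init,
                 epochs = as.integer(epochs), lr_min = lr_min,
                 early_stop_patience = as.integer(early_stop_patience),
                 weight_decay = weight_decay, seed = as.integer(seed),
                 lambda_seg = lambda_seg, lambda_cls = lambda_cls,
                 folds = as.integer(folds), augment = isTRUE(augment)),
            class = "train_config")
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(pred * target) + smooth) / (sum(pred) + sum(target) +
#' smooth)`, pooled over all pixels and batch elements.
#'
#' @param pred_prob predicted mask probabilities in `[0, 1]`.
#' @param target binary target mask of the same shape.
#' @param smooth smoothing constant protecting empty masks.
#' @return scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred_prob, target, smooth = 1) {
  if (!identical(dim(pred_prob) %||% length(pred_prob),
                 dim(target) %||% length(target))) {
    stop("pred_prob and target shapes differ")
  }
  inter <- sum(pred_prob * target)
  1 - (2 * inter + smooth) / (sum(pred_prob) + sum(target) + smooth)
}

# gradient of dice_loss w.r.t. pred_prob
dice_loss_grad <- function(pred_prob, target, smooth = 1) {
  inter <- sum(pred_prob * target)
  denom <- sum(pred_prob) + sum(target) + smooth
  num <- 2 * inter + smooth
  -(2 * target * denom - num) / denom^2
}

# softmax cross-entropy on (2, N) logits; y in {1, 2} (2 = positive class)
softmax_ce <- function(logits, y) {
  zx <- sweep(logits, 2, apply(logits, 2, max))
  p <- exp(zx)
  p <- sweep(p, 2, colSums(p), "/")
  n <- ncol(logits)
  loss <- -mean(log(pmax(p[cbind(y, seq_len(n))], 1e-12)))
  grad <- p
  grad[cbind(y, seq_len(n))] <- grad[cbind(y, seq_len(n))] - 1
  list(loss = loss, grad = grad / n, prob = p)
}

#' Per-group train/validation/test split
#'
#' Within each group: `n_train = round(f_train * n)`,
#' `n_test = floor(f_test * n)`, and the remainder goes to validation.
#' Indices are shuffled under the seed before assignment, so group
#' membership of the three sets is random but reproducible.
#'
#' @param group_sizes named or unnamed integer vector of group sizes.
#' @param fractions `c(train, val, test)` summing to 1.
#' @param seed shuffle seed.
#' @return a `split_plan`: per-group list of `train`/`val`/`test` index
#'   vectors (indices within the group), plus a `sizes` matrix.
#' @export
make_split <- function(group_sizes, fractions = c(0.64, 0.16, 0.20),
                       seed = 42L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  groups <- lapply(seq_along(group_sizes), function(i) {
    n <- group_sizes[i]
    n_train <- round(fractions[1] * n)
    n_test <- floor(fractions[3] * n)
    n_val <- n - n_train - n_test
    if (n_val < 0 || n_train < 0 || n_test < 0) {
      stop("computed split size negative for group ", i)
    }
    idx <- with_seed(seed + i, sample.int(max(n, 1L), n))
    list(train = sort(idx[seq_len(n_train)]),
         val = sort(idx[n_train + seq_len(n_val)]),
         test = sort(idx[n_train + n_val + seq_len(n_test)]))
  })
  names(groups) <- names(group_sizes) %||%
    paste0("group", seq_along(group_sizes))
  sizes <- t(vapply(groups, function(g) {
    c(train = length(g$train), val = length(g$val), test = length(g$test))
  }, numeric(3)))
  structure(list(groups = groups, sizes = sizes, fractions = fractions,
                 seed = seed), class = "split_plan")
}

#' Cosine annealing learning rate
#'
#' `lr_min + 0.5 * (lr_init - lr_min) * (1 + cos(pi * epoch / epochs))`.
#'
#' @param epoch current epoch in `0..epochs`.
#' @param lr_init,lr_min schedule endpoints.
#' @param epochs schedule length.
#' @return the learning rate.
#' @export
cosine_lr <- function(epoch, lr_init = 1e-3, epochs = 150L, lr_min = 1e-6) {
  stopifnot(epoch >= 0, epoch <= epochs)
  lr_min + 0.5 * (lr_init - lr_min) * (1 + cos(pi * epoch / epochs))
}

# stack a list of phantom samples into network tensors
samples_to_batch <- function(samples, augment = FALSE) {
  n <- length(samples)
  s1 <- samples[[1]]
  h <- nrow(s1$image); w <- ncol(s1$image)
  x <- array(0, c(h, w, 1L, n))
  msk <- array(0, c(h, w, 1L, n))
  y <- integer(n)
  for (i in seq_len(n)) {
    img <- samples[[i]]$image
    mk <- samples[[i]]$sn_mask
    if (augment) {
      a <- augment_pair(img, mk)
      img <- a$image; mk <- a$mask
    }
    x[, , 1, i] <- img
    msk[, , 1, i] <- mk
    y[i] <- if (samples[[i]]$label == "PD") 2L else 1L
  }
  list(x = x, mask = msk, y = y)
}

compute_losses <- function(net, batch, tc, with_grad = TRUE) {
  out <- forward(net, batch$x)
  sp <- out$sn_prob
  l_seg <- dice_loss(sp, batch$mask)
  ce <- softmax_ce(out$cls_logits, batch$y)
  loss <- tc$lambda_seg * l_seg + tc$lambda_cls * ce$loss
  if (!is.finite(loss)) {
    stop(sprintf("non-finite loss (seg %.4g, cls %.4g): aborting",
                 l_seg, ce$loss))
  }
  grads <- NULL
  if (with_grad) {
    g_sp <- tc$lambda_seg * dice_loss_grad(sp, batch$mask)
    g_seg <- g_sp * sp * (1 - sp)   # through the sigmoid
    g_cls <- tc$lambda_cls * ce$grad
    grads <- list(g_seg = g_seg, g_cls = g_cls)
  }
  list(loss = loss, l_seg = l_seg, l_cls = ce$loss, out = out, grads = grads)
}

#' Refresh batch-norm running statistics
#'
#' Re-estimates every batch-norm layer's running mean/variance as the
#' equal-weight average of per-batch statistics over the given samples,
#' with the current weights frozen. Short training runs leave the
#' exponential running estimates lagging the final weights; this pass
#' aligns evaluation-mode normalization with the trained network.
#'
#' @param net a network.
#' @param samples list of samples to estimate over (typically the training
#'   set).
#' @param batch_size forward batch size.
#' @return the network, invisibly.
#' @export
refresh_bn_stats <- function(net, samples, batch_size = 16L) {
  if (length(samples) < 2L) return(invisible(net))
  drops <- list()
  module_walk(net, function(mm) {
    if (inherits(mm, "nn_dropout")) {
      drops[[length(drops) + 1L]] <<- list(mod = mm, p = mm$p)
      mm$p <- 0
    }
  })
  on.exit(for (d in drops) d$mod$p <- d$p)
  module_walk(net, function(mm) {
    if (inherits(mm, "nn_bn")) {
      mm$refresh_mode <- TRUE
      mm$refresh_count <- 0L
      mm$running_mean[] <- 0
      mm$running_var[] <- 0
    }
  })
  set_training(net, TRUE)
  n <- length(samples)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    if (length(idx) < 2L) next  # batch statistics need >= 2 samples
    b <- samples_to_batch(samples[idx])
    invisible(forward(net, b$x))
  }
  module_walk(net, function(mm) {
    if (inherits(mm, "nn_bn")) mm$refresh_mode <- FALSE
  })
  set_training(net, FALSE)
  invisible(net)
}

#' Train a network
#'
#' Optimizes the combined segmentation + classification loss with Adam,
#' cosine annealing and early stopping on the validation loss; the weights
#' achieving the best validation loss are restored at the end. Fully
#' reproducible under `tc$seed`.
#'
#' @param net a built network (modified in place and returned).
#' @param train_samples,val_samples lists of `phantom_sample` (or
#'   compatible lists with `image`, `sn_mask`, `label`).
#' @param tc a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list with `net`, `history` (one row per epoch: epoch, lr,
#'   train/val losses) and `best_epoch`.
#' @export
train_model <- function(net, train_samples, val_samples = NULL,
                        tc = train_config(), verbose = FALSE) {
  stopifnot(inherits(tc, "train_config"))
  opt <- optim_adam(net, lr = tc$lr_init, weight_decay = tc$weight_decay)
  n <- length(train_samples)
  best_val <- Inf
  best_state <- NULL
  best_epoch <- 0L
  bad_epochs <- 0L
  hist <- list()
  with_seed(tc$seed, {
    for (epoch in seq_len(tc$epochs)) {
      lr <- cosine_lr(epoch - 1L, tc$lr_init, tc$epochs, tc$lr_min)
      set_training(net, TRUE)
      ord <- sample.int(n)
      ep_loss <- ep_seg <- ep_cls <- 0
      nb <- 0L
      for (start in seq(1L, n, by = tc$batch_size)) {
        idx <- ord[start:min(start + tc$batch_size - 1L, n)]
        batch <- samples_to_batch(train_samples[idx], augment = tc$augment)
        zero_grad(net)
        res <- compute_losses(net, batch, tc, with_grad = TRUE)
        backward(net, res$grads)
        adam_step(opt, lr = lr)
        ep_loss <- ep_loss + res$loss
        ep_seg <- ep_seg + res$l_seg
        ep_cls <- ep_cls + res$l_cls
        nb <- nb + 1L
      }
      row <- data.frame(epoch = epoch, lr = lr, train_loss = ep_loss / nb,
                        train_seg = ep_seg / nb, train_cls = ep_cls / nb,
                        val_loss = NA_real_)
      if (!is.null(val_samples) && length(val_samples) > 0) {
        set_training(net, FALSE)
        vb <- samples_to_batch(val_samples)
        vres <- compute_losses(net, vb, tc, with_grad = FALSE)
        row$val_loss <- vres$loss
        if (vres$loss < best_val - 1e-9) {
          best_val <- vres$loss
          best_state <- state_dict(net)
          best_epoch <- epoch
          bad_epochs <- 0L
        } else {
          bad_epochs <- bad_epochs + 1L
        }
      }
      hist[[epoch]] <- row
      if (verbose) {
        message(sprintf("epoch %3d lr %.2e train %.4f val %s", epoch, lr,
                        row$train_loss,
                        if (is.na(row$val_loss)) "-" else sprintf("%.4f", row$val_loss)))
      }
      if (!is.null(val_samples) && bad_epochs >= tc$early_stop_patience) break
    }
  })
  if (!is.null(best_state)) load_state_dict(net, best_state)
  refresh_bn_stats(net, train_samples, batch_size = tc$batch_size)
  set_training(net, FALSE)
  list(net = net, history = do.call(rbind, hist),
       best_epoch = if (best_epoch > 0) best_epoch else length(hist))
}

#' Stratified k-fold cross-validation
#'
#' Splits the cohort into `k` label-stratified folds under the config seed;
#' each fold in turn is held out as the test set while a fresh network is
#' trained on the remainder. Per-fold metrics plus their mean and standard
#' deviation are returned.
#'
#' @param samples list of phantom samples.
#' @param cfg a [model_config()] for the per-fold networks.
#' @param tc a [train_config()] (`tc$folds` is ignored in favour of `k`).
#' @param k number of folds (>= 2).
#' @return list with `fold_metrics` (data frame), `mean`, `sd` and
#'   `fold_assignment`.
#' @export
cross_validate <- function(samples, cfg, tc = train_config(), k = 5L) {
  stopifnot(k >= 2)
  labels <- vapply(samples, function(s) s$label, character(1))
  folds <- integer(length(samples))
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    if (length(idx) < k) {
      stop(sprintf("class '%s' has %d samples, fewer than k = %d folds",
                   lab, length(idx), k))
    }
    sh <- with_seed(tc$seed + match(lab, unique(labels)),
                    sample(idx, length(idx)))
    folds[sh] <- rep_len(seq_len(k), length(sh))
  }
  rows <- list()
  for (f in seq_len(k)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    if (length(unique(labels[test_idx])) < 2 ||
        length(unique(labels[train_idx])) < 2) {
      stop("stratification failure: a class is absent from a fold")
    }
    net <- build_model(cfg)
    fit <- train_model(net, samples[train_idx], val_samples = NULL, tc = tc)
    ev <- evaluate_run(fit$net, samples[test_idx])
    rows[[f]] <- cbind(data.frame(fold = f), as.data.frame(ev$metrics[
      c("accuracy", "precision", "recall", "f1", "miou")]))
  }
  fm <- do.call(rbind, rows)
  list(fold_metrics = fm,
       mean = colMeans(fm[, -1, drop = FALSE]),
       sd = apply(fm[, -1, drop = FALSE], 2, stats::sd),
       fold_assignment = folds)
}
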