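#' Confusion counts
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return a `confusion_counts` list.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(v < 0)) stop("confusion counts must be non-negative")
  structure(as.list(v), class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Standard definitions: accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`,
#' recall `TP/(TP+FN)`, F1 the harmonic mean of precision and recall.
#' Ratios with a zero denominator are reported as 0 and flagged in
#' `undefined` rather than returned as NaN, so downstream aggregation never
#' propagates missing values.
#'
#' @param cc a [confusion_counts()].
#' @return a list with `accuracy`, `precision`, `recall`, `f1` and a
#'   character vector `undefined` naming any zero-denominator metrics.
#' @export
classification_metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  total <- cc$tp + cc$tn + cc$fp + cc$fn
  if (total < 1) stop("at least one sample required")
  undef <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) {
      undef <<- c(undef, name)
      0
    } else {
      num / den
    }
  }
  precision <- safe_div(cc$tp, cc$tp + cc$fp, "precision")
  recall <- safe_div(cc$tp, cc$tp + cc$fn, "recall")
  f1 <- if (precision + recall == 0) {
    undef <- c(undef, "f1")
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(accuracy = (cc$tp + cc$tn) / total, precision = precision,
       recall = recall, f1 = f1, undefined = unique(undef))
}

#' Per-class IoU and mean IoU of a binary segmentation
#'
#' Intersection over union for the foreground (SN) and background classes,
#' `IoU_c = TP_c / (TP_c + FP_c + FN_c)`, and their mean.
#'
#' @param pred_mask,gt_mask binary arrays/matrices of identical shape.
#' @return list with `iou_per_class` (named: sn, background) and `miou`.
#' @export
segmentation_iou <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask) %||% length(pred_mask),
                 dim(gt_mask) %||% length(gt_mask))) {
    stop("mask shapes differ")
  }
  pv <- as.vector(pred_mask); gv <- as.vector(gt_mask)
  if (!all(pv %in% c(0, 1)) || !all(gv %in% c(0, 1))) {
    stop("masks must be binary (0/1)")
  }
  iou_class <- function(p, g) {
    tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g)
    if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
  }
  iou <- c(sn = iou_class(pv == 1, gv == 1),
           background = iou_class(pv == 0, gv == 0))
  list(iou_per_class = iou, miou = mean(iou))
}

#' Evaluate a trained network on a labelled dataset
#'
#' Runs the network (evaluation mode), thresholds class probabilities and
#' SN probabilities at `threshold`, and aggregates classification metrics
#' and per-sample segmentation IoU. Samples lacking masks yield a
#' classification-only report with a note.
#'
#' @param net a trained network.
#' @param samples list of phantom samples (fields `image`, `label`,
#'   optionally `sn_mask`).
#' @param threshold decision threshold on probabilities.
#' @param batch_size evaluation batch size.
#' @return list with `metrics` (accuracy, precision, recall, f1, miou,
#'   mean per-class IoU), `counts` (a [confusion_counts()]), `per_sample`
#'   data frame, and `note` (non-empty when masks were missing).
#' @export
evaluate_run <- function(net, samples, threshold = 0.5, batch_size = 16L) {
  set_training(net, FALSE)
  n <- length(samples)
  if (n < 1) stop("evaluate_run needs at least one sample")
  prob_pd <- numeric(n)
  iou_sn <- iou_bg <- miou <- rep(NA_real_, n)
  have_mask <- vapply(samples, function(s) !is.null(s$sn_mask), logical(1))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    nb <- length(idx)
    s1 <- samples[[idx[1]]]
    x <- array(0, c(nrow(s1$image), ncol(s1$image), 1L, nb))
    for (j in seq_len(nb)) x[, , 1, j] <- samples[[idx[j]]]$image
    out <- forward(net, x)
    zx <- sweep(out$cls_logits, 2, apply(out$cls_logits, 2, max))
    p <- exp(zx); p <- sweep(p, 2, colSums(p), "/")
    prob_pd[idx] <- p[2, ]
    for (j in seq_len(nb)) {
      i <- idx[j]
      if (have_mask[i]) {
        pm <- (out$sn_prob[, , 1, j] >= threshold) * 1
        r <- segmentation_iou(pm, samples[[i]]$sn_mask)
        iou_sn[i] <- r$iou_per_class["sn"]
        iou_bg[i] <- r$iou_per_class["background"]
        miou[i] <- r$miou
      }
    }
  }
  labels <- vapply(samples, function(s) s$label, character(1))
  pred <- ifelse(prob_pd >= threshold, "PD", "HC")
  cc <- confusion_counts(tp = sum(pred == "PD" & labels == "PD"),
                         tn = sum(pred == "HC" & labels == "HC"),
                         fp = sum(pred == "PD" & labels == "HC"),
                         fn = sum(pred == "HC" & labels == "PD"))
  cm <- classification_metrics(cc)
  note <- if (!all(have_mask)) {
    sprintf("%d/%d samples lack masks; segmentation metrics computed on the rest",
            sum(!have_mask), n)
  } else {
    ""
  }
  metrics <- list(accuracy = cm$accuracy, precision = cm$precision,
                  recall = cm$recall, f1 = cm$f1,
                  miou = if (any(have_mask)) mean(miou[have_mask]) else NA_real_,
                  iou_sn = if (any(have_mask)) mean(iou_sn[have_mask]) else NA_real_,
                  iou_background = if (any(have_mask)) mean(iou_bg[have_mask])
                                   else NA_real_,
                  undefined = cm$undefined)
  per_sample <- data.frame(
    id = vapply(seq_len(n), function(i) samples[[i]]$id %||% sprintf("s%04d", i),
                character(1)),
    label = labels, prediction = pred, probability = prob_pd,
    iou_sn = iou_sn, miou = miou, stringsAsFactors = FALSE)
  list(metrics = metrics, counts = cc, per_sample = per_sample, note = note)
}
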