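#' Model configuration
#'
#' Hyperparameters defining one constructible network. The defaults build
#' the full architecture: a 4-level encoder (hybrid ghost block + wavelet
#' downsampling per stage, channel ladder 16/24/40/80), a 160-channel
#' bottleneck, a mirrored decoder with coordinate attention and mid-level
#' skip connections, an auxiliary substantia-nigra segmentation head, and a
#' mask-gated two-layer classification head. The four `use_*` switches
#' select the ablation variants: with everything off a plain double-conv
#' U-Net with strided-conv downsampling is built.
#'
#' @param input_size spatial input size `c(H, W)`; both divisible by 16.
#' @param in_channels input channels (1 for a single MRI slice).
#' @param encoder_channels strictly increasing 4-vector of per-stage
#'   channel counts (the outputs of each downsampling).
#' @param bottleneck_channels bottleneck width.
#' @param wavelet_name wavelet for the downsampling transform.
#' @param combine_mode how fused details rejoin LL: `"concat"` or `"add"`.
#' @param use_hybrid_ghost,use_wavelet_down,use_attention,use_mid_skip
#'   ablation switches.
#' @param ghost list of ghost-block settings: `n_groups`, `ratio`,
#'   `kernel`, `cheap_kernel`, `exp_factor`.
#' @param ca list of coordinate-attention settings: `reduction`, `use_fc`.
#' @param gate_location which feature map the predicted SN mask gates:
#'   `"decoder"` (final decoder map, full resolution) or `"bottleneck"`.
#' @param cls_hidden width of the hidden fully connected layer.
#' @param dropout dropout rate in the classification head.
#' @param seed construction seed; two builds with equal config and seed
#'   have identical initial weights.
#' @return a `model_config` list.
#' @export
model_config <- function(input_size = c(192L, 192L),
                         in_channels = 1L,
                         encoder_channels = c(16L, 24L, 40L, 80L),
                         bottleneck_channels = 160L,
                         wavelet_name = "db2",
                         combine_mode = "concat",
                         use_hybrid_ghost = TRUE,
                         use_wavelet_down = TRUE,
                         use_attention = TRUE,
                         use_mid_skip = TRUE,
                         ghost = list(),
                         ca = list(),
                         gate_location = c("decoder", "bottleneck"),
                         cls_hidden = 64L,
                         dropout = 0.2,
                         seed = 42L) {
  gate_location <- match.arg(gate_location)
  ghost <- utils::modifyList(
    list(n_groups = 2L, ratio = 2L, kernel = 1L, cheap_kernel = 3L,
         exp_factor = 1), ghost)
  ca <- utils::modifyList(list(reduction = 8L, use_fc = TRUE), ca)
  cfg <- structure(list(
    input_size = as.integer(input_size), in_channels = as.integer(in_channels),
    encoder_channels = as.integer(encoder_channels),
    bottleneck_channels = as.integer(bottleneck_channels),
    wavelet_name = wavelet_name, combine_mode = combine_mode,
    use_hybrid_ghost = isTRUE(use_hybrid_ghost),
    use_wavelet_down = isTRUE(use_wavelet_down),
    use_attention = isTRUE(use_attention),
    use_mid_skip = isTRUE(use_mid_skip),
    ghost = ghost, ca = ca, gate_location = gate_location,
    cls_hidden = as.integer(cls_hidden), dropout = dropout,
    seed = as.integer(seed)), class = "model_config")
  validate_model_config(cfg)
  cfg
}

validate_model_config <- function(cfg) {
  if (length(cfg$encoder_channels) != 4L) {
    stop("encoder_channels must have exactly 4 entries")
  }
  if (any(diff(c(cfg$encoder_channels, cfg$bottleneck_channels)) <= 0)) {
    stop("channel ladder must be strictly increasing")
  }
  if (any(cfg$input_size %% 16L != 0L)) {
    stop(sprintf("input size %dx%d must be divisible by 2^4 = 16",
                 cfg$input_size[1], cfg$input_size[2]))
  }
  invisible(cfg)
}

# per-stage channel plan: block keeps channels, downsampling expands.
# pre[i]  = channels entering stage i's block
# skip[i] = channels of the stage-i skip (block output, pre-downsampling)
# enc[i]  = channels after stage i's downsampling
stage_plan <- function(cfg) {
  enc <- cfg$encoder_channels
  pre <- c(cfg$in_channels, enc[1:3])
  list(pre = pre, skip = c(enc[1], enc[1:3]), enc = enc)
}

#' Mid-skip wiring of a configuration
#'
#' Enumerates the encoder-to-decoder skip edges the model will build.
#' Every decoder level receives its same-resolution encoder skip; with
#' `use_mid_skip` the two highest-resolution decoder levels additionally
#' receive a cross-level edge from the encoder two levels deeper
#' (decoder 1 from encoder 3, decoder 2 from encoder 4), upsampled 4x and
#' 1x1-projected before concatenation.
#'
#' @param cfg a [model_config()].
#' @return a data frame with columns `decoder_level`, `encoder_level`,
#'   `type` (`"same"`/`"mid"`), `scale` (spatial upsampling factor applied
#'   to the source) and `channels` (channels delivered after projection).
#' @export
mid_skip_wiring <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  sp <- stage_plan(cfg)
  edges <- data.frame(decoder_level = 1:4, encoder_level = 1:4,
                      type = "same", scale = 1L, channels = sp$skip)
  if (cfg$use_mid_skip) {
    edges <- rbind(edges, data.frame(
      decoder_level = c(1L, 2L), encoder_level = c(3L, 4L),
      type = "mid", scale = 4L, channels = sp$skip[c(1L, 2L)]))
  }
  edges[order(edges$decoder_level, edges$type), , drop = FALSE]
}

#' Build the network
#'
#' Assembles the configured model. On a 192x192x1 input the default
#' encoder stages produce feature maps of shape (16, 96, 96), (24, 48, 48),
#' (40, 24, 24) and (80, 12, 12) (channels, height, width), the bottleneck
#' (160, 12, 12), and the decoder mirrors back to full resolution where the
#' segmentation head emits one logit channel and the mask-gated pooled
#' features feed the two-layer classification head.
#'
#' @param cfg a [model_config()].
#' @return a network module for [forward()], [backward()],
#'   [count_costs()].
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  validate_model_config(cfg)
  with_seed(cfg$seed, build_model_impl(cfg))
}

build_model_impl <- function(cfg) {
  sp <- stage_plan(cfg)
  g <- cfg$ghost
  make_block <- function(in_ch, out_ch, dfc) {
    if (cfg$use_hybrid_ghost) {
      hybrid_ghost_block(in_ch, out_ch, stride = 1L,
                         n_groups = g$n_groups, ratio = g$ratio,
                         kernel = g$kernel, cheap_kernel = g$cheap_kernel,
                         exp_factor = g$exp_factor,
                         use_dfc_attention = dfc && cfg$use_attention)
    } else {
      nn_plain_block(in_ch, out_ch)
    }
  }
  make_down <- function(in_ch, out_ch) {
    if (cfg$use_wavelet_down) {
      nn_wcnn_down(in_ch, out_ch, combine_mode = cfg$combine_mode,
                   wavelet_name = cfg$wavelet_name)
    } else if (cfg$use_hybrid_ghost) {
      hybrid_ghost_block(in_ch, out_ch, stride = 2L,
                         n_groups = g$n_groups, ratio = g$ratio,
                         kernel = g$kernel, cheap_kernel = g$cheap_kernel,
                         exp_factor = g$exp_factor)
    } else {
      nn_strided_down(in_ch, out_ch)
    }
  }

  enc_blocks <- lapply(1:4, function(i)
    make_block(sp$pre[i], sp$skip[i], dfc = TRUE))
  downs <- lapply(1:4, function(i) make_down(sp$skip[i], sp$enc[i]))
  bottleneck <- make_block(sp$enc[4], cfg$bottleneck_channels, dfc = FALSE)

  dec_ch <- rev(sp$enc)          # decoder target widths: 80, 40, 24, 16 (level 4..1)
  dec_target <- function(d) dec_ch[5 - d]
  up_in <- function(d) if (d == 4) cfg$bottleneck_channels else dec_target(d + 1)

  edges <- mid_skip_wiring(cfg)
  ups <- list(); up_projs <- list(); mid_projs <- list(); mid_ups <- list()
  fuses <- list(); dec_blocks <- list(); cas <- list()
  for (d in 4:1) {
    key <- as.character(d)
    ups[[key]] <- nn_resize(scale = 2L, mode = "bilinear")
    up_projs[[key]] <- nn_seq(list(
      nn_conv2d(up_in(d), dec_target(d), 1L, pad = 0L, bias = FALSE),
      nn_bn(dec_target(d)), nn_relu()))
    fuse_in <- dec_target(d) + sp$skip[d]
    has_mid <- cfg$use_mid_skip && d <= 2
    if (has_mid) {
      src <- d + 2L
      mid_ups[[key]] <- nn_resize(scale = 4L, mode = "bilinear")
      mid_projs[[key]] <- nn_seq(list(
        nn_conv2d(sp$skip[src], sp$skip[d], 1L, pad = 0L, bias = FALSE),
        nn_bn(sp$skip[d]), nn_relu()))
      fuse_in <- fuse_in + sp$skip[d]
    }
    fuses[[key]] <- nn_seq(list(
      nn_conv2d(fuse_in, dec_target(d), 1L, pad = 0L, bias = FALSE),
      nn_bn(dec_target(d)), nn_relu()))
    dec_blocks[[key]] <- make_block(dec_target(d), dec_target(d), dfc = FALSE)
    cas[[key]] <- if (cfg$use_attention) {
      nn_coordinate_attention(dec_target(d), cfg$ca$reduction, cfg$ca$use_fc)
    } else {
      nn_identity()
    }
  }

  # background-prior bias: the SN occupies a small fraction of the slice,
  # so the head starts predicting mostly background (speeds up Dice early)
  seg_head <- nn_conv2d(dec_target(1), 1L, 1L, pad = 0L, bias = TRUE)
  seg_head$b[] <- -2
  fc1 <- nn_linear(if (cfg$gate_location == "decoder") dec_target(1)
                   else cfg$bottleneck_channels, cfg$cls_hidden)
  net <- new_module("nn_ghostwave_net",
    cfg = cfg, plan = sp, edges = edges,
    enc_blocks = enc_blocks, downs = downs, bottleneck = bottleneck,
    ups = ups, up_projs = up_projs, mid_ups = mid_ups, mid_projs = mid_projs,
    fuses = fuses, dec_blocks = dec_blocks, cas = cas,
    seg_head = seg_head,
    cls_fc1 = fc1, cls_act = nn_relu(), cls_drop = nn_dropout(cfg$dropout),
    cls_fc2 = nn_linear(cfg$cls_hidden, 2L),
    cls_gap = nn_gap(),
    gate_resize = nn_resize(out_hw = NULL, mode = "bilinear"),
    children = c("enc_blocks", "downs", "bottleneck", "ups", "up_projs",
                 "mid_ups", "mid_projs", "fuses", "dec_blocks", "cas",
                 "seg_head", "cls_fc1", "cls_act", "cls_drop", "cls_fc2",
                 "cls_gap", "gate_resize"))
  net
}

#' Forward pass of the assembled network
#'
#' @param m a network from [build_model()].
#' @param x input batch `(H, W, 1, N)` matching the configured input size,
#'   intensities standardized.
#' @param gate_override optional fixed gate array replacing the predicted
#'   SN probability in the classification branch (used to audit the gating
#'   path); `NULL` uses `sn_prob`.
#' @param ... unused.
#' @return a `network_output` list: `seg_logits` `(H, W, 1, N)`,
#'   `sn_prob` in (0, 1) of the same shape, and `cls_logits` `(2, N)`.
#' @export
forward.nn_ghostwave_net <- function(m, x, gate_override = NULL, ...) {
  cfg <- m$cfg
  check_fm(x)
  d <- dim(x)
  if (d[1] != cfg$input_size[1] || d[2] != cfg$input_size[2] ||
      d[3] != cfg$in_channels) {
    stop(sprintf("expected input %dx%dx%d, got %dx%dx%d",
                 cfg$input_size[1], cfg$input_size[2], cfg$in_channels,
                 d[1], d[2], d[3]))
  }
  skips <- vector("list", 4)
  h <- x
  for (i in 1:4) {
    h <- forward(m$enc_blocks[[i]], h)
    skips[[i]] <- h
    h <- forward(m$downs[[i]], h)
  }
  h <- forward(m$bottleneck, h)
  bott <- h
  concat_sizes <- list()
  for (d_lvl in 4:1) {
    key <- as.character(d_lvl)
    h <- forward(m$up_projs[[key]], forward(m$ups[[key]], h))
    parts <- list(h, skips[[d_lvl]])
    if (!is.null(m$mid_projs[[key]])) {
      parts[[3]] <- forward(m$mid_projs[[key]],
                            forward(m$mid_ups[[key]], skips[[d_lvl + 2]]))
    }
    concat_sizes[[key]] <- vapply(parts, function(p) dim(p)[3], integer(1))
    h <- cat_channels(parts)
    h <- forward(m$fuses[[key]], h)
    h <- forward(m$dec_blocks[[key]], h)
    h <- forward(m$cas[[key]], h)
  }
  seg_logits <- forward(m$seg_head, h)
  sn_prob <- 1 / (1 + exp(-seg_logits))

  gate_src <- if (cfg$gate_location == "decoder") h else bott
  gate <- if (!is.null(gate_override)) gate_override else sn_prob
  if (!identical(dim(gate)[1:2], dim(gate_src)[1:2])) {
    m$gate_resize$out_hw <- dim(gate_src)[1:2]
    gate <- forward(m$gate_resize, gate)
    m$gate_resized <- TRUE
  } else {
    m$gate_resized <- FALSE
  }
  gated <- gate_src * rep_gate(gate, dim(gate_src))
  pooled <- forward(m$cls_gap, gated)
  z <- forward(m$cls_fc1, pooled)
  z <- forward(m$cls_act, z)
  z <- forward(m$cls_drop, z)
  cls_logits <- forward(m$cls_fc2, z)

  m$cache <- list(x_dim = d, gate_src = gate_src, gate = gate,
                  sn_prob = sn_prob, concat_sizes = concat_sizes,
                  gate_overridden = !is.null(gate_override))
  structure(list(seg_logits = seg_logits, sn_prob = sn_prob,
                 cls_logits = cls_logits), class = "network_output")
}

# broadcast a single-channel gate over C channels
rep_gate <- function(gate, dims) {
  g <- array(0, dims)
  for (c in seq_len(dims[3])) g[, , c, ] <- gate[, , 1, ]
  g
}

#' Backward pass of the assembled network
#'
#' @param m the network (after [forward()]).
#' @param gy list with `g_seg` (gradient on `seg_logits`, may be NULL) and
#'   `g_cls` (gradient on `cls_logits`, may be NULL).
#' @param ... unused.
#' @return gradient with respect to the input batch.
#' @export
backward.nn_ghostwave_net <- function(m, gy, ...) {
  cc <- m$cache
  cfg <- m$cfg
  g_seg <- gy$g_seg
  g_cls <- gy$g_cls
  dims_src <- dim(cc$gate_src)
  g_gate_src <- array(0, dims_src)
  g_seg_total <- if (is.null(g_seg)) array(0, dim(cc$sn_prob)) else g_seg

  if (!is.null(g_cls)) {
    gz <- backward(m$cls_fc2, g_cls)
    gz <- backward(m$cls_drop, gz)
    gz <- backward(m$cls_act, gz)
    g_pooled <- backward(m$cls_fc1, gz)
    g_gated <- backward(m$cls_gap, g_pooled)
    gate_rep <- rep_gate(cc$gate, dims_src)
    g_gate_src <- g_gated * gate_rep
    # gradient into the gate: sum over channels
    g_gate_full <- g_gated * cc$gate_src
    g_gate <- colSums(aperm(g_gate_full, c(3L, 1L, 2L, 4L)))  # sum channels
    dim(g_gate) <- dim(cc$gate)
    if (isTRUE(m$gate_resized)) g_gate <- backward(m$gate_resize, g_gate)
    if (!cc$gate_overridden) {
      g_seg_total <- g_seg_total + g_gate * cc$sn_prob * (1 - cc$sn_prob)
    }
  }

  g_h <- backward(m$seg_head, g_seg_total)
  if (cfg$gate_location == "decoder") g_h <- g_h + g_gate_src

  g_skips <- vector("list", 4)
  for (d_lvl in 1:4) {
    key <- as.character(d_lvl)
    g_h <- backward(m$cas[[key]], g_h)
    g_h <- backward(m$dec_blocks[[key]], g_h)
    g_h <- backward(m$fuses[[key]], g_h)
    parts <- split_channels(g_h, cc$concat_sizes[[key]])
    g_up <- parts[[1]]
    g_skips[[d_lvl]] <- add_or_set(g_skips[[d_lvl]], parts[[2]])
    if (length(parts) == 3) {
      g_mid <- backward(m$mid_ups[[key]], backward(m$mid_projs[[key]], parts[[3]]))
      g_skips[[d_lvl + 2]] <- add_or_set(g_skips[[d_lvl + 2]], g_mid)
    }
    g_h <- backward(m$ups[[key]], backward(m$up_projs[[key]], g_up))
  }
  if (cfg$gate_location == "bottleneck") g_h <- g_h + g_gate_src
  g_h <- backward(m$bottleneck, g_h)
  for (i in 4:1) {
    g_h <- backward(m$downs[[i]], g_h)
    g_h <- g_h + g_skips[[i]]
    g_h <- backward(m$enc_blocks[[i]], g_h)
  }
  g_h
}

add_or_set <- function(a, b) if (is.null(a)) b else a + b

#' Parameter and FLOP accounting
#'
#' Counts trainable parameters exactly from the weight arrays and
#' multiply-accumulate operations (MACs) of one forward pass at the given
#' input size, covering convolutions, fully connected layers, attention
#' aggregations, the wavelet filtering and the resampling interpolations.
#' Following the efficient-CNN literature the headline `flops_g` equals
#' MACs / 1e9; `flops_2x_g` (2 x MACs) is reported alongside for the
#' multiply-plus-add convention.
#'
#' @param net a built network.
#' @param input_size `c(H, W)`; defaults to the configured size.
#' @return a `cost_report` list: `trainable_parameters`, `macs`, `flops_g`,
#'   `flops_2x_g`, and a per-component `breakdown` data frame whose totals
#'   equal the headline numbers.
#' @export
count_costs <- function(net, input_size = NULL) {
  cfg <- net$cfg
  if (is.null(input_size)) input_size <- cfg$input_size
  was_training <- net$training
  set_training(net, FALSE)
  zero_grad(net)
  x <- array(0, c(input_size[1], input_size[2], cfg$in_channels, 1L))
  invisible(forward(net, x))
  set_training(net, was_training)

  components <- c("enc_blocks", "downs", "bottleneck", "ups", "up_projs",
                  "mid_ups", "mid_projs", "fuses", "dec_blocks", "cas",
                  "seg_head", "cls_fc1", "cls_fc2")
  rows <- lapply(components, function(nm) {
    ch <- net[[nm]]
    mods <- if (is.list(ch) && !inherits(ch, "nn_module")) ch else list(ch)
    p <- 0; mc <- 0
    for (mm in mods) {
      module_walk(mm, function(z) {
        for (pn in z$params) p <<- p + length(z[[pn]])
        mc <<- mc + z$macs
      })
    }
    data.frame(component = nm, params = p, macs = mc)
  })
  breakdown <- do.call(rbind, rows)
  # gap/gate resize live outside the named components; fold them in
  extra_macs <- net$gate_resize$macs + (net$cls_gap$macs %||% 0)
  if (extra_macs > 0) {
    breakdown <- rbind(breakdown,
                       data.frame(component = "other", params = 0,
                                  macs = extra_macs))
  }
  total_p <- sum(breakdown$params)
  total_m <- sum(breakdown$macs)
  stopifnot(abs(total_p - n_parameters(net)) < 0.5)
  structure(list(trainable_parameters = total_p,
                 macs = total_m,
                 flops_g = total_m / 1e9,
                 flops_2x_g = 2 * total_m / 1e9,
                 breakdown = breakdown),
            class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf("parameters: %s (%.3f M)\n",
              format(x$trainable_parameters, big.mark = ","),
              x$trainable_parameters / 1e6))
  cat(sprintf("MACs:       %s (%.3f G; 2x = %.3f G)\n",
              format(x$macs, big.mark = ","), x$flops_g, x$flops_2x_g))
  print(x$breakdown, row.names = FALSE)
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint containing the configuration and all weights and
#' running statistics.
#'
#' @param net a built network.
#' @param path file path.
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(cfg = net$cfg, state = state_dict(net)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- build_model(ck$cfg)
  load_state_dict(net, ck$state)
  net
}
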