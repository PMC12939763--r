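# Minimal layer framework: every layer/block is an environment carrying its
# weights, gradient slots and forward cache. `forward()` / `backward()` are S3
# generics dispatched on the layer class; composite blocks recurse through
# their named children. Reference semantics let the optimizer update weights
# in place.

new_module <- function(class, ...) {
  m <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = m)
  if (is.null(m$params)) m$params <- character(0)
  if (is.null(m$children)) m$children <- character(0)
  m$training <- TRUE
  m$grads <- list()
  m$macs <- 0
  class(m) <- c(class, "nn_module")
  m
}

#' Run a layer or network forward
#'
#' @param m a module built by one of the `nn_*` constructors or
#'   [build_model()].
#' @param x input feature map `(H, W, C, N)` (or a feature matrix for dense
#'   layers).
#' @param ... passed to methods.
#' @return the module output; composite modules cache intermediates for
#'   [backward()].
#' @export
forward <- function(m, x, ...) UseMethod("forward")

#' Backpropagate through a layer or network
#'
#' Accumulates parameter gradients into the module's gradient slots and
#' returns the gradient with respect to the module input. Must follow a
#' [forward()] call on the same module.
#'
#' @param m a module.
#' @param gy gradient of the loss with respect to the module output.
#' @param ... passed to methods.
#' @return gradient with respect to the module input.
#' @export
backward <- function(m, gy, ...) UseMethod("backward")

#' @export
forward.default <- function(m, x, ...) stop("not a module")

# walk the module tree, applying fn to every module (parents first)
module_walk <- function(m, fn) {
  fn(m)
  for (nm in m$children) {
    ch <- m[[nm]]
    if (is.list(ch) && !inherits(ch, "nn_module")) {
      for (c2 in ch) module_walk(c2, fn)
    } else {
      module_walk(ch, fn)
    }
  }
  invisible(m)
}

# list of (module, param-name) handles for the optimizer
parameters <- function(m) {
  out <- list()
  module_walk(m, function(mm) {
    for (p in mm$params) out[[length(out) + 1L]] <<- list(mod = mm, name = p)
  })
  out
}

n_parameters <- function(m) {
  sum(vapply(parameters(m), function(h) length(h$mod[[h$name]]), numeric(1)))
}

zero_grad <- function(m) {
  module_walk(m, function(mm) {
    mm$grads <- list()
    mm$macs <- 0
  })
}

acc_grad <- function(m, name, g) {
  cur <- m$grads[[name]]
  m$grads[[name]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

grad_of <- function(m, name) {
  g <- m$grads[[name]]
  if (is.null(g)) array(0, dim = dim(m[[name]]) %||% length(m[[name]])) else g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

set_training <- function(m, flag) {
  module_walk(m, function(mm) mm$training <- flag)
  invisible(m)
}

# state dict: flat named list of all parameter and buffer arrays ----------

state_dict <- function(m, prefix = "") {
  out <- list()
  grab <- function(mm, pre) {
    for (p in c(mm$params, mm$buffers)) {
      out[[paste0(pre, p)]] <<- mm[[p]]
    }
    for (nm in mm$children) {
      ch <- mm[[nm]]
      if (is.list(ch) && !inherits(ch, "nn_module")) {
        for (i in seq_along(ch)) grab(ch[[i]], paste0(pre, nm, i, "."))
      } else {
        grab(ch, paste0(pre, nm, "."))
      }
    }
  }
  grab(m, prefix)
  out
}

load_state_dict <- function(m, sd, prefix = "") {
  put <- function(mm, pre) {
    for (p in c(mm$params, mm$buffers)) {
      key <- paste0(pre, p)
      if (is.null(sd[[key]])) stop("missing state entry: ", key)
      mm[[p]] <- sd[[key]]
    }
    for (nm in mm$children) {
      ch <- mm[[nm]]
      if (is.list(ch) && !inherits(ch, "nn_module")) {
        for (i in seq_along(ch)) put(ch[[i]], paste0(pre, nm, i, "."))
      } else {
        put(ch, paste0(pre, nm, "."))
      }
    }
  }
  put(m, prefix)
  invisible(m)
}

# Adam with classic L2 weight decay added to the gradient ----------------

optim_adam <- function(net, lr = 1e-3, betas = c(0.9, 0.999), eps = 1e-8,
                       weight_decay = 0) {
  handles <- parameters(net)
  st <- new.env(parent = emptyenv())
  st$handles <- handles
  st$m <- vector("list", length(handles))
  st$v <- vector("list", length(handles))
  st$t <- 0L
  st$lr <- lr
  st$beta1 <- betas[1]; st$beta2 <- betas[2]
  st$eps <- eps; st$wd <- weight_decay
  class(st) <- "optim_adam"
  st
}

adam_step <- function(opt, lr = opt$lr) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t
  bc2 <- 1 - b2^opt$t
  for (i in seq_along(opt$handles)) {
    h <- opt$handles[[i]]
    w <- h$mod[[h$name]]
    g <- h$mod$grads[[h$name]]
    if (is.null(g)) next
    if (opt$wd > 0) g <- g + opt$wd * w
    if (is.null(opt$m[[i]])) {
      opt$m[[i]] <- g * 0
      opt$v[[i]] <- g * 0
    }
    opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
    opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g * g
    mhat <- opt$m[[i]] / bc1
    vhat <- opt$v[[i]] / bc2
    h$mod[[h$name]] <- w - lr * mhat / (sqrt(vhat) + opt$eps)
  }
  invisible(opt)
}

# weight init ------------------------------------------------------------

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}
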