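# Computation-graph executor for the segmentation network.
#
# The network is a DAG of typed nodes evaluated in topological order; the
# backward pass walks the list in reverse, accumulating gradients per input.
# Convolutions run through im2col/GEMM kernels in C++; everything else is
# vectorized R on (H, W, C, B) arrays.

add_node <- function(nodes, name, op, inputs = character(), ...) {
  nodes[[name]] <- c(list(name = name, op = op, inputs = inputs), list(...))
  nodes
}

# Concatenate 4-D arrays along the channel dimension.
concat4 <- function(arrs) {
  d1 <- dim(arrs[[1]])
  cs <- vapply(arrs, function(a) dim(a)[3], numeric(1))
  out <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0L
  for (a in arrs) {
    nc <- dim(a)[3]
    out[, , at + seq_len(nc), ] <- a
    at <- at + nc
  }
  out
}

# --- batch normalization ---------------------------------------------------

bn_stats_matrix <- function(a) {
  d <- dim(a)
  matrix(aperm(a, c(1, 2, 4, 3)), ncol = d[3])
}

bn_unflatten <- function(m, d) {
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

bn_forward <- function(a, gamma, beta, training, state, momentum = 0.9,
                       eps = 1e-5) {
  d <- dim(a)
  am <- bn_stats_matrix(a)
  if (training) {
    mu <- colMeans(am)
    va <- colMeans(sweep(am, 2, mu)^2)
    state$running_mean <- momentum * state$running_mean + (1 - momentum) * mu
    state$running_var <- momentum * state$running_var + (1 - momentum) * va
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(am, 2, mu), 2, inv_sd, `*`)
  ym <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(y = bn_unflatten(ym, d), state = state,
       cache = list(xhat = xhat, inv_sd = inv_sd, d = d))
}

bn_backward <- function(g, gamma, cache) {
  gm <- bn_stats_matrix(g)
  xhat <- cache$xhat
  m <- nrow(gm)
  dgamma <- colSums(gm * xhat)
  dbeta <- colSums(gm)
  t1 <- sweep(gm, 2, dbeta / m)
  t2 <- sweep(xhat, 2, dgamma / m, `*`)
  dxm <- sweep((t1 - t2), 2, gamma * cache$inv_sd, `*`)
  list(dx = bn_unflatten(dxm, cache$d), dgamma = dgamma, dbeta = dbeta)
}

# --- forward / backward ----------------------------------------------------

forward_graph <- function(model, x, training = FALSE) {
  nodes <- model$graph$nodes
  params <- model$params
  state <- model$state
  act <- new.env(parent = emptyenv())
  cache <- new.env(parent = emptyenv())
  assign("input", x, envir = act)
  for (node in nodes) {
    if (node$op == "input") next
    a <- if (length(node$inputs) == 1L) get(node$inputs, envir = act) else NULL
    y <- switch(
      node$op,
      conv = {
        pr <- params[[node$name]]
        .conv_fwd(a, pr$w, pr$b, node$k, node$stride, node$pad)
      },
      convt = {
        pr <- params[[node$name]]
        d <- dim(a)
        .convt_fwd(a, pr$w, pr$b, node$k, node$stride, node$pad,
                   d[1] * node$stride, d[2] * node$stride)
      },
      bn = {
        pr <- params[[node$name]]
        bnf <- bn_forward(a, pr$gamma, pr$beta, training, state[[node$name]])
        state[[node$name]] <- bnf$state
        assign(node$name, bnf$cache, envir = cache)
        bnf$y
      },
      relu = pmax(a, 0),
      lrelu = {
        y <- a
        y[a < 0] <- node$slope * a[a < 0]
        y
      },
      sigmoid = 1 / (1 + exp(-a)),
      dropout = {
        if (training && node$rate > 0) {
          keep <- array(runif(length(a)) >= node$rate, dim(a)) / (1 - node$rate)
          assign(node$name, keep, envir = cache)
          a * keep
        } else a
      },
      concat = concat4(lapply(node$inputs, get, envir = act)),
      abort(sprintf("unknown op '%s'", node$op))
    )
    if (node$op %in% c("relu", "lrelu", "sigmoid")) {
      assign(node$name, list(x = a, y = y), envir = cache)
    }
    assign(node$name, y, envir = act)
  }
  model$state <- state
  list(output = get(model$graph$out_name, envir = act),
       act = act, cache = cache, model = model)
}

backward_graph <- function(model, fwd, dout) {
  nodes <- model$graph$nodes
  params <- model$params
  grads <- new.env(parent = emptyenv())
  pgrads <- list()
  assign(model$graph$out_name, dout, envir = grads)
  acc <- function(name, g) {
    if (exists(name, envir = grads, inherits = FALSE)) {
      assign(name, get(name, envir = grads) + g, envir = grads)
    } else {
      assign(name, g, envir = grads)
    }
  }
  for (node in rev(nodes)) {
    if (node$op == "input") next
    if (!exists(node$name, envir = grads, inherits = FALSE)) next
    g <- get(node$name, envir = grads)
    switch(
      node$op,
      conv = {
        pr <- params[[node$name]]
        x_in <- get(node$inputs, envir = fwd$act)
        r <- .conv_bwd(x_in, pr$w, g, node$k, node$stride, node$pad)
        acc(node$inputs, r$dx)
        pgrads[[node$name]] <- list(w = matrix(r$dw, nrow(pr$w), ncol(pr$w)),
                                    b = r$db)
      },
      convt = {
        pr <- params[[node$name]]
        x_in <- get(node$inputs, envir = fwd$act)
        r <- .convt_bwd(x_in, pr$w, g, node$k, node$stride, node$pad)
        acc(node$inputs, r$dx)
        pgrads[[node$name]] <- list(w = matrix(r$dw, nrow(pr$w), ncol(pr$w)),
                                    b = r$db)
      },
      bn = {
        pr <- params[[node$name]]
        r <- bn_backward(g, pr$gamma, get(node$name, envir = fwd$cache))
        acc(node$inputs, r$dx)
        pgrads[[node$name]] <- list(gamma = r$dgamma, beta = r$dbeta)
      },
      relu = {
        cc <- get(node$name, envir = fwd$cache)
        acc(node$inputs, g * (cc$x > 0))
      },
      lrelu = {
        cc <- get(node$name, envir = fwd$cache)
        dx <- g
        dx[cc$x < 0] <- node$slope * g[cc$x < 0]
        acc(node$inputs, dx)
      },
      sigmoid = {
        cc <- get(node$name, envir = fwd$cache)
        acc(node$inputs, g * cc$y * (1 - cc$y))
      },
      dropout = {
        if (exists(node$name, envir = fwd$cache, inherits = FALSE)) {
          acc(node$inputs, g * get(node$name, envir = fwd$cache))
        } else {
          acc(node$inputs, g)
        }
      },
      concat = {
        at <- 0L
        for (inp in node$inputs) {
          nc <- dim(get(inp, envir = fwd$act))[3]
          acc(inp, g[, , at + seq_len(nc), , drop = FALSE])
          at <- at + nc
        }
      }
    )
  }
  pgrads
}

# --- loss ------------------------------------------------------------------

# Soft Dice over each sample, averaged; returns loss and d(loss)/d(pred).
dice_loss <- function(pred, target, eps = 1e-6) {
  B <- dim(pred)[4]
  loss <- 0
  grad <- array(0, dim(pred))
  for (b in seq_len(B)) {
    p <- pred[, , , b]; g <- target[, , , b]
    num <- 2 * sum(p * g) + eps
    den <- sum(p) + sum(g) + eps
    loss <- loss + (1 - num / den)
    grad[, , , b] <- -(2 * g * den - num) / den^2 / B
  }
  list(loss = loss / B, grad = grad)
}

bce_loss <- function(pred, target, eps = 1e-7) {
  p <- pmin(pmax(pred, eps), 1 - eps)
  n <- length(p)
  list(loss = -sum(target * log(p) + (1 - target) * log(1 - p)) / n,
       grad = array((p - target) / (p * (1 - p)) / n, dim(pred)))
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) lapply(p, function(v) {
    list(m = v * 0, v = v * 0)
  }))
}

adam_step <- function(params, pgrads, opt, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(pgrads)) {
    for (pn in names(pgrads[[nm]])) {
      g <- pgrads[[nm]][[pn]]
      st <- opt[[nm]][[pn]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      params[[nm]][[pn]] <- params[[nm]][[pn]] - lr * mhat / (sqrt(vhat) + eps)
      opt[[nm]][[pn]] <- st
    }
  }
  list(params = params, opt = opt)
}
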