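#' Segmentation network configuration
#'
#' The architecture downsamples exclusively with strided convolutions (no
#' pooling layers exist anywhere in the model): the full-resolution stem uses
#' stride 1 and every deeper encoder level a `encoder_stride x encoder_stride`
#' stride. The decoder path upsamples with transposed convolutions. With
#' `nested = TRUE` a grid of nested skip nodes is added: a node at level `i`,
#' column `j >= 1` up-convolves the level-`i+1` node of the previous column,
#' applies ReLU and batch normalization, concatenates its same-level inputs
#' (the encoder feature for `j = 1`; the previous nested node plus the
#' encoder feature for `j >= 2`), and fuses the channels with a 1x1
#' convolution. With `deep_supervision = TRUE` all full-resolution nested
#' outputs are concatenated and fused by a 1x1 convolution + sigmoid into the
#' single-channel probability map.
#'
#' The default filter widths (9, 18, 36, 72, 144) double per level from a
#' base width calibrated once so that the analytic operation count of the
#' default nested model at 320 x 480 x 1 lands on the architecture's nominal
#' ~1.5e10 FLOPs; they are frozen here.
#'
#' @param depth Number of encoder levels (default 5).
#' @param filters_per_level Channel count per level; length must equal `depth`.
#' @param kernel_size Odd convolution kernel size (default 5).
#' @param encoder_stride Downsampling stride (default 2).
#' @param leaky_slope Negative slope of the encoder leaky ReLU (default 0.2).
#' @param dropout_rate Dropout probability in the plain decoder (default 0.5).
#' @param input_shape `(rows, cols, channels)`, default `c(320, 480, 1)`.
#' @param nested `TRUE` for the nested variant, `FALSE` for the plain
#'   encoder-decoder baseline.
#' @param deep_supervision Fuse all top-level nested outputs (default: same
#'   as `nested`).
#' @return A validated list of class `network_config`.
#' @export
network_config <- function(depth = 5L,
                           filters_per_level = NULL,
                           kernel_size = 5L,
                           encoder_stride = 2L,
                           leaky_slope = 0.2,
                           dropout_rate = 0.5,
                           input_shape = c(320L, 480L, 1L),
                           nested = TRUE,
                           deep_supervision = nested) {
  if (is.null(filters_per_level)) {
    filters_per_level <- if (depth == 5L) {
      c(9L, 18L, 36L, 72L, 144L)
    } else {
      pmin(9L * 2L^(seq_len(depth) - 1L), 144L)
    }
  }
  cfg <- structure(
    list(depth = as.integer(depth),
         filters_per_level = as.integer(filters_per_level),
         kernel_size = as.integer(kernel_size),
         encoder_stride = as.integer(encoder_stride),
         leaky_slope = leaky_slope,
         dropout_rate = dropout_rate,
         input_shape = as.integer(input_shape),
         nested = isTRUE(nested),
         deep_supervision = isTRUE(deep_supervision)),
    class = "network_config")
  validate_network_config(cfg)
  cfg
}

validate_network_config <- function(cfg) {
  problems <- character()
  if (cfg$depth < 2L) problems <- c(problems, "depth must be >= 2")
  if (length(cfg$filters_per_level) != cfg$depth) {
    problems <- c(problems, sprintf("filters_per_level must have length depth (%d)", cfg$depth))
  }
  if (any(cfg$filters_per_level < 1L)) {
    problems <- c(problems, "all filter counts must be >= 1")
  }
  if (cfg$kernel_size %% 2L != 1L || cfg$kernel_size < 1L) {
    problems <- c(problems, "kernel_size must be a positive odd integer")
  }
  if (length(cfg$input_shape) != 3L) {
    problems <- c(problems, "input_shape must be (rows, cols, channels)")
  } else {
    div <- cfg$encoder_stride^(cfg$depth - 1L)
    if (cfg$input_shape[1] %% div != 0L || cfg$input_shape[2] %% div != 0L) {
      problems <- c(problems, sprintf(
        "input rows and cols must be divisible by encoder_stride^(depth-1) = %d", div))
    }
  }
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) {
    problems <- c(problems, "dropout_rate must lie in [0, 1)")
  }
  if (length(problems)) abort(paste(problems, collapse = "; "))
  invisible(cfg)
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam, batch size 32, at
#' most 47 epochs, learning rate 1e-4, weights initialized from a normal
#' distribution with mean 0 and standard deviation 0.02, Dice loss (the model
#' selection metric is Dice, so the loss matches it).
#'
#' @param batch_size Minibatch size (>= 1).
#' @param max_steps Maximum training epochs.
#' @param learning_rate Adam learning rate (> 0; 0 allowed and performs no
#'   updates, useful for diagnostics).
#' @param loss `"dice"` or `"bce"`.
#' @param init_sd Standard deviation of the normal weight initializer.
#' @param validation_fraction Fraction of the dataset held out for the
#'   per-epoch validation Dice.
#' @param seed Integer seed controlling the split, shuffling, and dropout.
#' @return A validated list of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, max_steps = 47L,
                         learning_rate = 1e-4, loss = c("dice", "bce"),
                         init_sd = 0.02, validation_fraction = 0.2,
                         seed = 1L) {
  loss <- match.arg(loss)
  if (batch_size < 1L) abort("batch_size must be >= 1")
  if (learning_rate < 0) abort("learning_rate must be >= 0")
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    abort("validation_fraction must lie in (0, 1)")
  }
  structure(list(batch_size = as.integer(batch_size),
                 max_steps = as.integer(max_steps),
                 learning_rate = learning_rate,
                 optimizer = "adam",
                 loss = loss, init_sd = init_sd,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

# --- graph construction ----------------------------------------------------

build_graph <- function(cfg) {
  d <- cfg$depth
  f <- cfg$filters_per_level
  K <- cfg$kernel_size
  s <- cfg$encoder_stride
  pad <- (K - 1L) %/% 2L
  in_ch <- cfg$input_shape[3]
  nodes <- list()
  nodes <- add_node(nodes, "input", "input")
  ch <- integer()  # output channels per named node

  conv_block <- function(nodes, name, input, cin, cout, k, stride,
                         act = "lrelu") {
    nodes <- add_node(nodes, paste0(name, "_conv"), "conv", input,
                      k = k, stride = stride, pad = (k - 1L) %/% 2L,
                      cin = cin, cout = cout)
    nodes <- add_node(nodes, paste0(name, "_bn"), "bn", paste0(name, "_conv"),
                      channels = cout)
    add_node(nodes, paste0(name, "_act"), act, paste0(name, "_bn"),
             slope = cfg$leaky_slope)
  }

  # encoder: full-resolution stem (stride 1) + d-1 strided levels
  for (i in seq_len(d) - 1L) {
    cin <- if (i == 0L) in_ch else f[i]
    nodes <- conv_block(nodes, sprintf("e%d", i), if (i == 0L) "input"
                        else sprintf("e%d_act", i - 1L),
                        cin, f[i + 1L], K, if (i == 0L) 1L else s)
    ch[sprintf("e%d_act", i)] <- f[i + 1L]
  }

  node_out <- function(i, j) {
    if (j == 0L) sprintf("e%d_act", i) else sprintf("n%d%d_act", i, j)
  }

  if (cfg$nested) {
    for (j in seq_len(d - 1L)) {
      for (i in 0:(d - 1L - j)) {
        nm <- sprintf("n%d%d", i, j)
        lower <- node_out(i + 1L, j - 1L)
        skips <- if (j == 1L) node_out(i, 0L) else
          c(node_out(i, j - 1L), node_out(i, 0L))
        nodes <- add_node(nodes, paste0(nm, "_up"), "convt", lower,
                          k = K, stride = s, pad = pad,
                          cin = ch[lower], cout = f[i + 1L])
        nodes <- add_node(nodes, paste0(nm, "_uprelu"), "relu", paste0(nm, "_up"))
        nodes <- add_node(nodes, paste0(nm, "_upbn"), "bn", paste0(nm, "_uprelu"),
                          channels = f[i + 1L])
        cat_in <- c(paste0(nm, "_upbn"), skips)
        cat_ch <- f[i + 1L] + sum(ch[skips])
        nodes <- add_node(nodes, paste0(nm, "_cat"), "concat", cat_in)
        nodes <- add_node(nodes, paste0(nm, "_fuse"), "conv", paste0(nm, "_cat"),
                          k = 1L, stride = 1L, pad = 0L,
                          cin = cat_ch, cout = f[i + 1L])
        nodes <- add_node(nodes, paste0(nm, "_act"), "relu", paste0(nm, "_fuse"))
        ch[paste0(nm, "_act")] <- f[i + 1L]
      }
    }
    head_in <- if (cfg$deep_supervision) {
      top <- vapply(seq_len(d - 1L), function(j) node_out(0L, j), character(1))
      nodes <- add_node(nodes, "head_cat", "concat", top)
      ch["head_cat"] <- sum(ch[top])
      "head_cat"
    } else {
      node_out(0L, d - 1L)
    }
    nodes <- add_node(nodes, "head_conv", "conv", head_in,
                      k = 1L, stride = 1L, pad = 0L,
                      cin = ch[head_in], cout = 1L)
  } else {
    prev <- node_out(d - 1L, 0L)
    for (i in (d - 2L):0L) {
      nm <- sprintf("d%d", i)
      nodes <- add_node(nodes, paste0(nm, "_up"), "convt", prev,
                        k = K, stride = s, pad = pad,
                        cin = ch[prev], cout = f[i + 1L])
      nodes <- add_node(nodes, paste0(nm, "_bn"), "bn", paste0(nm, "_up"),
                        channels = f[i + 1L])
      nodes <- add_node(nodes, paste0(nm, "_act"), "relu", paste0(nm, "_bn"))
      nodes <- add_node(nodes, paste0(nm, "_drop"), "dropout", paste0(nm, "_act"),
                        rate = cfg$dropout_rate)
      nodes <- add_node(nodes, paste0(nm, "_cat"), "concat",
                        c(paste0(nm, "_drop"), node_out(i, 0L)))
      ch[paste0(nm, "_cat")] <- f[i + 1L] + ch[node_out(i, 0L)]
      prev <- paste0(nm, "_cat")
    }
    nodes <- add_node(nodes, "head_conv", "conv", prev,
                      k = 1L, stride = 1L, pad = 0L,
                      cin = ch[prev], cout = 1L)
  }
  nodes <- add_node(nodes, "out", "sigmoid", "head_conv")
  list(nodes = nodes, out_name = "out", channels = ch)
}

# --- model -----------------------------------------------------------------

#' Build a segmentation model
#'
#' Instantiates the computation graph of [network_config()] and initializes
#' all convolution weights from `N(0, init_sd^2)` under the given seed
#' (batch-norm scales start at 1, offsets and biases at 0). Identical config
#' and seed give bit-identical initial weights.
#'
#' @param config A [network_config()].
#' @param seed Integer seed for initialization.
#' @param init_sd Normal initializer standard deviation (default 0.02).
#' @return An object of class `unet_model`.
#' @export
build_model <- function(config = network_config(), seed = 1L, init_sd = 0.02) {
  validate_network_config(config)
  graph <- build_graph(config)
  params <- list()
  state <- list()
  with_seed(seed, {
    for (node in graph$nodes) {
      if (node$op == "conv") {
        params[[node$name]] <- list(
          w = matrix(rnorm(node$k^2 * node$cin * node$cout, 0, init_sd),
                     node$k^2 * node$cin, node$cout),
          b = numeric(node$cout))
      } else if (node$op == "convt") {
        params[[node$name]] <- list(
          w = matrix(rnorm(node$k^2 * node$cout * node$cin, 0, init_sd),
                     node$k^2 * node$cout, node$cin),
          b = numeric(node$cout))
      } else if (node$op == "bn") {
        params[[node$name]] <- list(gamma = rep(1, node$channels),
                                    beta = numeric(node$channels))
        state[[node$name]] <- list(running_mean = numeric(node$channels),
                                   running_var = rep(1, node$channels))
      }
    }
  })
  structure(list(config = config, graph = graph, params = params,
                 state = state, seed = as.integer(seed)),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> %s, depth %d, filters [%s], input %s\n",
              if (x$config$nested) "nested (deep supervision)" else "plain encoder-decoder",
              x$config$depth,
              paste(x$config$filters_per_level, collapse = ", "),
              paste(x$config$input_shape, collapse = "x")))
  cat(sprintf("  %d conv/convt layers, %s parameters\n",
              sum(vapply(x$graph$nodes, function(n) n$op %in% c("conv", "convt"),
                         logical(1))),
              format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters of a model
#' @param model A `unet_model`.
#' @return Integer count.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, function(p) sum(vapply(p, length, numeric(1))),
             numeric(1)))
}

# --- FLOPs accounting ------------------------------------------------------

#' Per-layer FLOPs of a convolution
#'
#' `2 K^2 C_in C_out N`, with `N` the number of output spatial positions of
#' the layer (multiply-accumulate counted as two floating-point operations).
#'
#' @param k Kernel size, `c_in`/`c_out` channel counts, `n` output positions.
#' @return FLOPs count.
#' @export
conv_layer_flops <- function(k, c_in, c_out, n) {
  if (c_in < 1 || c_out < 1) abort("channel counts must be >= 1")
  2 * k^2 * c_in * c_out * n
}

#' Analytic FLOPs report for a network configuration
#'
#' Applies the per-layer convolution FLOPs formula to every convolution and
#' transposed convolution of the configured graph and sums; pure arithmetic,
#' no model instantiation.
#'
#' @param config A [network_config()].
#' @return Object of class `flops_report`: list with `per_layer` (tibble:
#'   layer, op, k, c_in, c_out, n, flops) and `total`.
#' @export
count_flops <- function(config = network_config()) {
  validate_network_config(config)
  graph <- build_graph(config)
  H <- config$input_shape[1]; W <- config$input_shape[2]
  dims <- list(input = c(H, W))
  rows <- list()
  for (node in graph$nodes) {
    if (node$op == "input") next
    din <- dims[[node$inputs[1]]]
    dout <- switch(node$op,
                   conv = (din + 2 * node$pad - node$k) %/% node$stride + 1,
                   convt = din * node$stride,
                   din)
    dims[[node$name]] <- dout
    if (node$op %in% c("conv", "convt")) {
      n <- prod(dout)
      rows[[node$name]] <- tibble(
        layer = node$name, op = node$op, k = node$k,
        c_in = node$cin, c_out = node$cout, n = n,
        flops = conv_layer_flops(node$k, node$cin, node$cout, n))
    }
  }
  per_layer <- dplyr::bind_rows(rows)
  structure(list(per_layer = per_layer, total = sum(per_layer$flops)),
            class = "flops_report")
}

#' @export
print.flops_report <- function(x, ...) {
  cat(sprintf("<flops_report> %d conv layers, total %.4g FLOPs\n",
              nrow(x$per_layer), x$total))
  print(x$per_layer, n = Inf)
  invisible(x)
}

#' @rdname tidy
#' @method tidy flops_report
#' @export
tidy.flops_report <- function(x, ...) x$per_layer

#' @rdname glance
#' @method glance flops_report
#' @export
glance.flops_report <- function(x, ...) {
  tibble(n_layers = nrow(x$per_layer), total_flops = x$total)
}

# --- training --------------------------------------------------------------

check_dataset <- function(images, masks, cfg) {
  if (is.null(dim(images)) || length(dim(images)) != 4L) {
    abort("images must be a (rows, cols, channels, n) array")
  }
  if (!identical(dim(images), dim(masks))) {
    abort(sprintf("mask/image shape mismatch: images %s vs masks %s",
                  paste(dim(images), collapse = "x"),
                  paste(dim(masks), collapse = "x")))
  }
  if (dim(images)[4] < 2L) abort("dataset must contain at least 2 pairs")
  if (!all(masks %in% c(0, 1))) abort("masks must be binary")
  if (!identical(dim(images)[1:3], as.integer(cfg$input_shape))) {
    abort(sprintf("dataset shape %s does not match configured input %s",
                  paste(dim(images)[1:3], collapse = "x"),
                  paste(cfg$input_shape, collapse = "x")))
  }
  invisible(TRUE)
}

#' Train a segmentation model
#'
#' Minibatch training with Adam on the configured loss; one step is one pass
#' over the training split. After every step the validation Dice (hard masks
#' at 0.5) is computed and the best-validation weights are checkpointed and
#' restored at the end. Fully reproducible given the seed.
#'
#' @param model A `unet_model` from [build_model()].
#' @param images,masks `(rows, cols, channels, n)` arrays; masks binary.
#' @param tc A [train_config()].
#' @param verbose Print per-step progress.
#' @return Object of class `unet_fit`: list with `model` (best weights),
#'   `history` (tibble: step, loss, val_dsc), `best_step`, `best_val_dsc`.
#' @export
train_model <- function(model, images, masks, tc = train_config(),
                        verbose = FALSE) {
  check_dataset(images, masks, model$config)
  n <- dim(images)[4]
  with_seed(tc$seed, {
    n_val <- max(1L, round(tc$validation_fraction * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    history <- vector("list", tc$max_steps)
    opt <- adam_init(model$params)
    best <- list(val = -Inf, params = model$params, state = model$state,
                 step = 0L)
    t_global <- 0L
    for (step in seq_len(tc$max_steps)) {
      ord <- sample(tr_idx)
      batches <- split(ord, ceiling(seq_along(ord) / tc$batch_size))
      losses <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        idx <- batches[[bi]]
        xb <- images[, , , idx, drop = FALSE]
        yb <- masks[, , , idx, drop = FALSE]
        fwd <- forward_graph(model, xb, training = TRUE)
        model <- fwd$model  # updated bn running stats
        ls <- if (tc$loss == "dice") dice_loss(fwd$output, yb) else
          bce_loss(fwd$output, yb)
        losses[bi] <- ls$loss
        if (tc$learning_rate > 0) {
          pgrads <- backward_graph(model, fwd, ls$grad)
          t_global <- t_global + 1L
          upd <- adam_step(model$params, pgrads, opt, tc$learning_rate, t_global)
          model$params <- upd$params
          opt <- upd$opt
        }
      }
      val_dsc <- evaluate_dsc(model, images[, , , val_idx, drop = FALSE],
                              masks[, , , val_idx, drop = FALSE])
      history[[step]] <- tibble(step = step, loss = mean(losses),
                                val_dsc = val_dsc)
      if (val_dsc > best$val) {
        best <- list(val = val_dsc, params = model$params,
                     state = model$state, step = step)
      }
      if (verbose) {
        message(sprintf("step %d/%d loss %.4f val_dsc %.4f",
                        step, tc$max_steps, mean(losses), val_dsc))
      }
    }
    model$params <- best$params
    model$state <- best$state
    structure(list(model = model, history = dplyr::bind_rows(history),
                   best_step = best$step, best_val_dsc = best$val,
                   train_config = tc),
              class = "unet_fit")
  })
}

# Mean hard Dice of a model over a labelled array (evaluation mode).
evaluate_dsc <- function(model, images, masks, batch = 8L) {
  n <- dim(images)[4]
  dscs <- numeric(n)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    fwd <- forward_graph(model, images[, , , idx, drop = FALSE],
                         training = FALSE)
    for (k in seq_along(idx)) {
      pm <- (fwd$output[, , 1, k] >= 0.5) * 1L
      gm <- masks[, , 1, idx[k]]
      dscs[idx[k]] <- suppressWarnings(
        overlap_metrics(matrix(as.integer(pm), dim(images)[1]),
                        matrix(as.integer(gm), dim(images)[1]))$dsc)
    }
  }
  mean(dscs)
}

#' @export
print.unet_fit <- function(x, ...) {
  cat(sprintf("<unet_fit> %d steps, best val DSC %.4f at step %d\n",
              nrow(x$history), x$best_val_dsc, x$best_step))
  invisible(x)
}

#' Tidy methods for fitted models and reports
#'
#' `tidy()` returns the per-step/-layer/-landmark table; `glance()` a one-row
#' summary.
#'
#' @param x Object to tidy.
#' @param ... Unused.
#' @name tidy
#' @method tidy unet_fit
#' @export
tidy.unet_fit <- function(x, ...) x$history

#' @rdname glance
#' @name glance
#' @method glance unet_fit
#' @export
glance.unet_fit <- function(x, ...) {
  tibble(steps = nrow(x$history),
         final_loss = x$history$loss[nrow(x$history)],
         best_val_dsc = x$best_val_dsc,
         best_step = x$best_step,
         n_params = n_params(x$model))
}

# --- inference -------------------------------------------------------------

#' Post-process a probability map into a clean binary mask
#'
#' Thresholds at `threshold`, keeps the largest 8-connected component, and
#' fills interior holes (segmentations of a solid organ are simply
#' connected).
#'
#' @param prob Numeric matrix of probabilities in `[0, 1]`.
#' @param threshold Binarization threshold (default 0.5).
#' @return Binary integer matrix.
#' @export
postprocess_probability <- function(prob, threshold = 0.5) {
  bin <- matrix(as.integer(prob >= threshold), nrow(prob), ncol(prob))
  if (!any(bin == 1L)) return(bin)
  lab <- .label8(bin)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  comp <- matrix(as.integer(lab == keep), nrow(bin), ncol(bin))
  .fill_holes(comp)
}

#' Predict a segmentation mask for one image
#'
#' Resizes the image to the model's input shape (recording the scale), runs
#' the network in evaluation mode, maps the probability map back to the
#' original frame, and post-processes it with [postprocess_probability()].
#'
#' @param model A `unet_model` or `unet_fit`.
#' @param image A [scan_image] or numeric grayscale matrix.
#' @param threshold Binarization threshold.
#' @return List with `prob` (probability matrix, original frame) and `mask`
#'   (binary matrix, original frame).
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  if (inherits(model, "unet_fit")) model <- model$model
  px <- if (inherits(image, "scan_image")) image$pixels else image
  if (!is.matrix(px)) {
    abort("image must be a grayscale matrix (single channel)")
  }
  shape <- model$config$input_shape
  H0 <- nrow(px); W0 <- ncol(px)
  xs <- resize_bilinear(px, shape[1], shape[2])
  x <- array(xs, c(shape[1], shape[2], 1L, 1L))
  fwd <- forward_graph(model, x, training = FALSE)
  prob_net <- matrix(fwd$output[, , 1, 1], shape[1], shape[2])
  prob <- resize_bilinear(prob_net, H0, W0)
  list(prob = prob, mask = postprocess_probability(prob, threshold))
}

# --- model persistence -----------------------------------------------------

#' Save / load model weights
#'
#' Weights, batch-norm state, and the generating config are stored with
#' `saveRDS`; `load_model` rebuilds the graph from the stored config and
#' restores the weights.
#'
#' @param model A `unet_model` or `unet_fit`.
#' @param path File path (`.rds`).
#' @return `load_model` returns a `unet_model`.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "unet_fit")) model <- model$model
  saveRDS(list(config = unclass(model$config), params = model$params,
               state = model$state, seed = model$seed), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  cfg <- do.call(network_config, obj$config[c(
    "depth", "filters_per_level", "kernel_size", "encoder_stride",
    "leaky_slope", "dropout_rate", "input_shape", "nested", "deep_supervision")])
  model <- build_model(cfg, seed = obj$seed)
  model$params <- obj$params
  model$state <- obj$state
  model
}

# --- hyperparameter grid search -------------------------------------------

#' Exhaustive hyperparameter grid search
#'
#' Evaluates every combination of the supplied grid (rows of
#' `expand.grid(grid)`, first parameter varying fastest) by calling
#' `train_fn(combo)` then `eval_fn(fit)`, and returns the combination with
#' the highest score. Ties are broken by the first occurrence in iteration
#' order.
#'
#' @param grid Named list of parameter value vectors (e.g. `learning_rate`,
#'   `batch_size`, `kernel_size`).
#' @param train_fn Function of one argument (a named list: one combination).
#' @param eval_fn Function of `train_fn`'s return; must return a single
#'   numeric score (mean validation Dice).
#' @return List with `best` (named list), `best_score`, and `results` (tibble
#'   of all combinations and scores).
#' @export
grid_search <- function(grid, train_fn, eval_fn) {
  if (!length(grid) || any(!lengths(grid))) {
    abort("grid must contain at least one value for every parameter")
  }
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  scores <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    combo <- as.list(combos[i, , drop = FALSE])
    scores[i] <- eval_fn(train_fn(combo))
  }
  best_i <- which.max(scores)  # first maximum = first in iteration order
  list(best = as.list(combos[best_i, , drop = FALSE]),
       best_score = scores[best_i],
       results = as_tibble(cbind(combos, score = scores)))
}
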