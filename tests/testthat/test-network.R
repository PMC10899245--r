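test_that("configuration invariants are enforced", {
  expect_error(network_config(input_shape = c(100L, 100L, 1L)),
               "divisible by encoder_stride")
  expect_error(network_config(depth = 3, filters_per_level = c(4L, 8L)),
               "length depth")
  expect_error(network_config(depth = 3, filters_per_level = c(4L, 8L, 0L),
                              input_shape = c(64L, 64L, 1L)),
               ">= 1")
  expect_error(train_config(batch_size = -1), "batch_size")
})

test_that("model output matches input spatial size with values in [0, 1]", {
  for (nested in c(TRUE, FALSE)) {
    cfg <- tiny_config(nested = nested)
    model <- build_model(cfg, seed = 1)
    x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
    out <- renalus:::forward_graph(model, x)$output
    expect_equal(dim(out), c(32, 32, 1, 2))
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("no pooling layers exist anywhere in the graph", {
  for (nested in c(TRUE, FALSE)) {
    ops <- vapply(build_model(tiny_config(nested = nested))$graph$nodes,
                  `[[`, character(1), "op")
    expect_false(any(grepl("pool", ops)))
    expect_true(all(ops %in% c("input", "conv", "convt", "bn", "relu",
                               "lrelu", "sigmoid", "dropout", "concat")))
  }
})

test_that("the plain variant has encoder + decoder layers and no nested nodes", {
  nodes <- build_model(tiny_config(nested = FALSE))$graph$nodes
  nms <- names(nodes)
  expect_false(any(grepl("^n\\d", nms)))
  d <- 3L
  expect_equal(sum(vapply(nodes, function(n) n$op == "conv" &&
                            grepl("^e", n$name), logical(1))), d)
  expect_equal(sum(vapply(nodes, function(n) n$op == "convt", logical(1))),
               d - 1L)
})

test_that("identical config and seed give identical models", {
  cfg <- tiny_config()
  m1 <- build_model(cfg, seed = 99)
  m2 <- build_model(cfg, seed = 99)
  expect_identical(m1$params, m2$params)
  expect_equal(n_params(m1), n_params(m2))
  m3 <- build_model(cfg, seed = 100)
  expect_false(identical(m1$params, m3$params))
})

test_that("FLOPs accounting is exact per layer and pinned in total", {
  expect_equal(conv_layer_flops(5, 1, 16, 64 * 64), 3276800)
  expect_error(conv_layer_flops(5, 1, 0, 64), ">= 1")

  fr <- count_flops(network_config())
  expect_s3_class(fr$per_layer, "tbl_df")
  expect_equal(fr$total, sum(fr$per_layer$flops))
  expect_equal(fr$per_layer$flops,
               with(fr$per_layer, 2 * k^2 * c_in * c_out * n))
  # pinned to the nominal architecture cost at 320x480x1
  expect_lt(abs(fr$total - 1.5e10) / 1.5e10, 0.1)
})

test_that("FLOPs are invariant to weights and batch size", {
  cfg <- tiny_config()
  f1 <- count_flops(cfg)
  f2 <- count_flops(cfg)  # pure arithmetic: no model, no data
  expect_identical(f1$total, f2$total)
  m <- build_model(cfg, seed = 1)
  m$params$e0_conv$w[] <- 1000
  expect_identical(count_flops(m$config)$total, f1$total)
})

test_that("zero learning rate leaves the loss unchanged across steps", {
  d <- phantom_training_set(8, seed = 3, shape = c(32L, 32L))
  model <- build_model(tiny_config(), seed = 2)
  fit <- train_model(model, d$images, d$masks,
                     train_config(batch_size = 8L, max_steps = 3L,
                                  learning_rate = 0, validation_fraction = 0.25,
                                  seed = 4))
  expect_equal(nrow(fit$history), 3)  # history length == completed steps
  expect_lt(diff(range(fit$history$loss)), 1e-10)
  expect_identical(fit$model$params, model$params)
})

test_that("training errors on malformed datasets", {
  model <- build_model(tiny_config(), seed = 1)
  img <- array(0, c(32, 32, 1, 4))
  expect_error(train_model(model, img, array(0, c(32, 32, 1, 3))),
               "mismatch")
  expect_error(train_model(model, img[, , , 1, drop = FALSE],
                           img[, , , 1, drop = FALSE]),
               "at least 2")
  bad <- img; bad[1] <- 0.5
  expect_error(train_model(model, img, bad), "binary")
})

test_that("a short training run reduces the Dice loss on phantoms", {
  d <- phantom_training_set(24, seed = 5, shape = c(32L, 32L))
  cfg <- network_config(depth = 3L, filters_per_level = c(4L, 8L, 16L),
                        kernel_size = 3L, input_shape = c(32L, 32L, 1L))
  model <- build_model(cfg, seed = 1)
  fit <- train_model(model, d$images, d$masks,
                     train_config(batch_size = 8L, max_steps = 50L,
                                  learning_rate = 3e-3, seed = 1))
  expect_lt(fit$history$loss[50], fit$history$loss[1])
  expect_gt(fit$best_val_dsc, 0.8)
  h <- tidy(fit)
  expect_named(h, c("step", "loss", "val_dsc"))
  expect_equal(glance(fit)$n_params, n_params(fit$model))
})

test_that("training is reproducible under a fixed seed", {
  d <- phantom_training_set(12, seed = 6, shape = c(32L, 32L))
  run <- function() {
    train_model(build_model(tiny_config(), seed = 3), d$images, d$masks,
                train_config(batch_size = 6L, max_steps = 2L,
                             learning_rate = 1e-3, seed = 9))
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("probability post-processing keeps the largest component, hole-free", {
  prob <- matrix(0, 40, 40)
  expect_equal(sum(postprocess_probability(prob)), 0)   # empty stays empty

  blob <- matrix(0, 40, 40)
  blob[5:25, 5:25] <- 1
  expect_equal(postprocess_probability(blob),
               matrix(as.integer(blob), 40, 40))        # idempotent on a blob

  two <- matrix(0, 40, 40)
  two[2:26, 2:21] <- 0.9                                # 500 px blob
  two[31:35, 31:34] <- 0.9                              # 20 px blob
  out <- postprocess_probability(two)
  expect_equal(sum(out), 500)
  expect_equal(sum(out[31:35, 31:34]), 0)

  holed <- matrix(0, 40, 40)
  holed[5:20, 5:20] <- 1; holed[10:12, 10:12] <- 0
  expect_equal(sum(postprocess_probability(holed)), 16 * 16)
})

test_that("predict_mask resizes to and from the model frame", {
  model <- build_model(tiny_config(), seed = 1)
  img <- matrix(runif(50 * 70), 50, 70)
  pred <- predict_mask(model, img)
  expect_equal(dim(pred$prob), c(50, 70))
  expect_true(all(pred$prob >= 0 & pred$prob <= 1))
  expect_true(all(pred$mask %in% c(0L, 1L)))
  expect_error(predict_mask(model, array(0, c(32, 32, 3))), "grayscale")
})

test_that("grid search is exhaustive with first-occurrence tie-breaking", {
  single <- grid_search(list(learning_rate = 0.01),
                        train_fn = identity, eval_fn = function(c) 1)
  expect_equal(single$best$learning_rate, 0.01)

  grid <- list(learning_rate = c(1e-4, 1e-3, 1e-2), batch_size = c(8, 16))
  res <- grid_search(grid, train_fn = identity,
                     eval_fn = function(combo) combo$learning_rate)
  expect_equal(res$best$learning_rate, 1e-2)
  expect_equal(nrow(res$results), 6)

  tied <- grid_search(list(kernel_size = c(3, 5)), train_fn = identity,
                      eval_fn = function(combo) 0.5)
  expect_equal(tied$best$kernel_size, 3)  # first in iteration order
  expect_error(grid_search(list(), identity, identity), "grid")
})

test_that("models round-trip through save and load", {
  withr::with_tempfile("f", fileext = ".rds", {
    model <- build_model(tiny_config(), seed = 12)
    save_model(model, f)
    re <- load_model(f)
    expect_identical(re$params, model$params)
    x <- array(runif(32 * 32), c(32, 32, 1, 1))
    expect_equal(renalus:::forward_graph(re, x)$output,
                 renalus:::forward_graph(model, x)$output)
  })
})
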