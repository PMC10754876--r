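test_that("every signal architecture builds and outputs probabilities", {
  rng <- local_rng(31)
  x <- array(rng$rnorm(3 * 101 * 9), c(3, 101, 9))
  for (nm in c("mlp_4_200", "lstm_4_500", "fcn", "resnet1d", "encoder",
               "tlenet", "transformer1d")) {
    m <- build_signal_model(nm, seed = 32)
    xin <- if (nm == "mlp_4_200") gaitcast:::flatten_batch(x) else x
    p <- predict_model(m, xin)
    expect_length(p, 3L)
    expect_true(all(p > 0 & p < 1), label = nm)
  }
})

test_that("the tuned MLP is four hidden layers of 200 on the 909 vector", {
  m <- build_signal_model("mlp_4_200")
  dense <- Filter(function(l) l$type == "dense", m$layers)
  expect_length(dense, 5L)
  expect_equal(dense[[1]]$d_in, 909L)
  expect_equal(vapply(dense[1:4], `[[`, numeric(1), "d_out"), rep(200, 4))
  expect_equal(dense[[5]]$d_out, 1L)
})

test_that("the stacked LSTM has 4 layers of 500 units with pre-output dropout", {
  m <- build_signal_model("lstm_4_500")
  expect_identical(vapply(m$layers, `[[`, character(1), "type"),
                   c("lstm", "dropout", "dense"))
  expect_equal(m$layers[[1]]$n_layers, 4L)
  expect_equal(m$layers[[1]]$units, 500L)
})

test_that("reference 1D designs keep their layer inventories", {
  fcn <- build_signal_model("fcn")
  convs <- Filter(function(l) l$type == "conv1d", fcn$layers)
  expect_equal(vapply(convs, `[[`, numeric(1), "c_out"), c(128, 256, 128))
  expect_equal(vapply(convs, `[[`, numeric(1), "k"), c(8, 5, 3))
  expect_equal(sum(vapply(fcn$layers, function(l)
    l$type == "batchnorm", logical(1))), 3L)
  expect_identical(fcn$layers[[length(fcn$layers) - 1L]]$type, "gap1d")

  res <- build_signal_model("resnet1d")
  blocks <- Filter(function(l) l$type == "residual1d", res$layers)
  expect_length(blocks, 3L)
  branch_kernels <- function(b) vapply(Filter(function(l)
    l$type == "conv1d", b$branch), `[[`, numeric(1), "k")
  for (b in blocks) expect_equal(branch_kernels(b), c(8, 5, 3))
  # channel-changing blocks project the shortcut; the last does not
  expect_identical(blocks[[1]]$shortcut[[1]]$type, "conv1d")
  expect_identical(blocks[[2]]$shortcut[[1]]$type, "conv1d")
  expect_identical(blocks[[3]]$shortcut[[1]]$type, "batchnorm")

  enc <- build_signal_model("encoder")
  enc_convs <- Filter(function(l) l$type == "conv1d", enc$layers)
  expect_equal(vapply(enc_convs, `[[`, numeric(1), "c_out"), c(128, 256, 512))
  expect_equal(vapply(enc_convs, `[[`, numeric(1), "k"), c(5, 11, 21))
  expect_true(any(vapply(enc$layers, function(l)
    l$type == "attention_split", logical(1))))

  tle <- build_signal_model("tlenet")
  tle_convs <- Filter(function(l) l$type == "conv1d", tle$layers)
  expect_equal(vapply(tle_convs, `[[`, numeric(1), "c_out"), c(5, 20))

  tr <- build_signal_model("transformer1d")
  expect_equal(sum(vapply(tr$layers, function(l)
    l$type == "transformer_block", logical(1))), 4L)
  expect_equal(Filter(function(l) l$type == "transformer_block",
                      tr$layers)[[1]]$n_heads, 4L)
})

test_that("the tailored CNN follows its tuned layer plan", {
  m <- build_image_model("tailored_cnn")
  types <- vapply(m$layers, `[[`, character(1), "type")
  expect_identical(types, c("conv2d", "relu", "conv2d", "relu", "dropout",
                            "maxpool2d", "batchnorm", "flatten", "dense",
                            "dense"))
  convs <- Filter(function(l) l$type == "conv2d", m$layers)
  expect_equal(vapply(convs, `[[`, numeric(1), "c_out"), c(4, 4))
  expect_equal(convs[[1]]$kh, 32L)
  # 8x8 pooling of the 101x9 map leaves 12x1 cells over 4 channels = 48
  dense <- Filter(function(l) l$type == "dense", m$layers)
  expect_equal(dense[[1]]$d_in, 48L)
  expect_equal(dense[[1]]$d_out, 300L)

  rng <- local_rng(33)
  xi <- array(rng$rnorm(3 * 101 * 9), c(3, 101, 9, 1))
  p <- predict_model(m, xi)
  expect_true(all(p > 0 & p < 1))
})

test_that("backbones below the minimum input size are rejected", {
  expect_error(build_image_model(architecture_spec("vgg16",
                                 input_shape = c(101, 9, 1))), "32")
  expect_s3_class(build_image_model(architecture_spec("vgg16",
                                    input_shape = c(101, 36, 1))),
                  "nn_inventory")
})

test_that("parameter counting is exact, convention-aware and build-stable", {
  rng <- local_rng(34)
  one <- gaitcast:::nn_model("probe", "flat",
                             list(gaitcast:::layer_dense(10L, 1L, rng)))
  expect_equal(count_parameters(one), 11)

  a <- count_parameters(build_signal_model("fcn", seed = 1))
  b <- count_parameters(build_signal_model("fcn", seed = 99))
  expect_identical(a, b)

  cnn <- build_image_model("tailored_cnn")
  expect_equal(count_parameters(cnn, "learnable_plus_norm_stats") -
                 count_parameters(cnn, "learnable_only"), 8)

  inv <- build_image_model("resnet34")
  expect_gt(count_parameters(inv, "learnable_plus_norm_stats"),
            count_parameters(inv, "learnable_only"))

  tab <- list_models()
  expect_equal(nrow(tab), 12L)
  expect_true(all(tab$learnable_plus_norm_stats >= tab$learnable))
})

test_that("random hyperparameter search is seeded and returns the argmax", {
  fake_train <- function(spec) {
    # deterministic surrogate objective: no model fitting needed
    with(spec$hyperparameters,
         1 / (1 + abs(num_filters - 8)) + units / 1000 + lr)
  }
  r1 <- random_search_tailored_cnn(list(), budget = 6L, seed = 35,
                                   train_fn = fake_train)
  r2 <- random_search_tailored_cnn(list(), budget = 6L, seed = 35,
                                   train_fn = fake_train)
  expect_identical(r1$evaluated, r2$evaluated)
  expect_equal(r1$best_val_auc, max(r1$evaluated$val_auc))
  single <- random_search_tailored_cnn(list(), budget = 1L, seed = 36,
                                       train_fn = fake_train)
  expect_equal(nrow(single$evaluated), 1L)
  expect_s3_class(single$best_spec, "architecture_spec")
  expect_error(random_search_tailored_cnn(list(units = integer(0)),
                                          budget = 1L, seed = 1,
                                          train_fn = fake_train), "empty")
})
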