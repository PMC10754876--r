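# Classifier architectures: signal-based 1D models consuming (101, 9) cycles
# (the MLP takes the 909-sample flattened vector) and image-based 2D models
# consuming FFT spectrum images, all ending in a single sigmoid output unit.
# Large pretrained-style backbones (VGG16, ResNet34, EfficientNet-B0,
# ViT-B/16) are represented as exact per-layer parameter inventories: they
# are constructed for architecture inspection and parameter counting, not
# materialized as trainable weight tensors.

SIGNAL_MODELS <- c("mlp_4_200", "lstm_4_500", "fcn", "resnet1d", "encoder",
                   "tlenet", "transformer1d")
IMAGE_MODELS <- c("tailored_cnn", "vgg16", "resnet34", "efficientnet_b0",
                  "vit_b16")

#' Describe a classifier architecture
#'
#' @param name One of `r paste0('"', c("mlp_4_200", "lstm_4_500", "fcn",
#'   "resnet1d", "encoder", "tlenet", "transformer1d", "tailored_cnn",
#'   "vgg16", "resnet34", "efficientnet_b0", "vit_b16"), '"', collapse = ", ")`.
#' @param hyperparameters Named list overriding the architecture's defaults
#'   (see [build_signal_model()] / [build_image_model()] for the recognised
#'   names per family).
#' @param input_shape `c(time, channels)` for 1D models (the MLP consumes the
#'   flattened 909 vector), `c(height, width, channels)` for 2D models.
#' @return An `architecture_spec` list.
#' @export
architecture_spec <- function(name, hyperparameters = list(),
                              input_shape = NULL) {
  name <- match.arg(name, c(SIGNAL_MODELS, IMAGE_MODELS))
  if (is.null(input_shape)) {
    input_shape <- if (name %in% SIGNAL_MODELS) c(101L, 9L) else c(101L, 9L, 1L)
    if (name %in% c("vgg16", "resnet34", "efficientnet_b0", "vit_b16")) {
      input_shape <- c(101L, 36L, 1L)
    }
  }
  structure(list(name = name, hyperparameters = hyperparameters,
                 input_shape = as.integer(input_shape)),
            class = "architecture_spec")
}

hp <- function(spec, key, default) {
  v <- spec$hyperparameters[[key]]
  if (is.null(v)) default else v
}

#' Build a signal-based (1D) classifier
#'
#' Constructs one of the time-series classifiers: the tuned MLP (4 hidden
#' layers of 200 neurons on the flattened 909-sample cycle), the stacked LSTM
#' (4 layers of 500 units, dropout before the output layer), or the reference
#' 1D designs FCN, ResNet, Encoder, t-LeNet and an encoder-only Transformer.
#' All end in a single-unit sigmoid output.
#'
#' @param spec An [architecture_spec()] with a 1D family name, or the name
#'   itself.
#' @param seed Integer seed for weight initialization.
#' @return An `nn_model`.
#' @export
build_signal_model <- function(spec, seed = 1L) {
  if (is.character(spec)) spec <- architecture_spec(spec)
  stopifnot(spec$name %in% SIGNAL_MODELS)
  rng <- local_rng(seed)
  Tt <- spec$input_shape[1]; C <- spec$input_shape[2]
  stopifnot(Tt == 101L, C == 9L)
  layers <- switch(spec$name,
    mlp_4_200 = {
      n_layers <- hp(spec, "num_layers", 4L)
      units <- hp(spec, "units", 200L)
      ls <- list()
      d <- Tt * C
      for (i in seq_len(n_layers)) {
        ls[[length(ls) + 1L]] <- layer_dense(d, units, rng, "relu")
        d <- units
      }
      ls[[length(ls) + 1L]] <- layer_dense(d, 1L, rng)
      ls
    },
    lstm_4_500 = {
      units <- hp(spec, "units", 500L)
      n_layers <- hp(spec, "num_layers", 4L)
      list(layer_lstm(C, units, n_layers, rng),
           layer_dropout(hp(spec, "dropout", 0.2)),
           layer_dense(units, 1L, rng))
    },
    fcn = {
      f <- hp(spec, "filters", c(128L, 256L, 128L))
      k <- hp(spec, "kernels", c(8L, 5L, 3L))
      ls <- list(); c_in <- C
      for (i in seq_along(f)) {
        ls[[length(ls) + 1L]] <- layer_conv1d(c_in, f[i], k[i], rng)
        ls[[length(ls) + 1L]] <- layer_batchnorm(f[i])
        ls[[length(ls) + 1L]] <- layer_relu()
        c_in <- f[i]
      }
      c(ls, list(layer_gap1d(), layer_dense(c_in, 1L, rng)))
    },
    resnet1d = {
      nf <- hp(spec, "filters", 64L)
      mk_block <- function(c_in, c_out, project, rng) {
        branch <- list(
          layer_conv1d(c_in, c_out, 8L, rng), layer_batchnorm(c_out),
          layer_relu(),
          layer_conv1d(c_out, c_out, 5L, rng), layer_batchnorm(c_out),
          layer_relu(),
          layer_conv1d(c_out, c_out, 3L, rng), layer_batchnorm(c_out))
        shortcut <- if (project) {
          list(layer_conv1d(c_in, c_out, 1L, rng), layer_batchnorm(c_out))
        } else {
          list(layer_batchnorm(c_in))
        }
        layer_residual1d(branch, shortcut)
      }
      list(mk_block(C, nf, TRUE, rng),
           mk_block(nf, 2L * nf, TRUE, rng),
           mk_block(2L * nf, 2L * nf, FALSE, rng),
           layer_gap1d(),
           layer_dense(2L * nf, 1L, rng))
    },
    encoder = {
      drop <- hp(spec, "dropout", 0.2)
      list(layer_conv1d(C, 128L, 5L, rng), layer_instancenorm(),
           layer_prelu(128L), layer_dropout(drop), layer_maxpool1d(2L),
           layer_conv1d(128L, 256L, 11L, rng), layer_instancenorm(),
           layer_prelu(256L), layer_dropout(drop), layer_maxpool1d(2L),
           layer_conv1d(256L, 512L, 21L, rng), layer_instancenorm(),
           layer_prelu(512L), layer_dropout(drop),
           layer_attention_split(),
           layer_dense(256L, 256L, rng, "relu"),
           layer_dense(256L, 1L, rng))
    },
    tlenet = {
      t_after <- (Tt %/% 2L) %/% 4L
      list(layer_conv1d(C, 5L, 5L, rng), layer_relu(), layer_maxpool1d(2L),
           layer_conv1d(5L, 20L, 5L, rng), layer_relu(), layer_maxpool1d(4L),
           layer_flatten(),
           layer_dense(t_after * 20L, hp(spec, "units", 500L), rng, "relu"),
           layer_dense(hp(spec, "units", 500L), 1L, rng))
    },
    transformer1d = {
      dm <- hp(spec, "d_model", 64L)
      heads <- hp(spec, "num_heads", 4L)
      blocks <- hp(spec, "num_blocks", 4L)
      ls <- list(layer_dense(C, dm, rng), layer_positional_encoding(Tt, dm))
      for (i in seq_len(blocks)) {
        ls[[length(ls) + 1L]] <- layer_transformer_block(dm, heads, 2L * dm, rng)
      }
      c(ls, list(layer_gap1d(), layer_dense(dm, 1L, rng)))
    })
  input_kind <- if (spec$name == "mlp_4_200") "flat" else "signal"
  nn_model(spec$name, input_kind, layers)
}

#' Build an image-based (2D) classifier
#'
#' `tailored_cnn` is the compact from-scratch spectrum classifier:
#' `num_layers` stride-1 'same'-padded 2D convolutions (ReLU), dropout,
#' non-overlapping 2D max pooling, batch normalization, flatten, a dense
#' hidden layer and a single sigmoid output. Defaults are its tuned values
#' (2 layers, 4 filters, 32 x 32 kernels, dropout 0, pool 8, 300 units); it
#' consumes the untiled 101 x 9 spectrum. `vgg16`, `resnet34`,
#' `efficientnet_b0` and `vit_b16` are the standard backbones with the first
#' layer adapted to 1 input channel and the classifier replaced by a single
#' output unit; they are returned as exact parameter inventories
#' (`nn_inventory`) for counting and inspection.
#'
#' @param spec An [architecture_spec()] with a 2D family name, or the name
#'   itself.
#' @param seed Integer seed for weight initialization (tailored CNN only).
#' @return An `nn_model` (tailored_cnn) or `nn_inventory` (backbones).
#' @export
build_image_model <- function(spec, seed = 1L) {
  if (is.character(spec)) spec <- architecture_spec(spec)
  stopifnot(spec$name %in% IMAGE_MODELS)
  H <- spec$input_shape[1]; W <- spec$input_shape[2]; C <- spec$input_shape[3]
  if (spec$name == "tailored_cnn") {
    rng <- local_rng(seed)
    n_layers <- hp(spec, "num_layers", 2L)
    nf <- hp(spec, "num_filters", 4L)
    ks <- hp(spec, "kernel_size", 32L)
    drop <- hp(spec, "dropout", 0)
    pool <- hp(spec, "pool_size", 8L)
    units <- hp(spec, "units", 300L)
    ls <- list(); c_in <- C
    for (i in seq_len(n_layers)) {
      ls[[length(ls) + 1L]] <- layer_conv2d(c_in, nf, ks, ks, rng)
      ls[[length(ls) + 1L]] <- layer_relu()
      c_in <- nf
    }
    ls[[length(ls) + 1L]] <- layer_dropout(drop)
    ls[[length(ls) + 1L]] <- layer_maxpool2d(pool, pool)
    ls[[length(ls) + 1L]] <- layer_batchnorm(nf)
    ls[[length(ls) + 1L]] <- layer_flatten()
    feat <- (H %/% pool) * (W %/% pool) * nf
    ls[[length(ls) + 1L]] <- layer_dense(feat, units, rng, "relu")
    ls[[length(ls) + 1L]] <- layer_dense(units, 1L, rng)
    return(nn_model("tailored_cnn", "image", ls))
  }
  if (spec$name == "vgg16" && (H < 32L || W < 32L)) {
    stop("vgg16 requires inputs of at least 32 x 32 pixels, got ",
         H, " x ", W, call. = FALSE)
  }
  inv <- switch(spec$name,
    vgg16 = inventory_vgg16(in_ch = C, num_classes = 1L),
    resnet34 = inventory_resnet34(in_ch = C, num_classes = 1L),
    efficientnet_b0 = inventory_efficientnet_b0(in_ch = C, num_classes = 1L),
    vit_b16 = inventory_vit_b16(in_ch = C, num_classes = 1L))
  structure(list(name = spec$name, input_shape = spec$input_shape,
                 inventory = inv),
            class = "nn_inventory")
}

#' @export
print.nn_inventory <- function(x, ...) {
  cat("<nn_inventory> ", x$name, ": ", nrow(x$inventory), " modules, ",
      format(sum(x$inventory$learnable), big.mark = ","),
      " learnable parameters\n", sep = "")
  invisible(x)
}

inv_row <- function(module, learnable, norm_stats = 0) {
  data.frame(module = module, learnable = learnable,
             norm_stats = norm_stats, stringsAsFactors = FALSE)
}

inv_conv <- function(name, c_in, c_out, k_h, k_w = k_h, bias = TRUE) {
  inv_row(name, k_h * k_w * c_in * c_out + if (bias) c_out else 0L)
}

inv_bn <- function(name, c) inv_row(name, 2L * c, 2L * c)

inv_fc <- function(name, d_in, d_out) inv_row(name, d_in * d_out + d_out)

inventory_vgg16 <- function(in_ch = 3L, num_classes = 1000L) {
  cfg <- c(64, 64, NA, 128, 128, NA, 256, 256, 256, NA,
           512, 512, 512, NA, 512, 512, 512, NA)
  rows <- list()
  c_in <- in_ch
  ci <- 0L
  for (v in cfg) {
    if (is.na(v)) next
    ci <- ci + 1L
    rows[[length(rows) + 1L]] <- inv_conv(sprintf("features.conv%d", ci),
                                          c_in, v, 3L)
    c_in <- v
  }
  rows[[length(rows) + 1L]] <- inv_fc("classifier.fc1", 512L * 7L * 7L, 4096L)
  rows[[length(rows) + 1L]] <- inv_fc("classifier.fc2", 4096L, 4096L)
  rows[[length(rows) + 1L]] <- inv_fc("classifier.head", 4096L, num_classes)
  do.call(rbind, rows)
}

inventory_resnet34 <- function(in_ch = 3L, num_classes = 1000L) {
  rows <- list(
    inv_conv("conv1", in_ch, 64L, 7L, bias = FALSE),
    inv_bn("bn1", 64L))
  stages <- list(c(64L, 3L), c(128L, 4L), c(256L, 6L), c(512L, 3L))
  c_in <- 64L
  for (si in seq_along(stages)) {
    ch <- stages[[si]][1]; reps <- stages[[si]][2]
    for (bi in seq_len(reps)) {
      pre <- sprintf("layer%d.block%d", si, bi)
      rows[[length(rows) + 1L]] <- inv_conv(paste0(pre, ".conv1"), c_in, ch,
                                            3L, bias = FALSE)
      rows[[length(rows) + 1L]] <- inv_bn(paste0(pre, ".bn1"), ch)
      rows[[length(rows) + 1L]] <- inv_conv(paste0(pre, ".conv2"), ch, ch,
                                            3L, bias = FALSE)
      rows[[length(rows) + 1L]] <- inv_bn(paste0(pre, ".bn2"), ch)
      if (bi == 1L && c_in != ch) {
        rows[[length(rows) + 1L]] <- inv_conv(paste0(pre, ".downsample"),
                                              c_in, ch, 1L, bias = FALSE)
        rows[[length(rows) + 1L]] <- inv_bn(paste0(pre, ".downsample.bn"), ch)
      }
      c_in <- ch
    }
  }
  rows[[length(rows) + 1L]] <- inv_fc("fc", 512L, num_classes)
  do.call(rbind, rows)
}

inventory_efficientnet_b0 <- function(in_ch = 3L, num_classes = 1000L) {
  rows <- list(
    inv_conv("stem.conv", in_ch, 32L, 3L, bias = FALSE),
    inv_bn("stem.bn", 32L))
  # (expand ratio, output channels, repeats, kernel size)
  cfg <- list(c(1, 16, 1, 3), c(6, 24, 2, 3), c(6, 40, 2, 5),
              c(6, 80, 3, 3), c(6, 112, 3, 5), c(6, 192, 4, 5),
              c(6, 320, 1, 3))
  c_in <- 32L
  bi <- 0L
  for (blk in cfg) {
    t <- blk[1]; c_out <- blk[2]; reps <- blk[3]; k <- blk[4]
    for (r in seq_len(reps)) {
      bi <- bi + 1L
      pre <- sprintf("block%d", bi)
      c_mid <- c_in * t
      if (t != 1) {
        rows[[length(rows) + 1L]] <- inv_conv(paste0(pre, ".expand"),
                                              c_in, c_mid, 1L, bias = FALSE)
        rows[[length(rows) + 1L]] <- inv_bn(paste0(pre, ".expand.bn"), c_mid)
      }
      # depthwise conv: one k x k filter per channel
      rows[[length(rows) + 1L]] <- inv_row(paste0(pre, ".dwconv"),
                                           k * k * c_mid)
      rows[[length(rows) + 1L]] <- inv_bn(paste0(pre, ".dwconv.bn"), c_mid)
      se <- max(1L, c_in %/% 4L)   # squeeze width from block input channels
      rows[[length(rows) + 1L]] <- inv_conv(paste0(pre, ".se.reduce"),
                                            c_mid, se, 1L)
      rows[[length(rows) + 1L]] <- inv_conv(paste0(pre, ".se.expand"),
                                            se, c_mid, 1L)
      rows[[length(rows) + 1L]] <- inv_conv(paste0(pre, ".project"),
                                            c_mid, c_out, 1L, bias = FALSE)
      rows[[length(rows) + 1L]] <- inv_bn(paste0(pre, ".project.bn"), c_out)
      c_in <- c_out
    }
  }
  rows[[length(rows) + 1L]] <- inv_conv("head.conv", 320L, 1280L, 1L,
                                        bias = FALSE)
  rows[[length(rows) + 1L]] <- inv_bn("head.bn", 1280L)
  rows[[length(rows) + 1L]] <- inv_fc("classifier", 1280L, num_classes)
  do.call(rbind, rows)
}

inventory_vit_b16 <- function(in_ch = 3L, num_classes = 1000L,
                              d = 768L, depth = 12L, mlp_ratio = 4L,
                              n_patches = 196L) {
  rows <- list(
    inv_conv("patch_embed", in_ch, d, 16L),
    inv_row("cls_token", d),
    inv_row("pos_embed", (n_patches + 1L) * d))
  for (b in seq_len(depth)) {
    pre <- sprintf("block%d", b)
    rows[[length(rows) + 1L]] <- inv_row(paste0(pre, ".ln1"), 2L * d)
    rows[[length(rows) + 1L]] <- inv_fc(paste0(pre, ".attn.qkv"), d, 3L * d)
    rows[[length(rows) + 1L]] <- inv_fc(paste0(pre, ".attn.proj"), d, d)
    rows[[length(rows) + 1L]] <- inv_row(paste0(pre, ".ln2"), 2L * d)
    rows[[length(rows) + 1L]] <- inv_fc(paste0(pre, ".mlp.fc1"), d,
                                        mlp_ratio * d)
    rows[[length(rows) + 1L]] <- inv_fc(paste0(pre, ".mlp.fc2"),
                                        mlp_ratio * d, d)
  }
  rows[[length(rows) + 1L]] <- inv_row("norm", 2L * d)
  rows[[length(rows) + 1L]] <- inv_fc("head", d, num_classes)
  do.call(rbind, rows)
}

#' Count model parameters
#'
#' Two counting conventions are supported, mirroring the two deep-learning
#' frameworks' reporting styles: `"learnable_only"` sums trainable weights,
#' biases and embeddings; `"learnable_plus_norm_stats"` additionally counts
#' the running mean/variance buffers of normalization layers (the convention
#' under which frameworks report them as non-trainable parameters).
#'
#' @param model An `nn_model` or `nn_inventory`.
#' @param convention `"learnable_only"` (default) or
#'   `"learnable_plus_norm_stats"`.
#' @return Non-negative integer-valued count.
#' @export
count_parameters <- function(model,
                             convention = c("learnable_only",
                                            "learnable_plus_norm_stats")) {
  convention <- match.arg(convention)
  if (inherits(model, "nn_inventory")) {
    n <- sum(model$inventory$learnable)
    if (convention == "learnable_plus_norm_stats") {
      n <- n + sum(model$inventory$norm_stats)
    }
    return(n)
  }
  stopifnot(inherits(model, "nn_model"))
  cnt <- collect_counts(model$layers)
  n <- cnt[["learnable"]]
  if (convention == "learnable_plus_norm_stats") n <- n + cnt[["norm_stats"]]
  unname(n)
}

#' List every architecture with its parameter counts
#'
#' @return Data frame: architecture name, family, and parameter counts under
#'   both conventions.
#' @export
list_models <- function() {
  rows <- lapply(c(SIGNAL_MODELS, IMAGE_MODELS), function(nm) {
    m <- if (nm %in% SIGNAL_MODELS) build_signal_model(nm) else
      build_image_model(nm)
    data.frame(name = nm,
               family = if (nm %in% SIGNAL_MODELS) "signal" else "image",
               learnable = count_parameters(m, "learnable_only"),
               learnable_plus_norm_stats =
                 count_parameters(m, "learnable_plus_norm_stats"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Seeded random search over tailored-CNN hyperparameters
#'
#' Samples `budget` hyperparameter settings from the search space (uniformly
#' per field; the learning rate log-uniformly) for each candidate depth,
#' trains each with the supplied function and returns the specification with
#' the highest validation AUC. Deterministic for a fixed seed.
#'
#' @param search_space Named list of candidate value vectors for
#'   `num_layers`, `num_filters`, `kernel_size`, `dropout`, `pool_size`,
#'   `units`, and a length-2 range `lr`.
#' @param budget Number of sampled settings (>= 1).
#' @param seed Integer seed.
#' @param train_fn Function(spec) returning the validation AUC of the
#'   trained candidate.
#' @return List: `best_spec`, `best_val_auc`, `evaluated` (data frame of all
#'   candidates and their AUCs).
#' @export
random_search_tailored_cnn <- function(search_space, budget, seed, train_fn) {
  stopifnot(budget >= 1)
  defaults <- list(num_layers = 1:5, num_filters = c(4L, 8L, 16L, 32L),
                   kernel_size = c(3L, 8L, 16L, 32L), dropout = c(0, 0.2, 0.5),
                   pool_size = c(2L, 4L, 8L), units = c(50L, 100L, 300L),
                   lr = c(1e-4, 1e-2))
  for (nm in names(defaults)) {
    if (is.null(search_space[[nm]])) search_space[[nm]] <- defaults[[nm]]
    if (!length(search_space[[nm]])) stop("empty search dimension: ", nm,
                                          call. = FALSE)
  }
  rng <- local_rng(seed)
  pick <- function(v) v[rng$sample(length(v), size = 1L)]
  evaluated <- list()
  best <- NULL; best_auc <- -Inf
  for (i in seq_len(budget)) {
    hpars <- list(num_layers = pick(search_space$num_layers),
                  num_filters = pick(search_space$num_filters),
                  kernel_size = pick(search_space$kernel_size),
                  dropout = pick(search_space$dropout),
                  pool_size = pick(search_space$pool_size),
                  units = pick(search_space$units),
                  lr = exp(rng$runif1(log(min(search_space$lr)),
                                      log(max(search_space$lr)))))
    spec <- architecture_spec("tailored_cnn", hpars)
    auc <- train_fn(spec)
    evaluated[[i]] <- data.frame(candidate = i, val_auc = auc,
                                 num_layers = hpars$num_layers,
                                 num_filters = hpars$num_filters,
                                 kernel_size = hpars$kernel_size,
                                 dropout = hpars$dropout,
                                 pool_size = hpars$pool_size,
                                 units = hpars$units, lr = hpars$lr)
    if (auc > best_auc) { best <- spec; best_auc <- auc }
  }
  list(best_spec = best, best_val_auc = best_auc,
       evaluated = do.call(rbind, evaluated))
}
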