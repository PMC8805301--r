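#' Network architecture configuration
#'
#' The classifier is a small convolutional network: four blocks, each with two
#' convolutional layers (same padding, ReLU) and batch normalization, closed
#' by a 2x2 max-pooling layer; then a flatten layer and two fully connected
#' layers separated by dropout; the output layer is a single sigmoid neuron,
#' so every plot maps to a score in \[0, 1\].
#'
#' @param filters Convolution filter counts per block (length 4).
#' @param kernel_size Odd convolution kernel side (default 3).
#' @param pool_size Max-pool window and stride (default 2).
#' @param dense_units Sizes of the two hidden dense layers.
#' @param dropout_rate Dropout fraction between dense layers.
#' @param batch_norm Use batch normalization in the conv blocks.
#' @param input_dim Square input side (default 80, matching [plot_config()]).
#' @return A list of class `architecture_config`.
#' @export
architecture_config <- function(filters = c(6, 12, 24, 48), kernel_size = 3,
                                pool_size = 2, dense_units = c(48, 24),
                                dropout_rate = 0.3, batch_norm = TRUE,
                                input_dim = 80) {
  if (length(filters) != 4) stop("four conv blocks are required: filters must have length 4")
  if (length(dense_units) != 2) stop("two hidden dense layers are required")
  if (kernel_size %% 2 != 1) stop("kernel_size must be odd")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  structure(list(n_blocks = 4L, convs_per_block = 2L,
                 filters = as.integer(filters), kernel = as.integer(kernel_size),
                 pool = as.integer(pool_size), dense = as.integer(dense_units),
                 dropout = dropout_rate, batch_norm = isTRUE(batch_norm),
                 input_dim = as.integer(input_dim)),
            class = "architecture_config")
}

#' Training configuration
#'
#' @param split_fraction Fraction of plots allocated randomly to the training
#'   set (default 0.8; the rest forms the validation set).
#' @param epochs Training epochs (default 10).
#' @param batch_size Mini-batch size (default 32).
#' @param learning_rate Adam learning rate for fresh training (default 1e-3).
#' @param transfer_learning_rate Reduced rate used when fine-tuning an
#'   already-trained network on a related observable (default 0.0005).
#' @param seed Integer seed controlling the split, weight initialization,
#'   shuffling and dropout; identical seeds give identical runs.
#' @param class_weighting Weight classes inversely to their frequency in the
#'   binary cross-entropy loss (default TRUE; ice-contaminated plots are
#'   typically a small minority).
#' @return A list of class `training_config`.
#' @export
training_config <- function(split_fraction = 0.8, epochs = 10, batch_size = 32,
                            learning_rate = 1e-3, transfer_learning_rate = 5e-4,
                            seed = 1, class_weighting = TRUE) {
  if (split_fraction <= 0 || split_fraction >= 1) stop("split_fraction must be in (0, 1)")
  if (learning_rate <= 0 || transfer_learning_rate <= 0) stop("learning rates must be positive")
  structure(list(split_fraction = split_fraction, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), learning_rate = learning_rate,
                 transfer_learning_rate = transfer_learning_rate,
                 seed = as.integer(seed), class_weighting = isTRUE(class_weighting)),
            class = "training_config")
}

# Ordered layer census of the architecture, for inspection and tests.
network_layers <- function(arch) {
  blocks <- unlist(lapply(seq_len(arch$n_blocks), function(b) {
    conv <- if (arch$batch_norm) c("conv", "batch_norm", "relu") else c("conv", "relu")
    c(rep(conv, arch$convs_per_block), "max_pool")
  }))
  c("input", blocks, "flatten",
    "dense", "relu", "dropout", "dense", "relu", "dropout", "sigmoid_output")
}

#' Build an untrained classifier
#'
#' @param arch An [architecture_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `ice_classifier` (untrained).
#' @export
build_network <- function(arch = architecture_config(), seed = 1) {
  if (!inherits(arch, "architecture_config")) stop("arch must be an architecture_config")
  weights <- cnn_init_core(unclass(arch), as.integer(seed))
  structure(list(arch = arch, weights = weights, kind = NA_character_,
                 threshold = 0.5, trained = FALSE, history = NULL),
            class = "ice_classifier")
}

#' @export
print.ice_classifier <- function(x, ...) {
  lay <- network_layers(x$arch)
  cat(sprintf("ice_classifier: %d conv / %d pool / %d dense layers, %s parameters\n",
              sum(lay == "conv"), sum(lay == "max_pool"), sum(lay == "dense") + 1,
              format(n_parameters(x), big.mark = ",")))
  cat(sprintf("  trained: %s   kind: %s   threshold: %.2f\n",
              x$trained, x$kind, x$threshold))
  invisible(x)
}

#' Number of trainable parameters of a classifier
#' @param model An `ice_classifier`.
#' @return Integer count (batch-norm running statistics excluded).
#' @export
n_parameters <- function(model) {
  w <- model$weights
  keep <- !grepl("_rm$|_rv$", names(w))
  sum(vapply(w[keep], length, numeric(1)))
}

# run code with a private RNG state seeded from `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

as_plot_array <- function(plots, input_dim) {
  if (is.array(plots) && length(dim(plots)) == 3) {
    arr <- plots
  } else {
    arr <- plots_to_array(plots)
  }
  if (dim(arr)[1] != input_dim || dim(arr)[2] != input_dim) {
    stop("plot shape ", dim(arr)[1], "x", dim(arr)[2],
         " does not match network input ", input_dim, "x", input_dim)
  }
  arr
}

plots_kind <- function(plots) {
  if (is.array(plots)) return(NA_character_)
  k <- unique(vapply(plots, function(p) p$kind, character(1)))
  if (length(k) != 1) stop("plots mix intensity and amplitude kinds")
  k
}

#' Train the classifier on labelled plots
#'
#' Plots are split randomly (by the configured seed) into training and
#' validation subsets; the network is optimized with Adam on a binary
#' cross-entropy objective, optionally with inverse-frequency class weights;
#' the weights from the epoch with the lowest validation loss are retained.
#'
#' @param plots List of `ice_plot` objects (or an input array).
#' @param labels Logical (or 0/1) contamination labels, one per plot.
#' @param arch An [architecture_config()].
#' @param tc A [training_config()].
#' @param kind Observable kind recorded on the classifier when `plots` is a
#'   bare array (inferred from `ice_plot` lists).
#' @return A trained `ice_classifier`; `$history` holds per-epoch training
#'   and validation loss/accuracy.
#' @export
train_network <- function(plots, labels, arch = architecture_config(),
                          tc = training_config(), kind = NULL) {
  base <- build_network(arch, seed = tc$seed)
  fit_network(base, plots, labels, tc, lr = tc$learning_rate, kind = kind)
}

#' Fine-tune a trained classifier on a related observable
#'
#' Continues optimization from the base network's weights at the moderate
#' transfer learning rate (default 0.0005), so the pattern-recognition
#' features already learned are adapted rather than overwritten. The result's
#' kind is set to the new plots' kind.
#'
#' @param base A trained `ice_classifier`.
#' @param plots,labels New training material (e.g. intensity plots for an
#'   amplitude-trained base).
#' @param tc A [training_config()]; `transfer_learning_rate` is used.
#' @param kind As in [train_network()].
#' @return A fine-tuned `ice_classifier`.
#' @export
transfer_network <- function(base, plots, labels, tc = training_config(), kind = NULL) {
  if (!inherits(base, "ice_classifier")) stop("base must be an ice_classifier")
  fit_network(base, plots, labels, tc, lr = tc$transfer_learning_rate, kind = kind)
}

fit_network <- function(model, plots, labels, tc, lr, kind = NULL) {
  arr <- as_plot_array(plots, model$arch$input_dim)
  y <- as.numeric(as.logical(labels))
  n <- dim(arr)[3]
  if (length(y) != n) stop("labels must match the number of plots")
  if (n == 0) stop("no plots to train on")
  if (tc$epochs > 0 && length(unique(y)) < 2) {
    stop("degenerate labels: training needs both classes present")
  }
  idx_tr <- with_seed(tc$seed, sort(sample.int(n, max(1, round(tc$split_fraction * n)))))
  idx_va <- setdiff(seq_len(n), idx_tr)
  w <- rep(1, n)
  if (tc$class_weighting) {
    n_pos <- sum(y[idx_tr] == 1); n_neg <- sum(y[idx_tr] == 0)
    if (n_pos > 0 && n_neg > 0) {
      w[y == 1] <- length(idx_tr) / (2 * n_pos)
      w[y == 0] <- length(idx_tr) / (2 * n_neg)
    }
  }
  res <- cnn_train_core(model$weights, unclass(model$arch),
                        arr[, , idx_tr, drop = FALSE], y[idx_tr], w[idx_tr],
                        arr[, , idx_va, drop = FALSE], y[idx_va], w[idx_va],
                        tc$epochs, tc$batch_size, lr, tc$seed, FALSE)
  model$weights <- res$weights
  model$history <- res$history
  model$trained <- model$trained || tc$epochs > 0
  model$kind <- if (!is.null(kind)) kind else plots_kind(plots)
  model
}

#' Scores for a batch of plots
#' @param model An `ice_classifier`.
#' @param plots List of `ice_plot` objects or an input array.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
predict_scores <- function(model, plots) {
  arr <- as_plot_array(plots, model$arch$input_dim)
  as.numeric(cnn_predict_core(model$weights, unclass(model$arch), arr))
}

#' Classify one plot
#'
#' Returns the network score in \[0, 1\] and the verdict
#' `contaminated = score >= threshold` (a score exactly at the threshold
#' counts as contaminated, the conservative choice for artefact flagging).
#' Blank or too-sparse plots bypass the network: they are nonpredictable and
#' carry no verdict.
#'
#' @param model A trained `ice_classifier`.
#' @param plot An `ice_plot`.
#' @return A list of class `plot_prediction`: `range_label`, `score`,
#'   `contaminated`, `predictable`.
#' @export
predict_plot <- function(model, plot) {
  if (!inherits(plot, "ice_plot")) stop("plot must be an ice_plot")
  if (!is.na(model$kind) && !is.na(plot$kind) && plot$kind != model$kind) {
    warning("plot kind (", plot$kind, ") differs from the network's (", model$kind, ")")
  }
  if (!plot$predictable) {
    warning("window ", plot$range_label,
            " is nonpredictable (blank or too few reflections); no verdict given")
    return(structure(list(range_label = plot$range_label, score = NA_real_,
                          contaminated = NA, predictable = FALSE),
                     class = "plot_prediction"))
  }
  s <- predict_scores(model, list(plot))
  structure(list(range_label = plot$range_label, score = s,
                 contaminated = s >= model$threshold, predictable = TRUE),
            class = "plot_prediction")
}

#' Classify every covered window of a reflection set
#'
#' Builds the plot for each ice-ring window contained in the data's
#' resolution span, scores each predictable plot, and aggregates: the data
#' set is contaminated when even a single window is classified contaminated.
#' If no window is predictable the dataset verdict is `"nonpredictable"`.
#'
#' @param model A trained `ice_classifier`.
#' @param set A [reflection_set()].
#' @param table Window table, default [ice_ring_windows()].
#' @param cfg A [plot_config()].
#' @return A list of class `dataset_prediction`: `windows` (data frame with
#'   label, d bounds, score, contaminated, predictable), `verdict` (one of
#'   `"contaminated"`, `"clean"`, `"nonpredictable"`), `plots`.
#' @export
predict_dataset <- function(model, set, table = ice_ring_windows(), cfg = plot_config()) {
  sel <- select_ranges(set, table)
  plots <- lapply(seq_len(nrow(sel)), function(i) make_plot(set, sel[i, ], cfg))
  preds <- lapply(plots, function(p) suppressWarnings(predict_plot(model, p)))
  for (p in plots) {
    if (!p$predictable) {
      warning("window ", p$range_label, " is nonpredictable (",
              if (p$blank) "blank resolution shell" else "too few reflections", ")")
    }
  }
  win <- data.frame(
    label = sel$label, d_high = sel$d_high, d_low = sel$d_low,
    score = vapply(preds, function(p) p$score, numeric(1)),
    contaminated = vapply(preds, function(p) as.logical(p$contaminated), logical(1)),
    predictable = vapply(preds, function(p) p$predictable, logical(1)))
  verdict <- if (nrow(win) == 0 || !any(win$predictable)) {
    "nonpredictable"
  } else if (any(win$contaminated[win$predictable])) {
    "contaminated"
  } else {
    "clean"
  }
  structure(list(windows = win, verdict = verdict, plots = plots),
            class = "dataset_prediction")
}

#' @export
print.dataset_prediction <- function(x, ...) {
  print(x$windows, row.names = FALSE)
  cat("dataset verdict:", x$verdict, "\n")
  invisible(x)
}

#' SmoothGrad sensitivity map
#'
#' Averages the input-gradient magnitude of the classifier score over
#' `n_samples` noise-perturbed copies of the plot, highlighting which pixels
#' drive the classification. With `n_samples = 1` and `noise_sigma = 0` this
#' is the plain gradient magnitude.
#'
#' @param model A trained `ice_classifier`.
#' @param plot An `ice_plot` (or a bare numeric grid).
#' @param n_samples Number of noisy copies (>= 1).
#' @param noise_sigma Gaussian noise scale as a fraction of the input value
#'   range.
#' @param seed Integer seed for the noise draws.
#' @return Numeric matrix of the input shape (mean absolute gradient).
#' @export
smoothgrad <- function(model, plot, n_samples = 25, noise_sigma = 0.1, seed = 1) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  g <- if (inherits(plot, "ice_plot")) plot$grid else plot
  rng <- diff(range(g))
  sd <- noise_sigma * if (rng > 0) rng else 1
  arr <- array(0, c(nrow(g), ncol(g), n_samples))
  with_seed(seed, {
    for (i in seq_len(n_samples)) {
      arr[, , i] <- g + if (sd > 0) matrix(stats::rnorm(length(g), 0, sd), nrow(g)) else 0
    }
  })
  grads <- cnn_input_grad_core(model$weights, unclass(model$arch), arr)
  apply(abs(grads), c(1, 2), mean)
}

#' Save / load a classifier bundle
#'
#' The bundle serializes the architecture, weights, kind, threshold and the
#' plot-generation configuration fingerprint together, so prediction always
#' reuses the featurization the network was trained with.
#'
#' @param model An `ice_classifier`.
#' @param path Bundle path (.rds).
#' @param plot_cfg The [plot_config()] used for its training plots.
#' @return `path` ([save_classifier()]) or the restored `ice_classifier`.
#' @export
save_classifier <- function(model, path, plot_cfg = plot_config()) {
  model$plot_cfg <- plot_cfg
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "ice_classifier")) stop("not a classifier bundle: ", path)
  model
}
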