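# Graph isomorphism network ---------------------------------------------
#
# Layer rule, for node v at layer k with shared weighted adjacency A:
#
#   h_v^(k) = MLP_k( (1 + eps_k) h_v^(k-1) + sum_u A[v, u] h_u^(k-1) )
#
# Readout: per-layer sum-pooling over nodes, p_G^(k) = sum_v h_v^(k);
# the K pooled vectors are concatenated and fed to a linear classifier
# whose output y passes through a sigmoid.  Because every subject shares
# one adjacency, a minibatch of B subjects is processed by a single
# (V x V) by (V x C*B) multiply per layer, so cost is linear in the
# number of edges.
#
# The forward and backward passes run in a fused C++ kernel
# (src/gin_ops.cpp); the Adam training loop, checkpointing and all
# user-facing contracts live in R.

#' GIN architecture configuration
#'
#' @param n_layers number of graph convolution layers K (default 5).
#' @param width per-layer MLP width = output feature dimension (default
#'   64).
#' @param input_dim input node-feature dimension (6: four ordinal level
#'   slots plus two binary slots).
#' @param epsilon `"learnable"` (initialised at 0) or `"zero"` (fixed).
#' @param dropout dropout fraction on hidden activations in \[0, 1).
#' @param batch_norm batch-normalize both affine outputs of every MLP
#'   (default `TRUE`).  Training uses batch statistics; prediction and
#'   gradients use the stored running statistics, so inference stays
#'   deterministic per subject.  Without normalization the repeated
#'   weighted aggregation inflates activations layer by layer and
#'   optimisation degrades noticeably.
#' @param identity_mlp if `TRUE`, every MLP is the identity map (feature
#'   dimension stays `input_dim`); used for closed-form checks and the
#'   logistic-regression limit.
#' @param learning_rate,batch_size,epochs Adam training hyperparameters.
#' @param binarize_edges if `TRUE`, retained edges are set to sign-less
#'   1 before aggregation (default keeps signed correlation weights).
#' @return object of class `gin_config`.
#' @export
gin_config <- function(n_layers = 5, width = 64, input_dim = 6,
                       epsilon = c("learnable", "zero"), dropout = 0,
                       batch_norm = TRUE, identity_mlp = FALSE,
                       learning_rate = 1e-3, batch_size = 256, epochs = 200,
                       binarize_edges = FALSE) {
  epsilon <- match.arg(epsilon)
  stopifnot(n_layers >= 1, width >= 1, dropout >= 0, dropout < 1)
  structure(list(n_layers = n_layers, width = width, input_dim = input_dim,
                 epsilon = epsilon, dropout = dropout,
                 batch_norm = isTRUE(batch_norm) && !isTRUE(identity_mlp),
                 identity_mlp = identity_mlp, learning_rate = learning_rate,
                 batch_size = batch_size, epochs = epochs,
                 binarize_edges = binarize_edges),
            class = "gin_config")
}

layer_dims <- function(config) {
  if (config$identity_mlp) rep(config$input_dim, config$n_layers)
  else rep(config$width, config$n_layers)
}

#' Initialise a GIN model
#'
#' He-uniform weight initialisation, epsilon at 0, zero biases; all
#' randomness comes from `seed`.
#'
#' @param config a [gin_config()].
#' @param vocab the `node_vocabulary` the model is trained on.
#' @param edges the shared `edge_matrix`.
#' @param seed integer seed for weight initialisation.
#' @return object of class `gin_model`.
#' @export
gin_init <- function(config, vocab, edges, seed = 1) {
  stopifnot(inherits(config, "gin_config"))
  if (!identical(attr(edges, "vocab_hash"), vocab_hash(vocab)))
    stop_ginscreen("edge matrix vocabulary does not match",
                   class = "ginscreen_vocab_error")
  set.seed(seed)
  dims <- c(config$input_dim, layer_dims(config))
  he <- function(n_in, n_out) {
    lim <- sqrt(6 / n_in)
    matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
  }
  layers <- lapply(seq_len(config$n_layers), function(k) {
    if (config$identity_mlp) return(list(eps = 0))
    ly <- list(eps = 0,
               W1 = he(dims[k], config$width), b1 = numeric(config$width),
               W2 = he(config$width, dims[k + 1]), b2 = numeric(dims[k + 1]))
    if (config$batch_norm) {
      ly$g1 <- rep(1, config$width); ly$be1 <- numeric(config$width)
      ly$g2 <- rep(1, dims[k + 1]); ly$be2 <- numeric(dims[k + 1])
      ly$rm1 <- numeric(config$width); ly$rv1 <- rep(1, config$width)
      ly$rm2 <- numeric(dims[k + 1]); ly$rv2 <- rep(1, dims[k + 1])
    }
    ly
  })
  d_cat <- sum(layer_dims(config))
  A <- unclass(edges)
  if (config$binarize_edges) A <- (A != 0) * 1
  structure(list(layers = layers,
                 w = runif(d_cat, -sqrt(6 / d_cat), sqrt(6 / d_cat)),
                 b = 0,
                 A = A, config = config, vocab = vocab,
                 vocab_hash = vocab_hash(vocab),
                 edge_meta = list(method = attr(edges, "method"),
                                  threshold = attr(edges, "threshold")),
                 seed = seed),
            class = "gin_model")
}

#' @export
print.gin_model <- function(x, ...) {
  cfg <- x$config
  cat("GIN model: ", cfg$n_layers, " layers, width ",
      if (cfg$identity_mlp) paste0(cfg$input_dim, " (identity MLP)")
      else cfg$width,
      ", ", nrow(x$A), " nodes\n", sep = "")
  if (!is.null(x$checkpoint))
    cat("  checkpoint: epoch ", x$checkpoint$epoch, " (constraint ",
        if (x$checkpoint$constraint_met) "met" else "NOT met", ")\n",
        sep = "")
  invisible(x)
}

# All heavy numerics run in one fused C++ call (src/gin_ops.cpp):
# one-hot expansion, the K aggregate/combine rounds, sum-pooling, the
# concatenated readout, and optionally the full backward pass.
# Activations inside the kernel are flat (V*B) x C matrices with node
# index fastest within subject, so each aggregation is one
# (V x V) * (V x B*C) BLAS product and cost is linear in the edges.
gin_run <- function(model, slot_rows, training = FALSE,
                    dropout_masks = NULL, labels = NULL,
                    want_grads = FALSE, want_input_grad = FALSE) {
  cfg <- model$config
  cpp_gin_run(slot_rows, model$A, model$layers, model$w, model$b,
              cfg$identity_mlp, cfg$batch_norm, training,
              0.1, 1e-5, dropout_masks, labels, want_grads, want_input_grad)
}

# forward over a batch of slot rows; thin wrapper kept for tests
gin_forward_batch <- function(model, slot_rows, training = FALSE,
                              dropout_masks = NULL) {
  gin_run(model, slot_rows, training = training,
          dropout_masks = dropout_masks)
}

#' Forward pass through a GIN
#'
#' @param model a trained or initialised `gin_model`.
#' @param graph a `subject_graph` or `subject_graphs` batch.
#' @return for a single graph, a list with the per-layer pooled graph
#'   features `embedding` (named list), the concatenated feature
#'   `concatenated`, the raw score `y` and the `sigmoid` score; for a
#'   batch, a list with vectors `y` and `sigmoid` and the matrix
#'   `concatenated`.
#' @export
gin_forward <- function(model, graph) {
  if (inherits(graph, "subject_graph")) {
    check_vocab(model, graph$vocab)
    slot_rows <- matrix(apply(graph$features, 1, which.max), nrow = 1)
    fw <- gin_forward_batch(model, slot_rows)
    offs <- c(0, cumsum(fw$layer_dims))
    emb <- lapply(seq_along(fw$layer_dims), function(k)
      fw$G[1, (offs[k] + 1):offs[k + 1]])
    names(emb) <- paste0("layer_", seq_along(emb))
    list(embedding = emb, concatenated = fw$G[1, ], y = fw$y[1],
         sigmoid = fw$p[1])
  } else {
    check_vocab(model, graph$vocab)
    fw <- gin_predict(model, graph, raw = TRUE)
    fw
  }
}

check_vocab <- function(model, vocab) {
  if (!identical(model$vocab_hash, vocab_hash(vocab)))
    stop_ginscreen("graph vocabulary does not match model vocabulary",
                   class = "ginscreen_vocab_error")
  invisible(TRUE)
}

# At inference batch norm applies the fixed running statistics, i.e. a
# per-feature affine map, which folds exactly into the neighbouring
# affine weights: Z W + b followed by (. - m) * g/sd + be equals
# Z (W diag(a)) + (b a + c) with a = g/sd, c = be - m a.  Folding once
# per call removes all normalization work from the prediction path.
fold_eval_model <- function(model, eps = 1e-5) {
  cfg <- model$config
  if (!cfg$batch_norm || cfg$identity_mlp) return(model)
  for (k in seq_along(model$layers)) {
    ly <- model$layers[[k]]
    a1 <- ly$g1 / sqrt(ly$rv1 + eps); c1 <- ly$be1 - ly$rm1 * a1
    a2 <- ly$g2 / sqrt(ly$rv2 + eps); c2 <- ly$be2 - ly$rm2 * a2
    ly$W1 <- ly$W1 * rep(a1, each = nrow(ly$W1))
    ly$b1 <- ly$b1 * a1 + c1
    ly$W2 <- ly$W2 * rep(a2, each = nrow(ly$W2))
    ly$b2 <- ly$b2 * a2 + c2
    ly[c("g1", "be1", "g2", "be2", "rm1", "rv1", "rm2", "rv2")] <- NULL
    model$layers[[k]] <- ly
  }
  model$config$batch_norm <- FALSE
  model
}

# batched prediction in fixed-size chunks to bound memory
gin_predict <- function(model, graphs, raw = FALSE, chunk = 4096L) {
  model <- fold_eval_model(model)
  n <- n_graphs(graphs)
  y <- numeric(n)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    fw <- gin_forward_batch(model, graphs$slots[s:e, , drop = FALSE])
    y[s:e] <- fw$y
  }
  if (raw) list(y = y, sigmoid = plogis(y)) else plogis(y)
}

#' Binary cross-entropy loss
#'
#' Mean negative log-likelihood of sigmoid scores, with scores clipped to
#' \[1e-7, 1 - 1e-7\].
#'
#' @param scores sigmoid scores in (0, 1).
#' @param labels binary labels.
#' @return scalar loss.
#' @export
bce_loss <- function(scores, labels) {
  if (length(scores) == 0) stop_ginscreen("empty score list",
                                          class = "ginscreen_invalid_spec")
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  p <- pmin(pmax(scores, 1e-7), 1 - 1e-7)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Gradient of the raw output with respect to the input features
#'
#' Computes d y / d x for the RAW (pre-sigmoid) score y, for every node
#' and every one-hot feature slot — the quantity averaged into attention
#' plots.
#'
#' @param model a `gin_model`.
#' @param graph a `subject_graph`, or a `subject_graphs` batch.
#' @return for a single graph, a nodes x 6 matrix; for a batch, an array
#'   (nodes, 6, n).
#' @export
input_gradient <- function(model, graph) {
  if (inherits(graph, "subject_graph")) {
    check_vocab(model, graph$vocab)
    slot_rows <- matrix(apply(graph$features, 1, which.max), nrow = 1)
    g <- input_gradient_slots(model, slot_rows)[, , 1]
    rownames(g) <- model$vocab$name
    g
  } else {
    check_vocab(model, graph$vocab)
    input_gradient_slots(model, graph$slots)
  }
}

input_gradient_slots <- function(model, slot_rows, chunk = 4096L) {
  model <- fold_eval_model(model)   # gradients at the inference map
  n <- nrow(slot_rows); V <- ncol(slot_rows)
  out <- array(0, c(V, model$config$input_dim, n))
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    rows <- slot_rows[s:e, , drop = FALSE]
    res <- gin_run(model, rows, want_input_grad = TRUE)
    out[, , s:e] <- aperm(array(res$input,
                                c(V, nrow(rows), model$config$input_dim)),
                          c(1, 3, 2))
  }
  out
}
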