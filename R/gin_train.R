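# GIN training: Adam, minibatching, checkpoint selection ----------------

new_adam_state <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^state$t)
      vh <- v / (1 - beta2^state$t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

bn_buffer_names <- c("rm1", "rv1", "rm2", "rv2")

model_params <- function(model) {
  layers <- lapply(model$layers, function(ly) {
    if (model$config$epsilon == "zero") ly$eps <- NULL
    ly[setdiff(names(ly), bn_buffer_names)]   # buffers are not trained
  })
  list(layers = layers, w = model$w, b = model$b)
}

snapshot_buffers <- function(model) {
  lapply(model$layers, function(ly) ly[intersect(names(ly), bn_buffer_names)])
}

set_buffers <- function(model, buffers) {
  for (k in seq_along(buffers))
    for (nm in names(buffers[[k]]))
      model$layers[[k]][[nm]] <- buffers[[k]][[nm]]
  model
}

set_model_params <- function(model, params) {
  for (k in seq_along(model$layers))
    for (nm in names(params$layers[[k]]))
      model$layers[[k]][[nm]] <- params$layers[[k]][[nm]]
  model$w <- params$w
  model$b <- params$b
  model
}

grads_as_params <- function(model, grads) {
  layers <- lapply(seq_along(grads$layers), function(k) {
    g <- grads$layers[[k]]
    if (model$config$epsilon == "zero") g$eps <- NULL
    g
  })
  list(layers = layers, w = grads$w, b = grads$b)
}

#' Select the checkpoint epoch from a validation trace
#'
#' The kept checkpoint is the epoch with minimal validation loss among
#' epochs whose validation sensitivity and specificity both exceed the
#' constraint thresholds (default 0.80), preventing selection of a
#' checkpoint that has collapsed onto the majority class.  If no epoch
#' satisfies the constraint, the minimal-loss epoch is returned with a
#' prominent warning.
#'
#' @param trace data frame with columns `loss`, `sens`, `spec` (one row
#'   per epoch).
#' @param rule a [checkpoint_rule()].
#' @return list with `epoch` (row index) and `constraint_met` (logical).
#' @export
select_checkpoint <- function(trace, rule = checkpoint_rule()) {
  stopifnot(nrow(trace) >= 1)
  ok <- !is.na(trace$sens) & !is.na(trace$spec) &
    trace$sens > rule$sens_min & trace$spec > rule$spec_min
  if (any(ok)) {
    cand <- which(ok)
    list(epoch = cand[which.min(trace$loss[cand])], constraint_met = TRUE)
  } else {
    warning("no epoch reached sensitivity > ", rule$sens_min,
            " and specificity > ", rule$spec_min,
            "; falling back to the minimal-loss checkpoint", call. = FALSE)
    list(epoch = which.min(trace$loss), constraint_met = FALSE)
  }
}

#' Checkpoint selection rule
#'
#' @param sens_min,spec_min validation sensitivity/specificity that a
#'   checkpoint must exceed (default 0.80 each).
#' @param threshold decision threshold on the sigmoid score used to
#'   compute validation sensitivity/specificity: a number (default 0.5),
#'   or `"youden"` to use, at every epoch, the validation threshold
#'   maximising sensitivity + specificity - 1.
#' @return object of class `checkpoint_rule`.
#' @export
checkpoint_rule <- function(sens_min = 0.8, spec_min = 0.8,
                            threshold = 0.5) {
  stopifnot(sens_min > 0, sens_min < 1, spec_min > 0, spec_min < 1)
  stopifnot(identical(threshold, "youden") ||
              (is.numeric(threshold) && threshold >= 0 && threshold <= 1))
  structure(list(sens_min = sens_min, spec_min = spec_min,
                 threshold = threshold), class = "checkpoint_rule")
}

#' Youden-optimal decision threshold
#'
#' The score cut maximising sensitivity + specificity - 1; candidate cuts
#' are midpoints between adjacent distinct scores.
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @return the threshold (scalar).
#' @export
youden_threshold <- function(scores, labels) {
  u <- sort(unique(scores))
  if (length(u) == 1) return(u)
  idx <- match(scores, u)
  tab_pos <- tabulate(idx[labels == 1], nbins = length(u))
  tab_neg <- tabulate(idx[labels == 0], nbins = length(u))
  n_pos <- sum(tab_pos); n_neg <- sum(tab_neg)
  # candidate i = midpoint of (u[i], u[i+1]); predicting >= midpoint
  # keeps exactly the scores above u[i]
  sens <- (n_pos - cumsum(tab_pos)) / max(n_pos, 1)
  spec <- cumsum(tab_neg) / max(n_neg, 1)
  j <- (sens + spec)[-length(u)]
  (u[which.max(j)] + u[which.max(j) + 1]) / 2
}

#' Train a GIN by minibatch Adam
#'
#' Trains on `train` graphs, evaluating loss / sensitivity / specificity
#' on `val` after every epoch, and returns the model at the checkpoint
#' chosen by `rule`.  One seed fixes initialisation, shuffling and
#' dropout, so identical inputs give identical traces.
#'
#' @param train,val `subject_graphs` for the training and validation
#'   partitions (the validation partition is never resampled).
#' @param config a [gin_config()].
#' @param rule a [checkpoint_rule()].
#' @param seed integer seed.
#' @param verbose print per-epoch progress.
#' @return a `gin_model` with elements `trace` (per-epoch data frame) and
#'   `checkpoint`.
#' @export
train_gin <- function(train, val, config = gin_config(),
                      rule = checkpoint_rule(), seed = 1, verbose = FALSE) {
  stopifnot(inherits(train, "subject_graphs"), inherits(val, "subject_graphs"))
  if (n_graphs(train) == 0)
    stop_ginscreen("empty training partition", class = "ginscreen_invalid_spec")
  model <- gin_init(config, train$vocab, train$edges, seed = seed)
  set.seed(seed + 1L)
  params <- model_params(model)
  state <- new_adam_state(params)
  n <- n_graphs(train)
  trace <- data.frame(epoch = integer(), loss = numeric(), sens = numeric(),
                      spec = numeric())
  best <- list(constrained = NULL, overall = NULL,
               c_loss = Inf, o_loss = Inf)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    for (s in seq(1, n, by = config$batch_size)) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      rows <- train$slots[idx, , drop = FALSE]
      masks <- NULL
      if (config$dropout > 0 && !config$identity_mlp) {
        masks <- lapply(seq_len(config$n_layers), function(k)
          matrix(rbinom(length(idx) * ncol(rows) * config$width, 1,
                        1 - config$dropout) / (1 - config$dropout),
                 length(idx) * ncol(rows), config$width))
      }
      res <- gin_run(model, rows, training = TRUE, dropout_masks = masks,
                     labels = as.numeric(train$labels[idx]),
                     want_grads = TRUE)
      upd <- adam_step(params, grads_as_params(model, res$grads), state,
                       lr = config$learning_rate)
      params <- upd$params; state <- upd$state
      model <- set_model_params(model, params)
      if (config$batch_norm && !config$identity_mlp)
        model <- set_buffers(model, res$bn_new)
    }
    vp <- gin_predict(model, val)
    vloss <- bce_loss(vp, val$labels)
    thr <- if (identical(rule$threshold, "youden"))
      youden_threshold(vp, val$labels) else rule$threshold
    cm <- confusion_metrics(vp, val$labels, threshold = thr)
    trace <- rbind(trace, data.frame(epoch = ep, loss = vloss,
                                     sens = cm$sensitivity,
                                     spec = cm$specificity))
    qualifies <- !is.na(cm$sensitivity) && !is.na(cm$specificity) &&
      cm$sensitivity > rule$sens_min && cm$specificity > rule$spec_min
    if (qualifies && vloss < best$c_loss) {
      best$constrained <- params; best$c_buf <- snapshot_buffers(model)
      best$c_loss <- vloss; best$c_epoch <- ep
    }
    if (vloss < best$o_loss) {
      best$overall <- params; best$o_buf <- snapshot_buffers(model)
      best$o_loss <- vloss; best$o_epoch <- ep
    }
    if (verbose)
      cat(sprintf("epoch %3d  val loss %.4f  sens %.3f  spec %.3f\n",
                  ep, vloss, cm$sensitivity, cm$specificity))
  }
  sel <- suppressWarnings(select_checkpoint(trace, rule))
  if (!sel$constraint_met)
    warning("no epoch reached sensitivity > ", rule$sens_min,
            " and specificity > ", rule$spec_min,
            "; keeping the minimal-loss checkpoint (epoch ",
            best$o_epoch, ")", call. = FALSE)
  chosen <- if (sel$constraint_met) best$constrained else best$overall
  model <- set_model_params(model, chosen)
  model <- set_buffers(model, if (sel$constraint_met) best$c_buf else best$o_buf)
  model$trace <- trace
  model$checkpoint <- list(epoch = sel$epoch, constraint_met = sel$constraint_met)
  model
}
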