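# Portable model archives ------------------------------------------------
#
# Models are stored as plain JSON: every matrix is flattened column-major
# next to its dimensions, and the archive records the config, vocabulary
# and vocabulary hash so that loading can verify the model is applied to
# graphs built from the same node set.

enc_mat <- function(m) list(dim = dim(m) %||% length(m), data = as.vector(m))
dec_mat <- function(e) {
  d <- unlist(e$dim)
  v <- unlist(e$data)
  if (length(d) == 1) v else array(v, d)
}

#' Save / load a GIN model as a JSON archive
#'
#' @param model a `gin_model`.
#' @param path archive path (JSON).
#' @return `path` (save) or the restored `gin_model` (load); loading
#'   verifies the stored vocabulary hash.
#' @export
save_gin_model <- function(model, path) {
  stopifnot(inherits(model, "gin_model"))
  arc <- list(
    layers = lapply(model$layers, function(ly) lapply(ly, enc_mat)),
    w = enc_mat(model$w), b = model$b, A = enc_mat(model$A),
    node_names = rownames(model$A) %||% model$vocab$name,
    config = unclass(model$config),
    vocab = as.list(as.data.frame(model$vocab)),
    vocab_hash = model$vocab_hash, edge_meta = model$edge_meta,
    seed = model$seed, checkpoint = model$checkpoint
  )
  jsonlite::write_json(arc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_gin_model
#' @export
load_gin_model <- function(path) {
  arc <- jsonlite::read_json(path, simplifyVector = FALSE)
  vocab <- structure(
    data.frame(name = unlist(arc$vocab$name), kind = unlist(arc$vocab$kind),
               column = unlist(arc$vocab$column), stringsAsFactors = FALSE),
    class = c("node_vocabulary", "data.frame"))
  if (!identical(vocab_hash(vocab), arc$vocab_hash))
    stop_ginscreen("vocabulary hash mismatch in model archive",
                   class = "ginscreen_vocab_error")
  cfg <- do.call(gin_config, arc$config[names(arc$config) %in%
                                          names(formals(gin_config))])
  A <- dec_mat(arc$A)
  dimnames(A) <- list(unlist(arc$node_names), unlist(arc$node_names))
  model <- structure(list(
    layers = lapply(arc$layers, function(ly) lapply(ly, function(p)
      if (is.list(p) && !is.null(p$dim)) dec_mat(p) else unlist(p))),
    w = dec_mat(arc$w), b = unlist(arc$b), A = A,
    config = cfg, vocab = vocab, vocab_hash = arc$vocab_hash,
    edge_meta = arc$edge_meta, seed = arc$seed,
    checkpoint = arc$checkpoint
  ), class = "gin_model")
  # eps is scalar; enc_mat stores it with dim 1
  for (k in seq_along(model$layers))
    model$layers[[k]]$eps <- as.numeric(model$layers[[k]]$eps)
  model
}
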