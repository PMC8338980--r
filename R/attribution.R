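# Gradient attention plots and odds ratios ------------------------------
#
# Saliency is the gradient of the raw (pre-sigmoid) score with respect to
# each input feature slot, averaged over a subject set and, for an
# ensemble, over the member models.  Three display normalizations are
# supported: row-wise (per level, over the ordinal nodes), column-wise
# (per binary node, min-max) and L1-column (per ordinal node, the L1 norm
# over its four level slots scaled so the top node is exactly 1).

#' Population attention matrix
#'
#' Mean input gradient of the raw output over a subject set, averaged
#' across the members of an ensemble (or computed from a single model).
#'
#' By default the mean is taken over the positive (acute-SI) subjects:
#' for a rare outcome, gradients evaluated at the background population
#' reflect the local geometry around typical negative inputs, whereas
#' gradients at case inputs reflect what actually drives case scores —
#' the quantity an attention plot is meant to display.  Set `subjects`
#' to `"all"` for the whole-set mean, or `"correct"` to average over
#' correctly classified subjects (at sigmoid threshold 0.5).
#'
#' @param model a `gin_model` or `gin_ensemble`.
#' @param graphs a `subject_graphs` set.
#' @param subjects which subjects to average over: `"positive"`
#'   (default), `"all"`, or `"correct"`.
#' @return object of class `attention_matrix`: a 6 x nodes matrix (rows =
#'   feature slots/levels) with attributes `normalization = "raw"` and
#'   `vocab`.
#' @export
population_attention <- function(model, graphs,
                                 subjects = c("positive", "all", "correct")) {
  subjects <- match.arg(subjects)
  if (n_graphs(graphs) == 0)
    stop_ginscreen("empty subject set", class = "ginscreen_invalid_spec")
  members <- if (inherits(model, "gin_ensemble")) model$members else list(model)
  keep <- switch(subjects,
    all = seq_len(n_graphs(graphs)),
    positive = which(graphs$labels == 1),
    correct = {
      sc <- if (inherits(model, "gin_ensemble"))
        ensemble_predict(model, graphs)
      else gin_predict(model, graphs)
      which((sc >= 0.5) == (graphs$labels == 1))
    })
  if (!length(keep))
    stop_ginscreen("no subjects left to average over (subjects = \"",
                   subjects, "\")", class = "ginscreen_invalid_spec")
  sub <- subset_graphs(graphs, keep)
  acc <- NULL
  for (m in members) {
    check_vocab(m, graphs$vocab)
    g <- input_gradient(m, sub)             # (V, 6, n)
    mg <- apply(g, c(1, 2), mean)           # V x 6
    acc <- if (is.null(acc)) mg else acc + mg
  }
  att <- t(acc / length(members))           # 6 x V
  colnames(att) <- graphs$vocab$name
  rownames(att) <- c(paste0("level_", 1:4), "binary_0", "binary_1")
  structure(att, class = c("attention_matrix", "matrix"),
            normalization = "raw", vocab = graphs$vocab,
            subjects = subjects, n_subjects = length(keep))
}

#' Normalize an attention matrix for display
#'
#' * `"row-wise"` — each of the four level rows is divided by its maximum
#'   absolute entry over the ordinal nodes (signs preserved); used to
#'   compare questionnaire items.
#' * `"column-wise"` — each binary node's column (its two binary slots)
#'   is min-max scaled to \[0, 1\]; used to compare binary items.
#' * `"l1-column"` — per ordinal node, the L1 norm of its four level
#'   slots, divided by the maximum so the top node scores exactly 1;
#'   returned as a 1 x nodes matrix.
#'
#' All-zero rows/columns are left at zero with a warning.
#'
#' @param matrix an `attention_matrix` in raw state.
#' @param mode one of `"row-wise"`, `"column-wise"`, `"l1-column"`.
#' @return the normalized `attention_matrix` (for `"l1-column"`, a 1-row
#'   matrix over the ordinal nodes).
#' @export
normalize_attention <- function(matrix,
                                mode = c("row-wise", "column-wise",
                                         "l1-column")) {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "attention_matrix"))
  if (identical(attr(matrix, "normalization"), mode))
    return(matrix)                     # idempotent in its own mode
  if (!identical(attr(matrix, "normalization"), "raw"))
    stop_ginscreen("input must be a raw attention matrix",
                   class = "ginscreen_invalid_spec")
  vocab <- attr(matrix, "vocab")
  ord <- vocab$kind == "ordinal"
  out <- unclass(matrix)
  if (mode == "row-wise") {
    for (r in 1:4) {
      mx <- max(abs(out[r, ord]))
      if (mx == 0) warning("all-zero level row ", r, " left unscaled")
      else out[r, ord] <- out[r, ord] / mx
    }
    out[, !ord] <- NA_real_
    out <- out[1:4, , drop = FALSE]
  } else if (mode == "column-wise") {
    bin <- which(!ord)
    if (!length(bin))
      stop_ginscreen("no binary nodes in vocabulary",
                     class = "ginscreen_invalid_spec")
    for (j in bin) {
      v <- out[5:6, j]
      rng <- range(v)
      if (diff(rng) == 0) warning("constant binary column ",
                                  vocab$name[j], " left unscaled")
      else out[5:6, j] <- (v - rng[1]) / diff(rng)
    }
    out[, ord] <- NA_real_
    out <- out[5:6, , drop = FALSE]
  } else {
    l1 <- colSums(abs(out[1:4, ord, drop = FALSE]))
    mx <- max(l1)
    if (mx == 0) warning("all-zero attention; L1 norms left at zero")
    else l1 <- l1 / mx
    out <- base::matrix(l1, nrow = 1,
                        dimnames = list("l1", vocab$name[ord]))
  }
  structure(out, class = c("attention_matrix", "matrix"),
            normalization = mode, vocab = vocab)
}

#' Odds ratios of binary items against acute SI
#'
#' 2x2 cross-tabulation of each binary item with the acute-SI label;
#' OR = (a d) / (b c) with a = item+/SI+, b = item+/SI-, c = item-/SI+,
#' d = item-/SI-.  When any cell is zero, the Haldane-Anscombe +0.5
#' correction is applied to all four cells and flagged.
#'
#' @param table cohort data frame with an `acute_SI` column.
#' @param items binary column names (default the three binary covariates
#'   plus `MaDE` when present).
#' @return data frame with columns `item`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `corrected`.
#' @export
binary_odds_ratios <- function(table, items = NULL) {
  if (is.null(items))
    items <- intersect(c("lifetime_SA", "MaDE", "gender_female",
                         "institution_hospital"), names(table))
  miss <- setdiff(items, names(table))
  if (length(miss))
    stop_ginscreen("item(s) not in table: ", paste(miss, collapse = ", "),
                   class = "ginscreen_schema_error")
  si <- table$acute_SI
  rows <- lapply(items, function(it) {
    v <- table[[it]]
    stopifnot(all(v %in% 0:1))
    a <- sum(v == 1 & si == 1); b <- sum(v == 1 & si == 0)
    cc <- sum(v == 0 & si == 1); d <- sum(v == 0 & si == 0)
    corrected <- any(c(a, b, cc, d) == 0)
    if (corrected) {
      or <- ((a + .5) * (d + .5)) / ((b + .5) * (cc + .5))
    } else {
      or <- (a * d) / (b * cc)
    }
    data.frame(item = it, a = a, b = b, c = cc, d = d, odds_ratio = or,
               corrected = corrected, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write an attention matrix as TSV with a JSON sidecar
#'
#' @param att an `attention_matrix`.
#' @param path TSV path; `normalization` metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_attention <- function(att, path) {
  write.table(as.data.frame(unclass(att)), path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  jsonlite::write_json(list(normalization = attr(att, "normalization")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
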