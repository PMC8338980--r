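# Shared correlation edge matrix and per-subject graph encoding ---------
#
# Every subject's graph uses the same node set and the same edge matrix;
# only the one-hot node features differ between subjects.  Ordinal nodes
# (questionnaire items and quartile-coded totals) occupy feature slots
# 1-4; binary nodes occupy slots 5 (absent) and 6 (present), so that
# level-resolved input gradients exist for every node.

#' Node vocabulary for a graph model
#'
#' The acute-SI model uses 19 ordinal nodes (9 PHQ items, 7 GAD items,
#' 3 quartile-coded scale totals) plus 4 binary nodes (lifetime suicide
#' attempt, MaDE, gender, institution).  The MaDE model uses the 19
#' ordinal nodes plus gender and institution only: MaDE is its target,
#' and lifetime SA is withheld from its inputs.
#'
#' @param model `"si"` or `"made"`.
#' @return object of class `node_vocabulary`: data frame with columns
#'   `name`, `kind` (`"ordinal"`/`"binary"`), `column` (source column in
#'   the cohort table).
#' @export
node_vocabulary <- function(model = c("si", "made")) {
  model <- match.arg(model)
  ordinal <- c(phq_cols(), gad_cols(), "STAI_q", "RAS_q", "RSES_q")
  bin <- if (model == "si") {
    c("lifetime_SA", "MaDE", "gender_female", "institution_hospital")
  } else {
    c("gender_female", "institution_hospital")
  }
  col_of <- function(nm) {
    if (nm %in% c("STAI_q", "RAS_q", "RSES_q"))
      paste0(sub("_q$", "_T", nm), "_q") else nm
  }
  v <- data.frame(
    name = c(ordinal, bin),
    kind = c(rep("ordinal", length(ordinal)), rep("binary", length(bin))),
    column = vapply(c(ordinal, bin), col_of, ""),
    stringsAsFactors = FALSE
  )
  rownames(v) <- NULL
  structure(v, class = c("node_vocabulary", "data.frame"), model = model)
}

vocab_hash <- function(vocab) content_hash(paste(vocab$name, vocab$kind))

#' Drop nodes from a vocabulary (ablation)
#'
#' Used e.g. to assess the model without the PHQ suicidality item
#' (PHQ_9).  The edge matrix must be re-fitted on the restricted set.
#'
#' @param vocab a `node_vocabulary`.
#' @param drop node names to remove.
#' @return the restricted vocabulary.
#' @export
restrict_vocabulary <- function(vocab, drop) {
  stopifnot(inherits(vocab, "node_vocabulary"))
  bad <- setdiff(drop, vocab$name)
  if (length(bad))
    stop_ginscreen("not in vocabulary: ", paste(bad, collapse = ", "),
                   class = "ginscreen_vocab_error")
  out <- vocab[!vocab$name %in% drop, , drop = FALSE]
  if (nrow(out) == 0)
    stop_ginscreen("cannot drop every node", class = "ginscreen_vocab_error")
  rownames(out) <- NULL
  structure(out, class = c("node_vocabulary", "data.frame"),
            model = attr(vocab, "model"))
}

# Integer node codes (ordinal 1..4, binary 0/1) for every subject.
node_codes <- function(table, vocab) {
  miss <- setdiff(vocab$column, names(table))
  if ("MaDE" %in% miss)
    stop_ginscreen("MaDE node required but no MaDE column present; ",
                   "run pseudo_label() first",
                   class = "ginscreen_missing_made")
  if (length(miss))
    stop_ginscreen("columns not found: ", paste(miss, collapse = ", "),
                   class = "ginscreen_schema_error")
  m <- as.matrix(table[, vocab$column, drop = FALSE])
  storage.mode(m) <- "integer"
  colnames(m) <- vocab$name
  if (any(is.na(m)))
    stop_ginscreen("missing node values; MaDE must be pseudo-labeled before ",
                   "encoding", class = "ginscreen_missing_made")
  m
}

#' Fit the shared sparse correlation edge matrix
#'
#' Pairwise correlations between the integer node codes of the training
#' split; entries with absolute value below `threshold` are zeroed, the
#' sign of retained entries is preserved, and the diagonal is zero (the
#' self-contribution enters through the GIN's (1 + epsilon) term
#' instead).  Constant columns get zero correlations with a warning.
#'
#' @param table cohort data frame (training split, quartile-coded and, for
#'   the SI vocabulary, MaDE-filled).
#' @param vocab a `node_vocabulary`.
#' @param method `"spearman"` (default; robust for ordinal codes) or
#'   `"pearson"`.
#' @param threshold sparsity threshold in \[0, 1\].
#' @return object of class `edge_matrix`: the weighted adjacency with
#'   attributes `method`, `threshold`, `vocab_hash`.
#' @export
fit_edge_matrix <- function(table, vocab, method = c("spearman", "pearson"),
                            threshold = 0.6) {
  method <- match.arg(method)
  stopifnot(threshold >= 0, threshold <= 1)
  codes <- node_codes(table, vocab)
  const <- apply(codes, 2, function(v) length(unique(v)) == 1L)
  if (any(const))
    warning("constant node column(s): ",
            paste(colnames(codes)[const], collapse = ", "),
            "; their correlations are set to 0")
  A <- suppressWarnings(cor(codes, method = method))
  A[!is.finite(A)] <- 0
  diag(A) <- 0
  A[abs(A) < threshold] <- 0
  structure(A, class = c("edge_matrix", "matrix"),
            method = method, threshold = threshold,
            vocab_hash = vocab_hash(vocab))
}

#' @export
print.edge_matrix <- function(x, ...) {
  nz <- sum(x != 0) / 2
  cat("Shared edge matrix: ", nrow(x), " nodes, ", nz, " edges (|rho| >= ",
      attr(x, "threshold"), ", ", attr(x, "method"), ")\n", sep = "")
  invisible(x)
}

#' Write / read an edge matrix as TSV plus JSON sidecar
#'
#' @param edges an `edge_matrix`.
#' @param path TSV path; metadata goes to `<path>.json`.
#' @return `path` (write) or the restored `edge_matrix` (read).
#' @export
write_edge_matrix <- function(edges, path) {
  write.table(as.data.frame(unclass(edges)), path, sep = "\t",
              quote = FALSE, row.names = TRUE, col.names = NA)
  jsonlite::write_json(
    list(method = attr(edges, "method"), threshold = attr(edges, "threshold"),
         vocab_hash = attr(edges, "vocab_hash")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_edge_matrix
#' @export
read_edge_matrix <- function(path) {
  m <- as.matrix(read.table(path, sep = "\t", header = TRUE, row.names = 1,
                            check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  structure(m, class = c("edge_matrix", "matrix"), method = meta$method,
            threshold = meta$threshold, vocab_hash = meta$vocab_hash)
}

# slot index per node: ordinal level l -> slot l; binary value b -> slot 5+b
slot_matrix <- function(codes, vocab) {
  S <- codes
  bin <- vocab$kind == "binary"
  if (any(bin)) S[, bin] <- S[, bin, drop = FALSE] + 5L
  if (any(S < 1L | S > 6L))
    stop_ginscreen("node codes out of range", class = "ginscreen_schema_error")
  S
}

#' Encode a cohort as subject graphs
#'
#' All subjects share `edges`; the per-subject state is a vector of
#' feature-slot indices, expanded to one-hot node-feature matrices
#' (nodes x 6) on demand.
#'
#' @param table quartile-coded cohort data frame (with a `MaDE` column
#'   when the SI vocabulary is used).
#' @param vocab a `node_vocabulary`.
#' @param edges an `edge_matrix` fitted on the same vocabulary.
#' @param label_column column carrying the graph label (default
#'   `"acute_SI"`; use `"MaDE_label"` for the MaDE model).
#' @return object of class `subject_graphs`.
#' @export
encode_subjects <- function(table, vocab, edges,
                            label_column = "acute_SI") {
  stopifnot(inherits(edges, "edge_matrix"))
  if (!identical(attr(edges, "vocab_hash"), vocab_hash(vocab)))
    stop_ginscreen("edge matrix was fitted on a different vocabulary",
                   class = "ginscreen_vocab_error")
  codes <- node_codes(table, vocab)
  labels <- table[[label_column]]
  structure(list(slots = slot_matrix(codes, vocab),
                 labels = as.integer(labels),
                 ids = table$subject_id %||% seq_len(nrow(table)),
                 vocab = vocab, edges = edges),
            class = "subject_graphs")
}

#' @export
print.subject_graphs <- function(x, ...) {
  cat("subject_graphs: ", nrow(x$slots), " subjects x ", ncol(x$slots),
      " nodes (", sum(x$labels, na.rm = TRUE), " positive)\n", sep = "")
  invisible(x)
}

n_graphs <- function(graphs) nrow(graphs$slots)

subset_graphs <- function(graphs, idx) {
  graphs$slots <- graphs$slots[idx, , drop = FALSE]
  graphs$labels <- graphs$labels[idx]
  graphs$ids <- graphs$ids[idx]
  graphs
}

#' Encode one subject
#'
#' @param row single-row cohort data frame.
#' @inheritParams encode_subjects
#' @return object of class `subject_graph` with the explicit one-hot
#'   `features` matrix (nodes x 6), the shared `edges`, and the label.
#' @export
encode_subject <- function(row, vocab, edges, label_column = "acute_SI") {
  g <- encode_subjects(row, vocab, edges, label_column)
  structure(list(features = one_hot(g$slots[1, ]),
                 edges = edges, vocab = vocab,
                 id = g$ids[1], label = g$labels[1]),
            class = "subject_graph")
}

# one-hot expansion of a slot vector -> nodes x 6 matrix
one_hot <- function(slots) {
  F <- matrix(0, length(slots), 6)
  F[cbind(seq_along(slots), slots)] <- 1
  rownames(F) <- names(slots)
  F
}

# one-hot expansion of a batch, flat (V*B) x 6 with node index fastest
one_hot_flat <- function(slot_rows) {
  V <- ncol(slot_rows); B <- nrow(slot_rows)
  H <- matrix(0, V * B, 6)
  H[cbind(seq_len(V * B), as.vector(t(slot_rows)))] <- 1
  H
}
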