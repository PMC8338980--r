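# Two-stage training pipeline -------------------------------------------
#
# Stage 1: train the MaDE model on the labeled subset, pseudo-label
# everyone else, so MaDE can serve as an input node.  Stage 2: train
# three acute-SI members on differently resampled training data (ratios
# 10, 5 via under-sampling, 1 via SMOTE-NC), select checkpoints under the
# sensitivity/specificity constraint, and soft-vote.  The external test
# cohort is never resampled and never touches quartile fitting, edge
# fitting, checkpointing or pseudo-label training.

#' Training/validation split plan
#'
#' Stratified split within the training cohort; the test cohort stays
#' fully external and is supplied separately.
#'
#' @param train_fraction fraction assigned to the training partition
#'   (default 0.8).
#' @param seed integer seed.
#' @return object of class `split_plan`.
#' @export
split_plan <- function(train_fraction = 0.8, seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(train_fraction = train_fraction, seed = as.integer(seed)),
            class = "split_plan")
}

#' Stratified train/validation partition
#'
#' Splits indices by class so both classes appear in the validation
#' partition whenever the minority class has at least two members.
#'
#' @param labels binary label vector.
#' @param plan a [split_plan()].
#' @return list with integer vectors `train` and `val`.
#' @export
stratified_split <- function(labels, plan) {
  set.seed(plan$seed)
  tr <- integer(0)
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    n_tr <- floor(plan$train_fraction * length(idx))
    if (length(idx) >= 2) n_tr <- min(n_tr, length(idx) - 1L)
    tr <- c(tr, idx[sample.int(length(idx), n_tr)])
  }
  tr <- sort(tr)
  list(train = tr, val = setdiff(seq_along(labels), tr))
}

#' Train the MaDE prediction model
#'
#' Trains a GIN on the subjects carrying a true MaDE label, using the
#' MaDE vocabulary (19 ordinal nodes + gender + institution; lifetime SA
#' and the MaDE/SI nodes are excluded).  The edge matrix is fitted on the
#' training partition of `edge_table` when given (e.g. the full training
#' cohort) or of the labeled subset otherwise.
#'
#' @param labeled quartile-coded cohort data frame with non-missing
#'   `MaDE_label` for every row.
#' @param config a [gin_config()].
#' @param split a [split_plan()].
#' @param rule a [checkpoint_rule()].
#' @param edge_table optional larger (quartile-coded) table for edge
#'   fitting.
#' @param edge_method,edge_threshold passed to [fit_edge_matrix()].
#' @param seed integer seed.
#' @return a trained `gin_model` for MaDE.
#' @export
train_made_model <- function(labeled, config = gin_config(),
                             split = split_plan(), rule = checkpoint_rule(),
                             edge_table = NULL, edge_method = "spearman",
                             edge_threshold = 0.6, seed = 1) {
  stopifnot(all(!is.na(labeled$MaDE_label)))
  if (length(unique(labeled$MaDE_label)) < 2)
    stop_ginscreen("labeled MaDE subset has a single class",
                   class = "ginscreen_single_class")
  vocab <- node_vocabulary("made")
  parts <- stratified_split(labeled$MaDE_label, split)
  edges <- fit_edge_matrix((edge_table %||% labeled[parts$train, ]), vocab,
                           method = edge_method, threshold = edge_threshold)
  g_tr <- encode_subjects(labeled[parts$train, ], vocab, edges,
                          label_column = "MaDE_label")
  g_va <- encode_subjects(labeled[parts$val, ], vocab, edges,
                          label_column = "MaDE_label")
  train_gin(g_tr, g_va, config, rule, seed = seed)
}

#' Pseudo-label MaDE for unlabeled subjects
#'
#' Every subject gets a MaDE value: the true label where one exists,
#' otherwise the binarized model probability (>= `threshold` maps to 1).
#' True labels are never overwritten.
#'
#' @param model a trained MaDE `gin_model`.
#' @param table quartile-coded cohort data frame.
#' @param threshold binarization threshold (default 0.5).
#' @return object of class `pseudo_label_set`: data frame with columns
#'   `subject_id`, `probability`, `MaDE`, `provenance`.
#' @export
pseudo_label <- function(model, table, threshold = 0.5) {
  vocab <- model$vocab
  edges <- structure(model$A, class = c("edge_matrix", "matrix"),
                     method = model$edge_meta$method,
                     threshold = model$edge_meta$threshold,
                     vocab_hash = model$vocab_hash)
  graphs <- encode_subjects(table, vocab, edges, label_column = "acute_SI")
  prob <- gin_predict(model, graphs)
  has_true <- !is.na(table$MaDE_label)
  out <- data.frame(
    subject_id = table$subject_id %||% seq_len(nrow(table)),
    probability = prob,
    MaDE = ifelse(has_true, table$MaDE_label,
                  as.integer(prob >= threshold)),
    provenance = ifelse(has_true, "true-label", "pseudo-label"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("pseudo_label_set", "data.frame")
  out
}

#' Attach pseudo-labeled MaDE values to a cohort table
#'
#' @param table cohort data frame.
#' @param labels a `pseudo_label_set` for the same subjects (row order).
#' @return `table` with a `MaDE` column.
#' @export
apply_pseudo_labels <- function(table, labels) {
  stopifnot(inherits(labels, "pseudo_label_set"),
            nrow(table) == nrow(labels))
  table$MaDE <- as.integer(labels$MaDE)
  table
}

#' Train one acute-SI ensemble member
#'
#' The member's training partition is resampled to the member's balance
#' ratio, and the member's own validation fold is carved (stratified
#' 80/20) from that resampled pool, so that the checkpoint rule's
#' validation loss and sensitivity/specificity are measured at the class
#' balance the member is trained for.  The external test set is never
#' resampled, and the shared edge matrix always comes from the original
#' (un-resampled) training partition, so synthetic rows never distort
#' the population correlation structure.
#'
#' @param table quartile-coded cohort data frame with a `MaDE` column
#'   (true or pseudo).
#' @param resample a [resample_spec()], or `NULL` to train on the raw
#'   imbalanced partition.
#' @param config a [gin_config()].
#' @param rule a [checkpoint_rule()].
#' @param split a [split_plan()].
#' @param vocab SI `node_vocabulary`.
#' @param edges shared `edge_matrix` (fitted on the un-resampled training
#'   partition).
#' @param seed integer seed.
#' @return a trained `gin_model`.
#' @export
train_si_member <- function(table, resample, config = gin_config(),
                            rule = checkpoint_rule(), split = split_plan(),
                            vocab = node_vocabulary("si"), edges = NULL,
                            seed = 1) {
  parts <- stratified_split(table$acute_SI, split)
  train_tab <- table[parts$train, ]
  if (is.null(edges))
    edges <- fit_edge_matrix(train_tab, vocab)
  if (!is.null(resample)) train_tab <- resample_table(train_tab, resample)
  if (nrow(train_tab) == 0)
    stop_ginscreen("empty training partition after resampling",
                   class = "ginscreen_resample_error")
  inner <- stratified_split(train_tab$acute_SI,
                            split_plan(split$train_fraction,
                                       seed = split$seed + 1L))
  g_tr <- encode_subjects(train_tab[inner$train, ], vocab, edges)
  g_va <- encode_subjects(train_tab[inner$val, ], vocab, edges)
  train_gin(g_tr, g_va, config, rule, seed = seed)
}

#' Soft-voting ensemble of GIN members
#'
#' @param members list of trained `gin_model`s sharing one vocabulary.
#' @return object of class `gin_ensemble`.
#' @export
gin_ensemble <- function(members) {
  stopifnot(length(members) >= 1)
  h <- unname(vapply(members, function(m) m$vocab_hash, ""))
  if (length(unique(h)) != 1)
    stop_ginscreen("ensemble members use different vocabularies",
                   class = "ginscreen_vocab_error")
  structure(list(members = members, vocab_hash = h[1]),
            class = "gin_ensemble")
}

#' Ensemble prediction by soft voting
#'
#' The ensemble sigmoid score is exactly the arithmetic mean of the
#' member sigmoid scores.
#'
#' @param ensemble a `gin_ensemble`.
#' @param graphs a `subject_graphs` set.
#' @return numeric vector of ensemble sigmoid scores.
#' @export
ensemble_predict <- function(ensemble, graphs) {
  stopifnot(inherits(ensemble, "gin_ensemble"))
  if (!identical(ensemble$vocab_hash, vocab_hash(graphs$vocab)))
    stop_ginscreen("graph vocabulary does not match ensemble vocabulary",
                   class = "ginscreen_vocab_error")
  scores <- vapply(ensemble$members, function(m) gin_predict(m, graphs),
                   numeric(n_graphs(graphs)))
  rowMeans(base::matrix(scores, ncol = length(ensemble$members)))
}

# raw (pre-sigmoid) ensemble score: mean of member raw outputs; used for
# the correlation validity analysis, mirroring reporting of the linear
# output before the sigmoid
ensemble_raw_score <- function(ensemble, graphs) {
  scores <- vapply(ensemble$members,
                   function(m) gin_predict(m, graphs, raw = TRUE)$y,
                   numeric(n_graphs(graphs)))
  rowMeans(base::matrix(scores, ncol = length(ensemble$members)))
}

#' Run the full screening pipeline on a train and an external test cohort
#'
#' End-to-end: quartile coding (fitted on the training partition), MaDE
#' model + pseudo-labels, shared SI edge matrix, three resampled members
#' (under-sampling ratios 10 and 5, SMOTE-NC ratio 1), soft-voting
#' ensemble, and evaluation on the untouched external test cohort.  All
#' randomness derives from `master_seed` via [stage_seed()].
#'
#' @param train_cohort,test_cohort validated cohort data frames.
#' @param config a [gin_config()] shared by all members.
#' @param made_config optional distinct config for the MaDE model.  By
#'   default it copies `config` with the batch size capped at 32: the
#'   labeled subset holds only a few hundred rows, and small batches
#'   keep the batch-norm running statistics tracking the weights (one
#'   large batch per epoch updates them far too slowly for calibrated
#'   inference scores).
#' @param rule a [checkpoint_rule()].
#' @param master_seed integer master seed.
#' @param edge_method,edge_threshold edge-matrix settings.
#' @param drop_nodes nodes to ablate (e.g. `"PHQ_9"`).
#' @param ratios named balance ratios for the three members.
#' @param smote_k SMOTE-NC neighbour count.
#' @param stage_epochs named epoch counts per training stage.  The MaDE
#'   model trains on the small labeled subset and the under-sampled
#'   members on 5-30x less data per epoch than the SMOTE member, so by
#'   default those stages run more epochs to receive a comparable number
#'   of optimisation updates; `NA` entries fall back to the config's
#'   epoch count.
#' @return object of class `si_pipeline_fit`: members, ensemble, test
#'   scores and metrics, pseudo-labels, vocabulary, edge matrix.
#' @export
run_si_pipeline <- function(train_cohort, test_cohort,
                            config = gin_config(),
                            made_config = NULL,
                            rule = checkpoint_rule(),
                            master_seed = 1,
                            edge_method = "spearman", edge_threshold = 0.6,
                            drop_nodes = character(),
                            ratios = c(u1 = 10, u2 = 5, smote = 1),
                            smote_k = 5,
                            stage_epochs = c(made = 400, u1 = 40, u2 = 60,
                                             smote = NA)) {
  if (is.null(made_config)) {
    made_config <- config
    made_config$batch_size <- min(config$batch_size, 32L)
  }
  with_epochs <- function(cfg, stage) {
    ep <- if (stage %in% names(stage_epochs)) stage_epochs[[stage]] else NA
    if (!is.na(ep)) cfg$epochs <- as.integer(ep)
    cfg
  }
  split <- split_plan(seed = stage_seed(master_seed, "split"))
  parts <- stratified_split(train_cohort$acute_SI, split)

  coder <- fit_quartile_coder(train_cohort[parts$train, ])
  train_q <- apply_quartile_coder(coder, train_cohort)
  test_q <- apply_quartile_coder(coder, test_cohort)

  labeled <- train_q[!is.na(train_q$MaDE_label), ]
  made_model <- train_made_model(
    labeled, with_epochs(made_config, "made"),
    split = split_plan(seed = stage_seed(master_seed, "made")),
    rule = rule, edge_table = train_q[parts$train, ],
    edge_method = edge_method, edge_threshold = edge_threshold,
    seed = stage_seed(master_seed, "made"))

  pl_train <- pseudo_label(made_model, train_q)
  pl_test <- pseudo_label(made_model, test_q)
  train_q <- apply_pseudo_labels(train_q, pl_train)
  test_q <- apply_pseudo_labels(test_q, pl_test)

  vocab <- node_vocabulary("si")
  if (length(drop_nodes)) vocab <- restrict_vocabulary(vocab, drop_nodes)
  edges <- fit_edge_matrix(train_q[parts$train, ], vocab,
                           method = edge_method, threshold = edge_threshold)

  specs <- list(
    u1 = resample_spec("under", ratios[["u1"]],
                       seed = stage_seed(master_seed, "u1")),
    u2 = resample_spec("under", ratios[["u2"]],
                       seed = stage_seed(master_seed, "u2")),
    smote = resample_spec("smote-nc", ratios[["smote"]], k = smote_k,
                          seed = stage_seed(master_seed, "smote"))
  )
  members <- lapply(names(specs), function(nm)
    train_si_member(train_q, specs[[nm]], with_epochs(config, nm), rule,
                    split, vocab, edges,
                    seed = stage_seed(master_seed, nm)))
  names(members) <- names(specs)

  ens <- gin_ensemble(members)
  g_test <- encode_subjects(test_q, vocab, edges)
  test_scores <- ensemble_predict(ens, g_test)
  member_scores <- lapply(members, function(m) gin_predict(m, g_test))

  structure(list(
    members = members, ensemble = ens, vocab = vocab, edges = edges,
    quartile_coder = coder, made_model = made_model,
    pseudo_labels = list(train = pl_train, test = pl_test),
    split = parts, train_table = train_q, test_table = test_q,
    test_graphs = g_test, test_scores = test_scores,
    member_scores = member_scores,
    test_metrics = metrics_report(test_scores, test_q$acute_SI),
    master_seed = master_seed
  ), class = "si_pipeline_fit")
}

#' @export
print.si_pipeline_fit <- function(x, ...) {
  m <- x$test_metrics
  cat("Acute-SI GIN ensemble (seed ", x$master_seed, ")\n", sep = "")
  cat(sprintf("  external test: n = %d (%d positive)\n", m$n, m$n_pos))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  accuracy %.3f\n",
              m$sensitivity, m$specificity, m$accuracy))
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f)\n", m$auc, m$auc_ci[1],
              m$auc_ci[2]))
  invisible(x)
}
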