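# Shared fixtures and independent oracles ------------------------------

# tiny hand-built vocabulary + edge matrix (bypassing fit_edge_matrix)
toy_vocab <- function(n_ordinal = 3, n_binary = 2) {
  nm <- c(paste0("o", seq_len(n_ordinal)),
          if (n_binary) paste0("b", seq_len(n_binary)))
  structure(data.frame(
    name = nm,
    kind = c(rep("ordinal", n_ordinal), rep("binary", n_binary)),
    column = nm, stringsAsFactors = FALSE
  ), class = c("node_vocabulary", "data.frame"))
}

toy_edges <- function(vocab, A = NULL, threshold = 0) {
  V <- nrow(vocab)
  if (is.null(A)) A <- matrix(0, V, V)
  dimnames(A) <- list(vocab$name, vocab$name)
  structure(A, class = c("edge_matrix", "matrix"), method = "spearman",
            threshold = threshold,
            vocab_hash = ginscreen:::vocab_hash(vocab))
}

toy_graph <- function(slots, vocab, edges, label = 0L) {
  F <- matrix(0, length(slots), 6)
  F[cbind(seq_along(slots), slots)] <- 1
  rownames(F) <- vocab$name
  structure(list(features = F, edges = edges, vocab = vocab,
                 id = "t1", label = label), class = "subject_graph")
}

toy_graphs <- function(slot_rows, vocab, edges, labels) {
  structure(list(slots = slot_rows, labels = as.integer(labels),
                 ids = seq_len(nrow(slot_rows)), vocab = vocab,
                 edges = edges), class = "subject_graphs")
}

# random slot rows for a vocabulary
random_slots <- function(n, vocab) {
  V <- nrow(vocab)
  m <- matrix(0L, n, V)
  for (j in seq_len(V))
    m[, j] <- if (vocab$kind[j] == "ordinal") sample(1:4, n, TRUE)
              else sample(5:6, n, TRUE)
  m
}

# small well-formed cohort table for I/O tests
toy_cohort <- function(n = 12, seed = 7) {
  set.seed(seed)
  df <- data.frame(subject_id = sprintf("S%03d", 1:n))
  for (cl in c(paste0("PHQ_", 1:9), paste0("GAD_", 1:7)))
    df[[cl]] <- sample(1:4, n, TRUE)
  df$STAI_T <- sample(20:80, n, TRUE)
  df$RAS_T <- sample(12:60, n, TRUE)
  df$RSES_T <- sample(10:40, n, TRUE)
  df$lifetime_SA <- rbinom(n, 1, 0.3)
  df$gender_female <- rbinom(n, 1, 0.5)
  df$institution_hospital <- rbinom(n, 1, 0.5)
  df$MaDE_label <- ifelse(seq_len(n) <= 4, rbinom(n, 1, 0.5), NA)
  df$acute_SI <- rbinom(n, 1, 0.4)
  df$KSSI_total <- ifelse(seq_len(n) %% 2 == 0, sample(0:30, n, TRUE), NA)
  df
}

# Independent naive SMOTE-NC: plain loops, no shared code with the
# package implementation beyond the documented RNG protocol.
oracle_smote_nc <- function(table, ratio, k, seed, nominal_columns,
                            label_column = "acute_SI") {
  cont_cols <- intersect(c(paste0("PHQ_", 1:9), paste0("GAD_", 1:7),
                           c("STAI_T", "RAS_T", "RSES_T")), names(table))
  y <- table[[label_column]]
  pos <- which(y == 1)
  n_pos <- length(pos); n_neg <- sum(y == 0)
  n_syn <- round(n_neg / ratio) - n_pos
  if (n_syn <= 0) return(table)
  med <- median(vapply(cont_cols, function(cl) sd(table[pos, cl]), 0))
  d2 <- function(i, j) {
    s <- 0
    for (cl in cont_cols) s <- s + (table[pos[i], cl] - table[pos[j], cl])^2
    for (cl in nominal_columns)
      if (table[pos[i], cl] != table[pos[j], cl]) s <- s + med^2
    s
  }
  nbrs <- lapply(seq_len(n_pos), function(i) {
    d <- vapply(seq_len(n_pos), function(j) d2(i, j), 0)
    d[i] <- Inf
    order(d)[seq_len(k)]
  })
  set.seed(seed)
  seed_i <- sample(n_pos, n_syn, replace = TRUE)
  nbr_choice <- sample(k, n_syn, replace = TRUE)
  gaps <- runif(n_syn)
  syn <- table[pos[seed_i], , drop = FALSE]
  for (i in seq_len(n_syn)) {
    a <- pos[seed_i[i]]
    b <- pos[nbrs[[seed_i[i]]][nbr_choice[i]]]
    for (cl in cont_cols) {
      v <- table[a, cl] + gaps[i] * (table[b, cl] - table[a, cl])
      v <- round(v)
      if (grepl("^(PHQ|GAD)_", cl)) v <- min(max(v, 1), 4)
      syn[i, cl] <- v
    }
    for (cl in nominal_columns) {
      vals <- table[pos[nbrs[[seed_i[i]]]], cl]
      uv <- sort(unique(vals))
      cnt <- sapply(uv, function(u) sum(vals == u))
      top <- uv[cnt == max(cnt)]
      syn[i, cl] <- if (length(top) == 1) top else table[a, cl]
    }
  }
  if ("subject_id" %in% names(syn))
    syn$subject_id <- sprintf("SYN%06d", seq_len(n_syn))
  if ("MaDE_label" %in% names(syn)) syn$MaDE_label <- NA_integer_
  if ("KSSI_total" %in% names(syn)) syn$KSSI_total <- NA_integer_
  syn[[label_column]] <- 1L
  out <- rbind(table, syn)
  rownames(out) <- NULL
  out
}

# rank-based AUC for oracles (independent of the package's midrank path:
# explicit pair counting)
oracle_auc_paircount <- function(scores, labels) {
  xs <- scores[labels == 1]; ys <- scores[labels == 0]
  tot <- 0
  for (x in xs) tot <- tot + sum(x > ys) + 0.5 * sum(x == ys)
  tot / (length(xs) * length(ys))
}

# fast AUC for bootstrap loops (midranks; only used to drive oracles)
boot_auc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * (length(labels) - n1))
}

# dense-matrix reference forward for a GIN with identity MLPs
dense_identity_forward <- function(A, eps, H0, w, b, K) {
  H <- H0
  G <- c()
  V <- nrow(H0)
  for (k in seq_len(K)) {
    H <- (A + (1 + eps[k]) * diag(V)) %*% H
    G <- c(G, colSums(H))
  }
  sum(G * w) + b
}
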