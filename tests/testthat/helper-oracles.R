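# Independent first-principles oracles and small fixture builders.

# --- metric oracle: recompute everything by explicit counting ---------------

# expand a confusion matrix (rows = truth, cols = pred) into label vectors
expand_confusion <- function(cm) {
  K <- nrow(cm)
  truth <- integer(0); pred <- integer(0)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (cm[i, j] > 0) {
      truth <- c(truth, rep(i, cm[i, j]))
      pred <- c(pred, rep(j, cm[i, j]))
    }
  }
  list(truth = truth, pred = pred)
}

oracle_metrics <- function(truth, pred, K) {
  n <- length(truth)
  bal <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    tp <- sum(truth == k & pred == k)
    fn <- sum(truth == k & pred != k)
    fp <- sum(truth != k & pred == k)
    tn <- sum(truth != k & pred != k)
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spe <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    bal[k] <- (rec + spe) / 2
  }
  po <- sum(truth == pred) / n
  pe <- 0
  for (k in seq_len(K))
    pe <- pe + (sum(truth == k) / n) * (sum(pred == k) / n)
  kappa <- if (abs(1 - pe) < 1e-12) { if (abs(po - 1) < 1e-12) 1 else 0 }
           else (po - pe) / (1 - pe)
  list(accuracy = po, balanced = bal,
       mean_balanced = mean(bal, na.rm = TRUE), kappa = kappa)
}

oracle_adjacent <- function(truth, pred, K, tolerance) {
  pred2 <- pred
  for (i in seq_along(pred))
    if (abs(truth[i] - pred[i]) <= tolerance) pred2[i] <- truth[i]
  oracle_metrics(truth, pred2, K)
}

# --- interpolation oracle: closed-form linear interpolation in ln(effort) --

oracle_effort_at <- function(effort, coverage, target) {
  i <- max(which(coverage <= target))
  if (coverage[i] == target) return(effort[i])
  j <- i + 1L
  w <- (target - coverage[i]) / (coverage[j] - coverage[i])
  exp(log(effort[i]) + w * (log(effort[j]) - log(effort[i])))
}

# --- tiny fixture writers ---------------------------------------------------

write_profile_fixture <- function(path = tempfile(fileext = ".tsv")) {
  df <- data.frame(
    taxon = c("k_Bacteria;p_Proteobacteria;c_Gammaproteobacteria;o_Pseudomonadales;f_Pseudomonadaceae;g_Pseudomonas;s_Pseudomonas fragi",
              "k_Bacteria;p_Firmicutes",
              "k_Eukaryota"),
    s1 = c(120L, 30L, 10L),
    s2 = c(80L, 0L, 5L),
    check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_metadata_fixture <- function(path = tempfile(fileext = ".csv"),
                                   n = 4) {
  vocab <- metasurv::default_metadata_vocabulary()
  df <- data.frame(sample_id = paste0("s", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (f in names(vocab)) df[[f]] <- rep_len(vocab[[f]], n)
  utils::write.csv(df, path, row.names = FALSE)
  path
}
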