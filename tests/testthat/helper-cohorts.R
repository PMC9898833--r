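# Builders for small hand-specified cohorts used across tests.

toy_meta <- function(names, kinds, ref_low = NA_real_, ref_high = NA_real_) {
  data.frame(name = names, kind = kinds,
             ref_low = rep_len(ref_low, length(names)),
             ref_high = rep_len(ref_high, length(names)),
             synonym_group = names, impute_exclude = FALSE,
             stringsAsFactors = FALSE)
}

# cohort from an explicit observed matrix (NAs allowed), one kind per column
toy_cohort <- function(observed, outcome, kinds,
                       ref_low = NA_real_, ref_high = NA_real_) {
  observed <- as.matrix(observed)
  nm <- colnames(observed)
  if (is.null(nm)) nm <- paste0("v", seq_len(ncol(observed)))
  colnames(observed) <- nm
  emr_cohort(observed, outcome, toy_meta(nm, kinds, ref_low, ref_high))
}

# brute-force AUROC by pairwise concordance counting (ties = 1/2)
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  total / (length(pos) * length(neg))
}

# brute-force Pearson chi-square from a contingency table
chisq_bruteforce <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# kappa straight from a confusion matrix
kappa_from_table <- function(tab) {
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  (p_o - p_e) / (1 - p_e)
}
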