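# Independent straight-line re-implementation of the labelling rules, kept
# deliberately naive (per-timepoint loops, no shared code with the package)
# so it can serve as an oracle for the labelling engine.
oracle_label <- function(baseline, baseline_rano, series, annotation,
                         window, metric, scheme) {
  s <- series[series$months < window, , drop = FALSE]
  v0 <- baseline[1] * baseline[2] * baseline[3]
  prog <- FALSE
  if (metric == "RANO_20") {
    for (k in seq_len(nrow(s))) {
      r <- s$rano_mm[k]
      if (is.na(r)) next
      big_enough <- baseline_rano >= 10 || (r - baseline_rano) >= 3
      if (r >= 1.2 * baseline_rano && big_enough) prog <- TRUE
    }
  } else {
    pct <- as.numeric(sub("VOL_", "", metric))
    for (k in seq_len(nrow(s))) {
      v <- s$d_pa_mm[k] * s$d_ml_mm[k] * s$d_si_mm[k]
      if (v >= v0 * (1 + pct / 100) && (v - v0) >= 27) prog <- TRUE
    }
  }
  adjudicated <- prog
  if (prog && annotation == "PP" &&
      !(scheme %in% c("TRUE_PLUS_PP", "TRUE_PLUS_RN_PP"))) adjudicated <- FALSE
  if (prog && annotation == "RN" &&
      !(scheme %in% c("TRUE_PLUS_RN", "TRUE_PLUS_RN_PP"))) adjudicated <- FALSE
  if (adjudicated) return("progressing")
  if (nrow(s) == 0) return("stable")
  if (metric == "RANO_20") {
    rr <- s$rano_mm[!is.na(s$rano_mm)]
    if (length(rr) > 0 && rr[length(rr)] <= 0.7 * baseline_rano) {
      return("regressing")
    }
    return("stable")
  }
  pct <- as.numeric(sub("VOL_", "", metric))
  n <- nrow(s)
  v_last <- s$d_pa_mm[n] * s$d_ml_mm[n] * s$d_si_mm[n]
  if (v_last <= v0 * (1 - pct / 100) && (v0 - v_last) >= 27) {
    return("regressing")
  }
  "stable"
}

# brute-force pairwise-concordance AUC
oracle_auc <- function(probs, labels) {
  pos <- probs[as.logical(labels)]
  neg <- probs[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}
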