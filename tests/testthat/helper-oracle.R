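# Independent brute-force oracles for the evaluation arithmetic. Deliberately
# naive (scalar loops, direct formulas) and shared by nothing in R/.

oracle_row <- function(tp, fp, fn, tn) {
  P <- if ((tp + fp) > 0) tp / (tp + fp) else NA_real_
  R <- if ((tp + fn) > 0) tp / (tp + fn) else NA_real_
  S <- if ((tn + fp) > 0) tn / (tn + fp) else NA_real_
  F1 <- if (tp == 0 && fp == 0 && fn == 0) {
    NA_real_
  } else if (!is.na(P) && !is.na(R) && (P + R) > 0) {
    2 * P * R / (P + R)
  } else {
    0
  }
  c(precision = P, recall = R, specificity = S, f1 = F1)
}

oracle_metrics <- function(counts) {
  # counts: data.frame label_id, tp, fp, fn, tn
  per <- t(mapply(oracle_row, counts$tp, counts$fp, counts$fn, counts$tn))
  micro <- oracle_row(sum(counts$tp), sum(counts$fp), sum(counts$fn), sum(counts$tn))
  macro <- apply(per, 2, function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  list(per_label = per, micro = micro, macro = macro)
}

oracle_confusion <- function(pred, gold, labels) {
  # pred/gold: named lists unit -> character labels; exhaustive unit x label scan
  units <- names(gold)
  tp <- fp <- fn <- tn <- integer(length(labels))
  for (u in units) {
    for (i in seq_along(labels)) {
      l <- labels[i]
      p <- l %in% pred[[u]]
      g <- l %in% gold[[u]]
      if (p && g) tp[i] <- tp[i] + 1L
      else if (p && !g) fp[i] <- fp[i] + 1L
      else if (!p && g) fn[i] <- fn[i] + 1L
      else tn[i] <- tn[i] + 1L
    }
  }
  data.frame(label_id = labels, tp = tp, fp = fp, fn = fn, tn = tn)
}

# Brute-force threshold sweep: re-threshold every patient at every k and pool.
oracle_sweep <- function(counts, gold, labels, k_max) {
  patients <- names(gold)
  res <- data.frame(k = seq_len(k_max), micro_p = NA_real_, micro_r = NA_real_,
                    micro_s = NA_real_, micro_f1 = NA_real_)
  for (k in seq_len(k_max)) {
    pred <- lapply(patients, function(p) {
      d <- counts[counts$patient_id == p, ]
      d$label_id[d$n_pos >= k]
    })
    names(pred) <- patients
    cc <- oracle_confusion(pred, gold, labels)
    m <- oracle_row(sum(cc$tp), sum(cc$fp), sum(cc$fn), sum(cc$tn))
    res[k, 2:5] <- m[c("precision", "recall", "specificity", "f1")]
  }
  f1 <- ifelse(is.na(res$micro_f1), -Inf, res$micro_f1)
  list(curve = res, k_best = res$k[which.max(f1)])
}
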