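# Metrics, protein- and residue-based evaluation, thresholding, and the
# resampling significance test.

#' Classification metrics for binding-residue prediction
#'
#' Recall, precision, F1, Matthews correlation coefficient at a threshold,
#' plus threshold-free AUC (rank statistic) and AUPR (step-interpolated
#' precision-recall integration). With a single observed class AUC/AUPR are
#' `NaN` and flagged by a message.
#'
#' @param scores Numeric score vector.
#' @param labels 0/1 labels.
#' @param threshold Decision threshold (score >= threshold is positive).
#' @return Named list: `recall, precision, f1, mcc, auc, aupr, tp, tn, fp, fn`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (recall + precision > 0) 2 * recall * precision / (recall + precision) else 0
  mcc_den <- sqrt(tp + fn) * sqrt(tp + fp) * sqrt(tn + fn) * sqrt(tn + fp)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else 0
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) {
    message("compute_metrics: single-class labels; AUC/AUPR undefined")
    auc <- aupr <- NaN
  } else {
    r <- rank(scores)
    auc <- (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
    aupr <- .aupr_step(scores, labels)
  }
  list(recall = recall, precision = precision, f1 = f1, mcc = mcc,
       auc = auc, aupr = aupr, tp = tp, tn = tn, fp = fp, fn = fn)
}

# step-interpolated AUPR; tied scores processed as one group
.aupr_step <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  np <- sum(y)
  groups <- cumsum(!duplicated(s))
  tp_cum <- cumsum(y); n_cum <- seq_along(y)
  last <- !duplicated(groups, fromLast = TRUE)
  tp_g <- tp_cum[last]; n_g <- n_cum[last]
  prec <- tp_g / n_g
  rec <- tp_g / np
  sum(diff(c(0, rec)) * prec)
}

#' Decision threshold maximising F1
#'
#' Scans the midpoints between consecutive unique scores (plus the
#' endpoints) and returns the threshold with the highest F1; the pipeline
#' fits it on training folds and stores it in the model bundle.
#'
#' @param scores,labels Training scores and 0/1 labels.
#' @return Numeric threshold.
#' @export
best_f1_threshold <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- unique(c(u, (u[-1] + u[-length(u)]) / 2, min(u) - 1e-9, max(u) + 1e-9))
  f1s <- vapply(cand, function(th) {
    m <- suppressMessages(compute_metrics(scores, labels, th))
    m$f1
  }, 0)
  cand[which.max(f1s)]
}

#' Protein-based evaluation
#'
#' Metrics are computed per protein and averaged without weighting; proteins
#' whose AUC/AUPR are undefined (single-class) are excluded from those means
#' with a message.
#'
#' @param score_list,label_list Parallel lists, one element per protein.
#' @param threshold Decision threshold.
#' @return Named list of averaged metrics plus `n_proteins`.
#' @export
protein_based_eval <- function(score_list, label_list, threshold = 0.5) {
  stopifnot(length(score_list) == length(label_list), length(score_list) >= 1)
  per <- mapply(function(s, l) {
    suppressMessages(compute_metrics(s, l, threshold))
  }, score_list, label_list, SIMPLIFY = FALSE)
  fields <- c("recall", "precision", "f1", "mcc", "auc", "aupr")
  out <- lapply(fields, function(f) {
    v <- vapply(per, `[[`, 0, f)
    if (f %in% c("auc", "aupr") && any(is.nan(v))) {
      message("protein_based_eval: ", sum(is.nan(v)),
              " protein(s) excluded from ", f, " mean (single class)")
    }
    mean(v[!is.nan(v)])
  })
  names(out) <- fields
  out$n_proteins <- length(per)
  out
}

#' Residue-based evaluation
#'
#' All residues of all proteins are pooled into one vector before computing
#' the metrics.
#'
#' @inheritParams protein_based_eval
#' @export
residue_based_eval <- function(score_list, label_list, threshold = 0.5) {
  compute_metrics(unlist(score_list), unlist(label_list), threshold)
}

#' Resampling significance test between two models
#'
#' Ten paired resamples of 70% of the proteins; per resample the mean
#' per-protein AUC of each model. The Anderson-Darling test (alpha 0.05) on
#' the paired differences gates the choice between a paired t-test and the
#' paired Wilcoxon signed-rank test. Identical models short-circuit to a
#' degenerate no-difference report.
#'
#' @param scores_a,scores_b Per-protein score lists for the two models.
#' @param labels Per-protein label list shared by both models.
#' @param reps Resampling repetitions (10).
#' @param frac Protein fraction per resample (0.7).
#' @param seed RNG seed.
#' @param metric `"auc"` or `"aupr"`.
#' @return List with `p.value`, `test`, `means_a`, `means_b`.
#' @export
significance_test <- function(scores_a, scores_b, labels, reps = 10, frac = 0.7,
                              seed = 1, metric = c("auc", "aupr")) {
  metric <- match.arg(metric)
  n <- length(labels)
  if (n < 3) stop("need at least 3 proteins")
  stopifnot(length(scores_a) == n, length(scores_b) == n)
  per_auc <- function(scores) {
    vapply(seq_len(n), function(i) {
      suppressMessages(compute_metrics(scores[[i]], labels[[i]]))[[metric]]
    }, 0)
  }
  va <- per_auc(scores_a); vb <- per_auc(scores_b)
  set.seed(seed)
  ma <- mb <- numeric(reps)
  for (r in seq_len(reps)) {
    idx <- sample(n, max(1, round(frac * n)))
    ma[r] <- mean(va[idx], na.rm = TRUE)
    mb[r] <- mean(vb[idx], na.rm = TRUE)
  }
  d <- ma - mb
  if (all(abs(d) < 1e-12)) {
    return(list(p.value = 1, test = "degenerate (no difference)", means_a = ma, means_b = mb))
  }
  normal <- tryCatch(nortest::ad.test(d)$p.value > 0.05, error = function(e) FALSE)
  if (normal) {
    tt <- stats::t.test(ma, mb, paired = TRUE)
    list(p.value = tt$p.value, test = "paired t-test", means_a = ma, means_b = mb)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(ma, mb, paired = TRUE))
    list(p.value = wt$p.value, test = "Wilcoxon signed-rank", means_a = ma, means_b = mb)
  }
}
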