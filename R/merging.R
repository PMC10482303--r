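# Stacked generalization: the 5 deep-learning scores and 3 template scores
# feed a gradient-boosted meta-classifier.

.stack_cols <- c(paste0("dl_seed", 1:5), "tl_rf", "tl_xgb", "tl_lgbm")

#' Assemble the 8-column stacking input
#'
#' Fixed column order `dl_seed1..5, tl_rf, tl_xgb, tl_lgbm`. A missing
#' template block is zero-filled with a warning (degraded, template-less
#' mode).
#'
#' @param dl_scores `n x 5` matrix of per-seed deep-learning probabilities.
#' @param tl_scores `n x 3` matrix of template-classifier probabilities, or
#'   `NULL`.
#' @return `n x 8` matrix.
#' @export
build_stack_features <- function(dl_scores, tl_scores = NULL) {
  dl_scores <- as.matrix(dl_scores)
  if (ncol(dl_scores) != 5) stop("expected 5 deep-learning score columns")
  if (is.null(tl_scores)) {
    warning("template scores missing; zero-filling 3 columns")
    tl_scores <- matrix(0, nrow(dl_scores), 3)
  }
  tl_scores <- as.matrix(tl_scores)
  if (ncol(tl_scores) != 3) stop("expected 3 template score columns")
  if (nrow(tl_scores) != nrow(dl_scores)) stop("residue count mismatch")
  out <- cbind(dl_scores, tl_scores)
  if (any(out < 0 | out > 1)) stop("stack scores must lie in [0, 1]")
  colnames(out) <- .stack_cols
  out
}

#' Train the stacking meta-classifier
#'
#' A shallow leaf-wise gradient-boosted model over the 8 lower-level scores.
#' Callers must supply out-of-fold lower-level scores for training rows (the
#' pipeline's trainer constructs them); full-model scores are used at
#' inference.
#'
#' @param stack `n x 8` matrix from [build_stack_features()].
#' @param labels 0/1 vector (both classes required).
#' @param nrounds,max_depth,eta Meta-learner hyperparameters.
#' @param seed RNG seed.
#' @return An `xgb.Booster` meta-model.
#' @export
train_meta <- function(stack, labels, nrounds = 200, max_depth = 4, eta = 0.05,
                       seed = 1) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes required to train the meta-model")
  set.seed(seed)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = eta,
                  tree_method = "hist", grow_policy = "lossguide",
                  max_leaves = 15, max_depth = max_depth,
                  scale_pos_weight = max(1, sum(labels == 0) / max(1, sum(labels == 1))),
                  nthread = 1),
    data = xgboost::xgb.DMatrix(stack, label = labels),
    nrounds = nrounds, verbose = 0
  )
}

#' Predict merged probabilities
#'
#' @param meta Meta-model from [train_meta()].
#' @param stack `n x 8` matrix.
#' @return Per-residue probabilities in \[0, 1\].
#' @export
predict_meta <- function(meta, stack) {
  as.numeric(stats::predict(meta, xgboost::xgb.DMatrix(as.matrix(stack))))
}
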