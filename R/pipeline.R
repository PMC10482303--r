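# End-to-end orchestration: feature assembly, bundle training with
# out-of-fold stacking, prediction with RWR post-processing, and
# protein-level cross-validation.

#' Pipeline configuration
#'
#' @param egat Deep-learning config from [egat_train_config()].
#' @param stack_folds Folds for out-of-fold stacking-input construction.
#' @param rwr Post-processing config from [rwr_config()].
#' @param alpha,l_max Descriptor parameters (ORC laziness, MFD box bound).
#' @param tl_ntree,tl_nrounds Template-classifier ensemble sizes.
#' @param threshold_fallback Decision threshold when F1 selection is
#'   impossible.
#' @export
nabind_config <- function(egat = egat_train_config(), stack_folds = 5,
                          rwr = rwr_config(), alpha = 0.5, l_max = 5,
                          tl_ntree = 300, tl_nrounds = 150,
                          threshold_fallback = 0.5) {
  list(egat = egat, stack_folds = stack_folds, rwr = rwr, alpha = alpha,
       l_max = l_max, tl_ntree = tl_ntree, tl_nrounds = tl_nrounds,
       threshold_fallback = threshold_fallback)
}

#' Prepare per-protein model inputs
#'
#' Computes RSA, the contact graph, the structural descriptor matrix, and
#' concatenates any extra feature block (synthetic embeddings, profile
#' transforms) in a fixed order.
#'
#' @param fixtures List of `list(protein, labels, ...)` entries (e.g. from
#'   [make_toy_protein()]).
#' @param features Optional parallel list of extra per-residue feature
#'   matrices.
#' @param cfg From [nabind_config()].
#' @param rsa Compute solvent accessibility (needed for RWR).
#' @return List of prepared entries: `protein, graph, labels, node_raw,
#'   edge_raw`.
#' @export
nabind_prepare <- function(fixtures, features = NULL, cfg = nabind_config(),
                           rsa = TRUE) {
  lapply(seq_along(fixtures), function(i) {
    fx <- fixtures[[i]]
    protein <- fx$protein
    if (rsa) protein <- compute_rsa(protein)
    graph <- build_graph(protein)
    desc <- struct_descriptor_matrix(protein, graph, alpha = cfg$alpha, l_max = cfg$l_max)
    extra <- if (!is.null(features)) features[[i]] else NULL
    node_raw <- if (is.null(extra)) desc else cbind(desc, extra)
    list(protein = protein, graph = graph, labels = fx$labels,
         node_raw = node_raw,
         edge_raw = cbind(dist = graph$edge_dist, orient = graph$edge_orient))
  })
}

#' Template features for a set of prepared proteins
#'
#' Selects templates for every protein once (selection does not depend on
#' training folds) and computes the 120-column feature matrix.
#'
#' @param prepared From [nabind_prepare()].
#' @param library Template library (list of [template_entry()]).
#' @return List with `X` (per-protein feature matrices) and `hits`.
#' @export
template_features_for <- function(prepared, library) {
  hits <- lapply(prepared, function(pp) select_templates(pp$protein, library))
  X <- mapply(function(pp, h) template_residue_features(pp$protein, h),
              prepared, hits, SIMPLIFY = FALSE)
  list(X = X, hits = hits)
}

.protein_folds <- function(n, k, seed) {
  if (k > n) stop("k exceeds the number of proteins")
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

.fit_lower <- function(prepared, tl_X, idx, cfg) {
  # z-score parameters and lower-level models on proteins `idx` only;
  # the same seeds are used in every fold so stack columns stay aligned
  zn <- zscore_fit(do.call(rbind, lapply(prepared[idx], `[[`, "node_raw")))
  ze <- zscore_fit(do.call(rbind, lapply(prepared[idx], `[[`, "edge_raw")))
  dataset <- lapply(prepared[idx], function(pp) {
    list(graph = pp$graph, H = zscore_apply(pp$node_raw, zn),
         Fe = zscore_apply(pp$edge_raw, ze), labels = pp$labels)
  })
  dl <- train_egat(dataset, cfg$egat)
  tl <- NULL
  if (!is.null(tl_X)) {
    Xtr <- do.call(rbind, tl_X[idx])
    ytr <- unlist(lapply(prepared[idx], `[[`, "labels"))
    tl <- tryCatch(
      train_template_classifiers(Xtr, ytr, seed = 1,
                                 ntree = cfg$tl_ntree, nrounds = cfg$tl_nrounds),
      error = function(e) { warning("template classifiers skipped: ", conditionMessage(e)); NULL }
    )
  }
  list(zn = zn, ze = ze, dl = dl, tl = tl)
}

.lower_scores <- function(lower, prepared, tl_X, idx) {
  lapply(idx, function(i) {
    pp <- prepared[[i]]
    H <- zscore_apply(pp$node_raw, lower$zn)
    Fe <- zscore_apply(pp$edge_raw, lower$ze)
    dl <- predict_egat(lower$dl, pp$graph, H, Fe)
    tl <- if (!is.null(lower$tl) && !is.null(tl_X)) {
      predict_template_classifiers(lower$tl, tl_X[[i]])
    } else NULL
    build_stack_features(dl, tl)
  })
}

#' Train a full prediction bundle
#'
#' Fits Z-score normalisation, the five-seed deep-learning ensemble and the
#' three template classifiers on the whole training set; builds the
#' stacking input from out-of-fold lower-level scores (protein-level folds)
#' and trains the meta-model on it; selects the F1-maximising decision
#' threshold on the out-of-fold merged scores.
#'
#' @param prepared Training proteins from [nabind_prepare()].
#' @param tl_X Optional per-protein template feature matrices from
#'   [template_features_for()]; `NULL` runs the degraded template-less mode.
#' @param cfg From [nabind_config()].
#' @param seed Fold-assignment seed.
#' @return A `nabind_bundle`.
#' @export
train_nabind <- function(prepared, tl_X = NULL, cfg = nabind_config(), seed = 1) {
  n <- length(prepared)
  full <- .fit_lower(prepared, tl_X, seq_len(n), cfg)
  folds <- .protein_folds(n, min(cfg$stack_folds, n), seed)
  oof <- vector("list", n)
  for (f in sort(unique(folds))) {
    tr <- which(folds != f); te <- which(folds == f)
    lower_f <- .fit_lower(prepared, tl_X, tr, cfg)
    oof[te] <- suppressWarnings(.lower_scores(lower_f, prepared, tl_X, te))
  }
  stack <- do.call(rbind, oof)
  y <- unlist(lapply(prepared, `[[`, "labels"))
  meta <- train_meta(stack, y)
  merged_oof <- predict_meta(meta, stack)
  threshold <- tryCatch(best_f1_threshold(merged_oof, y),
                        error = function(e) cfg$threshold_fallback)
  structure(
    list(zn = full$zn, ze = full$ze, dl = full$dl, tl = full$tl, meta = meta,
         threshold = threshold, cfg = cfg,
         manifest = full$zn$names),
    class = "nabind_bundle"
  )
}

#' Predict binding residues for one prepared protein
#'
#' Runs the deep-learning and template stages, merges them through the
#' stacking meta-model, applies the random-walk-with-restart correction on
#' surface residues, and thresholds the final probabilities.
#'
#' @param bundle From [train_nabind()].
#' @param pp One element of [nabind_prepare()] output.
#' @param tl_X_i Template feature matrix for this protein, or `NULL`.
#' @param rwr Apply the post-processing stage.
#' @return Data frame: `residue_id, p_dl_mean, p_tl_mean, p_merged, p_final,
#'   label_pred`.
#' @export
predict_nabind <- function(bundle, pp, tl_X_i = NULL, rwr = TRUE) {
  H <- zscore_apply(pp$node_raw, bundle$zn)
  Fe <- zscore_apply(pp$edge_raw, bundle$ze)
  dl <- predict_egat(bundle$dl, pp$graph, H, Fe)
  tl <- if (!is.null(bundle$tl) && !is.null(tl_X_i)) {
    predict_template_classifiers(bundle$tl, tl_X_i)
  } else NULL
  stack <- suppressWarnings(build_stack_features(dl, tl))
  merged <- predict_meta(bundle$meta, stack)
  final <- merged
  if (rwr) {
    surface <- build_surface_weights(pp$protein, bundle$cfg$rwr)
    final <- rwr_iterate(merged, surface, bundle$cfg$rwr)
  }
  data.frame(
    residue_id = pp$protein$residues$resno,
    p_dl_mean = rowMeans(dl),
    p_tl_mean = if (is.null(tl)) 0 else rowMeans(tl),
    p_merged = merged,
    p_final = final,
    label_pred = as.integer(final >= bundle$threshold)
  )
}

#' Protein-level cross-validation
#'
#' Splits proteins (never residues) into k folds, trains a full bundle on
#' each training split and evaluates on the held-out proteins. Nothing from
#' a test fold reaches normalisation, stacking or threshold selection.
#'
#' @param prepared From [nabind_prepare()].
#' @param tl_X Optional template features from [template_features_for()].
#' @param k Number of folds.
#' @param seed Fold seed.
#' @param cfg From [nabind_config()].
#' @return List with per-fold results, pooled per-protein score/label lists
#'   per stage (`dl`, `tl`, `merged`, `final`), and protein-based AUC per
#'   stage.
#' @export
cross_validate <- function(prepared, tl_X = NULL, k = 5, seed = 1,
                           cfg = nabind_config()) {
  n <- length(prepared)
  folds <- .protein_folds(n, k, seed)
  stages <- c("dl", "tl", "merged", "final")
  scores <- stats::setNames(rep(list(vector("list", n)), length(stages)), stages)
  labels <- lapply(prepared, `[[`, "labels")
  fold_out <- list()
  for (f in sort(unique(folds))) {
    tr <- which(folds != f); te <- which(folds == f)
    bundle <- train_nabind(prepared[tr], if (is.null(tl_X)) NULL else tl_X[tr],
                           cfg = cfg, seed = seed + f)
    for (i in te) {
      pred <- predict_nabind(bundle, prepared[[i]],
                             if (is.null(tl_X)) NULL else tl_X[[i]])
      scores$dl[[i]] <- pred$p_dl_mean
      scores$tl[[i]] <- pred$p_tl_mean
      scores$merged[[i]] <- pred$p_merged
      scores$final[[i]] <- pred$p_final
    }
    fold_out[[length(fold_out) + 1]] <- list(fold = f, test = te)
  }
  auc <- vapply(stages, function(st) {
    protein_based_eval(scores[[st]], labels)$auc
  }, 0)
  list(folds = fold_out, scores = scores, labels = labels,
       protein_auc = auc, fold_assignment = folds)
}

#' Save / load a trained bundle
#'
#' @param bundle `nabind_bundle`.
#' @param path File path (RDS archive with raw-serialised boosters).
#' @export
save_bundle <- function(bundle, path) {
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  readRDS(path)
}
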