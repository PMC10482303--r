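# Template-based module: query-template structural alignment, template
# selection, per-residue alignment features, and three tree-ensemble
# classifiers.

.blosum62_cache <- new.env(parent = emptyenv())

.blosum62 <- function() {
  # lazily pull (and cache) the matrix shipped with Biostrings
  if (is.null(.blosum62_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum62_cache$m <- e$BLOSUM62
  }
  .blosum62_cache$m
}

#' Create a template-library entry
#'
#' @param structure `protein_structure`.
#' @param binding 0/1 label vector of matching length.
#' @param id Template identifier.
#' @param ligand Optional nucleic-acid atom table (`element,x,y,z`).
#' @export
template_entry <- function(structure, binding, id, ligand = NULL) {
  stopifnot(length(binding) == structure$n)
  structure(list(structure = structure, binding = as.integer(binding),
                 id = id, ligand = ligand), class = "template_entry")
}

# global Needleman-Wunsch via Biostrings; returns aligned index pairs and
# identity over alignment length (gaps included)
.global_align <- function(seq_q, seq_t) {
  pa <- Biostrings::pairwiseAlignment(
    paste(seq_q, collapse = ""), paste(seq_t, collapse = ""),
    substitutionMatrix = .blosum62(), gapOpening = 11, gapExtension = 1,
    type = "global"
  )
  qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  ta <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  qi <- ti <- integer(0); q <- t <- 0L
  pairs_q <- pairs_t <- integer(0)
  n_ident <- 0L
  for (k in seq_along(qa)) {
    if (qa[k] != "-") q <- q + 1L
    if (ta[k] != "-") t <- t + 1L
    if (qa[k] != "-" && ta[k] != "-") {
      pairs_q <- c(pairs_q, q); pairs_t <- c(pairs_t, t)
      if (qa[k] == ta[k]) n_ident <- n_ident + 1L
    }
  }
  list(qi = pairs_q, ti = pairs_t, aln_len = length(qa),
       identity = n_ident / length(qa))
}

#' Kabsch superposition
#'
#' Least-squares rigid transform mapping `P` onto `Q` (both `k x 3`):
#' returns rotation `R` and translation `t` with fitted points `P %*% R + t`.
#'
#' @param P,Q Coordinate matrices of equal size (k >= 3).
#' @export
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), nrow(P) >= 3)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, t = as.numeric(cq - cp %*% R))
}

.tm_d0 <- function(L) max(0.5, 1.24 * (max(L, 16) - 15)^(1 / 3) - 1.8)

#' Align a query onto a template
#'
#' Seeds a residue mapping by global sequence alignment (BLOSUM62, gap
#' 11/1), then iterates Kabsch superposition with distance-based mapping
#' refinement, and scores the final superposition with the standard TM-score
#' normalised by the query length. Precomputed alignments from an external
#' structural aligner can be ingested instead via [parse_tmalign()].
#'
#' @param query,template `protein_structure`s with CA coordinates.
#' @param max_iter Refinement iterations.
#' @return A `template_hit`: `tm_score`, `seq_identity`, `mapping`
#'   (query index -> template index), `R`, `t`, `template_id`.
#' @export
align_query_template <- function(query, template, max_iter = 10) {
  ca_q <- ca_coords(query); ca_t <- ca_coords(template)
  if (sum(stats::complete.cases(ca_q)) < 3 || sum(stats::complete.cases(ca_t)) < 3) {
    stop("need at least 3 CA atoms on both sides")
  }
  al <- .global_align(query$seq, template$seq)
  if (length(al$qi) < 3) stop("alignment too short to superimpose")
  d0 <- .tm_d0(query$n)
  sel <- seq_along(al$qi)
  fit <- NULL
  for (it in seq_len(max_iter)) {
    fit <- kabsch(ca_q[al$qi[sel], , drop = FALSE], ca_t[al$ti[sel], , drop = FALSE])
    moved <- sweep(ca_q[al$qi, , drop = FALSE] %*% fit$R, 2, fit$t, "+")
    d <- sqrt(rowSums((moved - ca_t[al$ti, , drop = FALSE])^2))
    new_sel <- which(d < max(d0 + 1, 3))
    if (length(new_sel) < 3 || identical(new_sel, sel)) break
    sel <- new_sel
  }
  moved <- sweep(ca_q[al$qi, , drop = FALSE] %*% fit$R, 2, fit$t, "+")
  d <- sqrt(rowSums((moved - ca_t[al$ti, , drop = FALSE])^2))
  tm <- sum(1 / (1 + (d / d0)^2)) / query$n
  mapping <- stats::setNames(al$ti, al$qi)
  structure(
    list(tm_score = tm, seq_identity = al$identity, mapping = mapping,
         R = fit$R, t = fit$t, template_id = attr(template, "id")),
    class = "template_hit"
  )
}

#' Parse a TM-align text report
#'
#' Extracts the TM-score (normalised by chain 1), sequence identity and the
#' aligned-residue mapping from the standard three-line alignment block of
#' TM-align output, so externally computed alignments can substitute for the
#' internal superposition engine.
#'
#' @param path Report file.
#' @return List with `tm_score`, `seq_identity`, `mapping`.
#' @export
parse_tmalign <- function(path) {
  lines <- readLines(path)
  tm_line <- grep("TM-score=.*Chain_1", lines, value = TRUE)
  if (!length(tm_line)) tm_line <- grep("TM-score=", lines, value = TRUE)
  if (!length(tm_line)) stop("no TM-score line found")
  tm <- as.numeric(sub(".*TM-score=\\s*([0-9.]+).*", "\\1", tm_line[1]))
  id_line <- grep("Seq_ID", lines, value = TRUE)
  id <- if (length(id_line)) as.numeric(sub(".*Seq_ID=[^=]*=\\s*([0-9.]+).*", "\\1", id_line[1])) else NA_real_
  blk <- grep("^[A-Za-z-]+$", trimws(lines))
  blk <- blk[nchar(trimws(lines[blk])) > 10]
  mapping <- integer(0)
  if (length(blk) >= 2) {
    qa <- strsplit(trimws(lines[blk[1]]), "")[[1]]
    ta <- strsplit(trimws(lines[blk[length(blk)]]), "")[[1]]
    q <- t <- 0L
    for (k in seq_len(min(length(qa), length(ta)))) {
      if (qa[k] != "-") q <- q + 1L
      if (ta[k] != "-") t <- t + 1L
      if (qa[k] != "-" && ta[k] != "-") mapping[as.character(q)] <- t
    }
  }
  list(tm_score = tm, seq_identity = id,
       mapping = stats::setNames(as.integer(mapping), names(mapping)))
}

#' Select up to 20 templates for a query
#'
#' Aligns the query to every library entry, keeps hits with TM-score > 0.3
#' and sequence identity < 0.3, clusters survivors by greedy longest-first
#' 90% sequence identity, retains the highest-TM representative per cluster,
#' and returns at most `top_n` hits ranked by TM-score (ties broken by
#' template id).
#'
#' @param query `protein_structure`.
#' @param library List of [template_entry()] objects.
#' @param tm_min,id_max,cluster_id,top_n Filter and clustering parameters.
#' @return List of `list(hit, entry)` pairs, ranked.
#' @export
select_templates <- function(query, library, tm_min = 0.3, id_max = 0.3,
                             cluster_id = 0.9, top_n = 20) {
  stopifnot(length(library) >= 1)
  hits <- list()
  for (entry in library) {
    st <- entry$structure
    attr(st, "id") <- entry$id
    hit <- tryCatch(align_query_template(query, st), error = function(e) NULL)
    if (is.null(hit)) next
    if (hit$tm_score > tm_min && hit$seq_identity < id_max) {
      hits[[length(hits) + 1]] <- list(hit = hit, entry = entry)
    }
  }
  if (!length(hits)) return(list())
  # greedy longest-first identity clustering among survivors
  lens <- vapply(hits, function(h) h$entry$structure$n, 0)
  ids <- vapply(hits, function(h) h$entry$id, "")
  ord <- order(-lens, ids)
  cluster <- rep(NA_integer_, length(hits))
  n_cl <- 0
  for (k in ord) {
    if (!is.na(cluster[k])) next
    n_cl <- n_cl + 1
    cluster[k] <- n_cl
    for (j in ord) {
      if (!is.na(cluster[j])) next
      idpair <- .global_align(hits[[k]]$entry$structure$seq,
                              hits[[j]]$entry$structure$seq)$identity
      if (idpair >= cluster_id) cluster[j] <- n_cl
    }
  }
  reps <- vapply(split(seq_along(hits), cluster), function(members) {
    tms <- vapply(hits[members], function(h) h$hit$tm_score, 0)
    mids <- ids[members]
    members[order(-tms, mids)][1]
  }, 0L)
  reps <- reps[order(-vapply(hits[reps], function(h) h$hit$tm_score, 0), ids[reps])]
  hits[reps[seq_len(min(top_n, length(reps)))]]
}

#' Assign 3-state secondary structure from backbone dihedrals
#'
#' H (helix), E (strand) or C (coil) from phi/psi regions; chain termini and
#' residues with missing backbone atoms are coil.
#'
#' @param protein `protein_structure`.
#' @return Character vector of length `n`.
#' @export
assign_ss <- function(protein) {
  n <- protein$n
  get <- function(i, name) {
    a <- protein$atoms
    row <- a[a$res_idx == i & a$elety == name, c("x", "y", "z"), drop = FALSE]
    if (!nrow(row)) return(NULL)
    as.numeric(row[1, ])
  }
  dihedral <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    c1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3], b1[1] * b2[2] - b1[2] * b2[1])
    c2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3], b2[1] * b3[2] - b2[2] * b3[1])
    x <- sum(c1 * c2)
    y <- sum(b2 / sqrt(sum(b2^2)) * c(c1[2] * c2[3] - c1[3] * c2[2],
                                      c1[3] * c2[1] - c1[1] * c2[3],
                                      c1[1] * c2[2] - c1[2] * c2[1]))
    atan2(y, x) * 180 / pi
  }
  ss <- rep("C", n)
  for (i in seq_len(n)) {
    if (i == 1 || i == n) next
    cprev <- get(i - 1, "C"); nn <- get(i, "N"); ca <- get(i, "CA")
    cc <- get(i, "C"); nnext <- get(i + 1, "N")
    if (is.null(cprev) || is.null(nn) || is.null(ca) || is.null(cc) || is.null(nnext)) next
    phi <- dihedral(cprev, nn, ca, cc)
    psi <- dihedral(nn, ca, cc, nnext)
    if (phi < 0 && psi > -100 && psi < 60) ss[i] <- "H"
    else if (phi < -45 && (psi >= 60 || psi < -135)) ss[i] <- "E"
  }
  ss
}

#' Per-residue template features
#'
#' For each query residue and each of up to 20 template slots, six features:
#' hit-level sequence identity and TM-score, BLOSUM62 score of the aligned
#' pair, secondary-structure alignment score, CA distance between the
#' superimposed query residue and its aligned template residue, and a 0/1
#' binding probability (query residue's superimposed heavy atoms within
#' 4.5 A of any template nucleic-acid atom; the template's own binding label
#' when ligand coordinates are absent). Unaligned residues and empty
#' template slots are zero-filled, so the matrix width is always 120.
#'
#' @param query `protein_structure`.
#' @param hits Output of [select_templates()].
#' @param ss_match,ss_mismatch Secondary-structure score matrix entries.
#' @param bind_cutoff Nucleic-proximity cutoff, Angstrom (default 4.5).
#' @return `n x 120` matrix.
#' @export
template_residue_features <- function(query, hits, ss_match = 1, ss_mismatch = 0,
                                      bind_cutoff = 4.5) {
  n <- query$n
  out <- matrix(0, n, 120)
  colnames(out) <- as.vector(t(outer(sprintf("t%02d", 1:20),
                                     c("id", "tm", "blosum", "ss", "dist", "bind"),
                                     paste, sep = "_")))
  if (!length(hits)) return(out)
  if (length(hits) > 20) stop("more than 20 template hits supplied")
  B62 <- .blosum62()
  ss_q <- assign_ss(query)
  ca_q <- ca_coords(query)
  qa <- query$atoms[query$atoms$heavy, , drop = FALSE]
  for (k in seq_along(hits)) {
    hit <- hits[[k]]$hit; entry <- hits[[k]]$entry
    tmpl <- entry$structure
    ss_t <- assign_ss(tmpl)
    ca_t <- ca_coords(tmpl)
    qi <- as.integer(names(hit$mapping)); ti <- unname(hit$mapping)
    moved_ca <- sweep(ca_q %*% hit$R, 2, hit$t, "+")
    base <- (k - 1) * 6
    lig <- entry$ligand
    moved_atoms <- sweep(as.matrix(qa[, c("x", "y", "z")]) %*% hit$R, 2, hit$t, "+")
    for (m in seq_along(qi)) {
      i <- qi[m]; j <- ti[m]
      out[i, base + 1] <- hit$seq_identity
      out[i, base + 2] <- hit$tm_score
      out[i, base + 3] <- B62[query$seq[i], tmpl$seq[j]]
      out[i, base + 4] <- if (ss_q[i] == ss_t[j]) ss_match else ss_mismatch
      out[i, base + 5] <- sqrt(sum((moved_ca[i, ] - ca_t[j, ])^2))
      if (!is.null(lig) && nrow(lig)) {
        rows <- which(qa$res_idx == i)
        pl <- as.matrix(lig[, c("x", "y", "z")])
        dmin <- sqrt(min(outer(rowSums(moved_atoms[rows, , drop = FALSE]^2),
                               rowSums(pl^2), "+") -
                           2 * moved_atoms[rows, , drop = FALSE] %*% t(pl)))
        out[i, base + 6] <- as.integer(dmin < bind_cutoff)
      } else {
        out[i, base + 6] <- entry$binding[j]
      }
    }
  }
  out
}

#' Train the three template classifiers
#'
#' Random forest, depth-wise gradient boosting, and leaf-wise histogram
#' gradient boosting on the 120-column template feature matrix. The module
#' score is the mean of the three predicted probabilities.
#'
#' @param X Feature matrix.
#' @param y 0/1 labels (both classes required).
#' @param seed RNG seed.
#' @param ntree,nrounds Ensemble sizes.
#' @return A `template_classifiers` object.
#' @export
train_template_classifiers <- function(X, y, seed = 1, ntree = 300, nrounds = 150) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes required to train template classifiers")
  set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = factor(y, levels = c(0, 1)), ntree = ntree)
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  common <- list(objective = "binary:logistic", eta = 0.05,
                 scale_pos_weight = max(1, sum(y == 0) / max(1, sum(y == 1))),
                 nthread = 1)
  set.seed(seed)
  xgb <- xgboost::xgb.train(
    params = c(common, list(max_depth = 5)),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
  set.seed(seed)
  lgb <- xgboost::xgb.train(
    params = c(common, list(tree_method = "hist", grow_policy = "lossguide",
                            max_leaves = 31, max_depth = 0)),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
  structure(list(rf = rf, xgb = xgb, lgb = lgb), class = "template_classifiers")
}

#' Predict with the template classifiers
#'
#' @param models `template_classifiers`.
#' @param X Feature matrix.
#' @return `n x 3` matrix with columns `tl_rf`, `tl_xgb`, `tl_lgbm`.
#' @export
predict_template_classifiers <- function(models, X) {
  dm <- xgboost::xgb.DMatrix(X)
  cbind(
    tl_rf = stats::predict(models$rf, X, type = "prob")[, "1"],
    tl_xgb = stats::predict(models$xgb, dm),
    tl_lgbm = stats::predict(models$lgb, dm)
  )
}
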