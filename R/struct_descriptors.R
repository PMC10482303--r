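# Graph-based, distance-based and shape descriptors per residue, plus
# ingestion of external geometry descriptors and Z-score normalisation.

#' Ollivier-Ricci curvature
#'
#' Edge curvature `1 - W(m_x, m_y) / d(x, y)` where `m_x` is the lazy uniform
#' density (mass `alpha` on the node, `(1-alpha)/deg` on each neighbour), `W`
#' the exact Wasserstein-1 distance under the hop-count ground metric, and
#' `d(x, y) = 1` on an edge. The node descriptor sums the curvatures of
#' incident edges; isolated nodes score 0.
#'
#' @param graph `residue_graph`.
#' @param alpha Laziness in \[0, 1) (default 0.5).
#' @return For [ollivier_ricci_edge()] a per-edge vector aligned with
#'   `graph$edges`; for [ollivier_ricci_node()] a per-node vector.
#' @export
ollivier_ricci_edge <- function(graph, alpha = 0.5) {
  stopifnot(alpha >= 0, alpha < 1)
  ne <- nrow(graph$edges)
  if (!ne) return(numeric(0))
  nb <- .graph_neighbors(graph)
  hop <- igraph::distances(.graph_igraph(graph))
  curv <- numeric(ne)
  for (e in seq_len(ne)) {
    x <- graph$edges[e, 1]; y <- graph$edges[e, 2]
    sx <- c(x, nb[[x]]); sy <- c(y, nb[[y]])
    mx <- c(alpha, rep((1 - alpha) / length(nb[[x]]), length(nb[[x]])))
    my <- c(alpha, rep((1 - alpha) / length(nb[[y]]), length(nb[[y]])))
    w <- wasserstein1(mx, my, hop[sx, sy, drop = FALSE])
    curv[e] <- 1 - w
  }
  curv
}

#' @rdname ollivier_ricci_edge
#' @export
ollivier_ricci_node <- function(graph, alpha = 0.5) {
  curv <- ollivier_ricci_edge(graph, alpha)
  out <- numeric(graph$n_nodes)
  if (length(curv)) {
    for (e in seq_along(curv)) {
      out[graph$edges[e, 1]] <- out[graph$edges[e, 1]] + curv[e]
      out[graph$edges[e, 2]] <- out[graph$edges[e, 2]] + curv[e]
    }
  }
  out
}

#' Forman-Ricci curvature
#'
#' Augmented Forman curvature of an edge e = (x, y) with node weights `w_x`
#' and edge weights `w_e`:
#' `w_e * (w_x/w_e + w_y/w_e - sum_{e_x != e} w_x/sqrt(w_e w_ex)
#'                           - sum_{e_y != e} w_y/sqrt(w_e w_ey))`.
#' With unit weights this reduces to `4 - deg(x) - deg(y)`. The node value
#' sums incident edge curvatures.
#'
#' @param graph `residue_graph` with positive `node_weights`/`edge_weights`.
#' @return Per-edge (resp. per-node) curvature vector.
#' @export
forman_ricci_edge <- function(graph) {
  if (any(graph$node_weights <= 0) || any(graph$edge_weights <= 0)) {
    stop("Forman curvature requires positive weights")
  }
  ne <- nrow(graph$edges)
  if (!ne) return(numeric(0))
  # incident edge ids per node
  inc <- vector("list", graph$n_nodes)
  for (e in seq_len(ne)) {
    for (v in graph$edges[e, ]) inc[[v]] <- c(inc[[v]], e)
  }
  we <- graph$edge_weights; wn <- graph$node_weights
  curv <- numeric(ne)
  for (e in seq_len(ne)) {
    x <- graph$edges[e, 1]; y <- graph$edges[e, 2]
    ex <- setdiff(inc[[x]], e); ey <- setdiff(inc[[y]], e)
    curv[e] <- we[e] * (
      wn[x] / we[e] + wn[y] / we[e] -
        sum(wn[x] / sqrt(we[e] * we[ex])) -
        sum(wn[y] / sqrt(we[e] * we[ey]))
    )
  }
  curv
}

#' @rdname forman_ricci_edge
#' @export
forman_ricci_node <- function(graph) {
  curv <- forman_ricci_edge(graph)
  out <- numeric(graph$n_nodes)
  for (e in seq_along(curv)) {
    out[graph$edges[e, 1]] <- out[graph$edges[e, 1]] + curv[e]
    out[graph$edges[e, 2]] <- out[graph$edges[e, 2]] + curv[e]
  }
  out
}

#' Multifractal dimension of a node
#'
#' Box-covering mass scaling around a node: the box at scale `l` holds the
#' `M(l)` nodes within hop distance `l`; its size is the diameter `2l + 1`.
#' The descriptor is the least-squares slope of `log M(l)` against
#' `log(2l + 1)` over `l = 1..l_max` (exactly 1 on an infinite path, 2 on an
#' infinite 2-D grid). Isolated nodes score 0.
#'
#' @param graph `residue_graph`.
#' @param l_max Largest box radius in hops (default 5).
#' @return Per-node slope vector.
#' @export
multifractal_dimension <- function(graph, l_max = 5) {
  stopifnot(l_max >= 1)
  hop <- igraph::distances(.graph_igraph(graph))
  out <- numeric(graph$n_nodes)
  deg <- .graph_degrees(graph)
  x <- log(2 * seq_len(l_max) + 1)
  for (v in seq_len(graph$n_nodes)) {
    if (deg[v] == 0) next
    M <- vapply(seq_len(l_max), function(l) sum(is.finite(hop[v, ]) & hop[v, ] <= l), 0)
    y <- log(M)
    out[v] <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
  iso <- deg == 0
  if (any(iso)) message("multifractal_dimension: ", sum(iso), " isolated node(s) set to 0")
  out
}

#' Single-scale box mass value log(M(l)/l)
#'
#' The literal single-scale variant of the box-covering descriptor, retained
#' as an option alongside the regression slope.
#'
#' @param graph `residue_graph`.
#' @param l Box radius in hops.
#' @export
mfd_single_scale <- function(graph, l = 1) {
  hop <- igraph::distances(.graph_igraph(graph))
  vapply(seq_len(graph$n_nodes), function(v) {
    M <- sum(is.finite(hop[v, ]) & hop[v, ] <= l)
    log(M / l)
  }, 0)
}

.fragment_ranges <- function(n, m) {
  g <- seq_len(2^m)
  lo <- ceiling((g - 1) * n / 2^m) + 1
  hi <- ceiling(g * n / 2^m)
  bad <- lo > hi
  if (any(bad)) {
    message("fragment_centroid_distances: clamping empty fragment(s) to one residue")
    hi[bad] <- pmax(lo[bad], 1)
    lo[bad] <- pmin(lo[bad], n)
    hi[bad] <- pmin(hi[bad], n)
  }
  cbind(lo, hi)
}

#' Distances to fragment centroids at three scales
#'
#' The chain is split into 1, 2 and 4 contiguous fragments; the descriptor is
#' the Euclidean distance from the target residue's CA to each fragment's CA
#' centroid (7 values, ordered whole chain, halves, quarters).
#'
#' @param protein `protein_structure` (CA coordinates required).
#' @param target Residue index (1-based).
#' @return Numeric 7-vector in Angstrom.
#' @export
fragment_centroid_distances <- function(protein, target) {
  ca <- ca_coords(protein)
  if (anyNA(ca)) stop("CA coordinates missing")
  t_xyz <- ca[target, ]
  out <- numeric(0)
  for (m in 0:2) {
    rg <- .fragment_ranges(protein$n, m)
    for (g in seq_len(nrow(rg))) {
      cen <- colMeans(ca[rg[g, 1]:rg[g, 2], , drop = FALSE])
      out <- c(out, sqrt(sum((t_xyz - cen)^2)))
    }
  }
  out
}

#' Ultrafast shape recognition features of a residue
#'
#' Mean CA distances from all residues to three reference points: the target
#' residue r, the residue b farthest from r, and the residue g farthest from
#' b (argmax ties broken by lowest index).
#'
#' @param protein `protein_structure`.
#' @param target Residue index (1-based).
#' @return Named numeric vector `c(u_r, u_b, u_g)` in Angstrom.
#' @export
usr_features <- function(protein, target) {
  ca <- ca_coords(protein)
  if (anyNA(ca)) stop("CA coordinates missing")
  dvec <- function(p) sqrt(colSums((t(ca) - p)^2))
  dr <- dvec(ca[target, ])
  b <- which.max(dr)
  db <- dvec(ca[b, ])
  g <- which.max(db)
  dg <- dvec(ca[g, ])
  c(u_r = mean(dr), u_b = mean(db), u_g = mean(dg))
}

#' Ingest external geometry descriptors (pocket-detection output)
#'
#' Reads a per-residue TSV with columns `residue_id`, `mir` (minimum
#' inaccessible radius), `asv` (accessible shell volume) and `pocketness`.
#' Residues absent from the table are filled with supplied training means.
#'
#' @param path TSV file.
#' @param protein `protein_structure` whose author numbering resolves rows.
#' @param fill Optional named numeric vector of per-column fill values; the
#'   table's own column means are used when `NULL`.
#' @return `n x 3` matrix with columns `mir`, `asv`, `pocketness`.
#' @export
ingest_geometry_descriptors <- function(path, protein, fill = NULL) {
  lines <- readLines(path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", colClasses = "character"),
    error = function(e) stop("malformed geometry table: ", conditionMessage(e))
  )
  need <- c("residue_id", "mir", "asv", "pocketness")
  if (!all(need %in% names(df))) stop("geometry table must have columns: ", paste(need, collapse = ", "))
  vals <- sapply(df[c("mir", "asv", "pocketness")], function(col) suppressWarnings(as.numeric(col)))
  vals <- matrix(vals, ncol = 3, dimnames = list(NULL, c("mir", "asv", "pocketness")))
  bad <- which(rowSums(is.na(vals)) > 0)
  if (length(bad)) {
    stop("non-numeric geometry value at data line ", bad[1],
         " (file line ", bad[1] + 1, ")")
  }
  out <- matrix(NA_real_, protein$n, 3, dimnames = list(NULL, colnames(vals)))
  pos <- match(protein$residues$resno, as.integer(df$residue_id))
  out[!is.na(pos), ] <- vals[pos[!is.na(pos)], , drop = FALSE]
  if (anyNA(pos)) {
    fills <- if (is.null(fill)) colMeans(vals) else fill[colnames(vals)]
    for (k in 1:3) out[is.na(pos), k] <- fills[k]
    message("ingest_geometry_descriptors: imputed ", sum(is.na(pos)), " missing residue row(s)")
  }
  out
}

#' Fit / apply Z-score normalisation
#'
#' Column means and standard deviations are estimated on the training matrix
#' only; zero-variance columns are dropped with a message. `zscore_apply`
#' uses the stored parameters, never the statistics of its input.
#'
#' @param x Numeric matrix (training matrix for `zscore_fit`).
#' @param params Result of [zscore_fit()].
#' @return `zscore_fit`: list with `mean`, `sd`, `keep`; `zscore_apply`: the
#'   normalised matrix restricted to kept columns.
#' @export
zscore_fit <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  keep <- sd > 1e-12
  if (any(!keep)) {
    message("zscore_fit: dropping zero-variance column(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
  }
  list(mean = mu[keep], sd = sd[keep], keep = which(keep), names = colnames(x)[keep])
}

#' @rdname zscore_fit
#' @export
zscore_apply <- function(x, params) {
  x <- as.matrix(x)[, params$keep, drop = FALSE]
  out <- sweep(sweep(x, 2, params$mean, "-"), 2, params$sd, "/")
  if (anyNA(out)) stop("NaN after normalisation")
  out
}

#' Assemble the structural descriptor matrix of a protein
#'
#' Fixed column order: Ollivier-Ricci, Forman-Ricci, multifractal dimension,
#' 7 fragment-centroid distances, 3 USR means, then any ingested geometry
#' columns. This order is part of the model-bundle contract.
#'
#' @param protein `protein_structure`.
#' @param graph Optional precomputed `residue_graph`.
#' @param alpha ORC laziness.
#' @param l_max Multifractal box radius bound.
#' @param geometry Optional `n x 3` geometry matrix from
#'   [ingest_geometry_descriptors()].
#' @return `n x F` named matrix.
#' @export
struct_descriptor_matrix <- function(protein, graph = NULL, alpha = 0.5,
                                     l_max = 5, geometry = NULL) {
  if (is.null(graph)) graph <- build_graph(protein)
  n <- protein$n
  cd <- t(vapply(seq_len(n), function(i) fragment_centroid_distances(protein, i), numeric(7)))
  colnames(cd) <- c("cdist_m0", "cdist_m1_1", "cdist_m1_2", paste0("cdist_m2_", 1:4))
  us <- t(vapply(seq_len(n), function(i) usr_features(protein, i), numeric(3)))
  colnames(us) <- c("usr_r", "usr_b", "usr_g")
  out <- cbind(
    orc = ollivier_ricci_node(graph, alpha),
    frc = forman_ricci_node(graph),
    mfd = multifractal_dimension(graph, l_max),
    cd, us
  )
  if (!is.null(geometry)) out <- cbind(out, geometry)
  out
}

#' Write a descriptor matrix as TSV (one row per residue)
#'
#' @param protein `protein_structure` providing author residue numbers.
#' @param x Matrix with named columns.
#' @param path File path.
#' @export
write_descriptors <- function(protein, x, path) {
  utils::write.table(
    data.frame(residue_id = protein$residues$resno, x, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
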