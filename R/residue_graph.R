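# Residue contact graph with per-edge distance and orientation features.

#' Minimum inter-residue atom distance matrix
#'
#' @param protein `protein_structure`.
#' @param heavy_only Use heavy atoms only (the edge-feature convention); the
#'   contact test itself uses all atoms.
#' @return Symmetric `n x n` matrix of minimal atom-pair distances (diagonal 0).
#' @export
residue_distance_matrix <- function(protein, heavy_only = TRUE) {
  a <- protein$atoms
  if (heavy_only) {
    a <- a[a$heavy, , drop = FALSE]
    missing <- setdiff(seq_len(protein$n), unique(a$res_idx))
    if (length(missing)) {
      stop("residue(s) without heavy atoms: ",
           paste(protein$residues$resno[missing], collapse = ", "))
    }
  }
  xyz <- as.matrix(a[, c("x", "y", "z")])
  g <- a$res_idx
  n <- protein$n
  D <- as.matrix(stats::dist(xyz))
  M <- matrix(Inf, n, n)
  rows <- split(seq_along(g), g)
  for (i in seq_along(rows)) {
    sub <- D[rows[[i]], , drop = FALSE]
    colmin <- if (nrow(sub) == 1) sub[1, ] else do.call(pmin, lapply(seq_len(nrow(sub)), function(r) sub[r, ]))
    M[as.integer(names(rows)[i]), ] <- vapply(rows, function(cols) min(colmin[cols]), 0)
  }
  diag(M) <- 0
  M
}

#' Shortest heavy-atom distance between two residues
#'
#' @param protein `protein_structure`.
#' @param i,j Residue indices (1-based).
#' @return Distance in Angstrom.
#' @export
edge_distance <- function(protein, i, j) {
  a <- protein$atoms[protein$atoms$heavy, , drop = FALSE]
  ai <- a[a$res_idx == i, c("x", "y", "z"), drop = FALSE]
  aj <- a[a$res_idx == j, c("x", "y", "z"), drop = FALSE]
  if (!nrow(ai) || !nrow(aj)) stop("residue without heavy atoms")
  pa <- as.matrix(ai); pb <- as.matrix(aj)
  sqrt(max(0, min(outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb))))
}

.backbone_normal <- function(protein, i) {
  a <- protein$atoms
  get <- function(name) {
    row <- a[a$res_idx == i & a$elety == name, c("x", "y", "z"), drop = FALSE]
    if (!nrow(row)) return(NULL)
    as.numeric(row[1, ])
  }
  ca <- get("CA"); cc <- get("C"); nn <- get("N")
  if (is.null(ca) || is.null(cc) || is.null(nn)) return(NULL)
  v1 <- cc - ca; v2 <- nn - ca
  nvec <- c(v1[2] * v2[3] - v1[3] * v2[2],
            v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
  if (sqrt(sum(nvec^2)) < 1e-8) return(NULL)
  nvec / sqrt(sum(nvec^2))
}

#' Relative orientation between two residues
#'
#' Angle between the surface normals of the backbone planes (CA, carboxyl C,
#' amide N), folded into \[0, pi/2\] since plane normals carry no canonical
#' sign.
#'
#' @param protein `protein_structure`.
#' @param i,j Residue indices.
#' @return Radians in \[0, pi/2\], or `NA` when a plane is degenerate or a
#'   backbone atom is missing.
#' @export
edge_orientation <- function(protein, i, j) {
  n1 <- .backbone_normal(protein, i)
  n2 <- .backbone_normal(protein, j)
  if (is.null(n1) || is.null(n2)) return(NA_real_)
  acos(min(1, abs(sum(n1 * n2))))
}

#' Build the residue contact graph
#'
#' Residues are nodes; an edge joins i and j (i != j) when the distance
#' between any of their atoms is below `cutoff` (strict). Edge features are
#' the minimal heavy-atom distance and the backbone-plane orientation angle;
#' undefined orientations fall back to `orient_fill` with a message.
#'
#' @param protein `protein_structure`.
#' @param cutoff Contact cutoff in Angstrom (default 10).
#' @param orient_fill Fill value for undefined orientations.
#' @return A `residue_graph`: `n_nodes`, `edges` (2-column matrix, i < j),
#'   `edge_dist`, `edge_orient`, `node_weights`, `edge_weights`.
#' @export
build_graph <- function(protein, cutoff = 10, orient_fill = 0) {
  D_all <- residue_distance_matrix(protein, heavy_only = FALSE)
  D_heavy <- residue_distance_matrix(protein, heavy_only = TRUE)
  n <- protein$n
  pairs <- which(upper.tri(D_all) & D_all < cutoff, arr.ind = TRUE)
  edges <- cbind(i = pairs[, 1], j = pairs[, 2])
  ne <- nrow(edges)
  dist <- D_heavy[edges]
  normals <- lapply(seq_len(n), function(i) .backbone_normal(protein, i))
  orient <- rep(NA_real_, ne)
  for (e in seq_len(ne)) {
    n1 <- normals[[edges[e, 1]]]; n2 <- normals[[edges[e, 2]]]
    if (!is.null(n1) && !is.null(n2)) orient[e] <- acos(min(1, abs(sum(n1 * n2))))
  }
  und <- is.na(orient)
  if (any(und)) {
    message("build_graph: ", sum(und), " edge orientation(s) undefined; filled with ", orient_fill)
    orient[und] <- orient_fill
  }
  structure(
    list(
      n_nodes = n,
      edges = edges,
      edge_dist = dist,
      edge_orient = orient,
      node_weights = rep(1, n),
      edge_weights = rep(1, ne)
    ),
    class = "residue_graph"
  )
}

#' Construct a residue_graph from an explicit edge list
#'
#' Mainly for tests and descriptor work on abstract graphs.
#'
#' @param n_nodes Node count.
#' @param edges 2-column matrix (or empty) of node pairs.
#' @param edge_dist,edge_orient Optional per-edge features (default 1 and 0).
#' @param node_weights,edge_weights Positive weights (default 1).
#' @export
make_graph <- function(n_nodes, edges, edge_dist = NULL, edge_orient = NULL,
                       node_weights = NULL, edge_weights = NULL) {
  edges <- if (is.null(edges) || !length(edges)) {
    matrix(integer(), 0, 2)
  } else {
    matrix(as.integer(edges), ncol = 2)
  }
  if (nrow(edges)) {
    swap <- edges[, 1] > edges[, 2]
    edges[swap, ] <- edges[swap, 2:1]
    if (any(edges[, 1] == edges[, 2])) stop("self-edges not allowed")
    if (anyDuplicated(paste(edges[, 1], edges[, 2]))) stop("duplicate edges")
  }
  ne <- nrow(edges)
  structure(
    list(
      n_nodes = as.integer(n_nodes),
      edges = edges,
      edge_dist = if (is.null(edge_dist)) rep(1, ne) else edge_dist,
      edge_orient = if (is.null(edge_orient)) rep(0, ne) else edge_orient,
      node_weights = if (is.null(node_weights)) rep(1, n_nodes) else node_weights,
      edge_weights = if (is.null(edge_weights)) rep(1, ne) else edge_weights
    ),
    class = "residue_graph"
  )
}

#' @export
print.residue_graph <- function(x, ...) {
  cat(sprintf("<residue_graph> %d nodes, %d edges\n", x$n_nodes, nrow(x$edges)))
  invisible(x)
}

# adjacency list: neighbors[[i]] = integer vector
.graph_neighbors <- function(graph) {
  nb <- vector("list", graph$n_nodes)
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges[k, 1]; j <- graph$edges[k, 2]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  lapply(nb, function(v) if (is.null(v)) integer() else sort(v))
}

.graph_degrees <- function(graph) {
  tabulate(c(graph$edges[, 1], graph$edges[, 2]), nbins = graph$n_nodes)
}

.graph_igraph <- function(graph) {
  if (!nrow(graph$edges)) return(igraph::make_empty_graph(graph$n_nodes, directed = FALSE))
  igraph::make_graph(as.vector(t(graph$edges)), n = graph$n_nodes, directed = FALSE)
}

#' Export / import a residue graph as edge-list TSV
#'
#' Columns: `i`, `j`, `dist`, `orient`. The node count is stored in a header
#' comment so isolated nodes survive the round trip.
#'
#' @param graph `residue_graph`.
#' @param path File path.
#' @export
write_graph_tsv <- function(graph, path) {
  con <- file(path, "w")
  writeLines(sprintf("# n_nodes=%d", graph$n_nodes), con)
  df <- data.frame(i = graph$edges[, 1], j = graph$edges[, 2],
                   dist = graph$edge_dist, orient = graph$edge_orient)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_graph_tsv
#' @export
read_graph_tsv <- function(path) {
  first <- readLines(path, n = 1)
  n <- as.integer(sub(".*n_nodes=", "", first))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  make_graph(n, cbind(df$i, df$j), edge_dist = df$dist, edge_orient = df$orient)
}
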