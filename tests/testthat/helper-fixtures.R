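# Shared helpers: hand-built structures, graph families, and independent
# oracles (LP transport via boot::simplex, brute-force AUC).

# a protein_structure built directly from residue atom specs:
# res_list = list(list(resname=, atoms=data.frame(elety, element, x, y, z)), ...)
build_protein <- function(res_list, chain = "A") {
  atoms <- do.call(rbind, lapply(seq_along(res_list), function(i) {
    a <- res_list[[i]]$atoms
    data.frame(
      res_idx = i, chain = chain, resno = i,
      resname = res_list[[i]]$resname,
      elety = a$elety, element = a$element,
      x = a$x, y = a$y, z = a$z,
      heavy = toupper(a$element) != "H",
      stringsAsFactors = FALSE
    )
  }))
  residues <- data.frame(
    res_idx = seq_along(res_list), chain = chain,
    resno = seq_along(res_list),
    resname = vapply(res_list, `[[`, "", "resname"),
    stringsAsFactors = FALSE
  )
  nabres:::.new_protein(atoms, residues)
}

# single-atom "residues" at given CA-like positions (element C, name GLY)
point_protein <- function(coords, elety = "CA") {
  build_protein(lapply(seq_len(nrow(coords)), function(i) {
    list(resname = "GLY",
         atoms = data.frame(elety = elety, element = "C",
                            x = coords[i, 1], y = coords[i, 2], z = coords[i, 3]))
  }))
}

# residue with full CA/C/N backbone at explicit positions (3 x 3 matrix rows)
backbone_residue <- function(ca, c_, n_, resname = "ALA") {
  list(resname = resname,
       atoms = data.frame(elety = c("CA", "C", "N"), element = c("C", "C", "N"),
                          x = c(ca[1], c_[1], n_[1]),
                          y = c(ca[2], c_[2], n_[2]),
                          z = c(ca[3], c_[3], n_[3])))
}

# minimal hand-written PDB text (3 GLY residues, single CA atoms)
tiny_pdb_text <- function() {
  paste(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   3       7.600   0.000   0.000  1.00  0.00           C",
    "END",
    sep = "\n"
  )
}

# exact Wasserstein-1 by linear programming (boot::simplex), the
# independent oracle for the min-cost-flow implementation
lp_wasserstein1 <- function(a, b, cost) {
  n <- length(a); m <- length(b)
  a <- a / sum(a); b <- b / sum(b)
  obj <- as.vector(cost)  # column-major: x[i,j] at (j-1)*n + i
  A3 <- matrix(0, n + m - 1, n * m)
  b3 <- numeric(n + m - 1)
  for (i in seq_len(n)) {        # row sums = a
    A3[i, (seq_len(m) - 1) * n + i] <- 1
    b3[i] <- a[i]
  }
  for (j in seq_len(m - 1)) {    # col sums = b (last redundant, dropped)
    A3[n + j, (j - 1) * n + seq_len(n)] <- 1
    b3[n + j] <- b[j]
  }
  res <- boot::simplex(a = obj, A3 = A3, b3 = b3, maxi = FALSE)
  unname(res$value)
}

# lazy-uniform ORC edge curvatures via the LP oracle
lp_orc_edges <- function(graph, alpha = 0.5) {
  nb <- nabres:::.graph_neighbors(graph)
  hop <- igraph::distances(nabres:::.graph_igraph(graph))
  vapply(seq_len(nrow(graph$edges)), function(e) {
    x <- graph$edges[e, 1]; y <- graph$edges[e, 2]
    sx <- c(x, nb[[x]]); sy <- c(y, nb[[y]])
    mx <- c(alpha, rep((1 - alpha) / length(nb[[x]]), length(nb[[x]])))
    my <- c(alpha, rep((1 - alpha) / length(nb[[y]]), length(nb[[y]])))
    1 - lp_wasserstein1(mx, my, hop[sx, sy, drop = FALSE])
  }, 0)
}

# O(n^2) concordance AUC oracle
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  conc <- 0
  for (p in pos) conc <- conc + sum(p > neg) + 0.5 * sum(p == neg)
  conc / (length(pos) * length(neg))
}

# small enumerated graph family on <= 7 nodes (paths, cycles, stars,
# complete, seeded random)
graph_family <- function() {
  fam <- list()
  for (n in 3:7) {
    fam[[length(fam) + 1]] <- make_graph(n, cbind(1:(n - 1), 2:n))          # path
    fam[[length(fam) + 1]] <- make_graph(n, cbind(1:n, c(2:n, 1)))          # cycle
    fam[[length(fam) + 1]] <- make_graph(n, cbind(rep(1, n - 1), 2:n))      # star
    fam[[length(fam) + 1]] <- make_graph(n, t(utils::combn(n, 2)))          # complete
  }
  set.seed(2024)
  for (k in 1:6) {
    n <- sample(4:7, 1)
    all_e <- t(utils::combn(n, 2))
    keep <- which(stats::runif(nrow(all_e)) < 0.6)
    if (length(keep) < n - 1) keep <- seq_len(n - 1)
    g <- make_graph(n, all_e[keep, , drop = FALSE])
    fam[[length(fam) + 1]] <- g
  }
  fam
}

# rigid motion helper: random rotation (QR of a Gaussian) + translation
random_rigid <- function(seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = stats::rnorm(3, 0, 10))
}

apply_rigid <- function(protein, rigid) {
  xyz <- as.matrix(protein$atoms[, c("x", "y", "z")])
  moved <- sweep(xyz %*% rigid$R, 2, rigid$t, "+")
  protein$atoms$x <- moved[, 1]; protein$atoms$y <- moved[, 2]; protein$atoms$z <- moved[, 3]
  protein
}
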