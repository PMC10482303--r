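# Random walk with restart over the surface-residue network.

#' RWR configuration
#'
#' @param delta Distance cutoff for the surface network, Angstrom (10).
#' @param rsa_cutoff Surface threshold on relative solvent accessibility (0.1).
#' @param beta Restart probability (0.9).
#' @param tol Stopping tolerance on the iterate difference (1e-2).
#' @param max_iter Iteration safeguard (1000).
#' @param norm `"max"` (default) or `"l1"` stopping norm.
#' @export
rwr_config <- function(delta = 10, rsa_cutoff = 0.1, beta = 0.9, tol = 1e-2,
                       max_iter = 1000, norm = c("max", "l1")) {
  stopifnot(beta > 0, beta <= 1, delta > 0, tol > 0)
  list(delta = delta, rsa_cutoff = rsa_cutoff, beta = beta, tol = tol,
       max_iter = max_iter, norm = match.arg(norm))
}

#' Build the column-normalised surface transition matrix
#'
#' Raw weights `w_ij = (delta - d_ij)/delta` for `d_ij < delta` between
#' distinct surface residues (`rsa > rsa_cutoff` on both sides), zero
#' otherwise, followed by column-wise normalisation. Zero-sum columns stay
#' zero with a message.
#'
#' @param protein `protein_structure` with RSA computed.
#' @param cfg From [rwr_config()].
#' @param dist_mat Optional precomputed heavy-atom residue distance matrix.
#' @return List with `W` (s x s), `surface_idx` (residue indices).
#' @export
build_surface_weights <- function(protein, cfg = rwr_config(), dist_mat = NULL) {
  rsa <- protein$residues$rsa
  if (all(is.na(rsa))) stop("RSA not computed; call compute_rsa() first")
  surf <- which(!is.na(rsa) & rsa > cfg$rsa_cutoff)
  if (!length(surf)) {
    warning("no surface residues; post-processing is the identity")
    return(list(W = matrix(0, 0, 0), surface_idx = integer(0)))
  }
  if (is.null(dist_mat)) dist_mat <- residue_distance_matrix(protein)
  d <- dist_mat[surf, surf, drop = FALSE]
  W <- ifelse(d < cfg$delta, (cfg$delta - d) / cfg$delta, 0)
  diag(W) <- 0
  cs <- colSums(W)
  zero <- cs == 0
  if (any(zero)) message("build_surface_weights: ", sum(zero), " zero-sum column(s) left as zero")
  W[, !zero] <- sweep(W[, !zero, drop = FALSE], 2, cs[!zero], "/")
  list(W = W, surface_idx = surf)
}

#' Random walk with restart on surface probabilities
#'
#' Iterates the row-vector diffusion `p_{t+1} = (1 - beta) p_t W + beta p_0`
#' over surface residues until the stopping norm of the difference falls
#' below `tol` (or `max_iter`, with a warning). Buried residues keep their
#' input probabilities.
#'
#' @param p0 Full-length merged probability vector.
#' @param surface Output of [build_surface_weights()].
#' @param cfg From [rwr_config()].
#' @return Full-length corrected probability vector.
#' @export
rwr_iterate <- function(p0, surface, cfg = rwr_config()) {
  stopifnot(all(p0 >= 0 & p0 <= 1))
  out <- p0
  surf <- surface$surface_idx
  if (!length(surf)) return(out)
  W <- surface$W
  p_init <- p0[surf]
  p <- p_init
  for (it in seq_len(cfg$max_iter)) {
    p_new <- (1 - cfg$beta) * as.vector(p %*% W) + cfg$beta * p_init
    delta <- if (cfg$norm == "max") max(abs(p_new - p)) else sum(abs(p_new - p))
    p <- p_new
    if (delta < cfg$tol) {
      out[surf] <- p
      return(out)
    }
  }
  warning("rwr_iterate: max_iter reached before convergence")
  out[surf] <- p
  out
}
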