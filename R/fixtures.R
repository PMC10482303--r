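# Synthetic fixtures: toy backbones with planted binding patches, pseudo
# nucleic-acid ligands, perturbed template libraries, and synthetic feature
# tables. Geometry is idealised, not physical: downstream operators consume
# only coordinates.

.unit <- function(v) v / sqrt(sum(v^2))

.random_unit <- function() .unit(stats::rnorm(3))

# compact self-avoiding CA walk: step 3.8 A, clash < 4.0 A forbidden,
# soft confinement to a sphere sized for ~protein-like density
.ca_trace <- function(n, max_restarts = 50) {
  radius <- 3.2 * n^(1 / 3) + 2
  for (attempt in seq_len(max_restarts)) {
    ca <- matrix(NA_real_, n, 3)
    ca[1, ] <- c(0, 0, 0)
    dir <- .random_unit()
    ok <- TRUE
    for (i in 2:n) {
      placed <- FALSE
      for (try in 1:60) {
        prop_dir <- .unit(0.6 * dir + .random_unit())
        if (sqrt(sum(ca[i - 1, ]^2)) > radius) {
          prop_dir <- .unit(prop_dir - 0.8 * .unit(ca[i - 1, ]))
        }
        pos <- ca[i - 1, ] + 3.8 * prop_dir
        if (i > 2) {
          d2 <- rowSums(sweep(ca[1:(i - 2), , drop = FALSE], 2, pos)^2)
          if (min(d2) < 16) next
        }
        ca[i, ] <- pos; dir <- prop_dir; placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(ca)
  }
  stop("could not place a self-avoiding CA trace")
}

.backbone_from_ca <- function(ca, resnames, chain = "A") {
  n <- nrow(ca)
  ref <- c(0.123, 0.456, 0.789)
  atoms <- list()
  for (i in seq_len(n)) {
    prev <- if (i > 1) ca[i - 1, ] else ca[i, ] - c(3.8, 0, 0)
    nxt <- if (i < n) ca[i + 1, ] else ca[i, ] + c(3.8, 0, 0)
    u <- .unit(nxt - prev)
    w <- ref - sum(ref * u) * u
    if (sqrt(sum(w^2)) < 1e-6) w <- c(1, 0, 0) - u[1] * u
    w <- .unit(w)
    npos <- ca[i, ] - 0.70 * u + 1.20 * w
    cpos <- ca[i, ] + 0.70 * u + 1.20 * w
    atoms[[i]] <- data.frame(
      res_idx = i, chain = chain, resno = i, resname = resnames[i],
      elety = c("N", "CA", "C"), element = c("N", "C", "C"),
      x = c(npos[1], ca[i, 1], cpos[1]),
      y = c(npos[2], ca[i, 2], cpos[2]),
      z = c(npos[3], ca[i, 3], cpos[3]),
      heavy = TRUE, stringsAsFactors = FALSE
    )
  }
  at <- do.call(rbind, atoms)
  residues <- data.frame(res_idx = seq_len(n), chain = chain,
                         resno = seq_len(n), resname = resnames,
                         stringsAsFactors = FALSE)
  .new_protein(at, residues)
}

# one pseudo-nucleic atom floated off each patch residue's CA, so the ligand
# follows the local surface and the patch width tracks patch_radius
.make_ligand <- function(ca, anchors, patch_radius = 9, offset = 3.2,
                         jitter = 0.3, max_atoms = 12) {
  centroid <- colMeans(ca)
  lig <- list()
  for (a in anchors) {
    dca <- sqrt(rowSums(sweep(ca, 2, ca[a, ])^2))
    near <- which(dca < patch_radius)
    if (length(near) < 5) near <- order(dca)[1:5]  # guarantee a minimal patch
    near <- near[order(abs(near - a))]
    near <- near[seq_len(min(length(near), max_atoms))]
    pos <- t(vapply(near, function(j) {
      ca[j, ] + offset * .unit(ca[j, ] - centroid) + stats::rnorm(3, 0, jitter)
    }, numeric(3)))
    lig[[length(lig) + 1]] <- data.frame(
      element = rep(c("P", "O", "C", "O"), length.out = nrow(pos)),
      x = pos[, 1], y = pos[, 2], z = pos[, 3], stringsAsFactors = FALSE
    )
  }
  lig  # one data frame per anchor; callers rbind or keep patches separate
}

#' Generate a toy protein with a planted binding patch
#'
#' Builds a compact self-avoiding CA trace with idealised N/CA/C backbone
#' atoms, parks a pseudo-nucleic ligand (P/O/C chain) against one or more
#' surface patches, and derives the binding labels by running the labelling
#' rule end to end.
#'
#' @param length Residue count (>= 10).
#' @param n_patches Number of ligand patches.
#' @param seed RNG seed (bit-reproducible output).
#' @param ligand_offset Ligand standoff from patch-residue CAs, Angstrom.
#' @param patch_radius Patch extent around each anchor, Angstrom.
#' @return List with `protein` (`protein_structure`), `ligand` (atom table),
#'   `ligands` (per-patch atom tables), `labels` (0/1 vector), `anchors`
#'   (patch anchor residue indices).
#' @export
make_toy_protein <- function(length, n_patches = 1, seed = 1, ligand_offset = 3.2,
                             patch_radius = 9) {
  stopifnot(length >= 10)
  set.seed(seed)
  ca <- .ca_trace(length)
  resnames <- sample(.standard_aa, length, replace = TRUE)
  protein <- .backbone_from_ca(ca, resnames)
  centroid <- colMeans(ca)
  ddist <- sqrt(rowSums(sweep(ca, 2, centroid)^2))
  surface_pool <- order(-ddist)[seq_len(max(5, round(length / 3)))]
  anchors <- surface_pool[1]
  while (length(anchors) < n_patches) {
    cand <- surface_pool[!surface_pool %in% anchors]
    sep <- vapply(cand, function(c) min(sqrt(rowSums(sweep(ca[anchors, , drop = FALSE], 2, ca[c, ])^2))), 0)
    anchors <- c(anchors, cand[which.max(sep)])
  }
  ligands <- .make_ligand(ca, anchors, patch_radius = patch_radius,
                          offset = ligand_offset)
  ligand <- do.call(rbind, ligands)
  labels <- label_binding_residues(protein, ligand)
  list(protein = protein, ligand = ligand, ligands = ligands, labels = labels,
       anchors = anchors)
}

#' Generate a perturbed template library
#'
#' Each template is a copy of a source fixture with Gaussian coordinate
#' jitter and random residue mutations, carrying the source's binding labels
#' and (jittered) ligand atoms. The default mutation rate (0.8) yields
#' sequence identities around 0.24, below the 0.3 identity ceiling of the
#' template filter, while 1 A jitter keeps TM-scores high.
#'
#' @param sources List of [make_toy_protein()] outputs.
#' @param n_templates Library size (sources recycled; default one per source).
#' @param coord_noise Coordinate jitter sd, Angstrom.
#' @param mutation_rate Fraction of residues mutated to a random other type.
#' @param seed RNG seed.
#' @return List of [template_entry()] objects.
#' @export
make_template_library <- function(sources, n_templates = length(sources),
                                  coord_noise = 1.0, mutation_rate = 0.8, seed = 1) {
  stopifnot(coord_noise >= 0, mutation_rate >= 0, mutation_rate <= 1)
  set.seed(seed)
  out <- vector("list", n_templates)
  for (k in seq_len(n_templates)) {
    src <- sources[[(k - 1) %% length(sources) + 1]]
    p <- src$protein
    na <- nrow(p$atoms)
    p$atoms[, c("x", "y", "z")] <- p$atoms[, c("x", "y", "z")] +
      matrix(stats::rnorm(na * 3, 0, coord_noise), na, 3)
    mut <- which(stats::runif(p$n) < mutation_rate)
    for (i in mut) {
      p$residues$resname[i] <- sample(setdiff(.standard_aa, p$residues$resname[i]), 1)
    }
    p$atoms$resname <- p$residues$resname[p$atoms$res_idx]
    p$seq <- unname(.aa3to1[p$residues$resname])
    lig <- src$ligand
    if (!is.null(lig) && nrow(lig)) {
      lig[, c("x", "y", "z")] <- lig[, c("x", "y", "z")] +
        matrix(stats::rnorm(nrow(lig) * 3, 0, coord_noise), nrow(lig), 3)
    }
    out[[k]] <- template_entry(p, src$labels, sprintf("T%03d", k), ligand = lig)
  }
  out
}

#' Generate synthetic node features with a planted signal
#'
#' Standard-normal features; on signal rows (the binding labels by default,
#' or an explicit mask) the first `n_signal` columns are shifted by
#' `signal` standard deviations. `signal = 0` leaves nothing to learn.
#'
#' @param protein `protein_structure`.
#' @param labels 0/1 vector marking signal rows.
#' @param n_features Total feature columns.
#' @param n_signal Columns carrying the shift.
#' @param signal Effect size (mean shift in sd units).
#' @param seed RNG seed.
#' @param mask Optional explicit signal-row mask overriding `labels`.
#' @return `n x n_features` matrix, columns `emb_1..`.
#' @export
make_node_features <- function(protein, labels, n_features = 16, n_signal = 8,
                               signal = 3.0, seed = 1, mask = NULL) {
  stopifnot(signal >= 0)
  set.seed(seed)
  n <- protein$n
  X <- matrix(stats::rnorm(n * n_features), n, n_features)
  rows <- if (is.null(mask)) which(labels == 1) else which(mask == 1)
  if (length(rows) && n_signal > 0) {
    X[rows, seq_len(n_signal)] <- X[rows, seq_len(n_signal)] + signal
  }
  colnames(X) <- paste0("emb_", seq_len(n_features))
  X
}
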