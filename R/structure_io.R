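# Structure input/output, solvent accessibility, and binding-residue labels.

.guess_element <- function(elety, elesy = NULL) {
  if (!is.null(elesy)) {
    e <- toupper(trimws(elesy))
    if (length(e) && nzchar(e) && !is.na(e)) return(e)
  }
  lead <- sub("^[0-9']*", "", toupper(trimws(elety)))
  two <- substr(lead, 1, 2)
  if (two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "SE", "NA", "CA")) {
    # ambiguous two-letter cases are rare in polymers; CA the atom name is calcium
    # only in HETATM context, which this reader never keeps
  }
  substr(lead, 1, 1)
}

.new_protein <- function(atoms, residues) {
  residues$rsa <- NA_real_
  structure(
    list(
      atoms = atoms,
      residues = residues,
      n = nrow(residues),
      seq = unname(.aa3to1[residues$resname])
    ),
    class = "protein_structure"
  )
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf(
    "<protein_structure> %d residues, %d atoms, chain(s) %s\n",
    x$n, nrow(x$atoms), paste(unique(x$residues$chain), collapse = ",")
  ))
  invisible(x)
}

#' Read one protein chain from a PDB file
#'
#' Keeps standard amino-acid residues (plus configured aliases such as MSE)
#' in author order, resolves alternate locations to the highest-occupancy
#' copy, and flags hydrogens as non-heavy. Parsing is delegated to
#' [bio3d::read.pdb()].
#'
#' @param path PDB file.
#' @param chain Chain identifier; an error listing available chains is raised
#'   when absent.
#' @param aliases Named map from non-standard to parent residue names.
#' @return A `protein_structure`: atom table (`res_idx`, `chain`, `resno`,
#'   `resname`, `elety`, `element`, `x`, `y`, `z`, `heavy`) plus residue table
#'   with author numbering and an `rsa` slot filled by [compute_rsa()].
#' @export
read_pdb <- function(path, chain = NULL, aliases = .residue_aliases) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  chains <- unique(at$chain)
  if (is.null(chain)) chain <- chains[1]
  if (!chain %in% chains) {
    stop(sprintf(
      "chain '%s' not present; available chains: %s",
      chain, paste(chains, collapse = ", ")
    ))
  }
  at <- at[at$chain == chain, , drop = FALSE]

  resname <- trimws(at$resid)
  mapped <- resname %in% names(aliases)
  resname[mapped] <- aliases[resname[mapped]]
  keep <- resname %in% .standard_aa
  dropped <- unique(trimws(at$resid)[!keep])
  if (length(dropped)) {
    message("read_pdb: dropping non-standard residue(s): ", paste(dropped, collapse = ", "))
  }
  at <- at[keep, , drop = FALSE]
  resname <- resname[keep]
  if (!nrow(at)) stop("no standard amino-acid residues in chain ", chain)

  ins <- if ("insert" %in% names(at)) ifelse(is.na(at$insert), "", at$insert) else ""
  res_key <- paste(at$resno, ins, sep = "_")

  # altloc: keep the highest-occupancy copy of each (residue, atom name)
  alt <- if ("alt" %in% names(at)) ifelse(is.na(at$alt), "", at$alt) else ""
  occ <- if ("o" %in% names(at)) ifelse(is.na(at$o), 1, at$o) else 1
  akey <- paste(res_key, at$elety)
  ord <- order(akey, -occ, alt)
  at <- at[ord, , drop = FALSE]
  resname <- resname[ord]
  res_key <- res_key[ord]
  first <- !duplicated(paste(res_key, at$elety))
  at <- at[first, , drop = FALSE]
  resname <- resname[first]
  res_key <- res_key[first]

  # restore author order
  ord2 <- order(at$eleno)
  at <- at[ord2, , drop = FALSE]
  resname <- resname[ord2]
  res_key <- res_key[ord2]
  res_idx <- match(res_key, unique(res_key))
  element <- mapply(.guess_element, at$elety, at$elesy)
  atoms <- data.frame(
    res_idx = res_idx,
    chain = at$chain,
    resno = at$resno,
    resname = resname,
    elety = trimws(at$elety),
    element = unname(element),
    x = at$x, y = at$y, z = at$z,
    heavy = toupper(element) != "H",
    stringsAsFactors = FALSE
  )
  ri <- !duplicated(res_idx)
  residues <- data.frame(
    res_idx = res_idx[ri],
    chain = at$chain[ri],
    resno = at$resno[ri],
    resname = resname[ri],
    stringsAsFactors = FALSE
  )
  .new_protein(atoms, residues)
}

#' Extract nucleic-acid ligand atoms from a PDB file
#'
#' @param path PDB file.
#' @param chains Optional chain filter.
#' @param resnames Residue names treated as nucleic (defaults to the standard
#'   RNA/DNA nucleotide codes).
#' @return Data frame with columns `element`, `x`, `y`, `z`.
#' @export
read_ligand_atoms <- function(path, chains = NULL, resnames = nucleic_residue_names) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  at <- at[trimws(at$resid) %in% resnames, , drop = FALSE]
  if (!nrow(at)) {
    return(data.frame(element = character(), x = numeric(), y = numeric(), z = numeric()))
  }
  element <- mapply(.guess_element, at$elety, at$elesy)
  data.frame(element = unname(element), x = at$x, y = at$y, z = at$z,
             stringsAsFactors = FALSE)
}

#' Write a protein (and optional ligand) back to PDB
#'
#' @param protein `protein_structure`.
#' @param path Output file.
#' @param ligand Optional ligand atom table (`element,x,y,z`); written as a
#'   poly-nucleotide chain "X" of UNK-free single-atom residues.
#' @export
write_pdb_structure <- function(protein, path, ligand = NULL) {
  a <- protein$atoms
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  resno <- a$resno; chain <- a$chain; resid <- a$resname; elety <- a$elety
  elesy <- a$element
  if (!is.null(ligand) && nrow(ligand)) {
    xyz <- c(xyz, as.vector(t(as.matrix(ligand[, c("x", "y", "z")]))))
    resno <- c(resno, rep(max(a$resno) + 1L, nrow(ligand)))
    chain <- c(chain, rep("X", nrow(ligand)))
    resid <- c(resid, rep("DA", nrow(ligand)))
    elety <- c(elety, paste0(ligand$element, seq_len(nrow(ligand)) %% 10))
    elesy <- c(elesy, ligand$element)
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, chain = chain,
                   resid = resid, elety = elety, elesy = elesy)
  invisible(path)
}

# Deterministic golden-spiral points on the unit sphere.
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Body-fixed frame from the principal axes of the heavy-atom cloud, with
# skewness-based sign convention, so the sphere test points rotate with the
# molecule and SASA is exactly invariant under rigid motion.
.pca_frame <- function(xyz) {
  if (nrow(xyz) < 3) return(diag(3))
  Xc <- sweep(xyz, 2, colMeans(xyz))
  eg <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)
  v1 <- eg$vectors[, 1]; v2 <- eg$vectors[, 2]
  fix_sign <- function(v) {
    proj <- Xc %*% v
    s <- sum(proj^3)
    if (abs(s) < 1e-9) s <- proj[which.max(abs(proj))]
    if (s < 0) -v else v
  }
  v1 <- fix_sign(v1); v2 <- fix_sign(v2)
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  cbind(v1, v2, v3)
}

#' Relative solvent accessibility by Shrake-Rupley
#'
#' Computes per-residue solvent-accessible surface area on heavy atoms with a
#' 1.4 A probe and 960 test points per atom, then divides by the theoretical
#' maximum area of the residue type (clipped to \[0, 1\]).
#'
#' @param protein `protein_structure`.
#' @param probe Probe radius in Angstrom.
#' @param n_points Sphere test points per atom.
#' @param vdw Named element -> radius table.
#' @return The structure with `residues$rsa` filled; residues with fewer than
#'   3 heavy atoms keep `NA` and are reported.
#' @export
compute_rsa <- function(protein, probe = 1.4, n_points = 960, vdw = vdw_radii_bondi) {
  stopifnot(inherits(protein, "protein_structure"))
  if (protein$n < 1) stop("empty structure")
  a <- protein$atoms[protein$atoms$heavy, , drop = FALSE]
  if (!nrow(a)) stop("no heavy atoms present")
  unknown <- setdiff(unique(a$element), names(vdw))
  if (length(unknown)) stop("no vdW radius for element(s): ", paste(unknown, collapse = ", "))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  r <- unname(vdw[a$element]) + probe
  sp <- .sphere_points(n_points) %*% t(.pca_frame(xyz))
  na <- nrow(a)
  d2 <- as.matrix(stats::dist(xyz))^2
  area <- numeric(na)
  for (i in seq_len(na)) {
    pts <- sweep(sp * r[i], 2, xyz[i, ], "+")
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(na) != i)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 + (pts[, 3] - xyz[j, 3])^2
      acc <- acc & (dj2 >= r[j]^2)
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * r[i]^2 * sum(acc) / n_points
  }
  res_area <- vapply(split(area, a$res_idx), sum, 0)
  idx <- as.integer(names(res_area))
  rsa <- rep(NA_real_, protein$n)
  rsa[idx] <- pmin(1, res_area / .max_asa[protein$residues$resname[idx]])
  n_heavy <- tabulate(a$res_idx, nbins = protein$n)
  thin <- which(n_heavy < 3)
  if (length(thin)) {
    rsa[thin] <- NA_real_
    message("compute_rsa: rsa undefined for residue(s) with <3 heavy atoms: ",
            paste(protein$residues$resno[thin], collapse = ", "))
  }
  protein$residues$rsa <- rsa
  protein
}

#' Label nucleic-acid-binding residues
#'
#' A residue is positive when the distance between any of its atoms and any
#' ligand atom is strictly less than the sum of the two van der Waals radii
#' plus `margin` (default 0.5 A). Heavy atoms only by default, matching
#' hydrogen-free native structures.
#'
#' @param protein `protein_structure`.
#' @param ligand_atoms Data frame `element,x,y,z` (may be empty: all zeros).
#' @param vdw Named element -> radius table; unknown elements raise an error.
#' @param margin Slack added to the radii sum, Angstrom.
#' @param heavy_only Restrict both sides to heavy atoms.
#' @return Integer 0/1 vector of length `protein$n`.
#' @export
label_binding_residues <- function(protein, ligand_atoms, vdw = vdw_radii_bondi,
                                   margin = 0.5, heavy_only = TRUE) {
  stopifnot(inherits(protein, "protein_structure"))
  labels <- integer(protein$n)
  if (is.null(ligand_atoms) || !nrow(ligand_atoms)) return(labels)
  a <- protein$atoms
  if (heavy_only) a <- a[a$heavy, , drop = FALSE]
  lig <- ligand_atoms
  if (heavy_only) lig <- lig[toupper(lig$element) != "H", , drop = FALSE]
  if (!nrow(lig) || !nrow(a)) return(labels)
  unknown <- setdiff(unique(c(a$element, lig$element)), names(vdw))
  if (length(unknown)) stop("no vdW radius for element(s): ", paste(unknown, collapse = ", "))
  pa <- as.matrix(a[, c("x", "y", "z")])
  pb <- as.matrix(lig[, c("x", "y", "z")])
  ra <- unname(vdw[a$element]); rb <- unname(vdw[lig$element])
  # gap(a,b) = dist - (r_a + r_b); residue positive iff min gap < margin
  d <- sqrt(outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb))
  gap <- d - outer(ra, rb, "+")
  min_gap <- vapply(split(seq_len(nrow(a)), a$res_idx), function(rows) {
    min(gap[rows, , drop = FALSE])
  }, 0)
  labels[as.integer(names(min_gap))] <- as.integer(min_gap < margin)
  labels
}

#' Write / read per-residue binding labels as 2-column TSV
#'
#' @param protein `protein_structure` supplying author residue numbers.
#' @param labels 0/1 vector.
#' @param path File path.
#' @export
write_labels <- function(protein, labels, path) {
  stopifnot(length(labels) == protein$n)
  utils::write.table(
    data.frame(residue_id = protein$residues$resno, label = as.integer(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  stats::setNames(as.integer(df$label), df$residue_id)
}

#' Alpha-carbon coordinate matrix
#' @param protein `protein_structure`.
#' @return `n x 3` matrix (NA rows where CA is missing).
#' @export
ca_coords <- function(protein) {
  a <- protein$atoms[protein$atoms$elety == "CA", , drop = FALSE]
  m <- matrix(NA_real_, protein$n, 3)
  m[a$res_idx, ] <- as.matrix(a[, c("x", "y", "z")])
  m
}
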