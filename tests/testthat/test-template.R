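# Template alignment, selection, features and classifiers.

test_that("Kabsch recovers a known rigid transform and minimises RMSD", {
  set.seed(14)
  P <- matrix(rnorm(12, 0, 5), 4, 3)
  rigid <- random_rigid(9)
  Q <- sweep(P %*% rigid$R, 2, rigid$t, "+")
  fit <- kabsch(P, Q)
  expect_equal(fit$R, rigid$R, tolerance = 1e-9)
  expect_equal(fit$t, rigid$t, tolerance = 1e-9)
  moved <- sweep(P %*% fit$R, 2, fit$t, "+")
  expect_lt(sqrt(mean((moved - Q)^2)), 1e-9)
  # no random transform does better than the optimum on noisy points
  Qn <- Q + matrix(rnorm(12, 0, 0.5), 4, 3)
  best <- kabsch(P, Qn)
  rmsd <- function(R, t) sqrt(mean((sweep(P %*% R, 2, t, "+") - Qn)^2))
  opt <- rmsd(best$R, best$t)
  for (s in 1:10) {
    rr <- random_rigid(100 + s)
    expect_gte(rmsd(rr$R, rr$t), opt - 1e-9)
  }
})

test_that("aligning a structure to itself gives a perfect hit", {
  fx <- make_toy_protein(40, seed = 31)
  self <- fx$protein; attr(self, "id") <- "self"
  hit <- align_query_template(fx$protein, self)
  expect_equal(hit$tm_score, 1, tolerance = 1e-9)
  expect_equal(hit$seq_identity, 1)
  expect_equal(unname(hit$mapping), as.integer(names(hit$mapping)))
  ca <- ca_coords(fx$protein)
  moved <- sweep(ca %*% hit$R, 2, hit$t, "+")
  expect_lt(max(abs(moved - ca)), 1e-8)
})

test_that("a 1 A noisy copy keeps a high TM-score; decoys fall below 0.5", {
  # displacements of ~1 A magnitude (sd 1/sqrt(3) per coordinate); for
  # L = 100, d0 = 1.24*(85)^(1/3) - 1.8 = 3.65, so the TM-score formula on
  # the known identity mapping gives roughly 1/(1 + 1/d0^2) ~ 0.93
  fx <- make_toy_protein(100, seed = 32)
  noisy <- fx$protein
  set.seed(1)
  na <- nrow(noisy$atoms)
  noisy$atoms[, c("x", "y", "z")] <- noisy$atoms[, c("x", "y", "z")] +
    matrix(rnorm(na * 3, 0, 1 / sqrt(3)), na, 3)
  expect_gt(align_query_template(fx$protein, noisy)$tm_score, 0.9)

  decoy <- make_toy_protein(100, seed = 97)$protein
  expect_lt(align_query_template(fx$protein, decoy)$tm_score, 0.5)
})

test_that("template selection applies the tm/id filters and clustering", {
  fx <- make_toy_protein(45, seed = 33)
  # unmutated copy: id = 1 -> excluded; heavily mutated copies pass
  lib <- c(
    make_template_library(list(fx), n_templates = 1, coord_noise = 0.3,
                          mutation_rate = 0, seed = 1),
    make_template_library(list(fx), n_templates = 2, coord_noise = 0.8,
                          mutation_rate = 0.8, seed = 2)
  )
  lib[[1]]$id <- "identical"; lib[[2]]$id <- "mutA"; lib[[3]]$id <- "mutB"
  hits <- select_templates(fx$protein, lib)
  ids <- vapply(hits, function(h) h$entry$id, "")
  expect_false("identical" %in% ids)  # sequence identity 1 > 0.3 ceiling
  expect_true(all(c("mutA", "mutB") %in% ids))

  # three near-identical templates collapse to one representative
  trip <- make_template_library(list(fx), n_templates = 1, coord_noise = 0.5,
                                mutation_rate = 0.8, seed = 5)
  near <- lapply(1:3, function(k) {
    t2 <- trip[[1]]
    mut <- sample(t2$structure$n, 2)  # > 90% mutual identity remains
    for (i in mut) t2$structure$residues$resname[i] <- "GLY"
    t2$structure$seq <- unname(nabres:::.aa3to1[t2$structure$residues$resname])
    t2$id <- paste0("near", k)
    t2
  })
  hits2 <- select_templates(fx$protein, near)
  expect_equal(length(hits2), 1)

  # library order must not matter
  hits_rev <- select_templates(fx$protein, rev(lib))
  expect_equal(vapply(hits_rev, function(h) h$entry$id, ""), ids)
})

test_that("at most 20 templates survive, ranked by TM-score", {
  fx <- make_toy_protein(40, seed = 34)
  lib <- make_template_library(list(fx), n_templates = 25, coord_noise = 1,
                               mutation_rate = 0.85, seed = 6)
  hits <- select_templates(fx$protein, lib)
  expect_lte(length(hits), 20)
  expect_gt(length(hits), 15)  # mutated copies rarely cluster together
  tms <- vapply(hits, function(h) h$hit$tm_score, 0)
  expect_true(all(diff(tms) <= 1e-12))
})

test_that("self-template features reproduce labels, zero distance and BLOSUM diagonal", {
  fx <- make_toy_protein(35, seed = 36)
  entry <- template_entry(fx$protein, fx$labels, "self", ligand = fx$ligand)
  st <- fx$protein; attr(st, "id") <- "self"
  hit <- align_query_template(fx$protein, st)
  X <- template_residue_features(fx$protein, list(list(hit = hit, entry = entry)))
  expect_equal(dim(X), c(35, 120))
  expect_equal(unname(X[, "t01_dist"]), rep(0, 35), tolerance = 1e-8)
  # with ligand coordinates the binding column follows the 4.5 A proximity
  # rule, which is looser than the vdW labelling rule: a superset
  D <- as.matrix(dist(rbind(as.matrix(fx$protein$atoms[, c("x", "y", "z")]),
                            as.matrix(fx$ligand[, c("x", "y", "z")]))))
  na <- nrow(fx$protein$atoms)
  near45 <- vapply(split(seq_len(na), fx$protein$atoms$res_idx), function(rows) {
    as.numeric(min(D[rows, (na + 1):ncol(D)]) < 4.5)
  }, 0)
  expect_equal(unname(X[, "t01_bind"]), unname(near45))
  expect_true(all(X[, "t01_bind"] >= fx$labels))
  B62 <- nabres:::.blosum62()
  expect_equal(unname(X[, "t01_blosum"]),
               unname(B62[cbind(fx$protein$seq, fx$protein$seq)]))
  expect_true(all(X[, "t01_ss"] == 1))  # identical structure, identical states
  # slots beyond the single hit stay zero
  expect_equal(sum(X[, 7:120]), 0)
  # without ligand coordinates the template's labels stand in
  entry2 <- template_entry(fx$protein, fx$labels, "self2", ligand = NULL)
  X2 <- template_residue_features(fx$protein, list(list(hit = hit, entry = entry2)))
  expect_equal(unname(X2[, "t01_bind"]), as.numeric(fx$labels))
})

test_that("residues unaligned in a template are zero-filled", {
  fx <- make_toy_protein(40, seed = 37)
  trunc <- fx$protein
  keep <- 11:40
  trunc$atoms <- trunc$atoms[trunc$atoms$res_idx %in% keep, ]
  trunc$atoms$res_idx <- trunc$atoms$res_idx - 10
  trunc$residues <- trunc$residues[keep, ]
  trunc$residues$res_idx <- seq_along(keep)
  trunc$n <- length(keep)
  trunc$seq <- trunc$seq[keep]
  attr(trunc, "id") <- "trunc"
  hit <- align_query_template(fx$protein, trunc)
  entry <- template_entry(trunc, fx$labels[keep], "trunc")
  X <- template_residue_features(fx$protein, list(list(hit = hit, entry = entry)))
  unaligned <- setdiff(1:40, as.integer(names(hit$mapping)))
  expect_gt(length(unaligned), 0)
  expect_equal(sum(X[unaligned, ]), 0)
})

test_that("no templates means an all-zero 120-wide matrix", {
  fx <- make_toy_protein(20, seed = 38)
  X <- template_residue_features(fx$protein, list())
  expect_equal(dim(X), c(20, 120))
  expect_equal(sum(abs(X)), 0)
})

test_that("template classifiers learn planted signal and respect contracts", {
  set.seed(39)
  fx <- lapply(1:8, function(s) make_toy_protein(sample(50:80, 1), seed = 700 + s))
  lib <- make_template_library(fx, n_templates = 16, coord_noise = 1,
                               mutation_rate = 0.8, seed = 9)
  tfs <- lapply(fx, function(f) {
    template_residue_features(f$protein, select_templates(f$protein, lib))
  })
  Xtr <- do.call(rbind, tfs[1:6]); ytr <- unlist(lapply(fx[1:6], `[[`, "labels"))
  m <- train_template_classifiers(Xtr, ytr, seed = 2, ntree = 150, nrounds = 60)
  sc <- lapply(7:8, function(i) rowMeans(predict_template_classifiers(m, tfs[[i]])))
  lb <- lapply(fx[7:8], `[[`, "labels")
  expect_gte(protein_based_eval(sc, lb)$auc, 0.85)

  # permuted labels carry no signal
  set.seed(4)
  yperm <- sample(ytr)
  mp <- train_template_classifiers(Xtr, yperm, seed = 2, ntree = 100, nrounds = 40)
  pr <- predict_template_classifiers(mp, do.call(rbind, tfs[7:8]))
  auc_null <- suppressMessages(compute_metrics(rowMeans(pr), unlist(lb)))$auc
  expect_lt(abs(auc_null - 0.5), 0.12)

  # determinism under a fixed seed
  m2 <- train_template_classifiers(Xtr, ytr, seed = 2, ntree = 150, nrounds = 60)
  expect_equal(predict_template_classifiers(m, tfs[[7]]),
               predict_template_classifiers(m2, tfs[[7]]))
  expect_error(train_template_classifiers(Xtr, rep(1, length(ytr))), "classes")
})
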