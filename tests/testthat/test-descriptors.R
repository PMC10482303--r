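# Curvature, multifractal, distance-profile and shape descriptors, plus
# normalisation. The transport implementation is checked against an
# independent LP oracle (boot::simplex).

test_that("wasserstein1 matches the LP oracle on random transport problems", {
  set.seed(31)
  for (k in 1:20) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    a <- runif(n); a <- a / sum(a)
    b <- runif(m); b <- b / sum(b)
    cost <- matrix(sample(0:4, n * m, replace = TRUE), n, m)
    expect_equal(wasserstein1(a, b, cost), lp_wasserstein1(a, b, cost),
                 tolerance = 1e-8)
  }
})

test_that("ORC has the closed-form values on K2 and P3", {
  expect_equal(ollivier_ricci_edge(make_graph(2, rbind(c(1, 2)))), 1)
  p3 <- make_graph(3, rbind(c(1, 2), c(2, 3)))
  expect_equal(ollivier_ricci_edge(p3), c(0.5, 0.5))
  expect_equal(ollivier_ricci_node(p3), c(0.5, 1.0, 0.5))  # middle sums both edges
})

test_that("ORC equals the exhaustive LP oracle across the small-graph family", {
  for (g in graph_family()) {
    expect_equal(ollivier_ricci_edge(g), lp_orc_edges(g), tolerance = 1e-8)
  }
})

test_that("FRC with unit weights reduces to 4 - deg(x) - deg(y)", {
  p3 <- make_graph(3, rbind(c(1, 2), c(2, 3)))
  expect_equal(forman_ricci_edge(p3), c(1, 1))    # 4 - 1 - 2
  expect_equal(forman_ricci_node(p3)[2], 2)
  set.seed(17)
  for (k in 1:10) {
    n <- sample(5:50, 1)
    all_e <- t(utils::combn(n, 2))
    e <- all_e[runif(nrow(all_e)) < 3 / n, , drop = FALSE]
    if (nrow(e) < 2) next
    g <- make_graph(n, e)
    deg <- nabres:::.graph_degrees(g)
    expect_equal(forman_ricci_edge(g), 4 - deg[g$edges[, 1]] - deg[g$edges[, 2]])
  }
})

test_that("weighted FRC matches an independent term-wise evaluation", {
  set.seed(23)
  e <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(1, 6), c(2, 5))
  g <- make_graph(6, e, node_weights = runif(6, 0.5, 2),
                  edge_weights = runif(7, 0.5, 2))
  wn <- g$node_weights; we <- g$edge_weights
  manual <- sapply(seq_len(7), function(k) {
    x <- e[k, 1]; y <- e[k, 2]
    inc_x <- setdiff(which(e[, 1] == x | e[, 2] == x), k)
    inc_y <- setdiff(which(e[, 1] == y | e[, 2] == y), k)
    we[k] * (wn[x] / we[k] + wn[y] / we[k] -
               sum(wn[x] / sqrt(we[k] * we[inc_x])) -
               sum(wn[y] / sqrt(we[k] * we[inc_y])))
  })
  expect_equal(forman_ricci_edge(g), manual, tolerance = 1e-12)
  expect_error(forman_ricci_edge(make_graph(2, rbind(c(1, 2)), edge_weights = -1)),
               "positive")
})

test_that("multifractal dimension scales as 1 on a path and ~2 on a grid", {
  path <- make_graph(201, cbind(1:200, 2:201))
  expect_equal(multifractal_dimension(path)[101], 1, tolerance = 0.1)
  # 41 x 41 four-neighbour grid, interior node
  nn <- 41
  idx <- function(i, j) (i - 1) * nn + j
  e <- rbind(
    do.call(rbind, lapply(1:nn, function(i) cbind(idx(i, 1:(nn - 1)), idx(i, 2:nn)))),
    do.call(rbind, lapply(1:nn, function(j) cbind(idx(1:(nn - 1), j), idx(2:nn, j))))
  )
  grid <- make_graph(nn * nn, e)
  center <- idx(21, 21)
  expect_equal(multifractal_dimension(grid)[center], 2, tolerance = 0.15)
})

test_that("single-scale box mass at l=1 on a star center is log(n)", {
  n <- 9
  star <- make_graph(n, cbind(rep(1, n - 1), 2:n))
  expect_equal(mfd_single_scale(star, l = 1)[1], log(n))
  iso <- make_graph(3, rbind(c(1, 2)))
  expect_message(v <- multifractal_dimension(iso), "isolated")
  expect_equal(v[3], 0)
})

test_that("fragment centroid distances follow the 1+2+4 split", {
  # 4 collinear residues at x = 0, 1, 2, 3; target = first
  p <- point_protein(cbind(0:3, 0, 0), elety = "CA")
  expect_equal(fragment_centroid_distances(p, 1),
               c(1.5, 0.5, 2.5, 0, 1, 2, 3))
  # single-residue protein: every centroid coincides with the target
  p1 <- point_protein(matrix(c(2, 2, 2), 1), elety = "CA")
  expect_equal(suppressMessages(fragment_centroid_distances(p1, 1)), rep(0, 7))
  # translation invariance
  fx <- make_toy_protein(20, seed = 21)
  v1 <- fragment_centroid_distances(fx$protein, 5)
  moved <- fx$protein
  moved$atoms[, c("x", "y", "z")] <- moved$atoms[, c("x", "y", "z")] + 100
  expect_equal(fragment_centroid_distances(moved, 5), v1, tolerance = 1e-9)
})

test_that("USR features match the brute-force reference-point scan", {
  p2 <- point_protein(rbind(c(0, 0, 0), c(6, 0, 0)), elety = "CA")
  expect_equal(unname(usr_features(p2, 1)), c(3, 3, 3))
  p1 <- point_protein(matrix(0, 1, 3), elety = "CA")
  expect_equal(unname(usr_features(p1, 1)), c(0, 0, 0))
  set.seed(41)
  coords <- matrix(rnorm(60, 0, 8), 20, 3)
  p <- point_protein(coords, elety = "CA")
  for (target in c(1, 7, 20)) {
    d <- as.matrix(dist(coords))
    dr <- d[target, ]
    b <- which(dr == max(dr))[1]          # lowest-index tie break
    db <- d[b, ]
    g <- which(db == max(db))[1]
    expect_equal(unname(usr_features(p, target)),
                 c(mean(dr), mean(db), mean(d[g, ])), tolerance = 1e-12)
  }
})

test_that("geometry descriptor ingestion attaches, imputes and validates", {
  fx <- make_toy_protein(10, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(residue_id = 1:10, mir = 1:10 / 10, asv = 11:20, pocketness = 0.5)
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- ingest_geometry_descriptors(f, fx$protein)
  expect_equal(dim(m), c(10, 3))
  expect_equal(unname(m[, "mir"]), df$mir)

  write.table(df[1:7, ], f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(m2 <- ingest_geometry_descriptors(f, fx$protein), "imputed")
  expect_equal(unname(m2[8, "asv"]), mean(11:17))

  df_bad <- df; df_bad$mir <- as.character(df_bad$mir); df_bad$mir[3] <- "oops"
  write.table(df_bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(ingest_geometry_descriptors(f, fx$protein), "line")
})

test_that("z-scoring fits on training data only and drops constants", {
  set.seed(5)
  tr <- cbind(a = rnorm(50, 10, 2), b = rnorm(50), const = rep(3, 50))
  expect_message(zp <- zscore_fit(tr), "const")
  ztr <- zscore_apply(tr, zp)
  expect_equal(colnames(ztr), c("a", "b"))
  expect_equal(unname(colMeans(ztr)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(ztr, 2, sd)), c(1, 1), tolerance = 1e-9)
  # test-set application must use the training parameters, not its own stats
  te <- cbind(a = rnorm(20, 50, 1), b = rnorm(20, -5, 1), const = rep(3, 20))
  zte <- zscore_apply(te, zp)
  expect_equal(unname(zte[, "a"]), unname((te[, "a"] - zp$mean["a"]) / zp$sd["a"]))
  expect_gt(abs(mean(zte[, "a"])), 5)  # far from zero under train params
})

test_that("graph descriptors are invariant to node relabeling", {
  set.seed(77)
  e <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 3), c(4, 5))
  g <- make_graph(5, e)
  perm <- sample(5)
  e2 <- cbind(perm[e[, 1]], perm[e[, 2]])
  g2 <- make_graph(5, e2)
  expect_equal(ollivier_ricci_node(g2)[perm], ollivier_ricci_node(g))
  expect_equal(forman_ricci_node(g2)[perm], forman_ricci_node(g))
  expect_equal(multifractal_dimension(g2)[perm], multifractal_dimension(g))
})
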