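# Edge-featured graph attention layer: forward semantics, gradients,
# equivariance, and the training contract.

# straight-line reference implementation of the five update equations,
# independent of the vectorised production path
reference_egat <- function(graph, H, Fe, params, slope = 0.2) {
  n <- graph$n_nodes
  lrelu <- function(x) ifelse(x > 0, x, slope * x)
  Hp <- t(apply(H, 1, function(h) params$W %*% h + params$b))
  nb <- nabres:::.graph_neighbors(graph)
  efeat <- function(i, j) {
    for (k in seq_len(nrow(graph$edges))) {
      e <- graph$edges[k, ]
      if ((e[1] == i && e[2] == j) || (e[1] == j && e[2] == i)) return(Fe[k, ])
    }
    stop("no such edge")
  }
  H2 <- matrix(0, n, nrow(params$W))
  for (i in seq_len(n)) {
    if (!length(nb[[i]])) { H2[i, ] <- Hp[i, ]; next }
    evals <- vapply(nb[[i]], function(j) {
      fp <- lrelu(params$A %*% c(Hp[i, ], efeat(i, j), Hp[j, ]))
      as.numeric(params$Fv %*% fp)
    }, 0)
    a <- exp(evals - max(evals)); a <- a / sum(a)
    for (m in seq_along(nb[[i]])) H2[i, ] <- H2[i, ] + a[m] * Hp[nb[[i]][m], ]
  }
  p <- vapply(seq_len(n), function(i) {
    r <- pmax(params$W1 %*% c(H[i, ], H2[i, ]) + params$b1, 0)
    1 / (1 + exp(-(params$W2 %*% r + params$b2)))
  }, 0)
  list(H2 = H2, p = p)
}

rand_case <- function(seed, n = 6, d_in = 4) {
  set.seed(seed)
  all_e <- t(utils::combn(n, 2))
  e <- all_e[runif(nrow(all_e)) < 0.5, , drop = FALSE]
  if (nrow(e) < 2) e <- all_e[1:3, ]
  g <- make_graph(n, e)
  list(g = g, H = matrix(rnorm(n * d_in), n, d_in),
       Fe = matrix(rnorm(nrow(g$edges) * 2), ncol = 2),
       params = egat_init(d_in, 2, d_hidden = 5, d_edge_hidden = 4, d_head = 7,
                          seed = seed))
}

test_that("attention over neighbours sums to one", {
  cs <- rand_case(101)
  fw <- egat_forward(cs$g, cs$H, cs$Fe, cs$params)
  sums <- tapply(fw$attention$weight, fw$attention$src, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
})

test_that("the forward pass matches the straight-line reference", {
  for (seed in c(7, 19, 55)) {
    cs <- rand_case(seed)
    fw <- egat_forward(cs$g, cs$H, cs$Fe, cs$params)
    hd <- predict_head(cs$H, fw$H2, cs$params)
    ref <- reference_egat(cs$g, cs$H, cs$Fe, cs$params)
    expect_equal(fw$H2, ref$H2, tolerance = 1e-10)
    expect_equal(hd$p, ref$p, tolerance = 1e-10)
  }
})

test_that("zero head parameters output 0.5 and b2 acts monotonically", {
  cs <- rand_case(3)
  p0 <- cs$params
  p0$W1[] <- 0; p0$b1[] <- 0; p0$W2[] <- 0; p0$b2 <- 0
  fw <- egat_forward(cs$g, cs$H, cs$Fe, p0)
  expect_equal(predict_head(cs$H, fw$H2, p0)$p, rep(0.5, cs$g$n_nodes))
  p0$b2 <- 1
  expect_true(all(predict_head(cs$H, fw$H2, p0)$p > 0.5))
})

test_that("isolated nodes fall back to their projected features", {
  g <- make_graph(3, rbind(c(1, 2)))  # node 3 isolated
  set.seed(5)
  H <- matrix(rnorm(9), 3, 3)
  Fe <- matrix(rnorm(2), 1, 2)
  params <- egat_init(3, 2, d_hidden = 4, d_edge_hidden = 3, d_head = 5, seed = 2)
  fw <- egat_forward(g, H, Fe, params)
  expect_equal(fw$H2[3, ], as.numeric(params$W %*% H[3, ] + params$b))
})

test_that("outputs are equivariant under node permutation", {
  cs <- rand_case(23)
  n <- cs$g$n_nodes
  set.seed(1); perm <- sample(n)
  e2 <- cbind(perm[cs$g$edges[, 1]], perm[cs$g$edges[, 2]])
  swap <- e2[, 1] > e2[, 2]
  g2 <- make_graph(n, e2)
  # reorder edge features to the permuted graph's sorted edge order
  key2 <- paste(pmin(e2[, 1], e2[, 2]), pmax(e2[, 1], e2[, 2]))
  gkey <- paste(g2$edges[, 1], g2$edges[, 2])
  Fe2 <- cs$Fe[match(gkey, key2), , drop = FALSE]
  fw1 <- egat_forward(cs$g, cs$H, cs$Fe, cs$params)
  hd1 <- predict_head(cs$H, fw1$H2, cs$params)
  Hperm <- matrix(0, n, ncol(cs$H)); Hperm[perm, ] <- cs$H
  fw2 <- egat_forward(g2, Hperm, Fe2, cs$params)
  hd2 <- predict_head(Hperm, fw2$H2, cs$params)
  expect_equal(hd2$p[perm], hd1$p, tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  cs <- rand_case(42, n = 4)
  y <- c(1, 0, 0, 1)
  lg <- nabres:::.egat_loss_grad(cs$g, cs$H, cs$Fe, y, cs$params, pos_weight = 50)
  for (nm in c("W", "b", "A", "Fv", "W1", "b1", "W2", "b2")) {
    gref <- lg$grads[[nm]]
    num <- gref * 0
    for (i in seq_along(num)) {
      eps <- 1e-5
      p1 <- cs$params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- cs$params; p2[[nm]][i] <- p2[[nm]][i] - eps
      num[i] <- (nabres:::.egat_loss_grad(cs$g, cs$H, cs$Fe, y, p1, pos_weight = 50)$loss -
                   nabres:::.egat_loss_grad(cs$g, cs$H, cs$Fe, y, p2, pos_weight = 50)$loss) / (2 * eps)
    }
    rel <- max(abs(num - gref) / pmax(abs(num) + abs(gref), 1e-6))
    expect_lt(rel, 1e-4)
  }
})

test_that("pos_weight = 1 recovers plain cross-entropy on a 2-node example", {
  p <- c(0.8, 0.3); y <- c(1, 0)
  expect_equal(weighted_bce(p, y, pos_weight = 1),
               mean(-c(log(0.8), log(0.7))))
  # the positive term scales linearly in the weight
  expect_equal(weighted_bce(p, y, pos_weight = 50),
               mean(-c(50 * log(0.8), log(0.7))))
})

test_that("training descends, is seed-deterministic, and needs positives", {
  set.seed(8)
  mk <- function(s) {
    fx <- make_toy_protein(30, seed = s)
    g <- build_graph(fx$protein)
    list(graph = g,
         H = make_node_features(fx$protein, fx$labels, n_features = 6,
                                n_signal = 3, seed = s),
         Fe = cbind(g$edge_dist, g$edge_orient), labels = fx$labels)
  }
  ds <- lapply(1:3, mk)
  cfg <- egat_train_config(epochs = 3, seeds = 1:2, d_hidden = 6,
                           d_edge_hidden = 4, d_head = 8)
  e1 <- train_egat(ds, cfg)
  expect_lt(e1$models[[1]]$history[3], e1$models[[1]]$history[1])
  e2 <- train_egat(ds, cfg)
  expect_identical(e1$models[[1]]$params, e2$models[[1]]$params)

  ds0 <- lapply(ds, function(d) { d$labels[] <- 0L; d })
  expect_error(train_egat(ds0, cfg), "no positive")
})
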