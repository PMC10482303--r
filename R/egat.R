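# Edge-featured graph attention layer, prediction head, and training loop.
#
# One EGAT layer and one hidden fully connected layer, trained with weighted
# cross-entropy under Nesterov momentum. The forward/backward passes are
# vectorised over directed edges; gradients are analytic and are checked
# against finite differences in the test suite.

.glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialise EGAT parameters
#'
#' @param d_in Node feature dimension.
#' @param d_edge Edge feature dimension (distance + orientation = 2).
#' @param d_hidden Node projection width of the attention layer.
#' @param d_edge_hidden Width of the edge scoring map.
#' @param d_head Width of the fully connected head (default 256).
#' @param seed RNG seed.
#' @return List of parameter matrices `W, b, A, Fv, W1, b1, W2, b2`.
#' @export
egat_init <- function(d_in, d_edge = 2, d_hidden = 16, d_edge_hidden = 8,
                      d_head = 256, seed = 1) {
  set.seed(seed)
  list(
    W = .glorot(d_hidden, d_in), b = numeric(d_hidden),
    A = .glorot(d_edge_hidden, 2 * d_hidden + d_edge), Fv = .glorot(1, d_edge_hidden),
    W1 = .glorot(d_head, d_in + d_hidden), b1 = numeric(d_head),
    W2 = .glorot(1, d_head), b2 = 0,
    dims = c(d_in = d_in, d_edge = d_edge, d_hidden = d_hidden,
             d_edge_hidden = d_edge_hidden, d_head = d_head)
  )
}

# directed edge arrays from an undirected residue_graph + edge feature matrix
.directed_edges <- function(graph, Fe) {
  e <- graph$edges
  if (!nrow(e)) {
    return(list(src = integer(), dst = integer(), Fe = matrix(0, 0, ncol(Fe))))
  }
  list(src = c(e[, 1], e[, 2]), dst = c(e[, 2], e[, 1]), Fe = rbind(Fe, Fe))
}

#' EGAT layer forward pass
#'
#' Implements the update `h'_i = W h_i + b`;
#' `f'_ij = LeakyReLU(A [h'_i || f_ij || h'_j])`; `e_ij = F f'_ij`;
#' `a_ij = softmax_{j in N_i}(e_ij)`; `h''_i = sum_k a_ik h'_k`.
#' Nodes without neighbours fall back to `h''_i = h'_i`.
#'
#' @param graph `residue_graph`.
#' @param H `n x d_in` node feature matrix.
#' @param Fe `n_edges x d_edge` edge feature matrix (aligned with
#'   `graph$edges`; used symmetrically in both directions).
#' @param params From [egat_init()].
#' @param leaky_slope LeakyReLU negative slope (default 0.2).
#' @return List with `H2` (messages, `n x d_hidden`), `attention` (data frame
#'   `src, dst, weight`), and the cached intermediates used by the backward
#'   pass.
#' @export
egat_forward <- function(graph, H, Fe, params, leaky_slope = 0.2) {
  n <- graph$n_nodes
  stopifnot(nrow(H) == n, ncol(H) == params$dims["d_in"])
  de <- .directed_edges(graph, Fe)
  Hp <- tcrossprod(H, params$W) + matrix(params$b, n, length(params$b), byrow = TRUE)
  ne <- length(de$src)
  d_h <- ncol(Hp)
  if (ne) {
    U <- cbind(Hp[de$src, , drop = FALSE], de$Fe, Hp[de$dst, , drop = FALSE])
    Z <- tcrossprod(U, params$A)
    Fp <- ifelse(Z > 0, Z, leaky_slope * Z)
    s <- as.vector(tcrossprod(Fp, params$Fv))
    grp <- factor(de$src, levels = seq_len(n))
    mx <- tapply(s, grp, max)
    a_raw <- exp(s - mx[de$src])
    tot <- tapply(a_raw, grp, sum)
    a <- as.numeric(a_raw / tot[de$src])
    rs <- rowsum(a * Hp[de$dst, , drop = FALSE], de$src)
    H2 <- matrix(0, n, d_h)
    H2[as.integer(rownames(rs)), ] <- rs
  } else {
    U <- Z <- Fp <- NULL; s <- a <- numeric(0)
    H2 <- matrix(0, n, d_h)
  }
  iso <- setdiff(seq_len(n), unique(de$src))
  if (length(iso)) H2[iso, ] <- Hp[iso, , drop = FALSE]
  list(
    H2 = H2,
    attention = data.frame(src = de$src, dst = de$dst, weight = a),
    cache = list(H = H, Hp = Hp, U = U, Z = Z, Fp = Fp, a = a, de = de,
                 iso = iso, leaky_slope = leaky_slope, n = n)
  )
}

#' Prediction head
#'
#' `Y = sigmoid(W2 ReLU(W1 [H || H''] + b1) + b2)`, with inverted dropout on
#' the hidden layer during training.
#'
#' @param H Original node features.
#' @param H2 EGAT messages.
#' @param params From [egat_init()].
#' @param dropout_mask Optional 0/1 matrix (`n x d_head`); when supplied the
#'   hidden activations are masked and rescaled by `1/(1-dropout_rate)`.
#' @param dropout_rate Rate used for the rescale (default 0.5).
#' @return List with `p` (probabilities) and head cache.
#' @export
predict_head <- function(H, H2, params, dropout_mask = NULL, dropout_rate = 0.5) {
  X <- cbind(H, H2)
  R0 <- tcrossprod(X, params$W1) + matrix(params$b1, nrow(X), length(params$b1), byrow = TRUE)
  R1 <- pmax(R0, 0)
  scale <- if (is.null(dropout_mask)) 1 else 1 / (1 - dropout_rate)
  R1d <- if (is.null(dropout_mask)) R1 else R1 * dropout_mask * scale
  o <- as.vector(tcrossprod(R1d, params$W2)) + params$b2
  p <- 1 / (1 + exp(-o))
  list(p = p, cache = list(X = X, R0 = R0, R1d = R1d, mask = dropout_mask, scale = scale, o = o))
}

#' Weighted cross-entropy loss
#'
#' `mean(-w y log p - (1 - y) log(1 - p))` with positive-class weight `w`.
#'
#' @param p Predicted probabilities.
#' @param y 0/1 labels.
#' @param pos_weight Positive-class weight (50 by default downstream).
#' @export
weighted_bce <- function(p, y, pos_weight = 50) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  mean(-pos_weight * y * log(p) - (1 - y) * log(1 - p))
}

# full forward + analytic gradients for one protein graph
.egat_loss_grad <- function(graph, H, Fe, y, params, pos_weight = 50,
                            leaky_slope = 0.2, dropout_mask = NULL, dropout_rate = 0.5) {
  fw <- egat_forward(graph, H, Fe, params, leaky_slope)
  hd <- predict_head(H, fw$H2, params, dropout_mask, dropout_rate)
  p <- pmin(pmax(hd$p, 1e-12), 1 - 1e-12)
  n <- length(y)
  loss <- mean(-pos_weight * y * log(p) - (1 - y) * log(1 - p))

  go <- (-pos_weight * y * (1 - p) + (1 - y) * p) / n
  ch <- hd$cache; cc <- fw$cache
  dW2 <- matrix(go, 1) %*% ch$R1d
  db2 <- sum(go)
  dR1d <- go %*% params$W2
  dR1 <- if (is.null(ch$mask)) dR1d else dR1d * ch$mask * ch$scale
  dR0 <- dR1 * (ch$R0 > 0)
  dW1 <- crossprod(dR0, ch$X)
  db1 <- colSums(dR0)
  dX <- dR0 %*% params$W1
  d_in <- ncol(H); d_h <- ncol(cc$Hp)
  dH2 <- dX[, d_in + seq_len(d_h), drop = FALSE]

  dHp <- matrix(0, n, d_h)
  de <- cc$de; a <- cc$a
  if (length(de$src)) {
    da <- rowSums(dH2[de$src, , drop = FALSE] * cc$Hp[de$dst, , drop = FALSE])
    rs <- rowsum(a * dH2[de$src, , drop = FALSE], de$dst)
    dHp[as.integer(rownames(rs)), ] <- dHp[as.integer(rownames(rs)), ] + rs
    S <- tapply(a * da, factor(de$src, levels = seq_len(n)), sum)
    ds <- as.numeric(a * (da - S[de$src]))
    dFv <- matrix(ds, 1) %*% cc$Fp
    dFp <- ds %*% params$Fv
    dZ <- dFp * ifelse(cc$Z > 0, 1, cc$leaky_slope)
    dA <- crossprod(dZ, cc$U)
    dU <- dZ %*% params$A
    d_e <- ncol(de$Fe)
    rs1 <- rowsum(dU[, seq_len(d_h), drop = FALSE], de$src)
    dHp[as.integer(rownames(rs1)), ] <- dHp[as.integer(rownames(rs1)), ] + rs1
    rs2 <- rowsum(dU[, d_h + d_e + seq_len(d_h), drop = FALSE], de$dst)
    dHp[as.integer(rownames(rs2)), ] <- dHp[as.integer(rownames(rs2)), ] + rs2
  } else {
    dFv <- matrix(0, 1, ncol(params$Fv)); dA <- matrix(0, nrow(params$A), ncol(params$A))
  }
  if (length(cc$iso)) dHp[cc$iso, ] <- dHp[cc$iso, , drop = FALSE] + dH2[cc$iso, , drop = FALSE]
  dW <- crossprod(dHp, H)
  db <- colSums(dHp)

  list(loss = loss, p = hd$p,
       grads = list(W = dW, b = db, A = dA, Fv = dFv, W1 = dW1, b1 = db1,
                    W2 = dW2, b2 = db2))
}

#' Default deep-learning training configuration
#'
#' Mirrors the published recipe: 50 epochs, positive-class weight 50,
#' Nesterov momentum 0.9, L2 penalty 1e-6, learning rate 1e-4, dropout 0.5,
#' five models under five seeds.
#'
#' @param ... Overrides of any field.
#' @export
egat_train_config <- function(...) {
  cfg <- list(
    epochs = 50, pos_weight = 50, momentum = 0.9, l2 = 1e-6, lr = 1e-4,
    dropout = 0.5, seeds = 1:5, leaky_slope = 0.2,
    d_hidden = 16, d_edge_hidden = 8, d_head = 256
  )
  utils::modifyList(cfg, list(...))
}

#' Train the deep-learning module (ensemble over seeds)
#'
#' Full-graph gradient steps per protein, proteins shuffled each epoch under
#' the run seed; one model per seed in `cfg$seeds`. Inference averages the
#' ensemble.
#'
#' @param dataset List of `list(graph, H, Fe, labels)` entries.
#' @param cfg From [egat_train_config()].
#' @param verbose Print per-epoch loss.
#' @return List of per-seed parameter bundles, with `cfg` and per-epoch loss
#'   history attached.
#' @export
train_egat <- function(dataset, cfg = egat_train_config(), verbose = FALSE) {
  stopifnot(length(dataset) >= 1)
  if (!any(unlist(lapply(dataset, `[[`, "labels")) == 1)) {
    stop("no positive residues in the training set; weighted loss degenerate")
  }
  d_in <- ncol(dataset[[1]]$H)
  d_e <- ncol(dataset[[1]]$Fe)
  models <- list()
  for (seed in cfg$seeds) {
    params <- egat_init(d_in, d_e, cfg$d_hidden, cfg$d_edge_hidden, cfg$d_head, seed = seed)
    set.seed(seed)
    vel <- lapply(params[setdiff(names(params), "dims")], function(x) x * 0)
    history <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(length(dataset))
      ep_loss <- 0
      for (pi in ord) {
        d <- dataset[[pi]]
        mask <- if (cfg$dropout > 0) {
          matrix(stats::rbinom(length(d$labels) * cfg$d_head, 1, 1 - cfg$dropout),
                 length(d$labels), cfg$d_head)
        } else NULL
        lg <- .egat_loss_grad(d$graph, d$H, d$Fe, d$labels, params,
                              pos_weight = cfg$pos_weight,
                              leaky_slope = cfg$leaky_slope,
                              dropout_mask = mask, dropout_rate = cfg$dropout)
        for (nm in names(lg$grads)) {
          g <- lg$grads[[nm]] + cfg$l2 * params[[nm]]
          vel[[nm]] <- cfg$momentum * vel[[nm]] + g
          params[[nm]] <- params[[nm]] - cfg$lr * (g + cfg$momentum * vel[[nm]])
        }
        ep_loss <- ep_loss + lg$loss
      }
      history[ep] <- ep_loss / length(dataset)
      if (verbose) message(sprintf("seed %d epoch %d loss %.5f", seed, ep, history[ep]))
    }
    models[[length(models) + 1]] <- list(params = params, seed = seed, history = history)
  }
  structure(list(models = models, cfg = cfg), class = "egat_ensemble")
}

#' Predict with the deep-learning module
#'
#' @param ensemble From [train_egat()].
#' @param graph,H,Fe Protein graph and features.
#' @return Matrix `n x n_models` of per-seed probabilities; the module score
#'   is the row mean (`attr(.,"mean")` convenience accessor not used -- call
#'   `rowMeans`).
#' @export
predict_egat <- function(ensemble, graph, H, Fe) {
  out <- vapply(ensemble$models, function(m) {
    fw <- egat_forward(graph, H, Fe, m$params, ensemble$cfg$leaky_slope)
    predict_head(H, fw$H2, m$params)$p
  }, numeric(graph$n_nodes))
  matrix(out, nrow = graph$n_nodes,
         dimnames = list(NULL, paste0("dl_seed", seq_along(ensemble$models))))
}
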