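# nabres

Structure-based prediction of DNA- and RNA-binding residues.

Proteins touch nucleic acids through a small patch of residues; finding that
patch on a structure (experimental or predicted) is the target here. A
residue counts as *binding* when any of its atoms lies closer to a
nucleic-acid atom than the two van der Waals radii plus 0.5 Å.

`nabres` scores residues by merging two complementary predictors and a
network smoother:

1. **Deep-learning module.** The structure becomes a residue contact graph
   (any-atom distance < 10 Å). Nodes carry graph descriptors
   (Ollivier-Ricci curvature via exact optimal transport, Forman-Ricci
   curvature, multifractal box-mass dimension), distance-profile and
   ultrafast-shape-recognition features, optional pocket-geometry columns,
   and sequence-profile transforms (sigmoid of PSSM log-odds, `2^(-0.001x)`
   of HMM emission scores) or precomputed embeddings. Edges carry the
   heavy-atom distance and the backbone-plane orientation angle. One
   edge-featured graph attention (EGAT) layer

   `h'_i = W h_i + b`, `f'_ij = LeakyReLU(A[h'_i‖f_ij‖h'_j])`,
   `e_ij = F f'_ij`, `a_ij = softmax_{N_i}(e_ij)`,
   `h''_i = Σ_k a_ik h'_k`, `Y = σ(W₂ ReLU(W₁[H‖H''] + b₁) + b₂)`

   is trained with weighted cross-entropy (positive weight 50, Nesterov
   momentum 0.9, lr 1e-4, dropout 0.5, 50 epochs) under five seeds; the
   module score is the ensemble mean. Backpropagation is analytic and
   verified against finite differences.

2. **Template module.** Queries are aligned to an annotated template
   library (Needleman-Wunsch seeding, iterative Kabsch superposition,
   TM-score with `d0 = 1.24(L−15)^⅓ − 1.8`). Templates with TM-score > 0.3
   and sequence identity < 0.3 are clustered at 90% identity and the top 20
   retained; each residue gets 6 features per template (identity, TM-score,
   BLOSUM62, secondary-structure agreement, superposed CA distance, 0/1
   binding transfer at 4.5 Å), zero-padded to a fixed 120 columns. A random
   forest and two gradient-boosting variants average into the module score.

3. **Merging + post-processing.** A boosted meta-classifier stacks the 8
   lower-level scores (trained strictly on out-of-fold predictions), and a
   random walk with restart `p_{t+1} = (1−β) p_t W + β p_0` (β = 0.9,
   `w_ij = (δ−d_ij)/δ` for surface residues with RSA > 0.1, column
   normalised, stop at |Δp| < 1e-2) smooths isolated false positives off
   the protein surface.

A synthetic-fixture generator (toy backbones, planted binding patches,
perturbed template libraries, feature tables with a controllable effect
size) exercises the whole pipeline with no downloads, external binaries or
databases.

## Worked example

```r
library(nabres)

# 12 toy proteins with planted binding patches + a perturbed template library
fx    <- lapply(1:12, function(s) make_toy_protein(80, seed = s))
feats <- lapply(seq_along(fx), function(i)
  make_node_features(fx[[i]]$protein, fx[[i]]$labels, signal = 3, seed = 100 + i))
prep  <- nabind_prepare(fx, feats)
lib   <- make_template_library(fx, n_templates = 12, seed = 7)
tl    <- template_features_for(prep, lib)

cfg    <- nabind_config(egat = egat_train_config(epochs = 10, d_head = 32),
                        stack_folds = 3, tl_ntree = 150, tl_nrounds = 80)
bundle <- train_nabind(prep[1:10], tl$X[1:10], cfg = cfg, seed = 1)
pred   <- predict_nabind(bundle, prep[[11]], tl$X[[11]])
head(pred, 3)
#>   residue_id p_dl_mean  p_tl_mean     p_merged     p_final label_pred
#> 1          1 0.2805689 0.01063548 0.0008848934 0.003289000          0
#> 2          2 0.4192080 0.01691681 0.0008848934 0.003788374          0
#> 3          3 0.6335812 0.01063548 0.0008848934 0.016315120          0

compute_metrics(pred$p_final, fx[[11]]$labels)[c("auc", "aupr")]
#> $auc
#> [1] 1
#> $aupr
#> [1] 1
```

Columns: per-seed-averaged deep-learning score, template-module score,
stacked probability, diffusion-corrected probability, and the thresholded
call. On this planted fixture the final track ranks every true binding
residue above every non-binding one (AUC/AUPR = 1); real structures are
harder — see the methods vignette for what synthetic results do and do not
demonstrate.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/nabind.R fixtures --n 10 --length 80 --seed 1 --out fixtures/
Rscript inst/cli/nabind.R cv --fixtures fixtures/ --k 5 --seed 1 --out report.json
```

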