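# mmcdr — multimodal contrastive learning for cancer drug response

`mmcdr` predicts whether a cancer cell line is *sensitive* or *resistant*
to a drug by integrating three views of the cell line — gene expression,
copy-number variation (CNV), and a morphology image — with a molecular-
graph representation of the drug. It is aimed at computational biologists
who want a fully-tested, dependency-light R implementation of this model
family that can be exercised end to end on synthetic data, plus readers
of the drug-response literature who want to poke at the moving parts
(attention fusion, cross-modal contrastive alignment, graph convolution)
in isolation.

## The model

For cell line *i* and drug *j*:

* **Omics encoders.** Standardized expression and CNV matrices are
  projected by separate bias-free linear maps to *f* dimensions
  (`z_g = M_g W_g`, `z_c = M_c W_c`; default *f* = 18).
* **Attention fusion.** Per-sample scores `w = tanh(z w_s + b)` and a
  two-way softmax give convex weights:
  `h_omics = α_g z_g + α_c z_c`, `α_g + α_c = 1`.
* **Image encoder.** 224×224×3 images pass through two convolution
  blocks (3×3 kernels, ReLU, 2×2 average pooling), a global average pool
  and a linear head → `h_image` (m × f).
* **Contrastive alignment.** Matched omics/image rows are pulled
  together with a symmetric InfoNCE loss on L2-normalized embeddings,
  `s_ij = ⟨h_omics,i, h_image,j⟩`, temperature γ = 0.01:
  `L_cl = ½(L_o2I + L_I2o)` with
  `L_o2I = −(1/N) Σ_i log[ exp(s_ii/γ) / Σ_j exp(s_ij/γ) ]`.
* **Drug encoder.** SMILES → heavy-atom graph with 75-dimensional
  ConvMol-style atom features; two GCN layers
  `ReLU(D̃^{-1/2}(A+I)D̃^{-1/2} H W)` and global max pooling give a
  2f-dimensional drug vector.
* **Prediction.** An MLP head (4f → 2f → 1, sigmoid) scores the
  concatenation `[Z_cell, Z_drug]`; training minimizes
  `L = α L_c + β L_cl` (binary cross-entropy `L_c`; α = 0.6, β = 0.4)
  with full-batch Adam (lr 0.008, weight decay 1e-5), and evaluation is
  stratified k-fold cross-validation over (cell line, drug) pairs with
  AUROC and AUPR.

Labels come from screening data: sensitive iff IC50 ≤ the drug's maximum
screening concentration (inclusive).

## Worked example

The package ships a synthetic-data generator that plants a low-rank
cross-modal signal (see the vignette for exactly what is planted):

```r
library(mmcdr)

spec <- synthetic_spec(m = 40, n_drugs = 20, d_genes = 100,
                       image_size = 64, seed = 1)
ds <- generate_dataset(spec)
ds
#> Multimodal CDR dataset: 40 cell lines, 100 genes (expr), 100 genes (CNV),
#> 20 drugs, 800 labeled pairs

cfg <- model_config(f = 12, epochs = 200, folds = 3, seed = 1,
                    image_size = 64)
report <- cross_validate(ds, cfg)
report
#> Cross-validated evaluation (3 folds)
#>   mean AUROC = 0.7199, mean AUPR = 0.7246
```

(About 20 seconds on one CPU.) The mean AUROC is the probability that a
randomly chosen sensitive pair outranks a randomly chosen resistant pair
in the model's scores, averaged over the three held-out folds; 0.5 is
chance. This quick-start run recovers a useful fraction of the planted
signal; the package's full experiment (below) uses larger panels,
full-resolution images and longer training.

Individual components are exposed directly:

```r
g <- featurize_smiles("CCO")   # 3 heavy atoms, 2 bonds, 75-dim features
normalize_adjacency(g$A)       # GCN propagation matrix
contrastive_loss(diag(2), diag(2), gamma = 1)$L_cl
#> [1] 0.3132617
```

A command-line interface is installed as `exec/mmcdr`
(`mmcdr synth|preprocess|train-cv|sweep-alpha|embed`, YAML config
support, exit codes 0/2/3).

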