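# Drug representation: two graph-convolution layers over the molecular
# graph (75-dim atom features, symmetric-normalized adjacency with
# self-loops), ReLU after each layer, then global max pooling over atoms.

#' Single graph-convolution layer
#'
#' Computes `ReLU(A_hat %*% H %*% W)` where `A_hat` is the symmetric-
#' normalized adjacency with self-loops (see [normalize_adjacency()]).
#'
#' @param H Node feature matrix (n x d_in).
#' @param A_hat Normalized adjacency (n x n).
#' @param W Weight matrix (d_in x d_out).
#' @return Activated node features (n x d_out).
#' @export
gcn_layer <- function(H, A_hat, W) {
  H <- as.matrix(H)
  cdr_assert(nrow(A_hat) == nrow(H),
             "adjacency has ", nrow(A_hat), " nodes but features have ", nrow(H))
  if (ncol(H) != nrow(W)) {
    cdr_validation_error("GCN shape mismatch: features are ", nrow(H), "x",
                         ncol(H), " but weights are ", nrow(W), "x", ncol(W))
  }
  relu(A_hat %*% H %*% W)
}

#' Encode a molecular graph into a 2f-dimensional drug representation
#'
#' Two GCN layers (widths 75 -> 2f -> 2f, ReLU after each) followed by a
#' global elementwise max over atoms. Max pooling makes the representation
#' invariant to atom relabeling.
#'
#' @param g A `molecular_graph` from [featurize_smiles()].
#' @param params List with GCN weights `G1` (75 x 2f) and `G2` (2f x 2f).
#' @return Numeric vector of length 2f.
#' @export
encode_drug <- function(g, params) {
  cdr_assert(inherits(g, "molecular_graph"), "g must be a molecular_graph")
  if (g$n < 1) cdr_validation_error("cannot pool an empty graph")
  A_hat <- normalize_adjacency(g$A)
  H1 <- gcn_layer(g$X, A_hat, params$G1)
  H2 <- gcn_layer(H1, A_hat, params$G2)
  apply(H2, 2, max)
}

# Precompute per-drug constants reused every epoch: A_hat and A_hat %*% X.
drug_precompute <- function(graphs) {
  lapply(graphs, function(g) {
    A_hat <- normalize_adjacency(g$A)
    list(A_hat = A_hat, AX = A_hat %*% g$X, n = g$n, drug_id = g$drug_id)
  })
}

# Forward over the whole drug library; caches activations for backward.
drug_forward <- function(pre, params) {
  nd <- length(pre)
  f2 <- ncol(params$G2)
  Z <- matrix(0, nd, f2)
  cache <- vector("list", nd)
  for (j in seq_len(nd)) {
    M1 <- pre[[j]]$AX %*% params$G1
    H1 <- relu(M1)
    AH1 <- pre[[j]]$A_hat %*% H1
    M2 <- AH1 %*% params$G2
    H2 <- relu(M2)
    amax <- max.col(t(H2), ties.method = "first")   # argmax atom per channel
    Z[j, ] <- H2[cbind(amax, seq_len(f2))]
    cache[[j]] <- list(H1 = H1, AH1 = AH1, M1 = M1, M2 = M2, amax = amax)
  }
  list(Z_drug = Z, cache = cache)
}

drug_backward <- function(dZ, pre, params, cache) {
  f2 <- ncol(params$G2)
  dG1 <- matrix(0, nrow(params$G1), ncol(params$G1))
  dG2 <- matrix(0, nrow(params$G2), ncol(params$G2))
  for (j in seq_along(pre)) {
    dz <- dZ[j, ]
    if (all(dz == 0)) next
    cj <- cache[[j]]
    dH2 <- matrix(0, pre[[j]]$n, f2)
    dH2[cbind(cj$amax, seq_len(f2))] <- dz
    dM2 <- dH2 * (cj$M2 > 0)
    dG2 <- dG2 + crossprod(cj$AH1, dM2)
    dH1 <- crossprod(pre[[j]]$A_hat, dM2 %*% t(params$G2))
    dM1 <- dH1 * (cj$M1 > 0)
    dG1 <- dG1 + crossprod(pre[[j]]$AX, dM1)
  }
  list(G1 = dG1, G2 = dG2)
}
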