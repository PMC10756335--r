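# SMILES -> molecular graph featurization.
#
# Parsing and chemistry perception go through ChemmineR/ChemmineOB
# (OpenBabel): the kekulized SDF supplies elements, integer bond orders and
# formal charges; the MOL2 atom/bond typing supplies aromaticity and
# hybridization. The 75-dimensional per-atom feature layout follows the
# ConvMol convention used by graph-convolution models on molecules:
#   [1:44]  atom symbol one-hot over a fixed 44-symbol list ("Unknown" last)
#   [45:55] heavy-atom degree one-hot 0..10
#   [56:62] implicit-valence (implicit H count) one-hot 0..6
#   [63]    formal charge
#   [64]    number of radical electrons (0 for closed-shell parses)
#   [65:69] hybridization one-hot {SP, SP2, SP3, SP3D, SP3D2}
#   [70]    aromaticity flag
#   [71:75] total H count one-hot 0..4
# One-hot overflow falls in the last bucket.

ATOM_SYMBOLS <- c("C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na",
                  "Ca", "Fe", "As", "Al", "I", "B", "V", "K", "Tl", "Yb",
                  "Sb", "Sn", "Ag", "Pd", "Co", "Se", "Ti", "Zn", "H", "Li",
                  "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn", "Zr", "Cr", "Pt",
                  "Hg", "Pb", "Unknown")

one_hot <- function(value, levels, overflow_last = TRUE) {
  v <- numeric(length(levels))
  i <- match(value, levels)
  if (is.na(i)) {
    if (overflow_last) v[length(levels)] <- 1
  } else v[i] <- 1
  v
}

# MDL charge codes (SDF atom block field): 0->0, 1->+3, 2->+2, 3->+1,
# 4->radical, 5->-1, 6->-2, 7->-3.
mdl_charge <- function(code) {
  c(0, 3, 2, 1, 0, -1, -2, -3)[code + 1]
}

# Implicit H count from standard valence rules on the kekulized graph.
implicit_h_count <- function(symbol, bond_order_sum, charge) {
  base <- switch(symbol,
                 C = 4, Si = 4, B = 3, N = 3, P = 3, As = 3,
                 O = 2, S = 2, Se = 2,
                 F = 1, Cl = 1, Br = 1, I = 1, H = 1, 0)
  valence <- if (symbol %in% c("C", "Si", "B")) base - abs(charge) else base + charge
  max(0L, as.integer(round(valence - bond_order_sum)))
}

# Hybridization from the MOL2 atom type; degree+H > 4 upgrades to SP3D/SP3D2.
hybridization_from_type <- function(mol2_type, n_connections) {
  if (n_connections >= 6) return("SP3D2")
  if (n_connections == 5) return("SP3D")
  suffix <- sub("^[^.]+\\.?", "", mol2_type)
  switch(suffix,
         "1" = "SP",
         "2" = , "ar" = , "am" = , "pl3" = , "co2" = "SP2",
         "SP3")
}

# Fixed-width MDL V2000 connection table (kekulized output of OpenBabel's
# SMILES parser). Formal charges come from "M  CHG" property lines when
# present, else from the legacy atom-block charge codes.
parse_v2000 <- function(sdf_text) {
  lines <- strsplit(sdf_text, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4) cdr_runtime_error("empty SDF output")
  counts <- lines[4]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  if (is.na(n_atoms) || n_atoms < 1) cdr_runtime_error("no atoms in SDF output")
  atom_lines <- lines[4 + seq_len(n_atoms)]
  symbols <- trimws(substr(atom_lines, 32, 34))
  charges <- vapply(as.integer(substr(atom_lines, 37, 39)), mdl_charge, 0)
  bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  if (n_bonds > 0) {
    bond_lines <- lines[4 + n_atoms + seq_len(n_bonds)]
    bonds <- data.frame(a1 = as.integer(substr(bond_lines, 1, 3)),
                        a2 = as.integer(substr(bond_lines, 4, 6)),
                        order = as.integer(substr(bond_lines, 7, 9)))
  }
  for (chg in grep("^M  CHG", lines, value = TRUE)) {
    tok <- as.integer(strsplit(trimws(sub("^M  CHG", "", chg)),
                               "[[:space:]]+")[[1]])
    npair <- tok[1]
    for (p in seq_len(npair)) {
      charges[tok[2 * p]] <- tok[2 * p + 1]
    }
  }
  list(symbols = symbols, charges = charges, bonds = bonds)
}

parse_mol2 <- function(mol2_text) {
  lines <- strsplit(mol2_text, "\n", fixed = TRUE)[[1]]
  a0 <- which(lines == "@<TRIPOS>ATOM")[1]
  b0 <- which(lines == "@<TRIPOS>BOND")[1]
  sect <- function(start) {
    out <- character()
    i <- start + 1
    while (i <= length(lines) && !startsWith(lines[i], "@<TRIPOS>")) {
      if (nzchar(trimws(lines[i]))) out <- c(out, lines[i])
      i <- i + 1
    }
    out
  }
  atoms <- strsplit(trimws(sect(a0)), "[[:space:]]+")
  bonds <- strsplit(trimws(sect(b0)), "[[:space:]]+")
  list(types = vapply(atoms, `[`, "", 6),
       bonds = if (length(bonds))
         data.frame(a1 = as.integer(vapply(bonds, `[`, "", 2)),
                    a2 = as.integer(vapply(bonds, `[`, "", 3)),
                    type = vapply(bonds, `[`, "", 4))
       else data.frame(a1 = integer(), a2 = integer(), type = character()))
}

# Atoms that survive iterative leaf pruning lie on a cycle.
in_cycle <- function(adj) {
  deg <- rowSums(adj)
  active <- rep(TRUE, nrow(adj))
  repeat {
    leaves <- which(active & deg <= 1)
    if (!length(leaves)) break
    active[leaves] <- FALSE
    for (l in leaves) {
      nb <- which(adj[l, ] > 0 & active)
      deg[nb] <- deg[nb] - 1
    }
    deg[leaves] <- 0
  }
  active
}

connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] > 0 & comp == 0)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Convert a SMILES string into a featurized molecular graph
#'
#' Builds the heavy-atom graph of a molecule: a binary, symmetric,
#' zero-diagonal bond adjacency `A_d` (bond orders are not encoded) and a
#' 75-dimensional feature vector per atom (see the layout at the top of the
#' source file). Hydrogens are implicit. Multi-fragment SMILES (salts) keep
#' the largest fragment; the choice is reported via `message()`.
#'
#' @param smiles A syntactically valid SMILES string.
#' @param drug_id Identifier attached to the graph.
#' @return A `molecular_graph`: list with `X` (n x 75 feature matrix),
#'   `A` (n x n 0/1 adjacency), `n` (atom count), `drug_id`, `smiles`.
#' @export
#' @examples
#' \donttest{
#' g <- featurize_smiles("CCO")
#' g$n            # 3 heavy atoms
#' rowSums(g$A)   # bond degrees 1, 2, 1
#' }
featurize_smiles <- function(smiles, drug_id = smiles) {
  cdr_assert(is.character(smiles) && length(smiles) == 1 && nzchar(smiles),
             "smiles must be a single non-empty string")
  mol <- tryCatch(
    parse_v2000(ChemmineOB::convertFormat("SMI", "SDF", smiles)),
    error = function(e) cdr_validation_error(
      "cannot parse SMILES '", smiles, "': ", conditionMessage(e)))
  n_all <- length(mol$symbols)
  if (n_all < 1) cdr_validation_error("SMILES '", smiles, "' has zero atoms")
  symbols <- mol$symbols
  charges <- mol$charges
  adj_all <- matrix(0, n_all, n_all)
  order_sum <- numeric(n_all)
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$a1[r]; j <- mol$bonds$a2[r]; o <- mol$bonds$order[r]
      adj_all[i, j] <- 1
      adj_all[j, i] <- 1
      order_sum[i] <- order_sum[i] + o
      order_sum[j] <- order_sum[j] + o
    }
  }

  mol2 <- tryCatch(
    parse_mol2(ChemmineOB::convertFormat("SMI", "MOL2", smiles)),
    error = function(e) cdr_validation_error(
      "cannot derive atom types for SMILES '", smiles, "': ",
      conditionMessage(e)))
  if (length(mol2$types) != n_all) {
    cdr_runtime_error("atom count mismatch between SDF and MOL2 for '",
                      smiles, "'")
  }

  # aromaticity: OpenBabel's .ar typing, extended to ring heteroatoms (e.g.
  # furan O) that carry >= 2 aromatic bonds; acyclic atoms are never aromatic
  cyc <- in_cycle(adj_all)
  n_ar_bonds <- numeric(n_all)
  if (nrow(mol2$bonds)) {
    ar <- mol2$bonds[mol2$bonds$type == "ar", , drop = FALSE]
    for (r in seq_len(nrow(ar))) {
      n_ar_bonds[ar$a1[r]] <- n_ar_bonds[ar$a1[r]] + 1
      n_ar_bonds[ar$a2[r]] <- n_ar_bonds[ar$a2[r]] + 1
    }
  }
  aromatic <- cyc & (grepl("\\.ar$", mol2$types) | n_ar_bonds >= 2)

  # drop explicit hydrogens (rare in input SMILES) and keep largest fragment
  heavy <- symbols != "H"
  comp <- connected_components(adj_all)
  comp[!heavy] <- NA
  sizes <- table(comp[heavy])
  if (length(sizes) > 1) {
    message("SMILES '", smiles, "': ", length(sizes),
            " fragments; keeping the largest (",
            max(sizes), " atoms)")
  }
  if (!any(heavy)) cdr_validation_error("SMILES '", smiles, "' has no heavy atoms")
  keep_comp <- names(sizes)[which.max(sizes)]
  keep <- heavy & !is.na(comp) & comp == as.integer(keep_comp)

  idx <- which(keep)
  n <- length(idx)
  A <- adj_all[idx, idx, drop = FALSE]
  X <- matrix(0, n, 75)
  for (k in seq_len(n)) {
    a <- idx[k]
    # bonds to explicit H count toward total H, not heavy-atom degree
    h_exp <- sum(adj_all[a, !heavy & adj_all[a, ] > 0])
    degree <- sum(A[k, ])
    h_imp <- implicit_h_count(symbols[a], order_sum[a], charges[a])
    total_h <- h_imp + h_exp
    hyb <- if (aromatic[a]) "SP2" else
      hybridization_from_type(mol2$types[a], degree + total_h)
    X[k, ] <- c(
      one_hot(symbols[a], ATOM_SYMBOLS),
      one_hot(min(degree, 10), 0:10),
      one_hot(min(h_imp, 6), 0:6),
      charges[a],
      0,                                  # radical electrons
      one_hot(hyb, c("SP", "SP2", "SP3", "SP3D", "SP3D2")),
      as.numeric(aromatic[a]),
      one_hot(min(total_h, 4), 0:4))
  }
  structure(list(X = X, A = A, n = n, drug_id = drug_id, smiles = smiles),
            class = "molecular_graph")
}

#' Symmetric normalization of a molecular-graph adjacency
#'
#' Computes the GCN propagation matrix
#' \eqn{\hat A = \tilde D^{-1/2} (A + I) \tilde D^{-1/2}} where
#' \eqn{\tilde D} is the degree matrix of \eqn{\tilde A = A + I}.
#'
#' @param A Symmetric 0/1 adjacency with zero diagonal.
#' @return The normalized adjacency matrix (symmetric, entries in `[0, 1]`).
#' @export
#' @examples
#' normalize_adjacency(matrix(c(0, 1, 1, 0), 2))  # all entries 0.5
normalize_adjacency <- function(A) {
  A <- as.matrix(A)
  cdr_assert(nrow(A) == ncol(A), "adjacency must be square")
  if (max(abs(A - t(A))) > 0) cdr_validation_error("adjacency must be symmetric")
  if (any(diag(A) != 0)) cdr_validation_error("adjacency must have zero diagonal")
  At <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(At))
  At * outer(dinv, dinv)
}

#' Load and featurize a drug library
#'
#' @param path CSV with columns `drug_id`, `smiles`. Duplicate drug ids are
#'   rejected; any invalid SMILES aborts with its row number.
#' @return Named list of `molecular_graph` objects in file order.
#' @export
load_drug_library <- function(path) {
  if (!file.exists(path)) cdr_validation_error("drug library not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("drug_id", "smiles"), names(df))
  if (length(missing_cols)) {
    cdr_validation_error("drug library ", path, " lacks column(s): ",
                         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) {
    warning("drug library ", path, " is empty")
    return(structure(list(), names = character()))
  }
  dup <- which(duplicated(df$drug_id))
  if (length(dup)) {
    cdr_validation_error("duplicate drug_id '", df$drug_id[dup[1]],
                         "' at row ", dup[1])
  }
  graphs <- vector("list", nrow(df))
  for (r in seq_len(nrow(df))) {
    graphs[[r]] <- tryCatch(
      featurize_smiles(df$smiles[r], drug_id = df$drug_id[r]),
      error = function(e) cdr_validation_error(
        "row ", r, " (", df$drug_id[r], "): ", conditionMessage(e)))
  }
  names(graphs) <- df$drug_id
  graphs
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("Molecular graph '%s': %d heavy atoms, %d bonds\n",
              x$drug_id, x$n, sum(x$A) / 2))
  invisible(x)
}
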