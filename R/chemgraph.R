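# SMILES -> molecular graph with the 78-dimensional binary atom featurization
# used by the drug encoder. Parsing is delegated to OpenBabel through
# ChemmineR/ChemmineOB; this file owns only the featurization.

#' Element vocabulary of the atom featurizer
#'
#' The 44-slot element one-hot of the atom feature vector: 43 named symbols
#' (frozen, in this order) plus a final `"other"` fallback slot. The ordering
#' is part of the model definition and must not change between training and
#' prediction.
#'
#' @format character vector of length 44.
#' @export
ATOM_SYMBOLS <- c(
  "C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na", "Ca", "Fe",
  "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb", "Sn", "Ag", "Pd", "Co",
  "Se", "Ti", "Zn", "H", "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn",
  "Zr", "Cr", "Pt", "Hg", "Pb", "other"
)

#' Number of atom features
#'
#' 44 element slots + 11 degree slots + 11 hydrogen-count slots + 11
#' implicit-valence slots + 1 aromatic flag = 78.
#' @export
N_ATOM_FEATURES <- 44L + 11L + 11L + 11L + 1L

one_hot <- function(value, n_slots) {
  v <- integer(n_slots)
  v[value + 1L] <- 1L
  v
}

#' Binary feature vector of one atom
#'
#' Builds the 78-dimensional binary descriptor of a single atom: a 44-slot
#' element one-hot over [ATOM_SYMBOLS] (unknown elements fall into the final
#' `"other"` slot), an 11-slot one-hot for the heavy-atom degree (0-10), an
#' 11-slot one-hot for the total hydrogen count, an 11-slot one-hot for the
#' implicit valence, and one aromaticity flag.
#'
#' @param symbol element symbol, e.g. `"C"`.
#' @param degree number of heavy-atom neighbours, in 0-10.
#' @param total_hydrogens total attached hydrogens, in 0-10.
#' @param implicit_valence implicit valence (implicitly attached hydrogens),
#'   in 0-10.
#' @param is_aromatic logical aromaticity flag.
#' @return integer vector of length 78 containing 4 or 5 ones.
#' @export
#' @examples
#' f <- atom_features("C", degree = 4, total_hydrogens = 0,
#'                    implicit_valence = 0, is_aromatic = FALSE)
#' sum(f)  # 4: one per one-hot block, aromatic flag off
atom_features <- function(symbol, degree, total_hydrogens, implicit_valence,
                          is_aromatic) {
  counts <- c(degree = degree, total_hydrogens = total_hydrogens,
              implicit_valence = implicit_valence)
  if (any(counts < 0L | counts > 10L)) {
    bad <- names(counts)[counts < 0L | counts > 10L][1L]
    stop(bad, " must be in [0, 10], got ", counts[[bad]], call. = FALSE)
  }
  slot <- match(symbol, ATOM_SYMBOLS)
  if (is.na(slot)) slot <- length(ATOM_SYMBOLS) # "other"
  c(one_hot(slot - 1L, 44L),
    one_hot(as.integer(degree), 11L),
    one_hot(as.integer(total_hydrogens), 11L),
    one_hot(as.integer(implicit_valence), 11L),
    as.integer(isTRUE(is_aromatic) || (is.numeric(is_aromatic) && is_aromatic != 0)))
}

# Default valences of the organic subset; elements not listed get 0 implicit
# hydrogens. Formal charge is added to the default valence (covers the common
# N+, O-, S+ cases); this is a simplification for exotic charged carbons.
DEFAULT_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3,
                     S = 2, Cl = 1, As = 3, Se = 2, Br = 1, I = 1)

implicit_h_count <- function(symbol, bond_order_sum, formal_charge) {
  val <- DEFAULT_VALENCE[symbol]
  if (is.na(val)) return(0L)
  as.integer(max(0, val + formal_charge - bond_order_sum))
}

# V2000 old-style charge codes: 1..3 => +3..+1, 5..7 => -1..-3.
decode_charge_field <- function(code) {
  ifelse(code >= 1 & code <= 3, 4 - code, ifelse(code >= 5 & code <= 7, 4 - code, 0))
}

# Atoms, kekulized bonds (with orders) and formal charges of a SMILES.
# Primary path: ChemmineR's SDF container. ChemmineR flags bond-free (single
# heavy atom) SDFs as invalid, so those fall back to a minimal read of the
# fixed-width V2000 text that OpenBabel emitted.
parse_smiles_structure <- function(smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  usable <- !is.null(rownames(ab)) && nrow(ab) >= 1L &&
    all(grepl("_", rownames(ab)))
  if (usable) {
    symbols <- sub("_.*$", "", rownames(ab))
    bb <- ChemmineR::bondblock(mol)
    if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1L)
    bonds <- matrix(as.numeric(bb[, 1:3, drop = FALSE]), ncol = 3L)
    raw <- ChemmineR::sdf2str(mol)
  } else {
    raw <- strsplit(ChemmineOB::convertFormat("SMI", "SDF",
                                              paste0(smiles, "\n")),
                    "\n", fixed = TRUE)[[1]]
    n_at <- as.integer(substr(raw[4], 1, 3))
    n_bd <- as.integer(substr(raw[4], 4, 6))
    if (is.na(n_at) || n_at < 1L) stop("empty molecule", call. = FALSE)
    symbols <- vapply(strsplit(trimws(raw[5:(4 + n_at)]), "\\s+"),
                      function(f) f[4], character(1))
    bonds <- if (n_bd >= 1L) {
      bl <- raw[(5L + n_at):(4L + n_at + n_bd)]
      cbind(as.numeric(substr(bl, 1, 3)), as.numeric(substr(bl, 4, 6)),
            as.numeric(substr(bl, 7, 9)))
    } else matrix(numeric(0), ncol = 3L)
  }
  # formal charges: old-style atom-line codes, overridden by M CHG lines
  atom_lines <- raw[5:(4 + length(symbols))]
  charge <- vapply(strsplit(trimws(atom_lines), "\\s+"), function(f) {
    decode_charge_field(suppressWarnings(as.numeric(f[6])))
  }, numeric(1))
  charge[is.na(charge)] <- 0
  for (ln in grep("^M  CHG", raw, value = TRUE)) {
    v <- as.numeric(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    for (p in seq_len(v[1])) charge[v[2 * p]] <- v[2 * p + 1]
  }
  list(symbols = symbols, bonds = bonds, charge = charge)
}

# Aromatic-atom flags from a mol2 rendering of the same SMILES (OpenBabel
# keeps the input atom order across output formats). SDF V2000 is kekulized,
# so aromaticity has to come from a perception-aware format.
mol2_aromatic_flags <- function(smiles) {
  txt <- ChemmineOB::convertFormat("SMI", "MOL2", paste0(smiles, "\n"))
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  a0 <- which(lines == "@<TRIPOS>ATOM")
  a1 <- which(startsWith(lines, "@<TRIPOS>")) # next section
  a1 <- min(a1[a1 > a0])
  atom_lines <- lines[(a0 + 1L):(a1 - 1L)]
  types <- vapply(strsplit(trimws(atom_lines), "\\s+"),
                  function(f) f[6], character(1))
  grepl("\\.ar$", types)
}

#' Convert a SMILES string to a molecular graph
#'
#' Parses the SMILES with OpenBabel (via ChemmineR) and returns the graph
#' consumed by the drug encoder: one node per heavy atom in the parser's
#' atom order (explicit hydrogens are folded into their neighbour's hydrogen
#' count), a symmetric binary adjacency with zero diagonal, and the
#' 78-dimensional binary feature matrix from [atom_features()]. Bond orders,
#' stereochemistry and isotopes influence parsing but are not encoded beyond
#' connectivity.
#'
#' @param smiles a single SMILES string.
#' @param drug_id label stored on the graph; defaults to the SMILES itself.
#' @return an object of class `molecular_graph`: a list with `node_features`
#'   (N x 78 binary matrix), `adjacency` (N x N binary), `n_atoms`, `drug_id`.
#' @export
#' @examples
#' g <- smiles_to_graph("CC", "ethane")
#' g$adjacency
smiles_to_graph <- function(smiles, drug_id = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(trimws(smiles))) stop("empty SMILES string", call. = FALSE)

  parsed <- tryCatch(
    parse_smiles_structure(smiles),
    error = function(e) {
      stop("cannot parse SMILES '", smiles, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  symbols <- parsed$symbols
  n_all <- length(symbols)
  if (n_all < 1L) {
    stop("SMILES '", smiles, "' yields an empty molecule", call. = FALSE)
  }
  bb <- parsed$bonds
  n_bonds <- nrow(bb)
  charge <- parsed$charge

  aromatic <- mol2_aromatic_flags(smiles)
  if (length(aromatic) != n_all) aromatic <- rep(FALSE, n_all) # defensive

  adj_all <- matrix(0L, n_all, n_all)
  order_sum <- numeric(n_all)
  if (n_bonds > 0L) {
    for (b in seq_len(n_bonds)) {
      i <- bb[b, 1]; j <- bb[b, 2]; ord <- bb[b, 3]
      adj_all[i, j] <- 1L
      adj_all[j, i] <- 1L
      order_sum[i] <- order_sum[i] + ord
      order_sum[j] <- order_sum[j] + ord
    }
  }

  # fold explicit hydrogen atoms into their neighbour's hydrogen count
  is_h <- symbols == "H"
  heavy <- which(!is_h)
  if (length(heavy) == 0L) {
    stop("SMILES '", smiles, "' contains no heavy atoms", call. = FALSE)
  }
  explicit_h <- as.integer(adj_all[, is_h, drop = FALSE] %*%
                             rep(1L, sum(is_h)))[heavy]

  adj <- adj_all[heavy, heavy, drop = FALSE]
  degree <- as.integer(rowSums(adj))
  feats <- t(vapply(seq_along(heavy), function(k) {
    a <- heavy[k]
    imp_h <- implicit_h_count(symbols[a], order_sum[a], charge[a])
    atom_features(symbols[a], degree[k], imp_h + explicit_h[k], imp_h,
                  aromatic[a])
  }, integer(N_ATOM_FEATURES)))
  dimnames(adj) <- NULL

  structure(
    list(node_features = feats, adjacency = adj,
         n_atoms = length(heavy), drug_id = drug_id),
    class = "molecular_graph"
  )
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("molecular_graph '%s': %d heavy atoms, %d bonds, %d features/atom\n",
              x$drug_id, x$n_atoms, sum(x$adjacency) / 2, ncol(x$node_features)))
  invisible(x)
}

#' Dump molecular graphs as plain text for inspection
#'
#' Writes a tab-separated undirected edge list (`drug_id`, `i`, `j` with
#' `i < j`, 1-based) and, optionally, per-drug node-feature matrices.
#'
#' @param graphs a list of `molecular_graph` objects.
#' @param edge_file path for the edge list.
#' @param feature_dir optional directory for per-drug feature matrices
#'   (`<drug_id>.tsv`); skipped when `NULL`.
#' @return invisibly, the edge-list data frame.
#' @export
write_graph_edgelist <- function(graphs, edge_file, feature_dir = NULL) {
  rows <- do.call(rbind, lapply(graphs, function(g) {
    e <- which(upper.tri(g$adjacency) & g$adjacency == 1L, arr.ind = TRUE)
    if (nrow(e) == 0L) return(NULL)
    data.frame(drug_id = g$drug_id, i = e[, 1], j = e[, 2])
  }))
  if (is.null(rows)) rows <- data.frame(drug_id = character(), i = integer(),
                                        j = integer())
  utils::write.table(rows, edge_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(feature_dir)) {
    dir.create(feature_dir, showWarnings = FALSE, recursive = TRUE)
    for (g in graphs) {
      utils::write.table(g$node_features,
                         file.path(feature_dir, paste0(g$drug_id, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
  }
  invisible(rows)
}
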