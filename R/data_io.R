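# Dataset loading, validation, writing, and the seeded synthetic fixture
# generator that makes the whole pipeline runnable without any download.

#' Built-in pool of small-molecule SMILES
#'
#' Sixty curated, parseable small molecules (named) used by
#' [generate_fixtures()] to draw synthetic "drugs" without replacement.
#'
#' @format named character vector.
#' @export
SMILES_POOL <- c(
  methane = "C", ethane = "CC", propane = "CCC", butane = "CCCC",
  isobutane = "CC(C)C", methanol = "CO", ethanol = "CCO",
  acetic_acid = "CC(=O)O", acetone = "CC(C)=O", benzene = "c1ccccc1",
  toluene = "Cc1ccccc1", phenol = "Oc1ccccc1", aniline = "Nc1ccccc1",
  pyridine = "c1ccncc1", pyrrole = "c1cc[nH]c1", furan = "c1ccoc1",
  thiophene = "c1ccsc1", imidazole = "c1c[nH]cn1",
  naphthalene = "c1ccc2ccccc2c1", styrene = "C=Cc1ccccc1",
  benzaldehyde = "O=Cc1ccccc1", benzoic_acid = "OC(=O)c1ccccc1",
  aspirin = "CC(=O)Oc1ccccc1C(=O)O",
  caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  nicotine = "CN1CCC[C@H]1c1cccnc1",
  paracetamol = "CC(=O)Nc1ccc(O)cc1",
  ibuprofen = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
  glycine = "NCC(=O)O", alanine = "CC(N)C(=O)O", serine = "OCC(N)C(=O)O",
  cysteine = "SCC(N)C(=O)O", urea = "NC(N)=O",
  glucose = "OCC1OC(O)C(O)C(O)C1O", glycerol = "OCC(O)CO",
  citric_acid = "OC(=O)CC(O)(CC(=O)O)C(=O)O", lactic_acid = "CC(O)C(=O)O",
  pyruvic_acid = "CC(=O)C(=O)O", succinic_acid = "OC(=O)CCC(=O)O",
  fumaric_acid = "OC(=O)/C=C/C(=O)O", chlorobenzene = "Clc1ccccc1",
  bromobenzene = "Brc1ccccc1", fluorobenzene = "Fc1ccccc1",
  iodobenzene = "Ic1ccccc1", nitrobenzene = "O=[N+]([O-])c1ccccc1",
  benzonitrile = "N#Cc1ccccc1", anisole = "COc1ccccc1",
  dmso = "CS(C)=O", acetamide = "CC(N)=O", diethyl_ether = "CCOCC",
  thf = "C1CCOC1", cyclohexane = "C1CCCCC1", cyclopentane = "C1CCCC1",
  morpholine = "C1COCCN1", piperidine = "C1CCNCC1",
  indole = "c1ccc2[nH]ccc2c1", quinoline = "c1ccc2ncccc2c1",
  adenine = "Nc1ncnc2[nH]cnc12", uracil = "O=c1cc[nH]c(=O)[nH]1",
  thymine = "Cc1c[nH]c(=O)[nH]c1=O", cytosine = "Nc1cc[nH]c(=O)n1"
)

#' Number of drug/cell-line pairs in a full cross product
#'
#' @param n_drugs,n_cells positive integers.
#' @return their product as a double (to avoid integer overflow).
#' @export
#' @examples
#' pair_count(223, 948)  # 172114
pair_count <- function(n_drugs, n_cells) {
  stopifnot(n_drugs >= 1, n_cells >= 1)
  as.numeric(n_drugs) * as.numeric(n_cells)
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

new_bundle <- function(drugs, graphs, cells, responses) {
  structure(list(drugs = drugs, graphs = graphs, cells = cells,
                 responses = responses),
            class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat(sprintf("dataset_bundle: %d drugs x %d cell lines, %d response records\n",
              length(x$drugs), nrow(x$cells), nrow(x$responses)))
  invisible(x)
}

#' Generate a seeded synthetic dataset
#'
#' Emulates the three input tables (drug SMILES, binary cell-line mutation
#' vectors, IC50 responses) with a planted signal so the learning task is
#' solvable by construction. Drugs are drawn without replacement from
#' [SMILES_POOL]; each cell line gets 735 i.i.d. Bernoulli(0.1) mutation
#' indicators; the response of every drug/cell pair (full cross product) is
#' \deqn{\log(\mathrm{IC50}) = 1.5\, z_{cell} + 1.0\, z_{drug} + \varepsilon,
#'   \qquad \varepsilon \sim N(0, \mathrm{noise\_sd}^2),}
#' where `z_cell` is the count of ones among mutation slots 1-20 standardized
#' over the generated cells and `z_drug` the heavy-atom count standardized
#' over the generated drugs. Raw IC50 values are therefore always positive;
#' normalized values are attached via [normalize_ic50()].
#'
#' @param n_drugs number of drugs (at most `length(SMILES_POOL)`).
#' @param n_cells number of cell lines.
#' @param seed integer seed; the bundle is a pure function of the arguments.
#' @param noise_sd standard deviation of the log-scale noise (default 0.1).
#' @return a `dataset_bundle`: named `drugs` SMILES vector, parsed `graphs`,
#'   a `cells` binary matrix with cell ids as row names, and a `responses`
#'   data frame (`drug_id`, `cell_id`, `ic50_raw`, `ic50_norm`).
#' @export
generate_fixtures <- function(n_drugs, n_cells, seed = 1L, noise_sd = 0.1) {
  stopifnot(n_drugs >= 1, n_cells >= 1, noise_sd >= 0)
  if (n_drugs > length(SMILES_POOL)) {
    stop("requested ", n_drugs, " drugs but the SMILES pool holds only ",
         length(SMILES_POOL), call. = FALSE)
  }
  rng <- local_rng(seed)
  drugs <- SMILES_POOL[sort(rng$sample(seq_along(SMILES_POOL), n_drugs))]
  graphs <- lapply(names(drugs), function(id) smiles_to_graph(drugs[[id]], id))
  names(graphs) <- names(drugs)

  cells <- matrix(rng$rbinom(n_cells * CELL_INPUT_LEN, 1L, 0.1),
                  nrow = n_cells, ncol = CELL_INPUT_LEN)
  rownames(cells) <- sprintf("CELL%04d", seq_len(n_cells))

  z_cell <- standardize(rowSums(cells[, 1:20, drop = FALSE]))
  z_drug <- standardize(vapply(graphs, function(g) g$n_atoms, numeric(1)))

  grid <- expand.grid(cell = seq_len(n_cells), drug = seq_len(n_drugs),
                      KEEP.OUT.ATTRS = FALSE)
  eps <- rng$rnorm(nrow(grid), 0, noise_sd)
  log_ic50 <- 1.5 * z_cell[grid$cell] + 1.0 * z_drug[grid$drug] + eps
  ic50_raw <- exp(log_ic50)
  responses <- data.frame(
    drug_id = names(drugs)[grid$drug],
    cell_id = rownames(cells)[grid$cell],
    ic50_raw = ic50_raw,
    ic50_norm = normalize_ic50(ic50_raw),
    stringsAsFactors = FALSE
  )
  new_bundle(drugs, graphs, cells, responses)
}

#' Load a dataset from the three CSV tables
#'
#' Reads and cross-validates the drug table (`drug_id,smiles`), the cell-line
#' table (`cell_id` plus 735 binary mutation columns) and the response table
#' (`drug_id,cell_id,ic50`). Raw IC50 values are normalized on load. Column
#' names are remappable through `columns` for exports whose headers differ
#' (e.g. GDSC-style dumps); values are taken as given in the IC50 column.
#'
#' @param drug_csv,cell_csv,response_csv file paths (UTF-8, comma-separated,
#'   header row mandatory, `.` decimal).
#' @param columns named character vector remapping the expected column names,
#'   e.g. `c(ic50 = "LN_IC50_EXP")`.
#' @return a validated `dataset_bundle`.
#' @export
load_bundle <- function(drug_csv, cell_csv, response_csv,
                        columns = character(0)) {
  col <- function(name) if (name %in% names(columns)) columns[[name]] else name
  need <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop("missing column(s) ", paste(miss, collapse = ", "), " in ", file,
           call. = FALSE)
    }
  }
  drugs_df <- utils::read.csv(drug_csv, stringsAsFactors = FALSE)
  need(drugs_df, c(col("drug_id"), col("smiles")), drug_csv)
  drugs <- drugs_df[[col("smiles")]]
  names(drugs) <- drugs_df[[col("drug_id")]]
  if (anyDuplicated(names(drugs))) {
    stop("duplicate drug_id in ", drug_csv, call. = FALSE)
  }
  graphs <- lapply(names(drugs), function(id) smiles_to_graph(drugs[[id]], id))
  names(graphs) <- names(drugs)

  cells_df <- utils::read.csv(cell_csv, stringsAsFactors = FALSE,
                              check.names = FALSE)
  need(cells_df, col("cell_id"), cell_csv)
  cell_ids <- cells_df[[col("cell_id")]]
  cells <- as.matrix(cells_df[, setdiff(names(cells_df), col("cell_id")),
                              drop = FALSE])
  if (ncol(cells) != CELL_INPUT_LEN) {
    stop("expected ", CELL_INPUT_LEN, " mutation columns in ", cell_csv,
         ", found ", ncol(cells), call. = FALSE)
  }
  if (!all(cells %in% c(0, 1))) {
    stop("mutation entries must be 0/1 in ", cell_csv, call. = FALSE)
  }
  storage.mode(cells) <- "integer"
  rownames(cells) <- cell_ids
  if (anyDuplicated(cell_ids)) {
    stop("duplicate cell_id in ", cell_csv, call. = FALSE)
  }

  resp <- utils::read.csv(response_csv, stringsAsFactors = FALSE)
  need(resp, c(col("drug_id"), col("cell_id"), col("ic50")), response_csv)
  bad_drug <- which(!(resp[[col("drug_id")]] %in% names(drugs)))
  if (length(bad_drug)) {
    stop("response row ", bad_drug[1], " references unknown drug_id '",
         resp[[col("drug_id")]][bad_drug[1]], "'", call. = FALSE)
  }
  bad_cell <- which(!(resp[[col("cell_id")]] %in% cell_ids))
  if (length(bad_cell)) {
    stop("response row ", bad_cell[1], " references unknown cell_id '",
         resp[[col("cell_id")]][bad_cell[1]], "'", call. = FALSE)
  }
  y <- resp[[col("ic50")]]
  bad_y <- which(!is.finite(y) | y <= 0)
  if (length(bad_y)) {
    stop("response row ", bad_y[1], ": IC50 has to be a positive number ",
         "greater than zero (got ", y[bad_y[1]], ")", call. = FALSE)
  }
  dup <- which(duplicated(resp[, c(col("drug_id"), col("cell_id"))]))
  if (length(dup)) {
    stop("response row ", dup[1], " duplicates a (drug, cell) pair",
         call. = FALSE)
  }
  responses <- data.frame(
    drug_id = resp[[col("drug_id")]], cell_id = resp[[col("cell_id")]],
    ic50_raw = y, ic50_norm = normalize_ic50(y), stringsAsFactors = FALSE
  )
  new_bundle(drugs, graphs, cells, responses)
}

#' Write a dataset bundle to the three CSV tables
#'
#' Inverse of [load_bundle()]: writes `drugs.csv`, `cells.csv` and
#' `responses.csv` into `dir`. IC50 values are printed with 17 significant
#' digits so the round trip is exact.
#'
#' @param bundle a `dataset_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("drugs.csv", "cells.csv", "responses.csv"))
  utils::write.csv(
    data.frame(drug_id = names(bundle$drugs), smiles = unname(bundle$drugs),
               stringsAsFactors = FALSE),
    paths[1], row.names = FALSE, quote = FALSE)
  cells_df <- data.frame(cell_id = rownames(bundle$cells),
                         bundle$cells, check.names = FALSE,
                         stringsAsFactors = FALSE)
  colnames(cells_df) <- c("cell_id", sprintf("m%03d", seq_len(ncol(bundle$cells))))
  utils::write.csv(cells_df, paths[2], row.names = FALSE, quote = FALSE)
  resp <- bundle$responses
  resp_out <- data.frame(drug_id = resp$drug_id, cell_id = resp$cell_id,
                         ic50 = sprintf("%.17g", resp$ic50_raw),
                         stringsAsFactors = FALSE)
  utils::write.csv(resp_out, paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
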