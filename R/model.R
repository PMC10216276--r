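# Full model assembly: shared classical trunk (cell + drug encoders, fusion)
# with either the quantum depth-infused head or its classical twin
# (dense 256 -> 8 -> 1), plus IC50 target normalization and the MSE loss.

#' Normalize a raw IC50 value into (0, 1)
#'
#' Applies the logistic-like transform `norm(y) = 1 / (1 + y^0.1)`, which maps
#' positive IC50 values (any dose unit) into (0, 1) and is strictly
#' decreasing: more potent drugs (lower IC50) map to larger values.
#'
#' @param y positive numeric vector of raw IC50 values.
#' @return numeric vector in (0, 1).
#' @export
#' @examples
#' normalize_ic50(c(1, 1024, 1 / 1024))  # 0.5, 1/3, 2/3
normalize_ic50 <- function(y) {
  if (!is.numeric(y) || any(!is.finite(y)) || any(y <= 0)) {
    stop("IC50 has to be a positive number greater than zero", call. = FALSE)
  }
  1 / (1 + y^0.1)
}

#' Invert the IC50 normalization
#'
#' Exact inverse of [normalize_ic50()]: `y = (1/v - 1)^10`.
#'
#' @param v numeric vector in (0, 1).
#' @return positive numeric vector of raw IC50 values.
#' @export
denormalize_ic50 <- function(v) {
  if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0) || any(v >= 1)) {
    stop("normalized IC50 must lie strictly inside (0, 1)", call. = FALSE)
  }
  (1 / v - 1)^10
}

#' Mean squared error
#'
#' @param predictions,targets numeric vectors of equal length.
#' @return mean of squared differences.
#' @export
mse <- function(predictions, targets) {
  if (length(predictions) != length(targets) || length(targets) < 1L) {
    stop("predictions and targets must have equal positive length",
         call. = FALSE)
  }
  mean((predictions - targets)^2)
}

#' Build a drug-response model
#'
#' Assembles the shared classical trunk — the [cell_encoder_init()] branch,
#' the [drug_encoder_init()] branch and the drug-first fusion into a
#' 256-vector — with one of two heads:
#' \describe{
#'   \item{hybrid}{the 8-qubit quantum depth-infused layer ([qdi_params()]):
#'     1320 trainable rotation angles plus 2 affine readout scalars.}
#'   \item{classical}{two dense layers of 8 and 1 neurons
#'     (256x8 + 8 = 2056 parameters, then 8 + 1 = 9), ReLU between them.}
#' }
#' Both variants built from the same `seed` share bit-identical trunk
#' weights, so head comparisons are controlled.
#'
#' @param variant `"hybrid"` or `"classical"`.
#' @param seed integer seed; trunk and head seeds are derived from it.
#' @param cell_args,drug_args optional argument lists forwarded to the
#'   encoder initializers.
#' @param qdi_args optional argument list forwarded to [qdi_params()]
#'   (hybrid variant only).
#' @return an object of class `hqdr_model`.
#' @export
hqdr_model <- function(variant = c("hybrid", "classical"), seed = 1L,
                       cell_args = list(), drug_args = list(),
                       qdi_args = list()) {
  variant <- match.arg(variant)
  cell <- do.call(cell_encoder_init,
                  c(list(seed = derive_seed(seed, 1L)), cell_args))
  drug <- do.call(drug_encoder_init,
                  c(list(seed = derive_seed(seed, 2L)), drug_args))
  fused_dim <- 2L * cell$embed_dim
  if (variant == "hybrid") {
    head <- do.call(qdi_params,
                    c(list(seed = derive_seed(seed, 3L)), qdi_args))
    if (head$n_qubits * head$n_blocks != fused_dim) {
      stop("quantum layer expects ", head$n_qubits * head$n_blocks,
           " features but the fused embedding has ", fused_dim, call. = FALSE)
    }
  } else {
    rng <- local_rng(derive_seed(seed, 3L))
    head <- list(fc1 = list(W = glorot(rng, fused_dim, 8L), b = numeric(8L)),
                 fc2 = list(W = glorot(rng, 8L, 1L), b = numeric(1L)))
  }
  structure(
    list(variant = variant, cell = cell, drug = drug, head = head,
         seed = as.integer(seed), epochs_trained = 0L, opt = NULL),
    class = "hqdr_model"
  )
}

#' @export
print.hqdr_model <- function(x, ...) {
  cat(sprintf("hqdr_model (%s head), %d epochs trained\n", x$variant,
              x$epochs_trained))
  cnt <- count_head_parameters(x)
  cat("  head parameters:",
      paste(names(cnt$layers), cnt$layers, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

head_forward <- function(model, z) {
  if (model$variant == "hybrid") {
    qdi_readout(qdi_forward(z, model$head), model$head)
  } else {
    h <- relu(as.numeric(crossprod(model$head$fc1$W, z)) + model$head$fc1$b)
    as.numeric(crossprod(model$head$fc2$W, h)) + model$head$fc2$b
  }
}

#' Predict the normalized IC50 of one drug/cell-line pair
#'
#' Runs both trunk branches, fuses the embeddings (drug block first) and
#' applies the model head. The output approximates the normalized IC50; it is
#' not clamped to (0, 1) (the hybrid readout is affine).
#'
#' @param object an [hqdr_model()].
#' @param graph a `molecular_graph` for the drug.
#' @param profile binary mutation vector of length 735 for the cell line.
#' @param ... unused.
#' @return a single numeric prediction.
#' @export
predict.hqdr_model <- function(object, graph, profile, ...) {
  if (is.list(profile) && !is.null(profile$mutations)) profile <- profile$mutations
  z <- fuse(cell_encoder_forward(profile, object$cell),
            drug_encoder_forward(graph, object$drug))
  head_forward(object, z)
}

#' Per-layer head parameter counts
#'
#' For the hybrid head: the trainable rotation angles (8x5 + 8x5x32 = 1320
#' for the default geometry) with the 2 affine readout scalars reported
#' separately. For the classical head: the first dense layer
#' (256x8 weights + 8 biases = 2056) and the second (8 + 1 = 9), reported
#' per layer. Note the printed comparison figure for the classical head
#' (2056) covers its first layer only; the two-layer total is 2065.
#'
#' @param model an [hqdr_model()].
#' @return list with `variant`, `layers` (named integer vector) and `total`.
#' @export
count_head_parameters <- function(model) {
  stopifnot(inherits(model, "hqdr_model"))
  if (model$variant == "hybrid") {
    h <- model$head
    layers <- c(
      rotation_angles = count_parameters(h$n_qubits, h$n_layers_init,
                                         h$n_layers_block, h$n_blocks),
      affine_readout = 2L
    )
  } else {
    layers <- c(
      dense_1 = length(model$head$fc1$W) + length(model$head$fc1$b),
      dense_2 = length(model$head$fc2$W) + length(model$head$fc2$b)
    )
  }
  list(variant = model$variant, layers = layers, total = sum(layers))
}

# ---- flat parameter list <-> model (used by the optimizer and checkpoints)

model_param_list <- function(model) {
  p <- list()
  for (i in 1:3) {
    p[[paste0("cell.conv", i, ".W")]] <- model$cell$conv[[i]]$W
    p[[paste0("cell.conv", i, ".b")]] <- model$cell$conv[[i]]$b
  }
  p[["cell.fc.W"]] <- model$cell$fc$W
  p[["cell.fc.b"]] <- model$cell$fc$b
  for (i in 1:3) p[[paste0("drug.gcn", i)]] <- model$drug$gcn[[i]]
  p[["drug.fc1.W"]] <- model$drug$fc1$W
  p[["drug.fc1.b"]] <- model$drug$fc1$b
  p[["drug.fc2.W"]] <- model$drug$fc2$W
  p[["drug.fc2.b"]] <- model$drug$fc2$b
  if (model$variant == "hybrid") {
    p[["head.theta_init"]] <- model$head$theta_init
    p[["head.theta_blocks"]] <- model$head$theta_blocks
    p[["head.out_scale"]] <- model$head$out_scale
    p[["head.out_shift"]] <- model$head$out_shift
  } else {
    p[["head.fc1.W"]] <- model$head$fc1$W
    p[["head.fc1.b"]] <- model$head$fc1$b
    p[["head.fc2.W"]] <- model$head$fc2$W
    p[["head.fc2.b"]] <- model$head$fc2$b
  }
  p
}

model_set_param_list <- function(model, p) {
  shape_like <- function(new, old) {
    if (is.array(old) || is.matrix(old)) array(new, dim = dim(old)) else as.numeric(new)
  }
  for (i in 1:3) {
    model$cell$conv[[i]]$W <- shape_like(p[[paste0("cell.conv", i, ".W")]],
                                         model$cell$conv[[i]]$W)
    model$cell$conv[[i]]$b <- shape_like(p[[paste0("cell.conv", i, ".b")]],
                                         model$cell$conv[[i]]$b)
  }
  model$cell$fc$W <- shape_like(p[["cell.fc.W"]], model$cell$fc$W)
  model$cell$fc$b <- shape_like(p[["cell.fc.b"]], model$cell$fc$b)
  for (i in 1:3) {
    model$drug$gcn[[i]] <- shape_like(p[[paste0("drug.gcn", i)]],
                                      model$drug$gcn[[i]])
  }
  model$drug$fc1$W <- shape_like(p[["drug.fc1.W"]], model$drug$fc1$W)
  model$drug$fc1$b <- shape_like(p[["drug.fc1.b"]], model$drug$fc1$b)
  model$drug$fc2$W <- shape_like(p[["drug.fc2.W"]], model$drug$fc2$W)
  model$drug$fc2$b <- shape_like(p[["drug.fc2.b"]], model$drug$fc2$b)
  if (model$variant == "hybrid") {
    model$head$theta_init <- shape_like(p[["head.theta_init"]],
                                        model$head$theta_init)
    model$head$theta_blocks <- shape_like(p[["head.theta_blocks"]],
                                          model$head$theta_blocks)
    model$head$out_scale <- as.numeric(p[["head.out_scale"]])
    model$head$out_shift <- as.numeric(p[["head.out_shift"]])
  } else {
    model$head$fc1$W <- shape_like(p[["head.fc1.W"]], model$head$fc1$W)
    model$head$fc1$b <- shape_like(p[["head.fc1.b"]], model$head$fc1$b)
    model$head$fc2$W <- shape_like(p[["head.fc2.W"]], model$head$fc2$W)
    model$head$fc2$b <- shape_like(p[["head.fc2.b"]], model$head$fc2$b)
  }
  model
}

#' Save / load a model checkpoint
#'
#' Checkpoints are plain-text JSON: every weight array is stored flattened
#' alongside a manifest of array shapes, the variant, and the training state.
#'
#' @param model an [hqdr_model()].
#' @param path file path for the checkpoint (`.json`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "hqdr_model"))
  p <- model_param_list(model)
  manifest <- lapply(p, function(a) if (is.null(dim(a))) length(a) else dim(a))
  obj <- list(
    package = "hqdr", format = 1L, variant = model$variant,
    seed = model$seed, epochs_trained = model$epochs_trained,
    manifest = manifest,
    arrays = lapply(p, as.numeric),
    geometry = if (model$variant == "hybrid") {
      model$head[c("n_qubits", "n_blocks", "n_layers_init", "n_layers_block",
                   "encoding_scale")]
    }
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  qdi_args <- if (identical(obj$variant, "hybrid")) {
    as.list(obj$geometry)[c("n_qubits", "n_blocks", "n_layers_init",
                            "n_layers_block", "encoding_scale")]
  } else list()
  model <- hqdr_model(obj$variant, seed = obj$seed, qdi_args = qdi_args)
  model <- model_set_param_list(model, obj$arrays)
  model$epochs_trained <- as.integer(obj$epochs_trained)
  model
}
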