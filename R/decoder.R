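# Cell-conditioned decoder: a small hypernetwork maps each cell's embedding
# to the weights of that cell's 1x1 convolutional output filter, which is
# applied position-wise to the sequence embedding. RNA heads are stranded
# (2 output channels), ATAC heads unstranded (1 channel). Predictions live on
# the transformed (squashed) scale; softplus guarantees positivity.

#' Create a hypernetwork head
#'
#' A small MLP (one hidden GELU layer) mapping a D-dimensional cell embedding
#' to the `(E+1) x n_strands` decoder parameters for one assay: E filter
#' weights plus one bias per strand.
#'
#' @param d_embedding Cell-embedding dimension D (default 14).
#' @param e_width Sequence-embedding width E.
#' @param n_strands 2 for RNA, 1 for ATAC.
#' @param hidden Hidden-layer width (default 64).
#' @param seed Seed for initialization.
#' @return A `hypernet` list.
#' @export
make_hypernet <- function(d_embedding = 14L, e_width, n_strands,
                          hidden = 64L, seed = 1L) {
  set.seed(seed)
  out_dim <- (e_width + 1L) * n_strands
  structure(list(
    W1 = matrix(stats::rnorm(d_embedding * hidden, sd = sqrt(2 / d_embedding)),
                d_embedding, hidden),
    b1 = rep(0, hidden),
    W2 = matrix(stats::rnorm(hidden * out_dim, sd = sqrt(1 / hidden) * 0.1),
                hidden, out_dim),
    b2 = rep(0, out_dim),
    d = as.integer(d_embedding), e = as.integer(e_width),
    n_strands = as.integer(n_strands), hidden = as.integer(hidden)),
    class = "hypernet")
}

hypernet_forward <- function(hn, cell_emb) {
  # cell_emb: (n_cells x D)
  pre1 <- sweep(cell_emb %*% hn$W1, 2L, hn$b1, `+`)
  h <- gelu(pre1)
  out <- sweep(h %*% hn$W2, 2L, hn$b2, `+`)
  list(out = out, cache = list(X = cell_emb, pre1 = pre1, h = h))
}

hypernet_backward <- function(hn, dOut, cache) {
  dW2 <- crossprod(cache$h, dOut)
  db2 <- colSums(dOut)
  dh <- dOut %*% t(hn$W2)
  dpre1 <- dh * gelu_grad(cache$pre1)
  dW1 <- crossprod(cache$X, dpre1)
  db1 <- colSums(dpre1)
  list(dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

#' Generate per-cell decoder parameters
#'
#' Runs the hypernetwork on one or more cell embeddings and reshapes the
#' output to `(E+1, n_strands, n_cells)`: for each strand, E filter weights
#' followed by one bias. With the full-scale E = 1,920 this is (1921, 2, n)
#' for RNA and (1921, 1, n) for ATAC.
#'
#' @param hypernet A [make_hypernet()] head.
#' @param cell_embeddings Matrix `(n_cells x D)` (a single vector is
#'   accepted).
#' @return Array `(E+1, n_strands, n_cells)` of class `decoder_params`.
#' @export
generate_decoder_params <- function(hypernet, cell_embeddings) {
  if (is.null(dim(cell_embeddings)))
    cell_embeddings <- matrix(cell_embeddings, nrow = 1L)
  if (ncol(cell_embeddings) != hypernet$d)
    stop("cell embedding dimension ", ncol(cell_embeddings),
         " does not match hypernetwork input ", hypernet$d)
  out <- hypernet_forward(hypernet, cell_embeddings)$out
  params <- array(t(out), dim = c(hypernet$e + 1L, hypernet$n_strands,
                                  nrow(cell_embeddings)))
  class(params) <- c("decoder_params", "array")
  params
}

# Reshape hypernet output rows (n x (E+1)*S) to params array and back.
params_to_flat <- function(params) {
  d <- dim(params)
  t(matrix(params, d[1L] * d[2L], d[3L]))
}

#' Decode sequence embeddings into per-cell profiles
#'
#' Applies each cell's 1x1 convolution position-wise:
#' `out[b, s, c] = softplus( sum_e emb[b, e] * w[e, s, c] + bias[s, c] )`.
#' There is no cross-bin mixing.
#'
#' @param seq_embedding Matrix `(bins x E)`.
#' @param params `decoder_params` array `(E+1, n_strands, n_cells)`.
#' @param activation "softplus" (default) or "identity" (pre-activation).
#' @return Array `(bins x n_strands x n_cells)`.
#' @export
decode <- function(seq_embedding, params, activation = c("softplus", "identity")) {
  activation <- match.arg(activation)
  E <- ncol(seq_embedding)
  d <- dim(params)
  if (d[1L] != E + 1L)
    stop("embedding width ", E, " does not match decoder params (expect E+1=",
         d[1L], ")")
  S <- d[2L]; n <- d[3L]
  Wmat <- matrix(params[seq_len(E), , , drop = FALSE], E, S * n)
  bias <- as.vector(params[E + 1L, , ])
  pre <- sweep(seq_embedding %*% Wmat, 2L, bias, `+`)
  if (activation == "softplus") pre <- softplus(pre)
  array(pre, dim = c(nrow(seq_embedding), S, n))
}

# Backward through decode: dOut (bins x S x n) -> grads for params and
# embedding. pre must be recomputed or cached by the caller; here we cache.
decode_forward <- function(seq_embedding, params) {
  E <- ncol(seq_embedding)
  d <- dim(params)
  S <- d[2L]; n <- d[3L]
  Wmat <- matrix(params[seq_len(E), , , drop = FALSE], E, S * n)
  bias <- as.vector(params[E + 1L, , ])
  pre <- sweep(seq_embedding %*% Wmat, 2L, bias, `+`)
  out <- softplus(pre)
  list(out = array(out, c(nrow(seq_embedding), S, n)),
       cache = list(pre = pre, Wmat = Wmat, emb = seq_embedding,
                    E = E, S = S, n = n))
}

decode_backward <- function(dOut, cache) {
  dPre <- matrix(dOut, nrow(cache$emb), cache$S * cache$n) *
    softplus_grad(cache$pre)
  dW <- crossprod(cache$emb, dPre)            # E x S*n
  db <- colSums(dPre)
  dparams <- array(0, dim = c(cache$E + 1L, cache$S, cache$n))
  dparams[seq_len(cache$E), , ] <- array(dW, c(cache$E, cache$S, cache$n))
  dparams[cache$E + 1L, , ] <- array(db, c(cache$S, cache$n))
  dEmb <- dPre %*% t(cache$Wmat)
  list(dparams = dparams, dEmb = dEmb)
}

#' Decode only selected bin slices
#'
#' Returns decoded profiles restricted to the embedding slices overlapping
#' regions of interest (e.g. exons); bit-equal to the full decode restricted
#' to those bins. The decode is evaluated once over the window (position-wise
#' and cheap at these model sizes) and sliced, which guarantees exact
#' equality irrespective of BLAS blocking.
#'
#' @param seq_embedding Matrix `(bins x E)`.
#' @param params `decoder_params`.
#' @param bin_slices List of integer vectors of bin indices (1-based), or a
#'   single integer vector.
#' @param activation Output activation.
#' @return A list of arrays, one per slice (`(slice bins) x S x n`).
#' @export
decode_region <- function(seq_embedding, params, bin_slices,
                          activation = "softplus") {
  if (!is.list(bin_slices)) bin_slices <- list(bin_slices)
  full <- decode(seq_embedding, params, activation)
  lapply(bin_slices, function(sl) {
    if (length(sl) == 0L)
      return(array(0, c(0L, dim(params)[2L], dim(params)[3L])))
    if (any(sl < 1L | sl > nrow(seq_embedding)))
      stop("bin slice out of range [1, ", nrow(seq_embedding), "]")
    full[sl, , , drop = FALSE]
  })
}

# --- assembled model --------------------------------------------------------

#' Assemble a profile model
#'
#' Bundles the sequence backbone, per-assay hypernetwork heads, the target
#' transform, and an embedding cache into one model object.
#'
#' @param backbone A backbone.
#' @param d_embedding Cell-embedding dimension D.
#' @param hidden Hypernetwork hidden width.
#' @param transform The [target_transform()] used for targets.
#' @param cache_size Number of sequence embeddings kept in the cache
#'   (0 disables caching).
#' @param seed Seed for hypernetwork initialization.
#' @return An environment of class `profile_model`.
#' @export
profile_model <- function(backbone, d_embedding = 14L, hidden = 64L,
                          transform = target_transform(), cache_size = 8L,
                          seed = 1L) {
  m <- new.env(parent = emptyenv())
  m$backbone <- backbone
  E <- backbone$geometry$embedding_width
  m$hypernet_rna <- make_hypernet(d_embedding, E, 2L, hidden, seed)
  m$hypernet_atac <- make_hypernet(d_embedding, E, 1L, hidden, seed + 1L)
  m$transform <- transform
  m$cache_size <- as.integer(cache_size)
  m$cache <- new.env(parent = emptyenv())
  m$cache_keys <- character()
  m$backbone_calls <- 0L
  m$version <- 0L
  class(m) <- c("profile_model", "environment")
  m
}

#' @export
print.profile_model <- function(x, ...) {
  cat("profile_model with backbone:\n  ")
  print(x$backbone)
  cat(sprintf("  hypernets: D=%d, hidden=%d; cache size %d\n",
              x$hypernet_rna$d, x$hypernet_rna$hidden, x$cache_size))
  invisible(x)
}

model_version <- function(model) paste(model$version, model$backbone$version)

# Invalidate cached embeddings (called on any weight update).
bump_model_version <- function(model) {
  model$version <- model$version + 1L
  invisible(model)
}

# Cached embedding lookup keyed by (sequence digest, shift, rc, weights
# version); stale entries never hit because the key embeds the version.
model_embed_cached <- function(model, seq, shift = 0L, rc = FALSE) {
  if (model$cache_size <= 0L) {
    model$backbone_calls <- model$backbone_calls + 1L
    return(embed_sequence(model$backbone, one_hot(seq, shift, rc)))
  }
  key <- paste(substr(seq, 1, 64), nchar(seq),
               sum(utf8ToInt(seq) * (seq_len(nchar(seq)) %% 97 + 1)),
               shift, rc, model_version(model), sep = "|")
  hit <- model$cache[[key]]
  # guard against digest collisions: a hit must carry the exact sequence
  if (!is.null(hit) && identical(hit$seq, seq)) return(hit$emb)
  model$backbone_calls <- model$backbone_calls + 1L
  emb <- embed_sequence(model$backbone, one_hot(seq, shift, rc))
  if (is.null(hit) && length(model$cache_keys) >= model$cache_size) {
    drop <- model$cache_keys[1L]
    rm(list = drop, envir = model$cache)
    model$cache_keys <- model$cache_keys[-1L]
    model$cache_keys <- c(model$cache_keys, key)
  } else if (is.null(hit)) {
    model$cache_keys <- c(model$cache_keys, key)
  }
  model$cache[[key]] <- list(seq = seq, emb = emb)
  emb
}

#' Predict single-cell profiles for a sequence
#'
#' Embeds the sequence (through the cache: repeated calls for new cell
#' batches reuse the embedding) and decodes RNA and ATAC profiles for the
#' requested cells. Results are identical to uncached evaluation.
#'
#' @param model A [profile_model()].
#' @param seq DNA sequence of geometry `input_length`.
#' @param cell_embeddings Matrix `(n_cells x D)`.
#' @param shift,rc Augmentation applied to the input window.
#' @return List with `rna` `(bins x 2 x n)` and `atac` `(bins x 1 x n)`
#'   arrays on the transformed scale.
#' @export
cached_predict <- function(model, seq, cell_embeddings, shift = 0L, rc = FALSE) {
  emb <- model_embed_cached(model, seq, shift, rc)
  params_rna <- generate_decoder_params(model$hypernet_rna, cell_embeddings)
  params_atac <- generate_decoder_params(model$hypernet_atac, cell_embeddings)
  list(rna = decode(emb, params_rna), atac = decode(emb, params_atac))
}

# Flat parameter plumbing for the hypernets (names prefixed hn_rna/, hn_atac/).
hypernet_param_names <- function(prefix) {
  paste0(prefix, "/", c("W1", "b1", "W2", "b2"))
}

model_get_params <- function(model, names) {
  out <- lapply(names, function(nm) {
    toks <- strsplit(nm, "/", fixed = TRUE)[[1]]
    if (toks[1L] == "hn_rna") model$hypernet_rna[[toks[2L]]]
    else if (toks[1L] == "hn_atac") model$hypernet_atac[[toks[2L]]]
    else bb_get(model$backbone, nm)
  })
  names(out) <- names
  out
}

model_set_params <- function(model, params) {
  bb_params <- params[!grepl("^hn_", names(params))]
  if (length(bb_params)) backbone_set_params(model$backbone, bb_params)
  for (nm in grep("^hn_", names(params), value = TRUE)) {
    toks <- strsplit(nm, "/", fixed = TRUE)[[1]]
    if (toks[1L] == "hn_rna") model$hypernet_rna[[toks[2L]]] <- params[[nm]]
    else model$hypernet_atac[[toks[2L]]] <- params[[nm]]
  }
  bump_model_version(model)
  invisible(model)
}

# Trainable parameter names: LoRA factors (if injected, else nothing from the
# frozen base), the final trained projection, and both hypernets. Norm affine
# parameters join when the backbone is unfrozen and train_norm is set.
model_trainable_names <- function(model, train_norm = FALSE) {
  bb <- model$backbone
  nms <- c(backbone_param_names(bb, "lora"), backbone_param_names(bb, "final"),
           hypernet_param_names("hn_rna"), hypernet_param_names("hn_atac"))
  if (train_norm && !bb$norm_frozen) nms <- c(nms, backbone_param_names(bb, "norm"))
  nms
}

#' Save / load a model checkpoint
#'
#' Single-file archive of geometry, configuration and all weights.
#' @param model A `profile_model`.
#' @param path File path (.rds).
#' @export
save_checkpoint <- function(model, path) {
  bb <- model$backbone
  obj <- list(geometry = bb$geometry, channels = bb$channels,
              n_conv = bb$n_conv, n_attn = bb$n_attn,
              dropout_p = bb$dropout_p,
              stem = bb$stem, stem_bn = bb$stem_bn, stem2 = bb$stem2,
              blocks = bb$blocks, attns = bb$attns, final = bb$final,
              pos_enc = bb$pos_enc,
              hypernet_rna = model$hypernet_rna,
              hypernet_atac = model$hypernet_atac,
              transform = model$transform, cache_size = model$cache_size)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  bb <- make_mini_backbone(obj$geometry, obj$channels, obj$n_conv, obj$n_attn,
                           stem_channels = length(obj$stem$b),
                           dropout_p = obj$dropout_p, seed = 0L)
  bb$stem <- obj$stem; bb$stem_bn <- obj$stem_bn; bb$stem2 <- obj$stem2
  bb$blocks <- obj$blocks; bb$attns <- obj$attns
  bb$final <- obj$final
  if (!is.null(obj$pos_enc)) bb$pos_enc <- obj$pos_enc
  m <- profile_model(bb, d_embedding = obj$hypernet_rna$d,
                     hidden = obj$hypernet_rna$hidden,
                     transform = obj$transform, cache_size = obj$cache_size)
  m$hypernet_rna <- obj$hypernet_rna
  m$hypernet_atac <- obj$hypernet_atac
  m
}
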