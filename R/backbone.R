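# Sequence-encoder contract and a miniature trainable implementation.
#
# The encoder maps a one-hot DNA window to a per-bin embedding at bin_width
# (32 bp) resolution. The mini backbone is a strided-convolution stem (one
# patch per bin), residual convolution blocks across bins, an optional
# single-head self-attention block applied after the center crop, and a final
# trained projection with GELU nonlinearity whose output feeds the cell
# decoder. All adaptable layers (convolutions; attention query/value; MLP
# projections) expose LoRA injection points.

#' Create a miniature sequence backbone
#'
#' A small, CPU-trainable encoder honoring the sequence-embedding contract:
#' one-hot DNA in, center-cropped per-bin embedding out, with adaptable layers
#' enumerable by kind for LoRA injection.
#'
#' @param geometry A [model_geometry()].
#' @param channels Internal channel width.
#' @param n_conv Number of residual convolution blocks (kernel 5 across
#'   bins); block i uses dilation `dilations[i]`, so stacked blocks give bins
#'   a translation-invariant receptive field spanning distal regulatory
#'   sequence (e.g. a promoter several kb away).
#' @param n_attn Number of attention blocks (applied after the center crop).
#' @param dilations Per-block dilation factors (recycled to `n_conv`).
#' @param stem_channels Width of the first stem stage (default 3x `channels`):
#'   motif detection benefits from many first-layer filters, independent of
#'   the trunk width.
#' @param dropout_p Dropout probability inside blocks (default 0).
#' @param seed Integer seed for weight initialization.
#' @return An environment of class `mini_backbone`.
#' @export
make_mini_backbone <- function(geometry, channels = 32L, n_conv = 4L,
                               n_attn = 1L, dilations = c(1L, 4L, 16L, 48L),
                               stem_channels = 3L * channels,
                               dropout_p = 0, seed = 1L) {
  set.seed(seed)
  dilations <- rep_len(as.integer(dilations), n_conv)
  C <- as.integer(channels)
  k <- geometry$bin_width
  E <- geometry$embedding_width
  rn <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
  bb <- new.env(parent = emptyenv())
  bb$geometry <- geometry
  bb$channels <- C
  bb$n_conv <- as.integer(n_conv)
  bb$n_attn <- as.integer(n_attn)
  bb$dropout_p <- dropout_p
  bb$dropout_enabled <- TRUE
  bb$norm_frozen <- FALSE
  bb$version <- 0L
  # two-stage stem pyramid: overlapping k=16/stride=8 windows (any 8-mer sits
  # fully inside at least one window, so short motifs are detectable at any
  # phase), then a 4-fold strided aggregation down to one patch per bin
  if (k != 32L) stop("mini backbone assumes 32-bp bins")
  Cs <- as.integer(stem_channels)  # wide stem: motif-detection capacity
  bb$stem_channels <- Cs
  bb$stem <- list(W = rn(4L * 16L, Cs, sqrt(2 / 64)), b = rep(0, Cs),
                  k = 16L, stride = 8L, pad = 4L, kind = "convolution",
                  lora = NULL)
  bb$stem_bn <- nn_bn_init(Cs)
  bb$stem2 <- list(W = rn(4L * Cs, C, sqrt(2 / (4 * Cs))), b = rep(0, C),
                   k = 4L, stride = 4L, pad = 0L, kind = "convolution",
                   lora = NULL)
  bb$blocks <- lapply(seq_len(bb$n_conv), function(i) {
    d <- dilations[i]
    list(bn = nn_bn_init(C),
         conv = list(W = rn(5L * C, C, sqrt(2 / (5 * C))), b = rep(0, C),
                     k = 5L, stride = 1L, pad = 2L * d, dilation = d,
                     kind = "convolution", lora = NULL))
  })
  bb$attns <- lapply(seq_len(bb$n_attn), function(i) {
    list(bn1 = nn_bn_init(C),
         att = list(Wq = rn(C, C, sqrt(1 / C)), Wk = rn(C, C, sqrt(1 / C)),
                    Wv = rn(C, C, sqrt(1 / C)), Wo = rn(C, C, sqrt(1 / C)),
                    lora_q = NULL, lora_v = NULL),
         bn2 = nn_bn_init(C),
         mlp = list(W1 = rn(C, 2L * C, sqrt(2 / C)), b1 = rep(0, 2 * C),
                    W2 = rn(2L * C, C, sqrt(1 / (2 * C))), b2 = rep(0, C),
                    lora1 = NULL, lora2 = NULL))
  })
  bb$final <- list(W = rn(C, E, sqrt(2 / C)), b = rep(0, E))
  # fixed sinusoidal positional channels added to the cropped representation
  # before attention, so content-based attention can condition on position
  # (e.g. distance from the window center) and generalize across loci
  nb <- geometry$output_bins
  pos <- (seq_len(nb) - (nb + 1) / 2) / nb
  pe <- vapply(seq_len(C), function(j) {
    f <- 2^((j - 1) %/% 2)
    if (j %% 2 == 0) sin(2 * pi * f * pos) else cos(2 * pi * f * pos)
  }, numeric(nb))
  bb$pos_enc <- 0.3 * pe
  class(bb) <- c("mini_backbone", "environment")
  bb
}

#' @export
print.mini_backbone <- function(x, ...) {
  cat(sprintf("mini_backbone: C=%d, %d conv block(s), %d attention block(s), E=%d%s\n",
              x$channels, x$n_conv, x$n_attn, x$geometry$embedding_width,
              if (backbone_has_lora(x)) ", LoRA injected" else ""))
  invisible(x)
}

# Deep-copy a backbone environment (adapters and weights included).
backbone_clone <- function(bb) {
  out <- new.env(parent = emptyenv())
  for (nm in ls(bb, all.names = TRUE)) assign(nm, get(nm, envir = bb), envir = out)
  class(out) <- class(bb)
  out
}

backbone_has_lora <- function(bb) {
  if (!is.null(bb$stem$lora) || !is.null(bb$stem2$lora)) return(TRUE)
  for (bl in bb$blocks) if (!is.null(bl$conv$lora)) return(TRUE)
  for (ab in bb$attns) {
    if (!is.null(ab$att$lora_q) || !is.null(ab$att$lora_v)) return(TRUE)
    if (!is.null(ab$mlp$lora1) || !is.null(ab$mlp$lora2)) return(TRUE)
  }
  FALSE
}

#' Freeze / unfreeze normalization layers and dropout
#'
#' While frozen, batch-normalization layers use their running statistics (no
#' batch statistics, no updates) and dropout is disabled; used to stabilize
#' the first optimization step.
#' @param bb A backbone.
#' @export
freeze_norm <- function(bb) {
  bb$norm_frozen <- TRUE
  bb$dropout_enabled <- FALSE
  invisible(bb)
}

#' @rdname freeze_norm
#' @export
unfreeze_norm <- function(bb) {
  bb$norm_frozen <- FALSE
  bb$dropout_enabled <- TRUE
  invisible(bb)
}

# --- forward / backward -----------------------------------------------------

backbone_forward <- function(bb, X, training = FALSE) {
  if (nrow(X) != bb$geometry$input_length)
    stop("geometry mismatch: sequence length ", nrow(X), " != input_length ",
         bb$geometry$input_length)
  use_batch_stats <- training && !bb$norm_frozen
  caches <- list()
  st <- nn_conv_forward(X, bb$stem)
  sbn <- nn_bn_forward(st$Y, bb$stem_bn, use_batch_stats)
  if (!is.null(sbn$new_stats)) {
    bb$stem_bn$run_mean <- sbn$new_stats$run_mean
    bb$stem_bn$run_var <- sbn$new_stats$run_var
  }
  sg <- gelu(sbn$Y)
  st2 <- nn_conv_forward(sg, bb$stem2)
  H <- st2$Y
  caches$stem <- st$cache
  caches$stem_bn <- sbn$cache
  caches$stem_pre_gelu <- sbn$Y
  caches$stem2 <- st2$cache
  caches$blocks <- vector("list", bb$n_conv)
  for (i in seq_len(bb$n_conv)) {
    bl <- bb$blocks[[i]]
    bno <- nn_bn_forward(H, bl$bn, use_batch_stats)
    if (!is.null(bno$new_stats)) {
      bb$blocks[[i]]$bn$run_mean <- bno$new_stats$run_mean
      bb$blocks[[i]]$bn$run_var <- bno$new_stats$run_var
    }
    G <- gelu(bno$Y)
    cv <- nn_conv_forward(G, bl$conv)
    H <- H + cv$Y
    caches$blocks[[i]] <- list(bn = bno$cache, pre_gelu = bno$Y, conv = cv$cache)
  }
  cb <- bb$geometry$crop_bins
  Hc <- H[(cb + 1L):(cb + bb$geometry$output_bins), , drop = FALSE]
  if (bb$n_attn > 0L) Hc <- Hc + bb$pos_enc
  caches$pre_crop_dim <- dim(H)
  caches$attns <- vector("list", bb$n_attn)
  for (i in seq_len(bb$n_attn)) {
    ab <- bb$attns[[i]]
    b1 <- nn_bn_forward(Hc, ab$bn1, use_batch_stats)
    if (!is.null(b1$new_stats)) {
      bb$attns[[i]]$bn1$run_mean <- b1$new_stats$run_mean
      bb$attns[[i]]$bn1$run_var <- b1$new_stats$run_var
    }
    at <- nn_attn_forward(b1$Y, ab$att)
    Hc <- Hc + at$Y
    b2 <- nn_bn_forward(Hc, ab$bn2, use_batch_stats)
    if (!is.null(b2$new_stats)) {
      bb$attns[[i]]$bn2$run_mean <- b2$new_stats$run_mean
      bb$attns[[i]]$bn2$run_var <- b2$new_stats$run_var
    }
    W1e <- if (is.null(ab$mlp$lora1)) ab$mlp$W1 else
      ab$mlp$W1 + (ab$mlp$lora1$alpha / ab$mlp$lora1$rank) * (ab$mlp$lora1$A %*% ab$mlp$lora1$B)
    W2e <- if (is.null(ab$mlp$lora2)) ab$mlp$W2 else
      ab$mlp$W2 + (ab$mlp$lora2$alpha / ab$mlp$lora2$rank) * (ab$mlp$lora2$A %*% ab$mlp$lora2$B)
    pre1 <- sweep(b2$Y %*% W1e, 2L, ab$mlp$b1, `+`)
    g1 <- gelu(pre1)
    M <- sweep(g1 %*% W2e, 2L, ab$mlp$b2, `+`)
    drop_mask <- NULL
    if (training && bb$dropout_enabled && bb$dropout_p > 0) {
      drop_mask <- matrix(stats::rbinom(length(M), 1L, 1 - bb$dropout_p),
                          nrow(M)) / (1 - bb$dropout_p)
      M <- M * drop_mask
    }
    Hc <- Hc + M
    caches$attns[[i]] <- list(bn1 = b1$cache, att = at$cache, bn2 = b2$cache,
                              bn2_Y = b2$Y, pre1 = pre1, g1 = g1,
                              W1e = W1e, W2e = W2e, drop_mask = drop_mask)
  }
  fin <- nn_dense_forward(Hc, bb$final)
  caches$final <- fin$cache
  caches$pre_final <- fin$Y
  Emb <- gelu(fin$Y)
  list(Emb = Emb, caches = caches)
}

backbone_backward <- function(bb, dEmb, caches) {
  grads <- list()
  dPre <- dEmb * gelu_grad(caches$pre_final)
  fb <- nn_dense_backward(dPre, caches$final)
  grads[["final/W"]] <- fb$dW
  grads[["final/b"]] <- fb$db
  dHc <- fb$dX
  for (i in rev(seq_len(bb$n_attn))) {
    ab <- bb$attns[[i]]
    cc <- caches$attns[[i]]
    pfx <- paste0("attn", i)
    dM <- dHc
    if (!is.null(cc$drop_mask)) dM <- dM * cc$drop_mask
    dg1 <- dM %*% t(cc$W2e)
    dW2 <- crossprod(cc$g1, dM)
    db2 <- colSums(dM)
    dpre1 <- dg1 * gelu_grad(cc$pre1)
    dW1 <- crossprod(cc$bn2_Y, dpre1)
    db1 <- colSums(dpre1)
    dbn2Y <- dpre1 %*% t(cc$W1e)
    if (is.null(ab$mlp$lora1)) {
      grads[[paste0(pfx, "/mlp/W1")]] <- dW1
    } else {
      fg <- lora_factor_grads(list(lora = ab$mlp$lora1), dW1)
      grads[[paste0(pfx, "/mlp/lora1/A")]] <- fg$dA
      grads[[paste0(pfx, "/mlp/lora1/B")]] <- fg$dB
    }
    if (is.null(ab$mlp$lora2)) {
      grads[[paste0(pfx, "/mlp/W2")]] <- dW2
    } else {
      fg <- lora_factor_grads(list(lora = ab$mlp$lora2), dW2)
      grads[[paste0(pfx, "/mlp/lora2/A")]] <- fg$dA
      grads[[paste0(pfx, "/mlp/lora2/B")]] <- fg$dB
    }
    grads[[paste0(pfx, "/mlp/b1")]] <- db1
    grads[[paste0(pfx, "/mlp/b2")]] <- db2
    b2b <- nn_bn_backward(dbn2Y, cc$bn2)
    grads[[paste0(pfx, "/bn2/gamma")]] <- b2b$dgamma
    grads[[paste0(pfx, "/bn2/beta")]] <- b2b$dbeta
    dHc <- dHc + b2b$dX
    atb <- nn_attn_backward(dHc, ab$att, cc$att)
    if (is.null(ab$att$lora_q)) {
      grads[[paste0(pfx, "/att/Wq")]] <- atb$dWq
    } else {
      fg <- lora_factor_grads(list(lora = ab$att$lora_q), atb$dWq)
      grads[[paste0(pfx, "/att/lora_q/A")]] <- fg$dA
      grads[[paste0(pfx, "/att/lora_q/B")]] <- fg$dB
    }
    if (is.null(ab$att$lora_v)) {
      grads[[paste0(pfx, "/att/Wv")]] <- atb$dWv
    } else {
      fg <- lora_factor_grads(list(lora = ab$att$lora_v), atb$dWv)
      grads[[paste0(pfx, "/att/lora_v/A")]] <- fg$dA
      grads[[paste0(pfx, "/att/lora_v/B")]] <- fg$dB
    }
    grads[[paste0(pfx, "/att/Wk")]] <- atb$dWk
    grads[[paste0(pfx, "/att/Wo")]] <- atb$dWo
    b1b <- nn_bn_backward(atb$dX, cc$bn1)
    grads[[paste0(pfx, "/bn1/gamma")]] <- b1b$dgamma
    grads[[paste0(pfx, "/bn1/beta")]] <- b1b$dbeta
    dHc <- dHc + b1b$dX
  }
  cb <- bb$geometry$crop_bins
  dH <- matrix(0, caches$pre_crop_dim[1L], caches$pre_crop_dim[2L])
  dH[(cb + 1L):(cb + bb$geometry$output_bins), ] <- dHc
  for (i in rev(seq_len(bb$n_conv))) {
    bl <- bb$blocks[[i]]
    cc <- caches$blocks[[i]]
    pfx <- paste0("block", i)
    cvb <- nn_conv_backward(dH, bl$conv, cc$conv)
    if (is.null(bl$conv$lora)) {
      grads[[paste0(pfx, "/conv/W")]] <- cvb$dW
    } else {
      fg <- lora_factor_grads(bl$conv, cvb$dW)
      grads[[paste0(pfx, "/conv/lora/A")]] <- fg$dA
      grads[[paste0(pfx, "/conv/lora/B")]] <- fg$dB
    }
    grads[[paste0(pfx, "/conv/b")]] <- cvb$db
    dG <- cvb$dX * gelu_grad(cc$pre_gelu)
    bnb <- nn_bn_backward(dG, cc$bn)
    grads[[paste0(pfx, "/bn/gamma")]] <- bnb$dgamma
    grads[[paste0(pfx, "/bn/beta")]] <- bnb$dbeta
    dH <- dH + bnb$dX
  }
  st2b <- nn_conv_backward(dH, bb$stem2, caches$stem2)
  if (is.null(bb$stem2$lora)) {
    grads[["stem2/W"]] <- st2b$dW
  } else {
    fg <- lora_factor_grads(bb$stem2, st2b$dW)
    grads[["stem2/lora/A"]] <- fg$dA
    grads[["stem2/lora/B"]] <- fg$dB
  }
  grads[["stem2/b"]] <- st2b$db
  dSg <- st2b$dX * gelu_grad(caches$stem_pre_gelu)
  sbnb <- nn_bn_backward(dSg, caches$stem_bn)
  grads[["stem_bn/gamma"]] <- sbnb$dgamma
  grads[["stem_bn/beta"]] <- sbnb$dbeta
  stb <- nn_conv_backward(sbnb$dX, bb$stem, caches$stem)
  if (is.null(bb$stem$lora)) {
    grads[["stem/W"]] <- stb$dW
  } else {
    fg <- lora_factor_grads(bb$stem, stb$dW)
    grads[["stem/lora/A"]] <- fg$dA
    grads[["stem/lora/B"]] <- fg$dB
  }
  grads[["stem/b"]] <- stb$db
  list(grads = grads, dX = stb$dX)
}

#' Compute the sequence embedding for a one-hot window
#'
#' Runs the backbone in evaluation mode and returns the center-cropped
#' per-bin embedding (after the final trained GELU projection).
#'
#' @param backbone A backbone created by [make_mini_backbone()].
#' @param onehot A one-hot matrix from [one_hot()].
#' @return Matrix `(output_bins x embedding_width)` of class
#'   `sequence_embedding`, with `shift`/`rc` provenance attributes.
#' @export
embed_sequence <- function(backbone, onehot) {
  out <- backbone_forward(backbone, onehot, training = FALSE)
  emb <- out$Emb
  attr(emb, "shift") <- attr(onehot, "shift")
  attr(emb, "rc") <- attr(onehot, "rc")
  class(emb) <- c("sequence_embedding", "matrix", "array")
  emb
}

# --- parameter plumbing -----------------------------------------------------

# Resolve a flat parameter name ("block2/conv/W") to a value, or assign one.
bb_get <- function(bb, name) {
  toks <- strsplit(name, "/", fixed = TRUE)[[1]]
  node <- bb_root(bb, toks[1L])
  for (t in toks[-1L]) node <- node[[t]]
  node
}

bb_set <- function(bb, name, value) {
  toks <- strsplit(name, "/", fixed = TRUE)[[1]]
  root <- toks[1L]
  node <- bb_root(bb, root)
  node <- assign_path(node, toks[-1L], value)
  if (root == "stem") bb$stem <- node
  else if (root == "stem2") bb$stem2 <- node
  else if (root == "stem_bn") bb$stem_bn <- node
  else if (root == "final") bb$final <- node
  else if (grepl("^block", root)) bb$blocks[[as.integer(sub("block", "", root))]] <- node
  else if (grepl("^attn", root)) bb$attns[[as.integer(sub("attn", "", root))]] <- node
  else stop("unknown parameter root: ", root)
  invisible(bb)
}

bb_root <- function(bb, root) {
  if (root == "stem") return(bb$stem)
  if (root == "stem2") return(bb$stem2)
  if (root == "stem_bn") return(bb$stem_bn)
  if (root == "final") return(bb$final)
  if (grepl("^block", root)) return(bb$blocks[[as.integer(sub("block", "", root))]])
  if (grepl("^attn", root)) return(bb$attns[[as.integer(sub("attn", "", root))]])
  stop("unknown parameter root: ", root)
}

assign_path <- function(node, toks, value) {
  if (length(toks) == 0L) return(value)
  node[[toks[1L]]] <- assign_path(node[[toks[1L]]], toks[-1L], value)
  node
}

# Enumerate parameter names by role.
backbone_param_names <- function(bb, which = c("all", "base", "lora", "final", "norm")) {
  which <- match.arg(which)
  base <- c("stem/W", "stem/b", "stem2/W", "stem2/b")
  lora <- c(if (!is.null(bb$stem$lora)) c("stem/lora/A", "stem/lora/B"),
            if (!is.null(bb$stem2$lora)) c("stem2/lora/A", "stem2/lora/B"))
  norm <- c("stem_bn/gamma", "stem_bn/beta")
  for (i in seq_len(bb$n_conv)) {
    p <- paste0("block", i)
    base <- c(base, paste0(p, "/conv/W"), paste0(p, "/conv/b"))
    if (!is.null(bb$blocks[[i]]$conv$lora))
      lora <- c(lora, paste0(p, "/conv/lora/A"), paste0(p, "/conv/lora/B"))
    norm <- c(norm, paste0(p, "/bn/gamma"), paste0(p, "/bn/beta"))
  }
  for (i in seq_len(bb$n_attn)) {
    p <- paste0("attn", i)
    base <- c(base, paste0(p, "/att/Wq"), paste0(p, "/att/Wk"),
              paste0(p, "/att/Wv"), paste0(p, "/att/Wo"),
              paste0(p, "/mlp/W1"), paste0(p, "/mlp/b1"),
              paste0(p, "/mlp/W2"), paste0(p, "/mlp/b2"))
    ab <- bb$attns[[i]]
    if (!is.null(ab$att$lora_q)) lora <- c(lora, paste0(p, "/att/lora_q/A"), paste0(p, "/att/lora_q/B"))
    if (!is.null(ab$att$lora_v)) lora <- c(lora, paste0(p, "/att/lora_v/A"), paste0(p, "/att/lora_v/B"))
    if (!is.null(ab$mlp$lora1)) lora <- c(lora, paste0(p, "/mlp/lora1/A"), paste0(p, "/mlp/lora1/B"))
    if (!is.null(ab$mlp$lora2)) lora <- c(lora, paste0(p, "/mlp/lora2/A"), paste0(p, "/mlp/lora2/B"))
    norm <- c(norm, paste0(p, "/bn1/gamma"), paste0(p, "/bn1/beta"),
              paste0(p, "/bn2/gamma"), paste0(p, "/bn2/beta"))
  }
  fin <- c("final/W", "final/b")
  switch(which,
         all = c(base, fin, norm, lora),
         base = base, lora = lora, final = fin, norm = norm)
}

backbone_get_params <- function(bb, names) {
  out <- lapply(names, function(nm) bb_get(bb, nm))
  names(out) <- names
  out
}

backbone_set_params <- function(bb, params) {
  for (nm in names(params)) bb_set(bb, nm, params[[nm]])
  bb$version <- bb$version + 1L
  invisible(bb)
}

#' Count backbone parameters
#' @param bb A backbone.
#' @param which One of "all", "base", "lora", "final", "norm".
#' @return Total number of scalar parameters.
#' @export
backbone_n_params <- function(bb, which = "all") {
  sum(vapply(backbone_get_params(bb, backbone_param_names(bb, which)),
             length, integer(1)))
}

# --- LoRA -------------------------------------------------------------------

#' LoRA configuration
#'
#' @param rank Low-rank dimension r (default 8).
#' @param alpha Scaling numerator; the adapter contribution is scaled by
#'   `alpha / rank` (default: `rank`, i.e. unit scaling).
#' @param targets Layer kinds to adapt.
#' @return A `lora_config` list.
#' @export
lora_config <- function(rank = 8L, alpha = rank,
                        targets = c("convolution", "attention-query",
                                    "attention-value", "mlp-projection")) {
  structure(list(rank = as.integer(rank), alpha = alpha,
                 targets = match.arg(targets, several.ok = TRUE)),
            class = "lora_config")
}

new_lora <- function(W, rank, alpha) {
  if (rank > min(dim(W)))
    stop("LoRA rank ", rank, " exceeds layer dimension ", min(dim(W)))
  list(A = matrix(stats::rnorm(nrow(W) * rank, sd = 0.02), nrow(W), rank),
       B = matrix(0, rank, ncol(W)), rank = rank, alpha = alpha)
}

#' Inject LoRA adapters into a backbone
#'
#' Adds an additive low-rank term `(alpha/rank) * A %*% B` to every targeted
#' layer; `A` is initialized with small Gaussian noise and `B` with zeros, so
#' the adapted forward pass is initially identical to the base model.
#' Convolution kernels are treated as `(in_channels*kernel) x out_channels`
#' matrices for the factorization. The input backbone is left untouched.
#'
#' @param backbone A backbone.
#' @param config A [lora_config()].
#' @param seed Seed for adapter initialization.
#' @return A new adapted backbone.
#' @export
inject_lora <- function(backbone, config = lora_config(), seed = 1L) {
  set.seed(seed)
  bb <- backbone_clone(backbone)
  r <- config$rank; a <- config$alpha
  if ("convolution" %in% config$targets) {
    bb$stem$lora <- new_lora(bb$stem$W, r, a)
    bb$stem2$lora <- new_lora(bb$stem2$W, r, a)
    for (i in seq_len(bb$n_conv))
      bb$blocks[[i]]$conv$lora <- new_lora(bb$blocks[[i]]$conv$W, r, a)
  }
  for (i in seq_len(bb$n_attn)) {
    if ("attention-query" %in% config$targets)
      bb$attns[[i]]$att$lora_q <- new_lora(bb$attns[[i]]$att$Wq, r, a)
    if ("attention-value" %in% config$targets)
      bb$attns[[i]]$att$lora_v <- new_lora(bb$attns[[i]]$att$Wv, r, a)
    if ("mlp-projection" %in% config$targets) {
      bb$attns[[i]]$mlp$lora1 <- new_lora(bb$attns[[i]]$mlp$W1, r, a)
      bb$attns[[i]]$mlp$lora2 <- new_lora(bb$attns[[i]]$mlp$W2, r, a)
    }
  }
  bb$version <- bb$version + 1L
  bb
}

#' Merge LoRA adapters into the base weights
#'
#' Folds each adapter's `(alpha/rank) * A %*% B` term into its layer's weight
#' matrix and removes the adapter, so the merged model carries no extra
#' parameters and its forward pass matches the adapted model.
#'
#' @param backbone An adapted backbone.
#' @return A new plain backbone.
#' @export
merge_lora <- function(backbone) {
  if (!backbone_has_lora(backbone)) {
    warning("no LoRA adapters present; returning backbone unchanged")
    return(backbone)
  }
  bb <- backbone_clone(backbone)
  fold <- function(layer) {
    if (!is.null(layer$lora)) {
      layer$W <- conv_weight(layer)
      layer$lora <- NULL
    }
    layer
  }
  bb$stem <- fold(bb$stem)
  bb$stem2 <- fold(bb$stem2)
  for (i in seq_len(bb$n_conv)) bb$blocks[[i]]$conv <- fold(bb$blocks[[i]]$conv)
  for (i in seq_len(bb$n_attn)) {
    ab <- bb$attns[[i]]
    if (!is.null(ab$att$lora_q)) {
      ab$att$Wq <- ab$att$Wq + (ab$att$lora_q$alpha / ab$att$lora_q$rank) *
        (ab$att$lora_q$A %*% ab$att$lora_q$B)
      ab$att$lora_q <- NULL
    }
    if (!is.null(ab$att$lora_v)) {
      ab$att$Wv <- ab$att$Wv + (ab$att$lora_v$alpha / ab$att$lora_v$rank) *
        (ab$att$lora_v$A %*% ab$att$lora_v$B)
      ab$att$lora_v <- NULL
    }
    if (!is.null(ab$mlp$lora1)) {
      ab$mlp$W1 <- ab$mlp$W1 + (ab$mlp$lora1$alpha / ab$mlp$lora1$rank) *
        (ab$mlp$lora1$A %*% ab$mlp$lora1$B)
      ab$mlp$lora1 <- NULL
    }
    if (!is.null(ab$mlp$lora2)) {
      ab$mlp$W2 <- ab$mlp$W2 + (ab$mlp$lora2$alpha / ab$mlp$lora2$rank) *
        (ab$mlp$lora2$A %*% ab$mlp$lora2$B)
      ab$mlp$lora2 <- NULL
    }
    bb$attns[[i]] <- ab
  }
  bb$version <- bb$version + 1L
  bb
}
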