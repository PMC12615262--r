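# Inference-time aggregation and evaluation metrics: reverse-complement
# averaged prediction on the natural scale, count-level correlations,
# profile-level correlations against cells / pseudobulks / k-NN averages,
# and pseudotime smoothing.

#' Reverse-complement-averaged prediction on the natural scale
#'
#' Predicts on the input sequence and its reverse complement, reverse-flips
#' the latter (positions reversed; RNA strand channels swapped), averages the
#' two passes, and inverts the squashed-scale transform (ATAC values are
#' rescaled by `1/atac_scale`, 20 at defaults) to return natural-scale
#' profiles.
#'
#' @param model A [profile_model()].
#' @param seq DNA window of geometry `input_length`.
#' @param cell_embeddings Matrix `(n_cells x D)`.
#' @param rc_average Average the forward and reverse-complement passes
#'   (default TRUE). Models trained without reverse-complement augmentation
#'   (e.g. short desk-scale runs) should set FALSE: their reverse pass is
#'   untrained and averaging it in only adds noise.
#' @return List with natural-scale `rna` `(bins x 2 x n)` and `atac`
#'   `(bins x 1 x n)` arrays.
#' @export
predict_rc_averaged <- function(model, seq, cell_embeddings,
                                rc_average = TRUE) {
  fwd <- cached_predict(model, seq, cell_embeddings)
  if (rc_average) {
    rev <- cached_predict(model, seq, cell_embeddings, rc = TRUE)
    flip <- function(a, swap_strands) {
      a <- a[rev(seq_len(dim(a)[1L])), , , drop = FALSE]
      if (swap_strands) a <- a[, c(2L, 1L), , drop = FALSE]
      a
    }
    rna <- (fwd$rna + flip(rev$rna, TRUE)) / 2
    atac <- (fwd$atac + flip(rev$atac, FALSE)) / 2
  } else {
    rna <- fwd$rna
    atac <- fwd$atac
  }
  list(rna = array(unsquash_values(rna, model$transform, "RNA"), dim(rna)),
       atac = array(unsquash_values(atac, model$transform, "ATAC"), dim(atac)))
}

#' Across-gene correlation of predicted and observed counts
#'
#' Per cell type, the Pearson correlation over genes of `log2(x + 1)` between
#' predicted and observed pseudobulk counts. Cell types with zero variance in
#' either vector are skipped with a warning (`NA` returned).
#'
#' @param pred,obs Matrices `(cell types x genes)` of natural-scale counts.
#' @return Named numeric vector of per-cell-type correlations.
#' @export
across_gene_correlation <- function(pred, obs) {
  stopifnot(all(dim(pred) == dim(obs)))
  out <- rep(NA_real_, nrow(pred))
  names(out) <- rownames(pred)
  for (i in seq_len(nrow(pred))) {
    x <- log2(pred[i, ] + 1); y <- log2(obs[i, ] + 1)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("cell type ", i, " skipped: zero variance")
      next
    }
    out[i] <- stats::cor(x, y)
  }
  out
}

#' Deviation correlation (cell-type-specific expression)
#'
#' Double-centers the `log2(x + 1)` matrices (subtracting the mean across
#' genes, then the mean across cell types) and correlates all entries. Pure
#' additive gene + cell-type structure centers to all zeros; the correlation
#' is then undefined and `NaN` is returned with a warning.
#'
#' @param pred,obs Matrices `(cell types x genes)` of natural-scale counts.
#' @return Scalar Pearson correlation of the double-centered matrices.
#' @export
deviation_correlation <- function(pred, obs) {
  dc <- function(m) {
    m <- log2(m + 1)
    m <- sweep(m, 1L, rowMeans(m))   # mean across genes
    sweep(m, 2L, colMeans(m))        # mean across cell types
  }
  a <- dc(pred); b <- dc(obs)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("double-centered matrix has zero variance; correlation undefined")
    return(NaN)
  }
  stats::cor(as.vector(a), as.vector(b))
}

#' k-nearest-neighbor averaged profiles
#'
#' Euclidean k-NN on the cell-embedding matrix; each cell's smoothed profile
#' is the unweighted mean of its k neighbors' profiles (self excluded).
#'
#' @param profiles Matrix `(cells x positions)`.
#' @param embeddings Matrix `(cells x D)`.
#' @param k Number of neighbors (default 100, capped at n - 1).
#' @return Matrix `(cells x positions)` of neighbor-averaged profiles.
#' @export
knn_average_profiles <- function(profiles, embeddings, k = 100L) {
  n <- nrow(embeddings)
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(embeddings))
  out <- matrix(0, n, ncol(profiles))
  for (i in seq_len(n)) {
    nb <- order(d[i, -i])  # indices into the vector without i
    idx <- seq_len(n)[-i][nb[seq_len(k)]]
    out[i, ] <- colMeans(profiles[idx, , drop = FALSE])
  }
  rownames(out) <- rownames(profiles)
  out
}

#' Profile-level correlation on a logarithmic scale
#'
#' Row-wise Pearson correlation of `log(x * scale + 1)` between two profile
#' matrices (cells x positions); used to compare predictions against single
#' cells, pseudobulk or k-NN-averaged profiles.
#'
#' @param a,b Matrices `(cells x positions)`.
#' @param log_base Base of the logarithm (default natural).
#' @return Numeric vector of per-cell correlations (`NA` where a profile has
#'   zero variance).
#' @export
profile_correlation <- function(a, b, log_base = exp(1)) {
  stopifnot(all(dim(a) == dim(b)))
  la <- log1p(a) / log(log_base)
  lb <- log1p(b) / log(log_base)
  vapply(seq_len(nrow(a)), function(i) {
    x <- la[i, ]; y <- lb[i, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
}

#' Centered rolling mean along pseudotime
#'
#' Mean over a centered window of `window` cells; windows shrink at the
#' edges. `window = 1` is the identity.
#'
#' @param values Numeric vector ordered by pseudotime.
#' @param window Window size in cells (default 200).
#' @return Smoothed numeric vector of the same length.
#' @export
rolling_smooth <- function(values, window = 200L) {
  n <- length(values)
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window %/% 2L
  cs <- c(0, cumsum(values))
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Pseudobulk a cell-level count matrix
#' @param counts Matrix `(cells x genes)`.
#' @param labels Character vector of cell-type labels per cell.
#' @return Matrix `(cell types x genes)` of summed counts.
#' @export
pseudobulk_counts <- function(counts, labels) {
  rowsum(counts, labels)
}
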