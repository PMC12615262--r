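# Gene models: GTF in (1-based closed, converted to 0-based half-open
# internally), exon assembly, and exon/bin overlap helpers.

#' Read gene models from a GTF file
#'
#' Assembles per-gene exon structures from the exon features of a GTF.
#' Exons are merged (non-overlapping, sorted); the gene body spans the
#' outermost exon boundaries. Internal coordinates are 0-based half-open.
#'
#' @param path GTF file path.
#' @return A named list of class `gene_models`; each element has `gene_id`,
#'   `chrom`, `strand`, `start`, `end`, and `exons` (data.table with 0-based
#'   `start`, `end`).
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  ids <- as.character(ex$gene_id)
  out <- lapply(split(seq_along(ex), ids), function(i) {
    e <- ex[i]
    er <- IRanges::reduce(IRanges::ranges(e))
    data_exons <- data.table::data.table(start = IRanges::start(er) - 1L,
                                         end = IRanges::end(er))
    data.table::setorder(data_exons, start)
    list(gene_id = ids[i[1L]],
         chrom = as.character(GenomeInfoDb::seqnames(e))[1L],
         strand = as.character(BiocGenerics::strand(e))[1L],
         start = min(data_exons$start), end = max(data_exons$end),
         exons = data_exons)
  })
  class(out) <- "gene_models"
  out
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d gene(s) on %d contig(s)\n", length(x),
              length(unique(vapply(x, `[[`, "", "chrom")))))
  invisible(x)
}

# Gene body center, used to center prediction windows.
gene_center <- function(gene) (gene$start + gene$end) %/% 2L

# Genomic start of the output-bin window for a model window centered at
# `center`: the input window is centered there and the output covers the
# central output_bins bins.
output_window_start <- function(center, geometry) {
  win_start <- center - geometry$input_length %/% 2L
  win_start + geometry$crop_bins * geometry$bin_width
}

# 1-based indices of output bins overlapping any exon of `gene`, given the
# genomic start of the first output bin. A bin overlapping an exon by >= 1 bp
# is included fully. Exons outside the output window are flagged.
exon_bins <- function(gene, bins_start, geometry) {
  bw <- geometry$bin_width
  nb <- geometry$output_bins
  sel <- logical(nb)
  outside <- FALSE
  for (i in seq_len(nrow(gene$exons))) {
    s <- gene$exons$start[i]; e <- gene$exons$end[i]
    cs <- max(s, bins_start)
    ce <- min(e, bins_start + nb * bw)
    if (cs >= ce) { outside <- TRUE; next }
    if (s < bins_start || e > bins_start + nb * bw) outside <- TRUE
    b0 <- (cs - bins_start) %/% bw + 1L
    b1 <- (ce - 1L - bins_start) %/% bw + 1L
    sel[b0:b1] <- TRUE
  }
  structure(which(sel), truncated = outside)
}

#' Exon-summed gene counts from predicted profiles
#'
#' Sums the strand-matched RNA track over all output bins overlapping an exon
#' (a bin overlapping by >= 1 bp counts fully). Exons outside the output
#' window contribute nothing (a warning flags truncation).
#'
#' @param profiles Prediction list with `rna` array `(bins x 2 x cells)` on
#'   the natural scale.
#' @param gene A `gene_models` element.
#' @param bins_start Genomic position of the first output bin.
#' @param geometry The model geometry.
#' @return Numeric vector of per-cell counts.
#' @export
gene_counts <- function(profiles, gene, bins_start, geometry) {
  bins <- exon_bins(gene, bins_start, geometry)
  n <- dim(profiles$rna)[3L]
  if (length(bins) == 0L) {
    warning("gene ", gene$gene_id, " has no exon in the output window")
    return(rep(0, n))
  }
  if (isTRUE(attr(bins, "truncated")))
    warning("gene ", gene$gene_id, ": exon(s) extend beyond the output window")
  si <- if (gene$strand == "-") 2L else 1L
  colSums(matrix(profiles$rna[bins, si, ], length(bins), n))
}

#' Total predicted accessibility over the output window
#'
#' @param profiles Prediction list with `atac` array `(bins x 1 x cells)`.
#' @return Numeric vector of per-cell sums over all output bins.
#' @export
locus_accessibility <- function(profiles) {
  n <- dim(profiles$atac)[3L]
  colSums(matrix(profiles$atac[, 1L, ], dim(profiles$atac)[1L], n))
}

# Observed per-cell exon-summed RNA coverage for a gene, straight from the
# archive (per-base overlap of strand-matched segments with merged exons).
observed_gene_counts <- function(store, gene, cells = NULL) {
  if (is.null(cells)) cells <- seq_along(store$cells)
  seg <- store$rna[store$rna$chrom == gene$chrom &
                     store$rna$strand == gene$strand &
                     store$rna$cell %in% cells]
  out <- numeric(length(cells))
  names(out) <- store$cells[cells]
  if (!nrow(seg)) return(out)
  row_of <- integer(length(store$cells)); row_of[cells] <- seq_along(cells)
  for (i in seq_len(nrow(gene$exons))) {
    s <- gene$exons$start[i]; e <- gene$exons$end[i]
    ov <- pmin(seg$start + seg$len, e) - pmax(seg$start, s)
    pos <- ov > 0
    if (any(pos)) {
      agg <- rowsum(ov[pos], row_of[seg$cell[pos]])
      out[as.integer(rownames(agg))] <- out[as.integer(rownames(agg))] + agg[, 1L]
    }
  }
  out
}

#' Observed count matrix for a set of genes
#' @param store A `coverage_store`.
#' @param genes A `gene_models` list.
#' @param cells Cell indices (default all).
#' @return Matrix `(cells x genes)` of exon-summed coverage.
#' @export
observed_count_matrix <- function(store, genes, cells = NULL) {
  if (is.null(cells)) cells <- seq_along(store$cells)
  m <- vapply(genes, function(g) observed_gene_counts(store, g, cells),
              numeric(length(cells)))
  dimnames(m) <- list(store$cells[cells], vapply(genes, `[[`, "", "gene_id"))
  m
}
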