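# Interpretation: TF motif effect scoring by in silico motif replacement,
# per-gene target effects, eQTL variant effect prediction, negligible-effect
# filtering, and cell-type deconvolution ranking with baselines.

# Fetch the model input window centered at `center` on `chrom`, padding with
# N beyond contig ends. genome: named character vector of contig sequences.
fetch_window <- function(genome, chrom, center, input_length) {
  contig <- genome[[chrom]]
  if (is.null(contig)) stop("unknown chromosome: ", chrom)
  L <- nchar(contig)
  start <- center - input_length %/% 2L   # 0-based
  from <- max(start, 0L)
  to <- min(start + input_length, L)
  core <- substr(contig, from + 1L, to)
  paste0(strrep("N", from - start), core,
         strrep("N", start + input_length - to))
}

window_bins_start <- function(center, geometry) {
  output_window_start(center, geometry)
}

#' Score a TF motif by in silico replacement
#'
#' For each gene: the model input window is centered on the gene body, the
#' window is scanned for PWM hits (p <= `p_threshold`, both strands), all
#' hits are replaced with random sequence in each of `n_replicates`
#' alternative windows, and reference and alternative predictions are read
#' out per cell (exon-summed expression, or total window accessibility).
#' Replicate readouts are averaged. Each cell's readouts are divided by its
#' reference size factor (the cell's total reference readout over the window)
#' and scaled by the median reference size factor across cells. The per-cell
#' TF score is the mean over genes of `log2(alt / ref)`; genes without hits
#' contribute 0 and are flagged.
#'
#' @param model A `profile_model`.
#' @param genome Named character vector of contig sequences.
#' @param genes `gene_models` list of (typically differentially expressed)
#'   genes to score.
#' @param p A `pwm`.
#' @param cell_embeddings Matrix `(n_cells x D)`.
#' @param modality "expression" or "accessibility".
#' @param n_replicates Random replacements per window (default 10).
#' @param p_threshold Scan p-value cutoff (default 1e-4).
#' @param seed RNG seed for the replacements.
#' @return Numeric vector of per-cell scores with attribute `genes_without_hits`.
#' @export
tf_motif_effect <- function(model, genome, genes, p, cell_embeddings,
                            modality = c("expression", "accessibility"),
                            n_replicates = 10L, p_threshold = 1e-4, seed = 1L) {
  modality <- match.arg(modality)
  g <- model$backbone$geometry
  n <- nrow(cell_embeddings)
  per_gene <- matrix(0, n, length(genes))
  no_hits <- character()
  for (gi in seq_along(genes)) {
    gene <- genes[[gi]]
    center <- gene_center(gene)
    seq <- fetch_window(genome, gene$chrom, center, g$input_length)
    hits <- scan_pwm(seq, p, threshold = p_threshold)
    if (nrow(hits) == 0L) {
      no_hits <- c(no_hits, gene$gene_id)
      next
    }
    bins_start <- window_bins_start(center, g)
    readout <- function(s) {
      pred <- predict_rc_averaged(model, s, cell_embeddings)
      val <- if (modality == "expression")
        suppressWarnings(gene_counts(pred, gene, bins_start, g))
      else locus_accessibility(pred)
      size <- if (modality == "expression")
        colSums(matrix(pred$rna, prod(dim(pred$rna)[1:2]), n))
      else locus_accessibility(pred)
      list(val = val, size = size)
    }
    ref <- readout(seq)
    alts <- mutate_hits(seq, hits, n_replicates, seed = seed + gi)
    alt_val <- rowMeans(vapply(alts, function(s) readout(s)$val, numeric(n)))
    sf <- ref$size
    med <- stats::median(sf)
    ref_n <- ref$val / sf * med
    alt_n <- alt_val / sf * med
    per_gene[, gi] <- log2(alt_n / ref_n)
  }
  score <- rowMeans(per_gene)
  names(score) <- rownames(cell_embeddings)
  attr(score, "genes_without_hits") <- no_hits
  attr(score, "per_gene") <- per_gene
  score
}

#' Select target genes by motif effect size
#'
#' @param effects Named numeric vector (or single-column table) of per-gene
#'   effects.
#' @param threshold Absolute-effect cutoff (default 0.1; strictly exceeded).
#' @return data.table of retained genes with effect and sign
#'   ("up_on_mutation" / "down_on_mutation").
#' @export
target_gene_effects <- function(effects, threshold = 0.1) {
  dt <- data.table::data.table(gene = names(effects), effect = as.numeric(effects))
  dt <- dt[abs(dt$effect) > threshold]
  dt$direction <- ifelse(dt$effect > 0, "up_on_mutation", "down_on_mutation")
  dt[]
}

#' Read a variant table
#'
#' VCF-like TSV with columns chrom, pos (1-based), ref, alt, gene and any
#' optional extras (observed effect, PIP, fine-mapping flags, TSS distance).
#' Only single-nucleotide variants are retained.
#'
#' @param path TSV path.
#' @return data.table of variants.
#' @export
read_variants <- function(path) {
  v <- data.table::fread(path)
  v <- v[nchar(v$ref) == 1L & nchar(v$alt) == 1L]
  v[]
}

#' Predict the effect of a single-nucleotide variant
#'
#' Centers the input window on the variant, verifies the reference allele,
#' predicts reference and alternative profiles (reverse-complement averaged,
#' natural scale), and computes per-cell-group log2 fold changes with a
#' pseudocount of 1: expression from exon-summed counts of the target gene,
#' accessibility from the whole-window sum. The overall effect is the mean
#' over groups.
#'
#' @param model A `profile_model`.
#' @param genome Named character vector of contig sequences.
#' @param chrom,pos0 Variant position (0-based).
#' @param ref,alt Single-nucleotide alleles.
#' @param gene Target gene (`gene_models` element).
#' @param cell_embeddings Matrix `(n_cells x D)`.
#' @param groups Character vector of group labels per cell.
#' @return List with `expression` and `accessibility` named per-group effect
#'   vectors and `overall_expression` / `overall_accessibility` means.
#' @export
variant_effect <- function(model, genome, chrom, pos0, ref, alt, gene,
                           cell_embeddings, groups) {
  g <- model$backbone$geometry
  seq <- fetch_window(genome, chrom, pos0, g$input_length)
  center_idx <- g$input_length %/% 2L + 1L  # pos0 sits here (1-based in window)
  have <- substr(seq, center_idx, center_idx)
  if (have != toupper(ref))
    stop("reference allele mismatch at ", chrom, ":", pos0,
         " (genome has ", have, ", expected ", ref, ")")
  alt_seq <- seq
  substr(alt_seq, center_idx, center_idx) <- toupper(alt)
  pred_ref <- predict_rc_averaged(model, seq, cell_embeddings)
  pred_alt <- predict_rc_averaged(model, alt_seq, cell_embeddings)
  bins_start <- window_bins_start(pos0, g)
  expr_ref <- suppressWarnings(gene_counts(pred_ref, gene, bins_start, g))
  expr_alt <- suppressWarnings(gene_counts(pred_alt, gene, bins_start, g))
  acc_ref <- locus_accessibility(pred_ref)
  acc_alt <- locus_accessibility(pred_alt)
  lfc_by_group <- function(a, r) {
    sa <- rowsum(a, groups); sr <- rowsum(r, groups)
    out <- log2((sa[, 1L] + 1) / (sr[, 1L] + 1))
    names(out) <- rownames(sa)
    out
  }
  expression <- lfc_by_group(expr_alt, expr_ref)
  accessibility <- lfc_by_group(acc_alt, acc_ref)
  list(expression = expression, accessibility = accessibility,
       overall_expression = mean(expression),
       overall_accessibility = mean(accessibility))
}

#' Classify negligible predicted effects
#'
#' An effect is negligible iff `|log2 effect| < tau`. The attribute
#' `percent_fold_change` reports the equivalent percent fold change,
#' `(2^tau - 1) * 100` (3.5 percent at the default tau = 0.05).
#'
#' @param effects Numeric vector of log2 fold changes.
#' @param tau Threshold (default 0.05; the boundary is non-negligible).
#' @return Logical mask (TRUE = negligible).
#' @export
classify_negligible <- function(effects, tau = 0.05) {
  mask <- abs(effects) < tau
  attr(mask, "percent_fold_change") <- round((2^tau - 1) * 100, 1)
  mask
}

#' Rank cell types by predicted effect magnitude
#'
#' Descending by absolute effect, with a deterministic lexicographic
#' tie-break on the cell-type name.
#'
#' @param effects Named numeric vector of per-cell-type effects.
#' @return Character vector of cell types, strongest first.
#' @export
rank_cell_types <- function(effects) {
  names(effects)[order(-abs(effects), names(effects))]
}

#' Rank cell types by pseudobulk expression of the eGene
#' @param expression Named numeric vector of pseudobulk (size-factor
#'   normalized) expression per cell type.
#' @return Character vector of cell types, highest first.
#' @export
rank_by_expression <- function(expression) {
  names(expression)[order(-expression, names(expression))]
}

#' Rank cell types by accessibility of the peak at/nearest a variant
#'
#' @param peaks data.table with chrom, start, end and one accessibility
#'   column per cell type (size-factor normalized pseudobulk counts).
#' @param chrom,pos0 Variant position (0-based).
#' @param cell_types Names of the accessibility columns.
#' @return Character vector of cell types, most accessible first, or NULL
#'   (with a warning) when the variant's chromosome has no peak.
#' @export
rank_by_accessibility <- function(peaks, chrom, pos0, cell_types) {
  want <- chrom
  pk <- peaks[peaks$chrom == want]
  if (!nrow(pk)) {
    warning("no peak on chromosome ", chrom, "; variant skipped")
    return(NULL)
  }
  inside <- pk$start <= pos0 & pos0 < pk$end
  row <- if (any(inside)) which(inside)[1L] else
    which.min(pmax(pk$start - pos0, pos0 - pk$end + 1L, 0L))
  acc <- unlist(pk[row, cell_types, with = FALSE])
  names(acc)[order(-acc, names(acc))]
}

#' Precision at k of a ranking against a positive set
#' @param ranking Character vector, best first.
#' @param positives Character vector of true-positive labels.
#' @param k Depth.
#' @return Fraction of the top k that are positives.
#' @export
precision_at_k <- function(ranking, positives, k = 1L) {
  mean(ranking[seq_len(min(k, length(ranking)))] %in% positives)
}

#' Select eQTLs with strong, variable cell-type effects
#'
#' Two-stage filter: rows whose mean absolute effect exceeds
#' `mean_threshold`, then (within that set) rows in the top
#' `1 - var_quantile` of across-cell-type variance.
#'
#' @param effects Matrix `(variants x cell types)` of log2 effects.
#' @param mean_threshold Mean-magnitude cutoff (default 0.05).
#' @param var_quantile Variance quantile (default 0.85: top 15 percent kept).
#' @return Logical mask over rows.
#' @export
select_variable_eqtls <- function(effects, mean_threshold = 0.05,
                                  var_quantile = 0.85) {
  mean_pass <- rowMeans(abs(effects)) > mean_threshold
  keep <- rep(FALSE, nrow(effects))
  if (any(mean_pass)) {
    v <- apply(effects[mean_pass, , drop = FALSE], 1L, stats::var)
    cut <- stats::quantile(v, var_quantile)
    keep[which(mean_pass)[v > cut]] <- TRUE
  }
  keep
}

#' Sign concordance of predicted vs observed effects by TSS distance
#'
#' Per distance bin, the fraction of variants whose predicted effect has the
#' same sign as the observed effect, with and without removing negligible
#' predictions (|effect| < tau). Empty bins yield NaN with count 0.
#'
#' @param pred,obs Numeric vectors of effects.
#' @param tss_distance Numeric vector of distances to the TSS.
#' @param breaks Bin breaks for the distances.
#' @param tau Negligible-effect threshold.
#' @return data.table with per-bin concordance (all and filtered) and counts.
#' @export
sign_concordance_by_distance <- function(pred, obs, tss_distance, breaks,
                                         tau = 0.05) {
  bin <- cut(tss_distance, breaks, include.lowest = TRUE)
  keep <- !classify_negligible(pred, tau)
  conc <- sign(pred) == sign(obs)
  agg <- function(mask) {
    vapply(levels(bin), function(lv) {
      sel <- bin == lv & mask
      if (!any(sel)) return(NaN)
      mean(conc[sel])
    }, numeric(1))
  }
  data.table::data.table(
    bin = levels(bin),
    concordance_all = agg(rep(TRUE, length(pred))),
    n_all = as.integer(table(bin)),
    concordance_filtered = agg(keep),
    n_filtered = as.integer(table(bin[keep])))
}

#' Differentially expressed genes (helper)
#'
#' Routine Wilcoxon rank-sum test of each gene in one group against the rest
#' with Benjamini-Hochberg correction; pipelines may equally be given an
#' externally computed gene list.
#'
#' @param counts Matrix `(cells x genes)`.
#' @param labels Group labels per cell.
#' @param group Group to test against the rest.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return data.table of genes with p, adjusted p and log2 fold change,
#'   filtered to adjusted p <= alpha.
#' @export
de_genes <- function(counts, labels, group, alpha = 0.05) {
  in_g <- labels == group
  res <- lapply(colnames(counts), function(gn) {
    x <- counts[in_g, gn]; y <- counts[!in_g, gn]
    pv <- stats::wilcox.test(x, y, exact = FALSE)$p.value
    data.table::data.table(gene = gn, p = pv,
                           lfc = log2((mean(x) + 1) / (mean(y) + 1)))
  })
  dt <- data.table::rbindlist(res)
  dt$padj <- stats::p.adjust(dt$p, "BH")
  dt[dt$padj <= alpha][]
}
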