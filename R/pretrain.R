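# Backbone pretraining on pseudobulk tracks.
#
# Mirrors the transfer-learning recipe the single-cell stage assumes: the
# sequence encoder is first trained on dense aggregate coverage (per-group
# pseudobulk RNA strands and ATAC insertions, squashed scale) with a plain
# linear output head, then adapted to single cells with LoRA and the
# hypernetwork decoder. Pseudobulk targets are dense and low-noise, so the
# encoder learns sequence determinants (e.g. promoter motif content) far
# faster than from sparse single-cell tracks.

#' Pretrain a backbone on pseudobulk coverage tracks
#'
#' Trains all backbone weights plus a linear softplus head that predicts,
#' for every cell group, the group's pseudobulk RNA (two strands) and ATAC
#' (one) tracks, using the joint Poisson-multinomial loss on the squashed
#' scale with gene-centered training windows.
#'
#' @param backbone A plain (un-adapted) backbone; modified in place.
#' @param store A `coverage_store`.
#' @param labels Group label per store cell.
#' @param genome Named contig sequences.
#' @param split A `split_definition`.
#' @param genes `gene_models` used to center training windows.
#' @param transform Target transform.
#' @param epochs,steps_per_epoch,lr,batch_sequences Optimization scale.
#' @param pm_weight Poisson term weight.
#' @param gene_level_weight Weight of an auxiliary gene-level term: for every
#'   annotated gene inside the window, the squared difference of
#'   `log1p(exon-summed pred)` vs `log1p(exon-summed target)` per track.
#'   The positional (multinomial) part of the profile loss is insensitive to
#'   per-gene expression levels when a window holds few same-strand genes;
#'   this term keeps level information from being drowned out by profile
#'   shape during pretraining.
#' @param weight_decay Decoupled weight decay (default 1e-4: pretraining on
#'   a small gene set benefits from stronger shrinkage than fine-tuning).
#' @param grad_clip Gradient-norm clip.
#' @param seed RNG seed.
#' @return List: `backbone` (trained, same environment), `head` (E x tracks
#'   weights and bias), `log`.
#' @export
pretrain_backbone <- function(backbone, store, labels, genome, split, genes,
                              transform = target_transform(),
                              epochs = 10L, steps_per_epoch = 40L, lr = 4e-3,
                              batch_sequences = 4L, pm_weight = 0.2,
                              gene_level_weight = 2, weight_decay = 1e-4,
                              grad_clip = 1.0, seed = 1L) {
  set.seed(seed)
  geometry <- backbone$geometry
  groups <- sort(unique(labels))
  tracks_per_group <- 3L  # RNA +, RNA -, ATAC
  n_tracks <- length(groups) * tracks_per_group
  E <- geometry$embedding_width
  head <- list(W = matrix(stats::rnorm(E * n_tracks, sd = 0.01), E, n_tracks),
               b = rep(0, n_tracks))
  regions <- split$train
  train_genes <- genes[vapply(genes, function(g)
    any(regions$chrom == g$chrom & regions$start <= g$start &
          regions$end >= g$end), logical(1))]
  if (!length(train_genes)) stop("no training gene fits the training regions")
  group_cells <- lapply(groups, function(g) which(labels == g))
  bb_names <- c(backbone_param_names(backbone, "base"),
                backbone_param_names(backbone, "norm"),
                backbone_param_names(backbone, "final"))
  params <- c(backbone_get_params(backbone, bb_names),
              list(`head/W` = head$W, `head/b` = head$b))
  target_cache <- new.env(parent = emptyenv())
  opt <- adamw_init(params, weight_decay = weight_decay)
  total_steps <- epochs * steps_per_epoch
  log_rows <- list()
  step <- 0L
  for (epoch in seq_len(epochs)) {
    for (s in seq_len(steps_per_epoch)) {
      step <- step + 1L
      acc <- list()
      loss_sum <- 0
      for (b in seq_len(batch_sequences)) {
        gi_sel <- sample.int(length(train_genes), 1L)
        gene <- train_genes[[gi_sel]]
        chrom <- gene$chrom
        start <- gene_center(gene) - geometry$input_length %/% 2L
        lim <- regions[regions$chrom == chrom][1L]
        start <- min(max(start, lim$start), lim$end - geometry$input_length)
        out_start <- start + geometry$crop_bins * geometry$bin_width
        out_end <- out_start + geometry$output_bins * geometry$bin_width
        key <- paste0(chrom, ":", start)
        cached <- target_cache[[key]]
        if (is.null(cached)) {
          seqw <- substr(genome[[chrom]], start + 1L, start + geometry$input_length)
          target <- matrix(0, geometry$output_bins, n_tracks)
          for (gi in seq_along(groups)) {
            tr <- extract_binned(store, chrom, out_start, out_end, "RNA",
                                 group_cells[[gi]], geometry$bin_width)
            ta <- extract_binned(store, chrom, out_start, out_end, "ATAC",
                                 group_cells[[gi]], geometry$bin_width)
            rna_pb <- apply(tr$values, c(2L, 3L), sum)   # strands x bins
            atac_pb <- apply(ta$values, c(2L, 3L), sum)
            base <- (gi - 1L) * tracks_per_group
            target[, base + 1L] <- squash_values(rna_pb[1L, ], transform, "RNA")
            target[, base + 2L] <- squash_values(rna_pb[2L, ], transform, "RNA")
            target[, base + 3L] <- squash_values(atac_pb[1L, ], transform, "ATAC")
          }
          target_cache[[key]] <- list(seqw = seqw, target = target)
        } else {
          seqw <- cached$seqw
          target <- cached$target
        }
        X <- one_hot(seqw)
        fwd <- backbone_forward(backbone, X, training = TRUE)
        pre <- sweep(fwd$Emb %*% params$`head/W`, 2L, params$`head/b`, `+`)
        out <- softplus(pre)
        l <- poisson_multinomial_loss(array(out, c(nrow(out), 1L, n_tracks)),
                                      array(target, c(nrow(target), 1L, n_tracks)),
                                      pm_weight)
        dOut <- matrix(attr(l, "grad"), nrow(out), n_tracks)
        loss_b <- as.numeric(l)
        if (gene_level_weight > 0) {
          win_genes <- Filter(function(gg) gg$chrom == chrom &&
                                gg$start >= out_start && gg$end <= out_end,
                              genes)
          for (gg in win_genes) {
            bins <- exon_bins(gg, out_start, geometry)
            if (!length(bins)) next
            si <- if (gg$strand == "-") 2L else 1L
            cols <- (seq_along(groups) - 1L) * tracks_per_group + si
            for (tc in cols) {
              P <- sum(out[bins, tc]); Tt <- sum(target[bins, tc])
              diff <- log1p(P) - log1p(Tt)
              loss_b <- loss_b + gene_level_weight * diff^2
              dOut[bins, tc] <- dOut[bins, tc] +
                gene_level_weight * 2 * diff / (1 + P)
            }
          }
        }
        loss_sum <- loss_sum + loss_b
        dPre <- dOut * softplus_grad(pre)
        g_head_W <- crossprod(fwd$Emb, dPre)
        g_head_b <- colSums(dPre)
        dEmb <- dPre %*% t(params$`head/W`)
        bgr <- backbone_backward(backbone, dEmb, fwd$caches)$grads
        bgr$`head/W` <- g_head_W
        bgr$`head/b` <- g_head_b
        acc <- acc_grads(acc, bgr)
      }
      loss <- loss_sum / batch_sequences
      if (!is.finite(loss)) stop("pretraining diverged at step ", step)
      grads <- lapply(acc[names(params)[names(params) %in% names(acc)]],
                      function(g) g / batch_sequences)
      grads <- clip_grad_norm(grads, grad_clip)
      fac <- lr_schedule(step, max(20L, total_steps %/% 20L), total_steps)
      lr_by <- as.list(stats::setNames(rep(lr * fac, length(params)),
                                       names(params)))
      upd <- adamw_step(opt, params, grads, lr_by)
      opt <- upd$state
      params <- upd$params
      backbone_set_params(backbone, params[bb_names])
      log_rows[[length(log_rows) + 1L]] <-
        data.table::data.table(epoch = epoch, step = step, loss = loss)
    }
  }
  head$W <- params$`head/W`
  head$b <- params$`head/b`
  list(backbone = backbone, head = head,
       log = data.table::rbindlist(log_rows))
}
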