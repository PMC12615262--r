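# Training engine: joint Poisson-multinomial loss on squashed-scale targets,
# augmented batch sampling (window jitter, reverse complement with
# strand-flipped targets, random cell subsets), AdamW with two learning-rate
# groups, linear warmup then linear decay, gradient clipping, and
# checkpoint selection by the validation count correlation.

#' Training configuration
#'
#' Defaults follow the full-scale recipe: AdamW with learning rate 4e-4 for
#' the cell-state decoder (hypernetworks) and 2e-4 for the LoRA adapters and
#' the final trained projection, 1,000 warmup steps then linear decay over
#' the remaining steps, gradient clipping at 1.0, weight decay 1e-6, batches
#' of 8 sequences with 64 randomly sampled cells each, sequence shifts up to
#' 3 bp and reverse-complementation with probability 0.5. `pm_weight` is the
#' Poisson (total-count) term weight relative to the multinomial term.
#'
#' @param batch_sequences Sequences per optimization step.
#' @param cells_per_sequence Cells sampled (without replacement) per sequence.
#' @param lr_decoder,lr_adapters Learning rates for the two parameter groups.
#' @param warmup_steps Linear warmup length.
#' @param epochs Training epochs (decay reaches 0 at the end).
#' @param steps_per_epoch Optimization steps per epoch.
#' @param grad_clip Global gradient-norm clip.
#' @param weight_decay Decoupled weight decay.
#' @param shift_range Maximum sequence shift in bp.
#' @param rc_prob Reverse-complement probability.
#' @param pm_weight Poisson term weight (default 0.2).
#' @param seed RNG seed.
#' @return A `training_config` list.
#' @export
training_config <- function(batch_sequences = 8L, cells_per_sequence = 64L,
                            lr_decoder = 4e-4, lr_adapters = 2e-4,
                            warmup_steps = 1000L, epochs = 40L,
                            steps_per_epoch = 16L, grad_clip = 1.0,
                            weight_decay = 1e-6, shift_range = 3L,
                            rc_prob = 0.5, pm_weight = 0.2, seed = 1L) {
  structure(list(batch_sequences = as.integer(batch_sequences),
                 cells_per_sequence = as.integer(cells_per_sequence),
                 lr_decoder = lr_decoder, lr_adapters = lr_adapters,
                 warmup_steps = as.integer(warmup_steps),
                 epochs = as.integer(epochs),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 grad_clip = grad_clip, weight_decay = weight_decay,
                 shift_range = as.integer(shift_range), rc_prob = rc_prob,
                 pm_weight = pm_weight, seed = as.integer(seed)),
            class = "training_config")
}

#' Genomic split definition
#'
#' Pairwise-disjoint train/validation/test region sets (data.tables with
#' chrom, start, end; 0-based half-open).
#' @param train,validation,test Region tables.
#' @return A `split_definition`.
#' @export
split_definition <- function(train, validation, test) {
  regions <- list(train = data.table::as.data.table(train),
                  validation = data.table::as.data.table(validation),
                  test = data.table::as.data.table(test))
  combos <- utils::combn(names(regions), 2L)
  for (i in seq_len(ncol(combos))) {
    a <- regions[[combos[1L, i]]]; b <- regions[[combos[2L, i]]]
    for (ra in seq_len(nrow(a))) {
      ov <- b$chrom == a$chrom[ra] & b$start < a$end[ra] & b$end > a$start[ra]
      if (any(ov)) stop("split regions overlap: ", combos[1L, i], " and ",
                        combos[2L, i])
    }
  }
  structure(regions, class = "split_definition")
}

# Contig-level split helper: assign whole contigs to the three sets.
split_by_contig <- function(seqlengths, train, validation, test) {
  reg <- function(chroms) data.table::data.table(
    chrom = chroms, start = 0L, end = as.integer(seqlengths[chroms]))
  split_definition(reg(train), reg(validation), reg(test))
}

#' Joint Poisson-multinomial loss
#'
#' Per track (one strand of one cell and assay): the multinomial negative
#' log-likelihood of the positional distribution (target counts against
#' pred / sum(pred)) plus `pm_weight` times the Poisson negative
#' log-likelihood of the totals, both divided by the number of bins; the
#' result is averaged over tracks.
#'
#' @param pred,target Arrays `(bins x strands x cells)`; pred must be
#'   strictly positive.
#' @param pm_weight Poisson term weight (default 0.2).
#' @return Scalar loss with attribute `grad` (d loss / d pred).
#' @export
poisson_multinomial_loss <- function(pred, target, pm_weight = 0.2) {
  if (!all(dim(pred) == dim(target))) stop("shape mismatch")
  if (any(pred <= 0)) stop("predictions must be strictly positive")
  B <- dim(pred)[1L]
  n_tracks <- prod(dim(pred)[-1L])
  P <- matrix(pred, B, n_tracks)
  Tg <- matrix(target, B, n_tracks)
  Sp <- colSums(P)
  St <- colSums(Tg)
  mult <- -colSums(Tg * log(P)) + St * log(Sp)
  pois <- Sp - St * log(Sp)
  loss <- mean((mult + pm_weight * pois) / B)
  dP <- (-Tg / P + rep(St / Sp, each = B) +
           pm_weight * (1 - rep(St / Sp, each = B))) / (B * n_tracks)
  structure(loss, grad = array(dP, dim(pred)))
}

# Learning-rate schedule: linear warmup to 1 then linear decay to 0.
lr_schedule <- function(step, warmup, total) {
  if (step <= warmup) return(step / warmup)
  if (total <= warmup) return(1)
  max(0, (total - step) / (total - warmup))
}

#' Sample one training batch
#'
#' Draws `batch_sequences` windows uniformly from the training regions
#' (contigs weighted by length; windows fully inside a region), applies a
#' uniform shift in `[-shift_range, shift_range]` and reverse-complementation
#' with probability `rc_prob`, samples `cells_per_sequence` cells without
#' replacement, and extracts squashed-scale targets on the fly. For
#' reverse-complemented sequences the targets are reversed along position
#' and the RNA strand channels swapped.
#'
#' @param store A `coverage_store`.
#' @param genome Named character vector of contig sequences.
#' @param split A `split_definition`.
#' @param geometry The model geometry.
#' @param config A `training_config`.
#' @param transform The target transform.
#' @param genes Optional `gene_models`: when given, a fraction
#'   `gene_window_prob` of windows is centered on a random training gene
#'   (with +/- 1,024 bp jitter) instead of drawn uniformly, which
#'   concentrates optimization on gene loci at desk scale.
#' @param gene_window_prob Probability of a gene-centered window.
#' @param gene_jitter Maximum jitter (bp) applied to gene-centered windows.
#' @return List of per-sequence items: `seq`, `shift`, `rc`, `cells`,
#'   `target_rna`, `target_atac`.
#' @export
sample_training_batch <- function(store, genome, split, geometry, config,
                                  transform = target_transform(),
                                  genes = NULL, gene_window_prob = 0.8,
                                  gene_jitter = 1024L) {
  regions <- split$train
  w <- pmax(regions$end - regions$start - geometry$input_length, 0L)
  if (all(w == 0L)) stop("no training region can hold an input window")
  train_genes <- NULL
  if (!is.null(genes)) {
    in_train <- vapply(genes, function(g) {
      any(regions$chrom == g$chrom & regions$start <= g$start &
            regions$end >= g$end)
    }, logical(1))
    train_genes <- genes[in_train]
  }
  lapply(seq_len(config$batch_sequences), function(i) {
    start <- -1L
    if (!is.null(train_genes) && length(train_genes) &&
        stats::runif(1) < gene_window_prob) {
      gene <- train_genes[[sample.int(length(train_genes), 1L)]]
      chrom <- gene$chrom
      start <- gene_center(gene) - geometry$input_length %/% 2L +
        (if (gene_jitter > 0L) sample(-gene_jitter:gene_jitter, 1L) else 0L)
      lim <- regions[regions$chrom == chrom][1L]
      start <- min(max(start, lim$start), lim$end - geometry$input_length)
    }
    if (start < 0L) {
      ri <- sample.int(nrow(regions), 1L, prob = w)
      start <- regions$start[ri] + sample.int(w[ri] + 1L, 1L) - 1L
      chrom <- regions$chrom[ri]
    }
    seq <- substr(genome[[chrom]], start + 1L, start + geometry$input_length)
    shift <- sample(seq(-config$shift_range, config$shift_range), 1L)
    rc <- stats::runif(1) < config$rc_prob
    cells <- sample.int(length(store$cells), config$cells_per_sequence)
    out_start <- start + geometry$crop_bins * geometry$bin_width
    out_end <- out_start + geometry$output_bins * geometry$bin_width
    tr <- extract_binned(store, chrom, out_start, out_end, "RNA", cells,
                         geometry$bin_width)
    ta <- extract_binned(store, chrom, out_start, out_end, "ATAC", cells,
                         geometry$bin_width)
    # (cells x strands x bins) -> (bins x strands x cells)
    target_rna <- aperm(apply_transform(tr, transform)$values, c(3L, 2L, 1L))
    target_atac <- aperm(apply_transform(ta, transform)$values, c(3L, 2L, 1L))
    if (rc) {
      target_rna <- target_rna[rev(seq_len(dim(target_rna)[1L])), c(2L, 1L), ,
                               drop = FALSE]
      target_atac <- target_atac[rev(seq_len(dim(target_atac)[1L])), , ,
                                 drop = FALSE]
    }
    list(chrom = chrom, start = start, seq = seq, shift = shift, rc = rc,
         cells = cells, target_rna = target_rna, target_atac = target_atac)
  })
}

# One forward/backward pass over a batch item; returns loss and flat grads.
train_step_item <- function(model, item, embeddings, pm_weight) {
  bb <- model$backbone
  X <- one_hot(item$seq, item$shift, item$rc)
  fwd <- backbone_forward(bb, X, training = TRUE)
  ce <- embeddings[item$cells, , drop = FALSE]
  hr <- hypernet_forward(model$hypernet_rna, ce)
  ha <- hypernet_forward(model$hypernet_atac, ce)
  E <- bb$geometry$embedding_width
  pr <- array(t(hr$out), c(E + 1L, 2L, nrow(ce)))
  pa <- array(t(ha$out), c(E + 1L, 1L, nrow(ce)))
  dr <- decode_forward(fwd$Emb, pr)
  da <- decode_forward(fwd$Emb, pa)
  lr_ <- poisson_multinomial_loss(dr$out, item$target_rna, pm_weight)
  la_ <- poisson_multinomial_loss(da$out, item$target_atac, pm_weight)
  loss <- (as.numeric(lr_) + as.numeric(la_)) / 2
  br <- decode_backward(attr(lr_, "grad") / 2, dr$cache)
  ba <- decode_backward(attr(la_, "grad") / 2, da$cache)
  dEmb <- br$dEmb + ba$dEmb
  hgr <- hypernet_backward(model$hypernet_rna, params_to_flat(br$dparams), hr$cache)
  hga <- hypernet_backward(model$hypernet_atac, params_to_flat(ba$dparams), ha$cache)
  bbb <- backbone_backward(bb, dEmb, fwd$caches)
  grads <- bbb$grads
  grads[["hn_rna/W1"]] <- hgr$dW1; grads[["hn_rna/b1"]] <- hgr$db1
  grads[["hn_rna/W2"]] <- hgr$dW2; grads[["hn_rna/b2"]] <- hgr$db2
  grads[["hn_atac/W1"]] <- hga$dW1; grads[["hn_atac/b1"]] <- hga$db1
  grads[["hn_atac/W2"]] <- hga$dW2; grads[["hn_atac/b2"]] <- hga$db2
  list(loss = loss, grads = grads)
}

#' Train a profile model
#'
#' Only the LoRA adapters, the final trained projection and the
#' hypernetworks receive gradients; base backbone weights stay frozen.
#' Normalization layers are frozen and dropout disabled for the first step,
#' then unfrozen. The checkpoint with the best validation metric (mean
#' across cell types of the across-gene log-count correlation) is restored
#' at the end.
#'
#' @param model A `profile_model` (typically with LoRA injected).
#' @param store A `coverage_store`.
#' @param embeddings Cell-embedding matrix `(n_cells x D)`, rows aligned
#'   with `store$cells`.
#' @param genome Named character vector of contig sequences.
#' @param split A `split_definition`.
#' @param genes_val `gene_models` on validation regions (for the metric);
#'   NULL skips validation (last checkpoint kept).
#' @param labels Cell-type labels per cell (for the metric).
#' @param config A `training_config`.
#' @param genes_train Optional `gene_models` used to bias window sampling
#'   toward gene loci (see [sample_training_batch()]).
#' @param gene_window_prob,gene_jitter Gene-centered sampling controls,
#'   forwarded to [sample_training_batch()].
#' @param include_base Also train the base backbone weights. The default
#'   (FALSE) matches the transfer-learning recipe, which assumes a pretrained
#'   backbone; a mini backbone trained from scratch has no pretraining, so
#'   desk-scale runs typically set TRUE.
#' @param verbose Print per-epoch progress.
#' @return List: `model` (best weights), `log` (data.table of step losses
#'   and epoch metrics).
#' @export
train <- function(model, store, embeddings, genome, split, genes_val = NULL,
                  labels = NULL, config = training_config(),
                  include_base = FALSE, genes_train = NULL,
                  gene_window_prob = 0.8, gene_jitter = 1024L,
                  verbose = FALSE) {
  set.seed(config$seed)
  trainable <- model_trainable_names(model)
  if (include_base)
    trainable <- unique(c(trainable, backbone_param_names(model$backbone, "base"),
                          backbone_param_names(model$backbone, "norm")))
  params <- model_get_params(model, trainable)
  opt <- adamw_init(params, weight_decay = config$weight_decay)
  lr_group <- ifelse(grepl("^hn_", trainable), "decoder", "adapters")
  total_steps <- config$epochs * config$steps_per_epoch
  log_rows <- list()
  best_metric <- -Inf
  best_params <- params
  step <- 0L
  freeze_norm(model$backbone)
  for (epoch in seq_len(config$epochs)) {
    epoch_loss <- 0
    for (s in seq_len(config$steps_per_epoch)) {
      step <- step + 1L
      batch <- sample_training_batch(store, genome, split,
                                     model$backbone$geometry, config,
                                     model$transform, genes = genes_train,
                                     gene_window_prob = gene_window_prob,
                                     gene_jitter = gene_jitter)
      acc <- list()
      loss_sum <- 0
      for (item in batch) {
        res <- train_step_item(model, item, embeddings, config$pm_weight)
        loss_sum <- loss_sum + res$loss
        acc <- acc_grads(acc, res$grads)
      }
      loss <- loss_sum / length(batch)
      if (!is.finite(loss)) {
        dump <- tempfile("diverged_", fileext = ".rds")
        save_checkpoint(model, dump)
        stop("training diverged (non-finite loss) at step ", step,
             "; state dumped to ", dump)
      }
      grads <- lapply(acc, function(g) g / length(batch))
      grads <- grads[trainable[trainable %in% names(grads)]]
      grads <- clip_grad_norm(grads, config$grad_clip)
      fac <- lr_schedule(step, config$warmup_steps, total_steps)
      lr_by <- stats::setNames(
        ifelse(lr_group == "decoder", config$lr_decoder, config$lr_adapters) * fac,
        trainable)
      upd <- adamw_step(opt, params, grads, as.list(lr_by))
      opt <- upd$state
      params <- upd$params
      model_set_params(model, params)
      if (step == 1L) unfreeze_norm(model$backbone)
      epoch_loss <- epoch_loss + loss
      log_rows[[length(log_rows) + 1L]] <- data.table::data.table(
        epoch = epoch, step = step, loss = loss, lr_factor = fac,
        grad_norm = attr(grads, "norm"))
    }
    metric <- NA_real_
    if (!is.null(genes_val) && length(genes_val)) {
      # validate consistently with the augmentation regime: models never
      # trained on reverse-complemented inputs are validated forward-only
      metric <- validation_metric(model, store, embeddings, genome,
                                  genes_val, labels,
                                  rc_average = config$rc_prob > 0)
      if (is.finite(metric) && metric > best_metric) {
        best_metric <- metric
        best_params <- params
      }
    }
    log_rows[[length(log_rows)]]$val_metric <- metric
    if (verbose)
      message(sprintf("epoch %d: loss %.4f, val %.3f", epoch,
                      epoch_loss / config$steps_per_epoch, metric))
  }
  if (is.finite(best_metric)) model_set_params(model, best_params)
  list(model = model, log = data.table::rbindlist(log_rows, fill = TRUE),
       best_metric = best_metric)
}

#' Validation metric: pseudobulk count correlation
#'
#' For each cell type, the Pearson correlation over validation genes of
#' `log2(pseudobulk predicted counts + 1)` against
#' `log2(pseudobulk observed counts + 1)`; the mean across cell types is
#' returned. Cell types with zero variance are skipped with a warning.
#'
#' @param model A `profile_model`.
#' @param store A `coverage_store`.
#' @param embeddings Cell embeddings, rows aligned with store cells.
#' @param genome Named contig sequences.
#' @param genes `gene_models` on the validation regions.
#' @param labels Cell-type labels per cell.
#' @param rc_average Average forward and reverse-complement passes.
#' @return Mean across-cell-type correlation.
#' @export
validation_metric <- function(model, store, embeddings, genome, genes, labels,
                              rc_average = TRUE) {
  counts <- predicted_count_matrix(model, genome, genes, embeddings,
                                   rc_average)
  obs <- observed_count_matrix(store, genes)
  pred_pb <- pseudobulk_counts(counts, labels)
  obs_pb <- pseudobulk_counts(obs, labels)
  per_type <- across_gene_correlation(pred_pb, obs_pb)
  mean(per_type, na.rm = TRUE)
}

#' Predicted count matrix over a set of genes
#'
#' Centers the input window on each gene body, predicts RC-averaged
#' natural-scale profiles for all cells and sums the strand-matched RNA
#' track over exon-overlapping bins.
#'
#' @param model A `profile_model`.
#' @param genome Named contig sequences.
#' @param genes `gene_models`.
#' @param embeddings Cell-embedding matrix.
#' @param rc_average Average forward and reverse-complement passes (see
#'   [predict_rc_averaged()]).
#' @return Matrix `(cells x genes)`.
#' @export
predicted_count_matrix <- function(model, genome, genes, embeddings,
                                   rc_average = TRUE) {
  g <- model$backbone$geometry
  m <- vapply(genes, function(gene) {
    center <- gene_center(gene)
    seq <- fetch_window(genome, gene$chrom, center, g$input_length)
    pred <- predict_rc_averaged(model, seq, embeddings, rc_average)
    suppressWarnings(gene_counts(pred, gene, output_window_start(center, g), g))
  }, numeric(nrow(embeddings)))
  dimnames(m) <- list(rownames(embeddings), vapply(genes, `[[`, "", "gene_id"))
  m
}
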