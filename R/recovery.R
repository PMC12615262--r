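# End-to-end desk-scale study: fit the two-stage model on a synthetic
# multiome and evaluate recovery of the planted regulatory truth.

#' Fit the two-stage mini model on a synthetic fixture
#'
#' Stage 1 pretrains the mini backbone on pseudobulk tracks
#' ([pretrain_backbone()]); stage 2 injects LoRA adapters and fits the
#' hypernetwork decoder on single cells ([train()]). Contigs are split by
#' index: the last two become validation and test, the rest train.
#'
#' @param fx A fixture from [simulate_multiome()].
#' @param seed Seed controlling all model randomness.
#' @param channels,e_width,stem_channels,input_length Mini model size.
#' @param pretrain_epochs,pretrain_steps Stage-1 schedule (40 windows/step
#'   batch of 4 at lr 6e-3).
#' @param finetune_epochs,finetune_steps Stage-2 schedule.
#' @return List: `model`, `split`, `genes_train`, `genes_val`, `genes_test`,
#'   `best_val`, `pretrain_log`, `train_log`.
#' @export
fit_synthetic_model <- function(fx, seed = 1L, channels = 32L, e_width = 32L,
                                stem_channels = 64L, input_length = 16384L,
                                pretrain_epochs = 25L, pretrain_steps = 40L,
                                finetune_epochs = 8L, finetune_steps = 40L) {
  contigs <- names(fx$store$seqlengths)
  ncon <- length(contigs)
  tr_contigs <- contigs[seq_len(ncon - 2L)]
  split <- split_by_contig(fx$store$seqlengths, tr_contigs,
                           contigs[ncon - 1L], contigs[ncon])
  sel <- function(ch) {
    out <- fx$genes[vapply(fx$genes, function(x) x$chrom %in% ch, logical(1))]
    class(out) <- "gene_models"
    out
  }
  genes_train <- sel(tr_contigs)
  genes_val <- sel(contigs[ncon - 1L])
  genes_test <- sel(contigs[ncon])
  g <- model_geometry(input_length = input_length, bin_width = 32L,
                      embedding_width = e_width)
  bb <- make_mini_backbone(g, channels = channels, n_conv = 4L, n_attn = 1L,
                           stem_channels = stem_channels, seed = seed + 5L)
  pt <- pretrain_backbone(bb, fx$store, fx$population$labels,
                          fx$genome$sequences, split, genes_train,
                          epochs = pretrain_epochs,
                          steps_per_epoch = pretrain_steps,
                          lr = 6e-3, gene_level_weight = 2, seed = seed + 6L)
  ad <- inject_lora(bb, lora_config(rank = 8L), seed = seed + 7L)
  m <- profile_model(ad, d_embedding = ncol(fx$population$embeddings),
                     hidden = 32L, cache_size = 4L, seed = seed + 8L)
  # warm-start the hypernetwork by distilling the pretrained pseudobulk head
  # into it: each cell's target decoder is its group's head column scaled to
  # one cell, so fine-tuning starts from the full stage-1 solution including
  # group specificity
  groups <- sort(unique(fx$population$labels))
  gi_of <- match(fx$population$labels, groups)
  n_of <- as.vector(table(fx$population$labels))[gi_of]
  E <- g$embedding_width
  col_of <- function(gi, s) (gi - 1L) * 3L + s
  tgt_rna <- t(vapply(seq_along(gi_of), function(i) {
    c(pt$head$W[, col_of(gi_of[i], 1L)], pt$head$b[col_of(gi_of[i], 1L)],
      pt$head$W[, col_of(gi_of[i], 2L)], pt$head$b[col_of(gi_of[i], 2L)]) / n_of[i]^0.75
  }, numeric(2L * (E + 1L))))
  tgt_atac <- t(vapply(seq_along(gi_of), function(i) {
    c(pt$head$W[, col_of(gi_of[i], 3L)], pt$head$b[col_of(gi_of[i], 3L)]) / n_of[i]^0.75
  }, numeric(E + 1L)))
  m$hypernet_rna <- distill_hypernet(m$hypernet_rna,
                                     fx$population$embeddings, tgt_rna)
  m$hypernet_atac <- distill_hypernet(m$hypernet_atac,
                                      fx$population$embeddings, tgt_atac)
  cfg <- training_config(batch_sequences = 4L, cells_per_sequence = 32L,
                         warmup_steps = 50L, lr_decoder = 4e-3,
                         lr_adapters = 1e-3, epochs = finetune_epochs,
                         steps_per_epoch = finetune_steps,
                         shift_range = 0L, rc_prob = 0, seed = seed + 9L)
  res <- train(m, fx$store, fx$population$embeddings, fx$genome$sequences,
               split, genes_val = genes_val, labels = fx$population$labels,
               config = cfg, genes_train = genes_train,
               gene_window_prob = 1, gene_jitter = 0L)
  list(model = res$model, split = split, genes_train = genes_train,
       genes_val = genes_val, genes_test = genes_test,
       best_val = res$best_metric, pretrain_log = pt$log,
       train_log = res$log)
}

#' Evaluate recovery of the generative truth on held-out genes
#'
#' Predicts per-cell counts for the given genes, pseudobulks by group and
#' correlates (log2, pseudocount 1) against the generative expected counts,
#' per group.
#'
#' @param fit From [fit_synthetic_model()].
#' @param fx The fixture.
#' @param genes `gene_models` to evaluate (default: held-out test genes).
#' @param rc_average Average forward and reverse-complement passes; desk
#'   runs train without reverse-complement augmentation and default FALSE.
#' @return Named per-group correlation vector.
#' @export
evaluate_recovery <- function(fit, fx, genes = fit$genes_test,
                              rc_average = FALSE) {
  pred <- predicted_count_matrix(fit$model, fx$genome$sequences, genes,
                                 fx$population$embeddings, rc_average)
  pp <- pseudobulk_counts(pred, fx$population$labels)
  truth <- pseudobulk_counts(
    fx$reads$expected_counts[, colnames(pred), drop = FALSE],
    fx$population$labels)
  across_gene_correlation(pp, truth)
}


# Fit a hypernetwork to per-cell target outputs by least squares (Adam on
# MSE); used to distill the pretrained pseudobulk head into the decoder.
distill_hypernet <- function(hn, cell_embeddings, targets, steps = 400L,
                             lr = 1e-2) {
  params <- list(W1 = hn$W1, b1 = hn$b1, W2 = hn$W2 * 0.01, b2 = hn$b2)
  opt <- adamw_init(params, weight_decay = 0)
  n <- nrow(cell_embeddings)
  for (s in seq_len(steps)) {
    hf <- hypernet_forward(modifyList(hn, params), cell_embeddings)
    err <- hf$out - targets
    gr <- hypernet_backward(modifyList(hn, params), 2 * err / n, hf$cache)
    upd <- adamw_step(opt, params,
                      list(W1 = gr$dW1, b1 = gr$db1, W2 = gr$dW2, b2 = gr$db2),
                      list(W1 = lr, b1 = lr, W2 = lr, b2 = lr))
    opt <- upd$state
    params <- upd$params
  }
  modifyList(hn, params)
}
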