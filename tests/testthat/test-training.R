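# Training engine: loss against closed-form oracles, schedule, batch
# sampling invariants, trainable-set audit, checkpoint metric stability.

test_that("poisson-multinomial loss matches the closed form on a 4-bin toy", {
  target <- array(c(2, 1, 1, 0), c(4, 1, 1))
  pred <- array(c(2, 1, 1, 0.5), c(4, 1, 1))
  w <- 0.2
  got <- poisson_multinomial_loss(pred, target, w)
  # closed-form oracle
  Sp <- sum(pred); St <- sum(target)
  mult <- -sum(target * log(pred / Sp))
  pois <- Sp - St * log(Sp)
  expect_equal(as.numeric(got), (mult + w * pois) / 4)
  # uniform target and pred with matched totals: analytic value
  tu <- array(rep(2, 4), c(4, 1, 1))
  pu <- array(rep(2, 4), c(4, 1, 1))
  lu <- poisson_multinomial_loss(pu, tu, w)
  expect_equal(as.numeric(lu), (-8 * log(1 / 4) + w * (8 - 8 * log(8))) / 4)
})

test_that("pred = target attains the multinomial cross-entropy minimum", {
  set.seed(1)
  target <- array(rpois(8, 4) + 0.5, c(8, 1, 1))
  base <- poisson_multinomial_loss(target, target, 0)  # multinomial only
  for (i in 1:5) {
    other <- array(as.vector(target) * runif(8, 0.5, 2), c(8, 1, 1))
    expect_gte(as.numeric(poisson_multinomial_loss(other, target, 0)),
               as.numeric(base) - 1e-12)
  }
})

test_that("scaling predictions changes only the Poisson term", {
  set.seed(2)
  target <- array(rpois(6, 3) + 0.1, c(6, 1, 1))
  pred <- array(runif(6, 0.5, 2), c(6, 1, 1))
  m0 <- as.numeric(poisson_multinomial_loss(pred, target, 0))
  m1 <- as.numeric(poisson_multinomial_loss(pred * 3, target, 0))
  expect_equal(m0, m1, tolerance = 1e-12)
  p0 <- as.numeric(poisson_multinomial_loss(pred, target, 1)) - m0
  p1 <- as.numeric(poisson_multinomial_loss(pred * 3, target, 1)) - m1
  expect_gt(abs(p1 - p0), 0)
  expect_error(poisson_multinomial_loss(-pred, target), "positive")
})

test_that("loss gradient matches finite differences", {
  set.seed(3)
  target <- array(rpois(12, 3), c(4, 1, 3))
  pred <- array(runif(12, 0.5, 2), c(4, 1, 3))
  l <- poisson_multinomial_loss(pred, target, 0.2)
  g <- attr(l, "grad")
  h <- 1e-6
  for (idx in list(c(1, 1, 1), c(3, 1, 2), c(4, 1, 3))) {
    pp <- pred; pp[idx[1], idx[2], idx[3]] <- pp[idx[1], idx[2], idx[3]] + h
    pm <- pred; pm[idx[1], idx[2], idx[3]] <- pm[idx[1], idx[2], idx[3]] - h
    fd <- (as.numeric(poisson_multinomial_loss(pp, target, 0.2)) -
             as.numeric(poisson_multinomial_loss(pm, target, 0.2))) / (2 * h)
    expect_equal(g[idx[1], idx[2], idx[3]], fd, tolerance = 1e-5)
  }
})

test_that("loss is invariant to cell order and joint position reversal", {
  set.seed(4)
  target <- array(rpois(24, 2) + 0.2, c(4, 2, 3))
  pred <- array(runif(24, 0.5, 2), c(4, 2, 3))
  l0 <- as.numeric(poisson_multinomial_loss(pred, target))
  perm <- sample(3)
  expect_equal(as.numeric(poisson_multinomial_loss(pred[, , perm],
                                                   target[, , perm])), l0)
  expect_equal(as.numeric(poisson_multinomial_loss(pred[4:1, , ],
                                                   target[4:1, , ])), l0)
})

test_that("learning-rate schedule warms up linearly then decays to zero", {
  expect_equal(seqprofiler:::lr_schedule(500, 1000, 5000), 0.5)
  expect_equal(seqprofiler:::lr_schedule(1000, 1000, 5000), 1)
  expect_equal(seqprofiler:::lr_schedule(3000, 1000, 5000), 0.5)
  expect_equal(seqprofiler:::lr_schedule(5000, 1000, 5000), 0)
})

test_that("split definitions reject overlapping regions", {
  reg <- function(ch, s, e) data.table::data.table(chrom = ch, start = s, end = e)
  expect_s3_class(split_definition(reg("c1", 0, 10), reg("c2", 0, 10),
                                   reg("c1", 10, 20)), "split_definition")
  expect_error(split_definition(reg("c1", 0, 10), reg("c1", 5, 15),
                                reg("c2", 0, 10)), "overlap")
})

test_that("batch sampling is reproducible, augments and transforms targets", {
  fx_store <- local({
    set.seed(5)
    rec <- read_records(1:200, sample(sprintf("c%02d", 1:20), 200, TRUE),
                        paste0("u", 1:200), "chr1",
                        sample(0:8000, 200, TRUE), sample(20:60, 200, TRUE),
                        sample(c("+", "-"), 200, TRUE), "RNA")
    build_store(rec, NULL, whitelist = sprintf("c%02d", 1:20),
                seqlengths = c(chr1 = 8192L))
  })
  genome <- setNames(random_dna(8192, seed = 6), "chr1")
  split <- split_definition(
    data.table::data.table(chrom = "chr1", start = 0L, end = 8192L),
    data.table::data.table(chrom = "chr2", start = 0L, end = 1L),
    data.table::data.table(chrom = "chr3", start = 0L, end = 1L))
  g <- toy_geometry(input_length = 4096L)
  cfg <- training_config(batch_sequences = 3L, cells_per_sequence = 8L, seed = 9)
  set.seed(cfg$seed)
  b1 <- sample_training_batch(fx_store, genome, split, g, cfg)
  set.seed(cfg$seed)
  b2 <- sample_training_batch(fx_store, genome, split, g, cfg)
  expect_equal(b1, b2)  # fixed seed reproduces the batch
  for (item in b1) {
    expect_equal(length(unique(item$cells)), cfg$cells_per_sequence)
    expect_true(item$shift %in% -3:3)
    expect_equal(nchar(item$seq), 4096L)
    expect_equal(dim(item$target_rna), c(g$output_bins, 2L, 8L))
  }
  # rc targets equal reverse + strand swap of the forward extraction
  rc_items <- Filter(function(i) i$rc, b1)
  if (length(rc_items)) {
    it <- rc_items[[1]]
    out_start <- it$start + g$crop_bins * 32L
    raw <- extract_binned(fx_store, it$chrom, out_start,
                          out_start + g$output_bins * 32L, "RNA", it$cells)
    fwd <- aperm(apply_transform(raw)$values, c(3, 2, 1))
    expect_equal(it$target_rna,
                 fwd[rev(seq_len(dim(fwd)[1])), c(2, 1), , drop = FALSE])
  }
})

test_that("only adapters, final projection and hypernets are trainable by default", {
  g <- toy_geometry()
  bb <- inject_lora(toy_backbone(g), lora_config(rank = 2L))
  m <- profile_model(bb, d_embedding = 4L, hidden = 8L)
  nms <- seqprofiler:::model_trainable_names(m)
  expect_true(all(grepl("lora|final|hn_", nms)))
  expect_false(any(grepl("stem/W$|conv/W$|att/W[qkvo]$|bn", nms)))
})

test_that("validation metric is 1 for perfect predictions and signs mismatches", {
  # direct evaluation oracle on the metric core
  obs <- rbind(t1 = c(3, 8, 1), t2 = c(2, 5, 9))
  expect_equal(unname(across_gene_correlation(obs, obs)), c(1, 1))
  expect_equal(unname(across_gene_correlation(2 * obs, obs)[1]),
               cor(log2(2 * obs[1, ] + 1), log2(obs[1, ] + 1)))
  anti <- rbind(t1 = c(9, 1, 5))
  expect_lt(across_gene_correlation(anti, rbind(t1 = c(1, 9, 5)))[1], 0)
})

test_that("a short training run decreases the loss on synthetic data", {
  fx <- simulate_multiome("tiny", seed = 3)
  g <- model_geometry(input_length = 8192L, embedding_width = 12L)
  bb <- inject_lora(make_mini_backbone(g, channels = 12L, n_conv = 1L,
                                       n_attn = 1L, seed = 1),
                    lora_config(rank = 4L), seed = 2)
  m <- profile_model(bb, d_embedding = 14L, hidden = 16L, seed = 3)
  split <- split_by_contig(fx$store$seqlengths, paste0("contig", 1:3),
                           "contig4", "contig5")
  cfg <- training_config(batch_sequences = 2L, cells_per_sequence = 16L,
                         warmup_steps = 10L, epochs = 5L,
                         steps_per_epoch = 8L, lr_decoder = 2e-3,
                         lr_adapters = 1e-3, seed = 4)
  res <- train(m, fx$store, fx$population$embeddings, fx$genome$sequences,
               split, config = cfg, include_base = TRUE)
  lg <- res$log
  first <- mean(lg$loss[lg$epoch == 1])
  last <- mean(lg$loss[lg$epoch == 5])
  expect_lt(last, first)
  # merged checkpoint reproduces predictions within numerical tolerance
  merged <- merge_lora(res$model$backbone)
  m2 <- profile_model(merged, d_embedding = 14L, hidden = 16L, seed = 99)
  m2$hypernet_rna <- res$model$hypernet_rna
  m2$hypernet_atac <- res$model$hypernet_atac
  s <- substr(fx$genome$sequences[[1]], 1, 8192)
  ce <- fx$population$embeddings[1:4, ]
  p1 <- cached_predict(res$model, s, ce)
  p2 <- cached_predict(m2, s, ce)
  expect_lt(max(abs(p1$rna - p2$rna)), 1e-6)
})
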