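# Evaluation: RC-averaged inference, exon-summed counts, correlation metrics,
# k-NN profile averaging, pseudotime smoothing.

test_that("RC-averaged prediction equals the hand-composed two-pass average", {
  g <- toy_geometry()
  m <- profile_model(toy_backbone(g), d_embedding = 4L, hidden = 8L, seed = 1)
  set.seed(2)
  ce <- matrix(rnorm(8), 2)
  s <- random_dna(g$input_length, seed = 3)
  got <- predict_rc_averaged(m, s, ce)
  fwd <- cached_predict(m, s, ce)
  bwd <- cached_predict(m, s, ce, rc = TRUE)
  nb <- dim(fwd$rna)[1]
  rna <- (fwd$rna + bwd$rna[nb:1, c(2, 1), , drop = FALSE]) / 2
  atac <- (fwd$atac + bwd$atac[nb:1, , , drop = FALSE]) / 2
  tf <- m$transform
  expect_equal(got$rna,
               array(seqprofiler:::unsquash_values(rna, tf, "RNA"), dim(rna)))
  expect_equal(got$atac,
               array(seqprofiler:::unsquash_values(atac, tf, "ATAC"), dim(atac)))
})

test_that("RC-averaged prediction is invariant under reverse-complementing input", {
  g <- toy_geometry()
  m <- profile_model(toy_backbone(g), d_embedding = 4L, hidden = 8L, seed = 4)
  ce <- matrix(rnorm(4), 1)
  s <- random_dna(g$input_length, seed = 5)
  a <- predict_rc_averaged(m, s, ce)
  b <- predict_rc_averaged(m, reverse_complement(s), ce)
  nb <- dim(a$rna)[1]
  expect_equal(a$rna, b$rna[nb:1, c(2, 1), , drop = FALSE], tolerance = 1e-9)
  expect_equal(a$atac, b$atac[nb:1, , , drop = FALSE], tolerance = 1e-9)
})

test_that("ATAC inverse transform rescales a constant plane by 20 at defaults", {
  ones <- array(1, c(4, 1, 2))
  tf <- target_transform()
  nat <- seqprofiler:::unsquash_values(ones, tf, "ATAC")
  expect_equal(unique(as.vector(nat)), (1^(4 / 3)) / 0.05)
})

test_that("gene counts sum strand-matched exon bins fully", {
  g <- toy_geometry()  # 24 output bins of 32 bp
  bins_start <- 0L
  profiles <- list(rna = array(0, c(24, 2, 2)))
  profiles$rna[11:13, 1, 1] <- c(1, 2, 3)
  profiles$rna[11:13, 2, 1] <- 100  # minus-strand track must be ignored
  gene <- list(gene_id = "gX", chrom = "chr1", strand = "+",
               start = 320L, end = 416L,
               exons = data.table::data.table(start = 320L, end = 416L))
  expect_equal(gene_counts(profiles, gene, bins_start, g), c(6, 0))
  # an exon straddling a bin edge counts the bin once, fully
  gene2 <- list(gene_id = "gY", chrom = "chr1", strand = "+",
                start = 330L, end = 340L,
                exons = data.table::data.table(start = 330L, end = 340L))
  # exon spans only bin 11 partially -> full bin value 1
  expect_equal(gene_counts(profiles, gene2, bins_start, g)[1], 1)
  # per-base summation would give 10/32 of the bin; the bin rule differs
  expect_false(isTRUE(all.equal(1, 1 * 10 / 32)))
  # minus-strand gene reads the minus track
  gene3 <- gene; gene3$strand <- "-"
  expect_equal(gene_counts(profiles, gene3, bins_start, g), c(300, 0))
  # no exon in window -> zero with warning
  far <- list(gene_id = "gZ", chrom = "chr1", strand = "+",
              start = 10000L, end = 10100L,
              exons = data.table::data.table(start = 10000L, end = 10100L))
  expect_warning(z <- gene_counts(profiles, far, bins_start, g), "no exon")
  expect_equal(z, c(0, 0))
})

test_that("locus accessibility is the plain sum over output bins", {
  profiles <- list(atac = array(0.5, c(24, 1, 3)))
  expect_equal(locus_accessibility(profiles), rep(0.5 * 24, 3))
  profiles$atac[] <- 0
  expect_equal(locus_accessibility(profiles), rep(0, 3))
  set.seed(6)
  profiles$atac[] <- runif(24 * 3)
  expect_equal(locus_accessibility(profiles),
               apply(profiles$atac[, 1, ], 2, sum))
})

test_that("pseudobulk additivity holds exactly on the natural scale", {
  set.seed(7)
  counts <- matrix(rpois(5 * 4, 10), 5, 4,
                   dimnames = list(paste0("c", 1:5), paste0("g", 1:4)))
  labels <- c("a", "a", "b", "b", "b")
  pb <- pseudobulk_counts(counts, labels)
  expect_equal(pb["a", ], colSums(counts[1:2, ]))
  expect_equal(pb["b", ], colSums(counts[3:5, ]))
})

test_that("across-gene correlation matches direct evaluation and flags degeneracy", {
  pred <- rbind(a = c(1, 2, 4), b = c(3, 1, 2))
  obs <- rbind(a = c(2, 4, 8), b = c(5, 5, 5))
  expect_equal(unname(across_gene_correlation(pred, pred)), c(1, 1))
  expect_warning(r <- across_gene_correlation(pred, obs), "zero variance")
  expect_equal(unname(r["a"]),
               cor(log2(c(1, 2, 4) + 1), log2(c(2, 4, 8) + 1)))
  expect_true(is.na(r["b"]))
  # anti-ordered toy counts give a negative value
  anti <- rbind(a = c(4, 2, 1))
  expect_lt(across_gene_correlation(anti, rbind(a = c(1, 2, 4)))[1], 0)
})

test_that("deviation correlation isolates interaction structure", {
  # pure additive structure centers to zero -> NaN with warning
  add <- outer(c(1, 2, 3), c(10, 20, 30), `+`)
  m <- 2^add - 1  # so log2(m+1) is exactly additive
  expect_warning(r <- deviation_correlation(m, m), "undefined")
  expect_true(is.nan(r))
  # interaction structure: self-correlation 1, hand-computed toy
  set.seed(8)
  mi <- matrix(2^(rnorm(9)) , 3, 3)
  expect_equal(deviation_correlation(mi, mi), 1)
  dc <- function(x) {
    x <- log2(x + 1); x <- sweep(x, 1, rowMeans(x)); sweep(x, 2, colMeans(x))
  }
  other <- matrix(2^(rnorm(9)), 3, 3)
  expect_equal(deviation_correlation(mi, other),
               cor(as.vector(dc(mi)), as.vector(dc(other))))
})

test_that("k-NN averaging matches brute force on a 5-cell toy", {
  emb <- matrix(c(0, 0.1, 0.2, 5, 5.1), ncol = 1)
  prof <- matrix(seq_len(10), 5, 2)
  # k = 1: each cell's average is its single nearest neighbor
  k1 <- knn_average_profiles(prof, emb, k = 1)
  expect_equal(k1[1, ], prof[2, ])
  expect_equal(k1[4, ], prof[5, ])
  k2 <- knn_average_profiles(prof, emb, k = 2)
  expect_equal(k2[1, ], colMeans(prof[2:3, ]))
  # correlation of a cell with itself is 1
  set.seed(9)
  p <- matrix(rpois(20, 5), 2)
  expect_equal(profile_correlation(p, p), c(1, 1))
})

test_that("rolling smoothing has shrinking edge windows and exact interior means", {
  x <- rep(3, 50)
  expect_equal(rolling_smooth(x, 10), x)
  expect_equal(rolling_smooth(x, 1), x)
  step <- c(rep(0, 50), rep(1, 50))
  sm <- rolling_smooth(step, 20)
  expect_equal(sm[25], 0)  # far from the step
  expect_equal(sm[75], 1)
  expect_true(all(diff(sm) >= 0))
  ramp_width <- sum(sm > 0 & sm < 1)
  expect_equal(ramp_width, 19L)  # ~ window width
  # interior value equals the plain mean
  set.seed(10)
  y <- rnorm(100)
  expect_equal(rolling_smooth(y, 11)[50], mean(y[45:55]))
})
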