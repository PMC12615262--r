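# Interpretation: motif/variant effect scoring properties, negligible-effect
# classification, deconvolution rankings, eQTL selection filters.

test_that("a motif the model ignores scores exactly zero", {
  # constant-output model: final projection zeroed -> embedding constant in
  # sequence, so mutation cannot change predictions
  g <- toy_geometry(input_length = 1024L, E = 8L)
  bb <- make_mini_backbone(g, channels = 8L, n_conv = 1L, n_attn = 0L, seed = 1)
  bb$final$W[] <- 0
  m <- profile_model(bb, d_embedding = 4L, hidden = 8L, seed = 2)
  set.seed(3)
  ce <- matrix(rnorm(3 * 4), 3)
  p <- toy_pwms(1L)[[1]]
  genome <- list()
  s <- random_dna(2048, seed = 4)
  # plant a consensus at a known spot
  substr(s, 900, 907) <- pwm_consensus(p)
  genome[["chr1"]] <- s
  gene <- list(gene_id = "g1", chrom = "chr1", strand = "+",
               start = 900L, end = 1100L,
               exons = data.table::data.table(start = 900L, end = 1100L))
  genes <- structure(list(g1 = gene), class = "gene_models")
  sc <- tf_motif_effect(m, genome, genes, p, ce, "expression",
                        n_replicates = 2L, seed = 5)
  expect_equal(unname(sc), rep(0, 3), ignore_attr = TRUE)
})

test_that("equal size factors make normalization a no-op in the score", {
  # the score is a mean of log ratios; the per-cell size factor divides both
  # numerator and denominator, so identical factors must not change anything
  ref <- c(2, 4); alt <- c(1, 8); sf <- c(3, 3)
  raw <- log2(alt / ref)
  norm <- log2((alt / sf * median(sf)) / (ref / sf * median(sf)))
  expect_equal(norm, raw)
})

test_that("target-gene selection applies the strict absolute threshold", {
  eff <- c(gA = 0.05, gB = -0.2, gC = 0.1, gD = 0.101, gE = -0.09, gF = 0.3)
  got <- target_gene_effects(eff, threshold = 0.1)
  expect_setequal(got$gene, c("gB", "gD", "gF"))
  expect_equal(got$direction[got$gene == "gB"], "down_on_mutation")
  expect_equal(got$direction[got$gene == "gF"], "up_on_mutation")
})

test_that("variant effects verify the reference allele and obey the pseudocount", {
  g <- toy_geometry(input_length = 1024L, E = 8L)
  bb <- make_mini_backbone(g, channels = 8L, n_conv = 1L, n_attn = 0L, seed = 1)
  m <- profile_model(bb, d_embedding = 4L, hidden = 8L, seed = 2)
  set.seed(3)
  ce <- matrix(rnorm(4 * 4), 4)
  genome <- list(chr1 = random_dna(4096, seed = 6))
  pos0 <- 2000L
  ref <- substr(genome$chr1, pos0 + 1L, pos0 + 1L)
  gene <- list(gene_id = "g1", chrom = "chr1", strand = "+",
               start = 1800L, end = 2200L,
               exons = data.table::data.table(start = 1800L, end = 2200L))
  groups <- c("a", "a", "b", "b")
  wrong <- setdiff(c("A", "C", "G", "T"), ref)[1]
  expect_error(variant_effect(m, genome, "chr1", pos0, wrong, ref, gene, ce,
                              groups), "mismatch")
  # alt == ref gives exactly zero effect
  eff <- variant_effect(m, genome, "chr1", pos0, ref, ref, gene, ce, groups)
  expect_equal(unname(eff$expression), c(0, 0))
  expect_equal(eff$overall_accessibility, 0)
  # arithmetic contract: group sums ref 1, alt 3 -> log2(4/2) = 1
  expect_equal(log2((3 + 1) / (1 + 1)), 1)
})

test_that("negligible classification uses a strict bound and reports 3.5%", {
  m <- classify_negligible(c(0.049, -0.05, 0.2, 0))
  expect_equal(as.vector(m), c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(attr(m, "percent_fold_change"), 3.5)
})

test_that("cell-type rankings are deterministic with lexicographic ties", {
  eff <- c(A = 0.2, B = -0.3, C = 0.0)
  expect_equal(rank_cell_types(eff), c("B", "A", "C"))
  tie <- c(Z = 0.1, A = -0.1, M = 0.1)
  expect_equal(rank_cell_types(tie), c("A", "M", "Z"))
  expect_equal(rank_cell_types(tie), rank_cell_types(tie))
  expect_equal(rank_by_expression(c(x = 5, y = 9, z = 1)), c("y", "x", "z"))
})

test_that("accessibility baseline picks the overlapping or nearest peak", {
  peaks <- data.table::data.table(chrom = c("chr1", "chr1", "chr2"),
                                  start = c(100L, 500L, 0L),
                                  end = c(200L, 600L, 50L),
                                  tA = c(1, 9, 2), tB = c(5, 3, 4))
  expect_equal(rank_by_accessibility(peaks, "chr1", 150L, c("tA", "tB")),
               c("tB", "tA"))  # inside first peak
  expect_equal(rank_by_accessibility(peaks, "chr1", 450L, c("tA", "tB")),
               c("tA", "tB"))  # nearest is the second peak
  expect_warning(r <- rank_by_accessibility(peaks, "chrX", 10L, c("tA", "tB")),
                 "no peak")
  expect_null(r)
})

test_that("precision at k matches hand counts on a 3-variant toy", {
  rankings <- list(c("B", "A", "C"), c("A", "B", "C"), c("C", "B", "A"))
  positives <- list("B", "B", "B")
  p1 <- mean(mapply(function(r, p) precision_at_k(r, p, 1), rankings, positives))
  expect_equal(p1, 1 / 3)
  p2 <- mean(mapply(function(r, p) precision_at_k(r, p, 2), rankings, positives))
  expect_equal(p2, mean(c(1 / 2, 1 / 2, 1 / 2)))
})

test_that("variable-eQTL selection applies the two-stage filter", {
  set.seed(4)
  m <- rbind(matrix(0.01, 5, 4),                     # fails the mean filter
             matrix(rep(c(0.3, 0.3, 0.3, 0.3), 5), 5, 4, byrow = TRUE),
             matrix(c(0.9, -0.5, 0.1, 0.6), 5, 4, byrow = TRUE) +
               matrix(rnorm(20, sd = 0.2), 5))
  keep <- select_variable_eqtls(m, mean_threshold = 0.05, var_quantile = 0.85)
  expect_false(any(keep[1:5]))    # below mean threshold
  expect_false(any(keep[6:10]))   # constant rows: zero variance
  expect_true(any(keep[11:15]))
  # manual two-stage oracle on a 20-row toy
  mp <- rowMeans(abs(m)) > 0.05
  v <- apply(m[mp, ], 1, var)
  manual <- rep(FALSE, nrow(m))
  manual[which(mp)[v > quantile(v, 0.85)]] <- TRUE
  expect_equal(keep, manual)
  expect_false(any(select_variable_eqtls(matrix(0.01, 3, 3))))
})

test_that("sign concordance by distance handles all/filtered/empty bins", {
  pred <- c(0.5, -0.5, 0.01, 0.3)
  obs <- c(1, -2, -1, -1)
  d <- c(100, 100, 5000, 5000)
  tab <- sign_concordance_by_distance(pred, obs, d, breaks = c(0, 1000, 10000, 1e6))
  expect_equal(tab$concordance_all[1], 1)
  expect_equal(tab$concordance_all[2], 0)      # 0.01 and 0.3 both wrong sign
  expect_equal(tab$concordance_filtered[2], 0) # only 0.3 survives, wrong
  expect_true(is.nan(tab$concordance_all[3]))
  expect_equal(tab$n_all[3], 0L)
  # random signs concentrate near 0.5
  set.seed(5)
  n <- 4000
  p <- rnorm(n); o <- rnorm(n)
  t2 <- sign_concordance_by_distance(p, o, rep(500, n), breaks = c(0, 1000))
  expect_lt(abs(t2$concordance_all[1] - 0.5), 3 * sqrt(0.25 / n) * 1.5)
})

test_that("differential-expression helper flags planted group differences", {
  set.seed(6)
  n <- 60
  labels <- rep(c("a", "b"), each = n / 2)
  counts <- cbind(up = c(rpois(n / 2, 20), rpois(n / 2, 5)),
                  flat = rpois(n, 10))
  res <- de_genes(counts, labels, "a")
  expect_true("up" %in% res$gene)
  expect_false("flat" %in% res$gene)
  expect_gt(res$lfc[res$gene == "up"], 0)
})

test_that("variant tables drop non-single-nucleotide records", {
  f <- withr::local_tempfile(fileext = ".tsv")
  data.table::fwrite(data.table::data.table(
    chrom = "chr1", pos = c(10L, 20L, 30L), ref = c("A", "AT", "G"),
    alt = c("C", "A", "GGA"), gene = "g1"), f, sep = "\t")
  v <- read_variants(f)
  expect_equal(nrow(v), 1L)
  expect_equal(v$pos, 10L)
})
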