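# Coverage archive: alignment parsing, insertion conversion, binned
# extraction against a per-base brute-force oracle, transforms, store IO.

test_that("split RNA alignments are parsed into multi-segment records", {
  aln <- data.frame(chrom = "chr1", pos = 101L, cigar = "50M350N50M",
                    strand = "+", barcode = "c1", umi = "u1", xf = 25L)
  rec <- parse_alignments(aln, "RNA", require_valid_flag = TRUE)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$seg_start, c(100L, 500L))
  expect_equal(rec$seg_len, c(50L, 50L))
  expect_equal(unique(rec$read_id), rec$read_id[1])
})

test_that("soft clips are dropped and the validity flag filters", {
  aln <- data.frame(chrom = "chr1", pos = 11L, cigar = c("5S45M", "50M"),
                    strand = "+", barcode = c("c1", "c2"),
                    umi = c("u1", "u2"), xf = c(25L, 0L))
  rec <- parse_alignments(aln, "RNA", require_valid_flag = TRUE)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$seg_start, 10L)  # soft clip consumes no reference
  expect_equal(rec$seg_len, 45L)
})

test_that("malformed CIGAR errors and missing barcodes are counted", {
  bad <- data.frame(chrom = "chr1", pos = 1L, cigar = "50Q",
                    strand = "+", barcode = "c1", umi = "u1", xf = 25L)
  expect_error(parse_alignments(bad, "RNA"), "malformed CIGAR")
  nobc <- data.frame(chrom = "chr1", pos = 1L, cigar = "10M",
                     strand = "+", barcode = c(NA, "c1"),
                     umi = c("u1", "u2"), xf = 25L)
  expect_warning(rec <- parse_alignments(nobc, "RNA"), "missing barcode")
  expect_equal(nrow(rec), 1L)
})

test_that("deduplication matches a brute-force grouping oracle on a toy stream", {
  set.seed(42)
  n <- 10L
  aln <- data.frame(chrom = "chr1",
                    pos = sample(c(101L, 201L, 301L), n, TRUE),
                    cigar = "20M", strand = "+",
                    barcode = sample(c("c1", "c2"), n, TRUE),
                    umi = sample(c("u1", "u2"), n, TRUE), xf = 25L)
  rec <- parse_alignments(aln, "RNA")
  # oracle: unique (barcode, umi, chrom, start) combinations
  key <- unique(paste(aln$barcode, aln$umi, aln$chrom, aln$pos))
  expect_equal(nrow(rec), length(key))
  # ATAC dedup on the full segment
  atac <- data.frame(chrom = "chr1", pos = c(101L, 101L, 101L),
                     cigar = c("100M", "100M", "90M"), strand = ".",
                     barcode = "c1", xf = 25L)
  arec <- parse_alignments(atac, "ATAC")
  expect_equal(nrow(arec), 2L)
})

test_that("each fragment yields two insertions at start and end-1", {
  rec <- read_records(1:2, c("c1", "c1"), NA, "chr1",
                      c(100L, 50L), c(100L, 1L), ".", "ATAC")
  ins <- fragments_to_insertions(rec)
  expect_equal(nrow(ins), 4L)  # 2n conservation
  expect_setequal(ins$pos[c(1, 3)], c(100L, 199L))
  # length-1 fragment: two events at the same position
  expect_equal(ins$pos[c(2, 4)], c(50L, 50L))
  rna <- read_records(1L, "c1", "u1", "chr1", 10L, 20L, "+", "RNA")
  expect_error(fragments_to_insertions(rna), "ATAC")
})

test_that("store keeps only whitelisted cells and preserves totals", {
  rec <- read_records(1:3, c("c1", "c2", "c3"), paste0("u", 1:3), "chr1",
                      c(0L, 100L, 200L), c(10L, 10L, 10L), "+", "RNA")
  st <- toy_store(rna = rec, cells = c("c1", "c2"))
  expect_equal(length(st$cells), 2L)
  expect_equal(nrow(st$rna), 2L)
  expect_error(
    build_store(rec, whitelist = "c1", seqlengths = c(chrX = 100L)),
    "unknown chromosome")
  expect_warning(
    build_store(rec[0], whitelist = "c1", seqlengths = c(chr1 = 100L)),
    "empty")
})

test_that("binned extraction equals per-base brute force on random read sets", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    segs <- data.frame(start = sample(0:900, n, TRUE),
                       len = sample(1:80, n, TRUE))
    segs$len <- pmin(segs$len, 1024L - segs$start)
    rec <- read_records(seq_len(n), "c1", paste0("u", seq_len(n)), "chr1",
                        segs$start, segs$len, "+", "RNA")
    st <- toy_store(rna = rec, cells = "c1")
    tr <- extract_binned(st, "chr1", 0, 1024, "RNA", bin_width = 32)
    expect_equal(as.numeric(tr$values[1, 1, ]),
                 brute_binned(segs, 0, 1024, 32))
  }
})

test_that("extraction covers split reads, window boundaries and empty stores", {
  # one 64-bp segment over exactly two bins
  rec <- read_records(1L, "c1", "u1", "chr1", 0L, 64L, "+", "RNA")
  st <- toy_store(rna = rec, cells = "c1")
  tr <- extract_binned(st, "chr1", 0, 64, "RNA", bin_width = 32)
  expect_equal(as.numeric(tr$values[1, 1, ]), c(32, 32))
  # insertions at bin boundary positions 31 and 32
  ins <- data.table::data.table(barcode = "c1", chrom = "chr1",
                                pos = c(31L, 32L))
  st2 <- toy_store(atac = ins, cells = "c1")
  ta <- extract_binned(st2, "chr1", 0, 64, "ATAC", bin_width = 32)
  expect_equal(as.numeric(ta$values[1, 1, ]), c(1, 1))
  # empty store extracts zeros; indivisible length errors
  expect_warning(st3 <- build_store(whitelist = "c1", seqlengths = c(chr1 = 1024L)))
  expect_true(all(extract_binned(st3, "chr1", 0, 64, "RNA")$values == 0))
  expect_error(extract_binned(st, "chr1", 0, 63, "RNA"), "divisible")
})

test_that("extraction is independent of record insertion order", {
  set.seed(11)
  segs <- data.frame(start = sample(0:900, 25, TRUE), len = sample(1:60, 25, TRUE))
  rec1 <- read_records(1:25, "c1", paste0("u", 1:25), "chr1",
                       segs$start, segs$len, "+", "RNA")
  o <- sample(25)
  rec2 <- read_records(1:25, "c1", paste0("u", o), "chr1",
                       segs$start[o], segs$len[o], "+", "RNA")
  t1 <- extract_binned(toy_store(rna = rec1, cells = "c1"), "chr1", 0, 1024, "RNA")
  t2 <- extract_binned(toy_store(rna = rec2, cells = "c1"), "chr1", 0, 1024, "RNA")
  expect_equal(t1$values, t2$values)
})

test_that("squash transform round-trips within 1e-6 including clip straddle", {
  tf <- target_transform()
  x <- c(0, 0.1, 1, 5, 8, 8.5, 9, 50, 5000)  # straddles clip_soft^(4/3)
  for (assay in c("RNA", "ATAC")) {
    y <- squash_values(x, tf, assay)
    back <- unsquash_values(y, tf, assay)
    expect_lt(max(abs(back - x) / pmax(x, 1e-12)), 1e-6)
  }
  # ATAC inverse without rescale differs by exactly 1/atac_scale = 20
  y <- squash_values(100, tf, "ATAC")
  expect_equal(unsquash_values(y, tf, "RNA") * 20,
               unsquash_values(y, tf, "ATAC"), tolerance = 1e-12)
  expect_error(squash_values(-1, tf), "nonnegative")
})

test_that("transform on tracks flags state and rejects double application", {
  rec <- read_records(1L, "c1", "u1", "chr1", 0L, 64L, "+", "RNA")
  st <- toy_store(rna = rec, cells = "c1")
  tr <- extract_binned(st, "chr1", 0, 64, "RNA")
  tt <- apply_transform(tr)
  expect_true(tt$transformed)
  expect_error(apply_transform(tt), "already")
  expect_equal(invert_transform(tt)$values, tr$values, tolerance = 1e-9)
})

test_that("store round-trips losslessly through its on-disk container", {
  set.seed(3)
  rec <- read_records(1:30, sample(c("c1", "c2"), 30, TRUE),
                      paste0("u", 1:30), "chr1",
                      sample(0:900, 30, TRUE), sample(1:50, 30, TRUE),
                      sample(c("+", "-"), 30, TRUE), "RNA")
  ins <- data.table::data.table(barcode = sample(c("c1", "c2"), 20, TRUE),
                                chrom = "chr1", pos = sample(0:1000, 20, TRUE))
  st <- toy_store(rna = rec, atac = ins)
  d <- withr::local_tempdir()
  write_store(st, d)
  st2 <- read_store(d)
  expect_identical(st$cells, st2$cells)
  expect_equal(extract_binned(st, "chr1", 0, 1024, "RNA")$values,
               extract_binned(st2, "chr1", 0, 1024, "RNA")$values)
  expect_equal(extract_binned(st, "chr1", 0, 1024, "ATAC")$values,
               extract_binned(st2, "chr1", 0, 1024, "ATAC")$values)
})

test_that("pseudobulk bigWig export is additive across groups", {
  set.seed(5)
  rec <- read_records(1:40, sample(c("c1", "c2", "c3"), 40, TRUE),
                      paste0("u", 1:40), "chr1",
                      sample(0:900, 40, TRUE), sample(1:50, 40, TRUE),
                      "+", "RNA")
  st <- toy_store(rna = rec, cells = c("c1", "c2", "c3"))
  d <- withr::local_tempdir()
  one <- export_pseudobulk_bigwig(st, rep("all", 3), file.path(d, "one"))
  two <- export_pseudobulk_bigwig(st, c("a", "a", "b"), file.path(d, "two"))
  cov_of <- function(f) {
    gr <- rtracklayer::import.bw(f, as = "RleList")
    as.numeric(gr[["chr1"]])
  }
  expect_equal(cov_of(two[["a_rna_+"]]) + cov_of(two[["b_rna_+"]]),
               cov_of(one[["all_rna_+"]]))
})

test_that("leaky and rare features are filtered like the overlap brute force", {
  set.seed(9)
  feat <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(start = seq(1, 1000, by = 100),
                                                  width = 50))
  held <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(start = c(120, 810), width = 100))
  counts <- matrix(rbinom(10 * 200, 1, 0.3), nrow = 10)
  counts[3, ] <- 0
  counts[4, ] <- c(1, rep(0, 199))  # 0.5% prevalence
  keep <- filter_leaky_features(feat, held, counts, min_prevalence = 0.01)
  # brute-force interval overlap oracle
  brute <- vapply(seq_along(feat), function(i) {
    f <- feat[i]
    !any(GenomicRanges::start(held) <= GenomicRanges::end(f) &
           GenomicRanges::end(held) >= GenomicRanges::start(f))
  }, logical(1))
  brute <- brute & rowMeans(counts > 0) >= 0.01
  expect_equal(keep, brute)
  expect_false(keep[4])
})

test_that("BAM alignments parse with tags and validity flag", {
  d <- withr::local_tempdir()
  sam <- file.path(d, "toy.sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:2000",
    paste0("r1\t0\tchr1\t101\t255\t30M100N20M\t*\t0\t0\t",
           strrep("A", 50), "\t*\tCB:Z:c1\tUB:Z:u1\txf:i:25"),
    paste0("r2\t0\tchr1\t201\t255\t50M\t*\t0\t0\t",
           strrep("A", 50), "\t*\tCB:Z:c2\tUB:Z:u2\txf:i:0"),
    paste0("r3\t16\tchr1\t301\t255\t50M\t*\t0\t0\t",
           strrep("A", 50), "\t*\tCB:Z:c1\tUB:Z:u3\txf:i:25")),
    sam)
  bam <- Rsamtools::asBam(sam, file.path(d, "toy"), overwrite = TRUE)
  rec <- parse_alignments(bam, "RNA", require_valid_flag = TRUE)
  expect_equal(length(unique(rec$read_id)), 2L)  # r2 filtered out
  r1 <- rec[rec$barcode == "c1" & rec$umi == "u1"]
  expect_equal(r1$seg_start, c(100L, 230L))
  expect_equal(r1$seg_len, c(30L, 20L))
  r3 <- rec[rec$umi == "u3"]
  expect_equal(r3$strand, "-")
})
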