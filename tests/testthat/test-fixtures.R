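# Synthetic multiome generator: determinism, planted-motif recovery, read
# simulation against its generative expectation, variant construction.

test_that("fixture generation is reproducible bit-exactly per seed", {
  a <- make_genome(n_contigs = 2L, length = 16384L, genes_per_contig = 4L,
                   seed = 11)
  b <- make_genome(n_contigs = 2L, length = 16384L, genes_per_contig = 4L,
                   seed = 11)
  expect_identical(a, b)
  c <- make_genome(n_contigs = 2L, length = 16384L, genes_per_contig = 4L,
                   seed = 12)
  expect_false(identical(a$sequences, c$sequences))
})

test_that("gene models have valid sorted exons and round-trip through GTF", {
  gen <- make_genome(n_contigs = 2L, length = 32768L, genes_per_contig = 6L,
                     seed = 2)
  for (g in gen$genes) {
    expect_true(all(g$exons$start < g$exons$end))
    expect_true(all(diff(g$exons$start) > 0))
    # non-overlapping exons
    expect_true(all(g$exons$start[-1] >= g$exons$end[-nrow(g$exons)]))
    expect_equal(g$start, g$exons$start[1])
    expect_equal(g$end, g$exons$end[nrow(g$exons)])
  }
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(gen$genes, f)
  back <- read_gtf(f)
  expect_setequal(names(back), names(gen$genes))
  for (nm in names(gen$genes)) {
    expect_equal(back[[nm]]$exons, gen$genes[[nm]]$exons)
    expect_equal(back[[nm]]$strand, gen$genes[[nm]]$strand)
  }
})

test_that("planted consensus sites are recovered by the scanner", {
  gen <- make_genome(n_contigs = 2L, length = 32768L, genes_per_contig = 8L,
                     seed = 3)
  pwms <- toy_pwms(2L)
  pl <- plant_motifs(gen, pwms, c("g1", "g2"), seed = 4)
  inst <- pl$truth$instances
  expect_gt(nrow(inst), 0)
  # no planted site overlaps another
  data.table::setorder(inst, chrom, start)
  same <- inst$chrom[-1] == inst$chrom[-nrow(inst)]
  expect_true(all(inst$start[-1][same] >= inst$end[-nrow(inst)][same]))
  # scanner recovers >= 95% of planted sites at p <= 1e-4
  rec <- 0L
  for (ch in unique(inst$chrom)) {
    s <- pl$sequences[[ch]]
    for (pw in names(pwms)) {
      hits <- scan_pwm(s, pwms[[pw]], 1e-4)
      sub <- inst[inst$chrom == ch & inst$pwm == pw]
      rec <- rec + sum(sub$start %in% hits$start)
    }
  }
  expect_gte(rec / nrow(inst), 0.95)
  # unplanted positions unchanged
  untouched <- setdiff(seq_len(200), unlist(lapply(
    which(inst$chrom == "contig1" & inst$start < 200),
    function(i) (inst$start[i] + 1):(inst$end[i]))))
  expect_equal(substr(pl$sequences[["contig1"]], 1, 30),
               substr(gen$sequences[["contig1"]], 1, 30))
})

test_that("simulated read counts match the generative expectation", {
  gen <- make_genome(n_contigs = 2L, length = 32768L, genes_per_contig = 6L,
                     seed = 5)
  pwms <- toy_pwms(2L)
  pl <- plant_motifs(gen, pwms, c("g1", "g2"), seed = 6)
  genome <- list(sequences = pl$sequences, seqlengths = gen$seqlengths)
  pop <- make_population(n_cells = 100L, groups = c("g1", "g2"), seed = 7)
  reads <- simulate_reads(genome, gen$genes, pl$truth, pop, seed = 8)
  # per (group, gene) totals within 3 sigma of the Poisson expectation
  rna <- reads$rna
  first <- rna[!duplicated(rna$read_id)]
  per_cell_gene <- table(factor(first$barcode, levels = pop$barcodes))
  expected <- reads$expected_counts
  for (grp in c("g1", "g2")) {
    cells <- pop$labels == grp
    lam <- sum(expected[cells, ])
    got <- sum(per_cell_gene[cells])
    expect_lt(abs(got - lam), 3 * sqrt(lam) + 1)
  }
  # zero depth -> no reads
  none <- simulate_reads(genome, gen$genes, pl$truth, pop, depth = 0, seed = 9)
  expect_equal(nrow(none$rna), 0L)
  # ATAC records are single-segment; RNA split reads span exon junctions
  expect_true(all(table(reads$atac$read_id) == 1L))
  nseg <- table(reads$rna$read_id)
  expect_gt(sum(nseg > 1L), 0L)
})

test_that("motif-destroying variants break the hit and nulls sit clear", {
  fx <- simulate_multiome("tiny", seed = 5)
  v <- fx$variants
  expect_gt(sum(v$kind == "planted"), 0)
  expect_gt(sum(v$kind == "null"), 0)
  # ref alleles match the planted genome
  for (i in seq_len(nrow(v))) {
    expect_equal(substr(fx$genome$sequences[[v$chrom[i]]],
                        v$pos0[i] + 1L, v$pos0[i] + 1L), v$ref[i])
    expect_false(v$ref[i] == v$alt[i])
  }
  # destroying substitution weakens the planted run: strictly fewer hits
  # (tandem copies mean other copies of the run can still match)
  pv <- v[v$kind == "planted"][1]
  inst <- fx$truth$instances
  site <- inst[inst$gene == pv$gene & inst$pwm == paste0(
    "MOTIF", match(pv$group, fx$truth$groups)) & inst$copy == 1L][1]
  s <- fx$genome$sequences[[pv$chrom]]
  win <- substr(s, site$start - 10, site$end + 40)
  p <- fx$pwms[[site$pwm]]
  n_ref <- nrow(scan_pwm(win, p, 1e-4))
  expect_gt(n_ref, 0)
  alt_s <- s
  substr(alt_s, pv$pos0 + 1L, pv$pos0 + 1L) <- pv$alt
  win_alt <- substr(alt_s, site$start - 10, site$end + 40)
  expect_lt(nrow(scan_pwm(win_alt, p, 1e-4)), n_ref)
  # null variants are >= 100 bp from any planted site
  nulls <- v[v$kind == "null"]
  for (i in seq_len(nrow(nulls))) {
    d <- inst[inst$chrom == nulls$chrom[i]]
    expect_true(all(nulls$pos0[i] < d$start - 100L |
                      nulls$pos0[i] >= d$end + 100L))
  }
})

test_that("fixture files are written and read back consistently", {
  fx <- simulate_multiome("tiny", seed = 2, out_dir = withr::local_tempdir())
  d <- attr(fx, "dir")
  # write again explicitly to a fresh dir and check artifacts
  d <- withr::local_tempdir()
  seqprofiler:::write_fixture(fx, d)
  expect_true(all(file.exists(file.path(
    d, c("genome.fa", "genes.gtf", "fragments.tsv", "embeddings.csv",
         "variants.tsv", "motifs.meme", "truth.json")))))
  seqs <- read_fasta(file.path(d, "genome.fa"))
  expect_identical(seqs, fx$genome$sequences)
  frs <- read_fragments(file.path(d, "fragments.tsv"))
  # read_fragments deduplicates identical (barcode, chrom, segment) records
  uniq <- nrow(unique(fx$reads$atac[, c("barcode", "chrom", "seg_start",
                                        "seg_len")]))
  expect_equal(nrow(frs), uniq)
  emb <- data.table::fread(file.path(d, "embeddings.csv"))
  expect_equal(nrow(emb), length(fx$population$barcodes))
  # expected count matrix against itself is a perfect correlation
  pb <- pseudobulk_counts(fx$reads$expected_counts, fx$population$labels)
  expect_equal(unname(across_gene_correlation(pb, pb)),
               rep(1, nrow(pb)))
})

test_that("population embeddings linearly separate the groups", {
  pop <- make_population(n_cells = 150L, groups = c("a", "b", "c"), seed = 3)
  # nearest group-centroid classification is perfect at default separation
  cent <- rowsum(pop$embeddings, pop$labels) /
    as.vector(table(pop$labels))
  d <- as.matrix(stats::dist(rbind(cent, pop$embeddings)))[-(1:3), 1:3]
  assigned <- rownames(cent)[apply(d, 1L, which.min)]
  expect_equal(assigned, pop$labels)
})
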