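# Fully synthetic multiome generator with known ground truth: toy genome and
# gene models, planted PWM motifs driving group-specific expression and
# accessibility, a cell population with group-informative embeddings, RNA
# reads (split across exon junctions, optional 3' bias), ATAC fragments, and
# motif-destroying / null variants. Every stage is reproducible per seed.

#' Toy PWMs with sharp consensus sites
#'
#' One distinct motif per requested group; consensus probability 0.97.
#' The consensi mimic common low-complexity regulatory elements (a GC box,
#' a poly-dA:dT tract, a CA microsatellite-like element), whose internal
#' repetition matches how strong promoter-proximal elements look in real
#' genomes.
#' @param n Number of motifs (default 3).
#' @return Named list of `pwm` objects.
#' @export
toy_pwms <- function(n = 3L) {
  consensi <- c("GGGGCGGGG", "AAAATAAAA", "CACACACAC", "TGACGTCA",
                "TTGACCAA", "GCCACGTG")[seq_len(n)]
  out <- lapply(seq_len(n), function(i) {
    chars <- strsplit(consensi[i], "")[[1]]
    m <- matrix(0.01, length(chars), 4L)
    m[cbind(seq_along(chars), match(chars, DNA_CHANNELS))] <- 0.97
    pwm(m, name = paste0("MOTIF", i))
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Generate a random toy genome with gene models
#'
#' Random contigs carrying a dense layout of toy genes (2-3 exons, random
#' strand), deterministic per seed. Genes are spaced so several fall inside
#' one model output window and each fits a window centered on its body.
#'
#' @param n_contigs Number of contigs.
#' @param length Contig length in bp.
#' @param gc GC content.
#' @param genes_per_contig Genes per contig.
#' @param span_range Min/max gene span in bp.
#' @param seed RNG seed.
#' @return List with `sequences` (named character), `seqlengths`, and
#'   `genes` (a `gene_models` list).
#' @export
make_genome <- function(n_contigs = 5L, length = 65536L, gc = 0.41,
                        genes_per_contig = 20L, span_range = c(1200L, 2200L),
                        seed = 1L) {
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(n_contigs), function(i)
    paste(sample(DNA_CHANNELS, length, TRUE, prob = probs), collapse = ""),
    character(1))
  names(seqs) <- paste0("contig", seq_len(n_contigs))
  # gene-dense layout: several genes fall inside one model output window, so
  # relative expression levels shape the positional coverage distribution
  spacing <- (length - 8000L) %/% (genes_per_contig + 1L)
  genes <- list()
  for (ci in seq_len(n_contigs)) {
    for (gi in seq_len(genes_per_contig)) {
      span <- sample(span_range[1L]:span_range[2L], 1L)
      start <- 4000L + (gi - 1L) * spacing + sample(0:300, 1L)
      n_ex <- sample(2:3, 1L)
      # exon boundaries: cut the span into 2*n_ex-1 alternating exon/intron
      cuts <- sort(sample(seq(150L, span - 150L, by = 50L), 2L * n_ex - 2L))
      bounds <- c(0L, cuts, span)
      exons <- data.table::data.table(
        start = start + bounds[seq(1L, 2L * n_ex - 1L, by = 2L)],
        end = start + bounds[seq(2L, 2L * n_ex, by = 2L)])
      gene <- list(gene_id = sprintf("G%02d_%02d", ci, gi),
                   chrom = names(seqs)[ci],
                   strand = sample(c("+", "-"), 1L),
                   start = exons$start[1L], end = exons$end[nrow(exons)],
                   exons = exons)
      genes[[gene$gene_id]] <- gene
    }
  }
  class(genes) <- "gene_models"
  list(sequences = seqs,
       seqlengths = stats::setNames(rep(length, n_contigs), names(seqs)),
       genes = genes)
}

#' Write gene models as GTF (1-based, closed intervals)
#' @param genes A `gene_models` list.
#' @param path Output path.
#' @export
write_gtf <- function(genes, path) {
  lines <- unlist(lapply(genes, function(g) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s.t1";', g$gene_id, g$gene_id)
    c(sprintf("%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, g$start + 1L, g$end, g$strand, attrs),
      sprintf("%s\ttoy\texon\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, g$exons$start + 1L, g$exons$end, g$strand, attrs))
  }))
  writeLines(lines, path)
}

#' Write contig sequences as FASTA
#' @param sequences Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path)
}

#' Read contig sequences from FASTA
#' @param path FASTA path.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), sub("\\s.*", "", names(ss)))
}

# Strand-aware TSS of a gene.
gene_tss <- function(gene) if (gene$strand == "+") gene$start else gene$end

#' Plant motif consensus sites into promoters
#'
#' Each motif is tied to one cell group and acts as an activator: wherever
#' its consensus is written into a gene's promoter, that gene's expression
#' (and promoter accessibility) in the tied group is multiplied by
#' `expr_mult` (`acc_mult`) per planted copy. Sites are written on the gene
#' strand at fixed upstream offsets, never overlapping. Edited positions and
#' the resulting per-gene, per-group rate multipliers are recorded as the
#' generative truth.
#'
#' @param genome Output of [make_genome()].
#' @param pwms Named list of `pwm` objects, one per group (group i responds
#'   to motif i).
#' @param groups Character vector of group names (length = length(pwms)).
#' @param p_present Probability a (gene, motif) pair is planted.
#' @param expr_mult Expression multiplier per planted copy.
#' @param acc_mult Accessibility multiplier per planted copy.
#' @param seed RNG seed.
#' @return List: edited `sequences`, `truth` (instances table, rate
#'   multiplier matrices, configuration).
#' @export
plant_motifs <- function(genome, pwms, groups, p_present = 0.55,
                         expr_mult = 2.5, acc_mult = 2.0, seed = 1L) {
  stopifnot(length(pwms) == length(groups))
  set.seed(seed)
  seqs <- genome$sequences
  genes <- genome$genes
  inst <- list()
  expr_m <- matrix(1, length(genes), length(groups),
                   dimnames = list(names(genes), groups))
  acc_m <- expr_m
  for (gn in names(genes)) {
    gene <- genes[[gn]]
    tss <- gene_tss(gene)
    dir <- if (gene$strand == "+") -1L else 1L
    for (mi in seq_along(pwms)) {
      if (stats::runif(1) > p_present) next
      copies <- sample(1:3, 1L)
      cons <- pwm_consensus(pwms[[mi]])
      w <- nchar(cons)
      site <- if (gene$strand == "+") cons else reverse_complement(cons)
      for (k in seq_len(copies)) {
        # copies are planted in tandem (adjacent repeats), as multi-copy
        # promoter elements typically occur
        off <- 40L + (mi - 1L) * 220L + (k - 1L) * w
        s0 <- if (dir < 0L) tss - off - w else tss + off  # 0-based start
        if (s0 < 0L || s0 + w > nchar(seqs[[gene$chrom]])) next
        substr(seqs[[gene$chrom]], s0 + 1L, s0 + w) <- site
        inst[[length(inst) + 1L]] <- data.table::data.table(
          pwm = names(pwms)[mi], chrom = gene$chrom, start = s0,
          end = s0 + w, strand = gene$strand, gene = gn,
          group = groups[mi], copy = k)
      }
      expr_m[gn, mi] <- expr_mult^copies
      acc_m[gn, mi] <- acc_mult^copies
    }
  }
  truth <- list(instances = data.table::rbindlist(inst),
                expr_mult = expr_m, acc_mult = acc_m,
                groups = groups, pwm_names = names(pwms),
                expr_mult_per_copy = expr_mult, acc_mult_per_copy = acc_mult,
                seed = seed)
  list(sequences = seqs, truth = truth)
}

#' Generate a synthetic cell population
#'
#' Balanced group labels; group-informative embeddings (dimension D: the
#' first `n_groups` dimensions carry a separation of `sep` for the cell's
#' group plus isotropic noise, so groups are linearly separable) and
#' log-normal per-cell depth factors.
#'
#' @param n_cells Number of cells.
#' @param groups Character vector of group names.
#' @param d Embedding dimension (default 14).
#' @param sep Group separation (default 3).
#' @param noise Embedding noise SD.
#' @param depth_sdlog SD of log depth factors.
#' @param seed RNG seed.
#' @return List with `barcodes`, `labels`, `embeddings` (cells x D) and
#'   `depth` factors.
#' @export
make_population <- function(n_cells = 240L, groups = c("g1", "g2", "g3"),
                            d = 14L, sep = 3, noise = 0.4,
                            depth_sdlog = 0.35, seed = 1L) {
  set.seed(seed)
  labels <- rep(groups, length.out = n_cells)
  emb <- matrix(stats::rnorm(n_cells * d, sd = noise), n_cells, d)
  gi <- match(labels, groups)
  emb[cbind(seq_len(n_cells), gi)] <- emb[cbind(seq_len(n_cells), gi)] + sep
  barcodes <- sprintf("CELL%05d", seq_len(n_cells))
  rownames(emb) <- barcodes
  list(barcodes = barcodes, labels = labels, embeddings = emb,
       depth = stats::rlnorm(n_cells, 0, depth_sdlog))
}

# Map a transcript-coordinate interval [t0, t1) to genomic segments through
# the gene's exons (transcript direction follows the strand).
transcript_to_genomic <- function(gene, t0, t1) {
  widths <- gene$exons$end - gene$exons$start
  ord <- if (gene$strand == "+") seq_len(nrow(gene$exons)) else rev(seq_len(nrow(gene$exons)))
  segs_s <- integer(); segs_l <- integer()
  off <- 0L
  for (i in ord) {
    w <- widths[i]
    lo <- max(t0 - off, 0L); hi <- min(t1 - off, w)
    if (lo < hi) {
      if (gene$strand == "+") {
        segs_s <- c(segs_s, gene$exons$start[i] + lo)
      } else {
        segs_s <- c(segs_s, gene$exons$end[i] - hi)
      }
      segs_l <- c(segs_l, hi - lo)
    }
    off <- off + w
  }
  o <- order(segs_s)
  list(start = segs_s[o], len = segs_l[o])
}

#' Simulate RNA reads and ATAC fragments from the generative truth
#'
#' RNA read counts per (cell, gene) are Poisson with rate
#' `baseline * group multiplier * depth factor * depth`; reads are placed in
#' transcript coordinates (uniform, or 3'-biased with exponential weight
#' `exp(bias_3p * p)` toward the 3' end) and mapped through exons, so reads
#' spanning junctions become split records. ATAC fragments concentrate at
#' gene promoters with rate `atac_baseline * group multiplier * depth
#' factor`, plus uniform background. Returns the exact generative expected
#' count matrix alongside the records.
#'
#' @param genome_planted Edited genome (list with `sequences`, `seqlengths`).
#' @param genes `gene_models`.
#' @param truth Truth from [plant_motifs()].
#' @param population From [make_population()].
#' @param depth Global depth scaling.
#' @param baseline Baseline RNA reads per cell and gene.
#' @param atac_baseline Baseline promoter fragments per cell and gene.
#' @param atac_background Background fragments per cell and contig.
#' @param read_len RNA read length (transcript bp).
#' @param bias_3p 3' bias strength (0 = uniform).
#' @param seed RNG seed.
#' @return List with `rna` and `atac` `read_records` and `expected_counts`
#'   (cells x genes expected RNA reads).
#' @export
simulate_reads <- function(genome_planted, genes, truth, population,
                           depth = 1, baseline = 0.6, atac_baseline = 0.5,
                           atac_background = 0.3, read_len = 64L,
                           bias_3p = 0, seed = 1L) {
  set.seed(seed)
  n_cells <- length(population$barcodes)
  gi <- match(population$labels, truth$groups)
  gene_ids <- names(genes)
  # expected reads per cell x gene
  mult <- truth$expr_mult[gene_ids, , drop = FALSE]
  rate <- matrix(0, n_cells, length(gene_ids),
                 dimnames = list(population$barcodes, gene_ids))
  for (j in seq_along(gene_ids))
    rate[, j] <- baseline * depth * population$depth * mult[j, gi]
  rna <- list()
  rid_base <- 0L
  for (j in seq_along(gene_ids)) {
    gene <- genes[[gene_ids[j]]]
    counts <- stats::rpois(n_cells, rate[, j])
    tot <- sum(counts)
    if (tot == 0L) next
    cell_of <- rep(seq_len(n_cells), counts)
    widths <- gene$exons$end - gene$exons$start
    Lx <- sum(widths)
    eff <- max(Lx - read_len, 1L)
    if (bias_3p > 0) {
      u <- stats::runif(tot)
      p3 <- log1p(u * (exp(bias_3p) - 1)) / bias_3p  # density ~ exp(b*p) to 3'
      t0 <- as.integer(floor(p3 * eff))
    } else {
      t0 <- as.integer(floor(stats::runif(tot) * eff))
    }
    t1 <- pmin(t0 + read_len, Lx)
    # vectorized transcript->genome mapping: clip every read against every
    # exon (in transcript order) and keep nonempty pieces
    ord <- if (gene$strand == "+") seq_len(nrow(gene$exons)) else
      rev(seq_len(nrow(gene$exons)))
    off <- c(0L, cumsum(widths[ord]))[seq_along(ord)]
    seg_read <- integer(); seg_start <- integer(); seg_len <- integer()
    for (ei in seq_along(ord)) {
      i <- ord[ei]
      lo <- pmax(t0 - off[ei], 0L)
      hi <- pmin(t1 - off[ei], widths[i])
      sel <- which(lo < hi)
      if (!length(sel)) next
      gs <- if (gene$strand == "+") gene$exons$start[i] + lo[sel] else
        gene$exons$end[i] - hi[sel]
      seg_read <- c(seg_read, sel)
      seg_start <- c(seg_start, as.integer(gs))
      seg_len <- c(seg_len, as.integer(hi[sel] - lo[sel]))
    }
    rna[[length(rna) + 1L]] <- data.table::data.table(
      read_id = rid_base + seg_read,
      barcode = population$barcodes[cell_of[seg_read]],
      umi = sprintf("U%08d", rid_base + seg_read),
      chrom = gene$chrom, seg_start = seg_start, seg_len = seg_len,
      strand = gene$strand, assay = "RNA")
    rid_base <- rid_base + tot
  }
  rna <- if (length(rna)) data.table::rbindlist(rna) else
    empty_records("RNA")
  data.table::setorder(rna, read_id, seg_start)
  data.table::setattr(rna, "class", c("read_records", "data.table", "data.frame"))
  # ATAC: promoter-centered fragments + uniform background
  acc <- truth$acc_mult[gene_ids, , drop = FALSE]
  atac <- list()
  fid <- 0L
  for (j in seq_along(gene_ids)) {
    gene <- genes[[gene_ids[j]]]
    tss <- gene_tss(gene)
    counts <- stats::rpois(n_cells, atac_baseline * depth * population$depth * acc[j, gi])
    tot <- sum(counts)
    if (tot == 0L) next
    cell_of <- rep(seq_len(n_cells), counts)
    centers <- as.integer(round(tss + stats::rnorm(tot, 0, 80)))
    lens <- pmax(30L, as.integer(round(stats::rnorm(tot, 90, 25))))
    starts <- pmax(0L, centers - lens %/% 2L)
    cl <- genome_planted$seqlengths[[gene$chrom]]
    lens <- pmin(lens, cl - starts)
    atac[[length(atac) + 1L]] <- data.table::data.table(
      read_id = fid + seq_len(tot), barcode = population$barcodes[cell_of],
      umi = NA_character_, chrom = gene$chrom, seg_start = starts,
      seg_len = lens, strand = ".", assay = "ATAC")
    fid <- fid + tot
  }
  for (ch in names(genome_planted$seqlengths)) {
    counts <- stats::rpois(n_cells, atac_background * depth * population$depth)
    tot <- sum(counts)
    if (tot == 0L) next
    cell_of <- rep(seq_len(n_cells), counts)
    cl <- genome_planted$seqlengths[[ch]]
    starts <- as.integer(floor(stats::runif(tot) * (cl - 150L)))
    lens <- pmax(30L, as.integer(round(stats::rnorm(tot, 90, 25))))
    atac[[length(atac) + 1L]] <- data.table::data.table(
      read_id = fid + seq_len(tot), barcode = population$barcodes[cell_of],
      umi = NA_character_, chrom = ch, seg_start = starts,
      seg_len = pmin(lens, cl - starts), strand = ".", assay = "ATAC")
    fid <- fid + tot
  }
  atac <- if (length(atac)) data.table::rbindlist(atac) else
    empty_records("ATAC")
  data.table::setattr(atac, "class", c("read_records", "data.table", "data.frame"))
  list(rna = rna, atac = atac, expected_counts = rate)
}

#' Derive motif-destroying and null variants from the truth
#'
#' For up to `n_planted` planted sites (at most one per gene x motif), the
#' maximally score-reducing single-nucleotide substitution within the
#' consensus is recorded; the expected effect sign in the responsive group is
#' negative (activator destroyed). Null variants are placed at least 100 bp
#' from any planted site near gene centers, with a random alternative allele
#' and expected negligible effect.
#'
#' @param genome_planted Edited genome.
#' @param genes `gene_models`.
#' @param truth From [plant_motifs()].
#' @param pwms The planted PWM list.
#' @param n_planted,n_null Numbers of variants of each kind.
#' @param seed RNG seed.
#' @return data.table: chrom, pos0 (0-based), ref, alt, gene, kind
#'   ("planted"/"null"), group, expected_sign.
#' @export
make_variants <- function(genome_planted, genes, truth, pwms,
                          n_planted = 8L, n_null = 8L, seed = 1L) {
  set.seed(seed)
  inst <- truth$instances[truth$instances$copy == 1L]
  inst <- inst[sample(nrow(inst))]
  inst <- inst[!duplicated(inst$gene)]
  inst <- inst[seq_len(min(n_planted, nrow(inst)))]
  rows <- list()
  for (i in seq_len(nrow(inst))) {
    p <- pwms[[inst$pwm[i]]]
    m <- p$matrix
    # strongest column: largest drop from consensus to worst base
    drop <- apply(m, 1L, function(r) log(max(r)) - log(min(r)))
    jpos <- which.max(drop)
    worst <- DNA_CHANNELS[which.min(m[jpos, ])]
    if (inst$strand[i] == "+") {
      pos0 <- inst$start[i] + jpos - 1L
      alt <- worst
    } else {
      pos0 <- inst$end[i] - jpos
      alt <- chartr("ACGT", "TGCA", worst)
    }
    ref <- substr(genome_planted$sequences[[inst$chrom[i]]], pos0 + 1L, pos0 + 1L)
    rows[[length(rows) + 1L]] <- data.table::data.table(
      chrom = inst$chrom[i], pos0 = pos0, ref = ref, alt = alt,
      gene = inst$gene[i], kind = "planted", group = inst$group[i],
      expected_sign = -1L)
  }
  # null variants: near gene centers, >= 100 bp from any planted site
  all_inst <- truth$instances
  gene_pool <- sample(names(genes))
  added <- 0L
  for (gn in gene_pool) {
    if (added >= n_null) break
    gene <- genes[[gn]]
    for (try in 1:20) {
      pos0 <- gene_center(gene) + sample(-1500:1500, 1L)
      near <- which(all_inst$chrom == gene$chrom &
                      pos0 >= all_inst$start - 100L &
                      pos0 < all_inst$end + 100L)
      if (length(near)) next
      ref <- substr(genome_planted$sequences[[gene$chrom]], pos0 + 1L, pos0 + 1L)
      alt <- sample(setdiff(DNA_CHANNELS, ref), 1L)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        chrom = gene$chrom, pos0 = pos0, ref = ref, alt = alt,
        gene = gn, kind = "null", group = NA_character_,
        expected_sign = 0L)
      added <- added + 1L
      break
    }
  }
  data.table::rbindlist(rows)
}

#' Generate a complete synthetic multiome fixture
#'
#' Orchestrates genome generation, motif planting, the cell population, read
#' simulation, the coverage store, and variant derivation. The `tiny` preset
#' (12 contigs of 65,536 bp, 20 genes each, 3 groups, 240 cells) runs full
#' train-evaluate-interpret cycles on one CPU in minutes; `full-geometry`
#' (one 524,288-bp contig) supports full-scale-window architecture tests.
#' Optionally writes FASTA, GTF, fragment TSV, embedding CSV, variant TSV and
#' truth JSON to `out_dir`.
#'
#' @param preset "tiny" or "full-geometry".
#' @param seed RNG seed (all stages derive from it).
#' @param out_dir Optional output directory.
#' @param ... Overrides passed to [simulate_reads()].
#' @return List: `genome` (planted), `genes`, `pwms`, `truth`, `population`,
#'   `reads`, `store`, `variants`.
#' @export
simulate_multiome <- function(preset = c("tiny", "full-geometry"), seed = 1L,
                              out_dir = NULL, ...) {
  preset <- match.arg(preset)
  if (preset == "tiny") {
    gen <- make_genome(n_contigs = 12L, length = 65536L, genes_per_contig = 20L,
                       seed = seed)
  } else {
    gen <- make_genome(n_contigs = 1L, length = 524288L * 2L,
                       genes_per_contig = 8L, seed = seed)
  }
  pwms <- toy_pwms(3L)
  groups <- c("g1", "g2", "g3")
  planted <- plant_motifs(gen, pwms, groups, seed = seed + 1L)
  genome <- list(sequences = planted$sequences, seqlengths = gen$seqlengths,
                 genes = gen$genes)
  population <- make_population(seed = seed + 2L)
  reads <- simulate_reads(genome, gen$genes, planted$truth, population,
                          seed = seed + 3L, ...)
  ins <- fragments_to_insertions(reads$atac)
  store <- build_store(reads$rna, ins, whitelist = population$barcodes,
                       seqlengths = gen$seqlengths, genome_id = preset)
  variants <- make_variants(genome, gen$genes, planted$truth, pwms,
                            seed = seed + 4L)
  out <- list(genome = genome, genes = gen$genes, pwms = pwms,
              truth = planted$truth, population = population, reads = reads,
              store = store, variants = variants)
  if (!is.null(out_dir)) write_fixture(out, out_dir)
  out
}

write_fixture <- function(fx, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(fx$genome$sequences, file.path(out_dir, "genome.fa"))
  write_gtf(fx$genes, file.path(out_dir, "genes.gtf"))
  fr <- fx$reads$atac
  data.table::fwrite(
    data.table::data.table(chrom = fr$chrom, start = fr$seg_start,
                           end = fr$seg_start + fr$seg_len,
                           barcode = fr$barcode),
    file.path(out_dir, "fragments.tsv"), sep = "\t", col.names = FALSE)
  emb <- data.table::data.table(barcode = fx$population$barcodes,
                                group = fx$population$labels)
  emb <- cbind(emb, data.table::as.data.table(fx$population$embeddings))
  data.table::fwrite(emb, file.path(out_dir, "embeddings.csv"))
  data.table::fwrite(fx$variants, file.path(out_dir, "variants.tsv"), sep = "\t")
  write_meme(fx$pwms, file.path(out_dir, "motifs.meme"))
  jsonlite::write_json(
    list(groups = fx$truth$groups,
         expr_mult = as.data.frame(fx$truth$expr_mult),
         acc_mult = as.data.frame(fx$truth$acc_mult),
         instances = fx$truth$instances,
         seed = fx$truth$seed),
    file.path(out_dir, "truth.json"), dataframe = "columns")
  invisible(out_dir)
}
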