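# Per-cell coverage archive: alignments/fragments -> compact archive ->
# binned, squashed-scale target tracks.
#
# Coordinates are 0-based, half-open everywhere internally. Read records are
# kept as a data.table with one row per aligned segment (read_id groups the
# segments of one split read); this is the R-idiomatic form of a record list
# and keeps grouping/dedup operations vectorized.

#' @import data.table
NULL

#' Construct a read-record table
#'
#' One row per aligned segment; `read_id` groups split-read segments. RNA
#' records may have several segments (split reads); ATAC records have exactly
#' one (the fragment).
#'
#' @param read_id Integer id shared by segments of one read.
#' @param barcode,umi Cell barcode and UMI (`NA` allowed for UMI/ATAC).
#' @param chrom Chromosome name.
#' @param seg_start 0-based segment start.
#' @param seg_len Segment length (>= 1).
#' @param strand "+", "-" or ".".
#' @param assay "RNA" or "ATAC".
#' @return A `read_records` data.table.
#' @export
read_records <- function(read_id, barcode, umi = NA_character_, chrom,
                         seg_start, seg_len, strand = ".", assay = "RNA") {
  dt <- data.table::data.table(
    read_id = as.integer(read_id), barcode = as.character(barcode),
    umi = as.character(umi), chrom = as.character(chrom),
    seg_start = as.integer(seg_start), seg_len = as.integer(seg_len),
    strand = as.character(strand), assay = as.character(assay))
  if (any(dt$seg_len < 1L)) stop("segment lengths must be >= 1")
  data.table::setattr(dt, "class", c("read_records", class(dt)))
  dt[]
}

# Parse a CIGAR string into reference-space blocks (start offsets + lengths,
# relative to the alignment position). N gaps split blocks; I/S/H consume no
# reference; M/=/X/D extend the current block.
cigar_blocks <- function(cigar) {
  m <- gregexpr("([0-9]+)([MIDNSHP=X])", cigar)[[1]]
  if (m[1] == -1 || sum(attr(m, "match.length")) != nchar(cigar))
    stop("malformed CIGAR: ", cigar)
  parts <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[MIDNSHP=X]$", "", parts))
  ops <- sub("^[0-9]+", "", parts)
  off <- 0L
  cur_start <- NA_integer_
  cur_len <- 0L
  starts <- integer()
  blens <- integer()
  for (i in seq_along(ops)) {
    op <- ops[i]; l <- lens[i]
    if (op %in% c("M", "=", "X", "D")) {
      if (is.na(cur_start)) { cur_start <- off; cur_len <- 0L }
      cur_len <- cur_len + l
      off <- off + l
    } else if (op == "N") {
      if (!is.na(cur_start)) { starts <- c(starts, cur_start); blens <- c(blens, cur_len) }
      cur_start <- NA_integer_
      off <- off + l
    }
    # I, S, H, P consume no reference space
  }
  if (!is.na(cur_start)) { starts <- c(starts, cur_start); blens <- c(blens, cur_len) }
  if (length(starts) == 0L) stop("CIGAR with no reference-consuming op: ", cigar)
  list(starts = starts, lens = blens)
}

#' Parse alignments into read records
#'
#' Accepts a BAM file path or an in-memory data.frame of alignment fields
#' (`chrom`, `pos` 1-based, `cigar`, `strand`, plus barcode/umi/validity-flag
#' columns). Split RNA alignments yield one record with one segment per
#' aligned block (intron `N` gaps split, soft clips are dropped). Records
#' failing the validity flag (`xf == 25`, when required) are excluded.
#' Duplicates are removed: RNA on identical (barcode, umi, chrom,
#' first-segment start) — falling back to the full segment signature when no
#' UMIs are present — and ATAC on identical (barcode, chrom, segment).
#' Records missing the barcode tag are skipped with a counted warning.
#'
#' @param alignments BAM path or data.frame.
#' @param assay "RNA" or "ATAC".
#' @param barcode_tag,umi_tag BAM tag names (default "CB"/"UB").
#' @param require_valid_flag Keep only alignments with `xf == 25`.
#' @return A `read_records` data.table.
#' @export
parse_alignments <- function(alignments, assay = c("RNA", "ATAC"),
                             barcode_tag = "CB", umi_tag = "UB",
                             require_valid_flag = FALSE) {
  assay <- match.arg(assay)
  if (is.character(alignments) && length(alignments) == 1L) {
    aln <- read_bam_fields(alignments, barcode_tag, umi_tag)
  } else {
    aln <- as.data.frame(alignments, stringsAsFactors = FALSE)
  }
  if (!nrow(aln)) return(empty_records(assay))
  if (is.null(aln$xf)) aln$xf <- NA_integer_
  if (is.null(aln$umi)) aln$umi <- NA_character_
  if (is.null(aln$strand)) aln$strand <- "."
  if (require_valid_flag) aln <- aln[!is.na(aln$xf) & aln$xf == 25L, , drop = FALSE]
  no_bc <- is.na(aln$barcode) | aln$barcode == ""
  if (any(no_bc)) {
    warning(sum(no_bc), " record(s) skipped: missing barcode tag")
    aln <- aln[!no_bc, , drop = FALSE]
  }
  if (!nrow(aln)) return(empty_records(assay))
  blocks <- lapply(aln$cigar, cigar_blocks)
  nseg <- vapply(blocks, function(b) length(b$starts), integer(1))
  if (assay == "ATAC" && any(nseg != 1L))
    stop("ATAC alignments must map to a single reference block")
  dt <- data.table::data.table(
    read_id = rep(seq_len(nrow(aln)), nseg),
    barcode = rep(aln$barcode, nseg),
    umi = rep(as.character(aln$umi), nseg),
    chrom = rep(as.character(aln$chrom), nseg),
    seg_start = as.integer(rep(aln$pos - 1L, nseg) +
                             unlist(lapply(blocks, `[[`, "starts"))),
    seg_len = as.integer(unlist(lapply(blocks, `[[`, "lens"))),
    strand = rep(as.character(aln$strand), nseg),
    assay = assay)
  dedup_records(dt, assay)
}

empty_records <- function(assay) {
  read_records(integer(), character(), character(), character(),
               integer(), integer(), character(), character())
}

dedup_records <- function(dt, assay) {
  first_start <- seg_len <- seg_start <- read_id <- NULL
  if (assay == "RNA") {
    firsts <- dt[, list(first_start = min(seg_start),
                        sig = paste(seg_start, seg_len, collapse = ";")),
                 by = "read_id"]
    meta <- dt[, list(barcode = barcode[1L], umi = umi[1L], chrom = chrom[1L]),
               by = "read_id"]
    meta <- merge(meta, firsts, by = "read_id", sort = FALSE)
    if (all(is.na(meta$umi))) {
      keep <- meta[!duplicated(meta[, c("barcode", "chrom", "sig")]), read_id]
    } else {
      keep <- meta[!duplicated(meta[, c("barcode", "umi", "chrom", "first_start")]),
                   read_id]
    }
  } else {
    keep <- dt[!duplicated(dt[, c("barcode", "chrom", "seg_start", "seg_len")]),
               read_id]
  }
  out <- dt[read_id %in% keep]
  data.table::setattr(out, "class", c("read_records", class(data.table::data.table())))
  out[]
}

read_bam_fields <- function(path, barcode_tag, umi_tag) {
  param <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "cigar", "strand", "flag"),
    tag = c(barcode_tag, umi_tag, "xf"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  data.frame(chrom = as.character(b$rname), pos = b$pos, cigar = b$cigar,
             strand = as.character(b$strand),
             barcode = if (is.null(b$tag[[barcode_tag]])) NA_character_ else b$tag[[barcode_tag]],
             umi = if (is.null(b$tag[[umi_tag]])) NA_character_ else b$tag[[umi_tag]],
             xf = if (is.null(b$tag$xf)) NA_integer_ else b$tag$xf,
             stringsAsFactors = FALSE)
}

#' Read a fragment file
#'
#' BED-like (bgzipped or plain) TSV of ATAC fragments: chrom, start, end,
#' barcode, with 0-based half-open coordinates. Returns single-segment ATAC
#' read records.
#'
#' @param path Fragment file path.
#' @return A `read_records` data.table (assay ATAC).
#' @export
read_fragments <- function(path) {
  fr <- data.table::fread(path, header = FALSE)
  data.table::setnames(fr, seq_len(min(4L, ncol(fr))),
                       c("chrom", "start", "end", "barcode")[seq_len(min(4L, ncol(fr)))])
  dt <- read_records(seq_len(nrow(fr)), fr$barcode, NA_character_, fr$chrom,
                     fr$start, fr$end - fr$start, ".", "ATAC")
  dedup_records(dt, "ATAC")
}

#' Convert ATAC fragments to Tn5 insertion sites
#'
#' Each fragment yields exactly two insertion events: one at the fragment
#' start and one at `end - 1` (the last covered base). Input fragments are
#' assumed already Tn5-shifted by the upstream pipeline; an optional
#' `end_offset` lets callers switch to the half-open-end convention.
#'
#' @param records ATAC `read_records`.
#' @param end_offset Offset added to the fragment end (default -1: last
#'   covered base).
#' @return data.table with columns barcode, chrom, pos (0-based).
#' @export
fragments_to_insertions <- function(records, end_offset = -1L) {
  if (nrow(records) && any(records$assay != "ATAC"))
    stop("fragments_to_insertions expects ATAC records only")
  data.table::data.table(
    barcode = rep(records$barcode, 2L),
    chrom = rep(records$chrom, 2L),
    pos = c(records$seg_start,
            records$seg_start + records$seg_len - 1L + as.integer(end_offset) + 1L))
}

#' Build a per-cell coverage store
#'
#' Retains only whitelisted barcodes and archives RNA read segments (stranded)
#' and ATAC insertion events per chromosome for ranged binned extraction.
#'
#' @param rna_records RNA `read_records` (or NULL).
#' @param atac_insertions Insertion table from [fragments_to_insertions()]
#'   (or NULL).
#' @param whitelist Non-empty character vector of cell barcodes; fixes the
#'   cell ordering of the store.
#' @param seqlengths Named integer vector of chromosome lengths.
#' @param genome_id Free-text genome identifier.
#' @return A `coverage_store`.
#' @export
build_store <- function(rna_records = NULL, atac_insertions = NULL, whitelist,
                        seqlengths, genome_id = "synthetic") {
  if (length(whitelist) == 0L) stop("whitelist must be non-empty")
  whitelist <- as.character(whitelist)
  chk_chrom <- function(ch) {
    bad <- setdiff(unique(ch), names(seqlengths))
    if (length(bad)) stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  }
  rna <- data.table::data.table(cell = integer(), chrom = character(),
                                start = integer(), len = integer(),
                                strand = character())
  atac <- data.table::data.table(cell = integer(), chrom = character(),
                                 pos = integer())
  if (!is.null(rna_records) && nrow(rna_records)) {
    chk_chrom(rna_records$chrom)
    idx <- match(rna_records$barcode, whitelist)
    keep <- !is.na(idx)
    rna <- data.table::data.table(cell = idx[keep],
                                  chrom = rna_records$chrom[keep],
                                  start = rna_records$seg_start[keep],
                                  len = rna_records$seg_len[keep],
                                  strand = rna_records$strand[keep])
    data.table::setkey(rna, chrom, start)
  }
  if (!is.null(atac_insertions) && nrow(atac_insertions)) {
    chk_chrom(atac_insertions$chrom)
    idx <- match(atac_insertions$barcode, whitelist)
    keep <- !is.na(idx)
    atac <- data.table::data.table(cell = idx[keep],
                                   chrom = atac_insertions$chrom[keep],
                                   pos = atac_insertions$pos[keep])
    data.table::setkey(atac, chrom, pos)
  }
  if (!nrow(rna) && !nrow(atac))
    warning("coverage store is empty after whitelisting")
  structure(list(cells = whitelist, rna = rna, atac = atac,
                 seqlengths = seqlengths, genome_id = genome_id),
            class = "coverage_store")
}

#' @export
print.coverage_store <- function(x, ...) {
  cat(sprintf("coverage_store: %d cells, %d RNA segments, %d ATAC insertions, %d contig(s)\n",
              length(x$cells), nrow(x$rna), nrow(x$atac), length(x$seqlengths)))
  invisible(x)
}

#' Serialize / load a coverage store
#'
#' Writes a portable columnar text layout (TSV tables plus JSON metadata)
#' that round-trips the store losslessly.
#' @param store A `coverage_store`.
#' @param dir Output directory (created if needed).
#' @return `write_store`: the directory, invisibly. `read_store`: the store.
#' @export
write_store <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(store$rna, file.path(dir, "rna_segments.tsv"), sep = "\t")
  data.table::fwrite(store$atac, file.path(dir, "atac_insertions.tsv"), sep = "\t")
  writeLines(store$cells, file.path(dir, "cells.txt"))
  jsonlite::write_json(list(genome_id = store$genome_id,
                            seqlengths = as.list(store$seqlengths)),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_store
#' @export
read_store <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  rna <- data.table::fread(file.path(dir, "rna_segments.tsv"),
                           colClasses = list(character = c("chrom", "strand")))
  atac <- data.table::fread(file.path(dir, "atac_insertions.tsv"),
                            colClasses = list(character = "chrom"))
  if (!nrow(rna)) rna <- data.table::data.table(cell = integer(), chrom = character(),
                                                start = integer(), len = integer(),
                                                strand = character())
  if (!nrow(atac)) atac <- data.table::data.table(cell = integer(), chrom = character(),
                                                  pos = integer())
  data.table::setkey(rna, chrom, start)
  data.table::setkey(atac, chrom, pos)
  structure(list(cells = readLines(file.path(dir, "cells.txt")),
                 rna = rna, atac = atac,
                 seqlengths = unlist(meta$seqlengths),
                 genome_id = meta$genome_id),
            class = "coverage_store")
}

#' Extract binned per-cell coverage over an interval
#'
#' RNA bin values are total per-base read coverage within the bin (sum of
#' segment overlap lengths), per strand; ATAC bin values count insertion
#' events. Data outside the interval is ignored.
#'
#' @param store A `coverage_store`.
#' @param chrom,start,end Interval (0-based, half-open); length must be a
#'   multiple of `bin_width`.
#' @param assay "RNA" or "ATAC".
#' @param cells Integer indices into `store$cells` (default: all).
#' @param bin_width Bin width in bp (default 32).
#' @return A `binned_track`: list with `values` array
#'   `(cells x strands x bins)` (strands: RNA "+","-"; ATAC "*"),
#'   interval fields, and `transformed = FALSE`.
#' @export
extract_binned <- function(store, chrom, start, end, assay = c("RNA", "ATAC"),
                           cells = NULL, bin_width = 32L) {
  assay <- match.arg(assay)
  start <- as.integer(start); end <- as.integer(end)
  if ((end - start) %% bin_width != 0L)
    stop("interval length must be divisible by bin_width")
  if (is.null(cells)) cells <- seq_along(store$cells)
  nb <- (end - start) %/% bin_width
  nc <- length(cells)
  strands <- if (assay == "RNA") c("+", "-") else "*"
  vals <- array(0, dim = c(nc, length(strands), nb),
                dimnames = list(store$cells[cells], strands, NULL))
  cell_row <- integer(length(store$cells))
  cell_row[cells] <- seq_along(cells)
  qs <- start; qe <- end
  if (assay == "RNA" && nrow(store$rna)) {
    seg <- store$rna[chrom, on = "chrom", nomatch = NULL]
    seg <- seg[seg$cell %in% cells & seg$start + seg$len > qs & seg$start < qe]
    if (nrow(seg)) {
      s <- pmax(seg$start, start); e <- pmin(seg$start + seg$len, end)
      fb <- (s - start) %/% bin_width
      lb <- (e - 1L - start) %/% bin_width
      nspan <- lb - fb + 1L
      idx <- rep(seq_along(s), nspan)
      bin <- fb[idx] + (sequence(nspan) - 1L)
      bs <- start + bin * bin_width
      ov <- pmin(e[idx], bs + bin_width) - pmax(s[idx], bs)
      si <- ifelse(seg$strand[idx] == "-", 2L, 1L)
      acc <- data.table::data.table(r = cell_row[seg$cell[idx]], s = si,
                                    b = bin + 1L, v = ov)
      acc <- acc[, list(v = sum(v)), by = c("r", "s", "b")]
      vals[cbind(acc$r, acc$s, acc$b)] <- acc$v
    }
  } else if (assay == "ATAC" && nrow(store$atac)) {
    ins <- store$atac[chrom, on = "chrom", nomatch = NULL]
    ins <- ins[ins$cell %in% cells & ins$pos >= qs & ins$pos < qe]
    if (nrow(ins)) {
      acc <- data.table::data.table(r = cell_row[ins$cell],
                                    b = (ins$pos - start) %/% bin_width + 1L)
      acc <- acc[, list(v = .N), by = c("r", "b")]
      vals[cbind(acc$r, 1L, acc$b)] <- acc$v
    }
  }
  structure(list(chrom = chrom, start = start, end = end, assay = assay,
                 bin_width = as.integer(bin_width), values = vals,
                 transformed = FALSE),
            class = "binned_track")
}

# --- squashed-scale transform ----------------------------------------------

#' Target transform (squashed scale)
#'
#' Variance-stabilizing transform applied to training targets: values are
#' power-compressed (`v^exponent`) and soft-clipped above `clip_soft`
#' (`clip_soft + sqrt(v - clip_soft)`). ATAC values are additionally scaled
#' by `atac_scale` before squashing to put insertion counts on the same scale
#' as RNA coverage; the inverse rescales by `1/atac_scale` (20 at defaults).
#'
#' @param clip_soft Soft-clip threshold (default 5).
#' @param atac_scale ATAC pre-scaling factor (default 0.05).
#' @param exponent Compression exponent (default 3/4).
#' @return A `target_transform`.
#' @export
target_transform <- function(clip_soft = 5, atac_scale = 0.05, exponent = 3 / 4) {
  structure(list(clip_soft = clip_soft, atac_scale = atac_scale,
                 exponent = exponent), class = "target_transform")
}

squash_values <- function(x, transform, assay = "RNA") {
  if (any(x < 0)) stop("squash transform requires nonnegative input")
  if (assay == "ATAC") x <- x * transform$atac_scale
  u <- x^transform$exponent
  hi <- u > transform$clip_soft
  u[hi] <- transform$clip_soft + sqrt(u[hi] - transform$clip_soft)
  u
}

unsquash_values <- function(y, transform, assay = "RNA") {
  u <- y
  hi <- y > transform$clip_soft
  u[hi] <- transform$clip_soft + (y[hi] - transform$clip_soft)^2
  x <- pmax(u, 0)^(1 / transform$exponent)
  if (assay == "ATAC") x <- x / transform$atac_scale
  x
}

#' Apply / invert the squashed-scale transform on a binned track
#'
#' @param track A `binned_track`.
#' @param transform A [target_transform()].
#' @return The transformed (or restored) track.
#' @export
apply_transform <- function(track, transform = target_transform()) {
  if (isTRUE(track$transformed)) stop("track already transformed")
  track$values[] <- squash_values(track$values, transform, track$assay)
  track$transformed <- TRUE
  track
}

#' @rdname apply_transform
#' @export
invert_transform <- function(track, transform = target_transform()) {
  if (!isTRUE(track$transformed)) stop("track is not on the transformed scale")
  track$values[] <- unsquash_values(track$values, transform, track$assay)
  track$transformed <- FALSE
  track
}

# --- pseudobulk export ------------------------------------------------------

#' Export pseudobulk coverage to bigWig
#'
#' Writes one bigWig per cell group (two per group for RNA: plus and minus
#' strand; one for ATAC insertions). Per-base values sum over group members.
#'
#' @param store A `coverage_store`.
#' @param group_labels Character vector, one label per store cell.
#' @param out_dir Output directory.
#' @return Named character vector of written files, invisibly.
#' @export
export_pseudobulk_bigwig <- function(store, group_labels, out_dir) {
  if (length(group_labels) != length(store$cells))
    stop("group_labels must cover all cells")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sl <- store$seqlengths
  files <- character()
  for (g in unique(group_labels)) {
    cells <- which(group_labels == g)
    segs <- store$rna[cell %in% cells]
    ins <- store$atac[cell %in% cells]
    if (!nrow(segs) && !nrow(ins))
      warning("group '", g, "' has no data; writing zero tracks")
    for (strand in c("+", "-")) {
      ss <- segs[segs$strand == strand]
      cov <- coverage_rlelist(ss$chrom, ss$start, ss$start + ss$len, sl)
      f <- file.path(out_dir, paste0(g, "_rna_", ifelse(strand == "+", "plus", "minus"), ".bw"))
      rtracklayer::export.bw(cov, f)
      files[[paste0(g, "_rna_", strand)]] <- f
    }
    cov <- coverage_rlelist(ins$chrom, ins$pos, ins$pos + 1L, sl)
    f <- file.path(out_dir, paste0(g, "_atac.bw"))
    rtracklayer::export.bw(cov, f)
    files[[paste0(g, "_atac")]] <- f
  }
  invisible(files)
}

coverage_rlelist <- function(chrom, start, end, seqlengths) {
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = names(seqlengths)),
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    seqlengths = seqlengths)
  GenomicRanges::coverage(gr)
}

# --- embedding-input feature filter ----------------------------------------

#' Filter leaky and rare features before embedding computation
#'
#' Removes features (genes/peaks) overlapping any held-out (validation/test)
#' genomic region, to prevent information leakage from the embedding into
#' prediction, and features detected in fewer than `min_prevalence` of cells.
#' Input order is preserved.
#'
#' @param features `GRanges` of feature intervals.
#' @param heldout_regions `GRanges` of held-out regions.
#' @param counts Feature x cell matrix of detection counts (a feature is
#'   "detected" in a cell when its count is > 0). NULL skips the prevalence
#'   filter.
#' @param min_prevalence Minimum detected fraction of cells (default 0.01).
#' @return Logical keep-mask over features.
#' @export
filter_leaky_features <- function(features, heldout_regions, counts = NULL,
                                  min_prevalence = 0.01) {
  keep <- rep(TRUE, length(features))
  if (length(heldout_regions)) {
    hits <- GenomicRanges::findOverlaps(features, heldout_regions)
    keep[unique(S4Vectors::queryHits(hits))] <- FALSE
  }
  if (!is.null(counts)) {
    prevalence <- rowMeans(counts > 0)
    keep <- keep & prevalence >= min_prevalence
  }
  keep
}
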