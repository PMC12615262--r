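# Shared toy builders for the test suite.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

toy_geometry <- function(input_length = 2048L, E = 16L) {
  model_geometry(input_length = input_length, bin_width = 32L,
                 embedding_width = E)
}

toy_backbone <- function(geometry = toy_geometry(), channels = 8L, seed = 1L) {
  make_mini_backbone(geometry, channels = channels, n_conv = 2L, n_attn = 1L,
                     seed = seed)
}

# Brute-force per-base accumulation oracle for binned extraction.
brute_binned <- function(segments, start, end, bin_width) {
  # segments: data.frame(start, len); returns per-bin sums of base coverage
  cov <- numeric(end - start)
  for (i in seq_len(nrow(segments))) {
    s <- max(segments$start[i], start)
    e <- min(segments$start[i] + segments$len[i], end)
    if (s < e) {
      idx <- (s - start + 1L):(e - start)
      cov[idx] <- cov[idx] + 1
    }
  }
  colSums(matrix(cov, nrow = bin_width))
}

toy_store <- function(rna = NULL, atac = NULL, cells = c("c1", "c2"),
                      len = 1024L, chroms = "chr1") {
  build_store(rna, atac, whitelist = cells,
              seqlengths = stats::setNames(rep(len, length(chroms)), chroms))
}
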