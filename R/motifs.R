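# PWM machinery: MEME reading, exact-p-value log-odds scanning (dynamic
# programming over the discretized score distribution, FIMO-style), in silico
# motif replacement, and gradient-weighted PWMs.

#' Construct a position weight matrix
#'
#' @param matrix Numeric matrix `(positions x 4)`, columns A, C, G, T; rows
#'   must sum to 1 within 1e-6 (a pseudocount is applied on read to avoid
#'   zeros).
#' @param name Motif name.
#' @param background Background nucleotide probabilities (default uniform).
#' @param pseudocount Added to every entry before renormalization.
#' @return A `pwm` object.
#' @export
pwm <- function(matrix, name = "motif", background = rep(0.25, 4),
                pseudocount = 1e-4) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4L) stop("PWM must have 4 columns (A, C, G, T)")
  if (any(abs(rowSums(matrix) - 1) > 1e-6))
    stop("PWM rows must sum to 1")
  if (any(matrix < 0)) stop("PWM probabilities must be nonnegative")
  matrix <- matrix + pseudocount
  matrix <- matrix / rowSums(matrix)
  colnames(matrix) <- DNA_CHANNELS
  structure(list(name = name, matrix = matrix, background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': %d positions, consensus %s\n", x$name,
              nrow(x$matrix), pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM
#' @param p A `pwm`.
#' @return Character scalar.
#' @export
pwm_consensus <- function(p) {
  paste(DNA_CHANNELS[apply(p$matrix, 1L, which.max)], collapse = "")
}

#' Read PWMs from a MEME-format file
#'
#' Parses `MOTIF` blocks with their letter-probability matrices; alphabet is
#' assumed ACGT.
#'
#' @param path MEME file path.
#' @param pseudocount Pseudocount applied to each PWM.
#' @return Named list of `pwm` objects.
#' @export
read_meme <- function(path, pseudocount = 1e-4) {
  lines <- readLines(path)
  starts <- grep("^MOTIF", lines)
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(sub("^MOTIF", "", lines[s])), "\\s+")[[1]][1]
    h <- grep("^letter-probability matrix", lines[s:length(lines)])[1] + s - 1L
    w <- suppressWarnings(as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[h])))
    rows <- lines[(h + 1L):(h + w)]
    m <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
    out[[name]] <- pwm(m, name, pseudocount = pseudocount)
  }
  out
}

#' Write PWMs to a MEME-format file
#' @param pwms List of `pwm` objects.
#' @param path Output file.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       nrow(p$matrix)), con)
    for (i in seq_len(nrow(p$matrix)))
      writeLines(paste(sprintf("%.6f", p$matrix[i, ]), collapse = " "), con)
    writeLines("", con)
  }
}

# Reverse-complement a PWM (positions reversed, A<->T, C<->G).
pwm_rc <- function(p) {
  m <- p$matrix[rev(seq_len(nrow(p$matrix))), c(4L, 3L, 2L, 1L), drop = FALSE]
  colnames(m) <- DNA_CHANNELS
  structure(list(name = p$name, matrix = m, background = p$background),
            class = "pwm")
}

# Exact null distribution of the integerized log-odds score under the
# background, by dynamic programming: at each position, convolve the current
# score distribution with the position's 4 (score, background prob) pairs.
# Returns the p-value function P(score >= s) on the integer grid.
pwm_score_dp <- function(score_int, background) {
  w <- nrow(score_int)
  offset <- -apply(score_int, 1L, min)
  span <- apply(score_int, 1L, max) + offset  # per-position nonneg range
  total <- sum(span)
  dist <- numeric(total + 1L)
  dist[1L] <- 1
  cur_max <- 0L
  for (i in seq_len(w)) {
    nd <- numeric(total + 1L)
    sc <- score_int[i, ] + offset[i]
    for (b in 1:4) {
      idx <- seq_len(cur_max + 1L)
      nd[idx + sc[b]] <- nd[idx + sc[b]] + dist[idx] * background[b]
    }
    dist <- nd
    cur_max <- cur_max + span[i]
  }
  tail_p <- rev(cumsum(rev(dist)))  # P(S_int >= k), k = 0..total
  list(tail_p = tail_p, offset_total = sum(offset))
}

pwm_pvalue_fun <- function(p, granularity = 1e-3) {
  score_int <- round(log(p$matrix / rep(p$background, each = nrow(p$matrix))) /
                       granularity)
  storage.mode(score_int) <- "integer"
  dp <- pwm_score_dp(score_int, p$background)
  list(score_int = score_int,
       pvalue = function(s_int) {
         k <- s_int + dp$offset_total
         k <- pmin(pmax(k, 0L), length(dp$tail_p) - 1L)
         dp$tail_p[k + 1L]
       })
}

#' Scan a sequence for PWM hits with exact p-values
#'
#' Scores every window on both strands with the log-odds score
#' `sum(log(p_base / background))` and converts scores to p-values with an
#' exact dynamic program over the PWM's discretized score distribution
#' (granularity 1e-3). Windows containing N are skipped. Hits with
#' `p <= threshold` are returned sorted by position.
#'
#' @param sequence Character scalar over ACGTN.
#' @param p A `pwm`.
#' @param threshold P-value cutoff (default 1e-4).
#' @param granularity Score discretization step.
#' @return data.table with `start` (0-based), `end`, `strand`, `score`
#'   (log-odds, nats), `pvalue`.
#' @export
scan_pwm <- function(sequence, p, threshold = 1e-4, granularity = 1e-3) {
  w <- nrow(p$matrix)
  n <- nchar(sequence)
  empty <- data.table::data.table(start = integer(), end = integer(),
                                  strand = character(), score = numeric(),
                                  pvalue = numeric())
  if (w > n) return(empty)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  base_idx <- match(chars, DNA_CHANNELS)  # NA for N
  pv <- pwm_pvalue_fun(p, granularity)
  hits_list <- list()
  for (strand in c("+", "-")) {
    si <- if (strand == "+") pv$score_int else {
      m <- pv$score_int[rev(seq_len(w)), c(4L, 3L, 2L, 1L), drop = FALSE]
      m
    }
    # windowed integer score via per-offset accumulation
    n_win <- n - w + 1L
    sc <- numeric(n_win)
    valid <- rep(TRUE, n_win)
    for (j in seq_len(w)) {
      b <- base_idx[j:(j + n_win - 1L)]
      ok <- !is.na(b)
      valid <- valid & ok
      sc[ok] <- sc[ok] + si[j, ][b[ok]]
    }
    if (!any(valid)) next
    pvals <- pv$pvalue(as.integer(round(sc)))
    sel <- valid & pvals <= threshold
    if (any(sel)) {
      st <- which(sel) - 1L
      hits_list[[strand]] <- data.table::data.table(
        start = st, end = st + w, strand = strand,
        score = sc[sel] * granularity, pvalue = pvals[sel])
    }
  }
  if (!length(hits_list)) return(empty)
  hits <- data.table::rbindlist(hits_list)
  data.table::setorder(hits, start, strand)
  hits[]
}

#' Replace motif hits with random sequence
#'
#' Generates `n_replicates` alternative sequences in which every hit span is
#' replaced simultaneously by i.i.d. uniform ACGT of the same length.
#' Overlapping hits (either strand) are merged into one replaced span, so no
#' position is substituted twice. Sequence length is preserved.
#'
#' @param sequence Character scalar.
#' @param hits Hit table from [scan_pwm()] (only `start`/`end` are used).
#' @param n_replicates Number of alternative sequences (default 10).
#' @param seed RNG seed.
#' @return Character vector of length `n_replicates`.
#' @export
mutate_hits <- function(sequence, hits, n_replicates = 10L, seed = 1L) {
  if (nrow(hits) == 0L) return(rep(sequence, n_replicates))
  if (any(hits$start < 0L) || any(hits$end > nchar(sequence)))
    stop("hit outside sequence")
  spans <- merge_spans(hits$start, hits$end)
  set.seed(seed)
  vapply(seq_len(n_replicates), function(r) {
    s <- strsplit(sequence, "", fixed = TRUE)[[1]]
    for (i in seq_len(nrow(spans))) {
      idx <- (spans$start[i] + 1L):spans$end[i]
      s[idx] <- sample(DNA_CHANNELS, length(idx), replace = TRUE)
    }
    paste(s, collapse = "")
  }, character(1))
}

# Merge overlapping/adjacent half-open spans.
merge_spans <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(start)[-1L]) {
    if (start[i] < me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.table::data.table(start = c(out_s, ms), end = c(out_e, me))
}

#' Gradient-weighted PWM around a position
#'
#' Computes the gradient of a scalar readout (exon-summed expression on the
#' transformed scale for the chosen cells, summed over cells) with respect to
#' the one-hot input, exponentiates base 2 per nucleotide over a window of
#' `window` positions centered on `center`, and sum-normalizes each position.
#'
#' @param model A `profile_model`.
#' @param seq Input window of geometry `input_length`.
#' @param center 1-based position within `seq` at the window center.
#' @param cell_embeddings Matrix `(n_cells x D)` of the cells contributing to
#'   the readout.
#' @param readout_bins 1-based output-bin indices summed for the readout
#'   (e.g. exon bins); default all bins.
#' @param strand "+" or "-": RNA strand channel used for the readout.
#' @param window Window width in bp (default 10).
#' @return A `pwm` over the window.
#' @export
gradient_pwm <- function(model, seq, center, cell_embeddings,
                         readout_bins = NULL, strand = "+", window = 10L) {
  g <- model$backbone$geometry
  half_lo <- (window - 1L) %/% 2L
  lo <- center - half_lo
  hi <- lo + window - 1L
  if (lo < 1L || hi > nchar(seq)) stop("window exceeds sequence")
  X <- one_hot(seq)
  fwd <- backbone_forward(model$backbone, X, training = FALSE)
  params <- generate_decoder_params(model$hypernet_rna, cell_embeddings)
  dec <- decode_forward(fwd$Emb, params)
  if (is.null(readout_bins)) readout_bins <- seq_len(g$output_bins)
  si <- if (strand == "-") 2L else 1L
  dOut <- array(0, dim(dec$out))
  dOut[readout_bins, si, ] <- 1
  dEmb <- decode_backward(dOut, dec$cache)$dEmb
  dX <- backbone_backward(model$backbone, dEmb, fwd$caches)$dX
  grad <- dX[lo:hi, , drop = FALSE]
  wmat <- 2^grad
  wmat <- wmat / rowSums(wmat)
  pwm(wmat, name = sprintf("gradient_%d", center), pseudocount = 0)
}
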