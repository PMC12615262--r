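#' Model geometry
#'
#' Describes the sequence window the encoder consumes and the binned output it
#' emits. The encoder operates at `bin_width` (32 bp) resolution on
#' `input_length` bp of DNA and outputs the centered `output_bins` bins; with
#' the full-scale defaults (524,288 bp in, 6,144 bins out) the output spans
#' 196,608 bp.
#'
#' @param input_length Sequence length consumed by the encoder, in bp.
#' @param bin_width Output resolution in bp (default 32).
#' @param output_bins Number of centered output bins. Defaults to
#'   `(input_length / bin_width) * 3 / 8`, the full-scale center-crop ratio
#'   (6,144 of 16,384 bins).
#' @param embedding_width Width E of the per-bin sequence embedding
#'   (full-scale default 1,920; mini backbones use smaller values).
#' @return An object of class `model_geometry`.
#' @export
model_geometry <- function(input_length = 524288L, bin_width = 32L,
                           output_bins = NULL, embedding_width = 1920L) {
  input_length <- as.integer(input_length)
  bin_width <- as.integer(bin_width)
  if (input_length %% bin_width != 0L)
    stop("input_length must be divisible by bin_width")
  pre_crop_bins <- input_length %/% bin_width
  if (is.null(output_bins)) {
    output_bins <- as.integer(round(pre_crop_bins * 3 / 8))
  }
  output_bins <- as.integer(output_bins)
  if (output_bins > pre_crop_bins) stop("output_bins exceeds pre-crop bins")
  if ((pre_crop_bins - output_bins) %% 2L != 0L)
    stop("crop must be symmetric: pre_crop_bins - output_bins must be even")
  structure(list(
    input_length = input_length,
    bin_width = bin_width,
    pre_crop_bins = pre_crop_bins,
    output_bins = output_bins,
    crop_bins = (pre_crop_bins - output_bins) %/% 2L,
    embedding_width = as.integer(embedding_width)
  ), class = "model_geometry")
}

#' @export
print.model_geometry <- function(x, ...) {
  cat(sprintf(
    "model_geometry: %d bp in, %d-bp bins, %d/%d bins out (crop %d), E=%d\n",
    x$input_length, x$bin_width, x$output_bins, x$pre_crop_bins,
    x$crop_bins, x$embedding_width))
  invisible(x)
}

DNA_CHANNELS <- c("A", "C", "G", "T")

#' One-hot encode a DNA sequence
#'
#' Encodes a sequence as an `input_length x 4` matrix over channels A, C, G, T.
#' `N` bases become all-zero columns. A nonzero `shift` moves the sequence
#' along the window (positive shifts move it rightward/downstream), zero-padding
#' the vacated edge; `rc` reverse-complements (positions reversed, A<->T and
#' C<->G channels swapped).
#'
#' @param seq Character scalar over A, C, G, T, N (case-insensitive).
#' @param shift Integer offset applied within the window (typically in [-3, 3]).
#' @param rc Reverse-complement the encoding.
#' @return Matrix (length x 4) with attributes `shift` and `rc`.
#' @export
one_hot <- function(seq, shift = 0L, rc = FALSE) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- !(chars %in% c(DNA_CHANNELS, "N"))
  if (any(bad))
    stop("invalid character(s) in sequence: ",
         paste(unique(chars[bad]), collapse = ", "))
  n <- length(chars)
  x <- matrix(0, nrow = n, ncol = 4L, dimnames = list(NULL, DNA_CHANNELS))
  idx <- match(chars, DNA_CHANNELS)
  keep <- !is.na(idx)
  x[cbind(which(keep), idx[keep])] <- 1
  shift <- as.integer(shift)
  if (shift != 0L) {
    y <- matrix(0, nrow = n, ncol = 4L, dimnames = dimnames(x))
    if (shift > 0L) {
      y[(shift + 1L):n, ] <- x[1L:(n - shift), ]
    } else {
      y[1L:(n + shift), ] <- x[(1L - shift):n, ]
    }
    x <- y
  }
  if (rc) x <- reverse_complement_onehot(x)
  attr(x, "shift") <- shift
  attr(x, "rc") <- rc
  x
}

#' Reverse-complement a one-hot matrix
#'
#' @param x One-hot matrix (length x 4, channels A, C, G, T).
#' @return The reverse-complemented one-hot matrix.
#' @export
reverse_complement_onehot <- function(x) {
  y <- x[rev(seq_len(nrow(x))), c(4L, 3L, 2L, 1L), drop = FALSE]
  colnames(y) <- DNA_CHANNELS
  y
}

#' Reverse-complement a DNA string
#' @param seq Character scalar.
#' @return Character scalar.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
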