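# Bilinear resize with the align-corners convention: output pixel i of H_out
# samples input coordinate (i-1) * (H_in-1) / (H_out-1). Implemented as two
# interpolation-matrix products so resizing a (F x T) map costs two BLAS
# matmuls. Identity when the sizes already match.
interp_matrix <- function(n_in, n_out) {
  if (n_in == n_out) return(diag(n_in))
  pos <- if (n_out == 1L) (n_in + 1) / 2 else 1 + (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  lo <- pmin(floor(pos), n_in - 1L)
  w <- pos - lo
  M <- matrix(0, n_out, n_in)
  idx <- cbind(seq_len(n_out), lo)
  M[idx] <- 1 - w
  M[cbind(seq_len(n_out), lo + 1L)] <- M[cbind(seq_len(n_out), lo + 1L)] + w
  M
}

resize_bilinear <- function(x, h_out, w_out) {
  Mr <- interp_matrix(nrow(x), h_out)
  Mc <- interp_matrix(ncol(x), w_out)
  Mr %*% x %*% t(Mc)
}

#' Convert an amplitude TFM to a CNN input image
#'
#' Min-max scales the amplitude map to \[0, 1\] (a constant map becomes all
#' zeros), resizes to `size` by bilinear interpolation, flips so the lowest
#' frequency sits on the bottom image row, and replicates across `channels`.
#' Because of the min-max step the image is invariant to any positive
#' rescaling of the amplitudes, which makes the downstream features
#' insensitive to the DFT normalization convention.
#'
#' @param amp A `pcg_amp_tfm` from [st_amplitude()], or a plain nonnegative
#'   matrix with frequencies increasing along rows.
#' @param size Integer `(H, W)` output size in pixels.
#' @param channels Number of replicated channels (default 3).
#' @return Numeric array `H x W x channels` with values in \[0, 1\];
#'   row 1 is the top of the image (highest frequency).
#' @export
tfm_to_image <- function(amp, size = c(227L, 227L), channels = 3L) {
  v <- if (inherits(amp, "pcg_amp_tfm")) amp$values else as.matrix(amp)
  if (length(v) == 0L) stop("empty amplitude map")
  rng <- range(v)
  v <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
  v <- resize_bilinear(v, size[1], size[2])
  # numerical guard: interpolation of values in [0,1] stays in [0,1] up to fp
  v[v < 0] <- 0
  v[v > 1] <- 1
  v <- v[rev(seq_len(nrow(v))), , drop = FALSE] # low freq -> bottom row
  array(v, dim = c(size[1], size[2], channels))
}
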