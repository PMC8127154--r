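#' @keywords internal
"_PACKAGE"

# Centered FFT helpers. Convention: after fftshift the DC component sits at
# 0-based index floor(N/2) along every axis (1-based floor(N/2)+1).

fftshift3 <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) {
    c <- n %/% 2L
    c(seq_len(n)[(c + 1L):n], seq_len(c))
  })
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

ifftshift3 <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) {
    c <- n %/% 2L
    c(seq_len(n)[(n - c + 1L):n], seq_len(n - c))
  })
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# Forward centered DFT of a real/complex 3D volume; DC at floor(N/2) (0-based).
centered_fft3 <- function(vol) fftshift3(stats::fft(vol))

# Inverse of centered_fft3.
centered_ifft3 <- function(F) stats::fft(ifftshift3(F), inverse = TRUE) / length(F)

#' Derive a stage seed from a master seed
#'
#' Fans a single master seed out into independent per-stage seeds so that each
#' pipeline stage is reproducible in isolation. The derived seed is a stable
#' deterministic function of the master seed and a stage label, kept within
#' the 32-bit integer range.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return An integer seed in [0, 2^31 - 1).
#' @export
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483647)
}

# 6-connected component labelling of a 3D logical array. Returns an integer
# array of labels (0 = background).
label_components6 <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, d)
  nxt <- 1L
  idx <- which(mask)
  if (length(idx) == 0L) return(labels)
  offs <- rbind(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
                c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))
  ai <- arrayInd(idx, d)
  pos <- array(0L, d); pos[idx] <- seq_along(idx)
  for (start in seq_along(idx)) {
    if (labels[idx[start]] != 0L) next
    lab <- nxt; nxt <- nxt + 1L
    queue <- idx[start]
    labels[queue] <- lab
    while (length(queue)) {
      v <- queue[length(queue)]; queue <- queue[-length(queue)]
      p <- arrayInd(v, d)
      for (o in seq_len(6L)) {
        q <- p + offs[o, ]
        if (any(q < 1L) || any(q > d)) next
        li <- q[1] + (q[2] - 1L) * d[1] + (q[3] - 1L) * d[1] * d[2]
        if (mask[li] && labels[li] == 0L) {
          labels[li] <- lab
          queue <- c(queue, li)
        }
      }
    }
  }
  labels
}

# Polynomial detrending basis (orthogonal) for n time points, orders 0..order.
poly_basis <- function(n, order) {
  if (order == 0L) return(matrix(1, n, 1))
  cbind(1, stats::poly(seq_len(n), degree = order))
}
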