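#' Hankel trajectory-matrix embedding
#'
#' Maps a one-dimensional series of length `N` onto its `L x K` trajectory
#' matrix, `K = N - L + 1`, whose column `j` is the lagged window
#' `s[j], ..., s[j + L - 1]`. The result is Hankel: entries are constant
#' along anti-diagonals.
#'
#' @param s Numeric series.
#' @param L Window length, `2 <= L <= length(s) - 1`.
#' @return An `L x K` numeric matrix.
#' @seealso [diag_average()], [ssa_decompose()]
#' @export
#' @examples
#' ssa_embed(1:5, 2L)
ssa_embed <- function(s, L) {
  s <- as.numeric(s)
  N <- length(s)
  L <- as.integer(L)
  if (is.na(L) || L < 2L || L > N - 1L)
    stop("window length L must satisfy 2 <= L <= length(s) - 1", call. = FALSE)
  K <- N - L + 1L
  idx <- outer(seq_len(L), 0:(K - 1L), `+`)
  matrix(s[idx], nrow = L, ncol = K)
}

# number of matrix entries on each anti-diagonal of an L x K matrix
.antidiag_counts <- function(L, K) {
  n <- L + K - 1L
  pmin(seq_len(n), L, K, n - seq_len(n) + 1L)
}

#' Diagonal (anti-diagonal) averaging
#'
#' Averages the anti-diagonals of a matrix, mapping an `L x K` matrix back to
#' a series of length `L + K - 1`. On a Hankel matrix this is the exact
#' inverse of [ssa_embed()]; on a general matrix it is the nearest-Hankel
#' projection used in SSA reconstruction.
#'
#' @param M Numeric matrix.
#' @return Numeric series of length `nrow(M) + ncol(M) - 1`.
#' @export
#' @examples
#' diag_average(ssa_embed(sin(1:20), 5L))
diag_average <- function(M) {
  M <- as.matrix(M)
  L <- nrow(M); K <- ncol(M)
  if (L == 0L || K == 0L) stop("empty matrix", call. = FALSE)
  g <- as.vector(outer(seq_len(L), seq_len(K), `+`)) - 1L  # 2..L+K -> 1..n
  sums <- rowsum(as.vector(M), g)
  as.numeric(sums) / .antidiag_counts(L, K)
}

#' Singular spectrum analysis of a single-channel epoch
#'
#' Decomposes a series into additive reconstruction components (RCs):
#' the trajectory matrix `X` is eigen-decomposed through `X %*% t(X)`
#' (eigenvalues `lambda_1 >= ... >= lambda_L >= 0`, the squared singular
#' values of `X`), each rank-1 term `u_i (t(u_i) %*% X)` is diagonal-averaged
#' back to a series, and the RCs sum elementwise to the input.
#'
#' Diagonal averaging of a rank-1 outer product is computed as a normalized
#' linear convolution of its two factors, so the per-component cost is one
#' FFT rather than forming the L x K matrix.
#'
#' @param s Numeric series.
#' @param L Window length.
#' @param fs Sampling rate in Hz (carried for spectral operations on RCs).
#' @param n_rc Number of leading RCs to reconstruct (default all `L`).
#'   Eigenvalues are always computed for all `L` components.
#' @return An object of class `ssa_decomposition`: list with `eigenvalues`
#'   (length `L`, descending), `rcs` (`n_rc x N` matrix, row i = RC i),
#'   `window`, `source_len`, `fs`, `n_rc`.
#' @export
ssa_decompose <- function(s, L, fs, n_rc = L) {
  s <- as.numeric(s)
  N <- length(s)
  L <- as.integer(L); n_rc <- as.integer(n_rc)
  if (n_rc < 1L || n_rc > L)
    stop("n_rc must be between 1 and L", call. = FALSE)
  X <- ssa_embed(s, L)
  K <- ncol(X)
  ev <- eigen(tcrossprod(X), symmetric = TRUE)
  lambda <- pmax(ev$values, 0)
  U <- ev$vectors
  counts <- .antidiag_counts(L, K)
  Uh <- U[, seq_len(n_rc), drop = FALSE]
  W <- crossprod(X, Uh)                      # column i = t(X) %*% u_i
  # diag-average of the rank-1 term u_i %*% t(w_i): anti-diagonal sums are
  # the linear convolution conv(u_i, w_i); batch all components in one mvfft
  nf <- stats::nextn(N, 2L)
  FA <- stats::mvfft(rbind(Uh, matrix(0, nf - L, n_rc)))
  FB <- stats::mvfft(rbind(W, matrix(0, nf - K, n_rc)))
  conv <- Re(stats::mvfft(FA * FB, inverse = TRUE))[seq_len(N), , drop = FALSE] / nf
  rcs <- t(conv / counts)
  structure(
    list(eigenvalues = lambda, rcs = rcs, window = L, source_len = N,
         fs = fs, n_rc = n_rc),
    class = "ssa_decomposition"
  )
}

# full linear convolution of two real vectors via FFT
.lin_conv <- function(a, b) {
  n <- length(a) + length(b) - 1L
  nf <- stats::nextn(n, 2L)
  fa <- stats::fft(c(a, numeric(nf - length(a))))
  fb <- stats::fft(c(b, numeric(nf - length(b))))
  Re(stats::fft(fa * fb, inverse = TRUE))[seq_len(n)] / nf
}

#' @export
print.ssa_decomposition <- function(x, ...) {
  cat("SSA decomposition: N =", x$source_len, ", L =", x$window,
      ", fs =", x$fs, "Hz\n")
  tot <- sum(x$eigenvalues)
  top <- utils::head(x$eigenvalues, 5L)
  cat("  leading eigenvalue shares:",
      paste(sprintf("%.3f", if (tot > 0) top / tot else top), collapse = " "),
      "\n")
  invisible(x)
}

#' Group components with similar eigenvalues into periodic components
#'
#' Scans adjacent eigenvalues in descending order and joins indices i, i+1
#' when `1 - lambda[i+1] / lambda[i] < k_sim`; chains extend transitively,
#' so a run of near-equal eigenvalues forms one group. A sinusoid occupies a
#' pair of near-equal eigenvalues, which this rule detects. Exact-zero
#' eigenvalues at the tail are grouped together.
#'
#' @param eigenvalues Non-negative eigenvalues in descending order.
#' @param k_sim Similarity threshold (default 0.05).
#' @return List of integer index vectors partitioning `seq_along(eigenvalues)`.
#' @export
periodic_groups <- function(eigenvalues, k_sim = 0.05) {
  lambda <- as.numeric(eigenvalues)
  if (length(lambda) == 0L) return(list())
  if (is.unsorted(rev(lambda)) || any(lambda < 0))
    stop("eigenvalues must be non-negative and descending", call. = FALSE)
  n <- length(lambda)
  if (n == 1L) return(list(1L))
  ratio <- ifelse(lambda[-n] > 0, lambda[-1] / lambda[-n],
                  ifelse(lambda[-1] == 0, 1, 0))
  joined <- (1 - ratio) < k_sim
  grp <- cumsum(c(1L, !joined))
  unname(split(seq_len(n), grp))
}

#' Peak frequency of a reconstruction component
#'
#' The frequency bin (width `fs / length(rc)`) at which the one-sided FFT
#' magnitude is maximal, excluding the DC bin; ties break toward the lower
#' frequency. An all-zero series returns 0 with attribute `flagged = TRUE`.
#'
#' @param rc Numeric series.
#' @param fs Sampling rate, Hz.
#' @return Peak frequency in Hz.
#' @export
rc_peak_frequency <- function(rc, fs) {
  rc <- as.numeric(rc)
  N <- length(rc)
  if (N == 0L) stop("empty series", call. = FALSE)
  if (all(rc == 0)) return(structure(0, flagged = TRUE))
  mag <- Mod(stats::fft(rc))[seq_len(N %/% 2L + 1L)]
  i <- which.max(mag[-1L]) + 1L   # which.max takes the first (lowest-f) tie
  (i - 1L) * fs / N
}

#' Group reconstruction components into brain rhythms by peak frequency
#'
#' Components whose RC peak frequencies differ by at most `freq_tol` are
#' merged by single linkage; optionally, adjacent components joined by the
#' eigenvalue-similarity rule ([periodic_groups()]) are linked first, so a
#' periodic pair always lands in one rhythm. Each group is labeled with the
#' eigenvalue-weighted mean peak frequency of its members.
#'
#' @param d An [ssa_decompose()] result.
#' @param components Indices of the RCs to group (must be `<= d$n_rc`).
#' @param freq_tol Merge tolerance in Hz; default one FFT bin
#'   (`d$fs / d$source_len`).
#' @param k_sim If non-`NULL`, also link eigenvalue-similar adjacent
#'   components at this threshold before merging by frequency.
#' @return List of groups, each `list(peak = Hz, components = indices)`,
#'   ordered by decreasing total eigenvalue.
#' @export
rhythm_groups <- function(d, components = seq_len(d$n_rc),
                          freq_tol = d$fs / d$source_len, k_sim = NULL) {
  components <- as.integer(components)
  if (length(components) == 0L) return(list())
  if (any(components < 1L | components > d$n_rc))
    stop("components outside the reconstructed range", call. = FALSE)
  peaks <- vapply(components, function(i) rc_peak_frequency(d$rcs[i, ], d$fs),
                  numeric(1))
  m <- length(components)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  ord <- order(peaks)
  for (t in seq_len(m - 1L)) {
    if (peaks[ord[t + 1L]] - peaks[ord[t]] <= freq_tol + 1e-12)
      union2(ord[t], ord[t + 1L])
  }
  if (!is.null(k_sim)) {
    pg <- periodic_groups(d$eigenvalues[components], k_sim = k_sim)
    for (g in pg) if (length(g) > 1L)
      for (t in seq_len(length(g) - 1L)) union2(g[t], g[t + 1L])
  }
  roots <- vapply(seq_len(m), find, integer(1))
  groups <- lapply(unname(split(seq_len(m), roots)), function(ix) {
    comp <- components[ix]
    lam <- d$eigenvalues[comp]
    w <- if (sum(lam) > 0) lam / sum(lam) else rep(1 / length(lam), length(lam))
    list(peak = sum(w * peaks[ix]), components = comp)
  })
  tot <- vapply(groups, function(g) sum(d$eigenvalues[g$components]), numeric(1))
  groups[order(tot, decreasing = TRUE)]
}
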