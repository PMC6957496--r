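# Orthogonal wavelet filter banks and periodized transforms.
#
# No wavelet package ships with the dependency set, so the small amount of
# machinery the pipeline needs is implemented here: the standard orthogonal
# decomposition filters for the three wavelets used (Daubechies-8 and
# Coiflet-2 for denoising, Symlet-4 for S-peak detection), a periodized
# multilevel DWT/inverse pair, and the undecimated (a trous) stationary
# wavelet transform used by the detector.

# Scaling (low-pass) decomposition filters. These are the published
# orthonormal coefficients; the high-pass filter is derived by the
# quadrature-mirror relation below.
.wavelet_filters <- list(
  db8 = c(-0.00011747678412476953, 0.0006754494064505693,
          -0.00039174037337694705, -0.004870352993451574,
          0.008746094047405777, 0.013981027917398282,
          -0.044088253930794755, -0.017369301001807547,
          0.12874742662047847, 0.0004724845739132828,
          -0.2840155429615469, -0.015829105256349306,
          0.5853546836542067, 0.6756307362972898,
          0.31287159091429995, 0.05441584224310401),
  coif2 = c(-0.000720549445520347, -0.0018232088709110323,
            0.005611434819368834, 0.02368017194684777,
            -0.05943441864643109, -0.07648859907828076,
            0.4170051844232391, 0.8127236354494135,
            0.3861100668227629, -0.0673725547237256,
            -0.04146493678687178, 0.01638733646320364),
  sym4 = c(-0.07576571478927333, -0.02963552764599851,
           0.49761866763201545, 0.8037387518059161,
           0.29785779560527736, -0.09921954357684722,
           -0.012603967262037833, 0.0322231006040427)
)

.wavelet_bank <- function(wavelet) {
  g <- .wavelet_filters[[wavelet]]
  if (is.null(g)) {
    stop("unknown wavelet '", wavelet, "'; available: ",
         paste(names(.wavelet_filters), collapse = ", "), call. = FALSE)
  }
  m <- length(g)
  # quadrature mirror: h[j] = (-1)^j g[M-1-j] (0-based)
  h <- rev(g) * (-1)^(seq_len(m) - 1L)
  list(g = g, h = h, len = m)
}

# One analysis step of the periodized orthogonal DWT: correlate with the
# filters and keep every second sample. The resulting operator is orthogonal,
# so its adjoint (.idwt_step) is the exact inverse.
.dwt_step <- function(x, bank) {
  n <- length(x)
  idx <- (outer(seq(0L, n - 2L, by = 2L), seq_len(bank$len) - 1L, "+") %% n) + 1L
  X <- matrix(x[idx], nrow = n %/% 2L)
  list(a = drop(X %*% bank$g), d = drop(X %*% bank$h))
}

.idwt_step <- function(a, d, bank) {
  n <- 2L * length(a)
  idx <- (outer(seq(0L, n - 2L, by = 2L), seq_len(bank$len) - 1L, "+") %% n) + 1L
  contrib <- a %o% bank$g + d %o% bank$h
  x <- numeric(n)
  for (j in seq_len(bank$len)) {
    p <- idx[, j]
    x[p] <- x[p] + contrib[, j]
  }
  x
}

# Reflect-pad x on the right to length n_target (n_target < 2 * length(x)).
.reflect_pad <- function(x, n_target) {
  extra <- n_target - length(x)
  if (extra <= 0L) return(x)
  n <- length(x)
  if (extra > n) stop("cannot reflect-pad by more than the signal length")
  c(x, x[seq(n, by = -1L, length.out = extra)])
}

# Multilevel periodized DWT. The signal is reflect-padded to a multiple of
# 2^level; `n_orig` is kept so the inverse can crop.
.dwt <- function(x, wavelet, level) {
  bank <- .wavelet_bank(wavelet)
  n_orig <- length(x)
  block <- 2L^level
  n_pad <- as.integer(ceiling(n_orig / block) * block)
  if (n_orig < bank$len) {
    stop("signal too short (", n_orig, " samples) for a length-", bank$len,
         " wavelet filter", call. = FALSE)
  }
  x <- .reflect_pad(x, n_pad)
  details <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    st <- .dwt_step(a, bank)
    details[[j]] <- st$d
    a <- st$a
  }
  list(a = a, d = details, wavelet = wavelet, n_orig = n_orig)
}

.idwt <- function(decomp) {
  bank <- .wavelet_bank(decomp$wavelet)
  a <- decomp$a
  for (j in rev(seq_along(decomp$d))) {
    a <- .idwt_step(a, decomp$d[[j]], bank)
  }
  a[seq_len(decomp$n_orig)]
}

# Undecimated (a trous) transform: detail coefficients at `level`, aligned to
# the input grid. The cascade of forward-looking correlations advances the
# response by half the effective filter span; the output is circularly
# shifted back so a deflection at sample i produces its coefficient response
# near sample i.
.swt_detail <- function(x, wavelet, level) {
  bank <- .wavelet_bank(wavelet)
  n <- length(x)
  span <- (bank$len - 1L) * (2L^level - 1L)
  if (n <= span + bank$len) {
    stop("signal too short (", n, " samples) for SWT at level ", level,
         call. = FALSE)
  }
  a <- x
  d <- NULL
  for (j in seq_len(level)) {
    up <- 2L^(j - 1L)
    offs <- (seq_len(bank$len) - 1L) * up
    idx <- (outer(seq_len(n) - 1L, offs, "+") %% n) + 1L
    X <- matrix(a[idx], nrow = n)
    d <- drop(X %*% bank$h)
    a <- drop(X %*% bank$g)
  }
  shift <- as.integer(round(span / 2))
  if (shift > 0L) d <- c(d[(n - shift + 1L):n], d[seq_len(n - shift)])
  d
}
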