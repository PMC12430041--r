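#' Build an extended-FAST sample design
#'
#' One block of `Ns` points per factor of interest: within block `i`,
#' factor `i` is driven at the highest frequency
#' `omega_max = floor((Ns - 1) / (2 M))` and the remaining factors at low
#' complementary frequencies assigned cyclically over
#' `1 .. max(1, floor(omega_max / (2 M)))`, so that up to harmonic `M`
#' the frequency of interest does not interfere with the complementary
#' set. Points follow the periodic search curve
#' `x_j(s) = 1/2 + arcsin(sin(omega_j s + phi_j)) / pi` with seeded
#' random phases, sampled at `Ns` equispaced `s` values over one period.
#' Total design size is `n * Ns`.
#'
#' A block is statistically valid only when `Ns` is at least 65 (the
#' common samples-per-factor validity rule); smaller designs are allowed
#' with `strict = FALSE` (a warning) for toy functions.
#'
#' @param n Number of factors.
#' @param Ns Samples per factor block.
#' @param M Interference (harmonic) factor, default 4.
#' @param seed Integer seed for the phases.
#' @param strict Error (`TRUE`) or warn (`FALSE`) when `Ns < 65`.
#' @return List of class `fast_design`: `points` (an `(n*Ns) x n`
#'   matrix), `block` (factor-of-interest id per row), `omega_max`,
#'   `omega` (n x n matrix of frequencies used in each block), `Ns`, `M`,
#'   `seed`.
#' @export
build_fast_design <- function(n, Ns, M = 4, seed = 1L, strict = TRUE) {
  if (M < 1) stop("M must be >= 1")
  if (Ns < 65) {
    msg <- sprintf("Ns = %d is below the 65-samples-per-factor validity rule", Ns)
    if (strict) stop(msg) else warning(msg)
  }
  omega_max <- floor((Ns - 1) / (2 * M))
  if (omega_max < 1) stop("Ns too small for interference factor M")
  comp_max <- max(1, floor(omega_max / (2 * M)))
  s <- 2 * pi * (seq_len(Ns) - 1) / Ns
  set.seed(seed)
  pts <- matrix(NA_real_, n * Ns, n)
  omega <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    om <- numeric(n)
    om[i] <- omega_max
    if (n > 1) {
      om[-i] <- ((seq_len(n - 1) - 1) %% comp_max) + 1
    }
    phi <- stats::runif(n, 0, 2 * pi)
    rows <- (i - 1) * Ns + seq_len(Ns)
    for (j in seq_len(n)) {
      pts[rows, j] <- 0.5 + asin(sin(om[j] * s + phi[j])) / pi
    }
    omega[i, ] <- om
  }
  structure(list(points = pts, block = rep(seq_len(n), each = Ns),
                 omega_max = omega_max, omega = omega, n = n, Ns = Ns,
                 M = M, seed = seed),
            class = "fast_design")
}

#' EFAST variance decomposition: first-order and total-order indices
#'
#' Along each block's search curve the output is Fourier-analyzed: the
#' first-order variance of the factor of interest, `V_i`, accumulates
#' the harmonics `omega_max, 2 omega_max, ..., M omega_max`; the
#' complementary variance `V_-i` (everything not involving factor i)
#' occupies the low-frequency band below `omega_max`, which holds the
#' complementary fundamentals and their harmonic tails. Interactions of
#' the factor of interest appear as sidebands around its harmonics;
#' their lower halves fall into the complementary band and cannot be
#' separated from it, so the clean upper sidebands are counted twice
#' (spectral symmetry) to form the interaction variance `V_int`. The
#' total variance `V` is estimated from the pooled outputs of all
#' blocks: within a single block every complementary factor shares one
#' low frequency, so their contributions interfere along the curve and
#' the single-curve spectrum is a noisy estimate of the model's total
#' variance at small `Ns`; the pooled design, whose points cover the
#' hypercube with uniform marginals, is not. Then `Si = V_i / V` and
#' `STi = (V_i + V_int) / V`.
#'
#' A block whose output is (numerically) constant has no variance to
#' decompose; its indices are reported as 0 with `degenerate = TRUE`
#' rather than NaN so batch pipelines never halt on degenerate corners.
#'
#' @param design A [build_fast_design()].
#' @param outputs Numeric vector, one model output per design row.
#' @param factors Optional factor labels.
#' @return `data.frame` of class `fast_result` with columns
#'   `factor, Si, STi, rank, influential, degenerate`.
#' @export
variance_decomposition <- function(design, outputs, factors = NULL) {
  if (length(outputs) != nrow(design$points)) {
    stop("outputs length must match the design")
  }
  if (any(!is.finite(outputs))) stop("non-finite model output")
  n <- design$n; Ns <- design$Ns; M <- design$M
  wmax <- design$omega_max
  nh <- floor((Ns - 1) / 2)
  V <- stats::var(outputs) * (length(outputs) - 1) / length(outputs)
  Si <- STi <- numeric(n)
  degen <- logical(n)
  for (i in seq_len(n)) {
    y0 <- outputs[design$block == i]
    ybar <- mean(y0)
    y <- y0 - ybar
    sp <- (Mod(stats::fft(y))^2 / Ns^2)[2:(nh + 1)]  # power per harmonic
    Vblock <- 2 * sum(sp)
    if (Vblock <= 1e-14 * max(1, ybar^2) || V <= 0) {
      degen[i] <- TRUE
      next
    }
    harm <- wmax * seq_len(M)
    harm <- harm[harm <= nh]
    Vi <- 2 * sum(sp[harm])
    # interactions of the factor of interest appear as sidebands around
    # its harmonics; the lower sidebands overlap the complementary band
    # below omega_max, so the (clean) upper ones are counted twice by
    # spectral symmetry
    side <- setdiff(seq(wmax + 1, nh), harm)
    Vint <- 2 * sum(sp[side])
    Si[i] <- Vi / V
    STi[i] <- (Vi + 2 * Vint) / V
  }
  if (is.null(factors)) factors <- as.character(seq_len(n))
  out <- data.frame(factor = factors, Si = Si, STi = STi,
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$STi, ties.method = "first")
  out$influential <- out$Si > 0.05 & out$STi > 0.10
  out$degenerate <- degen
  class(out) <- c("fast_result", "data.frame")
  out
}

#' Influential factors under the EFAST screening rule
#'
#' Influential iff `Si > 0.05` and `STi > 0.10` (equivalently
#' `Si + STi > 0.15` with both thresholds respected).
#'
#' @param result A [variance_decomposition()] result.
#' @return Character vector of influential factor labels.
#' @export
classify_influential_fast <- function(result) {
  if (nrow(result) == 0) stop("empty result")
  result$factor[result$Si > 0.05 & result$STi > 0.10]
}

#' EFAST analysis of a function over the unit hypercube
#'
#' @param fn Function on `[0,1]^n` (row-wise, or matrix-wise when
#'   `vectorized`).
#' @param n,Ns,M,seed,strict Design parameters, see
#'   [build_fast_design()].
#' @param factors Optional labels.
#' @param vectorized If `TRUE`, `fn` accepts the whole point matrix.
#' @return A [variance_decomposition()] result.
#' @export
efast_sa <- function(fn, n, Ns = 70, M = 4, seed = 1L, factors = NULL,
                     strict = TRUE, vectorized = FALSE) {
  design <- build_fast_design(n, Ns, M, seed, strict = strict)
  y <- if (vectorized) fn(design$points) else apply(design$points, 1, fn)
  variance_decomposition(design, y, factors = factors)
}

#' Export / re-import an EFAST or Morris design for an external simulator
#'
#' Writes the design matrix as delimited text (one column per factor,
#' plus bookkeeping columns) so an external batch simulator can append an
#' `output` column; [read_design_outputs()] reads the outputs back in
#' design order. This reproduces, file-wise, the usual round trip between
#' a sampling tool and a batch-driven crop model.
#'
#' @param design A `fast_design` or `trajectory_design`.
#' @param path CSV path.
#' @export
write_design <- function(design, path) {
  df <- as.data.frame(design$points)
  names(df) <- paste0("x", seq_len(ncol(df)))
  df <- cbind(row = seq_len(nrow(df)),
              group = if (inherits(design, "fast_design")) design$block
                      else design$traj,
              df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @param n_expected Expected number of rows (defaults to any).
#' @export
read_design_outputs <- function(path, n_expected = NULL) {
  df <- utils::read.csv(path)
  if (!"output" %in% names(df)) stop("no 'output' column appended")
  df <- df[order(df$row), ]
  if (!is.null(n_expected) && nrow(df) != n_expected) {
    stop("expected ", n_expected, " rows, found ", nrow(df))
  }
  df$output
}
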