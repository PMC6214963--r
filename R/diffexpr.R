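#' Normalize a read count to reads per million
#'
#' Scales a count by one million over the library's clean-read total.
#' A zero result is replaced by the pseudo-expression 0.01 so that fold
#' changes stay defined; the substitution applies to the normalized
#' expression, not the raw count.
#'
#' @param count read count(s), >= 0.
#' @param libsize total clean reads of the library, > 0.
#' @return normalized expression, reads per million (0 mapped to 0.01).
#' @examples
#' normalizeRpm(5, 1e7)  # 0.5
#' normalizeRpm(0, 1e6)  # 0.01
#' @export
normalizeRpm <- function(count, libsize) {
  if (any(libsize <= 0)) stop("libsize must be > 0")
  if (any(count < 0)) stop("counts must be >= 0")
  rpm <- count * 1e6 / libsize
  rpm[rpm == 0] <- 0.01
  rpm
}

#' Audic-Claverie p-value for a two-library count comparison
#'
#' Exact conditional test for whether a tag's counts `x` and `y` in two
#' libraries of sizes `N1` and `N2` are compatible with equal relative
#' abundance. Conditional on `x`, the null distribution of the second
#' count is
#' \deqn{P(Y=y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
#'   \frac{(x+y)!}{x!\, y!\, (1 + N_2/N_1)^{x+y+1}}}
#' which is negative binomial with size `x + 1` and success probability
#' `N1 / (N1 + N2)`; the tails are evaluated through [stats::pnbinom]
#' in that parameterisation (log-space internally), avoiding any
#' explicit factorial summation. The two-sided p-value doubles the
#' smaller tail (each tail including the observed `y`) and is capped at
#' 1; `sided = 1` returns the smaller tail itself.
#'
#' Note the doubled-tail p-value is not exactly invariant under
#' swapping the libraries: the observed point mass enters the two
#' orders' tails differently, so `acPvalue(x, y, N1, N2)` and
#' `acPvalue(y, x, N2, N1)` can differ by up to about twice the point
#' probability of the observation. The difference vanishes as counts
#' grow.
#'
#' @param x,y read counts in the two libraries (vectorised).
#' @param N1,N2 library sizes (> 0).
#' @param sided 2 (default) or 1.
#' @return p-value(s) in (0, 1].
#' @examples
#' acPvalue(0, 0, 1e6, 1e6)   # 1
#' acPvalue(50, 5, 1e6, 1e6)  # strongly unequal counts
#' @export
acPvalue <- function(x, y, N1, N2, sided = 2L) {
  if (any(x < 0) || any(y < 0)) stop("counts must be >= 0")
  if (any(N1 <= 0) || any(N2 <= 0)) stop("library sizes must be > 0")
  p <- N1 / (N1 + N2)
  lo <- pnbinom(y, size = x + 1, prob = p)
  hi <- 1 - pnbinom(y - 1, size = x + 1, prob = p)
  tail <- pmin(lo, hi)
  if (sided == 2L) pmin(1, 2 * tail) else pmin(1, tail)
}

#' Call differentially expressed miRNAs between two libraries
#'
#' Applies the two-library differential-expression rule: per-million
#' normalization with the 0.01 zero substitution, the low-abundance
#' skip rule (no test when both normalized expressions are below 1),
#' log2 fold change `log2(rpm_BR / rpm_BS)` (positive = up-regulated in
#' the BR library), the Audic-Claverie p-value, and the thresholds
#' `|fc| >= fcCut` with `p <= pCut`.
#'
#' No multiple-testing correction enters the calls; a
#' Benjamini-Hochberg adjusted column (`fdr`) is emitted for reference.
#'
#' @param records data.frame with columns `id`, `x` (reads in BR) and
#'   `y` (reads in BS).
#' @param N1,N2 clean-read totals of the BR and BS libraries.
#' @param fcCut absolute log2 fold-change threshold (default 1).
#' @param pCut p-value threshold (default 0.05).
#' @param sided sidedness of the test (default 2).
#' @return data.frame with columns `id`, `x`, `y`, `rpm_BR`, `rpm_BS`,
#'   `fc`, `p`, `fdr`, `call` (one of `up`, `down`, `ns`,
#'   `skipped_low`).
#' @export
callDifferential <- function(records, N1, N2, fcCut = 1.0, pCut = 0.05,
                             sided = 2L) {
  stopifnot(all(c("id", "x", "y") %in% names(records)))
  if (N1 <= 0 || N2 <= 0) stop("library totals must be positive")
  x <- records$x
  y <- records$y
  rpmBR <- normalizeRpm(x, N1)
  rpmBS <- normalizeRpm(y, N2)
  fc <- log2(rpmBR / rpmBS)
  skip <- rpmBR < 1 & rpmBS < 1
  p <- rep(NA_real_, length(x))
  p[!skip] <- acPvalue(x[!skip], y[!skip], N1, N2, sided = sided)
  fdr <- rep(NA_real_, length(x))
  fdr[!skip] <- p.adjust(p[!skip], method = "BH")
  call <- rep("ns", length(x))
  call[skip] <- "skipped_low"
  call[!skip & fc >= fcCut & p <= pCut] <- "up"
  call[!skip & fc <= -fcCut & p <= pCut] <- "down"
  data.frame(id = records$id, x = x, y = y,
             rpm_BR = rpmBR, rpm_BS = rpmBS, fc = fc, p = p, fdr = fdr,
             call = call, stringsAsFactors = FALSE)
}
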