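#' Foreground pixel area of a binary mask
#'
#' The hair-density measure: the count of foreground pixels in the optimized
#' mask, comparable across sessions because every mask lives in the shared
#' baseline (T1) coordinate frame.
#'
#' @param mask binary `{0, 1}` matrix.
#' @return pixel count.
#' @export
pixel_area <- function(mask) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  sum(mask)
}

#' Percent change of hair density relative to baseline
#'
#' `delta = 100 (1 - A_t / A_T1)` is the percent loss;
#' `retained = 100 A_t / A_T1` the percent of baseline density remaining.
#' The two always sum to 100.
#'
#' @param a_t foreground area at time t.
#' @param a_t1 baseline foreground area (> 0).
#' @return list with `delta` and `retained` (percent).
#' @export
percent_change <- function(a_t, a_t1) {
  if (a_t1 <= 0) stop("undefined baseline: A(T1) must be > 0")
  retained <- 100 * a_t / a_t1
  list(delta = 100 - retained, retained = retained)
}

#' Intra-session standard deviation
#'
#' Sample (n-1 denominator) standard deviation of the retained-density
#' percentages over the replicate captures of one session; low values
#' indicate high repeatability of the measurement.
#'
#' @param x numeric vector of per-capture retained percentages (>= 2).
#' @return sample standard deviation.
#' @export
intra_session_std <- function(x) {
  if (length(x) < 2) stop("intra-session Std needs at least 2 measurements")
  stats::sd(x)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single rater/measurement.
#' From the two-way ANOVA decomposition with subjects as rows and repeated
#' captures as columns:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`
#' where MSR, MSC and MSE are the subject, capture and residual mean
#' squares.
#'
#' @param m numeric matrix, n subjects x k captures, no missing cells.
#' @return ICC estimate.
#' @export
icc_2_1 <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("ICC needs at least 2 subjects and 2 captures")
  if (any(!is.finite(m))) stop("ICC input must have no missing cells")
  gm <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_total <- sum((m - gm)^2)
  if (ss_total < .Machine$double.eps)
    stop("ICC undefined: zero total variance")
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sse <- ss_total - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Standard error of measurement and minimum detectable change
#'
#' `SEM = Std * sqrt(1 - ICC)` quantifies technical precision;
#' `MDC = SEM * 1.96 * sqrt(2)` is the smallest change distinguishable from
#' measurement noise at 95% confidence.
#'
#' @param std_pooled pooled intra-session standard deviation (>= 0).
#' @param icc intraclass correlation (<= 1).
#' @return list with `sem` and `mdc`, in the units of `std_pooled`.
#' @export
sem_mdc <- function(std_pooled, icc) {
  if (icc > 1) stop("ICC must be <= 1")
  if (std_pooled < 0) stop("Std must be >= 0")
  sem <- std_pooled * sqrt(1 - icc)
  list(sem = sem, mdc = sem * 1.96 * sqrt(2))
}

#' Percent-of-baseline for ordinal BETA scores
#'
#' Expresses expert BETA eyebrow scores per timepoint as percentages of the
#' baseline score, rounded to 1 decimal place, for comparison with the
#' pixel-based density series.
#'
#' @param scores numeric vector of BETA scores, baseline first (> 0).
#' @return vector of retained percentages (1 dp), baseline = 100.
#' @export
beta_comparison <- function(scores) {
  if (scores[1] <= 0) stop("zero baseline BETA score")
  round(100 * scores / scores[1], 1)
}

#' Repeatability statistics over a retained-density matrix
#'
#' Rows are sessions/subjects (e.g. timepoint x eye series), columns the
#' replicate captures. Reports the per-row intra-session Std, the pooled Std
#' (root mean square of per-row Stds), ICC(2,1) across rows, and the derived
#' SEM and MDC.
#'
#' @param m retained-percentage matrix, rows = sessions, cols = captures.
#' @return list with `std` (per row), `std_pooled`, `icc`, `sem`, `mdc`.
#' @export
repeatability_stats <- function(m) {
  m <- as.matrix(m)
  stds <- apply(m, 1, intra_session_std)
  std_pooled <- sqrt(mean(stds^2))
  icc <- icc_2_1(m)
  sm <- sem_mdc(std_pooled, icc)
  list(std = stds, std_pooled = std_pooled, icc = icc,
       sem = sm$sem, mdc = sm$mdc)
}
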