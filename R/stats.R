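# Statistical layer: normality gate, paired tests, fully within-subject
# repeated-measures ANOVA with Greenhouse-Geisser correction and partial eta
# squared, Bonferroni adjustment.
#
# The rm-ANOVA uses the univariate within-subject approach: for each effect,
# the cell means are projected onto an orthonormal contrast basis (Helmert,
# normalized; Kronecker products across factors, with the normalized unit
# vector for factors not in the effect). With scores S (subjects x q):
#   SS_effect = n * ||colMeans(S)||^2,  df1 = q
#   SS_error  = sum of centred squares of S, df2 = q (n - 1)
#   F = (SS_effect/df1) / (SS_error/df2)
#   GG epsilon = tr(Sigma)^2 / (q * tr(Sigma^2)), Sigma = cov of scores
#   partial eta^2 = SS_effect / (SS_effect + SS_error)

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over [stats::shapiro.test()] returning the package's common
#' test-result shape.
#'
#' @param x Numeric sample, 3 <= n <= 5000.
#' @return List: `test_name`, `statistic` (W), `p_value`, `n`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000)
    stop("Shapiro-Wilk needs 3 <= n <= 5000")
  if (stats::var(x) == 0) stop("zero-variance sample")
  s <- stats::shapiro.test(x)
  list(test_name = "shapiro_wilk", statistic = unname(s$statistic),
       p_value = s$p.value, n = length(x))
}

#' Wilcoxon signed-rank test (paired, normal approximation)
#'
#' Paired two-sided signed-rank test reported as a Z statistic, with average
#' ranks for ties, the tie correction to the null variance, and a 0.5
#' continuity correction. Zero differences are dropped.
#'
#' @param x,y Paired numeric vectors.
#' @return List: `test_name`, `statistic` (signed Z, positive when x > y
#'   dominates), `W` (the smaller of the positive- and negative-difference
#'   rank sums; 0 when all differences share one sign), `W_pos`, `p_value`,
#'   `n` (non-zero pairs).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n < 5) stop("need >= 5 non-zero differences")
  r <- rank(abs(d))
  W_pos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (W_pos == mu) 0 else
    (W_pos - mu - sign(W_pos - mu) * 0.5) / sqrt(sig2)
  list(test_name = "wilcoxon_signed_rank", statistic = z,
       W = min(W_pos, n * (n + 1) / 2 - W_pos), W_pos = W_pos,
       p_value = min(1, 2 * stats::pnorm(-abs(z))), n = n)
}

#' Paired t-test
#'
#' @param x,y Paired numeric vectors.
#' @return List: `test_name`, `statistic` (t, df = n - 1), `df`, `p_value`,
#'   `n`, `effect_size` (Cohen's dz).
#' @export
paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  if (n < 2) stop("need >= 2 pairs")
  if (stats::var(d) == 0) stop("zero-variance differences")
  tt <- stats::t.test(d)
  list(test_name = "paired_t", statistic = unname(tt$statistic),
       df = as.integer(n - 1), p_value = tt$p.value, n = n,
       effect_size = mean(d) / stats::sd(d))
}

# Orthonormal contrast basis (k x (k-1)) and normalized unit vector (k x 1).
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}
unit_column <- function(k) matrix(1 / sqrt(k), k, 1)

#' Greenhouse-Geisser epsilon
#'
#' Sphericity-correction factor from the covariance matrix of the effect's
#' orthonormal contrast scores: `tr(S)^2 / (q tr(S^2))`, bounded in
#' `[1/q, 1]` where q is the number of contrasts.
#'
#' @param S q x q covariance matrix of contrast scores.
#' @return Scalar epsilon.
#' @export
gg_epsilon <- function(S) {
  S <- as.matrix(S)
  q <- nrow(S)
  if (q != ncol(S)) stop("S must be square")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("S must be positive semi-definite")
  tr <- sum(diag(S))
  min(1, max(1 / q, tr^2 / (q * sum(S * S))))
}

#' Repeated-measures ANOVA (fully within-subject)
#'
#' All main effects and interactions of a complete crossed within-subject
#' design with one observation per subject x cell, each tested against its
#' own subject-by-effect error term, with Greenhouse-Geisser-corrected
#' p-values and partial eta squared.
#'
#' @param data Long-format data frame.
#' @param dv Name of the value column.
#' @param subject Name of the subject column.
#' @param within Character vector of within-subject factor columns.
#' @return Object of class `AnovaTable` (a data frame): per effect `name`,
#'   `df_num`, `df_den`, `ss_effect`, `ss_error`, `F`, `gg_epsilon`,
#'   `p_uncorrected`, `p_gg`, `partial_eta_sq`.
#' @export
rm_anova <- function(data, dv = "amplitude_uv", subject = "subject",
                     within) {
  data <- as.data.frame(data)
  for (v in c(dv, subject, within))
    if (!v %in% names(data)) stop("column '", v, "' not found")
  subjects <- unique(data[[subject]])
  n <- length(subjects)
  if (n < 2) stop("need >= 2 subjects")
  levs <- lapply(within, function(f) unique(as.character(data[[f]])))
  names(levs) <- within
  cells <- rev(expand.grid(rev(levs), KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE))
  names(cells) <- within
  key <- function(df) do.call(paste, c(df[within], sep = "\r"))
  cell_keys <- key(cells)
  data_keys <- key(data)
  if (anyDuplicated(paste(data[[subject]], data_keys)))
    stop("more than one observation per subject x cell")
  Y <- matrix(NA_real_, n, nrow(cells))
  for (i in seq_len(n)) {
    rows <- data[[subject]] == subjects[i]
    m <- match(cell_keys, data_keys[rows])
    if (anyNA(m))
      stop("incomplete design: subject ", subjects[i], " is missing ",
           sum(is.na(m)), " cell(s)")
    Y[i, ] <- data[[dv]][rows][m]
  }

  effects <- unlist(lapply(seq_along(within), function(k)
    utils::combn(within, k, simplify = FALSE)), recursive = FALSE)
  res <- lapply(effects, function(eff) {
    M <- Reduce(`%x%`, lapply(within, function(f)
      if (f %in% eff) orthonormal_contrasts(length(levs[[f]]))
      else unit_column(length(levs[[f]]))))
    S <- Y %*% M
    q <- ncol(S)
    mbar <- colMeans(S)
    ss_eff <- n * sum(mbar^2)
    Sc <- sweep(S, 2, mbar)
    E <- crossprod(Sc)
    ss_err <- sum(diag(E))
    # sums of squares at rounding-noise level are exact zeros
    tiny <- 1e-12 * max(sum(Y * Y), .Machine$double.eps)
    if (ss_eff < tiny) ss_eff <- 0
    if (ss_err < tiny) ss_err <- 0
    df1 <- q; df2 <- q * (n - 1)
    Fv <- if (ss_err > 0) (ss_eff / df1) / (ss_err / df2) else
      if (ss_eff > 0) Inf else 0
    eps <- if (q == 1) 1 else gg_epsilon(E / (n - 1))
    p_un <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
    p_gg <- stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE)
    data.frame(name = paste(eff, collapse = ":"), df_num = df1,
               df_den = df2, ss_effect = ss_eff, ss_error = ss_err,
               F = Fv, gg_epsilon = eps, p_uncorrected = p_un, p_gg = p_gg,
               partial_eta_sq = if (ss_eff + ss_err > 0)
                 ss_eff / (ss_eff + ss_err) else 0)
  })
  out <- do.call(rbind, res)
  class(out) <- c("AnovaTable", "data.frame")
  out
}

#' Partial eta squared from an F statistic
#'
#' `F df1 / (F df1 + df2)` — the identity that lets published effect sizes
#' be recomputed from published F values.
#'
#' @param f F statistic (>= 0); `df_num`, `df_den` its degrees of freedom.
#' @return Partial eta squared in [0, 1].
#' @export
#' @examples
#' partial_eta_sq_from_f(14.362, 1, 25)  # 0.365
partial_eta_sq_from_f <- function(f, df_num, df_den) {
  stopifnot(f >= 0, df_num >= 1, df_den >= 1)
  f * df_num / (f * df_num + df_den)
}

#' Bonferroni adjustment
#'
#' @param p P-values in [0, 1].
#' @param m Number of comparisons (default `length(p)`).
#' @return `pmin(1, m * p)`.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < 1) stop("m must be >= 1")
  if (any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  pmin(1, m * p)
}

#' Grand-average latency across conditions
#'
#' Unweighted mean of the condition means, rounded half-up to integer ms
#' (146 and 151 give 149; 168 and 198 give 183).
#'
#' @param condition_means Numeric vector of per-condition latency means (ms).
#' @return Integer-valued grand latency in ms.
#' @export
latency_grand_average <- function(condition_means) {
  round_half_up(mean(condition_means))
}

#' Normality-gated paired comparison
#'
#' The reporting chain applied to every paired contrast: Shapiro-Wilk on the
#' differences; paired t when normality is not rejected at `alpha`,
#' Wilcoxon signed-rank otherwise.
#'
#' @param x,y Paired vectors.
#' @param alpha Gate level (default 0.05).
#' @return The chosen test's result list, plus `gate_p` (Shapiro p) and
#'   `gate_normal`.
#' @export
paired_comparison <- function(x, y, alpha = 0.05) {
  g <- shapiro_wilk(x - y)
  res <- if (g$p_value >= alpha) paired_t(x, y)
         else wilcoxon_signed_rank(x, y)
  res$gate_p <- g$p_value
  res$gate_normal <- g$p_value >= alpha
  res
}
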