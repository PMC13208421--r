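# Two-sample comparisons and bivariate spore-size statistics.

assignStars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "ns"
}

# Exact two-sided Mann-Whitney by full enumeration of all C(n1+n2, n1)
# assignments of the (possibly tied) pooled ranks to group a. Ties are
# handled naturally because the observed mid-ranks are permuted.
mannWhitneyExact <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  Uobs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  Us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  p <- mean(abs(Us - mu) >= abs(Uobs - mu) - 1e-9)
  list(U = Uobs, p = p, exact = TRUE)
}

# Normal approximation with tie correction (no continuity correction).
mannWhitneyApprox <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  N <- n1 + n2
  r <- rank(c(a, b))
  Uobs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(a, b))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = Uobs, p = 1, exact = FALSE))
  z <- (Uobs - n1 * n2 / 2) / sqrt(sigma2)
  list(U = Uobs, p = min(1, 2 * stats::pnorm(-abs(z))), exact = FALSE)
}

#' Compare two groups of measurements
#'
#' Two-sided two-sample comparison. In \code{"auto"} mode each group is first
#' tested for normality with the Shapiro–Wilk test at alpha = 0.05: if both
#' pass, a t-test is run (Welch by default), otherwise a Mann–Whitney test.
#' The Mann–Whitney p-value is computed by exact enumeration of all rank
#' assignments when both groups have at most 8 observations, and by the
#' normal approximation with tie correction otherwise; two identical constant
#' groups give p = 1. Significance stars are assigned at the 0.05 / 0.01 /
#' 0.001 thresholds.
#'
#' @param a,b numeric vectors (each of length >= 2; >= 3 for auto mode).
#' @param method \code{"auto"}, \code{"t"} or \code{"mw"}.
#' @param tTest \code{"welch"} (unequal variances, default) or
#'   \code{"student"}.
#' @return A [TestResult-class].
#' @examples
#' compareGroups(c(1, 2, 3), c(4, 5, 6), method = "mw")  # exact p = 0.1
#' @export
compareGroups <- function(a, b, method = c("auto", "t", "mw"),
                          tTest = c("welch", "student")) {
  method <- match.arg(method)
  tTest <- match.arg(tTest)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  details <- list()
  if (method == "auto") {
    if (length(a) < 3L || length(b) < 3L)
      stop("auto mode needs at least 3 observations per group")
    swp <- vapply(list(a, b), function(x) {
      tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
    }, numeric(1))
    details$shapiroP <- swp
    method <- if (all(swp > 0.05)) "t" else "mw"
  }
  if (method == "t") {
    tt <- stats::t.test(a, b, var.equal = (tTest == "student"))
    res <- list(method = if (tTest == "welch") "welch_t" else "student_t",
                statistic = unname(tt$statistic), p = tt$p.value)
  } else {
    mw <- if (length(a) <= 8L && length(b) <= 8L) mannWhitneyExact(a, b)
          else mannWhitneyApprox(a, b)
    details$exact <- mw$exact
    res <- list(method = "mann_whitney", statistic = mw$U, p = mw$p)
  }
  new("TestResult", method = res$method, statistic = res$statistic,
      pValue = res$p, stars = assignStars(res$p),
      groupSizes = c(length(a), length(b)), details = details)
}

#' Isoprobability ellipse of a bivariate cloud
#'
#' Fits a bivariate normal (sample mean and covariance) and returns the
#' ellipse containing \code{probLevel} of the probability mass: the
#' covariance eigen-decomposition scaled by the square root of the
#' chi-square (2 df) quantile at \code{probLevel}. For normal data the
#' expected fraction of points inside the ellipse converges to
#' \code{probLevel}.
#'
#' @param points two-column matrix or data.frame of (L, W) pairs, at least 3
#'   non-collinear points.
#' @param probLevel probability mass inside the ellipse.
#' @return An [EllipseParams-class].
#' @export
isoEllipse <- function(points, probLevel = 0.95) {
  pts <- as.matrix(points)
  if (nrow(pts) < 3L) stop("need at least 3 points")
  if (probLevel <= 0 || probLevel >= 1) stop("probLevel must be in (0, 1)")
  mu <- colMeans(pts)
  S <- stats::cov(pts)
  if (det(S) <= 1e-12 * prod(pmax(diag(S), 1e-300)))
    stop("singular covariance (collinear points)")
  e <- eigen(S, symmetric = TRUE)
  r <- sqrt(stats::qchisq(probLevel, df = 2))
  ang <- atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi
  new("EllipseParams", center = unname(mu),
      semiMajor = r * sqrt(e$values[1]), semiMinor = r * sqrt(e$values[2]),
      angleDeg = ang %% 180, probLevel = probLevel)
}

#' Points of an ellipse outline
#'
#' @param ellipse an [EllipseParams-class].
#' @param n number of outline points.
#' @return Two-column matrix tracing the ellipse.
#' @export
ellipsePoints <- function(ellipse, n = 181) {
  t <- seq(0, 2 * pi, length.out = n)
  th <- ellipse@angleDeg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy <- cbind(ellipse@semiMajor * cos(t), ellipse@semiMinor * sin(t)) %*% t(R)
  sweep(xy, 2, ellipse@center, "+")
}

#' Membership of points in an ellipse
#'
#' @param ellipse an [EllipseParams-class].
#' @param points two-column matrix of points.
#' @return Logical vector: point inside (or on) the ellipse.
#' @export
ellipseContains <- function(ellipse, points) {
  pts <- sweep(as.matrix(points), 2, ellipse@center)
  th <- ellipse@angleDeg * pi / 180
  u <- pts %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  (u[, 1] / ellipse@semiMajor)^2 + (u[, 2] / ellipse@semiMinor)^2 <= 1
}

#' Two-dimensional Gaussian kernel density estimate
#'
#' Product-Gaussian KDE on a regular grid covering the data plus three
#' bandwidths on each side. The default per-axis bandwidth is Scott's rule
#' for two dimensions, \eqn{h_j = \hat\sigma_j n^{-1/6}}. The grid density
#' integrates to 1 within 1% by trapezoidal quadrature.
#'
#' @param points two-column matrix or data.frame of (L, W) pairs (>= 2 rows).
#' @param gridSize grid points per axis.
#' @param bandwidth optional per-axis bandwidth override (length 1 or 2).
#' @return A list with \code{x}, \code{y} (grid coordinates), \code{z}
#'   (density matrix, \code{z[i, j]} at \code{(x[i], y[j])}) and
#'   \code{bandwidth}.
#' @export
kde2 <- function(points, gridSize = 64, bandwidth = NULL) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (n < 2L) stop("need at least 2 points")
  sds <- apply(pts, 2, stats::sd)
  if (any(sds == 0))
    stop("zero variance in one axis; jitter the data or use a 1-D KDE")
  h <- if (is.null(bandwidth)) sds * n^(-1 / 6) else rep(bandwidth, 2)[1:2]
  gx <- seq(min(pts[, 1]) - 3 * h[1], max(pts[, 1]) + 3 * h[1],
            length.out = gridSize)
  gy <- seq(min(pts[, 2]) - 3 * h[2], max(pts[, 2]) + 3 * h[2],
            length.out = gridSize)
  Fx <- stats::dnorm(outer(gx, pts[, 1], "-"), sd = h[1])
  Fy <- stats::dnorm(outer(gy, pts[, 2], "-"), sd = h[2])
  list(x = gx, y = gy, z = Fx %*% t(Fy) / n, bandwidth = h)
}

# Trapezoidal integral of a kde2 grid (normalisation checks).
kdeIntegral <- function(k) {
  wx <- diff(k$x); wy <- diff(k$y)
  zx <- (k$z[-1, , drop = FALSE] + k$z[-nrow(k$z), , drop = FALSE]) / 2
  zxy <- (zx[, -1, drop = FALSE] + zx[, -ncol(zx), drop = FALSE]) / 2
  sum(zxy * outer(wx, wy))
}
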