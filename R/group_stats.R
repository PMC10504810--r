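#' Mann-Whitney U test
#'
#' Two-sided test reporting the small-side statistic `U = min(U1, U2)`
#' computed from midranks. The p-value uses the exact null distribution
#' (via [stats::pwilcox()]) when there are no ties and `n1 * n2 <= 400`,
#' and otherwise the normal approximation with tie correction.
#'
#' @param a,b numeric samples.
#' @param method `"auto"` (exact when tie-free and small, else normal), or
#'   force `"exact"` / `"normal"`.
#' @return list with `U`, `p`, and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(a, b, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (length(a) == 0 || length(b) == 0) stop("both samples must be nonempty")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)  # midranks
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  U <- min(U1, U2)
  ties <- table(pooled)
  has_ties <- any(ties > 1)
  use_exact <- if (method == "auto") !has_ties && n1 * n2 <= 400
               else method == "exact"
  if (use_exact && has_ties)
    stop("exact p-value is only available without ties")
  if (use_exact) {
    p <- min(1, 2 * pwilcox(U, n1, n2))
    method <- "exact"
  } else {
    N <- n1 + n2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- max(0, (abs(U1 - n1 * n2 / 2) - 0.5)) / sigma  # continuity corr.
      p <- 2 * pnorm(-z)
    }
    method <- "normal"
  }
  list(U = U, p = p, method = method)
}

#' Spearman rank correlation
#'
#' `rho` is the Pearson correlation of midranks; the two-sided p-value comes
#' from the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return list with `rho` and `p`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0)
    stop("constant vector: rank variance is zero")
  rho <- cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' Group comparison and correlation table for the sensory scales
#'
#' One row per sensory scale (total plus the seven modality subscales):
#' per-group median and SD (SD with divide-by-(n-1) on the full per-group
#' sample), the Mann-Whitney U and p for the group difference, and the
#' Spearman correlation (with p) between the scale and the trait total over
#' all respondents. Raw p-values are reported without multiplicity
#' correction.
#'
#' @param scores a `scale_scores` data frame from [score_subscales()].
#' @param group_flag binary vector (0 = reference group, 1 = comparison
#'   group), one element per respondent.
#' @return data frame with 8 rows.
#' @export
comparison_table <- function(scores, group_flag) {
  stopifnot(length(group_flag) == nrow(scores))
  g0 <- group_flag == 0
  g1 <- group_flag == 1
  if (!any(g0) || !any(g1)) stop("both groups must be nonempty")
  scales <- c("sensory_total", modality_names())
  rows <- lapply(scales, function(s) {
    x0 <- scores[[s]][g0]
    x1 <- scores[[s]][g1]
    mw <- mann_whitney(x0, x1)
    sp <- spearman_rho(scores[[s]], scores$trait_total)
    data.frame(scale = s,
               median_ref = median(x0), sd_ref = sd(x0),
               median_grp = median(x1), sd_grp = sd(x1),
               U = mw$U, p_U = mw$p, rho = sp$rho, p_rho = sp$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper over [stats::shapiro.test()] with the sample-size
#' preconditions made explicit.
#'
#' @param x numeric vector with `3 <= length(x) <= 5000`.
#' @return list with `W` and `p`.
#' @export
normality_check <- function(x) {
  n <- length(x)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (var(x) == 0) stop("constant vector")
  st <- shapiro.test(x)
  list(W = unname(st$statistic), p = st$p.value)
}
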