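#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum U statistic for sample `x` relative to `y`. Without ties and
#' with `min(n_x, n_y) <= 8` the two-tailed p-value comes from the exact
#' null distribution of U (`2 * min(P(U <= u), P(U >= u))`, capped at 1);
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact branch;
#'   default `NULL` chooses automatically. Exact with ties is an error.
#' @return A list with `U` (statistic for `x`), `p_value`, `method`,
#'   `n_x`, `n_y`.
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  nx <- length(x)
  ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (is.null(exact)) exact <- !ties && min(nx, ny) <= 8
  if (exact && ties) {
    stop("exact null distribution is unavailable with ties", call. = FALSE)
  }
  if (exact) {
    p_lo <- stats::pwilcox(u, nx, ny)
    p_hi <- 1 - stats::pwilcox(u - 1, nx, ny)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- nx * ny / 2
    n <- nx + ny
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1 # all observations identical: no evidence of separation
    } else {
      z <- max(0, abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-z))
    }
    method <- "normal_approximation"
  }
  list(U = u, p_value = p, method = method, n_x = nx, n_y = ny)
}
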