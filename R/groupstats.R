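#' Exact two-sample Wilcoxon rank-sum test
#'
#' Two-sided exact (unpaired) rank-sum test, the test used to compare the
#' glioma and metastasis cohorts. Ties receive mid-ranks and the null
#' distribution is the exact conditional distribution of the rank sum
#' given the observed (tied) ranks. For total n <= 20 the distribution is
#' built by full enumeration of all group assignments; above that, by a
#' shift-algorithm dynamic program over the (doubled, hence integer)
#' mid-ranks, which is exact as well. The two-sided p doubles the smaller
#' tail and is clipped at 1.
#'
#' @param x,y numeric vectors, both non-empty.
#' @return An object of class `htest`: rank-sum statistic `W` of `x` and
#'   the exact two-sided `p.value`.
#' @export
wilcoxon_exact <- function(x, y) {
  stop_if(length(x) == 0 || length(y) == 0, "both groups must be non-empty")
  stop_if(any(!is.finite(c(x, y))), "inputs must be finite")
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  eps <- 1e-9
  if (n <= 20) {
    cmb <- utils::combn(n, nx)
    sums <- colSums(matrix(r[cmb], nrow = nx))
    pl <- mean(sums <= W + eps)
    pg <- mean(sums >= W - eps)
  } else {
    s <- as.integer(round(2 * r))          # mid-ranks doubled -> integers
    S <- sum(s)
    # f[k+1, t+1] = number of nx-subsets ... of size k with doubled-rank sum t
    f <- matrix(0, nx + 1L, S + 1L)
    f[1L, 1L] <- 1
    for (v in s) {
      kmax <- min(nx, n)                   # fill top-down to avoid reuse
      for (k in kmax:1L) {
        idx <- seq_len(S + 1L - v)
        f[k + 1L, idx + v] <- f[k + 1L, idx + v] + f[k, idx]
      }
    }
    dist <- f[nx + 1L, ]
    tot <- sum(dist)
    W2 <- 2 * W
    tvals <- 0:S
    pl <- sum(dist[tvals <= W2 + eps]) / tot
    pg <- sum(dist[tvals >= W2 - eps]) / tot
  }
  structure(list(statistic = c(W = W),
                 p.value = min(1, 2 * min(pl, pg)),
                 alternative = "two.sided",
                 method = "Exact two-sample Wilcoxon rank-sum test (mid-ranks)",
                 data.name = paste(deparse(substitute(x)), "and",
                                   deparse(substitute(y)))),
            class = "htest")
}

#' One-way repeated-measures ANOVA on log10(x + 1)
#'
#' Compares a percentage (or any non-negative metric) across tissue
#' regions with region as the within-subject factor and specimen as the
#' subject, after the variance-stabilizing transform `log10(x + 1)`.
#' Specimens with a missing region are dropped (complete-case), matching
#' cohorts in which some specimens lack, e.g., a necrotic compartment.
#'
#' @param values numeric matrix or data.frame, specimens in rows, regions
#'   in columns.
#' @return An object of class `htest` with the F `statistic`, numerator /
#'   denominator `parameter` degrees of freedom, `p.value`, and the number
#'   of complete specimens used (`n_complete`).
#' @export
rm_anova_log <- function(values) {
  m <- as.matrix(values)
  stop_if(ncol(m) < 2, "need >= 2 regions")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  stop_if(nrow(m) < 2, "need >= 2 specimens with complete rows")
  stop_if(any(m < 0), "values must be >= 0 (percentages or counts)")
  y <- log10(m + 1)
  k <- ncol(y); ns <- nrow(y)
  d <- data.frame(y = as.vector(y),
                  region = factor(rep(colnames(y) %||% seq_len(k),
                                      each = ns)),
                  specimen = factor(rep(seq_len(ns), times = k)))
  fit <- stats::aov(y ~ region + Error(specimen), data = d)
  tab <- summary(fit)[["Error: Within"]][[1]]
  rows <- trimws(rownames(tab))
  ssr <- tab[rows == "region", "Sum Sq"]
  sse <- tab[rows == "Residuals", "Sum Sq"]
  Fv <- tab[rows == "region", "F value"]
  pv <- tab[rows == "region", "Pr(>F)"]
  tol <- 1e-12 * max(1, sum(y^2))
  if (ssr <= tol) {                     # no region effect at all
    Fv <- 0; pv <- 1
  } else if (!is.finite(Fv) || sse <= tol) {  # zero residual variance
    Fv <- Inf; pv <- 0
  }
  structure(list(statistic = c(F = Fv),
                 parameter = c(`num df` = k - 1,
                               `denom df` = (ns - 1) * (k - 1)),
                 p.value = pv, n_complete = ns,
                 method = "One-way repeated-measures ANOVA on log10(x + 1)",
                 data.name = deparse(substitute(values))),
            class = "htest")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR-adjusted p-values, order-preserving and clipped to 1.
#' Adjusted p below 0.05 is the package-wide significance convention.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_fdr <- function(p) {
  stop_if(any(!is.finite(p)) || any(p < 0 | p > 1),
          "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
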