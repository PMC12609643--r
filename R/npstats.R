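new_test_result <- function(statistic, p_raw, sided, method, comparison,
                            extra = list()) {
  structure(c(list(statistic = statistic,
                   p_raw = p_raw,
                   p_corrected = NA_real_,
                   sided = sided,
                   method = method,
                   comparison = comparison),
              extra),
            class = "pupil_test")
}

#' @export
print.pupil_test <- function(x, ...) {
  stat <- paste(names(x$statistic), "=", signif(unname(x$statistic), 5),
                collapse = ", ")
  cat(sprintf("%s (%s, %s-sided)%s: %s, p = %s%s\n",
              x$method, x$comparison %||% "", x$sided,
              "", stat, format.pval(x$p_raw, digits = 4),
              if (!is.na(x$p_corrected))
                sprintf(" (corrected %s)", format.pval(x$p_corrected, digits = 4))
              else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_sample <- function(x, name) {
  if (!length(x)) stop_domain(paste0(name, " must be non-empty"))
  if (any(!is.finite(x))) stop_domain(paste0(name, " must be finite numeric"))
}

# number of subsets of size n1 whose doubled-midrank sum equals each value:
# exact distribution of the rank sum over all C(N, n1) label assignments,
# computed by dynamic programming (equivalent to complete enumeration,
# tie-aware because mid-ranks enter the sum directly)
ranksum_distribution <- function(ranks2, n1) {
  N <- length(ranks2)
  smax <- sum(sort(ranks2, decreasing = TRUE)[seq_len(n1)])
  # count[k + 1][s + 1] = number of k-subsets with doubled-rank sum s
  count <- matrix(0, nrow = n1 + 1, ncol = smax + 1)
  count[1, 1] <- 1
  for (r in ranks2) {
    kmax <- n1
    for (k in kmax:1) {
      nz <- which(count[k, ] > 0)
      if (length(nz)) {
        dest <- nz + r
        keep <- dest <= smax + 1
        count[k + 1, dest[keep]] <- count[k + 1, dest[keep]] + count[k, nz[keep]]
      }
    }
  }
  count[n1 + 1, ]
}

#' Mann-Whitney U test with exact tie-aware enumeration
#'
#' Computes the Mann-Whitney U statistic for the first sample using mid-ranks
#' for ties. The exact p-value counts, over all `choose(n1 + n2, n1)` label
#' assignments of the pooled values, the assignments with a rank sum as or
#' more extreme than observed (the two-sided p is `min(1, 2 * min(lower tail,
#' upper tail))`; the one-sided p is the smaller tail, i.e. the tail in the
#' direction of the observed effect). The asymptotic method uses the normal
#' approximation with tie-corrected variance and a 0.5 continuity correction.
#'
#' @param x,y numeric samples, non-empty
#' @param sided `"two"` (default) or `"one"`
#' @param method `"auto"` (exact when `choose(n1 + n2, n1) <= exact_limit`,
#'   else asymptotic), `"exact"`, or `"asymptotic"`
#' @param exact_limit enumeration-count cap for the exact method (default 1e7)
#' @param comparison optional label carried into the result
#' @return a `pupil_test` with `statistic` (`U`), `p_raw`, `sided`,
#'   `method` as run (`"exact"`/`"asymptotic"`), and sample sizes `n`
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5), sided = "one")$p_raw   # 0.1 = 1/10
mann_whitney_u <- function(x, y, sided = c("two", "one"),
                           method = c("auto", "exact", "asymptotic"),
                           exact_limit = 1e7, comparison = NULL) {
  sided <- match.arg(sided)
  method <- match.arg(method)
  check_sample(x, "x"); check_sample(y, "y")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2

  n_assign <- choose(N, n1)
  if (method == "exact" && n_assign > exact_limit) {
    stop_domain(sprintf(
      "exact enumeration over %g assignments exceeds the limit %g",
      n_assign, exact_limit))
  }
  use_exact <- method == "exact" || (method == "auto" && n_assign <= exact_limit)

  if (use_exact) {
    ranks2 <- as.integer(round(2 * r))
    dist <- ranksum_distribution(ranks2, n1)
    w2 <- as.integer(round(2 * W))
    s <- seq_along(dist) - 1L
    p_le <- sum(dist[s <= w2]) / n_assign
    p_ge <- sum(dist[s >= w2]) / n_assign
    method_run <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tt <- table(pooled)
    tie_term <- sum(tt^3 - tt) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p_le <- p_ge <- 1
    } else {
      d <- U - mu
      dcc <- sign(d) * max(0, abs(d) - 0.5)   # continuity correction
      z <- dcc / sqrt(sigma2)
      p_le <- stats::pnorm(z)
      p_ge <- stats::pnorm(z, lower.tail = FALSE)
    }
    method_run <- "asymptotic"
  }

  p <- if (sided == "two") min(1, 2 * min(p_le, p_ge)) else min(p_le, p_ge)
  new_test_result(c(U = U), p, sided, method_run,
                  comparison %||% "x vs y",
                  extra = list(n = c(n1 = n1, n2 = n2)))
}

#' Kruskal-Wallis rank test with tie correction
#'
#' `H = [12 / (N (N + 1)) * sum(R_j^2 / n_j) - 3 (N + 1)] / C` with the tie
#' correction `C = 1 - sum(t^3 - t) / (N^3 - N)`; the p-value is the upper
#' chi-square tail on `k - 1` degrees of freedom. When all pooled values are
#' tied the statistic is 0 and p is 1.
#'
#' @param groups list of at least two non-empty numeric samples
#' @param comparison optional label
#' @return a `pupil_test` with `statistic` (`H`) and `df`
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))$statistic  # 32/7
kruskal_wallis <- function(groups, comparison = NULL) {
  if (!is.list(groups) || length(groups) < 2) {
    stop_domain("need a list of at least 2 groups")
  }
  for (i in seq_along(groups)) check_sample(groups[[i]], paste0("group ", i))
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  sizes <- lengths(groups)
  idx <- rep(seq_along(groups), sizes)
  Rj <- tapply(r, idx, sum)
  H0 <- 12 / (N * (N + 1)) * sum(Rj^2 / sizes) - 3 * (N + 1)
  tt <- table(pooled)
  corr <- 1 - sum(tt^3 - tt) / (N^3 - N)
  if (corr <= 0) {            # all values tied
    H <- 0; p <- 1
  } else {
    H <- H0 / corr
    if (abs(H) < 1e-12) H <- 0
    p <- stats::pchisq(H, df = length(groups) - 1, lower.tail = FALSE)
  }
  new_test_result(c(H = H), p, "two", "asymptotic",
                  comparison %||% "k groups",
                  extra = list(df = length(groups) - 1, n = sizes))
}

# all permutations of 1..n as an n! x n matrix (small n only)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Spearman rank correlation with exact permutation p-value
#'
#' `rho` is the Pearson correlation of the mid-ranks (tie-safe). For
#' `n <= exact_n` (default 8) the p-value is exact: the observed `rho` is
#' compared against its value under all `n!` permutations of one variable's
#' ranks (two-sided: proportion of permutations with `|rho|` at least the
#' observed `|rho|`). For larger n the usual t approximation on `n - 2`
#' degrees of freedom is used. A constant input yields a degenerate result
#' (`rho` and p `NA`, method `"degenerate"`) with a warning.
#'
#' @param x,y paired numeric vectors, equal length >= 3
#' @param sided `"two"` (default) or `"one"`
#' @param method `"auto"`, `"exact"` or `"asymptotic"`
#' @param exact_n largest n for which `"auto"` enumerates all permutations
#' @param comparison optional label
#' @return a `pupil_test` with `statistic` (`rho`) and `n`
#' @export
#' @examples
#' spearman_rho(1:3, 3:1)$statistic                  # -1
#' spearman_rho(1:4, c(2, 1, 4, 3))$statistic        # 0.6
spearman_rho <- function(x, y, sided = c("two", "one"),
                         method = c("auto", "exact", "asymptotic"),
                         exact_n = 8, comparison = NULL) {
  sided <- match.arg(sided)
  method <- match.arg(method)
  if (length(x) != length(y)) stop_domain("x and y must have equal length")
  if (length(x) < 3) stop_domain("need at least 3 pairs")
  check_sample(x, "x"); check_sample(y, "y")
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("constant input: Spearman rho is undefined")
    return(new_test_result(c(rho = NA_real_), NA_real_, sided, "degenerate",
                           comparison %||% "x vs y", extra = list(n = n)))
  }
  rho <- stats::cor(rx, ry)

  use_exact <- method == "exact" || (method == "auto" && n <= exact_n)
  if (method == "exact" && n > 10) {
    stop_domain("exact permutation enumeration limited to n <= 10")
  }

  if (use_exact) {
    perms <- all_permutations(n)
    # rho is affine in sum(rx * ry[perm]) for fixed marginals
    cx <- rx - mean(rx); cy <- ry - mean(ry)
    denom <- sqrt(sum(cx^2) * sum(cy^2))
    rhos <- as.vector((matrix(cy[perms], nrow(perms), n) %*% cx) / denom)
    eps <- 1e-12
    p_ge <- mean(rhos >= rho - eps)
    p_le <- mean(rhos <= rho + eps)
    p_two <- mean(abs(rhos) >= abs(rho) - eps)
    p <- if (sided == "two") p_two else min(p_le, p_ge)
    method_run <- "exact"
  } else {
    if (abs(rho) >= 1) {
      p_one <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p_one <- stats::pt(-abs(tstat), df = n - 2)
    }
    p <- if (sided == "two") min(1, 2 * p_one) else p_one
    method_run <- "asymptotic"
  }
  new_test_result(c(rho = rho), p, sided, method_run,
                  comparison %||% "x vs y", extra = list(n = n))
}

#' Bonferroni correction
#'
#' Multiply-and-cap family-wise correction: each p-value is multiplied by `m`
#' (default the number of p-values) and capped at 1; order is preserved.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`
#' @param m number of comparisons, `>= length(p_values)`
#' @return corrected p-values
#' @export
#' @examples
#' bonferroni(c(0.01, 0.02, 0.2))  # 0.03 0.06 0.60
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop_domain("p-values must lie in [0, 1]")
  }
  if (m < length(p_values)) stop_domain("m must be >= length(p_values)")
  pmin(1, p_values * m)
}
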