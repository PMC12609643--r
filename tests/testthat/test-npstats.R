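test_that("exact Mann-Whitney p-values match hand enumeration on known cases", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5), sided = "one", method = "exact")
  expect_equal(r$p_raw, 0.1)          # 1 of C(5,2)=10 assignments as extreme
  expect_equal(unname(r$statistic), 0)

  r2 <- mann_whitney_u(c(1, 2), c(1, 2), sided = "two", method = "exact")
  expect_equal(r2$p_raw, 1)           # symmetric, U at its mean

  # complete separation at the experiment's group sizes
  r3 <- mann_whitney_u(1:5, 11:22, sided = "two", method = "exact")
  expect_equal(r3$p_raw, 2 / choose(17, 5), tolerance = 1e-12)
  expect_equal(r3$method, "exact")
})

test_that("exact Mann-Whitney equals the brute-force enumeration oracle", {
  set.seed(404)
  for (i in 1:250) {
    n1 <- sample(2:7, 1)
    n2 <- sample(2:(9 - n1), 1)
    tied <- i %% 2 == 0
    x <- random_sample(n1, tied); y <- random_sample(n2, tied)
    mine <- mann_whitney_u(x, y, sided = "two", method = "exact")
    oracle <- mwu_enum_oracle(x, y)
    expect_equal(mine$p_raw, min(1, 2 * min(oracle$p_le, oracle$p_ge)),
                 tolerance = 1e-12)
    one <- mann_whitney_u(x, y, sided = "one", method = "exact")
    expect_equal(one$p_raw, min(oracle$p_le, oracle$p_ge), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney symmetry and U complementarity hold", {
  set.seed(405)
  for (i in 1:50) {
    x <- rnorm(sample(2:6, 1)); y <- rnorm(sample(2:6, 1))
    a <- mann_whitney_u(x, y, method = "exact")
    b <- mann_whitney_u(y, x, method = "exact")
    expect_equal(a$p_raw, b$p_raw, tolerance = 1e-12)
    expect_equal(unname(a$statistic + b$statistic), length(x) * length(y))
  }
})

test_that("exact Mann-Whitney agrees with wilcox.test on tie-free samples", {
  set.seed(406)
  for (i in 1:30) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1))
    mine <- mann_whitney_u(x, y, sided = "two", method = "exact")
    ref <- suppressWarnings(wilcox.test(x, y, exact = TRUE, correct = FALSE))
    expect_equal(mine$p_raw, ref$p.value, tolerance = 1e-10)
  }
})

test_that("asymptotic Mann-Whitney converges to exact at moderate sizes", {
  set.seed(407)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10, 0.5)
    pe <- mann_whitney_u(x, y, method = "exact")$p_raw
    pa <- mann_whitney_u(x, y, method = "asymptotic")$p_raw
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("exact enumeration limit is enforced", {
  expect_error(mann_whitney_u(rnorm(30), rnorm(30), method = "exact",
                              exact_limit = 1e4),
               class = "pupilratio_domain_error")
  r <- mann_whitney_u(rnorm(30), rnorm(30), method = "auto", exact_limit = 1e4)
  expect_equal(r$method, "asymptotic")
  expect_error(mann_whitney_u(numeric(0), 1:3),
               class = "pupilratio_domain_error")
})

test_that("Kruskal-Wallis reproduces hand-computed statistics and degenerate cases", {
  k <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(unname(k$statistic), 32 / 7, tolerance = 1e-12)
  expect_equal(k$df, 2)

  const <- kruskal_wallis(list(c(5, 5), c(5, 5, 5), c(5)))
  expect_equal(unname(const$statistic), 0)
  expect_equal(const$p_raw, 1)

  expect_error(kruskal_wallis(list(1:3)), class = "pupilratio_domain_error")
  expect_error(kruskal_wallis(list(1:3, numeric(0))),
               class = "pupilratio_domain_error")
})

test_that("Kruskal-Wallis is rank-based and matches kruskal.test", {
  set.seed(408)
  for (i in 1:25) {
    g <- list(rnorm(5), rnorm(5, 1), rnorm(12, 2))
    a <- kruskal_wallis(g)
    b <- kruskal_wallis(lapply(g, function(v) exp(v)))  # strictly monotone map
    expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
    ref <- kruskal.test(unlist(g), factor(rep(1:3, lengths(g))))
    expect_equal(unname(a$statistic), unname(ref$statistic), tolerance = 1e-10)
    expect_equal(a$p_raw, ref$p.value, tolerance = 1e-10)
  }
  # tie correction against kruskal.test on tied data
  g <- list(c(1, 2, 2), c(2, 3, 3), c(3, 4, 4))
  ref <- kruskal.test(unlist(g), factor(rep(1:3, each = 3)))
  expect_equal(unname(kruskal_wallis(g)$statistic), unname(ref$statistic),
               tolerance = 1e-10)
})

test_that("two-group Kruskal-Wallis equals the squared MWU z statistic", {
  set.seed(409)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(7, 0.3)
    H <- unname(kruskal_wallis(list(x, y))$statistic)
    U <- unname(mann_whitney_u(x, y)$statistic)
    n1 <- 6; n2 <- 7; N <- 13
    z <- (U - n1 * n2 / 2) / sqrt(n1 * n2 * (N + 1) / 12)
    expect_equal(H, z^2, tolerance = 1e-10)
  }
})

test_that("Spearman rho matches closed-form small examples", {
  expect_equal(unname(spearman_rho(1:3, 3:1)$statistic), -1)
  expect_equal(unname(spearman_rho(c(2, 5, 9), c(1, 4, 7))$statistic), 1)
  expect_equal(unname(spearman_rho(1:4, c(2, 1, 4, 3))$statistic), 0.6)
})

test_that("exact Spearman p equals full permutation enumeration", {
  set.seed(410)
  for (i in 1:120) {
    n <- sample(3:6, 1)
    tied <- i %% 3 == 0
    x <- random_sample(n, tied); y <- random_sample(n, tied)
    if (sd(rank(x)) == 0 || sd(rank(y)) == 0) next
    mine <- spearman_rho(x, y, method = "exact")
    oracle <- spearman_enum_oracle(x, y)
    expect_equal(unname(mine$statistic), oracle$rho, tolerance = 1e-12)
    expect_equal(mine$p_raw, oracle$p_two, tolerance = 1e-12)
    one <- spearman_rho(x, y, sided = "one", method = "exact")
    expect_equal(one$p_raw, min(oracle$p_le, oracle$p_ge), tolerance = 1e-12)
  }
})

test_that("exact Spearman p agrees with cor.test on tie-free data", {
  set.seed(411)
  for (i in 1:25) {
    n <- sample(5:8, 1)
    x <- rnorm(n); y <- rnorm(n)
    mine <- spearman_rho(x, y, method = "exact")
    ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
    expect_equal(unname(mine$statistic), unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p_raw, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Spearman handles large-n approximation and degenerate input", {
  set.seed(412)
  x <- rnorm(12); y <- x + rnorm(12, 0, 0.2)
  r <- spearman_rho(x, y)
  expect_equal(r$method, "asymptotic")
  ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(r$p_raw, ref$p.value, tolerance = 1e-10)

  expect_warning(d <- spearman_rho(rep(1, 5), rnorm(5)), "constant")
  expect_equal(d$method, "degenerate")
  expect_true(is.na(d$p_raw))
  expect_error(spearman_rho(1:3, 1:4), class = "pupilratio_domain_error")
  expect_error(spearman_rho(1:2, 1:2), class = "pupilratio_domain_error")
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(c(0.01, 0.02, 0.2)), c(0.03, 0.06, 0.6))
  expect_equal(bonferroni(0.5, m = 3), 1)
  expect_equal(bonferroni(2 / 6188, m = 3), 6 / 6188)
  expect_lt(bonferroni(2 / 6188, m = 3), 0.001)
  expect_error(bonferroni(c(0.5, 1.2)), class = "pupilratio_domain_error")
  expect_error(bonferroni(c(0.1, 0.2), m = 1), class = "pupilratio_domain_error")
})
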