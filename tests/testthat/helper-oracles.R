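# Brute-force oracles, independent of the package's computational paths.

# Mann-Whitney exact tail probabilities by literal enumeration of all
# choose(N, n1) label assignments of the pooled mid-ranks.
mwu_enum_oracle <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  W_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(r), n1)
  W_all <- apply(combos, 2, function(idx) sum(r[idx]))
  eps <- 1e-9
  list(p_le = mean(W_all <= W_obs + eps),
       p_ge = mean(W_all >= W_obs - eps))
}

# Spearman exact two-sided p by literal enumeration of all n! pairings,
# recomputing rho definitionally with cor() on ranks each time.
spearman_enum_oracle <- function(x, y) {
  n <- length(x)
  rho_obs <- stats::cor(rank(x), rank(y))
  perms <- perms_of(n)
  rx <- rank(x); ry <- rank(y)
  rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
  eps <- 1e-9
  list(rho = rho_obs,
       p_two = mean(abs(rhos) >= abs(rho_obs) - eps),
       p_le = mean(rhos <= rho_obs + eps),
       p_ge = mean(rhos >= rho_obs - eps))
}

perms_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# Brute-force solution of the non-increasing isotonic regression QP:
# minimise sum w_i (y_i - f_i)^2 subject to f_1 >= f_2 >= ... >= f_n.
# The optimum is piecewise constant on blocks with each block at its weighted
# mean, so enumerate all 2^(n-1) block partitions and keep the feasible
# minimiser.
iso_qp_oracle <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  best <- NULL; best_sse <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    fit <- numeric(n); means <- numeric(length(bounds) - 1)
    for (b in seq_len(length(bounds) - 1)) {
      idx <- (bounds[b] + 1):bounds[b + 1]
      means[b] <- sum(w[idx] * y[idx]) / sum(w[idx])
      fit[idx] <- means[b]
    }
    if (length(means) > 1 && any(diff(means) > 1e-12)) next  # not non-increasing
    sse <- sum(w * (y - fit)^2)
    if (sse < best_sse - 1e-12) { best_sse <- sse; best <- fit }
  }
  best
}

# small random cohort-free fixture helpers
random_sample <- function(n, tied = FALSE) {
  if (tied) sample(1:4, n, replace = TRUE) else stats::rnorm(n)
}

make_cohort_df <- function(pupil_diam, group, degen, id = NULL, dada = NULL,
                           degen_pct = NULL) {
  n <- length(pupil_diam)
  df <- data.frame(
    id = id %||% sprintf("s%02d", seq_len(n)),
    group = group,
    pupil_radius = pupil_diam / 2,
    iris_radius = NA_real_,
    dada_index = if (is.null(dada)) NA_real_ else dada,
    degen_density = degen,
    degen_pct = if (is.null(degen_pct)) NA_real_ else degen_pct,
    latent_severity = NA_real_,
    stringsAsFactors = FALSE)
  class(df) <- c("pupil_cohort", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
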