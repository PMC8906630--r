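# Independent oracles, deliberately coded as scalar/brute-force routes
# separate from the package implementation.

# --- colour models: scalar per-pixel formula evaluation -------------------

oracle_hsv <- function(r, g, b) {
  mx <- max(r, g, b); mn <- min(r, g, b)
  v <- mx
  s <- if (mx > 0) (mx - mn) / mx else 0
  h <- 0
  if (mx > mn) {
    if (mx == r) {
      h <- (g - b) / (mx - mn)
      if (h < 0) h <- h + 6
    } else if (mx == g) {
      h <- 2 + (b - r) / (mx - mn)
    } else {
      h <- 4 + (r - g) / (mx - mn)
    }
    h <- h / 6
    if (h >= 1) h <- h - 1
  }
  c(h, s, v)
}

# uses the kappa/epsilon algebraic form of the CIE functions rather than
# the 6/29 form in the implementation
oracle_lab <- function(r, g, b) {
  gam <- function(u) if (u <= 0.04045) u / 12.92 else ((u + 0.055) / 1.055)^2.4
  rl <- gam(r); gl <- gam(g); bl <- gam(b)
  x <- 0.4124564 * rl + 0.3575761 * gl + 0.1804375 * bl
  y <- 0.2126729 * rl + 0.7151522 * gl + 0.0721750 * bl
  z <- 0.0193339 * rl + 0.1191920 * gl + 0.9503041 * bl
  xn <- 0.4124564 + 0.3575761 + 0.1804375
  yn <- 0.2126729 + 0.7151522 + 0.0721750
  zn <- 0.0193339 + 0.1191920 + 0.9503041
  eps <- 216 / 24389; kap <- 24389 / 27
  f <- function(t) if (t > eps) t^(1 / 3) else (kap * t + 16) / 116
  fx <- f(x / xn); fy <- f(y / yn); fz <- f(z / zn)
  c(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
}

oracle_ycbcr <- function(r, g, b) {
  c(16 + 65.481 * r + 128.553 * g + 24.966 * b,
    128 - 37.797 * r - 74.203 * g + 112 * b,
    128 + 112 * r - 93.786 * g - 18.214 * b)
}

oracle_vector12 <- function(r255, g255, b255) {
  r <- r255 / 255; g <- g255 / 255; b <- b255 / 255
  c(r255, g255, b255, oracle_hsv(r, g, b), oracle_lab(r, g, b),
    oracle_ycbcr(r, g, b))
}

# --- Wilcoxon signed-rank: full sign-flip enumeration ---------------------

# two-sided p = P(min rank sum <= observed) over all 2^n sign assignments
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  total <- sum(r)
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  ws <- apply(signs, 1L, function(s) {
    wp <- sum(r[s])
    min(wp, total - wp)
  })
  mean(ws <= w_obs + 1e-12)
}

# --- Spearman: permutation enumeration via Pearson-of-ranks ---------------

oracle_all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    for (p in oracle_all_perms(n - 1L)) out[[length(out) + 1L]] <- c(k, rest[p])
  }
  out
}

oracle_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  rhos <- vapply(oracle_all_perms(length(x)),
                 function(idx) cor(rx, ry[idx]), numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# --- repeated-measures ANOVA: classical marginal-mean sums of squares -----

# p-values use unadjusted degrees of freedom (fixtures are chosen with
# Mauchly p > 0.05 so no correction applies on either route)
oracle_rm_anova <- function(arr) {
  n <- dim(arr)[1L]; a <- dim(arr)[2L]; k <- dim(arr)[3L]
  gm <- mean(arr)
  m_s <- apply(arr, 1L, mean)
  m_a <- apply(arr, 2L, mean)
  m_k <- apply(arr, 3L, mean)
  m_sa <- apply(arr, c(1L, 2L), mean)
  m_sk <- apply(arr, c(1L, 3L), mean)
  m_ak <- apply(arr, c(2L, 3L), mean)
  ss <- function(x) sum(x^2)
  ss_a <- n * k * ss(m_a - gm)
  ss_k <- n * a * ss(m_k - gm)
  ss_sa <- k * ss(sweep(sweep(m_sa, 1L, m_s), 2L, m_a) + gm)
  ss_sk <- a * ss(sweep(sweep(m_sk, 1L, m_s), 2L, m_k) + gm)
  ss_ak <- n * ss(sweep(sweep(m_ak, 1L, m_a), 2L, m_k) + gm)
  # three-way residual: cell minus all two-way margins plus all mains minus gm
  resid <- arr
  for (i in 1:n) for (j in 1:a) for (t in 1:k)
    resid[i, j, t] <- arr[i, j, t] - m_sa[i, j] - m_sk[i, t] - m_ak[j, t] +
      m_s[i] + m_a[j] + m_k[t] - gm
  ss_sak <- ss(resid)
  f_a <- (ss_a / (a - 1)) / (ss_sa / ((n - 1) * (a - 1)))
  f_k <- (ss_k / (k - 1)) / (ss_sk / ((n - 1) * (k - 1)))
  f_ak <- (ss_ak / ((a - 1) * (k - 1))) / (ss_sak / ((n - 1) * (a - 1) * (k - 1)))
  list(
    group = list(F = f_a, p = pf(f_a, a - 1, (n - 1) * (a - 1), lower.tail = FALSE)),
    time = list(F = f_k, p = pf(f_k, k - 1, (n - 1) * (k - 1), lower.tail = FALSE)),
    interaction = list(F = f_ak,
                       p = pf(f_ak, (a - 1) * (k - 1), (n - 1) * (a - 1) * (k - 1),
                              lower.tail = FALSE)))
}

# --- shared fixtures ------------------------------------------------------

# the frozen 5-subject x 2-group x 4-time fixture used by the ANOVA oracle
# comparisons (its Mauchly p-values are > 0.05 on both effects)
rm_fixture <- function() {
  set.seed(4242)
  arr <- array(rnorm(5 * 2 * 4, mean = rep(c(0, 0.5), each = 5), sd = 1),
               c(5, 2, 4))
  arr + rep(seq(0, 1.5, 0.5), each = 10)
}

uniform_image <- function(rgb, h = 8, w = 8, ...) {
  skin_image(array(rep(rgb, each = h * w), c(h, w, 3)), ...)
}
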