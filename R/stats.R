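# Statistical procedures of the longitudinal analysis:
#  - Spearman rank correlation (midrank ties; t approximation by default,
#    exact permutation enumeration available for small n)
#  - Wilcoxon signed-rank test (zero differences discarded, min-sum W,
#    exact tail for n <= 15 without ties, else normal approximation with
#    tie and continuity corrections), with a Bonferroni-adjusted level
#  - Two-way repeated-measures ANOVA with both factors within-subject,
#    Mauchly's sphericity test per multi-level effect, and the
#    Greenhouse-Geisser correction applied when sphericity is rejected.

#' Bonferroni-adjusted significance level
#'
#' @param family_alpha Family-wise level (default 0.05).
#' @param m Number of comparisons in the family.
#' @return `family_alpha / m`. With the default family of 3 longitudinal
#'   comparisons this is 0.0167 (4 dp).
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, m = 3) {
  if (m < 1) stop("`m` must be >= 1")
  family_alpha / m
}

#' Spearman rank correlation
#'
#' Ranks use midranks for ties; rho is the Pearson correlation of the rank
#' vectors. The two-sided p-value uses the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of freedom (the
#' behaviour of the large statistical suites this analysis mirrors); for
#' `method = "exact"` (n <= 8, no ties required for exactness) the full
#' permutation distribution of rho is enumerated instead. `|rho| = 1`
#' yields p = 0 under the t approximation (the degenerate limit).
#'
#' @param x,y Numeric vectors of equal length n >= 3.
#' @param method `"t-approx"` (default) or `"exact"`.
#' @return List with `rho`, `p`, `n`, `method`.
#' @export
spearman_corr <- function(x, y, method = c("t-approx", "exact")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (method == "exact") {
    if (n > 8) stop("exact enumeration supported for n <= 8")
    perms <- .all_permutations(n)
    rhos <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1 - 1e-15) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  list(rho = rho, p = p, n = n, method = method)
}

.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences of exactly zero are discarded (Wilcoxon's convention);
#' absolute differences are midranked and W is the smaller of the positive
#' and negative rank sums. The two-sided p-value is exact (signed-rank
#' null distribution) when the effective n is at most 15 and the absolute
#' differences are tie-free; otherwise a normal approximation with tie
#' correction and a continuity correction is used.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @param alpha_adjusted Significance level the `significant` flag is
#'   evaluated at; defaults to the Bonferroni-adjusted 0.05/3.
#' @return List with `statistic` (W), `p`, `n_effective`, `significant`,
#'   `method`.
#' @export
wilcoxon_signed_rank <- function(a, b, alpha_adjusted = bonferroni_alpha()) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length")
  d <- a - b
  if (!all(is.finite(d))) stop("inputs must be finite")
  d <- d[d != 0]
  n <- length(d)
  if (n < 1) stop("degenerate test: all paired differences are zero")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  w <- min(w_pos, w_neg)
  ties <- any(duplicated(abs(d)))
  if (n <= 15 && !ties) {
    method <- "exact"
    p <- min(1, 2 * stats::psignrank(w, n))
  } else {
    method <- "normal approximation"
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (w - n * (n + 1) / 4 + 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z))
  }
  list(statistic = w, p = p, n_effective = n,
       significant = p < alpha_adjusted, method = method)
}

# Orthonormal contrast matrix for a k-level within-subject factor
# (normalized Helmert contrasts), rows = k-1 contrasts.
.orthonormal_contrasts <- function(k) {
  h <- stats::contr.helmert(k)
  t(sweep(h, 2L, sqrt(colSums(h^2)), `/`))
}

# Mauchly's sphericity test and Greenhouse-Geisser epsilon from the
# covariance of subject-level orthonormal contrast scores (n x p matrix z).
.sphericity <- function(z) {
  n <- nrow(z); p <- ncol(z)
  S <- stats::cov(z)
  lambda <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  eps <- sum(lambda)^2 / (p * sum(lambda^2))
  if (p < 2 || n - 1 <= p || sum(lambda) <= 0)
    return(list(epsilon = ifelse(sum(lambda) <= 0, 1, eps), mauchly_p = NA_real_))
  W <- det(S) / (sum(diag(S)) / p)^p
  if (W <= 0) return(list(epsilon = eps, mauchly_p = 0))
  # Box's chi-square series approximation (the standard two-term form)
  d <- n - 1
  rho <- 1 - (2 * p^2 + p + 2) / (6 * p * d)
  # the 3*(p+1) term carries the raw level count, matching the reference
  # implementations in the major statistics packages
  w2 <- (p + 2) * (p - 1) * (p - 2) * (2 * p^3 + 6 * p^2 + 3 * (p + 1) + 2) /
    (288 * p^2 * d^2 * rho^2)
  z <- -d * rho * log(W)
  dof <- p * (p + 1) / 2 - 1
  pval <- stats::pchisq(z, dof, lower.tail = FALSE) +
    w2 * (stats::pchisq(z, dof + 4, lower.tail = FALSE) -
          stats::pchisq(z, dof, lower.tail = FALSE))
  list(epsilon = eps, mauchly_p = pval)
}

#' Two-way repeated-measures ANOVA (both factors within-subject)
#'
#' For a subjects x group x time array of one colour parameter, partitions
#' the within-subject variation into group, time and group x time effects,
#' each tested against its own subject-interaction error stratum. For
#' every effect with more than one degree of freedom, Mauchly's test is
#' run on the covariance of the subject-level orthonormal contrast scores;
#' when it rejects at `sphericity_alpha` the effect's degrees of freedom
#' are multiplied by the Greenhouse-Geisser epsilon (computed from the
#' eigenvalues of that covariance) before the p-value is evaluated.
#'
#' Degenerate strata (no variation in either the effect or its error sum
#' of squares) report F = 0 and p = 1.
#'
#' @param values Numeric array `n_subjects x n_groups x n_times` (groups
#'   or times may have a single level, in which case the corresponding
#'   effects are skipped), or a `LongitudinalMatrix`-style data frame with
#'   columns `subject`, `group`, `time`, `value`.
#' @param sphericity_alpha Level of Mauchly's test gating the correction
#'   (default 0.05).
#' @return Tibble with one row per effect: `effect`, `F`, `df1`, `df2`
#'   (epsilon-scaled when the correction applies), `epsilon_gg`,
#'   `mauchly_p`, `gg_applied`, `p`.
#' @export
rm_anova <- function(values, sphericity_alpha = 0.05) {
  if (is.data.frame(values)) values <- .long_to_array(values)
  d <- dim(values)
  if (length(d) != 3L) stop("`values` must be a subjects x groups x times array")
  n <- d[1L]; a <- d[2L]; k <- d[3L]
  if (n < 3) stop("need at least 3 subjects")
  if (any(!is.finite(values))) stop("the design must be complete (no missing cells)")
  # subject x cell matrix, cells ordered group-major (g1t1, g1t2, ..)
  Y <- matrix(values, nrow = n)
  mean_g <- rep(1 / sqrt(a), a)
  mean_k <- rep(1 / sqrt(k), k)
  Cg <- if (a > 1) .orthonormal_contrasts(a)
  Ck <- if (k > 1) .orthonormal_contrasts(k)
  # cell order of matrix(values, n): group index varies fastest
  effects <- list()
  if (a > 1) effects$group <- kronecker(matrix(mean_k, 1), Cg) # (a-1) x ak
  if (k > 1) effects$time <- kronecker(Ck, matrix(mean_g, 1)) # (k-1) x ak
  if (a > 1 && k > 1) effects$`group:time` <- kronecker(Ck, Cg)
  rows <- lapply(names(effects), function(nm) {
    D <- effects[[nm]]
    Z <- Y %*% t(D)
    zbar <- colMeans(Z)
    ss_eff <- n * sum(zbar^2)
    ss_err <- sum(sweep(Z, 2L, zbar)^2)
    df1 <- nrow(D)
    df2 <- (n - 1) * df1
    sph <- .sphericity(Z)
    gg <- !is.na(sph$mauchly_p) && sph$mauchly_p < sphericity_alpha
    if (ss_eff < 1e-12 && ss_err < 1e-12) {
      f <- 0; p <- 1
    } else if (ss_err < 1e-12) {
      f <- Inf; p <- 0
    } else {
      f <- (ss_eff / df1) / (ss_err / df2)
      e <- if (gg) sph$epsilon else 1
      p <- stats::pf(f, df1 * e, df2 * e, lower.tail = FALSE)
    }
    tibble::tibble(effect = nm, F = f,
                   df1 = df1 * (if (gg) sph$epsilon else 1),
                   df2 = df2 * (if (gg) sph$epsilon else 1),
                   epsilon_gg = sph$epsilon, mauchly_p = sph$mauchly_p,
                   gg_applied = gg, p = p)
  })
  dplyr::bind_rows(rows)
}

.long_to_array <- function(df) {
  need <- c("subject", "group", "time", "value")
  if (!all(need %in% names(df)))
    stop("long input needs columns: ", paste(need, collapse = ", "))
  subj <- sort(unique(df$subject))
  grp <- unique(df$group)
  tim <- unique(df$time)
  arr <- array(NA_real_, c(length(subj), length(grp), length(tim)),
               dimnames = list(subj, grp, tim))
  arr[cbind(match(df$subject, subj), match(df$group, grp),
            match(df$time, tim))] <- df$value
  arr
}
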