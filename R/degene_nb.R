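ALPHA_FLOOR <- 1e-8

#' Method-of-moments NB dispersion with trend shrinkage
#'
#' For each gene the dispersion of the NB2 parameterization
#' (`variance = mu + alpha mu^2`) is estimated on normalized counts as
#' `alpha = max((s2 - mu)/mu^2, alpha_floor)`, pooling the within-group
#' variance across the design groups. Because per-gene variances are noisy at
#' 2-3 replicates, the raw estimates are optionally shrunk (on the log scale)
#' toward a log-log linear mean-dispersion trend fitted across genes;
#' `shrink = 0` gives the pure method-of-moments estimator.
#'
#' @param counts Genes x samples count matrix.
#' @param nf Normalization-factor matrix (same shape) or per-sample size
#'   factors.
#' @param groups Factor of group membership per sample; every group needs at
#'   least 2 replicates.
#' @param shrink Shrinkage weight toward the fitted trend, in `[0, 1]`
#'   (default 0.5).
#' @param alpha_floor Lower bound for dispersion estimates.
#' @return Per-gene dispersion vector (named by gene).
#' @export
estimate_dispersion <- function(counts, nf, groups, shrink = 0.5,
                                alpha_floor = ALPHA_FLOOR) {
  counts <- as.matrix(counts)
  if (is.null(dim(nf))) {
    nf <- matrix(nf, nrow = nrow(counts), ncol = ncol(counts), byrow = TRUE)
  }
  groups <- as.factor(groups)
  if (any(table(groups) < 2)) stop("every group needs at least 2 replicates")
  norm <- counts / nf

  ss <- 0
  df <- 0
  mu <- rowMeans(norm)
  for (g in levels(groups)) {
    cols <- which(groups == g)
    dev <- norm[, cols, drop = FALSE] -
      rowMeans(norm[, cols, drop = FALSE])
    ss <- ss + rowSums(dev^2)
    df <- df + (length(cols) - 1L)
  }
  s2 <- ss / df
  raw <- ifelse(mu > 0, pmax((s2 - mu) / mu^2, alpha_floor), alpha_floor)

  alpha <- raw
  if (shrink > 0) {
    ok <- raw > 100 * alpha_floor & mu > 0
    if (sum(ok) >= 10) {
      fit <- lm(log(raw[ok]) ~ log(mu[ok]))
      trend <- coef(fit)[1] + coef(fit)[2] * log(pmax(mu, 1e-8))
      # small-sample Jensen correction: the log of a variance estimate with
      # df degrees of freedom underestimates the true log-variance by
      # digamma(df/2) - log(df/2); without it the blended dispersions are
      # biased low and the Wald test is anti-conservative at 2-3 replicates
      bias <- log(df / 2) - digamma(df / 2)
      alpha <- ifelse(mu > 0,
                      pmax(exp((1 - shrink) * log(raw) + shrink * trend +
                                 bias),
                           alpha_floor),
                      alpha_floor)
      # dispersion outliers ABOVE the trend by more than twice the sampling
      # noise of a log chi-square variance (sd = sqrt(trigamma(df/2))) are
      # genuine high-dispersion genes, not estimation noise: shrinking them
      # toward the trend understates their variance and manufactures false
      # positives, so they keep their gene-wise estimate
      resid <- log(raw) - trend
      sd_sampling <- sqrt(trigamma(df / 2))
      hi <- ok & resid > 2 * sd_sampling
      alpha[hi] <- pmax(raw[hi] * exp(bias), alpha[hi])
    }
  }
  alpha <- setNames(alpha, rownames(counts))
  # effective degrees of freedom of the variance information behind each
  # Wald statistic: blending log-dispersions with the (nearly noiseless)
  # trend at weight w scales their sampling variance by (1-w)^2, so the
  # equivalent chi-square df solves trigamma(df_eff/2) = (1-w)^2
  # trigamma(df/2)
  attr(alpha, "df_total") <- if (shrink > 0 && shrink < 1) {
    target <- (1 - shrink)^2 * trigamma(df / 2)
    2 * stats::uniroot(function(x) trigamma(x) - target,
                       interval = c(df / 2, 1000))$root
  } else {
    df
  }
  alpha
}

# Newton fit of an NB log-link GLM with known dispersion and log-offsets,
# using the expected Fisher information. Returns coefficients (natural log
# scale), their covariance, and a convergence/singularity flag.
nb_fit <- function(y, X, off, alpha, maxit = 50, tol = 1e-10,
                   beta_max = 50) {
  p <- ncol(X)
  mu0 <- pmax(y, 0.5)
  beta <- tryCatch(qr.solve(X, log(mu0) - off), error = function(e) rep(0, p))
  beta <- pmin(pmax(beta, -beta_max), beta_max)
  singular <- FALSE
  converged <- FALSE
  info <- NULL
  for (it in seq_len(maxit)) {
    mu <- exp(pmin(X %*% beta + off, 700))
    w <- as.vector(mu / (1 + alpha * mu))
    score <- crossprod(X, (y - mu) / (1 + alpha * mu))
    info <- crossprod(X, X * w)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) {
      step <- tryCatch(solve(info + diag(1e-8, p), score),
                       error = function(e) NULL)
      if (is.null(step)) { singular <- TRUE; break }
    }
    step <- pmin(pmax(step, -5), 5)   # damp huge steps near separation
    beta_new <- pmin(pmax(beta + step, -beta_max), beta_max)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  cov <- tryCatch(solve(info), error = function(e) {
    singular <<- TRUE
    matrix(NA_real_, p, p)
  })
  list(beta = as.vector(beta), cov = cov, converged = converged,
       singular = singular)
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' The reported `l2fc` is the (unshrunken) log2 ratio of the two group means
#' of normalized counts — the estimator implied by requiring exact
#' normalization equivariance (scaling one sample's counts and factors
#' together must leave every fold change unchanged, which an offset-GLM MLE
#' does not guarantee). Its standard error comes from the NB variance model
#' `Var(K) = mu + alpha mu^2` by the delta method, and the two-sided p-value
#' from the reference distribution of `l2fc/se`. Genes with all-zero counts
#' get `l2fc = 0`, `p = 1`; a group with an all-zero mean receives a 0.5
#' pseudo-count continuity correction and is flagged `zero_group`.
#'
#' By default the Wald statistic is referred to a t distribution whose
#' degrees of freedom reflect how much data went into the plug-in dispersion
#' (taken from the `df_total` attribute set by [estimate_dispersion()]); a
#' plain normal reference (`t_df = Inf`) ignores dispersion-estimation noise
#' and is anti-conservative in the extreme tail at 2-3 replicates.
#'
#' @param counts Genes x samples count matrix.
#' @param group Factor/character of group membership per sample (two levels).
#' @param nf Normalization-factor matrix (genes x samples) or per-sample size
#'   factors; `NULL` uses median-of-ratios size factors.
#' @param alpha Per-gene NB dispersion (scalar or vector), `>= 0`.
#' @param numerator,denominator Group labels fixing the sign convention:
#'   `l2fc = log2(numerator / denominator)`.
#' @param t_df Degrees of freedom for the t reference of the Wald statistic;
#'   default: the `df_total` attribute of `alpha` when present, else `Inf`
#'   (normal reference).
#' @return `data.frame` of class `contrast_result`: `gene`, `base_mean` (mean
#'   normalized count), `l2fc`, `se`, `p`, `flag`.
#' @export
nb_wald <- function(counts, group, nf = NULL, alpha, numerator,
                    denominator = NULL, t_df = NULL) {
  if (is.null(t_df)) {
    t_df <- attr(alpha, "df_total")
    if (is.null(t_df)) t_df <- Inf
  }
  counts <- as.matrix(counts)
  group <- as.character(group)
  if (is.null(denominator)) {
    denominator <- setdiff(unique(group), numerator)[1]
  }
  in_num <- group == numerator
  in_den <- group == denominator
  if (!any(in_num) || !any(in_den)) stop("both groups must be non-empty")
  if (any(alpha < 0)) stop("dispersion must be >= 0")
  if (is.null(nf)) nf <- size_factors(counts)
  if (is.null(dim(nf))) {
    nf <- matrix(nf, nrow = nrow(counts), ncol = ncol(counts), byrow = TRUE)
  }
  alpha <- rep(alpha, length.out = nrow(counts))

  use <- in_num | in_den
  norm <- counts / nf
  base_mean <- rowMeans(norm[, use, drop = FALSE])

  g <- nrow(counts)
  n_n <- sum(in_num); n_d <- sum(in_den)
  q_n <- rowMeans(norm[, in_num, drop = FALSE])
  q_d <- rowMeans(norm[, in_den, drop = FALSE])
  flag <- rep("ok", g)
  all_zero <- q_n == 0 & q_d == 0
  flag[all_zero] <- "all_zero"
  zero_grp <- xor(q_n == 0, q_d == 0)
  flag[zero_grp] <- "zero_group"
  # continuity correction for a group whose mean is exactly zero
  q_n <- ifelse(q_n == 0, 0.5 / rowSums(nf[, in_num, drop = FALSE]), q_n)
  q_d <- ifelse(q_d == 0, 0.5 / rowSums(nf[, in_den, drop = FALSE]), q_d)

  # delta method on log q_j: Var(mean_s y_s/f_s) = (1/n^2) sum(q/f_s + a q^2)
  se2_n <- rowSums(1 / (q_n * nf[, in_num, drop = FALSE])) / n_n^2 +
    alpha / n_n
  se2_d <- rowSums(1 / (q_d * nf[, in_den, drop = FALSE])) / n_d^2 +
    alpha / n_d
  log2e <- log(2)
  l2fc <- log2(q_n / q_d)
  se <- sqrt(se2_n + se2_d) / log2e
  p <- 2 * stats::pt(-abs(l2fc / se), df = t_df)
  l2fc[all_zero] <- 0
  se[all_zero] <- NA_real_
  p[all_zero] <- 1

  out <- data.frame(gene = rownames(counts), base_mean = base_mean,
                    l2fc = l2fc, se = se, p = p, flag = flag,
                    stringsAsFactors = FALSE)
  attr(out, "contrast") <- c(numerator = numerator,
                             denominator = denominator)
  class(out) <- c("contrast_result", "data.frame")
  rownames(out) <- NULL
  out
}

#' Negative-binomial Wald test on an arbitrary coefficient
#'
#' General-design variant of [nb_wald()] used for interaction tests: fits the
#' NB GLM with the given model matrix and reports the Wald test for one
#' coefficient on the log2 scale.
#'
#' @param counts Genes x samples count matrix.
#' @param X Model matrix (samples x coefficients), natural-log scale.
#' @param coef Name or index of the tested coefficient.
#' @param nf Normalization-factor matrix or per-sample factors.
#' @param alpha Per-gene dispersion vector.
#' @param t_df Degrees of freedom for the t reference (see [nb_wald()]).
#' @return `contrast_result` data frame (`l2fc` is the tested coefficient in
#'   log2 units).
#' @export
nb_wald_coef <- function(counts, X, coef, nf, alpha, t_df = NULL) {
  if (is.null(t_df)) {
    t_df <- attr(alpha, "df_total")
    if (is.null(t_df)) t_df <- Inf
  }
  counts <- as.matrix(counts)
  if (is.character(coef)) coef <- match(coef, colnames(X))
  if (is.na(coef)) stop("unknown coefficient")
  if (is.null(dim(nf))) {
    nf <- matrix(nf, nrow = nrow(counts), ncol = ncol(counts), byrow = TRUE)
  }
  alpha <- rep(alpha, length.out = nrow(counts))
  norm <- counts / nf
  g <- nrow(counts)
  l2fc <- numeric(g); se <- rep(NA_real_, g); p <- rep(1, g)
  flag <- rep("ok", g)
  for (i in seq_len(g)) {
    y <- counts[i, ]
    if (all(y == 0)) { flag[i] <- "all_zero"; next }
    fit <- nb_fit(y, X, log(nf[i, ]), alpha[i])
    l2fc[i] <- fit$beta[coef] / log(2)
    se[i] <- sqrt(fit$cov[coef, coef]) / log(2)
    if (fit$singular || !is.finite(se[i])) {
      flag[i] <- "singular"; p[i] <- NA_real_; next
    }
    if (!fit$converged) flag[i] <- "not_converged"
    p[i] <- 2 * stats::pt(-abs(l2fc[i] / se[i]), df = t_df)
  }
  out <- data.frame(gene = rownames(counts), base_mean = rowMeans(norm),
                    l2fc = l2fc, se = se, p = p, flag = flag,
                    stringsAsFactors = FALSE)
  class(out) <- c("contrast_result", "data.frame")
  rownames(out) <- NULL
  out
}
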