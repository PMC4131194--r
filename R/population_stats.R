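# Population-level inference on the per-cell feature table: one- vs
# two-component Gaussian comparison, K-means (k = 2) with separation test,
# Ward clustering on the seven z-scored intrinsic parameters, age-binned group
# probabilities, parabolic mean-variance fits and per-group correlations.

SEVEN_INTRINSIC <- c("rmp", "tau_m", "c_m", "r_in", "ap_threshold",
                     "peak_dvdt", "max_rate")
DEFAULT_SEED <- 20140724L

# ---- Gaussian comparison ----------------------------------------------------

# least-squares fit of k scaled Gaussians to (x, y) histogram density points
ls_gauss_fit <- function(x, y, k, starts) {
  sse_fun <- function(par) {
    yhat <- 0
    for (j in seq_len(k)) {
      p <- par[(3 * j - 2):(3 * j)]
      yhat <- yhat + p[3] * stats::dnorm(x, p[1], p[2])
    }
    sum((y - yhat)^2)
  }
  rng <- range(x); spread <- diff(rng)
  lo <- rep(c(rng[1] - spread, spread / 100, 0), k)
  hi <- rep(c(rng[2] + spread, spread * 2, 10), k)
  best <- NULL
  for (s in starts) {
    f <- tryCatch(stats::nlminb(s, sse_fun, lower = lo, upper = hi),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$objective < best$objective)) best <- f
  }
  if (is.null(best)) stopf("Gaussian least-squares fit failed to converge")
  best
}

# EM fit of a 1-D two-component Gaussian mixture; returns the log-likelihood
em_mixture_loglik <- function(v, mu1, mu2, s1, s2, w, smin, max_iter = 200,
                              tol = 1e-8) {
  ll_old <- -Inf
  for (i in seq_len(max_iter)) {
    d1 <- w * stats::dnorm(v, mu1, s1)
    d2 <- (1 - w) * stats::dnorm(v, mu2, s2)
    tot <- d1 + d2
    tot[tot < 1e-300] <- 1e-300
    r <- d1 / tot
    w <- min(max(mean(r), 1e-4), 1 - 1e-4)
    mu1 <- sum(r * v) / sum(r)
    mu2 <- sum((1 - r) * v) / sum(1 - r)
    s1 <- max(sqrt(sum(r * (v - mu1)^2) / sum(r)), smin)
    s2 <- max(sqrt(sum((1 - r) * (v - mu2)^2) / sum(1 - r)), smin)
    ll <- sum(log(tot))
    if (ll - ll_old < tol) break
    ll_old <- ll
  }
  list(loglik = ll, mu = c(mu1, mu2), sigma = c(s1, s2), w = c(w, 1 - w))
}

mixture_lrt_stat <- function(v, fast = FALSE) {
  mu <- mean(v); s <- stats::sd(v); smin <- s / 30
  ll1 <- sum(stats::dnorm(v, mu, s, log = TRUE))
  if (fast) {
    # bootstrap path: one EM start from a median split is enough to calibrate
    lo <- v <= stats::median(v)
    f1 <- em_mixture_loglik(v, mean(v[lo]), mean(v[!lo]),
                            max(stats::sd(v[lo]), smin),
                            max(stats::sd(v[!lo]), smin), mean(lo), smin,
                            max_iter = 150, tol = 1e-6)
    return(list(stat = max(2 * (f1$loglik - ll1), 0), fit = f1, ll1 = ll1))
  }
  km <- suppressWarnings(stats::kmeans(v, 2, nstart = 5L))
  o <- order(km$centers)
  sds <- pmax(tapply(v, km$cluster, stats::sd)[o], smin, na.rm = TRUE)
  sds[is.na(sds)] <- smin
  f1 <- em_mixture_loglik(v, km$centers[o][1], km$centers[o][2], sds[1], sds[2],
                          mean(km$cluster == o[1]), smin)
  f2 <- em_mixture_loglik(v, mu - s, mu + s, s, s, 0.5, smin)
  best <- if (f1$loglik >= f2$loglik) f1 else f2
  list(stat = max(2 * (best$loglik - ll1), 0), fit = best, ll1 = ll1)
}

#' Compare one- vs two-component Gaussian descriptions of a statistic
#'
#' Histogram least-squares fits (Freedman-Diaconis bin width with a floor of
#' `min_bins` bins so the 6-parameter two-component curve is identifiable) of
#' one and two scaled Gaussians, summarized by the extra-sum-of-squares F
#' statistic. Because 1-vs-2 component comparisons are non-regular, the
#' decision p-value is a parametric-bootstrap-calibrated likelihood-ratio test
#' (EM mixture fit; `n_boot` bootstrap cohorts drawn from the fitted single
#' Gaussian). Two components are preferred when that p-value is < 0.05.
#'
#' @param values per-cell statistic (e.g. pooled ASL); length >= 20.
#' @param n_boot bootstrap replicates for the calibrated p-value.
#' @param min_bins histogram bin-count floor.
#' @param seed optional seed for the bootstrap (NULL: ambient RNG).
#' @return a `gc_gaussian_cmp` list: `one_comp` and `two_comp` fit summaries
#'   (means, sigmas, weights, SSE, log-likelihood), `f_stat` and `f_p`
#'   (histogram extra-SS F and its nominal analytic p), `lrt_stat`, `p_value`
#'   (bootstrap-calibrated), `preferred`, `n`, `n_bins`.
#' @export
compare_gaussians <- function(values, n_boot = 120, min_bins = 12,
                              seed = NULL) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 20) stopf("need >= 20 values, got %d", n)
  if (stats::sd(values) == 0) stopf("degenerate input: all values equal")
  with_seed(seed, {
    nb <- max(grDevices::nclass.FD(values), min_bins)
    h <- graphics::hist(values, breaks = seq(min(values), max(values),
                                             length.out = nb + 1),
                        plot = FALSE)
    x <- h$mids; y <- h$density
    mu0 <- mean(values); s0 <- stats::sd(values)
    f1 <- ls_gauss_fit(x, y, 1, list(c(mu0, s0, 1), c(mu0, s0 / 2, 1),
                                     c(x[which.max(y)], s0 / 3, 1)))
    km <- suppressWarnings(stats::kmeans(values, 2, nstart = 10))
    o <- order(km$centers)
    sds <- pmax(tapply(values, km$cluster, stats::sd)[o], s0 / 20, na.rm = TRUE)
    sds[is.na(sds)] <- s0 / 20
    ws <- as.numeric(table(km$cluster)[o]) / n
    starts2 <- list(c(km$centers[o][1], sds[1], ws[1],
                      km$centers[o][2], sds[2], ws[2]),
                    c(f1$par[1], f1$par[2], f1$par[3], f1$par[1], f1$par[2], 0),
                    c(mu0 - s0, s0 / 2, 0.5, mu0 + s0, s0 / 2, 0.5))
    f2 <- ls_gauss_fit(x, y, 2, starts2)
    sse1 <- f1$objective
    sse2 <- min(f2$objective, sse1)  # nested model: never worse
    df2 <- nb - 6
    f_stat <- if (df2 >= 1) ((sse1 - sse2) / 3) / (sse2 / df2) else NA_real_
    f_p <- if (is.finite(f_stat)) stats::pf(f_stat, 3, df2, lower.tail = FALSE)
           else NA_real_
    obs <- mixture_lrt_stat(values)
    boot <- vapply(seq_len(n_boot), function(b)
      mixture_lrt_stat(stats::rnorm(n, mu0, s0), fast = TRUE)$stat, numeric(1))
    p_value <- (1 + sum(boot >= obs$stat)) / (n_boot + 1)
    ord2 <- order(f2$par[c(1, 4)])
    pm <- matrix(f2$par, nrow = 3)[, ord2, drop = FALSE]
    structure(list(
      one_comp = list(mu = f1$par[1], sigma = f1$par[2], amplitude = f1$par[3],
                      sse = sse1, loglik = obs$ll1),
      two_comp = list(mu = pm[1, ], sigma = pm[2, ], amplitude = pm[3, ],
                      sse = sse2, loglik = obs$ll1 + obs$stat / 2,
                      mixture = obs$fit),
      f_stat = f_stat, f_p = f_p, lrt_stat = obs$stat, p_value = p_value,
      preferred = if (p_value < 0.05) "two" else "one",
      n = n, n_bins = nb), class = "gc_gaussian_cmp")
  })
}

#' @export
print.gc_gaussian_cmp <- function(x, ...) {
  cat(sprintf(
    "Gaussian comparison (n = %d, %d bins)\n  one:  mu %.3f, sigma %.3f (SSE %.4g)\n  two:  mu %.3f/%.3f, sigma %.3f/%.3f (SSE %.4g)\n  extra-SS F = %.3g (nominal p = %.3g); bootstrap LRT p = %.4g -> prefer %s\n",
    x$n, x$n_bins, x$one_comp$mu, x$one_comp$sigma, x$one_comp$sse,
    x$two_comp$mu[1], x$two_comp$mu[2], x$two_comp$sigma[1], x$two_comp$sigma[2],
    x$two_comp$sse, x$f_stat, x$f_p, x$p_value, x$preferred))
  invisible(x)
}

# ---- K-means ----------------------------------------------------------------

#' Two-group K-means on one gain statistic
#'
#' K-means with k = 2 and 25 restarts under a fixed seed. The cluster with the
#' higher center is labeled `S` (sensitive: steeper, more variable gain), the
#' other `L` (linear). Separation is summarized by a one-way ANOVA of the
#' values by label.
#'
#' @param values per-cell statistic.
#' @param nstart K-means restarts.
#' @param seed RNG seed (the caller's RNG state is preserved).
#' @return a `gc_cluster` list: `labels` (factor S/L per value), `centers`,
#'   `mean_dist` (mean absolute distance from the center, per cluster),
#'   `separation_F`, `separation_p`.
#' @export
kmeans_two <- function(values, nstart = 25, seed = DEFAULT_SEED) {
  values <- as.numeric(values)
  if (anyNA(values)) stopf("values contain NA; filter incomplete cells first")
  if (length(unique(values)) < 2) stopf("no separation: all values equal")
  km <- with_seed(seed, suppressWarnings(
    stats::kmeans(values, centers = 2, nstart = nstart)))
  s_cluster <- which.max(km$centers)
  labels <- factor(ifelse(km$cluster == s_cluster, "S", "L"),
                   levels = c("S", "L"))
  centers <- c(S = km$centers[s_cluster], L = km$centers[-s_cluster])
  names(centers) <- c("S", "L")
  mean_dist <- vapply(c(S = "S", L = "L"), function(g)
    mean(abs(values[labels == g] - centers[[g]])), numeric(1))
  fit <- stats::lm(values ~ labels)
  an <- stats::anova(fit)
  structure(list(labels = labels, centers = centers, mean_dist = mean_dist,
                 separation_F = an$`F value`[1], separation_p = an$`Pr(>F)`[1]),
            class = "gc_cluster")
}

#' @export
print.gc_cluster <- function(x, ...) {
  cat(sprintf(
    "K-means (k = 2): S %.3f +/- %.3f (n = %d), L %.3f +/- %.3f (n = %d), ANOVA p = %.3g\n",
    x$centers["S"], x$mean_dist["S"], sum(x$labels == "S"),
    x$centers["L"], x$mean_dist["L"], sum(x$labels == "L"), x$separation_p))
  invisible(x)
}

# ---- Ward clustering on the seven intrinsic parameters ----------------------

#' Adjusted Rand index between two partitions
#' @param a,b cluster label vectors of equal length.
#' @return ARI in \[-1, 1\]; 0 is chance agreement.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(sum(tab))
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(0)
  (sum_ij - expected) / (mx - expected)
}

#' Ward clustering on the seven z-scored intrinsic parameters
#'
#' Z-scores RMP, membrane time constant, whole-cell capacitance, input
#' resistance, AP threshold, peak dV/dt and maximal firing rate per cohort,
#' runs Ward linkage (ward.D2 on Euclidean distance) and cuts at two clusters.
#' When functional S/L labels are supplied, agreement is reported as
#' best-permutation accuracy and adjusted Rand index.
#'
#' @param rows data.frame with the seven intrinsic parameter columns
#'   (`rmp`, `tau_m`, `c_m`, `r_in`, `ap_threshold`, `peak_dvdt`, `max_rate`);
#'   no missing values.
#' @param labels optional factor of S/L labels to compare against.
#' @return list with `cluster` (integer 1/2 per row), `agreement`
#'   (`accuracy`, `ari`; NULL without labels), and the `height` of the merge.
#' @export
ward_cluster_seven <- function(rows, labels = NULL) {
  miss <- setdiff(SEVEN_INTRINSIC, names(rows))
  if (length(miss)) stopf("missing intrinsic columns: %s",
                          paste(miss, collapse = ", "))
  X <- as.matrix(rows[SEVEN_INTRINSIC])
  if (anyNA(X)) stopf("intrinsic parameters contain NA; filter first")
  Z <- scale(X)
  Z[, apply(X, 2, stats::sd) == 0] <- 0
  hc <- stats::hclust(stats::dist(Z), method = "ward.D2")
  cl <- stats::cutree(hc, k = 2)
  agreement <- NULL
  if (!is.null(labels)) {
    labels <- factor(labels)
    acc <- max(mean((cl == 1) == (labels == levels(labels)[1])),
               mean((cl == 2) == (labels == levels(labels)[1])))
    agreement <- list(accuracy = acc, ari = adjusted_rand_index(cl, labels))
  }
  list(cluster = cl, agreement = agreement,
       height = utils::tail(hc$height, 1))
}

# ---- age-binned group probabilities ----------------------------------------

#' Weekly S/L group probabilities
#'
#' Cells are binned by integer postmitotic week (`floor(age_days / 7)`,
#' weeks 3-10); each bin reports the fraction of S and L cells.
#'
#' @param rows data.frame with `age_days`.
#' @param labels factor of S/L labels aligned with `rows`.
#' @return data.frame with `age_bin` (weeks), `n_cells`, `p_S`, `p_L`.
#' @export
age_group_probabilities <- function(rows, labels) {
  stopifnot(nrow(rows) == length(labels))
  week <- floor(rows$age_days / 7)
  out <- lapply(3:10, function(w) {
    sel <- which(week == w)
    if (!length(sel)) return(NULL)
    data.frame(age_bin = w, n_cells = length(sel),
               p_S = mean(labels[sel] == "S"), p_L = mean(labels[sel] == "L"))
  })
  empty <- (3:10)[vapply(out, is.null, logical(1))]
  if (length(empty)) warnf("empty age bin(s) omitted: week %s",
                           paste(empty, collapse = ", "))
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

# ---- mean-variance parabola -------------------------------------------------

#' Parabolic fit of the age-binned mean-variance relation
#'
#' Per weekly age bin the mean and variance of the statistic are computed; a
#' quadratic least-squares fit of variance on mean is summarized by its
#' adjusted R-squared and overall ANOVA p-value. A transition-age mixture
#' produces an inverted-U: variance peaks where both groups coexist.
#'
#' @param rows data.frame with `age_days` and the statistic column.
#' @param stat column name, default `"asl"`.
#' @param min_per_bin bins with fewer cells are dropped.
#' @return a `gc_fit` list: `kind`, `coefficients`, `adjusted_r2`, `p_value`,
#'   `points` (the bin table), `note`.
#' @export
mean_variance_parabola <- function(rows, stat = "asl", min_per_bin = 2) {
  week <- floor(rows$age_days / 7)
  x <- rows[[stat]]
  tab <- do.call(rbind, lapply(sort(unique(week)), function(w) {
    v <- x[week == w & !is.na(x)]
    if (length(v) < min_per_bin) return(NULL)
    data.frame(age_bin = w, n = length(v), mean = mean(v), variance = stats::var(v))
  }))
  if (is.null(tab) || nrow(tab) < 3) stopf("fewer than 3 usable age bins")
  fit <- stats::lm(variance ~ mean + I(mean^2), data = tab)
  sm <- summary(fit)
  note <- NULL
  p <- tryCatch({
    fs <- sm$fstatistic
    stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  }, error = function(e) NA_real_)
  if (nrow(tab) == 3) {
    p <- NA_real_
    note <- "exact fit with 0 residual df; p undefined"
  }
  structure(list(kind = "parabolic", coefficients = stats::coef(fit),
                 adjusted_r2 = sm$adj.r.squared, p_value = unname(p),
                 points = tab, note = note), class = "gc_fit")
}

#' @export
print.gc_fit <- function(x, ...) {
  cat(sprintf("%s fit: adjusted R^2 = %.3f, p = %s%s\n", x$kind,
              x$adjusted_r2,
              if (is.na(x$p_value)) "NA" else sprintf("%.3g", x$p_value),
              if (!is.null(x$note)) paste0(" (", x$note, ")") else ""))
  invisible(x)
}

# ---- per-group correlations -------------------------------------------------

#' Correlations of the gain statistics with input resistance, per group
#'
#' Ordinary least squares of each statistic on `r_in`, within the S group,
#' within the L group, and pooled.
#'
#' @param rows data.frame with `r_in` and the statistic columns.
#' @param labels factor of S/L labels aligned with `rows`.
#' @param stats_cols statistic columns to regress.
#' @return data.frame with one row per (statistic, scope): `n`, `slope`,
#'   `intercept`, `adjusted_r2`, `p_value` (slope t-test).
#' @export
group_correlations <- function(rows, labels,
                               stats_cols = c("asl", "var", "offset_norm")) {
  stopifnot(nrow(rows) == length(labels))
  scopes <- list(S = labels == "S", L = labels == "L",
                 pooled = rep(TRUE, nrow(rows)))
  out <- list()
  for (st in stats_cols) {
    for (sc in names(scopes)) {
      d <- rows[scopes[[sc]] & !is.na(rows[[st]]) & !is.na(rows$r_in), ]
      if (nrow(d) < 3)
        stopf("insufficient data for %s within %s (n = %d < 3)", st, sc, nrow(d))
      fit <- stats::lm(d[[st]] ~ d$r_in)
      sm <- summary(fit)
      out[[length(out) + 1L]] <- data.frame(
        stat = st, group = sc, n = nrow(d),
        slope = stats::coef(fit)[2], intercept = stats::coef(fit)[1],
        adjusted_r2 = sm$adj.r.squared,
        p_value = sm$coefficients[2, 4])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
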