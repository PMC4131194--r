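# Two-population inference machinery.

test_that("compare_gaussians separates a clear mixture and not a single one", {
  set.seed(30)
  g <- rbinom(200, 1, 0.5)
  bim <- ifelse(g == 1, rnorm(200, 2.409, 0.17), rnorm(200, 1.6, 0.18))
  cmp <- compare_gaussians(bim, seed = 1)
  expect_identical(cmp$preferred, "two")
  expect_lt(cmp$p_value, 0.01)
  # recovered component means echo the generating centers
  expect_equal(sort(cmp$two_comp$mixture$mu), c(1.6, 2.409), tolerance = 0.1)

  uni <- rnorm(200, 2, 0.3)
  cmp1 <- compare_gaussians(uni, seed = 2)
  expect_identical(cmp1$preferred, "one")
  expect_gte(cmp1$p_value, 0.05)
})

test_that("nested-model invariants hold on arbitrary inputs", {
  set.seed(31)
  for (k in 1:5) {
    v <- rnorm(60, 0, 1) + sample(c(0, 3), 60, replace = TRUE) * rbinom(1, 1, 0.5)
    cmp <- compare_gaussians(v, n_boot = 30, seed = k)
    expect_lte(cmp$two_comp$sse, cmp$one_comp$sse)
    if (is.finite(cmp$f_stat)) expect_gte(cmp$f_stat, 0)
    expect_gte(cmp$p_value, 0)
    expect_lte(cmp$p_value, 1)
    expect_gte(cmp$lrt_stat, 0)
  }
})

test_that("identical components collapse onto the one-component model", {
  set.seed(32)
  v <- rnorm(120, 2, 0.25)  # mu1 = mu2 in truth
  cmp <- compare_gaussians(v, seed = 3)
  expect_identical(cmp$preferred, "one")
  expect_lte(cmp$two_comp$sse, cmp$one_comp$sse)
})

test_that("compare_gaussians input validation", {
  expect_error(compare_gaussians(rnorm(10)), ">= 20 values")
  expect_error(compare_gaussians(rep(1, 30)), "all values equal")
})

test_that("kmeans_two: centers, distances, separation, degeneracy", {
  km <- suppressWarnings(kmeans_two(c(0, 0, 10, 10)))  # perfect-fit ANOVA
  expect_equal(unname(km$centers), c(10, 0))
  expect_equal(unname(km$mean_dist), c(0, 0))

  set.seed(33)
  truth <- rbinom(150, 1, 0.5)
  v <- ifelse(truth == 1, rnorm(150, 6, 1), rnorm(150, 0, 1))  # 6 sigma apart
  km2 <- kmeans_two(v)
  acc <- max(mean((km2$labels == "S") == (truth == 1)),
             mean((km2$labels == "L") == (truth == 1)))
  expect_gte(acc, 0.99)
  expect_lt(km2$separation_p, 1e-9)

  expect_error(kmeans_two(rep(2, 10)), "no separation")
})

test_that("kmeans labels are invariant to ordering and affine rescaling", {
  set.seed(34)
  v <- c(rnorm(40, 1.6, 0.18), rnorm(40, 2.4, 0.18))
  base <- kmeans_two(v)
  perm <- sample(seq_along(v))
  expect_identical(as.character(kmeans_two(v[perm])$labels),
                   as.character(base$labels[perm]))
  resc <- kmeans_two(3 * v - 1)
  expect_identical(as.character(resc$labels), as.character(base$labels))
})

test_that("ward_cluster_seven: positive control, chance control, duplicates", {
  set.seed(35)
  n <- 80
  # positive control: a cohort of two biophysical states - input resistance
  # bimodal and the passively coupled parameters (tau, Cm) moving with it -
  # with the functional label deterministically tied to r_in
  state <- rep(0:1, each = n / 2)
  rin <- exp(rnorm(n, ifelse(state == 1, log(2500), log(300)), 0.1))
  cm <- exp(rnorm(n, ifelse(state == 1, log(18), log(50)), 0.1))
  rows <- data.frame(rmp = rnorm(n, -75, 3), tau_m = rin * cm / 1000,
                     c_m = cm, r_in = rin,
                     ap_threshold = rnorm(n, -40, 2),
                     peak_dvdt = rnorm(n, 300, 40),
                     max_rate = rnorm(n, 60, 10))
  labels <- factor(ifelse(rin > 1000, "S", "L"))
  pos <- ward_cluster_seven(rows, labels)
  expect_gte(pos$agreement$accuracy, 0.95)
  # chance control: labels independent of all intrinsic parameters
  rand_labels <- factor(sample(c("S", "L"), n, replace = TRUE))
  chance <- ward_cluster_seven(rows, rand_labels)
  expect_lt(abs(chance$agreement$ari), 0.2)
  # duplicates land in the same cluster
  dup <- rbind(rows, rows[1:5, ])
  cl <- ward_cluster_seven(dup)$cluster
  expect_identical(unname(cl[(n + 1):(n + 5)]), unname(cl[1:5]))
})

test_that("adjusted_rand_index: identity, chance, label permutation", {
  a <- rep(1:2, each = 20)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, 3 - a), 1)  # relabeling is irrelevant
  set.seed(36)
  b <- sample(1:2, 40, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.3)
})

test_that("age_group_probabilities: bins, complements, empty-bin warning", {
  rows <- data.frame(age_days = c(22, 25, 43, 44, 45, 70))
  labels <- factor(c("S", "S", "S", "L", "L", "L"), levels = c("S", "L"))
  expect_warning(tab <- age_group_probabilities(rows, labels), "empty age bin")
  expect_identical(tab$age_bin, c(3L, 6L, 10L))
  expect_equal(tab$p_S + tab$p_L, rep(1, 3))
  expect_equal(tab$p_S, c(1, 1 / 3, 0))

  one <- data.frame(age_days = rep(30, 5))
  lab1 <- factor(rep(c("S", "L"), c(2, 3)), levels = c("S", "L"))
  expect_warning(t1 <- age_group_probabilities(one, lab1))
  expect_identical(nrow(t1), 1L)
  expect_equal(t1$p_S + t1$p_L, 1)
})

test_that("mean_variance_parabola: exact fit, mixture shape, 3-point flag", {
  # construct bins whose (mean, variance) lie exactly on 0.5 - 0.1*(m - 2)^2
  q <- function(m) 0.5 - 0.1 * (m - 2)^2
  ms <- c(1.2, 1.6, 2.0, 2.4, 2.8)
  rows <- do.call(rbind, lapply(seq_along(ms), function(k) {
    s <- sqrt(q(ms[k]) / 2)
    data.frame(age_days = 7 * (k + 2) + 1, asl = ms[k] + c(-s, s))
  }))
  fit <- suppressWarnings(mean_variance_parabola(rows))  # perfect fit
  expect_equal(fit$adjusted_r2, 1, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients[3]), -0.1, tolerance = 1e-6)

  # transition-age mixture: variance peaks at intermediate mean with a
  # negative quadratic coefficient (mixture algebra: w(1-w)*dmu^2 term)
  set.seed(37)
  ages <- sample(21:72, 400, replace = TRUE)
  p <- gcio::p_linear_of_age(ages)
  grp <- runif(400) < p
  asl <- ifelse(grp, rnorm(400, 1.627, 0.18), rnorm(400, 2.409, 0.18))
  mix <- mean_variance_parabola(data.frame(age_days = ages, asl = asl))
  expect_lt(unname(mix$coefficients[3]), 0)
  expect_gt(mix$adjusted_r2, 0.3)

  three <- rows[rows$age_days < 43, ]
  f3 <- mean_variance_parabola(three)
  expect_true(is.na(f3$p_value))
  expect_match(f3$note, "0 residual df")
})

test_that("group_correlations: collinearity, insufficient data", {
  n <- 30
  rin <- seq(100, 1000, length.out = n)
  rows <- data.frame(r_in = rin, asl = 2 + 0.001 * rin, var = 1 + 0.002 * rin,
                     offset_norm = 100 - 0.05 * rin)
  labels <- factor(rep(c("S", "L"), n / 2), levels = c("S", "L"))
  res <- suppressWarnings(group_correlations(rows, labels))  # collinear
  expect_equal(res$adjusted_r2, rep(1, nrow(res)), tolerance = 1e-9)
  expect_identical(nrow(res), 9L)

  tiny <- rows[1:4, ]
  lab_t <- factor(c("S", "S", "L", "L"), levels = c("S", "L"))
  expect_error(group_correlations(tiny, lab_t), "insufficient data")
})
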