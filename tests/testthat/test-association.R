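test_that("kruskal_wallis matches exact rank arithmetic and the stats oracle", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$statistic, 27 / 7, tolerance = 1e-12)  # 3.857 by hand
  # oracle: stats::kruskal.test on seeded data with and without ties
  set.seed(11)
  for (rep_i in 1:5) {
    x <- c(rnorm(12), round(rnorm(13), 1))  # second half has ties
    g <- sample(rep(c("u", "v", "w"), length.out = 25))
    mine <- kruskal_wallis(x, g)
    ref <- stats::kruskal.test(x, factor(g))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
  const <- kruskal_wallis(rep(2, 10), rep(c("a", "b"), 5))
  expect_equal(const$statistic, 0)
  expect_equal(const$p_value, 1)
})

test_that("kruskal_wallis type-I error is nominal under the null", {
  set.seed(12)
  reps <- 600
  p <- replicate(reps, {
    kruskal_wallis(rnorm(40), rep(c("a", "b"), each = 20))$p_value
  })
  rate <- mean(p < 0.05)
  ci <- 2.58 * sqrt(0.05 * 0.95 / reps)  # 99% binomial CI half-width
  expect_lt(abs(rate - 0.05), ci + 1e-12)
})

test_that("bicor handles exact, noisy, and degenerate inputs", {
  set.seed(13)
  x <- rnorm(50)
  expect_equal(bicor(x, x), 1)
  expect_equal(bicor(x, -x), -1)
  expect_equal(bicor(x, 2 * x + 5), 1, tolerance = 1e-12)
  y <- 0.5 * x + rnorm(50)
  expect_equal(bicor(x, y), bicor(y, x))  # symmetry
  # agreement with Pearson on clean Gaussian data
  n <- 1000
  xg <- rnorm(n); yg <- 0.5 * xg + sqrt(0.75) * rnorm(n)
  expect_lt(abs(bicor(xg, yg) - cor(xg, yg)), 0.05)
  # resistant to a gross outlier where Pearson is not
  xo <- c(rnorm(50), 100); yo <- c(rnorm(50), 100)
  expect_lt(abs(bicor(xo, yo)), 0.5)
  expect_gt(cor(xo, yo), 0.9)
  expect_warning(r0 <- bicor(c(1, 1, 1, 1, 2), rnorm(5)), "zero median")
  expect_error(bicor(1:2, 1:2), ">= 3")
})

test_that("bicor_matrix agrees with pairwise bicor", {
  set.seed(14)
  x <- matrix(rnorm(8 * 30), 8, 30,
              dimnames = list(paste0("cg", 1:8), NULL))
  R <- bicor_matrix(x)
  expect_equal(R, t(R))
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(R[i, j], bicor(x[i, ], x[j, ]), tolerance = 1e-12)
  }
  expect_equal(unname(diag(R)), rep(1, 8))
})

test_that("cor_test p-values behave and match a permutation oracle", {
  set.seed(15)
  x <- rnorm(30)
  y_null <- rnorm(30)
  expect_gt(cor_test(x, y_null)$p_value, 0.001)
  perfect <- cor_test(x, x)
  expect_equal(perfect$r, 1)
  expect_gt(perfect$p_value, 0)  # underflow-safe floor
  expect_error(cor_test(1:3, 1:3), "n >= 4")
  # permutation oracle within a factor of 2
  y <- 0.6 * x + rnorm(30)
  obs <- cor_test(x, y, method = "pearson")
  perm <- replicate(4000, abs(cor(x, sample(y))))
  p_perm <- (1 + sum(perm >= abs(obs$r))) / 4001
  expect_lt(obs$p_value / p_perm, 2)
  expect_gt(obs$p_value / p_perm, 0.5)
})

test_that("principal components match the eigendecomposition oracle", {
  set.seed(16)
  # rank-1 matrix: PC1 explains everything
  u <- rnorm(10); v <- rnorm(8)
  r1 <- outer(u, v)
  pc1 <- principal_components(r1, 2)
  expect_gt(pc1$var_explained[1], 1 - 1e-10)
  # oracle: eigenvectors of the sample covariance of the centered columns
  x <- matrix(rnorm(80), 10, 8)
  pc <- principal_components(x, 3)
  xc <- x - rowMeans(x)
  eig <- eigen(crossprod(xc))
  for (k in 1:3) {
    expect_equal(abs(sum(pc$scores[, k] * eig$vectors[, k])), 1,
                 tolerance = 1e-8)
  }
  expect_equal(pc$var_explained, (eig$values / sum(eig$values))[1:3],
               tolerance = 1e-8)
  # orthogonality
  g <- crossprod(pc$scores)
  expect_equal(g, diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(principal_components(x, 0), "positive")
})

test_that("fit_dnam_model recovers exact coefficients and fixed contrasts", {
  set.seed(17)
  n <- 80
  d <- data.frame(
    diagnosis = sample(c("HD", "control"), n, TRUE),
    age = runif(n, 20, 90),
    sex = sample(c("F", "M"), n, TRUE),
    bank = sample(c("NewZealand", "UCLA"), n, TRUE),
    region = sample(c("frontal", "parietal", "occipital"), n, TRUE))
  # noiseless response from known coefficients -> exact recovery
  d$dnam_age <- 4 + 2.5 * (d$diagnosis == "HD") + 0.7 * d$age -
    1.2 * (d$sex == "F") + 0.4 * (d$bank == "UCLA")
  # noiseless fits make summary() warn about a perfect fit; that is the point
  fit <- suppressWarnings(fit_dnam_model(d, model = 1))
  cf <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(unname(cf["hd"]), 2.5, tolerance = 1e-8)
  expect_equal(unname(cf["age"]), 0.7, tolerance = 1e-8)
  expect_equal(unname(cf["sexF"]), -1.2, tolerance = 1e-8)
  expect_equal(unname(cf["bankUCLA"]), 0.4, tolerance = 1e-8)
  # adding a constant moves only the intercept
  d2 <- d; d2$dnam_age <- d$dnam_age + 10
  fit2 <- suppressWarnings(fit_dnam_model(d2, model = 1))
  expect_equal(fit$coefficients$estimate[-1], fit2$coefficients$estimate[-1],
               tolerance = 1e-8)
  expect_equal(fit2$coefficients$estimate[1] - fit$coefficients$estimate[1],
               10, tolerance = 1e-8)
  # repeated individuals trigger the descriptive-inference warning
  d$individual_id <- rep(paste0("i", 1:(n / 2)), each = 2)
  w <- capture_warnings(fit_dnam_model(d, model = 1))
  expect_true(any(grepl("multiple samples", w)))
})

test_that("fit_dnam_model model 2 includes neurons; collinearity errors", {
  set.seed(18)
  n <- 60
  d <- data.frame(
    diagnosis = sample(c("HD", "control"), n, TRUE),
    age = runif(n, 20, 90), sex = sample(c("F", "M"), n, TRUE),
    bank = "NewZealand", region = "frontal",
    prop_neurons = runif(n, 0.2, 0.6))
  d$dnam_age <- 2 * (d$diagnosis == "HD") + 0.65 * d$age -
    14 * d$prop_neurons + rnorm(n)
  fit <- fit_dnam_model(d, model = 2)
  cf <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_lt(abs(cf[["prop_neurons"]] + 14), 3)
  # duplicated covariate -> rank deficiency reported
  d$PC1 <- d$age
  d$PC2 <- rnorm(n); d$PC3 <- rnorm(n); d$PC4 <- rnorm(n); d$PC5 <- rnorm(n)
  expect_error(suppressWarnings(fit_dnam_model(d, model = 3)),
               "rank-deficient")
})

test_that("least squares matches the normal-equation oracle on a printed fixture", {
  # 6-row, 2-covariate fixture solved by hand via (X'X)^{-1} X'y
  d <- data.frame(diagnosis = c("HD", "HD", "HD", "control", "control", "control"),
                  age = c(61, 72, 48, 55, 66, 80),
                  sex = c("M", "M", "M", "M", "M", "M"),
                  bank = "NewZealand", region = "frontal",
                  dnam_age = c(66.1, 73.9, 55.2, 52.8, 64.0, 79.5))
  X <- cbind(1, as.integer(d$diagnosis == "HD"), d$age)
  beta_hat <- solve(crossprod(X), crossprod(X, d$dnam_age))
  fit <- suppressWarnings(fit_dnam_model(d, model = 1))
  cf <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(unname(cf[c("(Intercept)", "hd", "age")]), drop(beta_hat),
               tolerance = 1e-10)
})

test_that("coefficient_to_years reproduces the worked ratios", {
  expect_equal(round(coefficient_to_years(2.06, 0.646), 1), 3.2)
  expect_equal(round(coefficient_to_years(1.704, 0.64), 1), 2.7)
  expect_equal(coefficient_to_years(0, 0.646), 0)
  expect_error(coefficient_to_years(2, 0), "> 0")
  expect_error(coefficient_to_years(2, -0.5), "> 0")
})
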