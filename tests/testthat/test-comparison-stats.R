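test_that("Bland-Altman statistics match hand arithmetic", {
  # x = (1,2,3), y = (2,3,5): d = (1,1,2), mean 4/3, sd sqrt(1/3)
  r <- bland_altman(c(1, 2, 3), c(2, 3, 5))
  expect_equal(r$mean_diff, 4 / 3)
  expect_equal(r$sd_diff, sqrt(1 / 3))
  expect_equal(r$loa_low, 4 / 3 - 1.96 * sqrt(1 / 3))
  expect_equal(r$loa_high, 4 / 3 + 1.96 * sqrt(1 / 3))
  expect_equal(r$mean_diff, r$mean_b - r$mean_a, tolerance = 1e-12)

  # identical methods and constant offsets
  x <- c(5.1, 6.2, 7.3, 8.4)
  r0 <- bland_altman(x, x)
  expect_equal(c(r0$mean_diff, r0$sd_diff, r0$loa_low, r0$loa_high),
               rep(0, 4))
  rc <- bland_altman(x, x + 2.5)
  expect_equal(rc$mean_diff, 2.5)
  expect_equal(rc$sd_diff, 0)

  # antisymmetry under swapping the methods
  set.seed(4)
  a <- rnorm(30, 10); b <- a + rnorm(30, 0.5, 0.8)
  expect_equal(bland_altman(a, b)$mean_diff, -bland_altman(b, a)$mean_diff)
  expect_equal(bland_altman(a, b)$sd_diff, bland_altman(b, a)$sd_diff)

  expect_error(bland_altman(1, numeric(0)), class = "hemowave_validation")
  expect_error(bland_altman(1, 2), class = "hemowave_validation")
})

test_that("Pearson correlation matches the textbook formula and t-test", {
  # fixed 10-pair fixture against an independent implementation
  x <- c(1.2, 2.1, 2.9, 4.3, 5.1, 5.8, 7.2, 8.4, 9.1, 10.5)
  y <- c(2.0, 1.5, 3.8, 3.9, 6.2, 5.1, 7.9, 7.5, 10.2, 9.8)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r_hand * sqrt(8 / (1 - r_hand^2))
  p_hand <- 2 * pt(-abs(tstat), df = 8)
  res <- pearson(x, y)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$p, p_hand, tolerance = 1e-12)

  # exact linear relation and orthogonalized residuals
  expect_equal(pearson(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  y_orth <- residuals(lm(y ~ x))
  expect_equal(pearson(x, y_orth)$r, 0, tolerance = 1e-10)

  # affine invariance with positive slope
  expect_equal(pearson(3 * x + 2, y)$r, res$r, tolerance = 1e-12)
  expect_error(pearson(x, rep(1, 10)), class = "hemowave_validation")
})

test_that("stepwise regression selects exactly the true predictors", {
  # one strong predictor among noise: exactly that one enters, and an
  # exhaustive best-subset (BIC) oracle agrees
  set.seed(2)
  n <- 60
  X <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  names(X) <- paste0("x", 1:6)
  X$y <- 5 * X$x3 + rnorm(n)
  sw <- stepwise_regression(X, "y", paste0("x", 1:6))
  expect_identical(sw$selected, "x3")

  subsets <- unlist(lapply(0:6, function(k)
    combn(paste0("x", 1:6), k, simplify = FALSE)), recursive = FALSE)
  bics <- vapply(subsets, function(v) {
    f <- if (length(v)) reformulate(v, "y") else y ~ 1
    BIC(lm(f, data = X))
  }, numeric(1))
  expect_identical(sort(subsets[[which.min(bics)]]), sort(sw$selected))

  # exact two-predictor linear response, no noise: both selected, adj R2 = 1
  X$y2 <- 2 * X$x1 - 3 * X$x5
  sw2 <- suppressWarnings(stepwise_regression(X, "y2", paste0("x", 1:6)))  # perfect fit
  expect_setequal(sw2$selected, c("x1", "x5"))
  expect_equal(sw2$adj_r2, 1, tolerance = 1e-9)

  # pure-noise response at a seed where no marginal p reaches 0.05
  set.seed(10)
  N <- as.data.frame(matrix(rnorm(40 * 6), 40, 6))
  names(N) <- paste0("x", 1:6)
  N$y <- rnorm(40)
  marg <- vapply(paste0("x", 1:6), function(v)
    summary(lm(reformulate(v, "y"), N))$coefficients[2, 4], numeric(1))
  expect_gte(min(marg), 0.05)
  sw3 <- stepwise_regression(N, "y", paste0("x", 1:6))
  expect_length(sw3$selected, 0)
})

test_that("stepwise on an orthogonal design reduces to marginal thresholding", {
  set.seed(1)
  n <- 50
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 4), n, 4))))[, 2:5] # orthonormal, centered
  d <- as.data.frame(Q); names(d) <- paste0("x", 1:4)
  d$y <- 8 * d$x1 + 6 * d$x4 + rnorm(n, 0, 0.5)
  marg <- vapply(paste0("x", 1:4), function(v)
    summary(lm(reformulate(v, "y"), d))$coefficients[2, 4], numeric(1))
  # well-separated case: marginal p-values cleanly below/above thresholds
  expect_true(all(marg[c(1, 4)] < 1e-4) && all(marg[c(2, 3)] > 0.1))
  sw <- stepwise_regression(d, "y", paste0("x", 1:4))
  expect_setequal(sw$selected, names(marg)[marg < 0.05])
})

test_that("stepwise reports Table-style coefficients, partial R and guards", {
  set.seed(12)
  n <- 80
  d <- data.frame(age = runif(n, 35, 56), bmi = rnorm(n, 26, 4))
  d$zc <- 0.2 - 0.002 * d$age + rnorm(n, 0, 0.01)
  sw <- stepwise_regression(d, "zc", c("age", "bmi"))
  expect_true("age" %in% sw$selected)
  i <- match("age", sw$terms$variable)
  fit <- lm(reformulate(sw$selected, "zc"), d)
  co <- summary(fit)$coefficients["age", ]
  expect_equal(sw$terms$coefficient[i], unname(co["Estimate"]))
  expect_equal(sw$terms$std_error[i], unname(co["Std. Error"]))
  # signed sqrt of t^2/(t^2+df)
  tv <- co["t value"]
  expect_equal(sw$terms$r_partial[i],
               unname(sign(co["Estimate"]) * sqrt(tv^2 / (tv^2 + fit$df.residual))))
  expect_lt(sw$terms$r_partial[i], 0)

  # collinear design is rejected
  d$age2 <- d$age * 2
  expect_error(stepwise_regression(d, "zc", c("age", "age2", "bmi")),
               class = "hemowave_validation")
  expect_error(stepwise_regression(d, "zc", c("age", "bmi"),
                                   p_enter = 0.1, p_remove = 0.05),
               class = "hemowave_validation")
})

test_that("subgroup summaries bin by age quartile and sex", {
  d <- data.frame(age = c(37, 37, 40, 41, 46, 51, 56),
                  sex = c("male", "female", "male", "male", "female", "male", "female"),
                  pwv = c(6, 6.5, 7, 7.2, 7.5, 8, 8.3))
  s <- subgroup_summary(d, "pwv", by_sex = FALSE)
  expect_identical(s$n, c(3L, 1L, 1L, 2L))      # 40|41 split across Q1/Q2
  expect_equal(s$pwv_mean[1], mean(c(6, 6.5, 7)))
  expect_equal(s$pwv_sd[4], sd(c(8, 8.3)))

  s2 <- subgroup_summary(d, "pwv", by_sex = TRUE)
  expect_equal(sum(s2$n), nrow(d))
  # brute-force recomputation of one cell
  q1m <- d$pwv[d$age <= 40 & d$sex == "male"]
  row <- s2[grepl("Q1", s2$group) & grepl("male", s2$group) &
              !grepl("female", s2$group), ]
  expect_equal(row$pwv_mean, mean(q1m))

  expect_error(subgroup_summary(data.frame(age = 60, sex = "male", pwv = 7),
                                "pwv"), class = "hemowave_validation")
})

test_that("ARTERY-style grading applies the mean/SD difference bands", {
  expect_identical(artery_rating(0.717, 1.25), "acceptable")
  expect_identical(artery_rating(1.2, 1.0), "not acceptable")
  expect_identical(artery_rating(0, 0), "acceptable")
  expect_identical(artery_rating(-0.9, 1.49), "acceptable")
  expect_identical(artery_rating(0.9, 1.5), "not acceptable")
  bands <- data.frame(grade = c("excellent", "acceptable"),
                      mean_max = c(0.5, 1.0), sd_max = c(0.8, 1.5))
  expect_identical(artery_rating(0.3, 0.5, bands), "excellent")
  expect_identical(artery_rating(0.7, 1.2, bands), "acceptable")
  expect_error(artery_rating(0.5, -1), class = "hemowave_validation")
})
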