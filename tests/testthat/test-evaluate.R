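# Evaluation: isodose Dice, %MAE, regression, power, cohort report.

make_dose <- function(values, rx = 74.8)
  dose_grid(values, prescription = rx, n_fractions = 34,
            spacing = c(1, 1, 1))

test_that("iDSC matches set-overlap enumeration and its edge cases", {
  dm <- c(4, 8, 8)
  a <- array(runif(prod(dm), 0, 80), dm)
  d1 <- make_dose(a)
  # identity at every level
  for (d in c(0, 20, 50, 74.8))
    expect_equal(idsc(d1, d1, d), 1)
  # disjoint iso-volumes
  x <- array(0, dm); x[1:2, , ] <- 60
  y <- array(0, dm); y[3:4, , ] <- 60
  expect_equal(idsc(make_dose(x), make_dose(y), 50), 0)
  # toy counts: |A| = 8, |B| = 6, |A intersect B| = 5
  x <- array(0, dm); x[1, 1:8, 1] <- 60
  y <- array(0, dm); y[1, 4:8, 1] <- 60; y[2, 1, 1] <- 60
  expect_equal(idsc(make_dose(x), make_dose(y), 50), 10 / 14)
  # both volumes empty: defined as 1
  expect_equal(idsc(make_dose(array(0, dm)), make_dose(array(0, dm)),
                    50), 1)
  # brute-force random fields + symmetry
  set.seed(4)
  for (rep in 1:5) {
    p <- array(runif(prod(dm), 0, 80), dm)
    q <- array(runif(prod(dm), 0, 80), dm)
    d <- runif(1, 0, 74.8)
    A <- p >= d; B <- q >= d
    brute <- if (sum(A) + sum(B) == 0) 1 else
      2 * sum(A & B) / (sum(A) + sum(B))
    expect_equal(idsc(make_dose(p), make_dose(q), d), brute)
    expect_equal(idsc(make_dose(p), make_dose(q), d),
                 idsc(make_dose(q), make_dose(p), d))
  }
})

test_that("mean iDSC averages the level grid and degrades with noise", {
  dm <- c(4, 8, 8)
  set.seed(8)
  base <- array(runif(prod(dm), 0, 74), dm)
  d1 <- make_dose(base)
  expect_equal(mean_idsc(d1, d1, 0, 1), 1)
  expect_equal(mean_idsc(d1, d1, 50, 1), 1)
  # the >= 50 Gy variant uses levels 50, 51, ..., 74 at 74.8 Gy
  expect_length(seq(50, 74.8, by = 1), floor((74.8 - 50) / 1) + 1)
  # degenerate grid: a single level equals plain iDSC
  pert <- make_dose(base * 0.9)
  expect_equal(mean_idsc(d1, pert, 74.8, 1), idsc(d1, pert, 74.8))
  expect_error(mean_idsc(d1, pert, 80, 1), "exceeds")
  # nested perturbations: mean iDSC non-increasing in noise amplitude
  set.seed(9)
  noise <- array(rnorm(prod(dm)), dm)
  vals <- vapply(c(2, 8, 20), function(eps) {
    pd <- make_dose(pmax(base + eps * noise, 0))
    mean_idsc(d1, pd, 0, 1)
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("%MAE follows the two field conventions", {
  expect_equal(pmae(c(50, 60), c(50, 60), "gy", 74.8), 0)
  expect_equal(pmae(14.58, 14.58, "percent"), 0)
  expect_equal(pmae(80, 78, "gy", 74.8), 100 * 2 / 74.8)
  expect_equal(pmae(14.58, 13.40, "percent"), 1.18)
  expect_error(pmae(1:3, 1:2, "percent"), "length mismatch")
})

test_that("regression matches an independent normal-equations oracle", {
  set.seed(15)
  x <- rnorm(15, 10, 3)
  y <- 0.8 * x + rnorm(15, 0, 1)
  r <- regress(x, y)
  # oracle: explicit normal equations + t CDF
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  s2 <- sum(resid^2) / (15 - 2)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  tval <- beta[2] / se
  p_oracle <- 2 * stats::pt(-abs(tval), df = 13)
  r2_oracle <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  expect_equal(r$slope, beta[2], tolerance = 1e-10)
  expect_equal(r$intercept, beta[1], tolerance = 1e-10)
  expect_equal(r$r2, r2_oracle, tolerance = 1e-10)
  expect_equal(r$p, p_oracle, tolerance = 1e-10)

  # perfect fit and no-association limits
  perfect <- regress(x, x)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$slope, 1)
  flat <- regress(x, rep(2, 15))
  expect_equal(flat$r2, 0)
  expect_error(regress(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(regress(1:2, 1:2), "3")

  # scale equivariance: R^2 and p unchanged under positive rescaling
  r_scaled <- regress(3.7 * x, 3.7 * y)
  expect_equal(r_scaled$r2, r$r2, tolerance = 1e-12)
  expect_equal(r_scaled$p, r$p, tolerance = 1e-12)
})

test_that("power of the slope test reproduces the design statement", {
  # n = 15, R^2 = 0.35, alpha = 0.05: about 0.81 under the normal
  # approximation, consistent with a designed 80% power
  p <- power_r2(15, 0.35, 0.05)
  expect_lt(abs(p - 0.80), 0.02)
  expect_equal(p, 0.8107, tolerance = 1e-3)
  # alpha -> 1: always reject
  expect_gt(power_r2(15, 0.35, 0.999), 0.99)
  # noncentral-F variant stays close at moderate n
  expect_lt(abs(power_r2(15, 0.35, 0.05, method = "ncf") - p), 0.1)

  # large-n check against a fixed-design Monte-Carlo of the slope test:
  # true slope chosen so the noncentrality b^2 * Sxx equals n * f2
  n <- 200; r2 <- 0.05; alpha <- 0.05; reps <- 2e5
  set.seed(123)
  x <- rnorm(n)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  f2 <- r2 / (1 - r2)
  b <- sqrt(n * f2 / sxx)
  E <- matrix(rnorm(n * reps), n)
  yv <- b * x + E
  bh <- as.numeric(crossprod(xc, yv)) / sxx
  ssy <- colSums(yv^2) - n * colMeans(yv)^2
  rss <- ssy - bh^2 * sxx
  tstat <- bh / sqrt(rss / (n - 2) / sxx)
  mc <- mean(abs(tstat) > stats::qt(1 - alpha / 2, n - 2))
  expect_lt(abs(power_r2(n, r2, alpha) - mc), 0.02)
})

test_that("cohort report reproduces the comparison-table layout", {
  cfg <- small_phantom_config()
  set.seed(77)
  cohort <- generate_cohort(cfg, n = 3)
  pre <- preprocess_cohort(cohort,
                           preprocess_config(target_size = 32))
  samples <- pre$samples
  # identity cohort: predicted == planned
  rep1 <- cohort_report(samples, lapply(samples, `[[`, "dose"))
  expect_equal(nrow(rep1$metrics), 31) # 23 DVH + 8 NTCP rows
  expect_true(all(rep1$metrics$pmae_mean == 0))
  expect_true(all(rep1$metrics$r2[!is.na(rep1$metrics$r2)] == 1))
  expect_equal(rep1$idsc_mean0, 1)
  expect_equal(rep1$idsc_mean50, 1)

  # perturbed cohort: report is deterministic and serializable
  pred <- lapply(samples, function(s) {
    d <- s$dose
    set.seed(nchar(s$id))
    d$values <- pmax(d$values + array(rnorm(length(d$values), 0, 1.5),
                                      dim = dim(d$values)), 0)
    d
  })
  dir <- withr::local_tempdir()
  rep2 <- cohort_report(samples, pred, out_dir = dir)
  rep3 <- cohort_report(samples, pred)
  expect_identical(rep2$metrics, rep3$metrics)
  expect_true(file.exists(file.path(dir, "report.csv")))
  expect_true(file.exists(file.path(dir, "idsc.csv")))
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(all(rep2$idsc$mean_idsc_0 <= 1 & rep2$idsc$mean_idsc_0 >= 0))
  expect_lt(rep2$idsc_mean0, 1)
  expect_error(cohort_report(samples[1:2], pred[1:2]), "3")
})
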