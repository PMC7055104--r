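# Logistic IRLS, C-statistic, Hosmer-Lemeshow, imputation, stepwise.

test_that("intercept-only fit equals the closed-form log-odds", {
  y <- c(rep(1, 3), rep(0, 7))
  fit <- fit_logistic_irls(matrix(nrow = 10, ncol = 0), y)
  expect_equal(unname(fit$coefficients[["(Intercept)"]]), log(3 / 7),
               tolerance = 1e-12)
  expect_true(fit$converged)
})

test_that("IRLS rejects degenerate inputs with informative errors", {
  expect_error(fit_logistic_irls(matrix(rnorm(10)), rep(1, 10)),
               "both classes")
  x <- cbind(a = rnorm(20), b = 0)   # constant column beyond the intercept
  y <- rep(c(0, 1), 10)
  expect_error(fit_logistic_irls(x, y), "rank deficient.*b")
  expect_error(fit_logistic_irls(cbind(a = c(rnorm(19), NA)), y), "finite")
})

test_that("IRLS matches glm and satisfies the score equations", {
  set.seed(11)
  n <- 800
  x <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  eta <- -2 + 0.8 * x[, 1] - 0.5 * x[, 2]
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_logistic_irls(x, y, tol = 1e-9, max_iter = 50)
  oracle <- glm(y ~ x1 + x2, data = data.frame(x, y), family = binomial,
                control = list(epsilon = 1e-12))
  expect_equal(unname(fit$coefficients), unname(coef(oracle)),
               tolerance = 1e-7)
  expect_equal(unname(fit$se), unname(summary(oracle)$coefficients[, 2]),
               tolerance = 1e-6)
  # score equations ~ 0 at the optimum; log-likelihood non-decreasing
  expect_lt(max(abs(fit$score)), 1e-6)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
})

test_that("IRLS recovers generating coefficients and flags separation", {
  set.seed(12)
  n <- 5000
  x <- matrix(rnorm(n), dimnames = list(NULL, "z"))
  y <- rbinom(n, 1, plogis(-1 + 1.5 * x[, 1]))
  fit <- fit_logistic_irls(x, y)
  expect_lt(abs(fit$coefficients[["z"]] - 1.5), 3 * fit$se[["z"]])
  expect_lte(fit$iterations, 25)

  # perfectly separated data diverge and are flagged
  xs <- matrix(c(-(20:1), 1:20) / 10, dimnames = list(NULL, "z"))
  ys <- rep(c(0, 1), each = 20)
  expect_warning(fs <- fit_logistic_irls(xs, ys, max_iter = 100),
                 "separation")
  expect_true(fs$separation)
})

test_that("AUC: exact and rank paths agree and match the U statistic", {
  set.seed(13)
  for (k in 1:60) {
    n <- sample(20:120, 1)
    # mix of continuous and heavily tied scores
    s <- if (k %% 2) rnorm(n) else sample(seq(0, 1, 0.1), n, replace = TRUE)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    a_ex <- c_statistic(s, y, method = "exact")
    a_rk <- c_statistic(s, y, method = "rank")
    expect_equal(a_ex$auc, a_rk$auc, tolerance = 1e-12)
    # AUC equals U / (n1 * n0) from the rank-sum statistic
    W <- suppressWarnings(wilcox.test(s[y == 1], s[y == 0]))$statistic
    expect_equal(a_ex$auc, unname(W) / (sum(y == 1) * sum(y == 0)),
                 tolerance = 1e-12)
    # DeLong variance identical across paths
    expect_equal(a_ex$se, a_rk$se, tolerance = 1e-10)
  }
})

test_that("AUC worked examples, invariance, and the single-class signal", {
  expect_equal(c_statistic(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))$auc, 1)
  # 4 event/non-event pairs: one win, one loss, two ties -> 0.5
  expect_equal(c_statistic(c(0.6, 0.4, 0.6, 0.4), c(1, 0, 0, 1))$auc, 0.5)
  set.seed(14)
  s <- rnorm(200)
  y <- rbinom(200, 1, 0.3)
  a <- c_statistic(s, y)
  b <- c_statistic(exp(2 * s) + 5, y)        # strictly increasing transform
  expect_equal(a$auc, b$auc, tolerance = 1e-12)
  expect_true(a$ci[1] <= a$auc && a$auc <= a$ci[2])
  expect_error(c_statistic(s, rep(1, 200)), class = "bpv_single_class")
})

test_that("DeLong interval matches the independent pROC implementation", {
  set.seed(15)
  n <- 400
  y <- rbinom(n, 1, 0.3)
  s <- rnorm(n) + y
  ours <- c_statistic(s, y)
  ref <- pROC::ci.auc(pROC::roc(y, s, quiet = TRUE, direction = "<"),
                      method = "delong")
  expect_equal(ours$auc, as.numeric(ref[2]), tolerance = 1e-10)
  expect_equal(ours$ci[1], as.numeric(ref[1]), tolerance = 1e-6)
  expect_equal(ours$ci[2], as.numeric(ref[3]), tolerance = 1e-6)
})

test_that("Hosmer-Lemeshow: perfect calibration, df rule, and power", {
  # predictions equal to empirical bin rates -> chi2 exactly 0
  p <- rep(seq(0.05, 0.95, 0.1), each = 20)
  set.seed(16)
  y <- unlist(lapply(seq(0.05, 0.95, 0.1), function(q) {
    ones <- round(q * 20)
    sample(c(rep(1, ones), rep(0, 20 - ones)))
  }))
  byp <- tapply(y, p, mean)
  p_cal <- byp[as.character(p)]
  hl <- hosmer_lemeshow(as.numeric(p_cal), y, groups = 10)
  expect_equal(hl$chi2, 0, tolerance = 1e-10)
  expect_equal(hl$df, nrow(hl$table) - 2)

  # miscalibrated predictions: statistic grows with n
  set.seed(17)
  chi_at <- vapply(c(500, 4000), function(n) {
    pp <- runif(n, 0.05, 0.95)
    yy <- rbinom(n, 1, pp)
    hosmer_lemeshow(pp^2, yy, groups = 10)$chi2
  }, numeric(1))
  expect_gt(chi_at[2], chi_at[1] * 2)

  expect_error(hosmer_lemeshow(runif(100), rbinom(100, 1, 0.5), groups = 2),
               "at least 3")
  expect_error(hosmer_lemeshow(c(0.5, 1.2, 0.3), c(0, 1, 0), groups = 3),
               "lie in")
})

test_that("Hosmer-Lemeshow null mean tracks its degrees of freedom", {
  # quick version of the calibration-null property (the acceptance test
  # runs the full-size replicate study)
  set.seed(18)
  chis <- replicate(60, {
    n <- 2000
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1 + x))
    fit <- fit_logistic_irls(matrix(x, dimnames = list(NULL, "x")), y)
    hosmer_lemeshow(fit$fitted, y, groups = 10)$chi2
  })
  expect_lt(abs(mean(chis) - 8), 8 * 0.25)
})

test_that("STS imputation: median fill, indicator flags, identity case", {
  r <- data.frame(sts_mm_score = c(0.01, 0.03, NA))
  out <- impute_missing_sts(r, "sts_mm_score")
  expect_equal(out$sts_mm_score, c(0.01, 0.03, 0.02))
  expect_equal(out$sts_mm_score_missing, c(0L, 0L, 1L))

  r2 <- data.frame(sts_mm_score = c(0.01, 0.03, 0.05))
  out2 <- impute_missing_sts(r2, "sts_mm_score")
  expect_equal(out2$sts_mm_score, r2$sts_mm_score)
  expect_equal(sum(out2$sts_mm_score_missing), 0)

  expect_error(impute_missing_sts(data.frame(sts_mm_score = c(NA_real_, NA)),
                                  "sts_mm_score"), "all values")

  # pluggable strategy
  out3 <- impute_missing_sts(r, "sts_mm_score",
                             strategy = function(x) 0.5)
  expect_equal(out3$sts_mm_score[3], 0.5)
})

test_that("MCAR imputation leaves adjusted-model AUC essentially unchanged", {
  set.seed(19)
  n <- 10000
  sts <- pmin(pmax(rlnorm(n, log(0.02), 0.9), 1e-3), 0.9)
  age10 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-3 + 1.0 * qlogis(sts) / 2 + 0.3 * age10))
  miss <- data.frame(sts_mm_score = sts)
  miss$sts_mm_score[runif(n) < 0.25] <- NA    # missing completely at random
  cc <- !is.na(miss$sts_mm_score)
  # complete-case fit vs fit on imputed data, discrimination compared on the
  # same (fully observed) evaluation set
  fit_cc <- fit_logistic_irls(
    cbind(sts_logit = qlogis(sts[cc]), age10 = age10[cc]), y[cc])
  imp <- impute_missing_sts(miss, "sts_mm_score")
  fit_imp <- fit_logistic_irls(
    cbind(sts_logit = qlogis(imp$sts_mm_score), age10 = age10,
          sts_missing = imp$sts_mm_score_missing), y)
  lp_imp_on_cc <- fit_imp$coefficients[["(Intercept)"]] +
    fit_imp$coefficients[["sts_logit"]] * qlogis(sts[cc]) +
    fit_imp$coefficients[["age10"]] * age10[cc]
  auc_cc <- c_statistic(fit_cc$fitted, y[cc])$auc
  auc_imp <- c_statistic(lp_imp_on_cc, y[cc])$auc
  expect_lt(abs(auc_cc - auc_imp), 0.01)
})

test_that("stepwise selection keeps forced terms and finds real signal", {
  set.seed(20)
  n <- 5000
  X <- as.data.frame(matrix(rnorm(n * 6), ncol = 6))
  names(X) <- c("signal", paste0("noise", 1:4), "forced_cov")
  y <- rbinom(n, 1, plogis(-2 + 2 * X$signal))
  sel <- stepwise_select(X, y, forced = "forced_cov")
  expect_true("forced_cov" %in% sel$selected)   # forced despite null effect
  expect_true("signal" %in% sel$selected)
  # selected noise terms must all pass the stay rule in the final fit
  noise_kept <- intersect(paste0("noise", 1:4), sel$selected)
  expect_lte(length(noise_kept), 2)
  expect_error(stepwise_select(X[, 0], y), "empty")
})

test_that("all-noise stepwise selects about as often as multiplicity implies", {
  set.seed(21)
  reps <- 40
  any_sel <- replicate(reps, {
    n <- 400
    X <- as.data.frame(matrix(rnorm(n * 5), ncol = 5))
    y <- rbinom(n, 1, 0.3)
    length(stepwise_select(X, y, p_enter = 0.05, p_stay = 0.10)$selected) > 0
  })
  # P(min of 5 null p-values < .05) = 1 - .95^5 ~ 0.226; allow 4 SE
  p0 <- 1 - 0.95^5
  expect_lt(abs(mean(any_sel) - p0), 4 * sqrt(p0 * (1 - p0) / reps))
})
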