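# Logistic outcome modelling: IRLS fitting with a coefficient-change
# convergence rule, concordance statistic with DeLong-style CI,
# Hosmer-Lemeshow calibration, median+indicator score imputation, and
# forward/backward stepwise selection on Wald p-values.

#' Fit a binary logistic regression by IRLS
#'
#' Maximum likelihood via iteratively reweighted least squares. Convergence
#' is declared when the maximum absolute coefficient change falls below
#' `tol` (default 0.001, the coefficient-change rule of classic SPSS-style
#' output). Standard errors come from the inverse observed information at
#' the final iterate.
#'
#' @param x design matrix or data frame of covariates (no intercept column;
#'   one is added unless `add_intercept = FALSE`).
#' @param y 0/1 response vector containing both classes.
#' @param tol maximum absolute coefficient change declaring convergence.
#' @param max_iter iteration cap (default 25).
#' @param add_intercept prepend an intercept column (default `TRUE`).
#' @return Object of class `bpv_logit`: `coefficients`, `se`, `vcov`,
#'   `fitted`, `linear_predictors`, `loglik` (per-iteration trace in
#'   `loglik_trace`), `iterations`, `converged`, `separation`, `n`.
#' @export
#' @examples
#' y <- c(rep(1, 3), rep(0, 7))
#' fit <- fit_logistic_irls(matrix(nrow = 10, ncol = 0), y)
#' fit$coefficients  # log(3/7)
fit_logistic_irls <- function(x, y, tol = 1e-3, max_iter = 25,
                              add_intercept = TRUE) {
  X <- as.matrix(x)
  if (is.null(colnames(X)) && ncol(X)) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2) stop("labels must contain both classes")
  if (nrow(X) != length(y)) stop("x and y dimensions do not match")
  if (any(!is.finite(X))) stop("design matrix must be finite (no NAs)")
  if (add_intercept) X <- cbind(`(Intercept)` = 1, X)

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop("design matrix is rank deficient; offending columns: ",
         paste(bad, collapse = ", "))
  }

  p <- ncol(X)
  beta <- numeric(p)
  names(beta) <- colnames(X)
  if (add_intercept) beta[1] <- stats::qlogis(mean(y))
  ll <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  loglik_trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  info <- NULL
  while (iter < max_iter) {
    iter <- iter + 1
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    info <- XtW %*% X
    beta_new <- drop(solve(info, XtW %*% z))
    names(beta_new) <- colnames(X)
    loglik_trace <- c(loglik_trace, ll(beta_new))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- t(X * w) %*% X
  vc <- solve(info)
  se <- sqrt(diag(vc))
  # perfect or quasi-separation: fitted values saturating at the observed
  # classes with runaway coefficients
  separation <- max(abs(beta)) > 25 &&
    mean(pmin(mu, 1 - mu) < 1e-4) > 0.5
  if (separation) {
    warning("possible (quasi-)separation: estimates diverging")
  }
  structure(
    list(coefficients = beta, se = se, vcov = vc, fitted = mu,
         linear_predictors = eta,
         loglik = loglik_trace[length(loglik_trace)],
         loglik_trace = loglik_trace, iterations = iter,
         converged = converged, separation = separation, n = length(y),
         score = drop(t(X) %*% (y - mu))),
    class = "bpv_logit"
  )
}

#' @export
print.bpv_logit <- function(x, ...) {
  cat(sprintf("<bpv_logit> n = %d, logLik = %.3f, %d iterations (%s)\n",
              x$n, x$loglik, x$iterations,
              if (x$converged) "converged" else "not converged"))
  tab <- cbind(estimate = x$coefficients, se = x$se,
               z = x$coefficients / x$se,
               p = 2 * stats::pnorm(-abs(x$coefficients / x$se)))
  print(round(tab, 4))
  invisible(x)
}

wald_p <- function(fit, term) {
  z <- fit$coefficients[[term]] / fit$se[[term]]
  2 * stats::pnorm(-abs(z))
}

#' Concordance statistic (AUC) with DeLong-style confidence interval
#'
#' AUC = (concordant pairs + 0.5 x tied pairs) / (n1 x n0) over all
#' event/non-event pairs. The exact pairwise path is used when
#' `n1 * n0 <= 1e4`, an algebraically identical midrank path otherwise;
#' `method` can force either. The CI uses the asymptotic variance of the
#' concordance estimator from the DeLong placement decomposition, clipped
#' to `[0, 1]`.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 outcome labels (both classes present).
#' @param method `"auto"`, `"exact"` (pairwise) or `"rank"` (midranks).
#' @param conf_level confidence level (default 0.95).
#' @return Object of class `c_statistic`: `auc`, `ci`, `se`, `n_events`,
#'   `n_nonevents`, `method`.
#' @export
#' @examples
#' c_statistic(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))$auc  # 1
c_statistic <- function(scores, labels,
                        method = c("auto", "exact", "rank"),
                        conf_level = 0.95) {
  method <- match.arg(method)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- as.numeric(labels[ok])
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    cond <- simpleError("AUC undefined: only one outcome class present")
    class(cond) <- c("bpv_single_class", class(cond))
    stop(cond)
  }
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  if (method == "auto") {
    method <- if (as.double(n1) * n0 <= 1e4) "exact" else "rank"
  }
  if (method == "exact") {
    cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
    auc <- mean(cmp)
    v10 <- rowMeans(cmp)
    v01 <- 1 - colMeans(cmp)      # placement of non-events, event-side scale
  } else {
    r_all <- rank(scores, ties.method = "average")
    r1 <- rank(s1, ties.method = "average")
    r0 <- rank(s0, ties.method = "average")
    v10 <- (r_all[labels == 1] - r1) / n0
    v01 <- 1 - (r_all[labels == 0] - r0) / n1
    auc <- mean(v10)
  }
  var_auc <- if (n1 > 1 && n0 > 1) {
    stats::var(v10) / n1 + stats::var(1 - v01) / n0
  } else NA_real_
  se <- sqrt(var_auc)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- if (is.na(se)) c(NA_real_, NA_real_) else {
    c(max(0, min(auc, auc - zq * se)), min(1, max(auc, auc + zq * se)))
  }
  structure(list(auc = auc, ci = ci, se = se, n_events = n1,
                 n_nonevents = n0, method = method,
                 conf_level = conf_level),
            class = "c_statistic")
}

#' @export
print.c_statistic <- function(x, ...) {
  cat(sprintf("<c_statistic> AUC = %.4f (%.0f%% CI %.4f-%.4f), %d events / %d non-events [%s]\n",
              x$auc, 100 * x$conf_level, x$ci[1], x$ci[2],
              x$n_events, x$n_nonevents, x$method))
  invisible(x)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Patients are sorted into `groups` quantile bins of predicted probability
#' (ties at bin boundaries go to the lower bin; bins with zero expected
#' count are merged with their neighbour and logged). The statistic sums
#' `(observed - expected)^2 / expected` over bins and both outcome states;
#' df = bins - 2.
#'
#' @param predicted fitted event probabilities in `[0, 1]`.
#' @param labels 0/1 outcome labels.
#' @param groups number of quantile groups (default 10 deciles; >= 3).
#' @return Object of class `hosmer_lemeshow`: `chi2`, `df`, `p_value`,
#'   `table` (per-bin n, observed and expected events), `n_merged`.
#' @export
hosmer_lemeshow <- function(predicted, labels, groups = 10) {
  if (groups < 3) stop("need at least 3 groups")
  ok <- !is.na(predicted) & !is.na(labels)
  p <- predicted[ok]
  y <- as.numeric(labels[ok])
  n <- length(p)
  if (n < groups) stop("need at least as many observations as groups")
  if (any(p < 0 | p > 1)) stop("predicted probabilities must lie in [0, 1]")
  brk <- unique(stats::quantile(p, probs = seq(0, 1, length.out = groups + 1),
                                type = 7, names = FALSE))
  if (length(brk) < 3) stop("predicted probabilities too discrete to group")
  # right-closed bins assign boundary ties to the lower bin
  bin <- cut(p, breaks = brk, include.lowest = TRUE, right = TRUE,
             labels = FALSE)
  agg <- function(b) {
    data.frame(bin = sort(unique(b)),
               n = as.vector(table(b)),
               o1 = as.vector(tapply(y, b, sum)),
               e1 = as.vector(tapply(p, b, sum)))
  }
  tab <- agg(bin)
  n_merged <- 0L
  # merge bins whose expected count (events or non-events) is zero
  repeat {
    e0 <- tab$n - tab$e1
    bad <- which(tab$e1 <= 0 | e0 <= 0)
    if (!length(bad) || nrow(tab) <= 3) break
    i <- bad[1]
    j <- if (i == 1) 2 else i - 1
    tab$n[j] <- tab$n[j] + tab$n[i]
    tab$o1[j] <- tab$o1[j] + tab$o1[i]
    tab$e1[j] <- tab$e1[j] + tab$e1[i]
    tab <- tab[-i, , drop = FALSE]
    n_merged <- n_merged + 1L
  }
  o0 <- tab$n - tab$o1
  e0 <- tab$n - tab$e1
  chi2 <- sum((tab$o1 - tab$e1)^2 / tab$e1 + (o0 - e0)^2 / e0)
  df <- nrow(tab) - 2
  structure(list(chi2 = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
                 table = tab, n_merged = n_merged, groups = groups),
            class = "hosmer_lemeshow")
}

#' @export
print.hosmer_lemeshow <- function(x, ...) {
  cat(sprintf("<hosmer_lemeshow> chi2 = %.3f, df = %d, p = %.4f (%d bins%s)\n",
              x$chi2, x$df, x$p_value, nrow(x$table),
              if (x$n_merged) sprintf(", %d merged", x$n_merged) else ""))
  invisible(x)
}

#' Impute missing STS risk scores
#'
#' Default strategy: replace missing scores by the observed median and add a
#' missingness-indicator column (`<score>_missing`) retained for modelling.
#' The strategy is pluggable via a function `function(x) imputed_values`.
#'
#' @param records data frame with score columns.
#' @param score_cols score column names (default both STS scores).
#' @param strategy `"median"` or a function of the full column returning
#'   imputed values for the missing entries.
#' @return `records` with missing scores filled and indicator columns added.
#' @export
#' @examples
#' r <- data.frame(sts_mm_score = c(0.01, 0.03, NA))
#' impute_missing_sts(r, "sts_mm_score")
impute_missing_sts <- function(records,
                               score_cols = c("sts_mm_score",
                                              "sts_renal_score"),
                               strategy = "median") {
  score_cols <- intersect(score_cols, names(records))
  if (!length(score_cols)) stop("no score columns found")
  for (sc in score_cols) {
    x <- records[[sc]]
    miss <- is.na(x)
    if (all(miss)) stop("all values of ", sc, " are missing; cannot impute")
    if (any(miss)) {
      fill <- if (is.function(strategy)) strategy(x)
      else stats::median(x, na.rm = TRUE)
      x[miss] <- fill
      records[[sc]] <- x
    }
    records[[paste0(sc, "_missing")]] <- as.integer(miss)
  }
  records
}

#' Stepwise variable selection on Wald p-values
#'
#' Forward selection with backward pruning: at each step the candidate with
#' the smallest Wald p below `p_enter` joins the model; any non-forced
#' variable whose Wald p rises above `p_stay` is then dropped. The forced
#' set (e.g. a fixed adjustment set) is always retained.
#'
#' @param x data frame / matrix of candidate covariates.
#' @param y 0/1 response.
#' @param forced column names always kept in the model.
#' @param candidates columns eligible for selection (default: all
#'   non-forced columns).
#' @param p_enter,p_stay entry and stay thresholds (defaults 0.05 / 0.10).
#' @param max_steps safety cap on selection rounds.
#' @return List: `selected` (forced + selected, in order), `history`
#'   (data frame of steps), `fit` (final `bpv_logit`).
#' @export
stepwise_select <- function(x, y, forced = character(),
                            candidates = NULL,
                            p_enter = 0.05, p_stay = 0.10, max_steps = 50) {
  X <- as.data.frame(x)
  if (is.null(candidates)) candidates <- setdiff(names(X), forced)
  if (!length(candidates)) stop("candidate set is empty")
  current <- character(0)
  history <- list()
  step <- 0
  repeat {
    step <- step + 1
    if (step > max_steps) break
    changed <- FALSE
    remaining <- setdiff(candidates, current)
    if (length(remaining)) {
      pvals <- vapply(remaining, function(v) {
        fit <- fit_logistic_irls(X[, c(forced, current, v), drop = FALSE], y)
        wald_p(fit, v)
      }, numeric(1))
      if (min(pvals) < p_enter) {
        add <- remaining[which.min(pvals)]
        current <- c(current, add)
        history[[length(history) + 1]] <-
          data.frame(step = step, action = "add", variable = add,
                     p = min(pvals), stringsAsFactors = FALSE)
        changed <- TRUE
      }
    }
    if (length(current)) {
      fit <- fit_logistic_irls(X[, c(forced, current), drop = FALSE], y)
      pv <- vapply(current, function(v) wald_p(fit, v), numeric(1))
      if (max(pv) > p_stay) {
        drop_v <- current[which.max(pv)]
        current <- setdiff(current, drop_v)
        history[[length(history) + 1]] <-
          data.frame(step = step, action = "drop", variable = drop_v,
                     p = max(pv), stringsAsFactors = FALSE)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sel <- c(forced, current)
  fit <- if (length(sel)) {
    fit_logistic_irls(X[, sel, drop = FALSE], y)
  } else {
    fit_logistic_irls(matrix(nrow = length(y), ncol = 0), y)
  }
  list(selected = sel,
       history = if (length(history)) do.call(rbind, history) else
         data.frame(step = integer(), action = character(),
                    variable = character(), p = numeric()),
       fit = fit)
}
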