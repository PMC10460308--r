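# ---- Multiple imputation by chained equations -----------------------------

# Bayesian-draw linear regression for predictive mean matching: returns
# observed-data predictions under the ML fit and missing-data predictions
# under a posterior parameter draw (type-1 matching).
pmm_draw <- function(X_obs, y_obs, X_mis, k = 5) {
  qrX <- qr(X_obs)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  X_obs <- X_obs[, keep, drop = FALSE]
  X_mis <- X_mis[, keep, drop = FALSE]
  fit <- stats::lm.fit(X_obs, y_obs)
  beta <- fit$coefficients
  res <- fit$residuals
  df <- max(length(y_obs) - length(beta), 1)
  sigma2 <- sum(res^2) / rchisq(1, df)
  XtXinv <- chol2inv(chol(crossprod(X_obs) +
                            diag(1e-8, ncol(X_obs))))
  beta_star <- beta + drop(chol(sigma2 * XtXinv +
                                  diag(1e-12, ncol(X_obs))) %*%
                             rnorm(length(beta)))
  yhat_obs <- drop(X_obs %*% beta)
  yhat_mis <- drop(X_mis %*% beta_star)
  idx <- vapply(yhat_mis, function(yh) {
    d <- abs(yhat_obs - yh)
    cand <- order(d)[seq_len(min(k, length(d)))]
    cand[sample.int(length(cand), 1)]
  }, integer(1))
  y_obs[idx]
}

logistic_draw <- function(X_obs, y_obs, X_mis) {
  qrX <- qr(X_obs)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  X_obs <- X_obs[, keep, drop = FALSE]
  X_mis <- X_mis[, keep, drop = FALSE]
  fit <- suppressWarnings(glm.fit(X_obs, y_obs, family = binomial()))
  beta <- fit$coefficients
  w <- fit$weights
  V <- tryCatch(chol2inv(chol(crossprod(X_obs * sqrt(w)) +
                                diag(1e-8, ncol(X_obs)))),
                error = function(e) diag(1e-4, ncol(X_obs)))
  beta_star <- beta + drop(chol(V + diag(1e-12, ncol(V))) %*%
                             rnorm(length(beta)))
  p <- plogis(drop(X_mis %*% beta_star))
  rbinom(length(p), 1, p) == 1
}

polytomous_draw <- function(X_obs, y_obs, X_mis) {
  df_obs <- data.frame(.y = y_obs, X_obs[, -1, drop = FALSE],
                       check.names = FALSE)
  fit <- tryCatch(
    fit_multinomial(.y ~ ., df_obs, tol = 1e-6, sep_limit = 25),
    error = function(e) NULL)
  lev <- levels(factor(y_obs))
  if (is.null(fit)) {  # fall back to observed-margin draw
    return(factor(sample(as.character(y_obs), nrow(X_mis), replace = TRUE),
                  levels = lev))
  }
  fl <- flatten_fit(fit)
  V <- as.matrix(fl$vcov)
  beta_star <- fl$coef + drop(chol(V + diag(1e-10, nrow(V))) %*%
                                rnorm(length(fl$coef)))
  B <- matrix(beta_star, nrow(fit$coefficients), byrow = TRUE)
  eta <- cbind(0, X_mis %*% t(B))
  eta <- eta - apply(eta, 1, max)
  Pmat <- exp(eta) / rowSums(exp(eta))
  picks <- apply(Pmat, 1, function(pr) sample.int(length(pr), 1, prob = pr))
  factor(fit$levels[picks], levels = lev)
}

#' Multiple imputation by chained equations
#'
#' Fills missing values by cycling per-variable conditional models:
#' predictive mean matching (`pmm_k` donors, type-1 matching with a
#' Bayesian parameter draw) for numeric variables, Bayesian logistic
#' regression for two-level variables and polytomous (multinomial)
#' regression for factors with more levels. Each of the `m` chains is
#' initialised by random draws from the observed margins and cycled
#' `maxit` times; all randomness derives from `seed`.
#'
#' @param data Data frame; character columns are treated as factors.
#' @param m Number of imputations.
#' @param maxit Chained-equation iterations per chain.
#' @param seed Integer seed.
#' @param pmm_k Donor-pool size for predictive mean matching.
#' @return Object of class `mice_result`: list with `imputations` (list of
#'   `m` completed data frames), `m`, `maxit`, `seed` and
#'   `missing_pattern` (per-variable missing counts).
#' @export
mice_impute <- function(data, m = 20, maxit = 10, seed = 1L, pmm_k = 5) {
  if (m < 2) stop("'m' must be at least 2")
  data <- as.data.frame(data)
  for (j in names(data)) {
    if (is.character(data[[j]]) || is.logical(data[[j]])) {
      data[[j]] <- factor(data[[j]])
    }
  }
  miss_n <- vapply(data, function(x) sum(is.na(x)), integer(1))
  incomplete <- names(miss_n)[miss_n > 0]
  for (v in incomplete) {
    obs <- data[[v]][!is.na(data[[v]])]
    if (length(unique(obs)) < 2) {
      stop("variable '", v, "' is constant among observed values; ",
           "it cannot be imputed")
    }
  }
  if (!length(incomplete)) {
    return(structure(list(imputations = replicate(m, data, simplify = FALSE),
                          m = m, maxit = 0, seed = seed,
                          missing_pattern = miss_n),
                     class = "mice_result"))
  }
  set.seed(seed)
  visit <- incomplete[order(miss_n[incomplete])]
  predictors <- names(data)
  imputations <- vector("list", m)
  for (chain in seq_len(m)) {
    comp <- data
    for (v in incomplete) {  # initial fill from observed margins
      nas <- is.na(comp[[v]])
      obs <- comp[[v]][!nas]
      comp[[v]][nas] <- obs[sample.int(length(obs), sum(nas), replace = TRUE)]
    }
    for (iter in seq_len(maxit)) {
      for (v in visit) {
        nas <- is.na(data[[v]])
        if (!any(nas)) next
        rhs <- setdiff(predictors, v)
        X <- model.matrix(~ ., comp[rhs])
        X_obs <- X[!nas, , drop = FALSE]
        X_mis <- X[nas, , drop = FALSE]
        y_obs <- data[[v]][!nas]
        if (is.numeric(y_obs)) {
          comp[[v]][nas] <- pmm_draw(X_obs, y_obs, X_mis, k = pmm_k)
        } else if (nlevels(factor(y_obs)) == 2) {
          lev <- levels(factor(y_obs))
          draw <- logistic_draw(X_obs, as.integer(factor(y_obs)) - 1L, X_mis)
          comp[[v]][nas] <- factor(lev[draw + 1L], levels = levels(comp[[v]]))
        } else {
          comp[[v]][nas] <- polytomous_draw(X_obs, factor(y_obs), X_mis)
        }
      }
    }
    imputations[[chain]] <- comp
  }
  structure(list(imputations = imputations, m = m, maxit = maxit,
                 seed = seed, missing_pattern = miss_n),
            class = "mice_result")
}

#' @export
print.mice_result <- function(x, ...) {
  cat("Chained-equation imputation:", x$m, "imputations,",
      x$maxit, "iterations;",
      sum(x$missing_pattern > 0), "incomplete variable(s)\n")
  invisible(x)
}
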