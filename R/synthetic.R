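# ---- Synthetic cohort generator -------------------------------------------
#
# Substance involvement arises from a Gaussian copula: one standard-normal
# latent per substance category, correlated across categories. Use in the
# past 3 months is the latent exceeding a prevalence threshold; graded
# frequency (q2) comes from further cut-points in the upper tail; each harm
# item loads on the same latent (loading alpha) with its own thresholds, so
# harms concentrate among heavier users but keep item-level noise.
# Covariates shift *group membership* (multinomial-logit relative risks);
# participants are then matched to latent draws conditional on their group,
# which preserves the marginal copula law exactly when the group
# probabilities are calibrated to the copula-implied shares.

gauss_hermite <- function(n) {
  # Golub-Welsch nodes/weights for the standard-normal weight function:
  # E[f(Z)] ~ sum(w * f(x))
  if (n == 1) return(list(x = 0, w = 1))
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1))
  J[cbind(seq_len(n - 1), 2:n)] <- off
  J[cbind(2:n, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = e$vectors[1, ord]^2)
}

hermite_poly <- function(z, K) {
  # probabilists' Hermite polynomials He_0..He_K at points z
  H <- matrix(0, length(z), K + 1)
  H[, 1] <- 1
  if (K >= 1) H[, 2] <- z
  if (K >= 2) for (k in 2:K) H[, k + 1] <- z * H[, k] - (k - 1) * H[, k - 1]
  H
}

freq_levels_upper <- c("once_or_twice", "monthly", "weekly",
                       "daily_or_almost_daily")

default_freq_mix <- function() {
  list(tobacco = c(0.20, 0.12, 0.21, 0.47),
       alcohol = c(0.35, 0.25, 0.30, 0.10),
       cannabis = c(0.25, 0.15, 0.25, 0.35),
       .default = c(0.30, 0.25, 0.25, 0.20))
}

default_harm_given_use <- function() {
  list(tobacco = c(urge = 0.60, problems = 0.15, failed_expect = 0.10,
                   concerns = 0.30, cutdown_fail = 0.35),
       cannabis = c(urge = 0.70, problems = 0.35, failed_expect = 0.30,
                    concerns = 0.35, cutdown_fail = 0.30),
       ats = c(urge = 0.75, problems = 0.50, failed_expect = 0.45,
               concerns = 0.50, cutdown_fail = 0.40),
       .default = c(urge = 0.60, problems = 0.35, failed_expect = 0.30,
                    concerns = 0.35, cutdown_fail = 0.30))
}

lookup_sub <- function(lst, s) if (!is.null(lst[[s]])) lst[[s]] else lst$.default

#' Synthetic cohort generator configuration
#'
#' @param n Participant count.
#' @param seed Integer seed; all randomness derives from it.
#' @param prevalence Named per-substance use prevalences in (0, 1).
#' @param target Dependence specification: a list with `type` either
#'   `"partial"` (matrix of target partial correlations of the
#'   log-involvement scores; converted to a latent correlation by
#'   standardized-precision inversion plus score-scale calibration) or
#'   `"latent"` (latent correlation matrix used as-is), and `matrix`.
#' @param freq_mix Per-substance probabilities of the four non-"never" q2
#'   levels conditional on use (list; `.default` entry used as fallback).
#' @param harm_given_use Per-substance probabilities of each harm item
#'   occurring, conditional on use (list with `.default`).
#' @param harm_level_mix Conditional level split for q3-q5 given occurrence
#'   (once/monthly/weekly/daily).
#' @param q6q7_past_share Share of "yes" answers to q6/q7 that fall in the
#'   past 3 months.
#' @param harm_loading Loading of harm-item latents on the substance latent.
#' @param covariate_effects `NULL`, or a list with one named numeric vector
#'   of log relative-risk ratios per non-reference group
#'   (`alcohol_tobacco_other`, `cannabis_no_ats`, `ats`); names must match
#'   columns of the generator's covariate design (see
#'   [covariate_design()]).
#' @param missing_rate MCAR missingness proportion in \[0, 0.2\].
#' @param missing_unit `"cell"` or `"assist_block"` (see
#'   [inject_missingness()]).
#' @param substances Category codes.
#' @return Validated list of class `generator_config`.
#' @export
generator_config <- function(n, seed = 1L,
                             prevalence = NULL,
                             target = NULL,
                             freq_mix = default_freq_mix(),
                             harm_given_use = default_harm_given_use(),
                             harm_level_mix = c(0.45, 0.25, 0.20, 0.10),
                             q6q7_past_share = 0.7,
                             harm_loading = 0.85,
                             covariate_effects = NULL,
                             missing_rate = 0,
                             missing_unit = c("cell", "assist_block"),
                             substances = assist_substances()) {
  p <- length(substances)
  if (is.null(prevalence)) {
    prevalence <- setNames(rep(0.2, p), substances)
  }
  if (is.null(target)) {
    target <- list(type = "latent", matrix = diag(p))
  }
  stopifnot(n >= 1, length(prevalence) == p,
            all(prevalence > 0 & prevalence < 1))
  if (is.null(names(prevalence))) names(prevalence) <- substances
  M <- as.matrix(target$matrix)
  if (!all(dim(M) == c(p, p)) || max(abs(M - t(M))) > 1e-8) {
    stop("target matrix must be a symmetric ", p, "x", p, " matrix")
  }
  if (missing_rate < 0 || missing_rate > 0.2) {
    stop("'missing_rate' must be in [0, 0.2]")
  }
  if (target$type == "latent") {
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) {
      stop("latent correlation matrix is not positive definite ",
           "(smallest eigenvalue ", format(min(ev), digits = 4), ")")
    }
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 substances = substances, prevalence = prevalence,
                 target = list(type = match.arg(target$type,
                                                c("partial", "latent")),
                               matrix = M),
                 freq_mix = freq_mix, harm_given_use = harm_given_use,
                 harm_level_mix = harm_level_mix / sum(harm_level_mix),
                 q6q7_past_share = q6q7_past_share,
                 harm_loading = harm_loading,
                 covariate_effects = covariate_effects,
                 missing_rate = missing_rate,
                 missing_unit = match.arg(missing_unit)),
            class = "generator_config")
}

#' Target partial-correlation matrix of the calibrated preset
#'
#' Strongest edges, in order: tobacco-cannabis 0.48, ATS-hallucinogens
#' 0.30, tobacco-alcohol 0.28, ATS-cocaine 0.26, sedatives-opioids 0.21;
#' ATS additionally carries moderate links to the remaining substances so
#' it is the hub of the network, and every other pair keeps a small
#' positive partial correlation.
#'
#' @return 10 x 10 symmetric matrix with unit diagonal.
#' @export
paper_like_partials <- function() {
  s <- assist_substances()
  P <- matrix(0.03, 10, 10, dimnames = list(s, s))
  set_p <- function(a, b, v) {
    P[a, b] <<- v; P[b, a] <<- v
  }
  set_p("tobacco", "cannabis", 0.48)
  set_p("ats", "hallucinogens", 0.30)
  set_p("tobacco", "alcohol", 0.28)
  set_p("ats", "cocaine", 0.26)
  set_p("sedatives", "opioids", 0.21)
  set_p("ats", "opioids", 0.13)
  set_p("ats", "sedatives", 0.11)
  set_p("ats", "inhalants", 0.10)
  set_p("ats", "cannabis", 0.11)
  set_p("ats", "tobacco", 0.10)
  set_p("ats", "other", 0.08)
  set_p("ats", "alcohol", 0.07)
  set_p("cannabis", "hallucinogens", 0.10)
  diag(P) <- 1
  P
}

#' Calibrated cohort generator preset
#'
#' Marginal use prevalences near the published cohort (tobacco 33%,
#' alcohol 63%, cannabis 27%, ATS 7.6%, cocaine 3.3%, ...), the
#' [paper_like_partials()] dependence structure on the log-score scale,
#' multinomial covariate effects on group membership of published sign and
#' magnitude, and ~5% block-structured missingness.
#'
#' @param n Cohort size.
#' @param seed Seed.
#' @param missing_rate Missingness proportion (0 disables injection).
#' @param covariate_effects Override the preset effect list (`NULL` keeps
#'   the preset; `FALSE` disables effects).
#' @return `generator_config`.
#' @export
paper_like_config <- function(n = 1107, seed = 1L, missing_rate = 0.05,
                              covariate_effects = NULL) {
  prevalence <- c(tobacco = 0.33, alcohol = 0.63, cannabis = 0.27,
                  cocaine = 0.033, ats = 0.076, inhalants = 0.02,
                  sedatives = 0.11, hallucinogens = 0.05, opioids = 0.036,
                  other = 0.03)
  if (is.null(covariate_effects)) {
    ln <- log
    covariate_effects <- list(
      alcohol_tobacco_other = c(
        age = ln(1.36), sexmale = ln(0.67), lgbtyes = ln(1.05),
        regionregional = ln(1.96), eduworking_only = ln(4.03),
        edustudying_and_working = ln(3.02), eduneither = ln(1.39),
        diaganxiety = ln(0.66), diagdepression_and_anxiety = ln(0.88),
        diagother = ln(0.71), zphq9 = ln(0.87), zgad7 = ln(0.86),
        zrrs10 = ln(1.06), zpsqi = ln(1.28), zcas = ln(1.08),
        zpq16 = ln(1.23)),
      cannabis_no_ats = c(
        age = ln(1.33), sexmale = ln(1.00), lgbtyes = ln(1.66),
        regionregional = ln(1.95), eduworking_only = ln(3.46),
        edustudying_and_working = ln(2.01), eduneither = ln(1.98),
        diaganxiety = ln(0.80), diagdepression_and_anxiety = ln(1.44),
        diagother = ln(1.36), zphq9 = ln(0.88), zgad7 = ln(0.86),
        zrrs10 = ln(1.06), zpsqi = ln(1.05), zcas = ln(1.37),
        zpq16 = ln(1.12)),
      ats = c(
        age = ln(1.58), sexmale = ln(0.87), lgbtyes = ln(0.92),
        regionregional = ln(3.13), eduworking_only = ln(8.41),
        edustudying_and_working = ln(3.56), eduneither = ln(3.08),
        diaganxiety = ln(0.94), diagdepression_and_anxiety = ln(0.97),
        diagother = ln(2.09), zphq9 = ln(1.09), zgad7 = ln(0.81),
        zrrs10 = ln(1.40), zpsqi = ln(1.10), zcas = ln(1.09),
        zpq16 = ln(1.25)))
  } else if (identical(covariate_effects, FALSE)) {
    covariate_effects <- NULL
  }
  generator_config(
    n = n, seed = seed, prevalence = prevalence,
    target = list(type = "partial", matrix = paper_like_partials()),
    covariate_effects = covariate_effects,
    missing_rate = missing_rate, missing_unit = "assist_block")
}

# ---- cut-points -----------------------------------------------------------

# P(H > t | Z > c) for (H, Z) standard bivariate normal with correlation a
cond_exceed <- function(t, c_use, a) {
  p_joint <- mvtnorm::pmvnorm(lower = c(t, c_use), upper = c(Inf, Inf),
                              corr = matrix(c(1, a, a, 1), 2))[1]
  p_joint / (1 - pnorm(c_use))
}

solve_cut <- function(target, c_use, a) {
  if (target <= 0) return(Inf)
  if (target >= 1) return(-Inf)
  uniroot(function(t) cond_exceed(t, c_use, a) - target,
          lower = -8, upper = 8, tol = 1e-10)$root
}

substance_cuts <- function(s, config) {
  prev <- config$prevalence[[s]]
  c_use <- qnorm(1 - prev)
  mix <- lookup_sub(config$freq_mix, s)
  mix <- mix / sum(mix)
  tails <- rev(cumsum(rev(mix)))  # P(level >= k | use)
  q2_cuts <- qnorm(1 - prev * tails[-1])  # cuts for monthly, weekly, daily
  a <- config$harm_loading
  hgu <- lookup_sub(config$harm_given_use, s)
  hmix <- config$harm_level_mix
  htails <- rev(cumsum(rev(hmix)))
  harm <- list()
  for (h in c("urge", "problems", "failed_expect")) {
    harm[[h]] <- vapply(htails, function(ts)
      solve_cut(hgu[[h]] * ts, c_use, a), numeric(1))
  }
  for (h in c("concerns", "cutdown_fail")) {
    harm[[h]] <- c(any = solve_cut(hgu[[h]], c_use, a),
                   past = solve_cut(hgu[[h]] * config$q6q7_past_share,
                                    c_use, a))
  }
  list(c_use = c_use, q2_cuts = q2_cuts, harm = harm, alpha = a)
}

# ---- score-scale calibration ----------------------------------------------

item_weight_sets <- function(substance, weights = assist_weights()) {
  items <- assist_items(substance, weights)
  lapply(setNames(items, items), function(it) weights[[it]])
}

# distribution of the raw involvement score given the substance latent z
score_dist_given_z <- function(z, cuts, wsets) {
  a <- cuts$alpha
  s_noise <- sqrt(1 - a^2)
  exceed <- function(t) pnorm((a * z - t) / s_noise)
  # q2 deterministic given z
  q2_cutpoints <- c(cuts$c_use, cuts$q2_cuts)
  q2_lvl <- sum(z > q2_cutpoints)  # 0..4
  base <- wsets$q2[[q2_lvl + 1]]
  max_total <- sum(vapply(wsets, max, numeric(1)))
  pmf <- numeric(max_total + 1)
  pmf[base + 1] <- 1
  add_item <- function(pmf, wts, probs) {
    out <- numeric(length(pmf))
    for (k in seq_along(wts)) {
      if (probs[k] <= 0) next
      w <- wts[k]
      out[(w + 1):length(pmf)] <- out[(w + 1):length(pmf)] +
        probs[k] * pmf[1:(length(pmf) - w)]
    }
    out
  }
  harm_items <- intersect(names(wsets), c("q3", "q4", "q5"))
  map_freq <- c(q3 = "urge", q4 = "problems", q5 = "failed_expect")
  for (it in harm_items) {
    cutv <- cuts$harm[[map_freq[[it]]]]
    pex <- vapply(cutv, exceed, numeric(1))  # P(level >= k), k=1..4
    probs <- c(1 - pex[1], -diff(pex), pex[length(pex)])
    pmf <- add_item(pmf, wsets[[it]], probs)
  }
  for (it in intersect(names(wsets), c("q6", "q7"))) {
    cutv <- cuts$harm[[c(q6 = "concerns", q7 = "cutdown_fail")[[it]]]]
    p_any <- exceed(cutv[["any"]])
    p_past <- exceed(cutv[["past"]])
    p_past <- min(p_past, p_any)
    probs <- c(1 - p_any, p_any - p_past, p_past)
    pmf <- add_item(pmf, wsets[[it]], probs)
  }
  pmf
}

# conditional mean/second moment of log(1 + score) given z, on GH nodes,
# and Hermite expansion of the conditional mean
score_scale_profile <- function(s, config, n_nodes = 60, K = 15,
                                weights = assist_weights()) {
  cuts <- substance_cuts(s, config)
  wsets <- item_weight_sets(s, weights)
  gh <- gauss_hermite(n_nodes)
  support <- 0:(sum(vapply(wsets, max, numeric(1))))
  g <- log(1 + support)
  m <- numeric(n_nodes); m2 <- numeric(n_nodes)
  for (i in seq_len(n_nodes)) {
    pmf <- score_dist_given_z(gh$x[i], cuts, wsets)
    m[i] <- sum(pmf * g)
    m2[i] <- sum(pmf * g^2)
  }
  mu <- sum(gh$w * m)
  var_total <- sum(gh$w * m2) - mu^2
  H <- hermite_poly(gh$x, K)
  a_k <- vapply(seq_len(K), function(k)
    sum(gh$w * m * H[, k + 1]) / factorial(k), numeric(1))
  list(substance = s, cuts = cuts, mu = mu, var_total = var_total,
       a_k = a_k, K = K)
}

# Pearson correlation of log-scores implied by latent correlation rho
score_cor_from_latent <- function(rho, prof_i, prof_j) {
  K <- min(prof_i$K, prof_j$K)
  k <- seq_len(K)
  cov <- sum(factorial(k) * prof_i$a_k[k] * prof_j$a_k[k] * rho^k)
  cov / sqrt(prof_i$var_total * prof_j$var_total)
}

# invert: latent correlation achieving a target observed correlation
latent_cor_for_target <- function(target, prof_i, prof_j) {
  f <- function(r) score_cor_from_latent(r, prof_i, prof_j) - target
  hi <- f(0.999); lo <- f(-0.999)
  if (target >= 0 && hi < 0) {
    stop(sprintf(
      "target correlation %.3f between %s and %s exceeds the maximum %.3f attainable on the score scale",
      target, prof_i$substance, prof_j$substance,
      score_cor_from_latent(0.999, prof_i, prof_j)))
  }
  if (target <= 0 && lo > 0) {
    stop("target correlation below the attainable minimum for pair ",
         prof_i$substance, "-", prof_j$substance)
  }
  uniroot(f, lower = -0.999, upper = 0.999, tol = 1e-9)$root
}

#' Convert a partial-correlation matrix to a correlation matrix
#'
#' Builds the standardized precision matrix (unit diagonal, off-diagonal
#' `-p_ij`), inverts it and rescales to unit variance. The partial
#' correlations of the result equal the input exactly.
#'
#' @param P Symmetric matrix with unit diagonal of partial correlations.
#' @return Correlation matrix.
#' @export
partial_to_correlation <- function(P) {
  P <- as.matrix(P)
  omega <- -P
  diag(omega) <- 1
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("standardized precision implied by the partial correlations is ",
         "not positive definite (smallest eigenvalue ",
         format(min(ev), digits = 4), ")")
  }
  sigma <- solve(omega)
  cov2cor(sigma)
}

#' Latent correlation matrix calibrated to the generator's targets
#'
#' For a `"latent"` target the matrix is returned as-is. For a
#' `"partial"` target the matrix of score-scale partial correlations is
#' first converted to a score-scale correlation matrix, then each pairwise
#' latent correlation is solved so that the population Pearson correlation
#' of the log involvement scores implied by the copula (computed from the
#' exact conditional score distributions by Gauss-Hermite quadrature and a
#' Hermite expansion) matches the target.
#'
#' @param config `generator_config`.
#' @return List with `R_latent`, `R_obs_target` (score-scale correlation
#'   target, `NULL` for latent targets) and `profiles` (per-substance
#'   score-scale summaries).
#' @export
calibrate_latent <- function(config) {
  subs <- config$substances
  p <- length(subs)
  profiles <- lapply(setNames(subs, subs),
                     function(s) score_scale_profile(s, config))
  if (config$target$type == "latent") {
    return(list(R_latent = config$target$matrix, R_obs_target = NULL,
                profiles = profiles))
  }
  R_obs <- partial_to_correlation(config$target$matrix)
  dimnames(R_obs) <- list(subs, subs)
  R_lat <- diag(p)
  dimnames(R_lat) <- list(subs, subs)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    r <- latent_cor_for_target(R_obs[i, j], profiles[[i]], profiles[[j]])
    R_lat[i, j] <- R_lat[j, i] <- r
  }
  ev <- eigen(R_lat, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) {
    stop("calibrated latent correlation matrix is not positive definite ",
         "(smallest eigenvalue ", format(min(ev), digits = 4), ")")
  }
  list(R_latent = R_lat, R_obs_target = R_obs, profiles = profiles)
}

# ---- covariates -----------------------------------------------------------

scale_params <- function() {
  list(phq9 = c(mean = 14, sd = 6.5, lo = 0, hi = 27),
       gad7 = c(mean = 10.5, sd = 5.5, lo = 0, hi = 21),
       rrs10 = c(mean = 27, sd = 7.5, lo = 10, hi = 40),
       psqi = c(mean = 9, sd = 4, lo = 0, hi = 21),
       cas = c(mean = 16, sd = 11, lo = 0, hi = 63),
       pq16 = c(mean = 6, sd = 4, lo = 0, hi = 16))
}

draw_covariates <- function(n) {
  age <- pmin(pmax(round(rnorm(n, 18.2, 2.9)), 12), 25)
  sex_at_birth <- sample(c("female", "male"), n, TRUE, c(0.65, 0.35))
  lgbtiqa <- sample(c("no", "yes"), n, TRUE, c(0.71, 0.29))
  region <- sample(c("metro", "regional"), n, TRUE, c(0.70, 0.30))
  edu_employment <- sample(c("studying_only", "working_only",
                             "studying_and_working", "neither"),
                           n, TRUE, c(0.55, 0.08, 0.22, 0.15))
  primary_diagnosis <- sample(c("depression", "anxiety",
                                "depression_and_anxiety", "other"),
                              n, TRUE, c(0.31, 0.26, 0.25, 0.18))
  f <- rnorm(n)  # shared internalising factor for the clinical scales
  sp <- scale_params()
  scales <- lapply(sp, function(pr) {
    raw <- pr[["mean"]] + pr[["sd"]] * (0.55 * f + sqrt(1 - 0.55^2) * rnorm(n))
    pmin(pmax(round(raw), pr[["lo"]]), pr[["hi"]])
  })
  data.frame(age = age, sex_at_birth = sex_at_birth, lgbtiqa = lgbtiqa,
             region = region, edu_employment = edu_employment,
             primary_diagnosis = primary_diagnosis, as.data.frame(scales))
}

#' Covariate design matrix used by the generator's group model
#'
#' Age is centred at 18 years; the six clinical scale totals enter as
#' z-scores (sample mean/sd). Column names match the names expected in
#' `covariate_effects`.
#'
#' @param cov Data frame of covariates.
#' @return Numeric matrix (no intercept column).
#' @export
covariate_design <- function(cov) {
  z <- function(x) (x - mean(x)) / ifelse(sd(x) > 0, sd(x), 1)
  cbind(
    age = cov$age - 18,
    sexmale = as.numeric(cov$sex_at_birth == "male"),
    lgbtyes = as.numeric(cov$lgbtiqa == "yes"),
    regionregional = as.numeric(cov$region == "regional"),
    eduworking_only = as.numeric(cov$edu_employment == "working_only"),
    edustudying_and_working =
      as.numeric(cov$edu_employment == "studying_and_working"),
    eduneither = as.numeric(cov$edu_employment == "neither"),
    diaganxiety = as.numeric(cov$primary_diagnosis == "anxiety"),
    diagdepression_and_anxiety =
      as.numeric(cov$primary_diagnosis == "depression_and_anxiety"),
    diagother = as.numeric(cov$primary_diagnosis == "other"),
    zphq9 = z(cov$phq9), zgad7 = z(cov$gad7), zrrs10 = z(cov$rrs10),
    zpsqi = z(cov$psqi), zcas = z(cov$cas), zpq16 = z(cov$pq16))
}

group_label_from_latents <- function(Z, c_use, substances) {
  used <- sweep(Z, 2, c_use, ">")
  colnames(used) <- substances
  ats <- used[, "ats"]
  can <- used[, "cannabis"]
  other <- rowSums(used[, setdiff(substances, c("ats", "cannabis")),
                        drop = FALSE]) > 0
  ifelse(ats, "ats",
         ifelse(can, "cannabis_no_ats",
                ifelse(other, "alcohol_tobacco_other", "none")))
}

calibrate_intercepts <- function(eta, pi0, maxit = 200, tol = 1e-10) {
  # eta: n x G matrix of covariate linear predictors (reference "none"
  # has no column); pi0: target marginal probabilities incl. none (first)
  G <- ncol(eta)
  a <- log(pi0[-1] / pi0[1])
  for (it in seq_len(maxit)) {
    lp <- cbind(0, sweep(eta, 2, a, "+"))
    lp <- lp - apply(lp, 1, max)
    pr <- exp(lp) / rowSums(exp(lp))
    pbar <- colMeans(pr)
    adj <- log(pi0[-1] / pbar[-1])
    a <- a + adj
    if (max(abs(adj)) < tol) break
  }
  a
}

# ---- generation -----------------------------------------------------------

#' Generate a synthetic cohort
#'
#' Draws covariates, assigns substance-use groups from a multinomial-logit
#' model with the configured covariate effects (intercepts calibrated to
#' the copula-implied group shares, so the marginal copula law of the
#' substance latents is preserved), matches each participant to a latent
#' vector drawn from the Gaussian copula conditional on their group, grades
#' ASSIST items from the latents and finally injects missingness.
#'
#' @param config `generator_config`, e.g. from [paper_like_config()].
#' @return Data frame of class `cohort`: `participant_id`, demographics,
#'   clinical scale totals and `<substance>_q2` ... `<substance>_q7` level
#'   strings (`tobacco_q5` is never administered and therefore absent).
#'   Attributes: `config`, `group` (generating group labels),
#'   `calibration` (latent correlation and score-scale targets),
#'   `config_hash`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  calib <- calibrate_latent(config)
  subs <- config$substances
  p <- length(subs)
  n <- config$n
  set.seed(config$seed)
  cov <- draw_covariates(n)
  c_use <- vapply(subs, function(s) calib$profiles[[s]]$cuts$c_use,
                  numeric(1))
  L <- chol(calib$R_latent)
  draw_pool <- function(size) {
    Z <- matrix(rnorm(size * p), size, p) %*% L
    colnames(Z) <- subs
    Z
  }
  if (is.null(config$covariate_effects)) {
    Z <- draw_pool(n)
    group <- group_label_from_latents(Z, c_use, subs)
  } else {
    pool <- draw_pool(max(8L * n, 8000L))
    pool_lab <- group_label_from_latents(pool, c_use, subs)
    pi0 <- prop.table(table(factor(pool_lab,
                                   levels = c("none", "alcohol_tobacco_other",
                                              "cannabis_no_ats", "ats"))))
    if (any(pi0 == 0)) {
      stop("copula-implied share of group '",
           names(pi0)[pi0 == 0][1], "' is zero; check prevalences")
    }
    X <- covariate_design(cov)
    eff <- config$covariate_effects
    groups_nz <- c("alcohol_tobacco_other", "cannabis_no_ats", "ats")
    eta <- vapply(groups_nz, function(g) {
      b <- eff[[g]]
      if (is.null(b)) return(numeric(nrow(X)))
      miss <- setdiff(names(b), colnames(X))
      if (length(miss)) stop("unknown covariate-effect term(s): ",
                             paste(miss, collapse = ", "))
      drop(X[, names(b), drop = FALSE] %*% b)
    }, numeric(n))
    a <- calibrate_intercepts(eta, as.numeric(pi0))
    lp <- cbind(0, sweep(eta, 2, a, "+"))
    lp <- lp - apply(lp, 1, max)
    pr <- exp(lp) / rowSums(exp(lp))
    group <- vapply(seq_len(n), function(i)
      c("none", groups_nz)[sample.int(4L, 1L, prob = pr[i, ])],
      character(1))
    # match participants to pool draws conditional on group
    Z <- matrix(NA_real_, n, p, dimnames = list(NULL, subs))
    for (g in unique(group)) {
      need <- which(group == g)
      avail <- which(pool_lab == g)
      tries <- 0
      while (length(avail) < length(need) && tries < 20) {
        extra <- draw_pool(4L * n)
        extra_lab <- group_label_from_latents(extra, c_use, subs)
        pool <- rbind(pool, extra)
        pool_lab <- c(pool_lab, extra_lab)
        avail <- which(pool_lab == g)
        tries <- tries + 1
      }
      if (length(avail) < length(need)) {
        stop("could not draw enough latent vectors for group '", g, "'")
      }
      Z[need, ] <- pool[avail[seq_along(need)], , drop = FALSE]
    }
  }
  # grade ASSIST items from the latents
  out <- data.frame(participant_id = seq_len(n))
  out <- cbind(out, cov)
  alpha <- config$harm_loading
  s_noise <- sqrt(1 - alpha^2)
  freq_all <- c("never", freq_levels_upper)
  for (s in subs) {
    cuts <- calib$profiles[[s]]$cuts
    z <- Z[, s]
    q2_lvl <- (z > cuts$c_use) + (z > cuts$q2_cuts[1]) +
      (z > cuts$q2_cuts[2]) + (z > cuts$q2_cuts[3])
    out[[paste0(s, "_q2")]] <- freq_all[q2_lvl + 1]
    items <- assist_items(s)
    map_item <- c(q3 = "urge", q4 = "problems", q5 = "failed_expect",
                  q6 = "concerns", q7 = "cutdown_fail")
    for (it in setdiff(items, "q2")) {
      H <- alpha * z + s_noise * rnorm(n)
      cutv <- cuts$harm[[map_item[[it]]]]
      if (it %in% c("q3", "q4", "q5")) {
        lvl <- (H > cutv[1]) + (H > cutv[2]) + (H > cutv[3]) + (H > cutv[4])
        out[[paste0(s, "_", it)]] <- freq_all[lvl + 1]
      } else {
        out[[paste0(s, "_", it)]] <-
          ifelse(H > cutv[["past"]], "yes_past_3mo",
                 ifelse(H > cutv[["any"]], "yes_not_past_3mo", "never"))
      }
    }
  }
  attr(out, "group") <- group
  if (config$missing_rate > 0) {
    miss_seed <- as.integer((as.numeric(config$seed) * 7919 + 13) %% 2147483647)
    out <- inject_missingness(out, config$missing_rate, seed = miss_seed,
                              unit = config$missing_unit)
  }
  attr(out, "config") <- config
  attr(out, "group") <- group
  attr(out, "calibration") <- list(R_latent = calib$R_latent,
                                   R_obs_target = calib$R_obs_target)
  attr(out, "config_hash") <- config_hash(config)
  class(out) <- c("cohort", "data.frame")
  out
}

#' Inject missing values completely at random
#'
#' With `unit = "cell"` every eligible cell (all columns except
#' `participant_id`) is independently set missing with probability `rate`.
#' With `unit = "assist_block"` each participant's entire block of ASSIST
#' item columns goes missing with probability `rate` (mirroring
#' questionnaire-section nonresponse) while other columns stay cell-level.
#'
#' @param table Cohort data frame.
#' @param rate Missingness proportion in \[0, 0.2\].
#' @param seed Integer seed.
#' @param unit `"cell"` or `"assist_block"`.
#' @return The table with `NA`s injected; attributes are preserved.
#' @export
inject_missingness <- function(table, rate, seed = 1L,
                               unit = c("cell", "assist_block")) {
  unit <- match.arg(unit)
  if (rate < 0 || rate > 0.2) stop("'rate' must be in [0, 0.2]")
  if (rate == 0) return(table)
  at <- attributes(table)
  set.seed(seed)
  cols <- setdiff(names(table), "participant_id")
  assist_cols <- grep("_q[2-7]$", cols, value = TRUE)
  n <- nrow(table)
  if (unit == "cell") {
    for (cl in cols) {
      table[[cl]][runif(n) < rate] <- NA
    }
  } else {
    block_out <- runif(n) < rate
    for (cl in assist_cols) table[[cl]][block_out] <- NA
    for (cl in setdiff(cols, assist_cols)) {
      table[[cl]][runif(n) < rate] <- NA
    }
  }
  for (a in setdiff(names(at), c("names", "row.names", "class"))) {
    attr(table, a) <- at[[a]]
  }
  table
}

#' Write / read a cohort CSV with a JSON sidecar
#'
#' The sidecar records the seed, configuration hash and generation
#' parameters so a written cohort can be traced to its generator call.
#'
#' @param cohort Cohort data frame.
#' @param path CSV path (sidecar written as `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "")
  cfg <- attr(cohort, "config")
  meta <- list(n = nrow(cohort),
               seed = if (!is.null(cfg)) cfg$seed else NA,
               config_hash = attr(cohort, "config_hash"),
               columns = names(cohort))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @param validate Check ASSIST level strings against the instrument?
#' @export
read_cohort <- function(path, validate = TRUE) {
  x <- read.csv(path, stringsAsFactors = FALSE,
                na.strings = c("", "NA"))
  if (validate) {
    for (cl in grep("_q[2-7]$", names(x), value = TRUE)) {
      item <- sub(".*_(q[2-7])$", "\\1", cl)
      lv <- assist_levels(item)
      bad <- !is.na(x[[cl]]) & !(x[[cl]] %in% lv)
      if (any(bad)) {
        stop("invalid level '", x[[cl]][which(bad)[1]], "' in column '",
             cl, "'")
      }
    }
  }
  class(x) <- c("cohort", "data.frame")
  x
}
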