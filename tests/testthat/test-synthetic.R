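binom_ci99 <- function(p, n) p + c(-1, 1) * qnorm(0.995) * sqrt(p * (1 - p) / n)

test_that("generation is deterministic given the configuration seed", {
  cfg <- paper_like_config(n = 150, seed = 77, missing_rate = 0.05)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c_ <- generate_cohort(paper_like_config(n = 150, seed = 78,
                                          missing_rate = 0.05))
  expect_false(identical(as.data.frame(a), as.data.frame(c_)))
})

test_that("an identity latent matrix yields near-zero tetrachorics", {
  cfg <- generator_config(n = 20000, seed = 5,
                          prevalence = setNames(rep(0.3, 10),
                                                assist_substances()),
                          target = list(type = "latent", matrix = diag(10)))
  coh <- generate_cohort(cfg)
  ind <- dichotomize_items(coh)
  for (pair in list(c("tobacco", "alcohol"), c("cannabis", "ats"),
                    c("sedatives", "opioids"))) {
    x <- ind[[paste0(pair[1], "_used")]]
    y <- ind[[paste0(pair[2], "_used")]]
    tab <- matrix(c(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y)),
                  2, 2, byrow = TRUE)
    expect_lt(abs(tetrachoric(tab)$r), 0.05)
  }
})

test_that("the copula reproduces a configured latent correlation", {
  R <- diag(10)
  R[1, 3] <- R[3, 1] <- 0.5  # tobacco-cannabis
  cfg <- generator_config(n = 20000, seed = 6,
                          prevalence = setNames(rep(0.3, 10),
                                                assist_substances()),
                          target = list(type = "latent", matrix = R))
  ind <- dichotomize_items(generate_cohort(cfg))
  x <- ind$tobacco_used; y <- ind$cannabis_used
  tab <- matrix(c(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y)),
                2, 2, byrow = TRUE)
  expect_lt(abs(tetrachoric(tab)$r - 0.5), 0.05)
})

test_that("use thresholds hit the target prevalence", {
  cfg <- generator_config(n = 10000, seed = 7,
                          prevalence = setNames(rep(0.3, 10),
                                                assist_substances()),
                          target = list(type = "latent", matrix = diag(10)))
  ind <- dichotomize_items(generate_cohort(cfg))
  ci <- binom_ci99(0.3, 10000)
  obs <- mean(ind$alcohol_used)
  expect_gt(obs, ci[1]); expect_lt(obs, ci[2])
})

test_that("paper-like preset prevalences land within 2 points of their targets", {
  cfg <- paper_like_config(n = 12000, seed = 8, missing_rate = 0,
                           covariate_effects = FALSE)
  ind <- dichotomize_items(generate_cohort(cfg))
  targets <- c(tobacco = 0.33, alcohol = 0.63, cannabis = 0.27,
               ats = 0.076, cocaine = 0.033)
  for (s in names(targets)) {
    expect_lt(abs(mean(ind[[paste0(s, "_used")]]) - targets[[s]]), 0.02)
  }
})

test_that("the calibrated latent matrix matches the score-scale targets", {
  cfg <- paper_like_config(n = 100, seed = 1, missing_rate = 0)
  cal <- calibrate_latent(cfg)
  # partials of the observed-scale target equal the requested partials
  expect_equal(-cov2cor(solve(cal$R_obs_target))["tobacco", "cannabis"],
               0.48, tolerance = 1e-8)
  expect_true(min(eigen(cal$R_latent, only.values = TRUE)$values) > 0)
  # latent correlations de-attenuate the observed targets
  expect_gt(cal$R_latent["tobacco", "cannabis"],
            cal$R_obs_target["tobacco", "cannabis"])
})

test_that("sample log-score correlations track the calibration target", {
  cfg <- paper_like_config(n = 20000, seed = 9, missing_rate = 0,
                           covariate_effects = FALSE)
  coh <- generate_cohort(cfg)
  cal <- attr(coh, "calibration")
  sc <- involvement_scores(coh)
  r_emp <- cor(sc$tobacco_logscore, sc$cannabis_logscore)
  expect_lt(abs(r_emp - cal$R_obs_target["tobacco", "cannabis"]), 0.03)
})

test_that("group labels are consistent with the generated ASSIST answers", {
  coh <- generate_cohort(paper_like_config(n = 800, seed = 10,
                                           missing_rate = 0))
  grp <- assign_group(dichotomize_items(coh))
  expect_equal(as.character(grp), attr(coh, "group"))
})

test_that("covariate effects reach the configured relative risks", {
  eff <- list(ats = c(regionregional = log(3)))
  cfg <- generator_config(
    n = 5000, seed = 11,
    prevalence = c(tobacco = 0.33, alcohol = 0.63, cannabis = 0.27,
                   cocaine = 0.033, ats = 0.076, inhalants = 0.02,
                   sedatives = 0.11, hallucinogens = 0.05, opioids = 0.036,
                   other = 0.03),
    target = list(type = "partial", matrix = paper_like_partials()),
    covariate_effects = eff)
  coh <- generate_cohort(cfg)
  grp <- factor(attr(coh, "group"),
                levels = c("none", "alcohol_tobacco_other",
                           "cannabis_no_ats", "ats"))
  d <- data.frame(grp = grp, region = factor(coh$region,
                                             levels = c("metro", "regional")))
  fit <- fit_multinomial(grp ~ region, d)
  expect_equal(exp(fit$coefficients["ats", "regionregional"]), 3,
               tolerance = 0.35)
})

test_that("a non-positive-definite latent matrix is rejected", {
  R <- matrix(0.9, 10, 10); diag(R) <- 1
  R[1, 2] <- R[2, 1] <- -0.9
  expect_error(generator_config(n = 100, target = list(type = "latent",
                                                       matrix = R)),
               "eigenvalue")
})

test_that("missingness injection is MCAR at the requested rate", {
  cfg <- generator_config(n = 2000, seed = 12,
                          prevalence = setNames(rep(0.3, 10),
                                                assist_substances()),
                          target = list(type = "latent", matrix = diag(10)))
  coh <- generate_cohort(cfg)
  expect_identical(inject_missingness(coh, 0, seed = 1), coh)
  dam <- inject_missingness(coh, 0.05, seed = 3)
  cells <- unlist(lapply(dam[setdiff(names(dam), "participant_id")], is.na))
  ci <- binom_ci99(0.05, length(cells))
  expect_gt(mean(cells), ci[1]); expect_lt(mean(cells), ci[2])
  dam2 <- inject_missingness(coh, 0.05, seed = 3)
  expect_identical(dam, dam2)
  expect_error(inject_missingness(coh, 0.5, seed = 1), "rate")
})

test_that("block missingness blanks whole ASSIST sections", {
  coh <- generate_cohort(generator_config(
    n = 2000, seed = 13,
    prevalence = setNames(rep(0.3, 10), assist_substances()),
    target = list(type = "latent", matrix = diag(10))))
  dam <- inject_missingness(coh, 0.05, seed = 5, unit = "assist_block")
  assist_cols <- grep("_q[2-7]$", names(dam), value = TRUE)
  na_rows <- rowSums(is.na(dam[assist_cols]))
  expect_true(all(na_rows %in% c(0, length(assist_cols))))
  ci <- binom_ci99(0.05, nrow(dam))
  frac <- mean(na_rows > 0)
  expect_gt(frac, ci[1]); expect_lt(frac, ci[2])
})

test_that("cohorts round-trip through CSV with validation", {
  coh <- generate_cohort(paper_like_config(n = 60, seed = 14,
                                           missing_rate = 0.05))
  path <- file.path(tempdir(), "cohort-test.csv")
  write_cohort(coh, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_cohort(path)
  expect_equal(nrow(back), 60)
  expect_identical(back$cannabis_q2, coh$cannabis_q2)
  bad <- back
  bad$cannabis_q2[1] <- "often"
  bad_path <- file.path(tempdir(), "cohort-bad.csv")
  write.csv(bad, bad_path, row.names = FALSE, na = "")
  expect_error(read_cohort(bad_path), "often")
  unlink(c(path, paste0(path, ".json"), bad_path))
})
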