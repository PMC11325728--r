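test_that("sigmoid families hit their closed-form landmarks", {
  expect_equal(sigmoid("logistic", t = 59.3, A = 2.06, k = 0.06, Ti = 59.3),
               2.06 / 2)
  expect_equal(sigmoid("gompertz", t = 50, A = 2.06, k = 0.1, Ti = 50),
               2.06 / exp(1))
  # direct evaluation at published-magnitude parameters
  expect_equal(sigmoid("logistic", t = 98, A = 2.06, k = 0.06, Ti = 59.3),
               1.876006, tolerance = 1e-6)
  # overflow-safe far from the inflection
  expect_equal(sigmoid("logistic", t = 1e6, A = 2, k = 0.06, Ti = 59), 2)
  expect_equal(sigmoid("gompertz", t = -1e6, A = 2, k = 0.06, Ti = 59), 0)
  expect_equal(sigmoid("richards3p", t = 1e6, A = 2, k = 0.06, Ti = 59), 2)
})

test_that("noise-free logistic data is recovered to 1e-4 relative accuracy", {
  pars <- tibble::tibble(genotype = "G1", A = 1.5, k = 0.06, Ti = 55)
  rec <- simulate_growth_records(pars, n_reps = 2, noise_sd = 0,
                                 replicate_sd = 0, seed = 1)
  fit <- fit_growth(rec, model = "logistic", restarts = 1)
  expect_equal(fit$coefficients$A, 1.5, tolerance = 1e-4)
  expect_equal(fit$coefficients$Ti, 55, tolerance = 1e-4 * 55)
  expect_equal(fit$k, 0.06, tolerance = 1e-4 * 0.06)
})

test_that("the hierarchical fit recovers multi-genotype parameters and AIC/BIC identities", {
  pars <- dplyr::transmute(cotton_genotypes(), genotype, A = A_ch, k = k_ch,
                           Ti = Ti_ch)
  rec <- simulate_growth_records(pars, n_reps = 8, noise_sd = 0.05,
                                 replicate_sd = 0.05, seed = 77)
  fit <- fit_growth(rec, trait = "value", model = "logistic", restarts = 1)
  co <- dplyr::left_join(fit$coefficients, pars, by = "genotype")
  expect_lt(max(abs(co$A.x - co$A.y) / co$A.y), 0.05)
  expect_lt(max(abs(co$Ti.x - co$Ti.y)), 2.5)
  expect_lt(abs(fit$k - 0.06) / 0.06, 0.15)
  # replicate intercept variance is detected
  expect_gt(fit$sigma_u, 0.015)
  expect_lt(fit$sigma_u, 0.12)
  expect_equal(fit$sigma, 0.05, tolerance = 0.1)
  # information-criterion identities
  expect_equal(fit$AIC, -2 * fit$loglik + 2 * fit$n_params)
  expect_equal(fit$BIC, -2 * fit$loglik + log(fit$n_obs) * fit$n_params)
  # tidy/glance surface the same estimates
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "k"], fit$k)
  expect_equal(nrow(td), 2 * 11 + 1)
  expect_equal(glance(fit)$AIC, fit$AIC)
})

test_that("a zero replicate effect is estimated at (near) zero", {
  pars <- tibble::tibble(genotype = c("a", "b"), A = c(1.3, 1.9), k = 0.06,
                         Ti = c(52, 58))
  rec <- simulate_growth_records(pars, n_reps = 6, noise_sd = 0.05,
                                 replicate_sd = 0, seed = 5)
  fit <- fit_growth(rec, model = "logistic", restarts = 1)
  expect_lt(fit$sigma_u, 0.02)
})

test_that("model ranking prefers the generating family", {
  pars <- dplyr::transmute(cotton_genotypes(), genotype, A = A_ch, k = k_ch,
                           Ti = Ti_ch)
  rec <- simulate_growth_records(pars, n_reps = 8, noise_sd = 0.05,
                                 replicate_sd = 0, seed = 11)
  fits <- lapply(c("logistic", "gompertz", "richards3p"), function(m)
    fit_growth(rec, model = m, restarts = 1, se = FALSE))
  cmp <- compare_models(fits)
  expect_equal(cmp$model[1], "logistic")
  expect_equal(cmp$dAIC[1], 0)
  expect_true(all(cmp$dAIC >= 0))
  # equal parameter counts: flagged non-nested, no LRT p-values
  expect_false(any(cmp$nested_vs_best))
  expect_true(all(is.na(cmp$lrt_p[-1]) | !cmp$nested_vs_best[-1]))

  single <- compare_models(fits[[1]])
  expect_equal(nrow(single), 1)
  expect_equal(single$dAIC, 0)
})

test_that("post-hoc contrasts separate well-spaced tiers with letters", {
  # two tiers of asymptotes, far apart relative to the noise
  pars <- tibble::tibble(genotype = sprintf("G%d", 1:6),
                         A = c(1.0, 1.02, 1.01, 1.8, 1.82, 1.81),
                         k = 0.06, Ti = 55)
  rec <- simulate_growth_records(pars, n_reps = 6, noise_sd = 0.04,
                                 replicate_sd = 0, seed = 13)
  fit <- fit_growth(rec, model = "logistic", restarts = 1)
  ph <- posthoc_contrasts(fit, "A", "bonferroni")
  lt <- ph$letters
  low <- lt$letters[lt$genotype %in% c("G1", "G2", "G3")]
  high <- lt$letters[lt$genotype %in% c("G4", "G5", "G6")]
  expect_equal(length(unique(low)), 1)
  expect_equal(length(unique(high)), 1)
  expect_false(any(strsplit(low[1], "")[[1]] %in% strsplit(high[1], "")[[1]]))
  # tukey adjustment is available and monotone with bonferroni decisions here
  ph_t <- posthoc_contrasts(fit, "A", "tukey")
  expect_true(all(ph_t$contrasts$adj.p.value <= 1))

  tab <- genotype_parameter_table(fit)
  expect_equal(nrow(tab), 6)
  expect_true(all(c("A_letters", "Ti_letters") %in% names(tab)))
})

test_that("estimates ten standard errors apart are always significant", {
  pars <- tibble::tibble(genotype = c("a", "b"), A = c(1.0, 2.0), k = 0.06,
                         Ti = c(55, 55))
  rec <- simulate_growth_records(pars, n_reps = 6, noise_sd = 0.03,
                                 replicate_sd = 0, seed = 17)
  fit <- fit_growth(rec, model = "logistic", restarts = 1)
  ph <- posthoc_contrasts(fit, "A", "bonferroni")
  expect_lt(ph$contrasts$adj.p.value, 1e-6)
  expect_false(grepl(ph$letters$letters[1], ph$letters$letters[2], fixed = TRUE))
})

test_that("predictions follow the fitted curves", {
  pars <- tibble::tibble(genotype = "G1", A = 1.5, k = 0.06, Ti = 55)
  rec <- simulate_growth_records(pars, n_reps = 2, noise_sd = 0,
                                 replicate_sd = 0, seed = 1)
  fit <- fit_growth(rec, model = "logistic", restarts = 1)
  pr <- predict(fit, tibble::tibble(genotype = "G1", dap = c(55, 98)))
  expect_equal(pr$.pred[1], 0.75, tolerance = 1e-3)
})

test_that("the two-layer fit agrees with a reference NLME implementation", {
  pars <- tibble::tibble(genotype = c("a", "b", "c"), A = c(1.3, 1.6, 2.0),
                         k = 0.06, Ti = c(50, 55, 60))
  rec <- simulate_growth_records(pars, n_reps = 6, noise_sd = 0.05,
                                 replicate_sd = 0.04, seed = 3)
  fit <- fit_growth(rec, model = "logistic", restarts = 1)
  rec$genotype <- factor(rec$genotype)
  ref <- nlme::nlme(value ~ A / (1 + exp(-k * (dap - Ti))),
                    fixed = list(A ~ genotype - 1, Ti ~ genotype - 1, k ~ 1),
                    random = A ~ 1 | replicate, data = rec,
                    start = c(rep(1.5, 3), rep(55, 3), 0.06), method = "ML")
  fe <- nlme::fixef(ref)
  expect_equal(fit$coefficients$A, unname(fe[1:3]), tolerance = 0.005)
  expect_equal(fit$coefficients$Ti, unname(fe[4:6]), tolerance = 0.005)
  expect_equal(fit$k, unname(fe[7]), tolerance = 0.005)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-4)
})
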