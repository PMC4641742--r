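test_that("K computation applies the strict exclusion bounds", {
  r <- compute_k(c(10, 10, 10), c(10000, 4900, 20000))
  expect_equal(r$K, c(10, 4.9, 20))
  expect_identical(r$excluded, c(FALSE, TRUE, FALSE))  # bounds are strict
  expect_error(compute_k(-1, 100), class = "hz_domain_error")
  # scale consistency: weight doubles K, size^3 divides it
  expect_equal(compute_k(5, 2000)$K, 2 * compute_k(5, 1000)$K)
  expect_equal(compute_k(10, 1000)$K, compute_k(5, 1000)$K / 8)
})

make_k_data <- function(n, sd = 0.3, sp_eff = 0.6, quad = -0.05, seed = 1) {
  set.seed(seed)
  d <- data.frame(env = sample(c("ref", "dur"), n, TRUE),
                  sp = sample(c("Cn", "Pt"), n, TRUE),
                  size_cm = runif(n, 8, 20))
  s <- d$size_cm - median(d$size_cm)
  mu <- 10 + 0.1 * s + quad * s^2 + ifelse(d$sp == "Pt", -sp_eff, sp_eff) +
    ifelse(d$env == "dur", -1, 1) * 0.5
  d$K <- mu + rnorm(n, 0, sd)
  d
}

test_that("trait model selects a sensible degree and tests effects", {
  d <- make_k_data(1000, sd = 0.2, seed = 5)
  tf <- fit_trait_model(d, "K")
  expect_s3_class(tf, "trait_fit")
  expect_lt(tf$degree, 6)
  expect_equal(tf$aic_table$degree[which.min(tf$aic_table$AIC)], tf$degree)
  expect_identical(tf$degree, 2L)  # generative surface is quadratic
  # species effect is real and detected
  t3 <- tf$type3
  expect_lt(t3$p_value[t3$term == "sp"], 1e-6)

  # null species effect: estimate within 2 SE of zero
  d0 <- make_k_data(800, sp_eff = 0, seed = 6)
  tf0 <- fit_trait_model(d0, "K")
  co <- summary(tf0$fit)$coefficients
  sp_row <- grep("^sp1$", rownames(co))
  expect_lt(abs(co[sp_row, 1]), 2 * co[sp_row, 2])

  # duplicating every row leaves the fitted surface identical (the
  # orthogonal-poly basis rescales, so compare predictions, not raw coefs)
  tf2 <- fit_trait_model(rbind(d, d), "K")
  expect_identical(tf2$degree, tf$degree)
  grid <- expand.grid(env = c("ref", "dur"), sp = c("Cn", "Pt"),
                      size_cm = c(9, 13, 19))
  grid$size_c <- grid$size_cm - tf$center
  expect_equal(predict(tf2$fit, grid), predict(tf$fit, grid),
               tolerance = 1e-8)

  # empty env x sp cell is a named fit error
  dbad <- d[!(d$env == "dur" & d$sp == "Pt"), ]
  expect_error(fit_trait_model(dbad, "K"), "dur:Pt", class = "hz_fit_error")

  # B-spline basis variant fits too
  tb <- fit_trait_model(d, "K", degrees = 3, basis = "bs")
  expect_s3_class(tb$fit, "lm")
})

test_that("mixture prediction is linear in h with exact endpoints", {
  d <- make_k_data(400, seed = 7)
  tf <- fit_trait_model(d, "K", degrees = 2)
  nd <- data.frame(h = c(0, 1, 0.5), size_cm = 14, env = "ref")
  pr <- predict_hybrid_mixture(tf, nd)
  p_cn <- hybridzone:::.predict_as_species(tf, nd[1, ], "Cn")
  p_pt <- hybridzone:::.predict_as_species(tf, nd[1, ], "Pt")
  expect_equal(pr[1], p_cn)
  expect_equal(pr[2], p_pt)
  expect_equal(pr[3], (p_cn + p_pt) / 2)
  # linearity across arbitrary h (tolerance 1e-10)
  hh <- seq(0, 1, 0.1)
  ndh <- data.frame(h = hh, size_cm = 12.3, env = "dur")
  prh <- predict_hybrid_mixture(tf, ndh)
  expect_equal(prh, prh[1] + hh * (prh[11] - prh[1]), tolerance = 1e-10)
  expect_error(predict_hybrid_mixture(tf, data.frame(h = 0.5, size_cm = 14,
                                                     env = "unknown")),
               class = "hz_prediction_error")
})

test_that("deviation model recovers exact and null structures", {
  set.seed(8)
  # all-zero deviations: all coefficients zero, zero residual variance
  dev0 <- data.frame(D = rep(0, 40), env = rep(c("a", "d"), 20),
                     size_cm = runif(40, 8, 20), h = runif(40))
  f0 <- fit_deviation_model(dev0)
  expect_equal(unname(coef(f0$fit)), rep(0, length(coef(f0$fit))),
               tolerance = 1e-12)
  expect_lt(sum(residuals(f0$fit)^2), 1e-20)

  # D = 2 (h - 0.5) exactly: h coefficient 2, intercept -1
  devh <- data.frame(D = NA, env = "a", size_cm = runif(40, 8, 20),
                     h = runif(40))
  devh$D <- 2 * (devh$h - 0.5)
  fh <- fit_deviation_model(devh)
  expect_match(fh$notes, "env terms dropped", all = FALSE)
  co <- coef(fh$fit)
  expect_equal(unname(co["h"]), 2, tolerance = 1e-10)
  expect_equal(unname(co["(Intercept)"]), -1, tolerance = 1e-10)
  expect_equal(unname(co["size_c"]), 0, tolerance = 1e-10)
  expect_error(fit_deviation_model(devh[1, ]), class = "hz_config_error")
})

test_that("additive hybrids show no mean deviation; heterosis is recovered", {
  # additive synthetic hybrids: mean D within 2 SE of zero
  cfg <- sim_config(n_cn = 150, n_pt = 150, n_hybrid = 120,
                    heterosis_delta = 0, seed = 17)
  ds <- simulate_dataset(cfg)
  cov <- ds$covariates
  cov$K <- compute_k(cov$size_cm, cov$weight_mg)$K
  cov$grp <- ds$truth$species_true
  pure <- cov[cov$grp != "Hybrid", ]
  tf <- fit_trait_model(data.frame(K = pure$K, env = pure$zone, sp = pure$grp,
                                   size_cm = pure$size_cm), "K")
  hyb <- cov[cov$grp == "Hybrid", ]
  dev <- hybrid_deviation(tf, data.frame(id = hyb$id, K = hyb$K,
                                         h = ds$truth$h_true[cov$grp == "Hybrid"],
                                         size_cm = hyb$size_cm, env = hyb$zone))
  se <- sd(dev$D) / sqrt(nrow(dev))
  expect_lt(abs(mean(dev$D)), 3 * se)

  # heterosis_delta = 1.5 shows up in the deviation-model intercept
  cfg2 <- sim_config(n_cn = 150, n_pt = 150, n_hybrid = 150,
                     heterosis_delta = 1.5, seed = 18)
  ds2 <- simulate_dataset(cfg2)
  cov2 <- ds2$covariates
  cov2$K <- compute_k(cov2$size_cm, cov2$weight_mg)$K
  cov2$grp <- ds2$truth$species_true
  p2 <- cov2[cov2$grp != "Hybrid", ]
  tf2 <- fit_trait_model(data.frame(K = p2$K, env = p2$zone, sp = p2$grp,
                                    size_cm = p2$size_cm), "K")
  h2 <- cov2[cov2$grp == "Hybrid", ]
  dev2 <- hybrid_deviation(tf2, data.frame(id = h2$id, K = h2$K,
                                           h = ds2$truth$h_true[cov2$grp == "Hybrid"],
                                           size_cm = h2$size_cm, env = h2$zone))
  dm2 <- fit_deviation_model(dev2)
  expect_gt(unname(coef(dm2$fit)["(Intercept)"]), 0.9)
  expect_lt(unname(coef(dm2$fit)["(Intercept)"]), 2.1)
})

test_that("age-adjusted size comparison behaves across designs", {
  set.seed(9)
  n <- 300
  d <- data.frame(group = sample(c("Cn", "Pt"), n, TRUE),
                  env = sample(c("ref", "dur"), n, TRUE),
                  age = sample(1:6, n, TRUE))
  d$size_cm <- 8 + 2 * d$age + rnorm(n, 0, 1)  # no group or env effect
  r <- size_age_comparison(d)
  expect_true(all(abs(r$contrasts$delta_size) < 3 * r$contrasts$se))

  # a known environment effect is recovered (first env level is reference)
  d2 <- d
  d2$size_cm <- d2$size_cm + ifelse(d2$env == "dur", -2.5, 0)
  d2$env <- factor(d2$env, levels = c("ref", "dur"))
  r2 <- size_age_comparison(d2)
  expect_equal(mean(r2$contrasts$delta_size), -2.5, tolerance = 0.5)
  expect_lt(max(r2$contrasts$p_value), 0.001)

  # age perfectly confounded with group: rank-deficiency error
  d3 <- data.frame(group = rep(c("Cn", "Pt"), each = 20),
                   env = "ref", age = rep(c(2, 5), each = 20))
  d3$size_cm <- rnorm(40, 12)
  expect_error(size_age_comparison(d3), class = "hz_fit_error")

  # missing ages are counted, excluded stations honoured
  d4 <- d; d4$age[1:5] <- NA; d4$station <- rep(c("s1", "s2"), 150)
  r4 <- size_age_comparison(d4, exclude_stations = "s2")
  expect_identical(r4$n_missing_age, sum(is.na(d4$age[d4$station == "s1"])))
})
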