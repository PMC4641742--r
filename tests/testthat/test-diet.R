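prey_groups <- c("diatom", rep("invertebrate", 7))

test_that("diet classification follows the detection-pattern rule", {
  row <- function(...) { v <- rep(0, 8); v[c(...)] <- 1; v }
  expect_identical(as.character(classify_diet(row(2), prey_groups)),
                   "invertebrate_eater")     # only Diptera
  expect_identical(as.character(classify_diet(row(1, 3), prey_groups)),
                   "omnivore")               # diatoms + Mollusca
  expect_identical(as.character(classify_diet(row(1), prey_groups)),
                   "diatom_eater")
  expect_identical(as.character(classify_diet(rep(0, 8), prey_groups)),
                   "no_detection")
  expect_error(classify_diet(c(rep(0, 7), 2), prey_groups),
               class = "hz_domain_error")

  # partition property over all 2^8 patterns
  pats <- as.matrix(expand.grid(rep(list(0:1), 8)))
  lab <- classify_diet(pats, prey_groups)
  expect_length(lab, 256)
  expect_false(anyNA(lab))
  expect_equal(sum(table(lab)), 256)
  expect_equal(unname(table(lab)["no_detection"]), 1)
  expect_equal(unname(table(lab)["diatom_eater"]), 1)       # item 1 only
  expect_equal(unname(table(lab)["invertebrate_eater"]), 127)
  expect_equal(unname(table(lab)["omnivore"]), 127)
})

test_that("feeding index separates archetypes and tracks diatoms", {
  # two archetypes repeated: axis 1 carries all inertia and separates them
  m <- rbind(matrix(rep(c(1, rep(0, 7)), 5), 5, byrow = TRUE),
             matrix(rep(c(0, 1, rep(0, 6)), 5), 5, byrow = TRUE))
  rownames(m) <- paste0("i", 1:10)
  fi <- feeding_index_pca(m, prey_groups)
  expect_equal(fi$inertia_frac, 1, tolerance = 1e-12)
  expect_true(all(fi$scores[1:5] > 0) && all(fi$scores[6:10] < 0))
  expect_equal(mean(fi$scores), 0, tolerance = 1e-12)
  expect_gte(fi$diatom_cor, 0)

  # duplicated dataset: identical scores (same centring)
  m2 <- rbind(m, m); rownames(m2) <- paste0("j", 1:20)
  fi2 <- feeding_index_pca(m2, prey_groups)
  expect_equal(unname(fi2$scores[1:10]), unname(fi$scores), tolerance = 1e-10)

  # all-zero rows are excluded and reported
  m3 <- rbind(m, zero = rep(0, 8))
  fi3 <- feeding_index_pca(m3, prey_groups)
  expect_identical(fi3$excluded_ids, "zero")
  expect_error(feeding_index_pca(matrix(0, 3, 8), prey_groups),
               class = "hz_estimation_error")

  # diatom <-> invertebrate trade-off gradient: strong diatom correlation
  set.seed(2)
  n <- 300
  grad <- runif(n)
  mm <- cbind(rbinom(n, 1, grad),
              sapply(1:7, function(j) rbinom(n, 1, 0.7 * (1 - grad))))
  rownames(mm) <- paste0("g", 1:n)
  fig <- feeding_index_pca(mm, prey_groups)
  expect_gte(abs(fig$diatom_cor), 0.9)
})

test_that("vacuity logistic model recovers coefficients and drops degenerates", {
  set.seed(3)
  n <- 1500
  d <- data.frame(h = runif(n), size_cm = runif(n, 8, 20),
                  season = sample(c("spring", "summer"), n, TRUE),
                  env = factor(sample(c("ref", "dur"), n, TRUE),
                               levels = c("ref", "dur")))
  # true model: intercept logit(0.7), h:env interaction +1.2
  eta <- qlogis(0.7) + 1.2 * d$h * (d$env == "dur")
  d$feces <- rbinom(n, 1, plogis(eta))
  vf <- fit_vacuity_model(d)
  co <- vf$coefficients
  expect_true(all(c("h", "season", "size_c", "env", "h:season", "h:size_c",
                    "h:env") %in% vf$lr_tests$term))
  i0 <- which(rownames(co) == "(Intercept)")
  expect_lt(abs(co$estimate[i0] - qlogis(0.7)), 2.5 * co$se[i0])
  ie <- grep("^h:env", rownames(co))
  expect_gt(co$estimate[ie], 0.8 - 2.5 * co$se[ie])
  expect_lt(co$estimate[ie], 1.6 + 2.5 * co$se[ie])

  # single-level season: dropped with a recorded note
  d1 <- d; d1$season <- "spring"
  vf1 <- fit_vacuity_model(d1)
  expect_match(vf1$notes, "season terms dropped", all = FALSE)
  expect_false(any(grepl("season", rownames(vf1$coefficients))))
})

test_that("logistic and multinomial fits match a numeric ML oracle", {
  set.seed(4)
  n <- 50
  d <- data.frame(h = runif(n), size_cm = runif(n, 8, 20),
                  season = sample(c("spring", "summer"), n, TRUE),
                  env = sample(c("ref", "dur"), n, TRUE))
  d$feces <- rbinom(n, 1, plogis(-0.3 + 0.8 * d$h))
  vf <- fit_vacuity_model(d)
  X <- model.matrix(vf$fit)
  b_oracle <- optim_logistic(X, d$feces)
  expect_equal(unname(coef(vf$fit)), b_oracle, tolerance = 1e-4)

  y <- factor(sample(c("omnivore", "invertebrate_eater", "diatom_eater"),
                     n, TRUE, prob = c(0.5, 0.2, 0.3)))
  y <- relevel(y, "omnivore")
  Xm <- cbind(1, scale(d$size_cm, scale = FALSE))
  colnames(Xm) <- c("(Intercept)", "size_c")
  fm <- mlogit_fit(Xm, y)
  Bo <- optim_mlogit(Xm, y)
  expect_equal(unname(fm$coefficients), unname(Bo), tolerance = 1e-4)
  # predicted probabilities sum to one
  expect_equal(rowSums(fm$fitted), rep(1, n), tolerance = 1e-9)
})

test_that("multinomial diet model recovers class structure and size sign", {
  # covariate-free class frequencies (0.1, 0.5, 0.4) via intercept-only fit
  set.seed(6)
  n <- 1000
  cls <- sample(c("invertebrate_eater", "omnivore", "diatom_eater"), n, TRUE,
                prob = c(0.1, 0.5, 0.4))
  d0 <- data.frame(diet_class = cls, season = "spring", env = "ref",
                   group = "Cn", size_cm = 13)
  dm0 <- fit_diet_multinomial(d0)
  ph <- colMeans(dm0$fit$fitted)
  expect_lt(abs(ph["omnivore"] - mean(cls == "omnivore")), 0.03)
  expect_lt(abs(ph["diatom_eater"] - mean(cls == "diatom_eater")), 0.03)

  # negative size effect for the diatom class is recovered
  d <- sim_diet_data(800, b_size = -0.4, seed = 7)
  dm <- fit_diet_multinomial(d)
  expect_lt(dm$fit$coefficients["size_c", "diatom_eater"], 0)
  expect_true("size_c" %in% dm$lr_tests$term)
  expect_lt(dm$lr_tests$p_value[dm$lr_tests$term == "size_c"], 0.01)
  # probability curves: small fish more diatom-eating than large fish
  pc <- dm$prob_curves
  expect_gt(pc$diatom_eater[1], pc$diatom_eater[nrow(pc)])
  expect_equal(unname(rowSums(pc[, -1])), rep(1, nrow(pc)), tolerance = 1e-9)
  # no_detection rows are excluded and counted
  d$diet_class[1:7] <- "no_detection"
  dm2 <- fit_diet_multinomial(d)
  expect_identical(dm2$n_excluded, 7L)
})

test_that("permuting class labels nulls the term tests", {
  # scaled down from the spec's 100 permutations for suite runtime
  d <- sim_diet_data(400, b_size = 0, seed = 8)
  set.seed(9)
  rej <- mean(replicate(60, {
    dp <- d
    dp$diet_class <- sample(dp$diet_class)
    f <- fit_diet_multinomial(dp)
    any(f$lr_tests$p_value[f$lr_tests$term == "env"] < 0.05)
  }))
  expect_lte(rej, 0.15)
})
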