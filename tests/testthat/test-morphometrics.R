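test_that("GPA aligns identical and transformed copies exactly", {
  # identical triangles: zero residuals, consensus equals the triangle shape
  lms <- make_lms(list(tri1(), tri1(), tri1()))
  g <- gpa_align(lms)
  expect_lt(max(g$residuals), 1e-10)
  # a rotated + translated copy aligns onto the original
  X <- tri1()
  lms2 <- make_lms(list(X, sim_transform(X, pi / 2, 1, c(5, -3))))
  g2 <- gpa_align(lms2)
  expect_lt(max(abs(g2$coords[, , 1] - g2$coords[, , 2])), 1e-10)
  # degenerate configuration errors with the specimen name
  bad <- make_lms(list(tri1(), matrix(1, 3, 2)), ids = c("ok", "flat"))
  expect_error(gpa_align(bad), "flat", class = "hz_alignment_error")
})

test_that("GPA output is invariant to similarity transforms of any input", {
  set.seed(4)
  base <- lapply(1:6, function(i) tri2() + matrix(rnorm(6, 0, 0.05), 3, 2))
  g0 <- gpa_align(make_lms(base))
  for (rep in 1:3) {
    tr <- base
    i <- sample(6, 1)
    tr[[i]] <- sim_transform(tr[[i]], runif(1, -pi, pi), runif(1, 0.2, 5),
                             runif(2, -100, 100))
    g1 <- gpa_align(make_lms(tr))
    expect_lt(max(abs(g1$coords - g0$coords)), 1e-9)
  }
  # invariants: centred, unit centroid size, 2k coordinates each
  for (i in 1:6) {
    A <- g0$coords[, , i]
    expect_lt(max(abs(colMeans(A))), 1e-9)
    expect_lt(abs(1 - sqrt(sum(A^2))), 1e-9)
  }
  # mean deviation from consensus is the zero configuration
  expect_lt(max(abs(apply(g0$coords, c(1, 2), mean) - g0$consensus)), 1e-7)
  # idempotence: realigning aligned shapes changes nothing
  g3 <- gpa_align(structure(list(coords = g0$coords, ids = g0$ids),
                            class = "landmark_set"))
  expect_lt(max(abs(g3$coords - g0$coords)), 1e-9)
})

test_that("pairwise rotation matches an angle-search oracle", {
  # independent oracle: brute-force the rotation angle minimising the
  # superimposition residual between the two centred, scaled triangles
  pre <- function(X) { X <- sweep(X, 2, colMeans(X)); X / sqrt(sum(X^2)) }
  A <- pre(tri1()); B <- pre(tri2())
  obj <- function(th) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sum((B %*% R - A)^2)
  }
  gr <- seq(-pi, pi, length.out = 20001)
  th0 <- gr[which.min(vapply(gr, obj, numeric(1)))]
  o <- optimize(obj, th0 + c(-0.01, 0.01))
  R_oracle <- matrix(c(cos(o$minimum), sin(o$minimum),
                       -sin(o$minimum), cos(o$minimum)), 2, 2)
  R_pkg <- hybridzone:::.procrustes_rotation(B, A)
  expect_equal(R_pkg, R_oracle, tolerance = 1e-6)
  expect_equal(det(R_pkg), 1, tolerance = 1e-12)
})

# small pure-species shape dataset via the simulator
shape_fixture <- function(seed = 5, n = 120, noise = 0.02) {
  cfg <- sim_config(n_cn = n, n_pt = n, n_hybrid = 0,
                    landmark_noise_sd = noise, seed = seed)
  ds <- simulate_dataset(cfg)
  g <- gpa_align(ds$landmarks)
  cov <- data.frame(id = ds$covariates$id, env = ds$covariates$zone,
                    sp = ds$truth$species_true,
                    size_cm = ds$covariates$size_cm)
  list(ds = ds, gpa = g, cov = cov)
}

test_that("constant shapes give intercept-only coordinate models", {
  set.seed(11)
  X <- hybridzone:::.landmark_template()
  mats <- replicate(40, X, simplify = FALSE)
  g <- gpa_align(make_lms(mats))
  cov <- data.frame(id = g$ids, env = rep(c("a", "b"), 20),
                    sp = rep(c("Cn", "Pt"), each = 20),
                    size_cm = runif(40, 8, 20))
  sf <- suppressWarnings(fit_shape_models(g, cov, degrees = 1))
  for (tf in sf$fits) {
    co <- coef(tf$fit)
    expect_lt(max(abs(co[-1])), 1e-9)
  }
})

test_that("deformation fields are antisymmetric and null on identity", {
  fx <- shape_fixture()
  sf <- fit_shape_models(fx$gpa, fx$cov, degrees = 1:2)
  condA <- list(env = "reference", sp = "Cn")
  condB <- list(env = "durance", sp = "Cn")
  # identity comparison: exact zero field, nothing flagged
  d0 <- deformation_between(sf, condA, condA)
  expect_true(all(abs(d0$coords$displacement) < 1e-12))
  expect_false(any(d0$landmarks$significant))
  # antisymmetry: swapping conditions negates every displacement
  dAB <- deformation_between(sf, condA, condB)
  dBA <- deformation_between(sf, condB, condA)
  expect_equal(dAB$coords$displacement, -dBA$coords$displacement,
               tolerance = 1e-12)
  # the simulated slendering (negative y-scale) deformation is detected
  expect_gt(sum(dAB$landmarks$significant), 0)
})

test_that("ontogenetic displacement tracks the generating allometry", {
  # linear allometric generative model: displacement between two sizes
  # should equal slope * delta_size within 2 SE on y-coordinates
  fx <- shape_fixture(seed = 6, n = 150, noise = 0.01)
  sf <- fit_shape_models(fx$gpa, fx$cov, degrees = 1)
  s1 <- 11; s2 <- 17
  dd <- deformation_between(sf, list(env = "reference", sp = "Cn", size = s1),
                            list(env = "reference", sp = "Cn", size = s2))
  # oracle: mean aligned shapes of reference Cn around the two sizes
  ids <- fx$cov$id[fx$cov$sp == "Cn" & fx$cov$env == "reference"]
  sz <- fx$cov$size_cm[match(ids, fx$cov$id)]
  near <- function(s) ids[abs(sz - s) < 2]
  m1 <- apply(fx$gpa$coords[, , fx$gpa$ids %in% near(s1), drop = FALSE],
              c(1, 2), mean)
  m2 <- apply(fx$gpa$coords[, , fx$gpa$ids %in% near(s2), drop = FALSE],
              c(1, 2), mean)
  emp <- as.vector(t(m2 - m1))
  expect_gt(cor(dd$coords$displacement, emp), 0.9)
})

test_that("hybrid shapes on the mixture line give zero deviations", {
  cfg <- sim_config(n_cn = 60, n_pt = 60, n_hybrid = 30,
                    landmark_noise_sd = 0, digitise = FALSE, seed = 8)
  ds <- simulate_dataset(cfg)
  g <- gpa_align(ds$landmarks)
  pure <- ds$truth$species_true != "Hybrid"
  gp <- structure(list(coords = g$coords[, , pure, drop = FALSE],
                       ids = g$ids[pure], n_landmarks = 21,
                       consensus = g$consensus,
                       centroid_size = g$centroid_size[pure],
                       residuals = g$residuals[pure],
                       iterations = g$iterations), class = "gpa")
  cov <- data.frame(id = ds$covariates$id, env = ds$covariates$zone,
                    sp = ds$truth$species_true,
                    size_cm = ds$covariates$size_cm)
  sf <- suppressWarnings(fit_shape_models(gp, cov[pure, ], degrees = 1))
  gh <- structure(list(coords = g$coords[, , !pure, drop = FALSE],
                       ids = g$ids[!pure]), class = "gpa")
  hcov <- data.frame(id = ds$covariates$id[!pure],
                     h = ds$truth$h_true[!pure],
                     size_cm = ds$covariates$size_cm[!pure],
                     env = ds$covariates$zone[!pure])
  hst <- suppressWarnings(hybrid_shape_test(sf, gh, hcov))
  # noise-free: GPA is near-linear over these small shape differences, so
  # deviations from the mixture prediction are numerically tiny
  expect_lt(max(abs(hst$coords$mean_D)), 1e-3)
  # h = 0 "hybrids": expectation equals the pure-Cn prediction exactly
  tf <- sf$fits[[1]]
  nd <- data.frame(h = 0, size_cm = 14, env = "reference")
  expect_equal(predict_hybrid_mixture(tf, nd),
               hybridzone:::.predict_as_species(tf, nd, "Cn"))
})

test_that("coordinate models at h in {0,1} match the deformation predictions", {
  fx <- shape_fixture(seed = 9, n = 60)
  sf <- fit_shape_models(fx$gpa, fx$cov, degrees = 1)
  nd0 <- data.frame(h = 0, size_cm = 14, env = "reference")
  nd1 <- data.frame(h = 1, size_cm = 14, env = "reference")
  for (j in c(1, 10, 42)) {
    tf <- sf$fits[[j]]
    expect_identical(predict_hybrid_mixture(tf, nd0),
                     hybridzone:::.predict_as_species(tf, nd0, "Cn"))
    expect_identical(predict_hybrid_mixture(tf, nd1),
                     hybridzone:::.predict_as_species(tf, nd1, "Pt"))
  }
})
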