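# Condition coefficient K, the species x environment x size trait model
# with AIC-selected basis degree and type-III tests, age-adjusted size
# comparisons, and the hybrid-additivity (h-mixture) deviation test.

#' Coefficient of condition K
#'
#' `K = weight (mg) / size (cm)^3`.  Values outside the strict bounds
#' `(5, 20)` are flagged as excluded (most likely weighing errors); boundary
#' values 5 and 20 are retained.
#'
#' @param size_cm,weight_mg positive numeric vectors.
#' @param id optional individual ids.
#' @return data.frame with columns `id`, `K`, `excluded`.
#' @export
compute_k <- function(size_cm, weight_mg, id = NULL) {
  .assert(all(size_cm > 0) && all(weight_mg > 0),
          "size and weight must be positive", "hz_domain_error")
  K <- weight_mg / size_cm^3
  data.frame(id = id %||% seq_along(K), K = K,
             excluded = K < 5 | K > 20, stringsAsFactors = FALSE)
}

#' Fit the environment x size-basis x species trait model
#'
#' Fits `response ~ env * basis(size - median, m) * sp` by least squares for
#' each candidate degree m, selecting m by AIC (Gaussian log-likelihood).
#' Size is centred on the dataset's own median so that simple effects are
#' interpreted at the median size.  Factors use sum-to-zero contrasts and
#' type-III tests are partial F-tests of each term against the model holding
#' all other terms.
#'
#' @param data data.frame with columns `env`, `sp`, `size_cm`, and the
#'   response.
#' @param response name of the response column.
#' @param degrees candidate basis degrees (subset of 1:5).
#' @param basis `"poly"` (orthogonal polynomial of degree m, the default
#'   reading) or `"bs"` (B-spline with m degrees of freedom).
#' @return an object of class `trait_fit`: the selected `lm` fit plus the
#'   AIC table, type-III table, centring constant and basis metadata.
#' @export
fit_trait_model <- function(data, response, degrees = 1:5,
                            basis = c("poly", "bs")) {
  basis <- match.arg(basis)
  .assert(all(degrees >= 1 & degrees < 6), "basis degree must be in 1..5",
          "hz_config_error")
  .assert(response %in% names(data), paste("no column", response),
          "hz_config_error")
  d <- data
  d$env <- droplevels(factor(d$env))
  d$sp <- droplevels(factor(d$sp))
  .assert(nlevels(d$sp) >= 1, "species column empty", "hz_config_error")
  center <- stats::median(d$size_cm)
  d$size_c <- d$size_cm - center
  # empty env x sp cells make the full interaction rank-deficient
  tab <- table(d$env, d$sp)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)
    stop(errorCondition(
      sprintf("empty design cell(s): %s",
              paste(rownames(tab)[empty[, 1]], colnames(tab)[empty[, 2]],
                    sep = ":", collapse = ", ")),
      class = c("hz_fit_error", "error", "condition")))
  }
  basis_term <- function(m) {
    if (basis == "poly") sprintf("poly(size_c, %d)", m)
    else sprintf("splines::bs(size_c, df = %d)", max(m, 3))
  }
  fits <- list(); aics <- numeric(length(degrees))
  ctr <- list(env = "contr.sum", sp = "contr.sum")
  if (nlevels(d$env) < 2) ctr$env <- NULL
  if (nlevels(d$sp) < 2) ctr$sp <- NULL
  for (k in seq_along(degrees)) {
    rhs <- basis_term(degrees[k])
    if (nlevels(d$env) >= 2) rhs <- paste0("env * ", rhs)
    if (nlevels(d$sp) >= 2) rhs <- paste0(rhs, " * sp")
    fo <- stats::as.formula(paste(response, "~", rhs))
    fits[[k]] <- stats::lm(fo, data = d, contrasts = ctr)
    aics[k] <- stats::AIC(fits[[k]])
  }
  sel <- which.min(aics)
  fit <- fits[[sel]]
  structure(list(fit = fit, response = response, degree = degrees[sel],
                 basis = basis, center = center,
                 aic_table = data.frame(degree = degrees, AIC = aics),
                 type3 = .type3_table(fit), data = d),
            class = "trait_fit")
}

#' @export
print.trait_fit <- function(x, ...) {
  cat(sprintf("Trait model for '%s': %s basis, degree %d (AIC-selected), n = %d\n",
              x$response, x$basis, x$degree, nrow(x$data)))
  cat("Type III tests:\n")
  print(x$type3, digits = 4)
  invisible(x)
}

# predict a trait_fit for given covariates and a forced species level
.predict_as_species <- function(tf, newdata, sp) {
  nd <- newdata
  nd$size_c <- nd$size_cm - tf$center
  if ("sp" %in% names(tf$fit$xlevels)) {
    .assert(sp %in% tf$fit$xlevels$sp,
            sprintf("species level '%s' not in fitted model", sp),
            "hz_prediction_error")
    nd$sp <- factor(sp, levels = tf$fit$xlevels$sp)
  }
  if ("env" %in% names(tf$fit$xlevels)) {
    bad <- setdiff(unique(as.character(nd$env)), tf$fit$xlevels$env)
    .assert(length(bad) == 0,
            paste("environment level(s) not in fitted model:",
                  paste(bad, collapse = ", ")), "hz_prediction_error")
    nd$env <- factor(as.character(nd$env), levels = tf$fit$xlevels$env)
  }
  unname(stats::predict(tf$fit, newdata = nd))
}

#' Hybrid trait prediction under the linear-mixture (additivity) null
#'
#' A hybrid with ancestry h is treated as a mixture of a P. toxostoma
#' specimen (proportion h) and a C. nasus specimen (proportion 1 - h) with
#' the same size and environment:
#' `prediction = h * fit(sp = Pt, ...) + (1 - h) * fit(sp = Cn, ...)`.
#'
#' @param tf a `trait_fit` from pure specimens.
#' @param newdata data.frame with `h`, `size_cm`, `env`.
#' @param sp_pt,sp_cn the species factor levels used in the fit.
#' @return numeric vector of mixture predictions.
#' @export
predict_hybrid_mixture <- function(tf, newdata, sp_pt = "Pt", sp_cn = "Cn") {
  stopifnot(inherits(tf, "trait_fit"))
  .assert(all(newdata$h >= 0 & newdata$h <= 1), "h must lie in [0, 1]",
          "hz_domain_error")
  p_pt <- .predict_as_species(tf, newdata, sp_pt)
  p_cn <- .predict_as_species(tf, newdata, sp_cn)
  newdata$h * p_pt + (1 - newdata$h) * p_cn
}

#' Per-hybrid deviation from the mixture prediction
#'
#' @param tf a `trait_fit` from pure specimens.
#' @param hybrids data.frame with the observed response column and `h`,
#'   `size_cm`, `env` (and optionally `id`).
#' @param common_support drop hybrids whose size lies outside the size range
#'   observed for *both* pure species (default TRUE).  The mixture
#'   prediction needs both species' surfaces at the hybrid's size; outside
#'   the common support one of them is a polynomial extrapolation, which
#'   contaminates the deviations.  The number of dropped hybrids is recorded
#'   in the `n_outside_support` attribute.
#' @return data.frame with `observed`, `predicted` and `D = observed -
#'   predicted` per hybrid, carrying the covariates through.
#' @export
hybrid_deviation <- function(tf, hybrids, common_support = TRUE) {
  n_out <- 0L
  if (common_support && "sp" %in% names(tf$data)) {
    lo <- max(tapply(tf$data$size_cm, tf$data$sp, min))
    hi <- min(tapply(tf$data$size_cm, tf$data$sp, max))
    inside <- hybrids$size_cm >= lo & hybrids$size_cm <= hi
    n_out <- sum(!inside)
    hybrids <- hybrids[inside, , drop = FALSE]
  }
  pred <- predict_hybrid_mixture(tf, hybrids)
  obs <- hybrids[[tf$response]]
  out <- data.frame(id = hybrids$id %||% seq_len(nrow(hybrids)),
                    env = hybrids$env, size_cm = hybrids$size_cm,
                    h = hybrids$h, observed = obs, predicted = pred,
                    D = obs - pred, stringsAsFactors = FALSE)
  attr(out, "n_outside_support") <- n_out
  out
}

#' Fit the deviation model D = env x size x h
#'
#' Least-squares fit of the hybrid deviations on the full interaction design.
#' With a single environment level the env terms are dropped, with a note
#' recorded in the result (never silently absorbed).
#'
#' @param dev data.frame from [hybrid_deviation()] (columns `D`, `env`,
#'   `size_cm`, `h`).
#' @return list with the `lm` fit, coefficient table, type-III table, the
#'   global F test (`statistic`, `df`, `p_value`), and `notes`.
#' @export
fit_deviation_model <- function(dev) {
  .assert(nrow(dev) >= 2, "need at least 2 hybrids", "hz_config_error")
  d <- dev
  d$env <- droplevels(factor(d$env))
  d$size_c <- d$size_cm - stats::median(d$size_cm)
  notes <- character(0)
  if (nlevels(d$env) < 2) {
    notes <- c(notes, "single environment level: env terms dropped")
    fo <- D ~ size_c * h
    ctr <- NULL
  } else {
    fo <- D ~ env * size_c * h
    ctr <- list(env = "contr.sum")
  }
  fit <- stats::lm(fo, data = d, contrasts = ctr)
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  fstat <- sm$fstatistic
  global <- if (is.null(fstat)) {
    list(statistic = NA_real_, df = c(NA, NA), p_value = NA_real_)
  } else {
    list(statistic = unname(fstat[1]), df = unname(fstat[2:3]),
         p_value = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  }
  coefs <- as.data.frame(sm$coefficients)
  names(coefs) <- c("estimate", "se", "t", "p_value")
  list(fit = fit, coefficients = coefs, type3 = .type3_table(fit),
       global_f = global, notes = notes)
}

#' Age-adjusted size comparison across genomic groups and environments
#'
#' ANCOVA `size ~ group * env + age` with sum-to-zero contrasts and type-III
#' tests; age is the adjustment covariate, so group-by-environment means are
#' evaluated at the overall mean age.
#'
#' @param data data.frame with `size_cm`, `group`, `env`, `age` (and
#'   optionally `station`).
#' @param exclude_stations stations to drop before fitting (the field
#'   practice of removing stations with known sampling artefacts).
#' @return list with the fit, type-III table, the adjusted-means table
#'   (`group`, `env`, `mean`, `se`), per-group environment contrasts vs the
#'   first env level, and the count of records dropped for missing age.
#' @export
size_age_comparison <- function(data, exclude_stations = NULL) {
  d <- data
  if (!is.null(exclude_stations) && "station" %in% names(d))
    d <- d[!d$station %in% exclude_stations, , drop = FALSE]
  n_missing_age <- sum(is.na(d$age))
  d <- d[!is.na(d$age), , drop = FALSE]
  d$group <- droplevels(factor(d$group))
  d$env <- droplevels(factor(d$env))
  .assert(nlevels(d$group) >= 2 && nlevels(d$env) >= 1,
          "need at least 2 groups", "hz_config_error")
  if (nlevels(d$env) < 2) {
    fit <- stats::lm(size_cm ~ group + age, data = d,
                     contrasts = list(group = "contr.sum"))
    .assert(all(!is.na(stats::coef(fit))),
            "rank-deficient design (confounded group/env/age)", "hz_fit_error")
    grid <- data.frame(group = levels(d$group), env = levels(d$env)[1])
    grid$age <- mean(d$age)
    X <- .design_rows(fit, grid)
    est <- vapply(seq_len(nrow(X)), function(i) .lincomb(fit, X[i, ]),
                  numeric(2))
    return(list(fit = fit, type3 = .type3_table(fit),
                adjusted_means = data.frame(grid[c("group", "env")],
                                            mean = est[1, ], se = est[2, ]),
                contrasts = NULL, n_missing_age = n_missing_age,
                notes = "single environment level: env terms dropped"))
  }
  notes <- character(0)
  tab <- table(d$group, d$env)
  if (any(tab == 0)) {
    # structural empty cell (e.g. no hybrids in reference populations):
    # the full interaction is inestimable, fall back to the additive model
    notes <- c(notes, "empty group:env cell(s): interaction dropped")
    fo <- size_cm ~ group + env + age
  } else {
    fo <- size_cm ~ group * env + age
  }
  fit <- stats::lm(fo, data = d,
                   contrasts = list(group = "contr.sum", env = "contr.sum"))
  .assert(all(!is.na(stats::coef(fit))),
          "rank-deficient design (confounded group/env/age)", "hz_fit_error")
  grid <- expand.grid(group = levels(d$group), env = levels(d$env))
  grid <- grid[tab[cbind(grid$group, grid$env)] > 0, , drop = FALSE]
  grid$age <- mean(d$age)
  X <- .design_rows(fit, grid)
  est <- vapply(seq_len(nrow(X)), function(i) .lincomb(fit, X[i, ]),
                numeric(2))
  means <- data.frame(grid[c("group", "env")], mean = est[1, ], se = est[2, ])
  # per-group environment effect vs the first env level
  ref_env <- levels(d$env)[1]
  contr <- list()
  for (g in levels(d$group)) for (e in setdiff(levels(d$env), ref_env)) {
    iA <- which(means$group == g & means$env == ref_env)
    iB <- which(means$group == g & means$env == e)
    if (length(iA) == 0 || length(iB) == 0) next
    cv <- X[iB, ] - X[iA, ]
    lc <- .lincomb(fit, cv)
    t <- lc["estimate"] / lc["se"]
    contr[[length(contr) + 1L]] <- data.frame(
      group = g, env = e, delta_size = unname(lc["estimate"]),
      se = unname(lc["se"]),
      p_value = 2 * stats::pt(-abs(t), fit$df.residual))
  }
  list(fit = fit, type3 = .type3_table(fit), adjusted_means = means,
       contrasts = do.call(rbind, contr), n_missing_age = n_missing_age,
       notes = notes)
}
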