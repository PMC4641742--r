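# Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Refit a fitted lm/glm on a reduced column set of its own design matrix.
# Returns RSS (lm) or deviance (glm) and residual df.
.refit_reduced <- function(fit, keep) {
  X <- stats::model.matrix(fit)
  y <- stats::model.response(stats::model.frame(fit))
  Xr <- X[, keep, drop = FALSE]
  if (inherits(fit, "glm")) {
    f <- suppressWarnings(stats::glm.fit(Xr, y, family = fit$family))
    list(stat = f$deviance, df = f$df.residual)
  } else {
    f <- stats::lm.fit(Xr, y)
    list(stat = sum(f$residuals^2), df = f$df.residual)
  }
}

# Type III tests: each term tested against the model containing all other
# terms.  Assumes the fit was made with sum-to-zero contrasts for factors;
# partial F for lm, likelihood-ratio chi-square for glm.
.type3_table <- function(fit) {
  tl <- attr(stats::terms(fit), "term.labels")
  X <- stats::model.matrix(fit)
  asgn <- attr(X, "assign")
  is_glm <- inherits(fit, "glm")
  if (is_glm) {
    dev_full <- fit$deviance
    df_full <- fit$df.residual
  } else {
    rss_full <- sum(stats::residuals(fit)^2)
    df_full <- fit$df.residual
  }
  rows <- lapply(seq_along(tl), function(i) {
    cols <- asgn != i
    df_i <- sum(asgn == i)
    red <- .refit_reduced(fit, cols)
    if (is_glm) {
      lr <- red$stat - dev_full
      data.frame(term = tl[i], df = df_i, statistic = lr,
                 p_value = stats::pchisq(lr, df_i, lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    } else {
      ssr <- red$stat - rss_full
      Fv <- (ssr / df_i) / (rss_full / df_full)
      data.frame(term = tl[i], df = df_i, statistic = Fv,
                 p_value = stats::pf(Fv, df_i, df_full, lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Design-matrix row(s) for new data on an existing lm fit, honouring
# stored predvars (poly/bs bases) and factor levels.
.design_rows <- function(fit, newdata) {
  tt <- stats::delete.response(stats::terms(fit))
  mf <- stats::model.frame(tt, newdata, xlev = fit$xlevels)
  stats::model.matrix(tt, mf, contrasts.arg = attr(stats::model.matrix(fit), "contrasts"))
}

# Linear combination c'beta with standard error from the fit's vcov.
.lincomb <- function(fit, cvec) {
  b <- stats::coef(fit)
  ok <- !is.na(b)
  est <- sum(cvec[ok] * b[ok])
  V <- stats::vcov(fit)
  se <- sqrt(drop(t(cvec[ok]) %*% V %*% cvec[ok]))
  c(estimate = est, se = se)
}

# Deterministic per-stage seed derived from a root seed (kept below 2^31).
.stage_seed <- function(seed, stage) {
  offs <- c(simulate = 101L, genetics = 211L, condition = 307L,
            morpho = 401L, diet = 503L, pipeline = 601L)
  as.integer((as.numeric(seed) * 1009 + offs[[stage]]) %% 2147483647)
}

.assert <- function(cond, msg, class = "hz_error") {
  if (!cond) stop(errorCondition(msg, class = c(class, "error", "condition")))
  invisible(TRUE)
}
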