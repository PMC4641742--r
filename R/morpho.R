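# Landmark-based geometric morphometrics: generalized Procrustes analysis,
# per-coordinate trait models, deformation fields between conditions, and
# the hybrid shape additivity test.

# Optimal rotation of X onto Y (both centred), proper rotation only
# (determinant +1; reflections corrected), from the SVD of the 2x2
# cross-covariance.
.procrustes_rotation <- function(X, Y) {
  C <- crossprod(X, Y)
  sv <- svd(C)
  s <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, s)) %*% t(sv$v)
}

#' Generalized Procrustes alignment
#'
#' Full Procrustes superimposition: each configuration is centred, scaled to
#' unit centroid size, and rotated to the running consensus by the
#' orthogonal-Procrustes solution (rotations only; reflections corrected);
#' the consensus is re-estimated and the procedure iterated to convergence.
#'
#' @param lms a `landmark_set`.
#' @param tol convergence tolerance on the consensus change.
#' @param max_iter iteration cap.
#' @return an object of class `gpa`: aligned coordinate array, `consensus`,
#'   pre-scaling `centroid_size`, per-specimen Procrustes `residuals`
#'   (root-sum-of-squares distance to consensus) and iteration count.
#' @export
gpa_align <- function(lms, tol = 1e-11, max_iter = 200L) {
  stopifnot(inherits(lms, "landmark_set"))
  n <- dim(lms$coords)[3]
  .assert(n >= 2, "need at least 2 configurations", "hz_config_error")
  k <- dim(lms$coords)[1]
  aligned <- array(NA_real_, dim(lms$coords), dimnames = dimnames(lms$coords))
  cs <- numeric(n)
  for (i in seq_len(n)) {
    X <- lms$coords[, , i]
    X <- sweep(X, 2, colMeans(X))
    cs[i] <- sqrt(sum(X^2))
    .assert(cs[i] > 0,
            sprintf("degenerate configuration '%s': all landmarks coincide",
                    lms$ids[i]), "hz_alignment_error")
    aligned[, , i] <- X / cs[i]
  }
  consensus <- aligned[, , 1]
  for (it in seq_len(max_iter)) {
    for (i in seq_len(n)) {
      R <- .procrustes_rotation(aligned[, , i], consensus)
      aligned[, , i] <- aligned[, , i] %*% R
    }
    # consensus is the plain mean of the aligned set (kept un-rescaled so
    # that aligned deviations from it average to exactly zero)
    new_cons <- apply(aligned, c(1, 2), mean)
    new_cons <- sweep(new_cons, 2, colMeans(new_cons))
    delta <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) break
  }
  # canonical orientation: rotate the whole set so the consensus lies on its
  # principal axes (proper rotation only), resolving the 180-degree ambiguity
  # by the sign of the consensus x at its most extreme landmark.  This makes
  # the output invariant to the orientation of the inputs.
  ev <- eigen(crossprod(consensus), symmetric = TRUE)$vectors
  if (det(ev) < 0) ev[, 2] <- -ev[, 2]
  rot <- function(M) M %*% ev
  cons_r <- rot(consensus)
  imax <- which.max(abs(cons_r[, 1]))
  if (cons_r[imax, 1] < 0) ev <- -ev  # 180-degree turn, still det +1
  consensus <- rot(consensus)
  for (i in seq_len(n)) aligned[, , i] <- rot(aligned[, , i])
  resid <- vapply(seq_len(n),
                  function(i) sqrt(sum((aligned[, , i] - consensus)^2)),
                  numeric(1))
  structure(list(coords = aligned, consensus = consensus, centroid_size = cs,
                 residuals = resid, iterations = it, ids = lms$ids,
                 n_landmarks = k),
            class = "gpa")
}

#' @export
print.gpa <- function(x, ...) {
  cat(sprintf("GPA alignment: %d specimens, %d landmarks, %d iterations\n",
              length(x$ids), x$n_landmarks, x$iterations))
  cat(sprintf("Procrustes residuals: median %.4g, max %.4g\n",
              stats::median(x$residuals), max(x$residuals)))
  invisible(x)
}

# flatten a gpa coordinate array to an n x 2k matrix (x1, y1, x2, y2, ...)
.flatten_shapes <- function(coords) {
  k <- dim(coords)[1]; n <- dim(coords)[3]
  out <- matrix(NA_real_, n, 2 * k)
  for (i in seq_len(n)) out[i, ] <- as.vector(t(coords[, , i]))
  colnames(out) <- paste0(rep(paste0("L", seq_len(k)), each = 2), c("_x", "_y"))
  rownames(out) <- dimnames(coords)[[3]]
  out
}

#' Per-coordinate trait models for aligned shapes
#'
#' Models each of the 2k aligned coordinates with the same
#' env x basis(size) x species construction used for the condition
#' coefficient (AIC-selected degree per coordinate); size acts as a
#' development surrogate, so size terms read as ontogenetic deformation.
#'
#' @param gpa a `gpa` object (pure specimens).
#' @param covariates data.frame with `id`, `env`, `sp`, `size_cm`, matched
#'   to the aligned specimens by `id`.
#' @param degrees candidate basis degrees.
#' @param basis passed to [fit_trait_model()].
#' @return an object of class `shape_fits`: list of `trait_fit`s (one per
#'   coordinate), the coordinate labels, and the pooled median size.
#' @export
fit_shape_models <- function(gpa, covariates, degrees = 1:5, basis = "poly") {
  stopifnot(inherits(gpa, "gpa"))
  Y <- .flatten_shapes(gpa$coords)
  m <- match(gpa$ids, covariates$id)
  .assert(!anyNA(m), "covariates missing for some aligned specimens",
          "hz_structure_error")
  cov <- covariates[m, , drop = FALSE]
  fits <- vector("list", ncol(Y))
  for (j in seq_len(ncol(Y))) {
    d <- data.frame(y = Y[, j], env = cov$env, sp = cov$sp,
                    size_cm = cov$size_cm)
    fits[[j]] <- tryCatch(
      fit_trait_model(d, "y", degrees = degrees, basis = basis),
      error = function(e) stop(errorCondition(
        sprintf("coordinate %s: %s", colnames(Y)[j], conditionMessage(e)),
        class = c("hz_fit_error", "error", "condition"))))
  }
  names(fits) <- colnames(Y)
  structure(list(fits = fits, coord_names = colnames(Y),
                 median_size = stats::median(cov$size_cm),
                 n_landmarks = gpa$n_landmarks),
            class = "shape_fits")
}

# condition spec -> one-row data.frame of covariates for prediction
.condition_row <- function(cond, default_size) {
  data.frame(env = cond$env, sp = cond$sp,
             size_cm = cond$size %||% default_size,
             stringsAsFactors = FALSE)
}

#' Deformation field between two conditions
#'
#' Per coordinate, the displacement is the difference of model predictions
#' between condition B and condition A at a common evaluation size (default:
#' pooled median); Wald tests of each per-coordinate contrast are adjusted
#' across the 2k coordinates and a landmark is flagged if either of its
#' coordinates is significant.
#'
#' @param sf a `shape_fits` object.
#' @param cond_a,cond_b named lists with `env`, `sp` and optionally `size`.
#' @param at_size evaluation size override for both conditions.
#' @param alpha significance level after adjustment.
#' @param p_adjust multiplicity method (see [stats::p.adjust()]).
#' @return a `deformation_field`: per-coordinate table (displacement, se,
#'   p, p_adj, significant) and a per-landmark table with `dx`, `dy`,
#'   `magnitude`, `significant`.
#' @export
deformation_between <- function(sf, cond_a, cond_b, at_size = NULL,
                                alpha = 0.05, p_adjust = "BH") {
  stopifnot(inherits(sf, "shape_fits"))
  size_a <- at_size %||% cond_a$size %||% sf$median_size
  size_b <- at_size %||% cond_b$size %||% sf$median_size
  rows <- lapply(seq_along(sf$fits), function(j) {
    tf <- sf$fits[[j]]
    nd_a <- .condition_row(c(cond_a, list(size = size_a)), sf$median_size)
    nd_b <- .condition_row(c(cond_b, list(size = size_b)), sf$median_size)
    nd_a$size_c <- nd_a$size_cm - tf$center
    nd_b$size_c <- nd_b$size_cm - tf$center
    for (v in c("env", "sp")) {
      lv <- tf$fit$xlevels[[v]]
      if (!is.null(lv)) {
        .assert(nd_a[[v]] %in% lv && nd_b[[v]] %in% lv,
                sprintf("condition level '%s'/'%s' not in fitted model",
                        nd_a[[v]], nd_b[[v]]), "hz_prediction_error")
        nd_a[[v]] <- factor(nd_a[[v]], levels = lv)
        nd_b[[v]] <- factor(nd_b[[v]], levels = lv)
      }
    }
    cv <- .design_rows(tf$fit, nd_b) - .design_rows(tf$fit, nd_a)
    lc <- .lincomb(tf$fit, drop(cv))
    t <- if (lc["se"] > 0) lc["estimate"] / lc["se"] else 0
    data.frame(coord = sf$coord_names[j],
               displacement = unname(lc["estimate"]), se = unname(lc["se"]),
               p = 2 * stats::pt(-abs(t), tf$fit$df.residual),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  # identical conditions: exact zero field, never flagged
  same <- isTRUE(all.equal(c(cond_a$env, cond_a$sp, size_a),
                           c(cond_b$env, cond_b$sp, size_b)))
  if (same) tab$p <- 1
  tab$p_adj <- stats::p.adjust(tab$p, method = p_adjust)
  tab$significant <- tab$p_adj < alpha
  k <- sf$n_landmarks
  lmk <- data.frame(landmark = paste0("L", seq_len(k)),
                    dx = tab$displacement[seq(1, 2 * k, 2)],
                    dy = tab$displacement[seq(2, 2 * k, 2)])
  lmk$magnitude <- sqrt(lmk$dx^2 + lmk$dy^2)
  lmk$significant <- tab$significant[seq(1, 2 * k, 2)] |
    tab$significant[seq(2, 2 * k, 2)]
  structure(list(coords = tab, landmarks = lmk,
                 cond_a = cond_a, cond_b = cond_b,
                 at_size = c(size_a, size_b)),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  cat("Deformation field:", sum(x$landmarks$significant), "of",
      nrow(x$landmarks), "landmarks significant\n")
  print(utils::head(x$landmarks[order(-x$landmarks$magnitude), ], 5),
        digits = 3)
  invisible(x)
}

#' Hybrid shape additivity test
#'
#' Per aligned coordinate, the expected hybrid value is the h-mixture of the
#' two pure-species model predictions at the hybrid's size and environment;
#' deviations `D = observed - expected` are modelled as
#' `D = env x size x h` and the per-coordinate deviation intercept tests are
#' adjusted across coordinates.
#'
#' @param sf a `shape_fits` from pure specimens.
#' @param gpa_hybrids a `gpa`-aligned set of hybrid shapes (aligned in the
#'   same GPA space as the pure specimens).
#' @param covariates data.frame with `id`, `h`, `size_cm`, `env` for the
#'   hybrids.
#' @param alpha,p_adjust multiplicity control across coordinates.
#' @return list: per-coordinate deviation table (`mean_D`, intercept test,
#'   adjusted p), the per-landmark observed-minus-expected mean displacement
#'   field, and the per-coordinate deviation-model fits.
#' @export
hybrid_shape_test <- function(sf, gpa_hybrids, covariates, alpha = 0.05,
                              p_adjust = "BH") {
  stopifnot(inherits(sf, "shape_fits"))
  Y <- .flatten_shapes(gpa_hybrids$coords)
  m <- match(rownames(Y), covariates$id)
  .assert(!anyNA(m), "hybrid covariates missing for some specimens",
          "hz_structure_error")
  cov <- covariates[m, , drop = FALSE]
  dev_fits <- vector("list", ncol(Y))
  rows <- lapply(seq_len(ncol(Y)), function(j) {
    tf <- sf$fits[[j]]
    nd <- data.frame(h = cov$h, size_cm = cov$size_cm, env = cov$env)
    expd <- predict_hybrid_mixture(tf, nd)
    D <- Y[, j] - expd
    dd <- data.frame(D = D, env = cov$env, size_cm = cov$size_cm, h = cov$h)
    dfit <- fit_deviation_model(dd)
    dev_fits[[j]] <<- dfit
    ic <- dfit$coefficients["(Intercept)", ]
    data.frame(coord = sf$coord_names[j], mean_D = mean(D),
               intercept = ic$estimate, se = ic$se, p = ic$p_value,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- stats::p.adjust(tab$p, method = p_adjust)
  tab$significant <- tab$p_adj < alpha
  k <- sf$n_landmarks
  lmk <- data.frame(landmark = paste0("L", seq_len(k)),
                    dx = tab$mean_D[seq(1, 2 * k, 2)],
                    dy = tab$mean_D[seq(2, 2 * k, 2)])
  lmk$magnitude <- sqrt(lmk$dx^2 + lmk$dy^2)
  lmk$significant <- tab$significant[seq(1, 2 * k, 2)] |
    tab$significant[seq(2, 2 * k, 2)]
  names(dev_fits) <- sf$coord_names
  list(coords = tab, landmarks = lmk, deviation_fits = dev_fits)
}
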