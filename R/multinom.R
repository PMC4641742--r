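# Baseline-category multinomial logistic regression, fitted by damped
# Newton-Raphson on the multinomial log-likelihood.  Written in-package
# because no multinomial fitter ships with the base/recommended stack; the
# test suite cross-checks it against a generic numeric optimiser.

# log-likelihood, score and Hessian of the baseline-logit model.
# B: p x (K-1) coefficient matrix (baseline category has all-zero column).
.mlogit_probs <- function(X, B) {
  eta <- X %*% B
  eta <- cbind(0, eta)                     # baseline first
  eta <- eta - apply(eta, 1, max)          # overflow guard
  E <- exp(eta)
  E / rowSums(E)
}

.mlogit_loglik <- function(X, Yi, B) {
  P <- .mlogit_probs(X, B)
  sum(log(P[cbind(seq_len(nrow(X)), Yi)]))
}

#' Fit a baseline-category multinomial logistic model
#'
#' Maximum likelihood by damped Newton-Raphson with analytic score and
#' Hessian.  The first level of `y` is the baseline category.
#'
#' @param X design matrix (n x p, including intercept).
#' @param y factor response with K >= 2 levels.
#' @param max_iter,tol Newton iteration controls.
#' @return object of class `mlogit_fit`: coefficient matrix
#'   (p x (K-1), columns named by non-baseline levels), `vcov` of the
#'   vectorised coefficients, `loglik`, `fitted` probabilities, and a
#'   `separation` flag (TRUE when coefficients diverge, reported with the
#'   offending term).
#' @export
mlogit_fit <- function(X, y, max_iter = 100L, tol = 1e-10) {
  y <- droplevels(factor(y))
  K <- nlevels(y)
  .assert(K >= 2, "need at least 2 response classes", "hz_config_error")
  n <- nrow(X); p <- ncol(X)
  Yi <- as.integer(y)                       # 1 = baseline
  Yind <- matrix(0, n, K - 1)
  for (k in 2:K) Yind[, k - 1] <- as.numeric(Yi == k)
  B <- matrix(0, p, K - 1)
  ll <- .mlogit_loglik(X, Yi, B)
  for (it in seq_len(max_iter)) {
    P <- .mlogit_probs(X, B)
    Pnb <- P[, -1, drop = FALSE]
    grad <- as.vector(crossprod(X, Yind - Pnb))
    H <- matrix(0, p * (K - 1), p * (K - 1))
    for (j in seq_len(K - 1)) for (k in seq_len(K - 1)) {
      w <- Pnb[, j] * ((j == k) - Pnb[, k])
      blk <- crossprod(X * w, X)
      ri <- (j - 1) * p + seq_len(p); ci <- (k - 1) * p + seq_len(p)
      H[ri, ci] <- -blk
    }
    step <- tryCatch(solve(H + diag(-1e-10, nrow(H)), -grad),
                     error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      Bn <- B + matrix(lambda * step, p, K - 1)
      lln <- .mlogit_loglik(X, Yi, Bn)
      if (lln >= ll - 1e-12 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    moved <- max(abs(Bn - B))
    B <- Bn
    if (abs(lln - ll) < tol && moved < 1e-8) { ll <- lln; break }
    ll <- lln
  }
  sep <- max(abs(B)) > 15
  sep_term <- if (sep) {
    w <- which(abs(B) == max(abs(B)), arr.ind = TRUE)[1, ]
    colnames(X)[w[1]]
  } else NA_character_
  P <- .mlogit_probs(X, B)
  Pnb <- P[, -1, drop = FALSE]
  H <- matrix(0, p * (K - 1), p * (K - 1))
  for (j in seq_len(K - 1)) for (k in seq_len(K - 1)) {
    w <- Pnb[, j] * ((j == k) - Pnb[, k])
    ri <- (j - 1) * p + seq_len(p); ci <- (k - 1) * p + seq_len(p)
    H[ri, ci] <- -crossprod(X * w, X)
  }
  V <- tryCatch(solve(-H), error = function(e) matrix(NA, nrow(H), ncol(H)))
  dimnames(B) <- list(colnames(X), levels(y)[-1])
  colnames(P) <- levels(y)
  structure(list(coefficients = B, vcov = V, loglik = ll, fitted = P,
                 levels = levels(y), separation = sep,
                 separation_term = sep_term, n = n, df = p * (K - 1)),
            class = "mlogit_fit")
}

#' @export
print.mlogit_fit <- function(x, ...) {
  cat(sprintf("Multinomial logit fit: %d obs, %d classes (baseline '%s'), logLik %.2f\n",
              x$n, length(x$levels), x$levels[1], x$loglik))
  print(x$coefficients, digits = 4)
  if (x$separation)
    cat("WARNING: quasi-separation suspected (term:", x$separation_term, ")\n")
  invisible(x)
}

#' Predicted class probabilities for a multinomial logit fit
#'
#' @param object an `mlogit_fit`.
#' @param newX design matrix with the same columns as used for fitting.
#' @param ... unused.
#' @return matrix of class probabilities (rows sum to 1).
#' @export
predict.mlogit_fit <- function(object, newX, ...) {
  P <- .mlogit_probs(newX, object$coefficients)
  colnames(P) <- object$levels
  P
}
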