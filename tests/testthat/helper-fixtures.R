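# Shared fixture builders (all data generated in code).

# a hand-built genotype table: panels + focal individuals
make_geno <- function(a1, a2, pop, loci = colnames(a1)) {
  ids <- rownames(a1) %||% sprintf("i%02d", seq_len(nrow(a1)))
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  structure(list(a1 = a1, a2 = a2, ids = ids, loci = loci, pop = pop),
            class = "genotype_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fully diagnostic two-species frequency profile over n loci
diagnostic_freqs <- function(n_loci = 4) {
  loci <- lapply(seq_len(n_loci), function(i)
    list(cn = c("001" = 1, "002" = 0), pt = c("001" = 0, "002" = 1)))
  names(loci) <- paste0("L", seq_len(n_loci))
  structure(list(loci = loci), class = "allele_freqs")
}

# landmark_set from a list of k x 2 matrices
make_lms <- function(mats, ids = sprintf("s%02d", seq_along(mats))) {
  k <- nrow(mats[[1]])
  coords <- array(NA_real_, c(k, 2, length(mats)),
                  dimnames = list(paste0("L", 1:k), c("x", "y"), ids))
  for (i in seq_along(mats)) coords[, , i] <- mats[[i]]
  structure(list(coords = coords, ids = ids), class = "landmark_set")
}

tri1 <- function() matrix(c(0, 0, 1, 0, 0, 1), ncol = 2, byrow = TRUE)
tri2 <- function() matrix(c(0, 0, 2, 0.2, -0.2, 1.8), ncol = 2, byrow = TRUE)

# random similarity transform of a configuration
sim_transform <- function(X, theta, scale, shift) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(scale * (X %*% R), 2, shift, `+`)
}

# numeric ML oracle: direct optimisation of a written log-likelihood
optim_logistic <- function(X, y) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))$par
}

# class data from a known baseline-logit diet model (omnivore baseline;
# diatom class favoured at small size when b_size < 0)
sim_diet_data <- function(n, b_size = -0.4, seed = 1) {
  set.seed(seed)
  d <- data.frame(season = sample(c("spring", "summer"), n, TRUE),
                  env = sample(c("ref", "dur"), n, TRUE),
                  group = sample(c("Cn", "Pt"), n, TRUE),
                  size_cm = runif(n, 8, 20))
  s <- d$size_cm - median(d$size_cm)
  eta_inv <- -1 + 0.2 * (d$env == "ref")
  eta_dia <- -0.3 + b_size * s
  den <- 1 + exp(eta_inv) + exp(eta_dia)
  p <- cbind(1 / den, exp(eta_inv) / den, exp(eta_dia) / den)
  cls <- apply(p, 1, function(pr) sample(c("omnivore", "invertebrate_eater",
                                           "diatom_eater"), 1, prob = pr))
  d$diet_class <- cls
  d
}

optim_mlogit <- function(X, y) {
  y <- droplevels(factor(y))
  K <- nlevels(y); p <- ncol(X)
  Yi <- as.integer(y)
  nll <- function(b) {
    B <- matrix(b, p, K - 1)
    eta <- cbind(0, X %*% B)
    -sum(eta[cbind(seq_len(nrow(X)), Yi)] - log(rowSums(exp(eta))))
  }
  matrix(stats::optim(rep(0, p * (K - 1)), nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))$par,
         p, K - 1)
}
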