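# Feces-based diet analysis: the feeding-activity (gut vacuity) logistic
# model, the prey-composition feeding index (PCA axis 1), the three-way diet
# classification rule, and the multinomial diet model.

#' Classify diet from a prey-detection pattern
#'
#' Deterministic rule on the 8-item binary detection row: only diatom-group
#' items detected -> `diatom_eater`; only invertebrate-group items ->
#' `invertebrate_eater`; both -> `omnivore`; none -> `no_detection`.
#'
#' @param prey binary matrix (individuals x items) or a single row vector.
#' @param groups character vector assigning each item to `"diatom"` or
#'   `"invertebrate"`; defaults to the matrix's `groups` attribute, else
#'   item 1 diatom and the rest invertebrate.
#' @return factor of diet classes, one per row.
#' @export
classify_diet <- function(prey, groups = NULL) {
  if (is.null(dim(prey))) prey <- matrix(prey, nrow = 1)
  groups <- groups %||% attr(prey, "groups") %||%
    c("diatom", rep("invertebrate", ncol(prey) - 1))
  .assert(length(groups) == ncol(prey) &&
            all(groups %in% c("diatom", "invertebrate")),
          "groups must map every item to diatom or invertebrate",
          "hz_config_error")
  .assert(all(prey %in% c(0, 1)), "prey entries must be 0/1", "hz_domain_error")
  has_dia <- rowSums(prey[, groups == "diatom", drop = FALSE]) > 0
  has_inv <- rowSums(prey[, groups == "invertebrate", drop = FALSE]) > 0
  lab <- ifelse(has_dia & has_inv, "omnivore",
         ifelse(has_dia, "diatom_eater",
         ifelse(has_inv, "invertebrate_eater", "no_detection")))
  factor(lab, levels = c("omnivore", "invertebrate_eater", "diatom_eater",
                         "no_detection"))
}

#' Feeding index: first principal axis of the prey-composition PCA
#'
#' Rows are normalised to composition vectors (detections divided by the
#' row total; all-zero rows are excluded and reported), then a centred,
#' unscaled PCA is taken and the first-axis scores returned.  The axis sign
#' is fixed so that its correlation with the diatom proportion is
#' non-negative.
#'
#' @param prey binary detection matrix with item columns.
#' @param groups item-group map as in [classify_diet()].
#' @return list with `scores` (named by individual), `inertia_frac`
#'   (fraction of total inertia on axis 1), `diatom_cor`, `excluded_ids`,
#'   and the `rotation` vector.
#' @export
feeding_index_pca <- function(prey, groups = NULL) {
  groups <- groups %||% attr(prey, "groups") %||%
    c("diatom", rep("invertebrate", ncol(prey) - 1))
  tot <- rowSums(prey)
  keep <- tot > 0
  .assert(sum(keep) >= 2, "need at least 2 individuals with detections",
          "hz_estimation_error")
  comp <- prey[keep, , drop = FALSE] / tot[keep]
  pc <- stats::prcomp(comp, center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1]
  dia_prop <- rowSums(comp[, groups == "diatom", drop = FALSE])
  r <- suppressWarnings(stats::cor(scores, dia_prop))
  if (!is.na(r) && r < 0) { scores <- -scores; pc$rotation[, 1] <- -pc$rotation[, 1]; r <- -r }
  list(scores = scores,
       inertia_frac = pc$sdev[1]^2 / sum(pc$sdev^2),
       diatom_cor = r,
       excluded_ids = rownames(prey)[!keep] %||% which(!keep),
       rotation = pc$rotation[, 1])
}

#' Feeding-activity (gut vacuity) logistic model
#'
#' Fits `logit(P(feces present)) = h * (season + size + env)` by maximum
#' likelihood: main effects of h, season, size and environment plus the
#' h:season, h:size and h:env interactions.  Degenerate single-level factors
#' are dropped with a recorded note; likelihood-ratio tests are computed per
#' term against the model holding all other terms.
#'
#' @param data data.frame with `feces` (0/1), `h`, `size_cm`, `season`,
#'   `env`.
#' @return list with the `glm` fit, coefficient table, per-term LR table,
#'   `notes`, and a `separation` flag naming the offending term if complete
#'   separation is suspected.
#' @export
fit_vacuity_model <- function(data) {
  d <- data
  .assert(all(d$feces %in% c(0, 1)), "feces must be 0/1", "hz_domain_error")
  .assert(length(unique(d$feces)) == 2, "response is constant",
          "hz_config_error")
  d$season <- droplevels(factor(d$season))
  d$env <- droplevels(factor(d$env))
  d$size_c <- d$size_cm - stats::median(d$size_cm)
  notes <- character(0)
  parts <- c("season", "size_c", "env")
  if (nlevels(d$season) < 2) {
    parts <- setdiff(parts, "season")
    notes <- c(notes, "single season level: season terms dropped")
  }
  if (nlevels(d$env) < 2) {
    parts <- setdiff(parts, "env")
    notes <- c(notes, "single environment level: env terms dropped")
  }
  fo <- stats::as.formula(paste("feces ~ h * (", paste(parts, collapse = " + "), ")"))
  fit <- withCallingHandlers(
    stats::glm(fo, family = stats::binomial(), data = d),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  sep <- max(abs(co[, 1])) > 15
  sep_term <- if (sep) rownames(co)[which.max(abs(co[, 1]))] else NA_character_
  coefs <- as.data.frame(co)
  names(coefs) <- c("estimate", "se", "z", "p_value")
  list(fit = fit, coefficients = coefs, lr_tests = .type3_table(fit),
       notes = notes, separation = sep, separation_term = sep_term)
}

#' Multinomial diet model
#'
#' Baseline-logit model of the three diet classes (baseline: omnivore, the
#' modal class) on season, environment, group and size; `no_detection` rows
#' are excluded and counted.  Per-term likelihood-ratio chi-square tests are
#' computed by refitting without each term's columns, and predicted
#' class-probability curves against size are returned for plotting.
#'
#' @param data data.frame with `diet_class`, `season`, `env`, `group`,
#'   `size_cm`.
#' @param baseline baseline category (default `"omnivore"`).
#' @param size_grid sizes (cm) at which to evaluate the probability curves.
#' @return list with the `mlogit_fit`, the per-term LR table, `n_excluded`
#'   (no_detection rows), and `prob_curves` (data.frame over `size_grid` at
#'   reference factor levels).
#' @export
fit_diet_multinomial <- function(data, baseline = "omnivore",
                                 size_grid = NULL) {
  d <- data[data$diet_class != "no_detection", , drop = FALSE]
  n_excluded <- nrow(data) - nrow(d)
  d$diet_class <- droplevels(factor(as.character(d$diet_class)))
  .assert(nlevels(d$diet_class) >= 2, "need at least 2 diet classes",
          "hz_config_error")
  if (baseline %in% levels(d$diet_class))
    d$diet_class <- stats::relevel(d$diet_class, baseline)
  d$season <- droplevels(factor(d$season))
  d$env <- droplevels(factor(d$env))
  d$group <- droplevels(factor(d$group))
  d$size_c <- d$size_cm - stats::median(d$size_cm)
  parts <- c("season", "env", "group")[c(nlevels(d$season) > 1,
                                         nlevels(d$env) > 1,
                                         nlevels(d$group) > 1)]
  fo <- stats::as.formula(paste("~", paste(c(parts, "size_c"), collapse = " + ")))
  mf <- stats::model.frame(fo, d)
  X <- stats::model.matrix(fo, mf)
  fit <- mlogit_fit(X, d$diet_class)
  # per-term LR tests
  asgn <- attr(X, "assign")
  tl <- attr(stats::terms(fo), "term.labels")
  lr <- lapply(seq_along(tl), function(i) {
    Xr <- X[, asgn != i, drop = FALSE]
    fr <- mlogit_fit(Xr, d$diet_class)
    df <- (ncol(X) - ncol(Xr)) * (nlevels(d$diet_class) - 1)
    chi <- 2 * (fit$loglik - fr$loglik)
    data.frame(term = tl[i], df = df, chisq = chi,
               p_value = stats::pchisq(chi, df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  # probability-vs-size curves at reference factor levels
  size_grid <- size_grid %||%
    seq(min(d$size_cm), max(d$size_cm), length.out = 50)
  nd <- d[rep(1, length(size_grid)), , drop = FALSE]
  for (v in parts) nd[[v]] <- factor(levels(d[[v]])[1], levels = levels(d[[v]]))
  nd$size_c <- size_grid - stats::median(d$size_cm)
  Xg <- stats::model.matrix(fo, stats::model.frame(fo, nd))
  Pg <- predict(fit, Xg)
  curves <- data.frame(size_cm = size_grid, Pg, check.names = FALSE)
  list(fit = fit, lr_tests = do.call(rbind, lr), n_excluded = n_excluded,
       prob_curves = curves, baseline = levels(d$diet_class)[1])
}
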