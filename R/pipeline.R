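# End-to-end orchestration: simulate -> genetics -> condition ->
# morphometrics -> diet, with input validation, stage toggles, delimited
# outputs and a consolidated report.

#' Pipeline run configuration
#'
#' @param out_dir output directory.
#' @param sim a [sim_config()] to generate inputs, or NULL to read them from
#'   `paths`.
#' @param paths named list of input files (`genotypes`, `covariates`,
#'   `mtdna`, `landmarks`, `prey`) when not simulating.
#' @param ref_cn,ref_pt reference population labels for the two species.
#' @param t_low,t_high genomic class thresholds.
#' @param alpha,p_adjust significance level and multiplicity method.
#' @param stages character subset of
#'   `c("genetics", "condition", "morpho", "diet")`.
#' @param seed root seed; all stage seeds derive from it.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, sim = NULL, paths = NULL,
                       ref_cn = "ref_cn", ref_pt = "ref_pt",
                       t_low = 0.086, t_high = 0.934,
                       alpha = 0.05, p_adjust = "BH",
                       stages = c("genetics", "condition", "morpho", "diet"),
                       seed = 1L) {
  .assert(t_low > 0 && t_low < t_high && t_high < 1,
          "thresholds must satisfy 0 < t_low < t_high < 1", "hz_config_error")
  .assert(!is.null(sim) || !is.null(paths),
          "either a simulation config or input paths are required",
          "hz_config_error")
  structure(list(out_dir = out_dir, sim = sim, paths = paths,
                 ref_cn = ref_cn, ref_pt = ref_pt, t_low = t_low,
                 t_high = t_high, alpha = alpha, p_adjust = p_adjust,
                 stages = stages, seed = as.integer(seed)),
            class = "run_config")
}

#' Validate linked input tables
#'
#' Checks id uniqueness and cross-table linkage, unit sanity (size in a
#' plausible cm range; weights that give K far below the 5-20 operating
#' range are flagged as probable grams), landmark counts and binary prey
#' entries.  Nothing here is fatal; the report lists severities.
#'
#' @param covariates covariate data.frame (needs `id`; uses `size_cm`,
#'   `weight_mg` when present).
#' @param geno optional `genotype_table`.
#' @param landmarks optional `landmark_set`.
#' @param prey optional binary matrix with rownames.
#' @return data.frame with columns `severity` (`error`/`warning`) and
#'   `message`; zero rows when clean.
#' @export
validate_inputs <- function(covariates, geno = NULL, landmarks = NULL,
                            prey = NULL) {
  out <- list()
  add <- function(sev, msg) out[[length(out) + 1L]] <<-
    data.frame(severity = sev, message = msg, stringsAsFactors = FALSE)
  ids <- covariates$id
  if (anyDuplicated(ids))
    add("error", paste("duplicate ids:",
                       paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (!is.null(geno)) {
    orphan <- setdiff(geno$ids, ids)
    if (length(orphan))
      add("error", sprintf("%d genotyped id(s) missing from covariates: %s",
                           length(orphan),
                           paste(utils::head(orphan, 10), collapse = ", ")))
  }
  if (all(c("size_cm", "weight_mg") %in% names(covariates))) {
    sz <- covariates$size_cm
    if (any(sz < 1 | sz > 120, na.rm = TRUE))
      add("warning", "size_cm outside the plausible 1-120 cm range")
    K <- covariates$weight_mg / sz^3
    if (stats::median(K, na.rm = TRUE) < 0.1)
      add("warning",
          "median K far below the 5-20 operating range: weight probably in grams, not mg")
  }
  if (!is.null(landmarks)) {
    if (dim(landmarks$coords)[1] != 21)
      add("warning", sprintf("landmark count is %d, expected 21",
                             dim(landmarks$coords)[1]))
    orphan <- setdiff(landmarks$ids, ids)
    if (length(orphan))
      add("error", sprintf("%d landmark id(s) missing from covariates",
                           length(orphan)))
  }
  if (!is.null(prey)) {
    if (!all(prey %in% c(0, 1)))
      add("error", "prey matrix has non-binary entries")
    orphan <- setdiff(rownames(prey), ids)
    if (length(orphan))
      add("error", sprintf("%d prey id(s) missing from covariates",
                           length(orphan)))
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(severity = character(0), message = character(0))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full hybrid-zone analysis pipeline
#'
#' Executes the enabled stages in dependency order, writes every result as a
#' delimited table under `cfg$out_dir`, and returns (and writes) a
#' consolidated report.  All randomness derives from `cfg$seed`, so a rerun
#' with the same configuration is byte-identical.
#'
#' @param cfg a [run_config()].
#' @return object of class `run_report` (invisibly written to
#'   `report.json` and `report.txt` in the output directory).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  if (!is.null(cfg$sim)) {
    sim <- cfg$sim
    sim$seed <- .stage_seed(cfg$seed, "simulate")
    ds <- simulate_dataset(sim)
    data_dir <- file.path(cfg$out_dir, "data")
    write_dataset(ds, data_dir)
    say("simulate: %d individuals written to data/", nrow(ds$covariates))
    cov <- ds$covariates
    geno <- ds$genotypes
    lms <- ds$landmarks
    prey <- ds$prey
  } else {
    geno <- read_genepop(cfg$paths$genotypes)
    cov <- utils::read.delim(cfg$paths$covariates, stringsAsFactors = FALSE)
    mt <- utils::read.delim(cfg$paths$mtdna, stringsAsFactors = FALSE)
    cov$mtdna <- mt$mtdna[match(cov$id, mt$id)]
    lms <- read_tps(cfg$paths$landmarks)
    prey_df <- utils::read.delim(cfg$paths$prey, check.names = FALSE,
                                 stringsAsFactors = FALSE)
    prey <- as.matrix(prey_df[, -1])
    rownames(prey) <- prey_df[[1]]
    attr(prey, "groups") <- c("diatom", rep("invertebrate", ncol(prey) - 1))
    say("load: %d individuals read", nrow(cov))
  }

  checks <- validate_inputs(cov, geno, lms, prey)
  .write_tsv(checks, file.path(cfg$out_dir, "validation.tsv"))
  if (any(checks$severity == "error")) {
    stop(errorCondition(
      paste("input integrity error(s):",
            paste(checks$message[checks$severity == "error"], collapse = "; ")),
      class = c("hz_integrity_error", "error", "condition")))
  }

  report <- list(seed = cfg$seed,
                 thresholds = c(t_low = cfg$t_low, t_high = cfg$t_high),
                 stages = cfg$stages)

  ## --- genetics ---------------------------------------------------------
  if ("genetics" %in% cfg$stages) {
    freqs <- estimate_allele_frequencies(geno, cfg$ref_cn, cfg$ref_pt)
    hi <- hybrid_index(geno, freqs)
    cls <- classify_genomic(hi$h, cov$mtdna[match(hi$id, cov$id)],
                            cfg$t_low, cfg$t_high)
    hi$label <- cls$label
    hi$reason <- cls$reason
    .write_tsv(hi, file.path(cfg$out_dir, "hybrid_index.tsv"))
    stn <- cov$station[match(hi$id, cov$id)]
    comp <- summarize_population(hi$label, hi$h, stn)
    .write_tsv(comp, file.path(cfg$out_dir, "station_composition.tsv"))
    say("genetics: %d individuals estimated (%d loci used at median)",
        nrow(hi), stats::median(hi$n_loci_used))
    report$station_composition <- comp
    cov$h <- hi$h[match(cov$id, hi$id)]
    cov$group <- hi$label[match(cov$id, hi$id)]
  } else {
    .assert(all(c("h", "group") %in% names(cov)),
            "genetics stage disabled but covariates lack h/group",
            "hz_config_error")
  }

  pure <- cov[cov$group %in% c("Cn", "Pt"), , drop = FALSE]
  hyb <- cov[cov$group == "Hybrid", , drop = FALSE]

  ## --- condition --------------------------------------------------------
  if ("condition" %in% cfg$stages) {
    kk <- compute_k(cov$size_cm, cov$weight_mg, cov$id)
    cov$K <- kk$K
    cov$K_excluded <- kk$excluded
    say("condition: %d of %d records excluded for extreme K",
        sum(kk$excluded), nrow(kk))
    dp <- cov[cov$group %in% c("Cn", "Pt") & !cov$K_excluded, ]
    tf <- fit_trait_model(data.frame(K = dp$K, env = dp$zone, sp = dp$group,
                                     size_cm = dp$size_cm), "K")
    .write_tsv(tf$type3, file.path(cfg$out_dir, "condition_type3.tsv"))
    .write_tsv(tf$aic_table, file.path(cfg$out_dir, "condition_aic.tsv"))
    report$condition <- list(degree = tf$degree, type3 = tf$type3)
    dh <- cov[cov$group == "Hybrid" & !cov$K_excluded, ]
    if (nrow(dh) >= 2) {
      dev <- hybrid_deviation(tf, data.frame(id = dh$id, K = dh$K,
                                             h = dh$h, size_cm = dh$size_cm,
                                             env = dh$zone))
      dm <- fit_deviation_model(dev)
      .write_tsv(dev, file.path(cfg$out_dir, "hybrid_K_deviation.tsv"))
      .write_tsv(cbind(term = rownames(dm$coefficients), dm$coefficients),
                 file.path(cfg$out_dir, "hybrid_K_deviation_model.tsv"))
      report$hybrid_additivity_K <- list(
        mean_D = mean(dev$D), global_f_p = dm$global_f$p_value,
        verdict = if (is.na(dm$global_f$p_value) ||
                        dm$global_f$p_value >= cfg$alpha)
          "consistent_with_additivity" else "deviates_from_additivity")
      say("condition: hybrid additivity global F p = %.3g",
          dm$global_f$p_value)
    }
    sz <- size_age_comparison(data.frame(size_cm = cov$size_cm,
                                         group = cov$group, env = cov$zone,
                                         age = cov$age,
                                         station = cov$station))
    .write_tsv(sz$contrasts, file.path(cfg$out_dir, "size_age_contrasts.tsv"))
    report$size_contrasts <- sz$contrasts
  }

  ## --- morphometrics ----------------------------------------------------
  if ("morpho" %in% cfg$stages) {
    gp <- gpa_align(lms)
    flat <- .flatten_shapes(gp$coords)
    .write_tsv(data.frame(id = rownames(flat), flat, check.names = FALSE),
               file.path(cfg$out_dir, "aligned_shapes.tsv"))
    pure_ids <- pure$id[pure$id %in% gp$ids]
    keep <- match(pure_ids, gp$ids)
    gp_pure <- structure(list(coords = gp$coords[, , keep, drop = FALSE],
                              consensus = gp$consensus,
                              centroid_size = gp$centroid_size[keep],
                              residuals = gp$residuals[keep],
                              iterations = gp$iterations, ids = pure_ids,
                              n_landmarks = gp$n_landmarks), class = "gpa")
    sf <- fit_shape_models(gp_pure,
                           data.frame(id = pure$id, env = pure$zone,
                                      sp = pure$group, size_cm = pure$size_cm))
    envs <- unique(pure$zone)
    ref_env <- if ("reference" %in% envs) "reference" else envs[1]
    fields <- list()
    for (e in setdiff(envs, ref_env)) for (spp in c("Cn", "Pt")) {
      df <- deformation_between(sf, list(env = ref_env, sp = spp),
                                list(env = e, sp = spp),
                                alpha = cfg$alpha, p_adjust = cfg$p_adjust)
      key <- paste0(spp, "_", ref_env, "_vs_", e)
      fields[[key]] <- df
      .write_tsv(df$landmarks,
                 file.path(cfg$out_dir, paste0("deformation_", key, ".tsv")))
    }
    report$deformations <- lapply(fields, function(f)
      c(n_significant = sum(f$landmarks$significant),
        max_magnitude = max(f$landmarks$magnitude)))
    say("morpho: %d specimens aligned in %d iterations",
        length(gp$ids), gp$iterations)
    hyb_ids <- hyb$id[hyb$id %in% gp$ids]
    if (length(hyb_ids) >= 2) {
      kh <- match(hyb_ids, gp$ids)
      gp_hyb <- structure(list(coords = gp$coords[, , kh, drop = FALSE],
                               ids = hyb_ids), class = "gpa")
      hst <- hybrid_shape_test(sf, gp_hyb,
                               data.frame(id = hyb$id, h = hyb$h,
                                          size_cm = hyb$size_cm,
                                          env = hyb$zone),
                               alpha = cfg$alpha, p_adjust = cfg$p_adjust)
      .write_tsv(hst$coords, file.path(cfg$out_dir, "hybrid_shape_deviation.tsv"))
      report$hybrid_shape <- list(
        n_significant = sum(hst$coords$significant),
        verdict = if (sum(hst$coords$significant) == 0)
          "consistent_with_mixture" else "deviates_from_mixture")
    }
  }

  ## --- diet -------------------------------------------------------------
  if ("diet" %in% cfg$stages) {
    vd <- data.frame(feces = cov$feces, h = cov$h, size_cm = cov$size_cm,
                     season = cov$season, env = cov$zone)
    vf <- fit_vacuity_model(vd)
    .write_tsv(cbind(term = rownames(vf$coefficients), vf$coefficients),
               file.path(cfg$out_dir, "vacuity_model.tsv"))
    report$vacuity <- list(lr_tests = vf$lr_tests, notes = vf$notes)
    dc <- classify_diet(prey)
    fed <- which(cov$feces == 1)
    say("diet: %d individuals with feces, classes: %s",
        length(fed), paste(names(table(dc[fed])), table(dc[fed]),
                           sep = "=", collapse = ", "))
    fi <- tryCatch(feeding_index_pca(prey), error = function(e) NULL)
    if (!is.null(fi)) {
      .write_tsv(data.frame(id = names(fi$scores), score = fi$scores),
                 file.path(cfg$out_dir, "feeding_index.tsv"))
      report$feeding_index <- list(inertia_pct = 100 * fi$inertia_frac,
                                   diatom_cor = fi$diatom_cor)
    }
    dd <- data.frame(diet_class = dc, season = cov$season, env = cov$zone,
                     group = cov$group, size_cm = cov$size_cm)[fed, ]
    dm <- tryCatch(fit_diet_multinomial(dd), error = function(e) NULL)
    if (!is.null(dm)) {
      .write_tsv(dm$lr_tests, file.path(cfg$out_dir, "diet_multinomial_lr.tsv"))
      .write_tsv(dm$prob_curves, file.path(cfg$out_dir, "diet_prob_curves.tsv"))
      report$diet_model <- list(lr_tests = dm$lr_tests,
                                baseline = dm$baseline,
                                n_excluded = dm$n_excluded)
    }
    cls_tab <- as.data.frame(table(class = dc[fed],
                                   zone = cov$zone[fed],
                                   group = cov$group[fed]))
    .write_tsv(cls_tab, file.path(cfg$out_dir, "diet_class_composition.tsv"))
  }

  report$log <- log
  writeLines(log, file.path(cfg$out_dir, "run.log"))
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  txt <- c("Hybrid-zone pipeline report",
           sprintf("seed: %d; stages: %s", cfg$seed,
                   paste(cfg$stages, collapse = ", ")),
           "", log)
  writeLines(txt, file.path(cfg$out_dir, "report.txt"))
  class(report) <- "run_report"
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Hybrid-zone pipeline report (seed", x$seed, ")\n")
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}
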