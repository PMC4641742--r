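# Synthetic hybrid-zone data generator.
#
# Emulates a two-species cyprinid hybrid zone: two parental gene pools with
# partially diagnostic microsatellite-style loci, hybrids with known ancestry
# proportion h, mtDNA lineage, age/size growth curves, a condition surface
# K(size, species, environment), species-specific allometric body shapes on a
# 21-landmark template, and a feces-based prey-detection process.

# 21-landmark fish body template (arbitrary digitising-unit coordinates of a
# generic cyprinid outline; snout at the origin, tail to the right).
.landmark_template <- function() {
  m <- matrix(c(
    0.0,  0.0,   # 1  snout tip
    0.5,  0.6,   # 2  top of head
    0.3, -0.5,   # 3  lower jaw
    2.0,  1.2,   # 4  nape
    3.5,  1.6,   # 5  dorsal fin, anterior
    4.8,  1.4,   # 6  dorsal fin, posterior
    6.5,  0.9,   # 7  dorsal caudal peduncle
    8.0,  0.6,   # 8  upper caudal base
    8.6,  0.9,   # 9  caudal fin, top
    9.3,  0.4,   # 10 tail, upper
    9.6,  0.0,   # 11 fork
    9.3, -0.4,   # 12 tail, lower
    8.6, -0.9,   # 13 caudal fin, bottom
    8.0, -0.6,   # 14 lower caudal base
    6.5, -0.8,   # 15 anal fin, posterior
    5.5, -1.0,   # 16 anal fin, anterior
    4.2, -1.2,   # 17 pelvic fin
    2.8, -1.1,   # 18 pectoral fin
    1.5, -0.8,   # 19 operculum, bottom
    1.2,  0.2,   # 20 eye
    1.8,  0.4    # 21 operculum, top
  ), ncol = 2, byrow = TRUE)
  dimnames(m) <- list(paste0("L", 1:21), c("x", "y"))
  m
}

.default_zones <- function() {
  list(
    reference = list(size_effect = 0.0,  k_effect = 0.0,  shape_scale = 0.0),
    ardeche   = list(size_effect = 1.5,  k_effect = 0.3,  shape_scale = 0.3),
    durance   = list(size_effect = -2.5, k_effect = -1.5, shape_scale = 1.0)
  )
}

.default_diet_profiles <- function() {
  # detection probabilities for the 8 prey items, by species class and zone;
  # item 1 is the diatom group, items 2-8 invertebrates (Diptera, Mollusca,
  # Malacostraca named; 4 further invertebrate items generic).
  base <- rbind(
    Cn     = c(0.80, 0.35, 0.20, 0.15, 0.20, 0.15, 0.10, 0.10),
    Pt     = c(0.60, 0.55, 0.35, 0.25, 0.30, 0.25, 0.20, 0.15),
    Hybrid = c(0.70, 0.45, 0.28, 0.20, 0.25, 0.20, 0.15, 0.12)
  )
  shift <- c(reference = 0, ardeche = -0.8, durance = 0.8) # logit shift, diatoms
  inv_shift <- c(reference = 0, ardeche = 0.6, durance = -0.6)
  out <- list()
  for (z in names(shift)) {
    p <- base
    p[, 1] <- stats::plogis(stats::qlogis(base[, 1]) + shift[[z]])
    p[, 2:8] <- stats::plogis(stats::qlogis(base[, 2:8]) + inv_shift[[z]])
    out[[z]] <- p
  }
  out
}

.default_prey_items <- function() {
  c("diatoms", "Diptera", "Mollusca", "Malacostraca",
    "Ephemeroptera", "Trichoptera", "Oligochaeta", "Crustacea_other")
}

#' Simulation configuration for a synthetic hybrid zone
#'
#' Builds and validates the full parameter set of the synthetic-data
#' generator.  Defaults describe a plausible two-species riverine hybrid
#' zone: 41 partially diagnostic codominant loci, saturating (von
#' Bertalanffy) growth with species- and zone-specific parameters, a
#' condition surface K(size, species, zone) around K ~ 10, linear allometric
#' landmark drift with size, and a logistic feces-presence process feeding a
#' per-item prey-detection model.
#'
#' @param n_loci number of codominant loci.
#' @param n_alleles_per_locus alleles per locus (>= 2).
#' @param divergence allele-frequency differential in `[0,1]` between the two
#'   parental pools; 1 = fully diagnostic loci, 0 = no information.
#' @param n_cn,n_pt,n_hybrid group sizes for pure C. nasus, pure
#'   P. toxostoma and hybrids.
#' @param h_distribution distribution of hybrid ancestry h: a list with
#'   `type` one of `"beta"` (fields `shape1`, `shape2`), `"uniform"`, or
#'   `"point"` (field `value`).
#' @param zones named list of environment levels, each with `size_effect`
#'   (cm), `k_effect` (condition units) and `shape_scale` (multiplier on the
#'   built-in slendering deformation pattern).
#' @param allometry list with per-species scalar allometric rates
#'   (`cn`, `pt`): fractional body-depth change per cm of size.
#' @param heterosis_delta additive condition shift applied to hybrids on top
#'   of the h-mixture expectation (0 = strict additivity).
#' @param vacuity_coefs named coefficients of the logistic feces-presence
#'   model on the scale of `h * (season + size + env)`.
#' @param diet_profiles per-(species class, zone) detection probabilities for
#'   the 8 prey items; see `hybridzone:::.default_diet_profiles()`.
#' @param diet_size_coef per-item logit slope of detection probability on
#'   centred size (negative first entry: diatoms detected more in small fish).
#' @param landmark_noise_sd isotropic Gaussian landmark noise (template
#'   units; body length is about 10 units).
#' @param weight_cv coefficient of variation of the multiplicative log-normal
#'   weight noise.
#' @param digitise apply a random similarity transform (rotation, scale,
#'   offset) to each written landmark configuration, emulating digitisation.
#' @param seed integer seed; fully determines the generated dataset.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_loci = 41L, n_alleles_per_locus = 4L, divergence = 0.8,
                       n_cn = 80L, n_pt = 80L, n_hybrid = 40L,
                       h_distribution = list(type = "beta", shape1 = 1.5, shape2 = 1.5),
                       zones = .default_zones(),
                       allometry = list(cn = 0.008, pt = -0.004),
                       heterosis_delta = 0,
                       vacuity_coefs = c(intercept = 0.8, h = -0.4, size = -0.02,
                                         season_summer = -0.5, season_autumn = -0.4,
                                         env_ardeche = -0.6, env_durance = -0.9,
                                         h_size = 0.01, h_season_summer = 0.3,
                                         h_season_autumn = 0.2, h_env_ardeche = 0.2,
                                         h_env_durance = 0.1),
                       diet_profiles = .default_diet_profiles(),
                       diet_size_coef = c(-0.15, rep(0.05, 7)),
                       landmark_noise_sd = 0.02,
                       weight_cv = 0.05,
                       digitise = TRUE,
                       seed = 1L) {
  .assert(is.numeric(divergence) && length(divergence) == 1 &&
            divergence >= 0 && divergence <= 1,
          "divergence must be a single value in [0, 1]", "hz_config_error")
  .assert(n_alleles_per_locus >= 2, "need at least 2 alleles per locus",
          "hz_config_error")
  .assert(all(c(n_loci, n_cn, n_pt, n_hybrid) >= 0), "counts must be >= 0",
          "hz_config_error")
  .assert(is.list(zones) && length(zones) >= 1 && !is.null(names(zones)),
          "zones must be a named list", "hz_config_error")
  for (p in diet_profiles) {
    .assert(all(p >= 0 & p <= 1), "diet profile probabilities must be in [0,1]",
            "hz_config_error")
  }
  .assert(h_distribution$type %in% c("beta", "uniform", "point"),
          "unknown h_distribution type", "hz_config_error")
  cfg <- list(n_loci = as.integer(n_loci),
              n_alleles_per_locus = as.integer(n_alleles_per_locus),
              divergence = divergence, n_cn = as.integer(n_cn),
              n_pt = as.integer(n_pt), n_hybrid = as.integer(n_hybrid),
              h_distribution = h_distribution, zones = zones,
              allometry = allometry, heterosis_delta = heterosis_delta,
              vacuity_coefs = vacuity_coefs, diet_profiles = diet_profiles,
              diet_size_coef = diet_size_coef,
              landmark_noise_sd = landmark_noise_sd, weight_cv = weight_cv,
              digitise = isTRUE(digitise), seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Generate parental allele-frequency profiles
#'
#' Draws, per locus, two parental frequency vectors whose most divergent
#' allele has frequency differential exactly equal to `divergence`: a common
#' Dirichlet background is mixed with mass `divergence` placed on one
#' species-private allele per pool, so `divergence = 1` yields fully
#' diagnostic loci and `divergence = 0` identical pools.
#'
#' @param cfg a [sim_config()].
#' @return an `allele_freqs` object: per locus, named frequency vectors `cn`
#'   and `pt` over the allele labels.
#' @export
gen_allele_frequencies <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.stage_seed(cfg$seed, "simulate"))
  k <- cfg$n_alleles_per_locus
  d <- cfg$divergence
  alleles <- sprintf("%03d", seq_len(k))
  loci <- lapply(seq_len(cfg$n_loci), function(i) {
    base <- stats::rgamma(k, shape = 1.2)
    base <- base / sum(base)
    picks <- sample.int(k, 2)  # species-private alleles, one per pool
    p_cn <- (1 - d) * base; p_cn[picks[1]] <- p_cn[picks[1]] + d
    p_pt <- (1 - d) * base; p_pt[picks[2]] <- p_pt[picks[2]] + d
    names(p_cn) <- names(p_pt) <- alleles
    list(cn = p_cn, pt = p_pt)
  })
  names(loci) <- sprintf("loc%02d", seq_len(cfg$n_loci))
  structure(list(loci = loci), class = "allele_freqs")
}

# draw hybrid ancestry values
.draw_h <- function(n, hd) {
  switch(hd$type,
         beta = stats::rbeta(n, hd$shape1, hd$shape2),
         uniform = stats::runif(n),
         point = rep(hd$value, n))
}

# von Bertalanffy size at age, mixed across species by h
.vb_size <- function(age, h, zone_eff) {
  linf <- h * 19 + (1 - h) * 32
  kgr <- h * 0.35 + (1 - h) * 0.25
  linf * (1 - exp(-kgr * (age + 0.5))) + zone_eff
}

# condition surfaces for the two parental species (degree <= 2 in size)
.k_surface <- function(size, sp, k_eff) {
  s <- size - 13
  if (sp == "Pt") 9.8 - 0.03 * s - 0.004 * s^2 + k_eff
  else            10.5 + 0.04 * s - 0.002 * s^2 + k_eff
}

# species mean landmark configuration at a given size
.species_shape <- function(sp, size, allometry, zone_scale) {
  tmpl <- .landmark_template()
  depth <- if (sp == "Pt") -0.10 else 0.10
  rate <- if (sp == "Pt") allometry$pt else allometry$cn
  shp <- tmpl
  shp[, 2] <- shp[, 2] * (1 + depth + rate * (size - 13))
  # zone deformation: slendering pattern concentrated on dorsal/ventral points
  slender <- -0.06 * tmpl[, 2]
  shp[, 2] <- shp[, 2] + zone_scale * slender
  shp
}

#' Simulate a complete synthetic hybrid-zone dataset
#'
#' Generates genotypes (two independent allele draws per locus from the
#' mixture `h * p_Pt + (1 - h) * p_Cn`), mtDNA lineage (Pt with probability
#' h), age/size/weight covariates, 21-landmark configurations (hybrid mean
#' shape is the exact h-interpolation of the two species shapes), feces
#' presence and prey detections, together with a ground-truth table.
#'
#' @param cfg a [sim_config()].
#' @param freqs optional [gen_allele_frequencies()] output; generated from
#'   `cfg` when missing.
#' @return an object of class `hz_dataset` with elements `covariates`
#'   (data.frame), `genotypes` (`genotype_table`), `landmarks`
#'   (`landmark_set`), `prey` (binary matrix with item-group attribute),
#'   `truth` (data.frame) and `config`.
#' @export
simulate_dataset <- function(cfg, freqs = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(freqs)) freqs <- gen_allele_frequencies(cfg)
  .assert(length(freqs$loci) == cfg$n_loci,
          "frequency profile does not match n_loci", "hz_structure_error")
  set.seed(.stage_seed(cfg$seed, "pipeline"))

  n <- cfg$n_cn + cfg$n_pt + cfg$n_hybrid
  grp <- rep(c("Cn", "Pt", "Hybrid"), c(cfg$n_cn, cfg$n_pt, cfg$n_hybrid))
  h <- c(rep(0, cfg$n_cn), rep(1, cfg$n_pt),
         .draw_h(cfg$n_hybrid, cfg$h_distribution))
  ids <- sprintf("ind%04d", seq_len(n))

  zn <- names(cfg$zones)
  syntopic <- setdiff(zn, "reference")
  if (length(syntopic) == 0) syntopic <- zn
  zone <- character(n)
  pure <- grp != "Hybrid"
  # pures: half in their reference population, rest across syntopic zones
  zone[pure] <- sample(c("reference", syntopic), sum(pure), replace = TRUE,
                       prob = c(0.5, rep(0.5 / length(syntopic), length(syntopic))))
  if (!"reference" %in% zn) zone[pure] <- sample(zn, sum(pure), replace = TRUE)
  zone[!pure] <- sample(syntopic, sum(!pure), replace = TRUE)
  station <- ifelse(zone == "reference",
                    ifelse(grp == "Pt", "ref_pt", "ref_cn"),
                    paste0(substr(zone, 1, 3),
                           sample(1:2, n, replace = TRUE)))
  season <- sample(c("spring", "summer", "autumn"), n, replace = TRUE,
                   prob = c(0.4, 0.4, 0.2))

  age <- sample(1:8, n, replace = TRUE, prob = c(2, 3, 3, 2.5, 2, 1.5, 1, 0.5))
  zeff <- vapply(zone, function(z) cfg$zones[[z]]$size_effect, numeric(1))
  size <- pmax(3, .vb_size(age, h, zeff) + stats::rnorm(n, 0, 1))

  keff <- vapply(zone, function(z) cfg$zones[[z]]$k_effect, numeric(1))
  k_cn <- mapply(function(s, ke) .k_surface(s, "Cn", ke), size, keff)
  k_pt <- mapply(function(s, ke) .k_surface(s, "Pt", ke), size, keff)
  k_true <- h * k_pt + (1 - h) * k_cn +
    ifelse(grp == "Hybrid", cfg$heterosis_delta, 0)
  weight <- k_true * size^3 * exp(stats::rnorm(n, 0, cfg$weight_cv))

  # mtDNA lineage: maternal pool Pt with probability h
  mtdna <- ifelse(stats::runif(n) < h, "Pt", "Cn")

  # genotypes: each gene copy from pool Pt with probability h
  loci <- names(freqs$loci)
  a1 <- a2 <- matrix(NA_character_, n, cfg$n_loci, dimnames = list(ids, loci))
  for (j in seq_len(cfg$n_loci)) {
    pc <- freqs$loci[[j]]$cn; pp <- freqs$loci[[j]]$pt
    al <- names(pc)
    for (copy in 1:2) {
      from_pt <- stats::runif(n) < h
      draws <- character(n)
      if (any(from_pt)) draws[from_pt] <- sample(al, sum(from_pt), TRUE, prob = pp)
      if (any(!from_pt)) draws[!from_pt] <- sample(al, sum(!from_pt), TRUE, prob = pc)
      if (copy == 1) a1[, j] <- draws else a2[, j] <- draws
    }
  }
  geno <- structure(list(a1 = a1, a2 = a2, ids = ids, loci = loci,
                         pop = station), class = "genotype_table")

  # landmarks: exact h-interpolation of species mean shapes, plus noise and
  # an optional random digitising similarity transform
  coords <- array(NA_real_, c(21, 2, n),
                  dimnames = list(paste0("L", 1:21), c("x", "y"), ids))
  for (i in seq_len(n)) {
    zs <- cfg$zones[[zone[i]]]$shape_scale
    shp_cn <- .species_shape("Cn", size[i], cfg$allometry, zs)
    shp_pt <- .species_shape("Pt", size[i], cfg$allometry, zs)
    shp <- h[i] * shp_pt + (1 - h[i]) * shp_cn
    shp <- shp + matrix(stats::rnorm(42, 0, cfg$landmark_noise_sd), 21, 2)
    if (cfg$digitise) {
      th <- stats::runif(1, -0.3, 0.3)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      sc <- 30 * exp(stats::runif(1, -0.15, 0.15))  # ~pixels per unit
      off <- stats::runif(2, 50, 400)
      shp <- sweep(sc * (shp %*% R), 2, off, `+`)
    }
    coords[, , i] <- shp
  }
  lms <- structure(list(coords = coords, ids = ids), class = "landmark_set")

  # feces presence (gut vacuity indicator) and prey detections
  vc <- cfg$vacuity_coefs
  eta <- vc["intercept"] + vc["h"] * h + vc["size"] * (size - 13) +
    (season == "summer") * vc["season_summer"] +
    (season == "autumn") * vc["season_autumn"] +
    (zone == "ardeche") * vc["env_ardeche"] +
    (zone == "durance") * vc["env_durance"] +
    h * ((size - 13) * vc["h_size"] +
           (season == "summer") * vc["h_season_summer"] +
           (season == "autumn") * vc["h_season_autumn"] +
           (zone == "ardeche") * vc["h_env_ardeche"] +
           (zone == "durance") * vc["h_env_durance"])
  feces <- stats::rbinom(n, 1, stats::plogis(unname(eta)))

  items <- .default_prey_items()
  prey <- matrix(0L, n, 8, dimnames = list(ids, items))
  for (i in seq_len(n)) {
    if (feces[i] == 1) {
      zkey <- if (zone[i] %in% names(cfg$diet_profiles)) zone[i] else "reference"
      p <- cfg$diet_profiles[[zkey]][grp[i], ]
      p <- stats::plogis(stats::qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6)) +
                           cfg$diet_size_coef * (size[i] - 13))
      prey[i, ] <- stats::rbinom(8, 1, p)
    }
  }
  attr(prey, "groups") <- c("diatom", rep("invertebrate", 7))

  cov <- data.frame(id = ids, station = station, zone = zone, season = season,
                    age = age, size_cm = size, weight_mg = weight,
                    mtdna = mtdna, feces = feces, stringsAsFactors = FALSE)
  truth <- data.frame(id = ids, h_true = h, species_true = grp,
                      k_true = k_true, zone = zone, stringsAsFactors = FALSE)
  structure(list(covariates = cov, genotypes = geno, landmarks = lms,
                 prey = prey, truth = truth, config = cfg),
            class = "hz_dataset")
}

#' @export
print.hz_dataset <- function(x, ...) {
  cat("Synthetic hybrid-zone dataset:",
      nrow(x$covariates), "individuals,",
      length(x$genotypes$loci), "loci,",
      dim(x$landmarks$coords)[1], "landmarks\n")
  print(table(x$truth$species_true, x$truth$zone))
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits a Genepop genotype file, a TPS landmark file, and delimited
#' covariate / mtDNA / prey / truth tables under `dir`.
#'
#' @param ds an `hz_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "hz_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genotypes = file.path(dir, "genotypes.gen"),
             covariates = file.path(dir, "covariates.tsv"),
             mtdna = file.path(dir, "mtdna.tsv"),
             landmarks = file.path(dir, "landmarks.tps"),
             prey = file.path(dir, "prey.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_genepop(ds$genotypes, paths["genotypes"])
  utils::write.table(ds$covariates[setdiff(names(ds$covariates), "mtdna")],
                     paths["covariates"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ds$covariates[c("id", "mtdna")], paths["mtdna"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_tps(ds$landmarks, paths["landmarks"])
  prey_df <- data.frame(id = rownames(ds$prey), ds$prey, check.names = FALSE)
  utils::write.table(prey_df, paths["prey"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ds$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
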