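# Maximum-likelihood hybrid index from codominant genotypes, and the
# three-way genomic classification with an mtDNA-discordance override.
#
# Model: each gene copy of an individual with ancestry proportion h carries
# allele a with probability h * p_Pt(a) + (1 - h) * p_Cn(a); the
# log-likelihood is the sum over all non-missing gene copies, maximised over
# h in [0, 1].  Orientation: h = 0 is C. nasus, h = 1 is P. toxostoma.

#' Estimate per-species allele frequencies from reference panels
#'
#' Frequencies are computed per locus over the union of alleles observed
#' anywhere in the table, with a per-allele pseudo-count
#' `eps = 1 / (2 * n_typed + 1)` so that alleles private to a focal
#' individual never produce a `-Inf` likelihood:
#' `freq = (count + eps) / (2 * n_typed + eps * n_alleles)`.
#'
#' @param geno a `genotype_table`.
#' @param ref_cn,ref_pt character vectors of population labels forming the
#'   C. nasus and P. toxostoma reference panels.
#' @return an `allele_freqs` object; loci with no data in either panel are
#'   dropped and listed in the `dropped_loci` attribute.
#' @export
estimate_allele_frequencies <- function(geno, ref_cn, ref_pt) {
  stopifnot(inherits(geno, "genotype_table"))
  in_cn <- geno$pop %in% ref_cn
  in_pt <- geno$pop %in% ref_pt
  .assert(any(in_cn), "no individuals in the Cn reference panel",
          "hz_config_error")
  .assert(any(in_pt), "no individuals in the Pt reference panel",
          "hz_config_error")
  panel_freq <- function(a1, a2, alleles) {
    obs <- c(a1, a2)
    obs <- obs[!is.na(obs)]
    n_typed <- length(obs) / 2
    if (n_typed == 0) return(NULL)
    eps <- 1 / (2 * n_typed + 1)
    cnt <- table(factor(obs, levels = alleles))
    p <- (as.numeric(cnt) + eps) / (2 * n_typed + eps * length(alleles))
    names(p) <- alleles
    p
  }
  loci <- list(); dropped <- character(0)
  for (j in seq_along(geno$loci)) {
    alleles <- sort(unique(stats::na.omit(c(geno$a1[, j], geno$a2[, j]))))
    p_cn <- panel_freq(geno$a1[in_cn, j], geno$a2[in_cn, j], alleles)
    p_pt <- panel_freq(geno$a1[in_pt, j], geno$a2[in_pt, j], alleles)
    if (is.null(p_cn) || is.null(p_pt) || length(alleles) == 0) {
      dropped <- c(dropped, geno$loci[j])
      next
    }
    loci[[geno$loci[j]]] <- list(cn = p_cn, pt = p_pt)
  }
  structure(list(loci = loci),
            class = "allele_freqs", dropped_loci = dropped)
}

# log-likelihood of h for one individual's gene copies
.h_loglik <- function(h, p_pt, p_cn) {
  sum(log(h * p_pt + (1 - h) * p_cn))
}

# collect per-gene-copy parental allele frequencies for one individual
.copy_freqs <- function(a1, a2, freqs) {
  loci <- names(freqs$loci)
  p_pt <- p_cn <- numeric(0)
  n_used <- 0L
  for (j in seq_along(loci)) {
    fr <- freqs$loci[[j]]
    used <- FALSE
    for (a in c(a1[j], a2[j])) {
      if (is.na(a)) next
      if (!a %in% names(fr$cn)) next  # allele unseen in panels: uninformative
      p_pt <- c(p_pt, fr$pt[[a]]); p_cn <- c(p_cn, fr$cn[[a]])
      used <- TRUE
    }
    if (used) n_used <- n_used + 1L
  }
  list(p_pt = p_pt, p_cn = p_cn, n_loci_used = n_used)
}

#' Maximum-likelihood hybrid index
#'
#' Maximises the per-allele mixture log-likelihood over `h` in `[0, 1]` for
#' each individual.  The log-likelihood is concave in h, so a bounded
#' scalar search (golden-section via [stats::optimize()]) with an explicit
#' boundary check suffices.
#'
#' @param geno a `genotype_table` (all individuals are estimated; subset
#'   beforehand if needed).
#' @param freqs an `allele_freqs` from [estimate_allele_frequencies()].
#' @return data.frame with columns `id`, `h`, `log_likelihood`,
#'   `n_loci_used`.
#' @export
hybrid_index <- function(geno, freqs) {
  stopifnot(inherits(geno, "genotype_table"), inherits(freqs, "allele_freqs"))
  loci <- intersect(geno$loci, names(freqs$loci))
  .assert(length(loci) > 0, "no locus shared between genotypes and frequencies",
          "hz_structure_error")
  jg <- match(loci, geno$loci)
  fr <- structure(list(loci = freqs$loci[loci]), class = "allele_freqs")
  out <- lapply(seq_along(geno$ids), function(i) {
    cf <- .copy_freqs(geno$a1[i, jg], geno$a2[i, jg], fr)
    if (length(cf$p_pt) == 0) {
      stop(errorCondition(
        sprintf("individual '%s': all loci missing, cannot estimate h",
                geno$ids[i]),
        class = c("hz_estimation_error", "error", "condition")))
    }
    ll <- function(h) .h_loglik(h, cf$p_pt, cf$p_cn)
    opt <- stats::optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-8)
    cand_h <- c(opt$maximum, 0, 1)
    cand_ll <- c(opt$objective, ll(0), ll(1))
    best <- which.max(cand_ll)
    data.frame(id = geno$ids[i], h = cand_h[best],
               log_likelihood = cand_ll[best], n_loci_used = cf$n_loci_used,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Grid-search hybrid index (independent oracle)
#'
#' Evaluates the same mixture log-likelihood on a regular grid over
#' `[0, 1]`.  Intended as a brute-force cross-check for [hybrid_index()].
#'
#' @param geno a `genotype_table`.
#' @param freqs an `allele_freqs`.
#' @param step grid step (default 1e-4).
#' @return data.frame with `id`, `h`, `log_likelihood`.
#' @export
hybrid_index_grid <- function(geno, freqs, step = 1e-4) {
  grid <- seq(0, 1, by = step)
  loci <- intersect(geno$loci, names(freqs$loci))
  jg <- match(loci, geno$loci)
  fr <- structure(list(loci = freqs$loci[loci]), class = "allele_freqs")
  out <- lapply(seq_along(geno$ids), function(i) {
    cf <- .copy_freqs(geno$a1[i, jg], geno$a2[i, jg], fr)
    # copies x grid matrix of per-copy mixture probabilities
    lls <- colSums(log(cf$p_cn + (cf$p_pt - cf$p_cn) %o% grid))
    best <- which.max(lls)
    data.frame(id = geno$ids[i], h = grid[best], log_likelihood = lls[best],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Genomic classification from hybrid index and mtDNA
#'
#' Nuclear label: `Cn` on the closed range `[0, t_low]`, `Pt` on
#' `[t_high, 1]`, `Hybrid` on the open interval between.  A nuclear-pure
#' individual whose mtDNA belongs to the other species is overridden to
#' `Hybrid` (reason `mtDNA_discordance`); missing mtDNA skips the override.
#'
#' @param h numeric vector of hybrid indices in `[0, 1]`.
#' @param mtdna character vector (`"Cn"`, `"Pt"`, or `NA`), recycled.
#' @param t_low,t_high class thresholds (defaults 0.086 and 0.934).
#' @return data.frame with columns `label` and `reason`.
#' @export
classify_genomic <- function(h, mtdna = NA_character_,
                             t_low = 0.086, t_high = 0.934) {
  .assert(all(h >= 0 & h <= 1, na.rm = TRUE), "h must lie in [0, 1]",
          "hz_domain_error")
  .assert(t_low > 0 && t_low < t_high && t_high < 1,
          "thresholds must satisfy 0 < t_low < t_high < 1", "hz_config_error")
  mtdna <- rep_len(as.character(mtdna), length(h))
  nuclear <- ifelse(h <= t_low, "Cn", ifelse(h >= t_high, "Pt", "Hybrid"))
  reason <- rep("nuclear_range", length(h))
  disc <- !is.na(mtdna) &
    ((nuclear == "Cn" & mtdna == "Pt") | (nuclear == "Pt" & mtdna == "Cn"))
  label <- nuclear
  label[disc] <- "Hybrid"
  reason[disc] <- "mtDNA_discordance"
  data.frame(label = label, reason = reason, stringsAsFactors = FALSE)
}

#' Per-station class composition and hybrid-index summary
#'
#' @param classes character vector of class labels (`Cn`/`Pt`/`Hybrid`).
#' @param h numeric vector of hybrid indices.
#' @param station character vector of station labels.
#' @return data.frame with per-station percentages (summing to 100 within
#'   rounding), h quartiles and skewness direction.
#' @export
summarize_population <- function(classes, h, station) {
  stopifnot(length(classes) == length(h), length(h) == length(station))
  rows <- lapply(unique(station), function(s) {
    i <- station == s
    n <- sum(i)
    q <- stats::quantile(h[i], c(0.25, 0.5, 0.75), names = FALSE)
    skew <- if (mean(h[i]) > stats::median(h[i]) + 1e-12) "toward_Pt"
            else if (mean(h[i]) < stats::median(h[i]) - 1e-12) "toward_Cn"
            else "symmetric"
    data.frame(station = s, n = n,
               pct_cn = 100 * mean(classes[i] == "Cn"),
               pct_pt = 100 * mean(classes[i] == "Pt"),
               pct_hybrid = 100 * mean(classes[i] == "Hybrid"),
               h_q1 = q[1], h_median = q[2], h_q3 = q[3],
               skewness = skew, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
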