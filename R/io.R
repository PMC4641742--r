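# Readers and writers for the field's plain-text formats: Genepop genotype
# files (2- and 3-digit allele coding), long-format delimited genotype
# tables, and TPS landmark files.

#' Write a genotype table as a Genepop file
#'
#' Individuals are grouped by population; each name line is written as
#' `"<pop> <id> ,"` followed by 3-digit-coded genotypes (missing = `000000`).
#'
#' @param geno a `genotype_table`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_genepop <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("Codominant multilocus genotypes", con)
  writeLines(geno$loci, con)
  for (p in unique(geno$pop)) {
    writeLines("Pop", con)
    for (i in which(geno$pop == p)) {
      g <- paste0(ifelse(is.na(geno$a1[i, ]), "000", geno$a1[i, ]),
                  ifelse(is.na(geno$a2[i, ]), "000", geno$a2[i, ]))
      writeLines(paste(p, geno$ids[i], ",", paste(g, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a Genepop file
#'
#' Accepts 2-digit and 3-digit allele coding (all-zero = missing), locus
#' names one per line or comma-separated on one line, and name fields of the
#' form `"id ,"` or `"pop id ,"`.
#'
#' @param path a Genepop file.
#' @return a `genotype_table`.
#' @export
read_genepop <- function(path) {
  lines <- readLines(path)
  .assert(length(lines) >= 3, "Genepop file too short", "hz_parse_error")
  lines <- lines[trimws(lines) != ""]
  body <- lines[-1]
  is_pop <- toupper(trimws(body)) == "POP"
  first_pop <- which(is_pop)[1]
  .assert(!is.na(first_pop), "no 'Pop' line found", "hz_parse_error")
  loc_lines <- trimws(body[seq_len(first_pop - 1)])
  loci <- unlist(strsplit(paste(loc_lines, collapse = ","), ","))
  loci <- trimws(loci[trimws(loci) != ""])
  nl <- length(loci)

  pop_idx <- cumsum(is_pop)
  recs <- which(!is_pop & pop_idx >= 1)
  ids <- pops <- character(length(recs))
  a1 <- a2 <- matrix(NA_character_, length(recs), nl)
  pop_names <- paste0("pop", seq_len(max(pop_idx)))
  for (r in seq_along(recs)) {
    ln <- body[recs[r]]
    parts <- strsplit(ln, ",")[[1]]
    .assert(length(parts) >= 2,
            sprintf("malformed Genepop record at line %d", recs[r] + 1),
            "hz_parse_error")
    name <- trimws(parts[1])
    toks <- strsplit(name, "[[:space:]]+")[[1]]
    if (length(toks) >= 2) {
      pops[r] <- toks[1]; ids[r] <- paste(toks[-1], collapse = "_")
    } else {
      pops[r] <- pop_names[pop_idx[recs[r]]]; ids[r] <- toks[1]
    }
    g <- strsplit(trimws(paste(parts[-1], collapse = " ")), "[[:space:]]+")[[1]]
    .assert(length(g) == nl,
            sprintf("individual '%s' has %d genotypes, expected %d",
                    ids[r], length(g), nl), "hz_parse_error")
    w <- nchar(g[1]) / 2
    .assert(all(nchar(g) %in% c(4, 6)) && w %in% c(2, 3),
            sprintf("unsupported allele coding width at '%s'", ids[r]),
            "hz_parse_error")
    x1 <- substr(g, 1, w); x2 <- substr(g, w + 1, 2 * w)
    miss <- function(x) x == strrep("0", w)
    a1[r, ] <- ifelse(miss(x1), NA, x1)
    a2[r, ] <- ifelse(miss(x2), NA, x2)
  }
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  structure(list(a1 = a1, a2 = a2, ids = ids, loci = loci, pop = pops),
            class = "genotype_table")
}

#' Read a long-format delimited genotype table
#'
#' Expects columns `id`, `pop`, `locus`, `allele1`, `allele2` (missing
#' alleles empty or NA).
#'
#' @param path delimited file (tab- or comma-separated, sniffed).
#' @return a `genotype_table`.
#' @export
read_genotypes_long <- function(path) {
  sep <- if (grepl(",", readLines(path, n = 1))) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character")
  need <- c("id", "pop", "locus", "allele1", "allele2")
  .assert(all(need %in% names(df)),
          paste("missing columns:", paste(setdiff(need, names(df)), collapse = ", ")),
          "hz_parse_error")
  ids <- unique(df$id); loci <- unique(df$locus)
  a1 <- a2 <- matrix(NA_character_, length(ids), length(loci),
                     dimnames = list(ids, loci))
  clean <- function(x) ifelse(is.na(x) | x == "" | x == "NA", NA_character_, x)
  a1[cbind(match(df$id, ids), match(df$locus, loci))] <- clean(df$allele1)
  a2[cbind(match(df$id, ids), match(df$locus, loci))] <- clean(df$allele2)
  pop <- df$pop[match(ids, df$id)]
  structure(list(a1 = a1, a2 = a2, ids = ids, loci = loci, pop = pop),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("Genotype table:", length(x$ids), "individuals x", length(x$loci),
      "loci;", length(unique(x$pop)), "populations\n")
  invisible(x)
}

#' Write landmark configurations as a TPS file
#'
#' @param lms a `landmark_set` (array `coords` of dim `n_landmarks x 2 x n`).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_tps <- function(lms, path) {
  stopifnot(inherits(lms, "landmark_set"))
  con <- file(path, "w")
  on.exit(close(con))
  k <- dim(lms$coords)[1]
  for (i in seq_along(lms$ids)) {
    writeLines(sprintf("LM=%d", k), con)
    writeLines(sprintf("%.6f %.6f", lms$coords[, 1, i], lms$coords[, 2, i]), con)
    writeLines(sprintf("ID=%s", lms$ids[i]), con)
  }
  invisible(path)
}

#' Read a TPS landmark file
#'
#' Parses `LM=`, coordinate pairs, and `ID=`/`IMAGE=`/`SCALE=` records.
#' Records whose landmark count differs from `expected_lm` are rejected and
#' reported in the `rejected` attribute; the rest are kept.
#'
#' @param path a TPS file.
#' @param expected_lm required landmarks per configuration (default 21).
#' @return a `landmark_set` with attribute `rejected` (data.frame of id and
#'   landmark count for dropped records).
#' @export
read_tps <- function(path, expected_lm = 21L) {
  lines <- readLines(path)
  lm_at <- grep("^\\s*LM\\s*=", lines)
  .assert(length(lm_at) > 0, "no LM= records found", "hz_parse_error")
  bounds <- c(lm_at, length(lines) + 1L)
  keep_coords <- list(); keep_ids <- character(0)
  rej <- list()
  for (r in seq_along(lm_at)) {
    block <- lines[lm_at[r]:(bounds[r + 1] - 1L)]
    k <- suppressWarnings(as.integer(sub("^\\s*LM\\s*=\\s*", "", block[1])))
    .assert(!is.na(k), sprintf("malformed LM= line at line %d", lm_at[r]),
            "hz_parse_error")
    coord_lines <- grep("^\\s*[-0-9]", block[-1], value = TRUE)
    id_line <- grep("^\\s*ID\\s*=", block, value = TRUE)
    img_line <- grep("^\\s*IMAGE\\s*=", block, value = TRUE)
    id <- if (length(id_line)) sub("^\\s*ID\\s*=\\s*", "", id_line[1])
          else if (length(img_line)) sub("^\\s*IMAGE\\s*=\\s*", "", img_line[1])
          else paste0("spec", r)
    .assert(length(coord_lines) == k,
            sprintf("record '%s': %d coordinate rows for LM=%d (line %d)",
                    id, length(coord_lines), k, lm_at[r]), "hz_parse_error")
    vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(coord_lines),
                                                        "[[:space:]]+"))))
    .assert(length(vals) == 2 * k && !anyNA(vals),
            sprintf("record '%s': malformed coordinates (line %d)", id, lm_at[r]),
            "hz_parse_error")
    if (k != expected_lm) {
      rej[[length(rej) + 1L]] <- data.frame(id = id, n_landmarks = k)
      next
    }
    keep_coords[[length(keep_coords) + 1L]] <-
      matrix(vals, ncol = 2, byrow = TRUE)
    keep_ids <- c(keep_ids, id)
  }
  coords <- array(NA_real_, c(expected_lm, 2, length(keep_ids)),
                  dimnames = list(paste0("L", seq_len(expected_lm)),
                                  c("x", "y"), keep_ids))
  for (i in seq_along(keep_ids)) coords[, , i] <- keep_coords[[i]]
  out <- structure(list(coords = coords, ids = keep_ids),
                   class = "landmark_set")
  attr(out, "rejected") <- if (length(rej)) do.call(rbind, rej)
                           else data.frame(id = character(0), n_landmarks = integer(0))
  out
}

#' @export
print.landmark_set <- function(x, ...) {
  d <- dim(x$coords)
  cat("Landmark set:", d[3], "configurations of", d[1], "2-D landmarks\n")
  invisible(x)
}
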