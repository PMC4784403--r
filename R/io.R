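# Genotype and panel file I/O.
#
# Two text dialects are supported: a headered TSV (one row per sample,
# one column per SNP, additive 0/1/2 codes) and the PLINK text pair
# (.ped/.map). Missing genotypes may be written as "NA", "-9" or "." on
# input; writers always emit "NA". All writers are deterministic: the
# same object always produces the same bytes.

MISSING_TOKENS <- c("NA", "-9", ".")

# full-precision, locale-independent number formatting so that
# write -> read round trips are bit-exact
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (!is.na(v) && v == round(v) && abs(v) < 1e15)
      return(format(as.integer(round(v))))
    formatC(v, digits = 17, format = "g")
  }, character(1))
  out
}

#' Read an additive-coded genotype file
#'
#' @param path path to a headered genotype TSV, or to a PLINK text
#'   fileset (the `.ped` file, or the common prefix of the pair).
#' @param dialect `"tsv"` (first column `sample_id`, remaining columns
#'   one SNP each, tokens 0/1/2 or a missing sentinel) or
#'   `"plink_text"` (.ped/.map pair; the count refers to the
#'   alphabetically first allele observed at each SNP).
#' @return A [genotype_matrix()]. For the TSV dialect the coded allele is
#'   unknown (`NA`) and assumed to match the reference panel until
#'   [harmonize_alleles()] is applied.
#' @export
read_additive_genotypes <- function(path, dialect = c("tsv", "plink_text")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") read_genotype_tsv(path) else read_plink_text(path)
}

read_genotype_tsv <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("genotype file has no sample rows: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  snp_ids <- header[-1]
  P <- length(snp_ids)
  n <- length(lines) - 1L
  values <- matrix(NA_real_, n, P)
  sample_ids <- character(n)
  for (i in seq_len(n)) {
    tok <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
    if (length(tok) != P + 1L)
      stop("row ", i, " (", tok[1], ") has ", length(tok) - 1L,
           " genotype fields, expected ", P)
    sample_ids[i] <- tok[1]
    g <- tok[-1]
    miss <- g %in% MISSING_TOKENS
    num <- suppressWarnings(as.numeric(g))
    bad <- which(!miss & (is.na(num) | !(num %in% c(0, 1, 2))))
    if (length(bad))
      stop("malformed genotype token '", g[bad[1]], "' at row ", i,
           " (sample ", tok[1], "), column ", bad[1],
           " (SNP ", snp_ids[bad[1]], "): expected 0/1/2 or a missing code")
    num[miss] <- NA_real_
    values[i, ] <- num
  }
  genotype_matrix(values, sample_ids, snp_ids)
}

read_plink_text <- function(path) {
  prefix <- sub("\\.ped$", "", path)
  ped <- paste0(prefix, ".ped")
  map <- paste0(prefix, ".map")
  if (!file.exists(ped)) stop("PLINK .ped file not found: ", ped)
  if (!file.exists(map)) stop("PLINK .map file not found: ", map)

  map_tab <- utils::read.table(map, header = FALSE, sep = "",
                               colClasses = "character")
  if (ncol(map_tab) < 4) stop(".map file must have 4 columns: ", map)
  snp_ids <- map_tab[[2]]
  P <- length(snp_ids)

  lines <- readLines(ped)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  sample_ids <- character(n)
  a1 <- matrix(NA_character_, n, P)
  a2 <- matrix(NA_character_, n, P)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6L + 2L * P)
      stop(".ped row ", i, " has ", length(tok),
           " fields, expected ", 6L + 2L * P)
    sample_ids[i] <- tok[2]
    al <- tok[-(1:6)]
    bad <- which(!(al %in% c("A", "C", "G", "T", "0")))
    if (length(bad))
      stop("malformed allele '", al[bad[1]], "' at .ped row ", i,
           " (sample ", tok[2], "), SNP ",
           snp_ids[ceiling(bad[1] / 2)])
    a1[i, ] <- al[seq(1, 2 * P, by = 2)]
    a2[i, ] <- al[seq(2, 2 * P, by = 2)]
  }
  a1[a1 == "0"] <- NA_character_
  a2[a2 == "0"] <- NA_character_
  # a genotype with either allele missing is treated as a missing call
  half <- xor(is.na(a1), is.na(a2))
  a1[half] <- NA_character_
  a2[half] <- NA_character_

  values <- matrix(NA_real_, n, P)
  coded <- rep(NA_character_, P)
  other <- rep(NA_character_, P)
  for (j in seq_len(P)) {
    alleles <- sort(unique(stats::na.omit(c(a1[, j], a2[, j]))))
    if (length(alleles) > 2)
      stop("SNP ", snp_ids[j], " has more than two alleles: ",
           paste(alleles, collapse = "/"))
    if (length(alleles) == 0) next            # all-missing column
    coded[j] <- alleles[1]
    if (length(alleles) == 2) other[j] <- alleles[2]
    values[, j] <- (a1[, j] == coded[j]) + (a2[, j] == coded[j])
  }
  genotype_matrix(values, sample_ids, snp_ids, coded, other)
}

#' Write a genotype matrix as a headered TSV
#'
#' @param G a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_additive_genotypes <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  con <- file(path, open = "wb")   # binary: stable newlines across platforms
  on.exit(close(con))
  writeLines(paste(c("sample_id", G$snp_ids), collapse = "\t"), con)
  for (i in seq_along(G$sample_ids)) {
    writeLines(paste(c(G$sample_ids[i], fmt_num(G$values[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a genotype matrix as a PLINK text pair (.ped/.map)
#'
#' Requires integer genotypes and per-SNP allele annotations. Map
#' positions are synthetic (index-based); coordinates never enter any
#' computation downstream.
#'
#' @param G a [genotype_matrix()] with values in \{0, 1, 2, NA\}.
#' @param prefix output path prefix; `<prefix>.ped` and `<prefix>.map`
#'   are written.
#' @return `prefix`, invisibly.
#' @export
write_plink_text <- function(G, prefix) {
  stopifnot(inherits(G, "genotype_matrix"))
  v <- G$values
  if (any(!is.na(v) & !(v %in% c(0, 1, 2))))
    stop("PLINK text output requires integer 0/1/2 genotypes")
  if (anyNA(G$coded_allele))
    stop("PLINK text output requires coded_allele for every SNP")
  P <- length(G$snp_ids)
  map_con <- file(paste0(prefix, ".map"), open = "wb")
  writeLines(sprintf("1\t%s\t0\t%d", G$snp_ids, seq_len(P)), map_con)
  close(map_con)

  other <- G$other_allele
  other[is.na(other)] <- G$coded_allele[is.na(other)]  # monomorphic SNPs
  ped_con <- file(paste0(prefix, ".ped"), open = "wb")
  on.exit(close(ped_con))
  for (i in seq_along(G$sample_ids)) {
    gi <- v[i, ]
    first <- ifelse(is.na(gi), "0", ifelse(gi >= 1, G$coded_allele, other))
    second <- ifelse(is.na(gi), "0", ifelse(gi == 2, G$coded_allele, other))
    writeLines(paste(c(G$sample_ids[i], G$sample_ids[i], "0", "0", "0", "-9",
                       as.vector(rbind(first, second))), collapse = "\t"),
               ped_con)
  }
  invisible(prefix)
}

#' Read a reference-allele panel file
#'
#' The panel fixes, for every SNP in the marker set, which allele the
#' additive count refers to. Columns: `snp_id`, `ref_allele`,
#' `alt_allele` and optionally `training_mean` (per-SNP mean genotype in
#' the training data, used for imputation and projection centering).
#'
#' @param path panel TSV path.
#' @return A data.frame of class `allele_panel`.
#' @export
read_allele_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           comment.char = "#")
  need <- c("snp_id", "ref_allele", "alt_allele")
  if (!all(need %in% names(tab)))
    stop("panel file must have columns snp_id, ref_allele, alt_allele")
  panel <- data.frame(snp_id = tab$snp_id,
                      ref_allele = toupper(tab$ref_allele),
                      alt_allele = toupper(tab$alt_allele),
                      stringsAsFactors = FALSE)
  if ("training_mean" %in% names(tab))
    panel$training_mean <- as.numeric(tab$training_mean)
  validate_allele_panel(panel)
}

#' Construct / validate an allele panel
#'
#' @param panel data.frame with columns `snp_id`, `ref_allele`,
#'   `alt_allele` and optionally `training_mean`.
#' @return The validated panel with class `allele_panel`.
#' @export
validate_allele_panel <- function(panel) {
  if (anyDuplicated(panel$snp_id))
    stop("duplicate SNP IDs in panel: ",
         paste(unique(panel$snp_id[duplicated(panel$snp_id)]), collapse = ", "))
  bases <- c("A", "C", "G", "T")
  if (!all(panel$ref_allele %in% bases) || !all(panel$alt_allele %in% bases))
    stop("panel alleles must be A, C, G or T")
  if (any(panel$ref_allele == panel$alt_allele))
    stop("ref and alt allele identical for SNP(s): ",
         paste(panel$snp_id[panel$ref_allele == panel$alt_allele],
               collapse = ", "))
  if (!is.null(panel$training_mean)) {
    tm <- panel$training_mean
    if (any(!is.na(tm) & (tm < 0 | tm > 2)))
      stop("training_mean values must lie in [0, 2]")
  }
  class(panel) <- c("allele_panel", "data.frame")
  panel
}

#' Write a reference-allele panel file
#'
#' @param panel an allele panel data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_allele_panel <- function(panel, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  has_tm <- !is.null(panel$training_mean)
  header <- c("snp_id", "ref_allele", "alt_allele",
              if (has_tm) "training_mean")
  writeLines(paste(header, collapse = "\t"), con)
  for (i in seq_len(nrow(panel))) {
    row <- c(panel$snp_id[i], panel$ref_allele[i], panel$alt_allele[i],
             if (has_tm) fmt_num(panel$training_mean[i]))
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}
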