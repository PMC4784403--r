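# Allele harmonization and genotype QC.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Harmonize genotype coding against a reference-allele panel
#'
#' Recodes every SNP so the additive count refers to the panel's
#' reference allele, resolving strand differences by base
#' complementation (A<->T, C<->G) where possible. Output SNP columns
#' follow panel order. SNPs whose coded allele is unknown (TSV input)
#' are assumed to already count the panel reference allele.
#'
#' Strand-ambiguous SNPs (A/T or C/G allele pairs) cannot be resolved by
#' complementation; by default they are assumed to be on the forward
#' strand already (with a warning); `strict = TRUE` drops them instead.
#'
#' @param G a [genotype_matrix()].
#' @param panel an allele panel (see [read_allele_panel()]).
#' @param strict drop strand-ambiguous SNPs instead of warning.
#' @return A `genotype_matrix` whose counts refer to `panel$ref_allele`,
#'   columns in panel order.
#' @export
harmonize_alleles <- function(G, panel, strict = FALSE) {
  stopifnot(inherits(G, "genotype_matrix"))
  idx <- match(G$snp_ids, panel$snp_id)
  if (anyNA(idx))
    stop("SNP(s) absent from panel: ",
         paste(utils::head(G$snp_ids[is.na(idx)], 10), collapse = ", "),
         if (sum(is.na(idx)) > 10) ", ...")

  P <- length(G$snp_ids)
  ref <- panel$ref_allele[idx]
  alt <- panel$alt_allele[idx]
  ambiguous <- ref == COMPLEMENT[alt]          # A/T or C/G SNPs
  flip <- logical(P)                           # recode x -> 2 - x
  fail <- logical(P)

  for (j in seq_len(P)) {
    ca <- G$coded_allele[j]
    oa <- G$other_allele[j]
    if (is.na(ca)) next                        # assumed reference-coded
    match_pair <- function(c1, o1) {
      if (c1 == ref[j] && (is.na(o1) || o1 == alt[j])) return("keep")
      if (c1 == alt[j] && (is.na(o1) || o1 == ref[j])) return("flip")
      NA_character_
    }
    m <- match_pair(ca, oa)
    if (is.na(m) && !ambiguous[j]) {
      m <- match_pair(COMPLEMENT[[ca]],
                      if (is.na(oa)) NA_character_ else COMPLEMENT[[oa]])
    }
    if (is.na(m)) fail[j] <- TRUE else flip[j] <- (m == "flip")
  }
  if (any(fail))
    stop("allele pair irreconcilable with panel for SNP(s): ",
         paste(G$snp_ids[fail], collapse = ", "))

  has_own <- !is.na(G$coded_allele)
  amb_checked <- ambiguous & has_own
  keep <- rep(TRUE, P)
  if (any(amb_checked)) {
    if (strict) {
      keep[amb_checked] <- FALSE
      warning("dropped ", sum(amb_checked), " strand-ambiguous SNP(s): ",
              paste(G$snp_ids[amb_checked], collapse = ", "))
    } else {
      warning("strand-ambiguous SNP(s) assumed on forward strand: ",
              paste(G$snp_ids[amb_checked], collapse = ", "))
    }
  }

  values <- G$values
  if (any(flip)) values[, flip] <- 2 - values[, flip]
  out <- genotype_matrix(values[, keep, drop = FALSE],
                         G$sample_ids, G$snp_ids[keep],
                         ref[keep], alt[keep], dosage = G$dosage)
  # panel column order
  ord <- order(match(out$snp_ids, panel$snp_id))
  subset_genotypes(out, snps = ord)
}

#' Remove samples, then SNPs, exceeding a missing-call threshold
#'
#' Sample-level filtering runs first (a high per-sample missing rate can
#' masquerade as an artefactual extra "population" in the PC scores);
#' SNP missing fractions are then recomputed on the surviving samples.
#' Survivor order is preserved.
#'
#' @param G a [genotype_matrix()].
#' @param max_sample_missing maximum tolerated fraction of missing calls
#'   per sample (default 0.05).
#' @param max_snp_missing maximum tolerated fraction of missing calls
#'   per SNP, computed after sample removal (default 0.05).
#' @return The filtered `genotype_matrix`, with attributes
#'   `samples_removed` and `snps_removed` listing dropped IDs.
#' @export
filter_by_missing_rate <- function(G, max_sample_missing = 0.05,
                                   max_snp_missing = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"),
            max_sample_missing >= 0, max_sample_missing <= 1,
            max_snp_missing >= 0, max_snp_missing <= 1)
  miss <- is.na(G$values)
  sample_rate <- rowMeans(miss)
  keep_s <- sample_rate <= max_sample_missing
  if (!any(keep_s))
    stop("all ", length(keep_s), " samples exceed the missing-rate ",
         "threshold of ", max_sample_missing)
  snp_rate <- colMeans(miss[keep_s, , drop = FALSE])
  keep_v <- snp_rate <= max_snp_missing
  out <- subset_genotypes(G, samples = which(keep_s), snps = which(keep_v))
  attr(out, "samples_removed") <- G$sample_ids[!keep_s]
  attr(out, "snps_removed") <- G$snp_ids[!keep_v]
  out
}

#' Replace missing genotypes with training or in-sample means
#'
#' Each missing call is replaced by the panel's stored training mean for
#' that SNP when available, so that scores computed at different sites
#' stay comparable; otherwise by the SNP's mean over the non-missing
#' calls in `G`.
#'
#' @param G a [genotype_matrix()].
#' @param panel optional allele panel carrying a `training_mean` column.
#' @return A dosage-valued `genotype_matrix` with no missing entries;
#'   non-missing cells are untouched. Attribute `cells_imputed` gives
#'   the number of replaced cells.
#' @export
impute_missing <- function(G, panel = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  values <- G$values
  miss <- is.na(values)
  n_imputed <- sum(miss)
  if (n_imputed > 0) {
    tm <- rep(NA_real_, ncol(values))
    if (!is.null(panel) && !is.null(panel$training_mean)) {
      idx <- match(G$snp_ids, panel$snp_id)
      tm[!is.na(idx)] <- panel$training_mean[idx[!is.na(idx)]]
    }
    for (j in which(colSums(miss) > 0)) {
      fill <- tm[j]
      if (is.na(fill)) {
        obs <- values[!miss[, j], j]
        if (length(obs) == 0)
          stop("SNP ", G$snp_ids[j],
               " is entirely missing and has no training mean")
        fill <- mean(obs)
      }
      values[miss[, j], j] <- fill
    }
  }
  out <- genotype_matrix(values, G$sample_ids, G$snp_ids,
                         G$coded_allele, G$other_allele, dosage = TRUE)
  attr(out, "cells_imputed") <- n_imputed
  out
}
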