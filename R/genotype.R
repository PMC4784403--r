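#' Additive-coded genotype matrix
#'
#' Container for an N-sample x P-SNP genotype matrix in additive coding:
#' each entry counts copies (0, 1 or 2) of the SNP's coded allele, with
#' `NA` marking missing calls. After imputation entries may be real-valued
#' dosages in \[0, 2\].
#'
#' @param values numeric N x P matrix; entries in \{0, 1, 2\} or `NA`
#'   (real-valued in \[0, 2\] when `dosage = TRUE`).
#' @param sample_ids character vector of N unique sample identifiers.
#' @param snp_ids character vector of P unique SNP identifiers.
#' @param coded_allele optional per-SNP base (A/C/G/T) that the counts
#'   refer to; `NA` means "assumed to match the reference panel".
#' @param other_allele optional per-SNP second allele; `NA` allowed
#'   (e.g. monomorphic SNPs read from a .ped file).
#' @param dosage logical; allow non-integer entries (post-imputation).
#'
#' @return An object of class `genotype_matrix` with fields `values`
#'   (dimnamed matrix), `sample_ids`, `snp_ids`, `coded_allele`,
#'   `other_allele`, `dosage`.
#' @export
genotype_matrix <- function(values, sample_ids, snp_ids,
                            coded_allele = NULL, other_allele = NULL,
                            dosage = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != length(sample_ids))
    stop("sample_ids length (", length(sample_ids),
         ") does not match row count (", nrow(values), ")")
  if (ncol(values) != length(snp_ids))
    stop("snp_ids length (", length(snp_ids),
         ") does not match column count (", ncol(values), ")")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(snp_ids))
    stop("duplicate SNP IDs: ",
         paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "))
  obs <- values[!is.na(values)]
  if (dosage) {
    if (length(obs) && (min(obs) < 0 || max(obs) > 2))
      stop("dosage values must lie in [0, 2]")
  } else {
    if (length(obs) && !all(obs %in% c(0, 1, 2)))
      stop("genotype values must be 0, 1, 2 or missing")
  }
  P <- length(snp_ids)
  coded_allele <- if (is.null(coded_allele)) rep(NA_character_, P)
                  else as.character(coded_allele)
  other_allele <- if (is.null(other_allele)) rep(NA_character_, P)
                  else as.character(other_allele)
  if (length(coded_allele) != P || length(other_allele) != P)
    stop("allele annotations must have one entry per SNP")
  bad <- !is.na(coded_allele) & !is.na(other_allele) &
    coded_allele == other_allele
  if (any(bad))
    stop("coded and other allele identical for SNP(s): ",
         paste(snp_ids[bad], collapse = ", "))
  dimnames(values) <- list(sample_ids, snp_ids)
  structure(
    list(values = values,
         sample_ids = as.character(sample_ids),
         snp_ids = as.character(snp_ids),
         coded_allele = coded_allele,
         other_allele = other_allele,
         dosage = isTRUE(dosage)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n_miss <- sum(is.na(x$values))
  cat(sprintf(
    "genotype_matrix: %d samples x %d SNPs (%s; %d missing calls, %.2f%%)\n",
    nrow(x$values), ncol(x$values),
    if (x$dosage) "dosage" else "additive 0/1/2",
    n_miss, 100 * n_miss / max(1, length(x$values))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Subset a genotype matrix by sample and/or SNP index
#'
#' @param G a [genotype_matrix()].
#' @param samples integer or logical index over samples (rows).
#' @param snps integer or logical index over SNPs (columns).
#' @return The subsetted `genotype_matrix`.
#' @export
subset_genotypes <- function(G, samples = NULL, snps = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  si <- if (is.null(samples)) seq_along(G$sample_ids) else samples
  vi <- if (is.null(snps)) seq_along(G$snp_ids) else snps
  genotype_matrix(G$values[si, vi, drop = FALSE],
                  G$sample_ids[si], G$snp_ids[vi],
                  G$coded_allele[vi], G$other_allele[vi],
                  dosage = G$dosage)
}
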