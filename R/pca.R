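# PCA on genotype matrices: fitting, SNP-weight export, projection.
#
# The decomposition is of the sample covariance of the mean-centered
# genotype matrix Y (N samples x P SNPs): C = t(Y) %*% Y / (N - 1).
# The top-k eigenvectors of C are the "SNP weights": together with the
# training column means they let any later study place its samples into
# the same score space (scores = centered genotypes %*% loadings),
# provided the same marker panel is used. Weights are most reliable
# when trained on many more samples than SNPs (N >> P), which keeps the
# eigenvector estimates stable and avoids variance shrinkage when they
# are reused on new data.

#' SNP-weight object
#'
#' @param snp_ids character vector of P SNP IDs, in panel order.
#' @param loadings P x k matrix of eigenvector loadings (unit columns).
#' @param training_means length-P vector of per-SNP training means.
#' @param eigenvalues length-k nonincreasing eigenvalues.
#' @param n_training number of training samples.
#' @param ref_allele,alt_allele optional per-SNP allele annotations
#'   carried through to the weights file.
#' @return An object of class `snp_weights`.
#' @export
snp_weights <- function(snp_ids, loadings, training_means, eigenvalues,
                        n_training, ref_allele = NULL, alt_allele = NULL) {
  loadings <- as.matrix(loadings)
  P <- length(snp_ids)
  k <- ncol(loadings)
  if (nrow(loadings) != P)
    stop("loadings must have one row per SNP")
  if (length(training_means) != P)
    stop("training_means must have one entry per SNP")
  if (length(eigenvalues) != k)
    stop("eigenvalues must have one entry per component")
  if (any(diff(eigenvalues) > 1e-8))
    stop("eigenvalues must be nonincreasing")
  if (any(eigenvalues < -1e-8))
    stop("eigenvalues must be nonnegative (within tolerance)")
  norms <- sqrt(colSums(loadings^2))
  if (any(abs(norms - 1) > 1e-9))
    stop("loading columns must have unit Euclidean norm")
  dimnames(loadings) <- list(snp_ids, paste0("pc", seq_len(k)))
  structure(
    list(snp_ids = as.character(snp_ids),
         loadings = loadings,
         training_means = as.numeric(training_means),
         eigenvalues = as.numeric(eigenvalues),
         k = k,
         n_training = as.integer(n_training),
         ref_allele = if (is.null(ref_allele)) rep(NA_character_, P)
                      else as.character(ref_allele),
         alt_allele = if (is.null(alt_allele)) rep(NA_character_, P)
                      else as.character(alt_allele)),
    class = "snp_weights")
}

#' @export
print.snp_weights <- function(x, ...) {
  cat(sprintf("snp_weights: %d SNPs x %d components (trained on %d samples)\n",
              length(x$snp_ids), x$k, x$n_training))
  cat("eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  invisible(x)
}

#' PC score matrix
#'
#' @param sample_ids character vector of N sample IDs.
#' @param scores N x k numeric matrix of PC scores.
#' @return An object of class `score_matrix`.
#' @export
score_matrix <- function(sample_ids, scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) != length(sample_ids))
    stop("sample_ids length does not match score row count")
  if (any(!is.finite(scores)))
    stop("scores must be finite")
  dimnames(scores) <- list(sample_ids, paste0("pc", seq_len(ncol(scores))))
  structure(list(sample_ids = as.character(sample_ids), scores = scores),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d samples x %d components\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

# flip each column so its largest-|entry| element is positive
# (first such index on ties); returns the sign vector applied
canonical_signs <- function(loadings) {
  vapply(seq_len(ncol(loadings)), function(j) {
    col <- loadings[, j]
    i <- which.max(abs(col))
    if (col[i] < 0) -1 else 1
  }, numeric(1))
}

#' Canonicalize eigenvector signs
#'
#' Eigenvector signs are mathematically arbitrary and differ across
#' linear-algebra backends. Each loading column is flipped, if needed,
#' so that its largest-absolute-value entry is positive (ties broken by
#' the lowest SNP index). Idempotent; makes weight files reproducible.
#'
#' @param weights a [snp_weights()] object.
#' @return The canonicalized `snp_weights`.
#' @export
sign_canonicalize <- function(weights) {
  stopifnot(inherits(weights, "snp_weights"))
  s <- canonical_signs(weights$loadings)
  weights$loadings <- sweep(weights$loadings, 2, s, "*")
  weights
}

#' Fit PCA on a genotype matrix
#'
#' Computes per-SNP means, mean-centers, and extracts the top-k
#' components either by eigendecomposition of the P x P covariance
#' matrix (efficient when N > P) or by singular value decomposition of
#' the centered matrix itself (preferred when N <= P, or for very large
#' problems). Both routes yield identical weights after sign
#' canonicalization, which is applied before scores are computed.
#'
#' @param G a [genotype_matrix()] with no missing values (impute first).
#' @param k number of components; use populations - 1 (2 for a
#'   three-population analysis, 3 for four).
#' @param method `"auto"` (covariance eigendecomposition when N > P,
#'   otherwise SVD), `"covariance_eigen"`, or `"svd"`.
#' @return A list with elements `weights` ([snp_weights()]) and
#'   `scores` ([score_matrix()], the training scores).
#' @export
fit_pca <- function(G, k, method = c("auto", "covariance_eigen", "svd")) {
  stopifnot(inherits(G, "genotype_matrix"))
  method <- match.arg(method)
  X <- G$values
  if (anyNA(X)) stop("genotype matrix has missing values; impute first")
  N <- nrow(X); P <- ncol(X)
  if (N < 2) stop("PCA requires at least 2 samples")
  if (k < 1 || k > min(N - 1, P))
    stop("k = ", k, " exceeds min(N - 1, P) = ", min(N - 1, P))
  if (method == "auto") method <- if (N > P) "covariance_eigen" else "svd"

  means <- colMeans(X)
  Y <- sweep(X, 2, means)
  if (method == "covariance_eigen") {
    C <- crossprod(Y) / (N - 1)
    ee <- eigen(C, symmetric = TRUE)
    loadings <- ee$vectors[, seq_len(k), drop = FALSE]
    eigenvalues <- ee$values[seq_len(k)]
  } else {
    sv <- svd(Y, nu = 0, nv = k)
    loadings <- sv$v
    eigenvalues <- (sv$d[seq_len(k)]^2) / (N - 1)
  }
  loadings <- sweep(loadings, 2, canonical_signs(loadings), "*")
  w <- snp_weights(G$snp_ids, loadings, means, pmax(eigenvalues, 0),
                   n_training = N,
                   ref_allele = G$coded_allele, alt_allele = G$other_allele)
  list(weights = w, scores = score_matrix(G$sample_ids, Y %*% w$loadings))
}

#' Project samples into an existing score space
#'
#' Multiplies mean-centered genotypes by stored SNP-weight loadings.
#' With `centering = "training_means"` (the default) the stored training
#' column means are subtracted, so the resulting scores live in the same
#' coordinate system as the training scores and reference centroids.
#' With `centering = "own_means"` the new data are centered by their own
#' column means; this makes each projected batch internally
#' mean-centered but shifts it relative to the training score space by a
#' constant row offset equal to (training means - own means) x loadings.
#'
#' @param G_new a [genotype_matrix()], harmonized and imputed, with
#'   exactly the weights' SNP set (any column order).
#' @param weights a [snp_weights()] object.
#' @param centering `"training_means"` or `"own_means"`.
#' @return A [score_matrix()].
#' @export
project_scores <- function(G_new, weights,
                           centering = c("training_means", "own_means")) {
  stopifnot(inherits(G_new, "genotype_matrix"),
            inherits(weights, "snp_weights"))
  centering <- match.arg(centering)
  idx <- match(weights$snp_ids, G_new$snp_ids)
  missing_snps <- weights$snp_ids[is.na(idx)]
  extra_snps <- setdiff(G_new$snp_ids, weights$snp_ids)
  if (length(missing_snps) || length(extra_snps))
    stop("SNP set mismatch with weights; missing: ",
         paste(utils::head(missing_snps, 5), collapse = ", "),
         if (length(missing_snps) > 5) ", ...",
         "; extra: ", paste(utils::head(extra_snps, 5), collapse = ", "),
         if (length(extra_snps) > 5) ", ...")
  X <- G_new$values[, idx, drop = FALSE]
  if (anyNA(X)) stop("genotype matrix has missing values; impute first")
  mu <- if (centering == "training_means") weights$training_means
        else colMeans(X)
  score_matrix(G_new$sample_ids, sweep(X, 2, mu) %*% weights$loadings)
}

#' Write SNP weights to a portable TSV file
#'
#' One row per SNP with columns `snp_id`, `ref_allele`, `alt_allele`,
#' `training_mean`, `pc1..pck`; comment header lines record k, the
#' training sample count and the eigenvalues. Deterministic output.
#'
#' @param weights a [snp_weights()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_snp_weights <- function(weights, path) {
  stopifnot(inherits(weights, "snp_weights"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    "# popsimplex snp_weights v1",
    paste0("# k=", weights$k),
    paste0("# n_training=", weights$n_training),
    paste0("# eigenvalues=", paste(fmt_num(weights$eigenvalues),
                                   collapse = ","))), con)
  writeLines(paste(c("snp_id", "ref_allele", "alt_allele", "training_mean",
                     paste0("pc", seq_len(weights$k))), collapse = "\t"), con)
  ra <- weights$ref_allele; ra[is.na(ra)] <- "NA"
  aa <- weights$alt_allele; aa[is.na(aa)] <- "NA"
  for (i in seq_along(weights$snp_ids)) {
    writeLines(paste(c(weights$snp_ids[i], ra[i], aa[i],
                       fmt_num(weights$training_means[i]),
                       fmt_num(weights$loadings[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a SNP-weights file written by [write_snp_weights()]
#'
#' @param path weights TSV path.
#' @return A [snp_weights()] object.
#' @export
read_snp_weights <- function(path) {
  if (!file.exists(path)) stop("weights file not found: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get_field <- function(name) {
    m <- hdr[startsWith(hdr, paste0("# ", name, "="))]
    if (length(m) != 1) stop("weights file missing header field: ", name)
    sub(paste0("# ", name, "="), "", m, fixed = TRUE)
  }
  k <- as.integer(get_field("k"))
  n_training <- as.integer(get_field("n_training"))
  eigenvalues <- as.numeric(strsplit(get_field("eigenvalues"), ",")[[1]])
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.delim(text = body, header = TRUE, sep = "\t",
                           colClasses = "character")
  loadings <- matrix(as.numeric(as.matrix(tab[paste0("pc", seq_len(k))])),
                     nrow = nrow(tab))
  ra <- tab$ref_allele; ra[ra == "NA"] <- NA_character_
  aa <- tab$alt_allele; aa[aa == "NA"] <- NA_character_
  snp_weights(tab$snp_id, loadings, as.numeric(tab$training_mean),
              eigenvalues, n_training, ra, aa)
}

#' Write PC scores as TSV
#'
#' @param scores a [score_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "score_matrix"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  k <- ncol(scores$scores)
  writeLines(paste(c("sample_id", paste0("pc", seq_len(k))),
                   collapse = "\t"), con)
  for (i in seq_along(scores$sample_ids)) {
    writeLines(paste(c(scores$sample_ids[i], fmt_num(scores$scores[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a PC score TSV written by [write_scores()]
#'
#' @param path score TSV path.
#' @return A [score_matrix()].
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("score file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  pcs <- grep("^pc[0-9]+$", names(tab), value = TRUE)
  mat <- matrix(as.numeric(as.matrix(tab[pcs])), nrow = nrow(tab))
  score_matrix(tab$sample_id, mat)
}
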