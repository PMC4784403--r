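# Two-step workflow orchestration:
#   step 1 (run_scoring)  genotypes -> QC -> harmonize -> impute ->
#                         project on SNP weights -> score TSV
#   step 2 (run_ancestry) scores + reference geometry -> ancestry.out
#
# ancestry.out is a headered TSV with, for three populations, exactly
# six columns: sample_id, pc1, pc2, then one ancestry-proportion column
# per population; for four populations, eight columns (three scores,
# four proportions). Proportions in every row sum to 1.

#' Assemble a pipeline run configuration
#'
#' @param genotype path to the genotype file.
#' @param panel path to the reference-allele panel TSV.
#' @param out_dir output directory (created if needed).
#' @param dialect genotype dialect, `"tsv"` or `"plink_text"`.
#' @param weights path to an existing SNP-weights file, or `NULL` to
#'   fit PCA from scratch on the input genotypes.
#' @param fit_k component count when fitting from scratch; defaults to
#'   `n_populations - 1`.
#' @param n_populations 3 or 4.
#' @param reference_mode how the ancestry simplex is obtained:
#'   `"shipped_centroids"` (a centroid TSV), `"labeled_reference_samples"`
#'   (a sample-to-population label TSV; centroids are the labeled
#'   samples' score means) or `"self_derived"` (cluster the study
#'   scores themselves; sensible only for large studies that clearly
#'   contain all populations).
#' @param centroids_file,labels_file paths backing the first two modes.
#' @param populations optional population name order (and the names
#'   given to self-derived clusters).
#' @param max_sample_missing,max_snp_missing QC thresholds for
#'   [filter_by_missing_rate()].
#' @param centering projection centering, `"training_means"` or
#'   `"own_means"` (see [project_scores()]).
#' @param plot write a PC1/PC2 scatter PNG during scoring.
#' @param seed integer seed recorded in logs/manifests (the pipeline
#'   itself is deterministic; the seed matters for simulation-backed
#'   inputs).
#' @return A list of class `run_config`.
#' @export
run_config <- function(genotype, panel, out_dir,
                       dialect = c("tsv", "plink_text"),
                       weights = NULL, fit_k = NULL,
                       n_populations = 3,
                       reference_mode = c("shipped_centroids",
                                          "labeled_reference_samples",
                                          "self_derived"),
                       centroids_file = NULL, labels_file = NULL,
                       populations = NULL,
                       max_sample_missing = 0.05, max_snp_missing = 0.05,
                       centering = c("training_means", "own_means"),
                       plot = FALSE, seed = NULL) {
  dialect <- match.arg(dialect)
  reference_mode <- match.arg(reference_mode)
  centering <- match.arg(centering)
  if (!(n_populations %in% c(3, 4)))
    stop("n_populations must be 3 or 4")
  structure(list(
    genotype = genotype, panel = panel, out_dir = out_dir,
    dialect = dialect, weights = weights, fit_k = fit_k,
    n_populations = n_populations, reference_mode = reference_mode,
    centroids_file = centroids_file, labels_file = labels_file,
    populations = populations,
    max_sample_missing = max_sample_missing,
    max_snp_missing = max_snp_missing,
    centering = centering, plot = isTRUE(plot), seed = seed),
    class = "run_config")
}

log_line <- function(log_path, ...) {
  msg <- paste0(...)
  cat(msg, "\n", sep = "", file = log_path, append = TRUE)
  message(msg)
}

# extend G to exactly the weights' SNP set: absent panel SNPs are
# filled with their stored training mean (a whole-column imputation);
# SNPs not in the weights are dropped
align_to_weights <- function(G, weights, log_path = NULL) {
  drop <- setdiff(G$snp_ids, weights$snp_ids)
  if (length(drop)) {
    G <- subset_genotypes(G, snps = which(!(G$snp_ids %in% drop)))
    if (!is.null(log_path))
      log_line(log_path, "dropped ", length(drop),
               " SNP(s) absent from the weights")
  }
  absent <- setdiff(weights$snp_ids, G$snp_ids)
  if (length(absent)) {
    idx <- match(absent, weights$snp_ids)
    tm <- weights$training_means[idx]
    if (anyNA(tm))
      stop("panel SNP(s) absent from input and lacking a training mean: ",
           paste(utils::head(absent[is.na(tm)], 10), collapse = ", "))
    fill <- matrix(rep(tm, each = nrow(G$values)),
                   nrow = nrow(G$values))
    values <- cbind(G$values, fill)
    G <- genotype_matrix(values, G$sample_ids, c(G$snp_ids, absent),
                         c(G$coded_allele, weights$ref_allele[idx]),
                         c(G$other_allele, weights$alt_allele[idx]),
                         dosage = TRUE)
    if (!is.null(log_path))
      log_line(log_path, "imputed ", length(absent),
               " absent panel SNP column(s) from training means")
  }
  ord <- match(weights$snp_ids, G$snp_ids)
  subset_genotypes(G, snps = ord)
}

#' Step 1: compute PC scores from genotypes
#'
#' Reads and harmonizes the genotypes, applies missing-rate QC and
#' imputation, loads (or fits) SNP weights, projects, and writes
#' `scores.tsv` (plus `weights.tsv` when fitting, and an optional
#' `scores.png` scatter of the first two components). Per-stage sample
#' and SNP attrition counts go to `scoring.log`.
#'
#' @param config a [run_config()].
#' @return The [score_matrix()], invisibly; attribute `weights` holds
#'   the [snp_weights()] used.
#' @export
run_scoring <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "scoring.log")
  cat("", file = log_path)

  panel <- read_allele_panel(config$panel)
  G <- read_additive_genotypes(config$genotype, config$dialect)
  log_line(log_path, "read ", nrow(G$values), " samples x ",
           ncol(G$values), " SNPs (", sum(is.na(G$values)),
           " missing calls)")

  G <- harmonize_alleles(G, panel)
  log_line(log_path, "harmonized ", ncol(G$values), " SNPs to panel coding")

  n0 <- nrow(G$values); p0 <- ncol(G$values)
  G <- filter_by_missing_rate(G, config$max_sample_missing,
                              config$max_snp_missing)
  log_line(log_path, "QC removed ", n0 - nrow(G$values), " sample(s) and ",
           p0 - ncol(G$values), " SNP(s) by missing rate")
  G <- impute_missing(G, panel)
  log_line(log_path, "imputed ", attr(G, "cells_imputed"), " missing cell(s)")

  if (!is.null(config$weights)) {
    w <- read_snp_weights(config$weights)
    G <- align_to_weights(G, w, log_path)
    scores <- project_scores(G, w, config$centering)
    log_line(log_path, "projected on stored weights (k=", w$k, ", centering=",
             config$centering, ")")
  } else {
    k <- if (is.null(config$fit_k)) config$n_populations - 1 else config$fit_k
    fit <- fit_pca(G, k)
    w <- fit$weights
    scores <- fit$scores
    write_snp_weights(w, file.path(config$out_dir, "weights.tsv"))
    log_line(log_path, "fitted PCA from scratch (k=", k, ", N=",
             nrow(G$values), ", P=", ncol(G$values), ")")
  }

  write_scores(scores, file.path(config$out_dir, "scores.tsv"))
  if (config$plot) plot_scores(scores, file.path(config$out_dir, "scores.png"))
  log_line(log_path, "wrote scores for ", length(scores$sample_ids),
           " samples")
  attr(scores, "weights") <- w
  invisible(scores)
}

plot_scores <- function(scores, path, labels = NULL) {
  grDevices::png(path, width = 700, height = 700)
  on.exit(grDevices::dev.off())
  col <- if (is.null(labels)) "grey30"
         else as.integer(factor(labels)) + 1L
  graphics::plot(scores$scores[, 1], scores$scores[, 2], col = col,
                 pch = 20, xlab = "PC1", ylab = "PC2",
                 main = "PC scores")
  if (!is.null(labels))
    graphics::legend("topright", legend = levels(factor(labels)),
                     col = seq_along(levels(factor(labels))) + 1L, pch = 20)
  invisible(path)
}

#' Read a sample-to-population label TSV
#'
#' Columns `sample_id` and `population`; samples missing from the file
#' are treated as unlabeled.
#'
#' @param path label TSV path.
#' @return Data.frame with `sample_id` and `population`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (!all(c("sample_id", "population") %in% names(tab)))
    stop("label file must have columns sample_id, population")
  tab
}

# deterministic cluster labeling: farthest-point initialization on the
# first k dimensions, then k-means refinement; clusters are named (or
# matched to supplied names) in order of their first-coordinate mean
derive_cluster_labels <- function(scores, m, populations = NULL) {
  X <- scores$scores[, seq_len(m - 1), drop = FALSE]
  n <- nrow(X)
  if (n < m) stop("self-derivation needs at least ", m, " samples")
  centers <- matrix(NA_real_, m, ncol(X))
  d0 <- rowSums(sweep(X, 2, colMeans(X))^2)
  centers[1, ] <- X[which.max(d0), ]
  mind <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in 2:m) {
    centers[j, ] <- X[which.max(mind), ]
    mind <- pmin(mind, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  km <- stats::kmeans(X, centers = centers, iter.max = 100)
  ord <- order(km$centers[, 1], km$centers[, ncol(X)])
  rank_of <- match(seq_len(m), ord)
  names_out <- if (is.null(populations)) paste0("cluster", seq_len(m))
               else populations
  names_out[rank_of[km$cluster]]
}

#' Step 2: infer ancestry proportions from scores
#'
#' Resolves the reference geometry according to the configured mode,
#' estimates per-sample proportions, and writes `ancestry.out` (TSV:
#' `sample_id`, the k score columns, then one proportion column per
#' population — six columns in total for three populations, eight for
#' four). Region labels are returned but not written to ancestry.out.
#'
#' @param config a [run_config()].
#' @param scores a [score_matrix()]; defaults to reading
#'   `scores.tsv` from the configured output directory.
#' @return Data.frame of estimates (with `region`), invisibly;
#'   attribute `geometry` holds the [reference_geometry()] used.
#' @export
run_ancestry <- function(config, scores = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(scores))
    scores <- read_scores(file.path(config$out_dir, "scores.tsv"))
  m <- config$n_populations
  k <- m - 1
  if (ncol(scores$scores) < k)
    stop("scores have ", ncol(scores$scores), " components; need ", k)

  if (config$reference_mode == "shipped_centroids" &&
      is.null(config$centroids_file))
    stop("shipped_centroids mode requires centroids_file")
  if (config$reference_mode == "labeled_reference_samples" &&
      is.null(config$labels_file))
    stop("labeled_reference_samples mode requires labels_file")
  geometry <- switch(config$reference_mode,
    shipped_centroids = read_geometry(config$centroids_file),
    labeled_reference_samples = {
      lab_tab <- read_labels(config$labels_file)
      labels <- lab_tab$population[match(scores$sample_ids,
                                         lab_tab$sample_id)]
      if (all(is.na(labels)))
        stop("no labeled samples match the score matrix")
      compute_centroids(scores, labels, config$populations)
    },
    self_derived = {
      labels <- derive_cluster_labels(scores, m, config$populations)
      compute_centroids(scores, labels, config$populations)
    })
  if (length(geometry$labels) != m)
    stop("geometry has ", length(geometry$labels),
         " populations; config expects ", m)

  est <- estimate_ancestry_all(scores, geometry)
  out_path <- file.path(config$out_dir, "ancestry.out")
  con <- file(out_path, open = "wb")
  writeLines(paste(c("sample_id", paste0("pc", seq_len(k)),
                     geometry$labels), collapse = "\t"), con)
  for (i in seq_len(nrow(est))) {
    writeLines(paste(c(est$sample_id[i],
                       fmt_num(scores$scores[i, seq_len(k)]),
                       fmt_num(unlist(est[i, geometry$labels]))),
                     collapse = "\t"), con)
  }
  close(con)
  attr(est, "geometry") <- geometry
  invisible(est)
}
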