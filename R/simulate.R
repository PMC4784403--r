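# Synthetic genotype data: Balding-Nichols differentiated populations
# with optional admixture.
#
# The generator emulates the study setting this tool targets: a panel
# of unlinked ancestry-informative markers with common alleles, a few
# hundred labeled reference individuals per continental population,
# and study individuals of unknown, possibly admixed, ancestry. Allele
# frequencies per population are drawn around a shared ancestral
# frequency with Beta dispersion parameterized by FST
# (Balding-Nichols); genotypes are binomial in those frequencies, and
# an admixed individual draws each of its two allele copies from a
# population chosen by its true admixture vector q.

#' Simulation specification
#'
#' @param n_pops number of populations, 3 or 4.
#' @param n_snps panel size P.
#' @param n_per_pop reference samples per population (scalar or
#'   length-`n_pops` vector).
#' @param n_admixed number of admixed study individuals.
#' @param fst differentiation parameter in (0, 1); continental human
#'   populations are commonly near 0.1-0.15.
#' @param dirichlet_alpha Dirichlet concentration for admixture
#'   proportions (scalar or length-`n_pops`); 1 gives uniform draws
#'   over the simplex.
#' @param missing_rate per-cell missing-call probability.
#' @param seed integer seed (mandatory; all outputs are reproducible
#'   from it).
#' @param population_names population labels; defaults to continental
#'   names (European, African, Asian, NativeAmerican).
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_pops = 3, n_snps = 1000, n_per_pop = 200,
                            n_admixed = 0, fst = 0.15,
                            dirichlet_alpha = 1, missing_rate = 0,
                            seed, population_names = NULL) {
  if (!(n_pops %in% c(3, 4))) stop("n_pops must be 3 or 4")
  if (fst <= 0 || fst >= 1) stop("fst must lie in (0, 1)")
  if (length(n_per_pop) == 1) n_per_pop <- rep(n_per_pop, n_pops)
  if (length(n_per_pop) != n_pops || any(n_per_pop < 1))
    stop("n_per_pop must be positive, one per population")
  if (n_snps < 1) stop("n_snps must be positive")
  if (n_admixed < 0) stop("n_admixed must be nonnegative")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (length(dirichlet_alpha) == 1)
    dirichlet_alpha <- rep(dirichlet_alpha, n_pops)
  if (length(dirichlet_alpha) != n_pops || any(dirichlet_alpha <= 0))
    stop("dirichlet_alpha must be positive, one per population")
  if (is.null(population_names))
    population_names <- c("European", "African", "Asian",
                          "NativeAmerican")[seq_len(n_pops)]
  if (length(population_names) != n_pops)
    stop("population_names must have one entry per population")
  structure(list(n_pops = n_pops, n_snps = as.integer(n_snps),
                 n_per_pop = as.integer(n_per_pop),
                 n_admixed = as.integer(n_admixed), fst = fst,
                 dirichlet_alpha = dirichlet_alpha,
                 missing_rate = missing_rate, seed = as.integer(seed),
                 population_names = population_names),
            class = "simulation_spec")
}

#' Draw per-population allele frequencies (Balding-Nichols)
#'
#' Ancestral frequencies are uniform on (0.1, 0.9) — bounded away from
#' fixation to mimic common-variant ancestry-informative panels — and
#' each population's frequency is Beta(p(1-F)/F, (1-p)(1-F)/F) around
#' ancestral p with F = `fst`.
#'
#' @param spec a [simulation_spec()].
#' @return `n_pops` x `n_snps` matrix of allele frequencies, attribute
#'   `ancestral` holding the ancestral frequencies.
#' @export
simulate_allele_freqs <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  P <- spec$n_snps
  p <- stats::runif(P, 0.1, 0.9)
  F <- spec$fst
  a <- p * (1 - F) / F
  b <- (1 - p) * (1 - F) / F
  freqs <- t(vapply(seq_len(spec$n_pops),
                    function(j) stats::rbeta(P, a, b),
                    numeric(P)))
  dimnames(freqs) <- list(spec$population_names,
                          sprintf("snp%05d", seq_len(P)))
  attr(freqs, "ancestral") <- p
  freqs
}

# one admixed genotype vector: each of the two allele copies at each
# SNP picks its source population according to q, then is Bernoulli in
# that population's allele frequency
draw_admixed <- function(q, freqs) {
  P <- ncol(freqs)
  m <- nrow(freqs)
  copies <- numeric(P)
  for (cp in 1:2) {
    src <- sample.int(m, P, replace = TRUE, prob = q)
    copies <- copies + stats::rbinom(P, 1, freqs[cbind(src, seq_len(P))])
  }
  copies
}

#' Draw genotypes given population allele frequencies
#'
#' Reference individuals from population j have genotype ~
#' Binomial(2, f_j) per SNP. Admixed individuals draw a true admixture
#' vector q ~ Dirichlet(alpha); each of their two allele copies at each
#' SNP picks a source population according to q, then is Bernoulli in
#' that population's frequency. Genotype draws are seeded at
#' `spec$seed + 1` so frequency and genotype stages are independently
#' reproducible.
#'
#' @param freqs frequency matrix from [simulate_allele_freqs()].
#' @param spec the same [simulation_spec()].
#' @return A list: `genotypes` ([genotype_matrix()]), `truth`
#'   (data.frame `sample_id`, `population` — `"admixed"` for admixed
#'   individuals — and true proportions `q_<pop>`), and `freqs`.
#' @export
simulate_genotypes <- function(freqs, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!all(dim(freqs) == c(spec$n_pops, spec$n_snps)))
    stop("frequency matrix does not match spec dimensions")
  set.seed(spec$seed + 1L)
  m <- spec$n_pops
  P <- spec$n_snps
  n_ref <- sum(spec$n_per_pop)
  n <- n_ref + spec$n_admixed

  values <- matrix(NA_real_, n, P)
  sample_ids <- character(n)
  pop_lab <- character(n)
  qmat <- matrix(0, n, m, dimnames = list(NULL, spec$population_names))

  row <- 0L
  for (j in seq_len(m)) {
    for (i in seq_len(spec$n_per_pop[j])) {
      row <- row + 1L
      values[row, ] <- stats::rbinom(P, 2, freqs[j, ])
      sample_ids[row] <- sprintf("%s_%04d", spec$population_names[j], i)
      pop_lab[row] <- spec$population_names[j]
      qmat[row, j] <- 1
    }
  }
  if (spec$n_admixed > 0) {
    for (i in seq_len(spec$n_admixed)) {
      row <- row + 1L
      g <- stats::rgamma(m, shape = spec$dirichlet_alpha)
      q <- g / sum(g)
      values[row, ] <- draw_admixed(q, freqs)
      sample_ids[row] <- sprintf("ADM_%04d", i)
      pop_lab[row] <- "admixed"
      qmat[row, ] <- q
    }
  }
  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(n * P) < spec$missing_rate, n, P)
    values[mask] <- NA_real_
  }
  G <- genotype_matrix(values, sample_ids, colnames(freqs),
                       coded_allele = rep("A", P),
                       other_allele = rep("G", P))
  truth <- data.frame(sample_id = sample_ids, population = pop_lab,
                      stringsAsFactors = FALSE)
  qdf <- as.data.frame(qmat)
  names(qdf) <- paste0("q_", spec$population_names)
  list(genotypes = G, truth = cbind(truth, qdf), freqs = freqs)
}

#' Run a full simulation and optionally write fixture files
#'
#' Convenience wrapper: draws frequencies and genotypes, and when
#' `dir` is given writes `genotypes.tsv`, `panel.tsv` (synthetic
#' ref/alt alleles A/G, training means = 2 x mean allele frequency
#' over populations), `labels.tsv` (reference samples only) and
#' `truth.tsv`.
#'
#' @param spec a [simulation_spec()].
#' @param dir optional output directory for fixture files.
#' @return The [simulate_genotypes()] result, with `spec` attached.
#' @export
simulate_study <- function(spec, dir = NULL) {
  freqs <- simulate_allele_freqs(spec)
  sim <- simulate_genotypes(freqs, spec)
  sim$spec <- spec
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_additive_genotypes(sim$genotypes, file.path(dir, "genotypes.tsv"))
    panel <- validate_allele_panel(data.frame(
      snp_id = sim$genotypes$snp_ids,
      ref_allele = "A", alt_allele = "G",
      training_mean = 2 * colMeans(freqs),
      stringsAsFactors = FALSE))
    write_allele_panel(panel, file.path(dir, "panel.tsv"))
    ref <- sim$truth$population != "admixed"
    con <- file(file.path(dir, "labels.tsv"), open = "wb")
    writeLines("sample_id\tpopulation", con)
    writeLines(paste(sim$truth$sample_id[ref], sim$truth$population[ref],
                     sep = "\t"), con)
    close(con)
    con <- file(file.path(dir, "truth.tsv"), open = "wb")
    qcols <- grep("^q_", names(sim$truth), value = TRUE)
    writeLines(paste(c("sample_id", "population", qcols), collapse = "\t"),
               con)
    for (i in seq_len(nrow(sim$truth)))
      writeLines(paste(c(sim$truth$sample_id[i], sim$truth$population[i],
                         fmt_num(unlist(sim$truth[i, qcols]))),
                       collapse = "\t"), con)
    close(con)
  }
  sim
}
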