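# Independent oracle implementations used to cross-check the package.
# These deliberately use different geometric primitives than the
# implementation (cross products and Pythagoras instead of affine
# projectors, direct distance ratios instead of inverse-distance
# sums), so agreement is a genuine two-route check.

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

embed3 <- function(v) if (length(v) == 2) c(v, 0) else v

# two-way split along an edge: direct ratio form L2 / (L1 + L2)
oracle_edge_prop <- function(point, cA, cB) {
  u <- cB - cA
  t_ <- sum((point - cA) * u) / sum(u * u)
  foot <- cA + t_ * u
  L1 <- sqrt(sum((foot - cA)^2))
  L2 <- sqrt(sum((foot - cB)^2))
  c(L2, L1) / (L1 + L2)
}

# three-way blend: H from the cross-product area formula, foot-to-
# endpoint distances from Pythagoras, shares as direct ratios
oracle_triangle_eq4 <- function(point, tri) {
  sides <- list(c(1, 2), c(1, 3), c(2, 3))
  H <- numeric(3)
  share <- matrix(0, 3, 3)   # share[s, pop]
  for (s in seq_along(sides)) {
    a <- tri[sides[[s]][1], ]; b <- tri[sides[[s]][2], ]
    ab <- sqrt(sum((b - a)^2))
    H[s] <- sqrt(sum(cross3(embed3(b - a), embed3(point - a))^2)) / ab
    La <- sqrt(max(sum((point - a)^2) - H[s]^2, 0))
    Lb <- sqrt(max(sum((point - b)^2) - H[s]^2, 0))
    share[s, sides[[s]]] <- c(Lb, La) / (La + Lb)
  }
  w <- 1 / H
  colSums(share * w) / sum(w)
}

# tetrahedron interior: explicit plane normals, orthogonal projection,
# Eq-4 on each face, zero-padded average
oracle_tetra_interior <- function(point, tet) {
  faces <- utils::combn(4, 3)
  pr <- numeric(4)
  for (j in seq_len(ncol(faces))) {
    f <- faces[, j]
    a <- tet[f[1], ]
    n <- cross3(tet[f[2], ] - a, tet[f[3], ] - a)
    n <- n / sqrt(sum(n^2))
    proj <- point - sum((point - a) * n) * n
    pr[f] <- pr[f] + oracle_triangle_eq4(proj, tet[f, , drop = FALSE])
  }
  pr / 4
}

# exact transcription of the perpendicular-lines partition of the
# plane around a triangle: vertex wedges, edge slabs, interior.
# Returns the region plus the smallest decision margin, so callers can
# skip points within numerical reach of a boundary.
oracle_triangle_region <- function(point, tri) {
  cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]
  margins <- c()
  for (i in 1:3) {
    others <- setdiff(1:3, i)
    d1 <- sum((point - tri[i, ]) * (tri[others[1], ] - tri[i, ]))
    d2 <- sum((point - tri[i, ]) * (tri[others[2], ] - tri[i, ]))
    margins <- c(margins, abs(d1), abs(d2))
    if (d1 <= 0 && d2 <= 0)
      return(list(region = paste0("vertex:", i), margin = min(abs(d1), abs(d2))))
  }
  edges <- list(c(1, 2), c(1, 3), c(2, 3))
  for (e in edges) {
    k <- setdiff(1:3, e)
    u <- tri[e[2], ] - tri[e[1], ]
    d_in1 <- sum((point - tri[e[1], ]) * u)
    d_in2 <- sum((point - tri[e[2], ]) * (-u))
    s_point <- cross2(u, point - tri[e[1], ])
    s_opp <- cross2(u, tri[k, ] - tri[e[1], ])
    margins <- c(margins, abs(s_point))
    if (d_in1 >= 0 && d_in2 >= 0 && s_point * s_opp < 0)
      return(list(region = paste0("edge:", e[1], ",", e[2]),
                  margin = min(abs(s_point), abs(d_in1), abs(d_in2))))
  }
  list(region = "interior", margin = min(margins))
}

# non-degenerate random geometries for property tests
random_geometry <- function(m, seed, scale = 5) {
  set.seed(seed)
  labels <- LETTERS[seq_len(m)]
  repeat {
    cen <- matrix(stats::rnorm(m * (m - 1), sd = scale), m, m - 1)
    ok <- tryCatch({
      reference_geometry(cen, labels)
    }, error = function(e) NULL)
    if (!is.null(ok)) return(ok)
  }
}

# small hand-coded genotype matrix fixture
tiny_genotypes <- function() {
  genotype_matrix(rbind(c(0, 1, 2, 0),
                        c(1, NA, 2, 1),
                        c(2, 0, NA, 2)),
                  c("s1", "s2", "s3"),
                  c("rs1", "rs2", "rs3", "rs4"),
                  coded_allele = c("A", "C", "G", "T"),
                  other_allele = c("G", "T", "A", "C"))
}

# run the Eq-3 / Eq-4 queries through the arbitrary-precision python
# oracle (mpmath, 40 significant digits); rows of `queries` are lists
# with fields mode ("eq3"/"eq4"), point, and the relevant centroids
run_mpmath_oracle <- function(queries) {
  infile <- tempfile(fileext = ".tsv")
  outfile <- tempfile(fileext = ".tsv")
  lines <- vapply(queries, function(q) {
    coords <- c(q$point, t(q$centroids))
    paste(c(q$mode, length(q$point),
            formatC(coords, digits = 17, format = "g")), collapse = "\t")
  }, character(1))
  writeLines(lines, infile)
  script <- test_path("oracle_inverse_distance.py")
  status <- system2("python", c(script, infile, outfile))
  if (status != 0) stop("python oracle failed with status ", status)
  out <- readLines(outfile)
  lapply(strsplit(out, "\t"), as.numeric)
}
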