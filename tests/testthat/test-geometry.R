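# equilateral reference triangle used by several cases
equilateral3 <- function() {
  reference_geometry(rbind(E = c(0, 1),
                           A = c(-sqrt(3) / 2, -1 / 2),
                           S = c(sqrt(3) / 2, -1 / 2)),
                     c("European", "African", "Asian"))
}

regular_tetrahedron <- function() {
  cen <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  reference_geometry(cen, c("European", "African", "Asian", "NativeAm"))
}

test_that("centroid construction: singleton and symmetric labeled samples", {
  sc <- score_matrix(paste0("s", 1:3), rbind(c(0, 0), c(1, 0), c(0, 1)))
  geo <- compute_centroids(sc, c("x", "y", "z"), c("x", "y", "z"))
  expect_equal(unname(geo$centroids), rbind(c(0, 0), c(1, 0), c(0, 1)))

  # pairs symmetric about the same three points give identical centroids
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1))
  jit <- rbind(c(0.1, -0.2), c(-0.3, 0.05), c(0.2, 0.15))
  sc2 <- score_matrix(paste0("s", 1:6),
                      rbind(pts + jit, pts - jit))
  geo2 <- compute_centroids(sc2, rep(c("x", "y", "z"), 2), c("x", "y", "z"))
  expect_equal(geo2$centroids, geo$centroids)

  expect_error(compute_centroids(sc, c("x", "y", "y")), "3 or 4")
})

test_that("centroids estimated from simulated scores track the generator means", {
  set.seed(21)
  mu <- rbind(c(-4, 0), c(4, 1), c(0, 5))
  n <- 100
  sd_pt <- 0.8
  X <- do.call(rbind, lapply(1:3, function(j)
    cbind(rnorm(n, mu[j, 1], sd_pt), rnorm(n, mu[j, 2], sd_pt))))
  sc <- score_matrix(sprintf("s%03d", 1:(3 * n)), X)
  geo <- compute_centroids(sc, rep(c("p1", "p2", "p3"), each = n))
  se <- sd_pt / sqrt(n)
  # joint bound over 6 independent coordinates: 4 SE keeps the false
  # alarm probability of the max-|z| statistic below 1e-4
  expect_true(all(abs(geo$centroids - mu) < 4 * se))
})

test_that("degenerate (collinear / flat) centroid sets are rejected", {
  expect_error(reference_geometry(rbind(c(0, 0), c(1, 1), c(2, 2)),
                                  c("a", "b", "c")), "degenerate")
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_error(reference_geometry(flat, c("a", "b", "c", "d")), "degenerate")
})

test_that("region classification matches the perpendicular-line construction", {
  geo <- equilateral3()
  # at a centroid -> vertex region, proportion 1 downstream
  cls <- classify_region(geo$centroids[1, ], geo)
  expect_identical(cls$region, "vertex:European")
  expect_equal(estimate_ancestry(geo$centroids[1, ], geo)$proportions,
               c(European = 1, African = 0, Asian = 0))

  # edge midpoint pushed outward perpendicular stays an edge point
  mid <- colMeans(geo$centroids[1:2, ])
  u <- geo$centroids[2, ] - geo$centroids[1, ]
  out_normal <- c(-u[2], u[1])
  out_normal <- out_normal / sqrt(sum(out_normal^2))
  # orient away from the third centroid
  if (sum(out_normal * (geo$centroids[3, ] - mid)) > 0)
    out_normal <- -out_normal
  for (d in c(0.01, 0.5, 3)) {
    cls <- classify_region(mid + d * out_normal, geo)
    expect_identical(cls$region, "edge:European,African")
    expect_equal(cls$closest, mid, tolerance = 1e-9)
  }

  # random points against the independent wedge/slab transcription
  for (seed in c(5, 6)) {
    g <- random_geometry(3, seed)
    set.seed(seed + 100)
    pts <- matrix(rnorm(2 * 500, sd = 8), ncol = 2)
    for (i in seq_len(nrow(pts))) {
      oracle <- oracle_triangle_region(pts[i, ], g$centroids)
      if (oracle$margin < 1e-6) next   # numerically on a boundary
      got <- classify_region(pts[i, ], g)$region
      want <- switch(substr(oracle$region, 1, 4),
        vert = paste0("vertex:",
                      g$labels[as.integer(sub("vertex:", "", oracle$region))]),
        edge = {
          ij <- as.integer(strsplit(sub("edge:", "", oracle$region),
                                    ",")[[1]])
          paste0("edge:", paste(g$labels[ij], collapse = ","))
        },
        inte = "interior")
      expect_identical(got, want, label = paste("point", i, "seed", seed))
    }
  }
})

test_that("edge proportions follow the inverse-distance rule with exact limits", {
  # A=(0,0), B=(4,0); query below the segment at x=1: foot (1,0),
  # L1=1, L2=3 -> P_A = (1/1)/(1/1 + 1/3) = 0.75
  geo <- reference_geometry(rbind(c(0, 0), c(4, 0), c(2, 5)),
                            c("A", "B", "C"))
  pr <- edge_proportions(c(1, -2), geo, c(1, 2))
  expect_equal(unname(pr), c(0.75, 0.25, 0))

  pr_mid <- edge_proportions(c(2, -1), geo, c(1, 2))
  expect_equal(unname(pr_mid), c(0.5, 0.5, 0))

  # L1 -> 0 limit: proportion 1 at the endpoint
  pr_end <- edge_proportions(c(0, -3), geo, c(1, 2))
  expect_equal(unname(pr_end), c(1, 0, 0))

  expect_error(edge_proportions(c(9, -2), geo, c(1, 2)), "inconsistency")
})

test_that("triangle interior proportions: symmetry, limits, and oracle", {
  geo <- equilateral3()
  expect_equal(unname(interior_proportions_triangle(c(0, 0),
                                                    geo$centroids)),
               rep(1 / 3, 3))

  # approaching the European-African side midpoint from inside
  mid <- colMeans(geo$centroids[1:2, ])
  inward <- -mid + c(0, 0)  # direction towards the origin (interior)
  inward <- (c(0, 0) - mid); inward <- inward / sqrt(sum(inward^2))
  # the blend deviates from the side's two-way split linearly in the
  # distance from the side (the off-side weight is H1 / sum(1/H))
  for (eps in c(1e-3, 1e-6, 1e-9)) {
    pr <- interior_proportions_triangle(mid + eps * inward, geo$centroids)
    expect_lt(max(abs(pr - c(0.5, 0.5, 0))), 5 * eps)
  }
  # exactly on the side: reduces to the two-way split
  expect_equal(unname(interior_proportions_triangle(mid, geo$centroids)),
               c(0.5, 0.5, 0))

  # random interior points vs the independent transcription
  set.seed(31)
  g <- random_geometry(3, 31)
  for (i in 1:200) {
    w <- rgamma(3, 1); w <- w / sum(w)
    p <- drop(w %*% g$centroids)
    expect_lt(max(abs(interior_proportions_triangle(p, g$centroids) -
                      oracle_triangle_eq4(p, g$centroids))), 1e-10)
  }
})

test_that("three-population dispatch covers vertex, edge and interior", {
  geo <- equilateral3()
  est <- estimate_ancestry(geo$centroids[2, ], geo)
  expect_identical(est$region, "vertex:African")
  expect_equal(unname(est$proportions), c(0, 1, 0))

  # far beyond the European vertex: still 100 % European
  far <- geo$centroids[1, ] * 10
  est2 <- estimate_ancestry(far, geo)
  expect_identical(est2$region, "vertex:European")
  expect_equal(unname(est2$proportions), c(1, 0, 0))

  # proportions vary continuously across an edge-region -> interior
  # boundary (walk crossing the European-African side)
  mid <- colMeans(geo$centroids[1:2, ])
  dir_in <- -mid / sqrt(sum(mid^2))
  ts <- seq(-0.05, 0.05, by = 1e-4)
  props <- t(vapply(ts, function(t_)
    estimate_ancestry(mid + t_ * dir_in, geo)$proportions, numeric(3)))
  jumps <- apply(abs(diff(props)), 1, max)
  expect_lt(max(jumps), 1e-3)
})

test_that("tetrahedron estimates: vertices, barycenter, oracle agreement", {
  geo <- regular_tetrahedron()
  est <- estimate_ancestry(geo$centroids[4, ], geo)
  expect_identical(est$region, "vertex:NativeAm")
  expect_equal(unname(est$proportions), c(0, 0, 0, 1))

  bc <- colMeans(geo$centroids)
  est_bc <- estimate_ancestry(bc, geo)
  expect_identical(est_bc$region, "interior")
  expect_equal(unname(est_bc$proportions), rep(0.25, 4))

  # random interior points vs the independent face-by-face oracle
  set.seed(41)
  g <- random_geometry(4, 41)
  for (i in 1:150) {
    w <- rgamma(4, 1); w <- w / sum(w)
    p <- drop(w %*% g$centroids)
    est_i <- estimate_ancestry(p, g)
    expect_identical(est_i$region, "interior")
    expect_lt(max(abs(est_i$proportions -
                      oracle_tetra_interior(p, g$centroids))), 1e-10)
    expect_equal(sum(est_i$proportions), 1, tolerance = 1e-9)
  }

  # exterior point nearest a face: single-face projection
  g2 <- regular_tetrahedron()
  face_center <- colMeans(g2$centroids[1:3, ])
  n_out <- face_center - colMeans(g2$centroids)   # outward normal direction
  p_out <- face_center + 2 * n_out
  est_f <- estimate_ancestry(p_out, g2)
  expect_match(est_f$region, "^face:")
  expect_equal(unname(est_f$proportions), c(1, 1, 1, 0) / 3)
})

test_that("proportions are affinely equivariant and label-permutation symmetric", {
  g <- random_geometry(3, 51)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  shift <- c(3, -2)
  g_rot <- reference_geometry(sweep(g$centroids %*% R, 2, shift, "+"),
                              g$labels)
  g4 <- random_geometry(4, 52)
  perm <- c(3, 1, 4, 2)
  g4_perm <- reference_geometry(g4$centroids[perm, ], g4$labels[perm])

  set.seed(53)
  for (i in 1:100) {
    p <- rnorm(2, sd = 6)
    a <- estimate_ancestry(p, g)$proportions
    b <- estimate_ancestry(drop(p %*% R) + shift, g_rot)$proportions
    expect_equal(unname(b), unname(a), tolerance = 1e-8)

    q <- rnorm(3, sd = 6)
    x <- estimate_ancestry(q, g4)$proportions
    y <- estimate_ancestry(q, g4_perm)$proportions
    expect_equal(y[g4$labels], x[g4$labels], tolerance = 1e-12)
  }
})

test_that("points on an open edge assign zero to off-edge populations", {
  g <- random_geometry(3, 61)
  set.seed(61)
  for (i in 1:50) {
    t_ <- runif(1, 0.1, 0.9)
    onedge <- (1 - t_) * g$centroids[1, ] + t_ * g$centroids[2, ]
    est <- estimate_ancestry(onedge, g)
    expect_equal(unname(est$proportions[3]), 0)
    expect_equal(unname(est$proportions[1:2]),
                 unname(oracle_edge_prop(onedge, g$centroids[1, ],
                                         g$centroids[2, ])),
                 tolerance = 1e-12)
  }
})

test_that("geometry files round-trip through TSV", {
  dir <- withr::local_tempdir()
  g <- random_geometry(4, 71)
  path <- file.path(dir, "geom.tsv")
  write_geometry(g, path)
  g2 <- read_geometry(path)
  expect_identical(g2$centroids, g$centroids)
  expect_identical(g2$labels, g$labels)
})
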