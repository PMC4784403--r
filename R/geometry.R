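# The ancestry simplex: reference centroids, nearest-feature
# classification, and inverse-distance admixture proportions.
#
# With m reference populations (m = 3 or 4) the population centroids in
# the first k = m - 1 PC score dimensions span a triangle or
# tetrahedron. A query point is classified by the feature of the
# simplex closest to it:
#   vertex   -> 100 % of that population,
#   edge     -> a two-way mixture, split by inverse distances along the
#               edge from the perpendicular foot to the two centroids,
#   face     -> (tetrahedron only) a three-way mixture estimated inside
#               the face triangle,
#   interior -> a full mixture combining the per-side estimates with
#               inverse perpendicular-distance weights (triangle), or
#               an average of all four face estimates (tetrahedron).
# The nearest-feature rule is exactly the classical construction that
# partitions the plane around a triangle with perpendiculars through
# the centroids: exterior regions facing a vertex map to that vertex,
# exterior slabs facing a side map to the side.

INV_DIST_EPS <- 1e-12   # distances below this are treated as the exact limit

#' Reference ancestry geometry (triangle or tetrahedron)
#'
#' @param centroids m x k numeric matrix of population centroids, one
#'   row per population, with k = m - 1 (2D triangle, 3D tetrahedron).
#' @param labels character vector of m unique population names.
#' @return An object of class `reference_geometry` with fields `labels`,
#'   `centroids`, `edges` (index pairs), `faces` (index triples, 4
#'   populations only) and precomputed projection operators per feature.
#' @export
reference_geometry <- function(centroids, labels) {
  centroids <- as.matrix(centroids)
  m <- nrow(centroids)
  if (!(m %in% c(3, 4)))
    stop("geometry requires 3 or 4 populations, got ", m)
  if (length(labels) != m || anyDuplicated(labels))
    stop("labels must be ", m, " unique population names")
  if (ncol(centroids) != m - 1)
    stop("centroids must have k = populations - 1 = ", m - 1,
         " coordinates, got ", ncol(centroids))
  edge_mat <- t(centroids[-1, , drop = FALSE]) -
    centroids[1, ]                      # k x (m-1) edge-vector matrix
  if (min(svd(edge_mat)$d) <= 1e-9)
    stop("degenerate simplex: centroids are affinely dependent")
  dimnames(centroids) <- list(labels, paste0("pc", seq_len(m - 1)))

  subsets <- simplex_subsets(m)
  projectors <- lapply(subsets, function(S) make_projector(centroids, S))
  edges <- Filter(function(S) length(S) == 2, subsets)
  faces <- if (m == 4) Filter(function(S) length(S) == 3, subsets) else list()
  structure(
    list(labels = as.character(labels), centroids = centroids,
         edges = edges, faces = faces,
         subsets = subsets, projectors = projectors),
    class = "reference_geometry")
}

#' @export
print.reference_geometry <- function(x, ...) {
  cat(sprintf("reference_geometry: %d populations (%s), %dD score space\n",
              length(x$labels), paste(x$labels, collapse = ", "),
              ncol(x$centroids)))
  print(round(x$centroids, 4))
  invisible(x)
}

# all nonempty vertex subsets, ordered by size then lexicographically;
# this ordering is the deterministic tie-break (vertex beats edge beats
# face beats interior when distances are equal, i.e. on boundaries)
simplex_subsets <- function(m) {
  out <- list()
  for (size in seq_len(m)) {
    combs <- utils::combn(m, size)
    for (j in seq_len(ncol(combs))) out[[length(out) + 1L]] <- combs[, j]
  }
  out
}

# precompute the affine projector onto the hull of centroid subset S:
# x |-> barycentric coords w over S of the point on aff(S) closest to x
make_projector <- function(centroids, S) {
  c0 <- centroids[S[1], ]
  if (length(S) == 1)
    return(list(S = S, c0 = c0, A = NULL, M = NULL))
  A <- t(centroids[S[-1], , drop = FALSE]) - c0   # k x (|S|-1)
  M <- solve(crossprod(A), t(A))                  # (|S|-1) x k
  list(S = S, c0 = c0, A = A, M = M)
}

# closest point to x on the convex hull of the subset's centroids,
# or NULL if the affine projection falls outside that sub-simplex
project_subset <- function(proj, x) {
  if (is.null(proj$A)) {
    w <- 1
    pt <- proj$c0
  } else {
    t_ <- drop(proj$M %*% (x - proj$c0))
    w <- c(1 - sum(t_), t_)
    if (any(w < -INV_DIST_EPS)) return(NULL)
    pt <- proj$c0 + drop(proj$A %*% t_)
  }
  list(point = pt, weights = w, dist = sqrt(sum((x - pt)^2)))
}

#' Estimate population centroids from labeled reference scores
#'
#' Each centroid is the coordinate-wise mean of that population's PC
#' scores over the first k = populations - 1 dimensions (higher
#' components are ignored).
#'
#' @param scores a [score_matrix()].
#' @param labels per-sample population assignment; `NA` for unlabeled
#'   samples (ignored).
#' @param populations optional character vector fixing the population
#'   order; defaults to the sorted unique labels.
#' @return A [reference_geometry()].
#' @export
compute_centroids <- function(scores, labels, populations = NULL) {
  stopifnot(inherits(scores, "score_matrix"))
  labels <- as.character(labels)
  if (length(labels) != length(scores$sample_ids))
    stop("labels must have one entry per sample")
  if (is.null(populations)) populations <- sort(unique(stats::na.omit(labels)))
  m <- length(populations)
  if (!(m %in% c(3, 4)))
    stop("need 3 or 4 populations, got ", m)
  absent <- setdiff(populations, labels)
  if (length(absent))
    stop("no labeled samples for population(s): ",
         paste(absent, collapse = ", "))
  k <- m - 1
  if (ncol(scores$scores) < k)
    stop("scores have ", ncol(scores$scores),
         " dimensions; need at least ", k)
  cen <- t(vapply(populations, function(p) {
    colMeans(scores$scores[which(labels == p), seq_len(k), drop = FALSE])
  }, numeric(k)))
  reference_geometry(cen, populations)
}

#' Classify a score point by its nearest simplex feature
#'
#' Computes the closest point on the ancestry simplex by enumerating
#' every face of the convex hull of the centroids (vertices, edges,
#' faces, full simplex), keeping candidates whose affine projection has
#' nonnegative barycentric coordinates, and taking the minimum
#' distance. Ties (boundary points, within 1e-12) resolve to the
#' lowest-dimensional feature and then to the lowest population
#' indices.
#'
#' @param point numeric vector, length = geometry dimension.
#' @param geometry a [reference_geometry()].
#' @return A list: `region` (one of `"vertex:<pop>"`,
#'   `"edge:<popA>,<popB>"`, `"face:<a>,<b>,<c>"`, `"interior"`),
#'   `feature` (vertex indices of the closest feature), `closest`
#'   (closest point on the simplex) and `dist`.
#' @export
classify_region <- function(point, geometry) {
  stopifnot(inherits(geometry, "reference_geometry"))
  point <- as.numeric(point)
  if (length(point) != ncol(geometry$centroids))
    stop("point has ", length(point), " dimensions; geometry needs ",
         ncol(geometry$centroids))
  if (any(!is.finite(point))) stop("point must be finite")

  best <- NULL
  for (proj in geometry$projectors) {
    cand <- project_subset(proj, point)
    if (is.null(cand)) next
    # subsets are ordered by size then lexicographic index, so strict
    # improvement keeps the first (lowest) feature among ties
    if (is.null(best) || cand$dist < best$dist - INV_DIST_EPS) {
      best <- cand
      best$S <- proj$S
    }
  }
  m <- length(geometry$labels)
  S <- best$S
  region <- if (length(S) == 1) {
    paste0("vertex:", geometry$labels[S])
  } else if (length(S) == 2) {
    paste0("edge:", paste(geometry$labels[S], collapse = ","))
  } else if (length(S) == m) {
    "interior"
  } else {
    paste0("face:", paste(geometry$labels[S], collapse = ","))
  }
  list(region = region, feature = S, closest = best$point, dist = best$dist)
}

# inverse-distance split of unity between two endpoint distances,
# with exact limits when either distance underflows
inv_distance_pair <- function(L1, L2) {
  if (L1 < INV_DIST_EPS && L2 < INV_DIST_EPS) return(c(0.5, 0.5))
  if (L1 < INV_DIST_EPS) return(c(1, 0))
  if (L2 < INV_DIST_EPS) return(c(0, 1))
  p <- (1 / L1) / (1 / L1 + 1 / L2)
  c(p, 1 - p)
}

#' Two-way proportions for a point whose nearest feature is an edge
#'
#' The query is dropped perpendicularly onto the edge; with L1 and L2
#' the distances from the foot to the two endpoint centroids, the first
#' population's share is (1/L1) / (1/L1 + 1/L2) and the second is its
#' complement (equivalently L2 / (L1 + L2): closer centroid, larger
#' share). All other populations get 0.
#'
#' @param point numeric score point.
#' @param geometry a [reference_geometry()].
#' @param edge integer pair of population indices.
#' @param check verify that the perpendicular foot lies inside the edge
#'   segment (it must, when classification returned this edge).
#' @return Named length-m proportion vector.
#' @export
edge_proportions <- function(point, geometry, edge, check = TRUE) {
  cA <- geometry$centroids[edge[1], ]
  cB <- geometry$centroids[edge[2], ]
  u <- cB - cA
  t_ <- sum((point - cA) * u) / sum(u * u)
  if (check && (t_ < -1e-9 || t_ > 1 + 1e-9))
    stop("internal inconsistency: perpendicular foot outside edge segment")
  foot <- cA + t_ * u
  L1 <- sqrt(sum((foot - cA)^2))
  L2 <- sqrt(sum((foot - cB)^2))
  pr <- numeric(length(geometry$labels))
  pr[edge] <- inv_distance_pair(L1, L2)
  names(pr) <- geometry$labels
  pr
}

# per-side perpendicular geometry for a triangle of centroids (rows of
# `tri`, any ambient dimension; `point` assumed in the triangle's
# plane): perpendicular distance H to each side line and the two
# distances from the perpendicular foot to the side's endpoints
triangle_side_geometry <- function(point, tri) {
  sides <- list(c(1, 2), c(1, 3), c(2, 3))
  lapply(sides, function(s) {
    a <- tri[s[1], ]; b <- tri[s[2], ]
    u <- b - a
    t_ <- sum((point - a) * u) / sum(u * u)
    foot <- a + t_ * u
    list(ends = s,
         H = sqrt(sum((point - foot)^2)),
         L = c(sqrt(sum((foot - a)^2)), sqrt(sum((foot - b)^2))))
  })
}

#' Three-way proportions for a point inside a triangle of centroids
#'
#' For each side, the point is dropped perpendicularly onto the side
#' line; H is the perpendicular distance and L1, L2 the distances from
#' the foot to the side's endpoint centroids. Each side contributes its
#' two-way inverse-distance split, weighted by 1/H, and the three side
#' weights are normalized:
#'   P(pop) = sum over sides incident to pop of (1/H_side) x
#'            (pop's two-way share on that side) / sum over sides (1/H).
#' When the point lies on a side (H below 1e-12) the estimate reduces
#' exactly to that side's two-way split; on a vertex, to that
#' population alone.
#'
#' @param point numeric point, assumed in the plane of the triangle.
#' @param tri 3 x d matrix of the three centroids.
#' @return Length-3 proportion vector (order of `tri` rows).
#' @export
interior_proportions_triangle <- function(point, tri) {
  geom <- triangle_side_geometry(point, tri)
  H <- vapply(geom, `[[`, numeric(1), "H")
  on_side <- H < INV_DIST_EPS
  pr <- numeric(3)
  if (any(on_side)) {
    if (sum(on_side) >= 2) {
      # on two side lines at once: the point is at their shared vertex
      shared <- Reduce(intersect, lapply(geom[on_side], `[[`, "ends"))
      pr[shared[1]] <- 1
      return(pr)
    }
    s <- geom[[which(on_side)]]
    pr[s$ends] <- inv_distance_pair(s$L[1], s$L[2])
    return(pr)
  }
  wH <- 1 / H
  for (s in geom) {
    share <- inv_distance_pair(s$L[1], s$L[2])
    pr[s$ends] <- pr[s$ends] + (1 / s$H) * share
  }
  pr / sum(wH)
}

#' Ancestry proportions for one score point
#'
#' Dispatches on [classify_region()]: a vertex gives a one-hot vector;
#' an edge the two-way inverse-distance split; a face (four populations
#' only) an orthogonal projection onto the face plane followed by the
#' triangle estimator among that face's centroids; the interior of a
#' triangle the inverse-perpendicular-distance blend of the three side
#' estimates; the interior of a tetrahedron the average over its four
#' faces of the projected triangle estimates, with each face's absent
#' population scored 0 (each face estimate sums to 1, so the average
#' does too).
#'
#' @param point numeric score point (first k = populations - 1
#'   dimensions are used; extra trailing dimensions are dropped).
#' @param geometry a [reference_geometry()].
#' @return A list: `region` and named `proportions` summing to 1.
#' @export
estimate_ancestry <- function(point, geometry) {
  stopifnot(inherits(geometry, "reference_geometry"))
  m <- length(geometry$labels)
  k <- m - 1
  point <- as.numeric(point)
  if (length(point) > k) point <- point[seq_len(k)]
  cls <- classify_region(point, geometry)
  S <- cls$feature
  pr <- numeric(m)
  if (length(S) == 1) {
    pr[S] <- 1
  } else if (length(S) == 2) {
    pr <- unname(edge_proportions(point, geometry, S))
  } else if (length(S) == 3 && m == 3) {
    pr <- interior_proportions_triangle(point, geometry$centroids)
  } else if (length(S) == 3 && m == 4) {
    pr[S] <- face_triangle_estimate(point, geometry$centroids[S, , drop = FALSE])
  } else {
    # tetrahedron interior: average the four projected face estimates
    for (f in geometry$faces) {
      pr[f] <- pr[f] +
        face_triangle_estimate(point, geometry$centroids[f, , drop = FALSE])
    }
    pr <- pr / length(geometry$faces)
  }
  names(pr) <- geometry$labels
  list(region = cls$region, proportions = pr)
}

# orthogonally project a 3D point onto the plane of a face triangle,
# then run the triangle estimator inside that plane
face_triangle_estimate <- function(point, tri) {
  a <- tri[1, ]
  B <- t(tri[-1, , drop = FALSE]) - a      # 3 x 2 basis of the plane
  t_ <- solve(crossprod(B), crossprod(B, point - a))
  proj <- a + drop(B %*% t_)
  interior_proportions_triangle(proj, tri)
}

#' Ancestry proportions for every row of a score matrix
#'
#' @param scores a [score_matrix()] (only the first populations - 1
#'   components are used).
#' @param geometry a [reference_geometry()].
#' @return A data.frame: `sample_id`, `region`, then one proportion
#'   column per population.
#' @export
estimate_ancestry_all <- function(scores, geometry) {
  stopifnot(inherits(scores, "score_matrix"))
  m <- length(geometry$labels)
  n <- length(scores$sample_ids)
  regions <- character(n)
  props <- matrix(NA_real_, n, m, dimnames = list(NULL, geometry$labels))
  for (i in seq_len(n)) {
    est <- estimate_ancestry(scores$scores[i, ], geometry)
    regions[i] <- est$region
    props[i, ] <- est$proportions
  }
  out <- data.frame(sample_id = scores$sample_ids, region = regions,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(props))
}

#' Write reference centroids to a TSV file
#'
#' The geometry file lets a consortium ship fixed ("gold standard")
#' centroid positions alongside the SNP weights.
#'
#' @param geometry a [reference_geometry()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "reference_geometry"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  k <- ncol(geometry$centroids)
  writeLines(paste(c("population", paste0("pc", seq_len(k))),
                   collapse = "\t"), con)
  for (i in seq_along(geometry$labels)) {
    writeLines(paste(c(geometry$labels[i], fmt_num(geometry$centroids[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a centroid geometry TSV written by [write_geometry()]
#'
#' @param path geometry TSV path.
#' @return A [reference_geometry()].
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) stop("geometry file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  pcs <- grep("^pc[0-9]+$", names(tab), value = TRUE)
  cen <- matrix(as.numeric(as.matrix(tab[pcs])), nrow = nrow(tab))
  reference_geometry(cen, tab$population)
}
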