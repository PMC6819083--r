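#' Read and write SWC neuron morphologies
#'
#' Standard SWC: 7 whitespace-separated columns (`id`, `type`, `x`, `y`,
#' `z`, `radius`, `parent`), `#` comments, 1-based ids, parent `-1` for the
#' root. Coordinates are in micrometers. The tree is validated on read:
#' exactly one root, all parents must exist, no cycles.
#'
#' @param path SWC file path.
#' @return tibble of nodes (`id`, `type`, `x`, `y`, `z`, `radius`,
#'   `parent`).
#' @export
read_swc <- function(path) {
  df <- utils::read.table(
    path, comment.char = "#",
    col.names = c("id", "type", "x", "y", "z", "radius", "parent")
  )
  tree <- as_tibble(df)
  tree$id <- as.integer(tree$id)
  tree$type <- as.integer(tree$type)
  tree$parent <- as.integer(tree$parent)
  validate_neuron_tree(tree)
  tree
}

#' @rdname read_swc
#' @param tree SWC node tibble.
#' @export
write_swc <- function(tree, path) {
  validate_neuron_tree(tree)
  lines <- sprintf(
    "%d %d %.17g %.17g %.17g %.17g %d",
    tree$id, tree$type, tree$x, tree$y, tree$z, tree$radius, tree$parent
  )
  writeLines(c("# id type x y z radius parent", lines), path)
  invisible(tree)
}

#' Validate an SWC node table as a rooted tree
#'
#' @param tree tibble with columns `id`, `type`, `x`, `y`, `z`, `radius`,
#'   `parent`.
#' @return `tree`, invisibly; errors name the offending node.
#' @export
validate_neuron_tree <- function(tree) {
  check_columns(tree, c("id", "type", "x", "y", "z", "radius", "parent"), "`tree`")
  if (anyDuplicated(tree$id)) {
    abort(sprintf("Duplicate node id %d.", tree$id[duplicated(tree$id)][1]))
  }
  roots <- tree$id[tree$parent == -1]
  if (length(roots) != 1) {
    abort(sprintf("Tree must have exactly one root; found %d.", length(roots)))
  }
  known <- c(-1, tree$id)
  orphan <- tree$id[!(tree$parent %in% known)]
  if (length(orphan) > 0) {
    abort(sprintf("Node %d references a missing parent.", orphan[1]))
  }
  if (!all(is.finite(tree$x) & is.finite(tree$y) & is.finite(tree$z))) {
    abort("All node coordinates must be finite.")
  }
  # cycle check: walk each node to the root
  parent_of <- setNames(tree$parent, tree$id)
  for (start in tree$id) {
    seen <- 0L
    cur <- start
    while (cur != -1) {
      cur <- parent_of[[as.character(cur)]]
      seen <- seen + 1L
      if (seen > nrow(tree)) {
        abort(sprintf("Cycle detected involving node %d.", start))
      }
    }
  }
  invisible(tree)
}

# per-segment endpoint distances from the soma (root node coordinates)
segment_distances <- function(tree, planar = FALSE) {
  root <- tree[tree$parent == -1, ]
  segs <- tree[tree$parent != -1, ]
  if (nrow(segs) == 0) {
    return(tibble(d_parent = numeric(), d_child = numeric(), length = numeric()))
  }
  pidx <- match(segs$parent, tree$id)
  dist_root <- function(x, y, z) {
    dz <- if (planar) 0 else (z - root$z)
    sqrt((x - root$x)^2 + (y - root$y)^2 + dz^2)
  }
  seg_len <- {
    dz <- if (planar) 0 else (segs$z - tree$z[pidx])
    sqrt((segs$x - tree$x[pidx])^2 + (segs$y - tree$y[pidx])^2 + dz^2)
  }
  tibble(
    d_parent = dist_root(tree$x[pidx], tree$y[pidx], tree$z[pidx]),
    d_child = dist_root(segs$x, segs$y, segs$z),
    length = seg_len
  )
}

#' Sholl analysis of a neuron tree
#'
#' Counts neurite intersections with concentric shells of radius `step_um`,
#' `2 * step_um`, ... centered on the soma (the root node). A parent-child
#' segment crosses the shell of radius r when its endpoint distances from
#' the soma straddle r: `min(d) < r <= max(d)` (a segment reaching exactly
#' distance r from below counts as crossing; one starting exactly at r does
#' not count again). A long segment crossing k shells contributes once to
#' each. Distances are 3D Euclidean; set `planar = TRUE` for 2D traces.
#'
#' @param tree SWC node tibble (see [read_swc()], [simulate_morphology()]).
#' @param step_um shell spacing in micrometers (default 5).
#' @param max_radius_um outermost shell; defaults to the smallest multiple
#'   of `step_um` at or beyond the most distal node.
#' @param planar use 2D (xy) distances instead of 3D.
#' @return tibble of class `"sholl_profile"` with columns `radius_um`,
#'   `intersections`, and the total neurite length in attribute
#'   `"total_length_um"` (also via [glance()]).
#' @examples
#' sholl(simulate_morphology("radial", length_um = 23))
#' @export
sholl <- function(tree, step_um = 5, max_radius_um = NULL, planar = FALSE) {
  validate_neuron_tree(tree)
  segs <- segment_distances(tree, planar = planar)
  max_d <- if (nrow(segs) > 0) max(segs$d_parent, segs$d_child) else 0
  if (is.null(max_radius_um)) {
    max_radius_um <- max(step_um, ceiling(max_d / step_um) * step_um)
  }
  radii <- seq(step_um, max_radius_um, by = step_um)
  lo <- pmin(segs$d_parent, segs$d_child)
  hi <- pmax(segs$d_parent, segs$d_child)
  # the straddle comparison carries a 1e-9 relative slack so that endpoints
  # constructed to lie exactly on a shell are not lost to rounding
  counts <- vapply(
    radii,
    function(r) sum(lo < r & r <= hi + 1e-9 * max(1, r)),
    numeric(1)
  )
  out <- tibble(radius_um = radii, intersections = as.integer(counts))
  attr(out, "total_length_um") <- sum(segs$length)
  attr(out, "step_um") <- step_um
  class(out) <- c("sholl_profile", class(out))
  out
}

#' @method glance sholl_profile
#' @export
glance.sholl_profile <- function(x, ...) {
  tibble(
    total_length_um = attr(x, "total_length_um"),
    max_intersections = if (nrow(x)) max(x$intersections) else 0L,
    n_shells = nrow(x)
  )
}

#' Total neurite length of a tree
#'
#' Sum of Euclidean lengths of all parent-child segments (the soma root has
#' no incoming segment).
#'
#' @param tree SWC node tibble.
#' @return length in micrometers.
#' @export
total_neurite_length <- function(tree) {
  validate_neuron_tree(tree)
  sum(segment_distances(tree)$length)
}

#' Soma cross-section morphometry from a traced contour
#'
#' From a simple (non-self-intersecting) 2D polygon: the cross-sectional
#' area (shoelace formula) and the equivalent-ellipse axes derived from the
#' polygon's second-order area moments — the ellipse with the same area
#' moments has semi-axes `2 * sqrt(eigenvalue)` of the region covariance, so
#' the reported major/minor axis lengths are `4 * sqrt(lambda)` diameters.
#'
#' @param contour data frame with ordered vertex columns `x_um`, `y_um`
#'   (>= 3 vertices; closing vertex optional).
#' @return one-row tibble: `area_um2`, `major_axis_um`, `minor_axis_um`,
#'   `aspect_ratio` (major/minor, >= 1).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 257)[-257]
#' soma_metrics(tibble::tibble(x_um = 10 * cos(th), y_um = 10 * sin(th)))
#' @export
soma_metrics <- function(contour) {
  check_columns(contour, c("x_um", "y_um"), "`contour`")
  x <- contour$x_um
  y <- contour$y_um
  n <- length(x)
  # drop an explicit closing vertex
  if (n > 1 && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]
    y <- y[-n]
    n <- n - 1
  }
  if (n < 3) abort("`contour` needs at least 3 distinct vertices.")
  if (polygon_self_intersects(x, y)) {
    abort("`contour` is self-intersecting; soma contours must be simple polygons.")
  }
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  area_signed <- sum(cross) / 2
  if (abs(area_signed) < .Machine$double.eps * 100) {
    abort("`contour` is degenerate (zero area).")
  }
  cx <- sum((x + xn) * cross) / (6 * area_signed)
  cy <- sum((y + yn) * cross) / (6 * area_signed)
  # second moments of the region about the origin (Green's theorem)
  ixx <- sum((y^2 + y * yn + yn^2) * cross) / 12
  iyy <- sum((x^2 + x * xn + xn^2) * cross) / 12
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cross) / 24
  # region covariance (moments normalized by area, centered)
  cov_xx <- iyy / area_signed - cx^2
  cov_yy <- ixx / area_signed - cy^2
  cov_xy <- ixy / area_signed - cx * cy
  eig <- eigen(matrix(c(cov_xx, cov_xy, cov_xy, cov_yy), 2, 2),
               symmetric = TRUE)$values
  major <- 4 * sqrt(max(eig[1], 0))
  minor <- 4 * sqrt(max(eig[2], 0))
  tibble(
    area_um2 = abs(area_signed),
    major_axis_um = major,
    minor_axis_um = minor,
    aspect_ratio = major / minor
  )
}

# brute-force simple-polygon check: any two non-adjacent edges intersecting?
polygon_self_intersects <- function(x, y) {
  n <- length(x)
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1) next
      if (i == 1 && j == n) next # adjacent through the wrap-around
      a <- c(x[i], y[i])
      b <- c(x[i %% n + 1], y[i %% n + 1])
      c_ <- c(x[j], y[j])
      d_ <- c(x[j %% n + 1], y[j %% n + 1])
      if (seg_int(a, b, c_, d_)) return(TRUE)
    }
  }
  FALSE
}

#' Read a soma contour CSV
#'
#' @param path CSV with ordered vertex columns `x_um`, `y_um`.
#' @return contour tibble.
#' @export
read_contour <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("x_um", "y_um"), sprintf("'%s'", path))
  df
}
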