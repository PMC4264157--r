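#' Construct a plunge-needle electrode grid
#'
#' Builds the recording geometry used throughout the package: a set of
#' transmural plunge needles laid out on a 2-D epicardial plane, each
#' carrying up to three recording layers (endocardial, midwall,
#' epicardial). The default 23-needle layout is a 5 x 5 rectangular
#' lattice with two corners removed, approximating an array fitted to the
#' anterior coronary anatomy; the true study layout is not published, so
#' the lattice is a documented stand-in and fully configurable via
#' `positions`.
#'
#' @param n_needles number of needles (1-23 for the default layout).
#' @param spacing_mm inter-needle lattice spacing in mm (typically 6-10).
#' @param layers character vector of layer labels, ordered endo -> epi,
#'   subset of `c("endo", "mid", "epi")`.
#' @param positions optional n x 2 matrix of needle x/y positions (mm);
#'   overrides the default lattice.
#' @param layer_depth_mm transmural distance between consecutive layers on
#'   one needle (mm); used only for geodesic path lengths.
#' @param adjacency_factor needles whose in-plane distance is at most
#'   `adjacency_factor * spacing_mm` are considered adjacent.
#'
#' @return An object of class `electrode_grid`: a list with `sites` (one
#'   row per recording site: `site`, `needle`, `layer`, `x`, `y`,
#'   `depth`), `needle_xy`, `spacing_mm`, `layers`, and the site-level
#'   logical `adjacency` matrix (layers on one needle are always mutually
#'   adjacent; sites on adjacent needles are adjacent across any layer).
#' @export
make_grid <- function(n_needles = 23L, spacing_mm = 8, layers = c("endo", "mid", "epi"),
                      positions = NULL, layer_depth_mm = 4, adjacency_factor = 1.5) {
  if (length(n_needles) != 1L || is.na(n_needles) || n_needles < 1)
    stop("n_needles must be a positive count")
  if (!is.numeric(spacing_mm) || spacing_mm <= 0)
    stop("spacing_mm must be positive")
  layers <- match.arg(layers, c("endo", "mid", "epi"), several.ok = TRUE)
  # keep canonical transmural order
  layers <- c("endo", "mid", "epi")[c("endo", "mid", "epi") %in% layers]
  if (is.null(positions)) {
    positions <- default_needle_layout(n_needles, spacing_mm)
  } else {
    positions <- as.matrix(positions)
    if (nrow(positions) != n_needles || ncol(positions) != 2L)
      stop("positions must be an n_needles x 2 matrix")
  }
  depth <- stats::setNames(seq(0, by = layer_depth_mm, length.out = 3L), c("epi", "mid", "endo"))
  sites <- expand.grid(layer = layers, needle = seq_len(n_needles),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sites <- sites[order(sites$needle, match(sites$layer, c("endo", "mid", "epi"))), , drop = FALSE]
  sites <- data.frame(site = seq_len(nrow(sites)),
                      needle = sites$needle,
                      layer = sites$layer,
                      x = positions[sites$needle, 1L],
                      y = positions[sites$needle, 2L],
                      depth = unname(depth[sites$layer]),
                      stringsAsFactors = FALSE)
  g <- structure(list(sites = sites, needle_xy = positions, spacing_mm = spacing_mm,
                      layers = layers, layer_depth_mm = layer_depth_mm,
                      adjacency_factor = adjacency_factor),
                 class = "electrode_grid")
  g$adjacency <- grid_adjacency(g)
  g
}

# Default 23-needle layout: 5x5 lattice minus the two corners farthest from
# the origin row; smaller n take the first n lattice points row-major.
default_needle_layout <- function(n_needles, spacing_mm) {
  full <- expand.grid(x = 0:4, y = 0:4, KEEP.OUT.ATTRS = FALSE)
  full <- full[order(full$y, full$x), ]
  drop <- !(full$x %in% c(0, 4) & full$y == 4)
  pts <- as.matrix(full[drop, c("x", "y")])
  if (n_needles > nrow(pts))
    stop("default layout supports at most ", nrow(pts), " needles; supply positions")
  pts[seq_len(n_needles), , drop = FALSE] * spacing_mm
}

#' Site adjacency matrix of an electrode grid
#'
#' Two sites are adjacent when they sit on the same needle (any layer
#' pair) or on needles whose in-plane distance is at most
#' `adjacency_factor * spacing_mm` (any layer pair). This is the adjacency
#' used by the reentry definition (earliest site of a complex immediately
#' adjacent to the latest site of the previous one).
#'
#' @param grid an `electrode_grid`.
#' @param factor adjacency threshold as a multiple of `spacing_mm`;
#'   defaults to the grid's stored factor.
#' @return logical site x site matrix (diagonal `FALSE`).
#' @export
grid_adjacency <- function(grid, factor = grid$adjacency_factor) {
  st <- grid$sites
  d2 <- as.matrix(stats::dist(st[, c("x", "y")]))
  same_needle <- outer(st$needle, st$needle, "==")
  adj <- same_needle | d2 <= factor * grid$spacing_mm
  diag(adj) <- FALSE
  dimnames(adj) <- list(st$site, st$site)
  adj
}

#' Geodesic distances between grid sites
#'
#' Shortest-path distance (mm) over the adjacency graph, with each edge
#' weighted by the 3-D Euclidean distance between the two sites (in-plane
#' needle offset plus transmural depth offset). Used by the simulator to
#' turn conduction velocity into activation delays.
#'
#' @param grid an `electrode_grid`.
#' @return numeric site x site matrix of path lengths (mm).
#' @export
grid_geodesic <- function(grid) {
  st <- grid$sites
  adj <- grid$adjacency
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  w <- sqrt((st$x[idx[, 1]] - st$x[idx[, 2]])^2 +
            (st$y[idx[, 1]] - st$y[idx[, 2]])^2 +
            (st$depth[idx[, 1]] - st$depth[idx[, 2]])^2)
  gr <- igraph::graph_from_edgelist(cbind(idx[, 1], idx[, 2]), directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0L, nrow(st) - igraph::vcount(gr)))
  igraph::distances(gr, weights = w)
}

#' @export
print.electrode_grid <- function(x, ...) {
  cat("<electrode_grid> ", length(unique(x$sites$needle)), " needles x {",
      paste(x$layers, collapse = ","), "} = ", nrow(x$sites), " sites, spacing ",
      x$spacing_mm, " mm\n", sep = "")
  invisible(x)
}

# site id lookup by needle+layer
grid_site_id <- function(grid, needle, layer) {
  st <- grid$sites
  i <- which(st$needle == needle & st$layer == layer)
  if (length(i) != 1L) stop("no unique site for needle ", needle, " layer ", layer)
  st$site[i]
}
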