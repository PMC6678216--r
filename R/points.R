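#' Generate a synthetic cell-centroid point pattern
#'
#' Emulates the spatial arrangement underlying the cell-scattering metric:
#' cobble-type cells sit in contiguous clusters (inter-point spacing below the
#' neighbor radius), while scattered classes are placed by a hard-core process
#' whose minimum spacing to *every* other point exceeds the neighbor radius,
#' so their neighbor count is zero by construction. A `"paired"` class places
#' isolated touching pairs, giving each member exactly one neighbor — the
#' arrangement that reproduces a per-class median neighbor count of one.
#'
#' @param n_per_class named integer vector of point counts per class label.
#' @param clustering named list/vector giving, per class, either a numeric
#'   cluster radius in µm (points grouped in discs of that radius),
#'   `"scattered"`, or `"paired"`.
#' @param field field of view `c(width, height)` in µm.
#' @param neighbor_radius the adjacency radius the pattern is built against
#'   (default 30 µm).
#' @param cluster_size points per cluster for clustered classes.
#' @param seed RNG seed.
#' @param max_tries rejection-sampling budget per point before giving up.
#' @return A `point_pattern`: list with `coords` (n x 2 matrix, µm) and
#'   `class` (character vector).
#' @export
scatter_pattern <- function(n_per_class,
                            clustering = list(cobble = 12, spindle = "paired",
                                              circular = "scattered"),
                            field = c(1500, 1500), neighbor_radius = 30,
                            cluster_size = 8, seed = 1L, max_tries = 5000L) {
  if (is.null(names(n_per_class)) || any(!nzchar(names(n_per_class))))
    stopf("n_per_class must be named by class label")
  if (any(n_per_class < 0)) stopf("counts must be >= 0")
  if (sum(n_per_class) < 1L) stopf("need at least one point")
  field <- as.numeric(field)
  hard_core <- neighbor_radius * 1.05
  with_seed(seed, {
    coords <- matrix(numeric(0), ncol = 2L)
    cls <- character(0)
    min_dist_to <- function(p) {
      if (!nrow(coords)) Inf
      else sqrt(min((coords[, 1L] - p[1L])^2 + (coords[, 2L] - p[2L])^2))
    }
    place_far <- function(margin) {
      for (i in seq_len(max_tries)) {
        p <- stats::runif(2L) * field
        if (min_dist_to(p) > margin) return(p)
      }
      stopf("field %g x %g too small for hard-core spacing %g after %d tries",
            field[1L], field[2L], margin, max_tries)
    }
    # clustered classes first so scattered points can avoid them
    cluster_spec_of <- function(lab) {
      s <- clustering[[lab]]
      if (is.null(s)) "scattered" else s
    }
    labs <- names(n_per_class)
    numeric_first <- order(!vapply(labs, function(l) is.numeric(cluster_spec_of(l)), TRUE))
    for (lab in labs[numeric_first]) {
      n <- n_per_class[[lab]]
      if (n == 0L) next
      spec <- cluster_spec_of(lab)
      if (is.numeric(spec)) {
        r_cl <- spec
        if (2 * r_cl >= neighbor_radius)
          warnf("cluster radius %g does not guarantee within-cluster adjacency at radius %g",
                r_cl, neighbor_radius)
        placed <- 0L
        while (placed < n) {
          centre <- place_far(hard_core + r_cl)
          k <- min(cluster_size, n - placed)
          ang <- stats::runif(k, 0, 2 * pi)
          rad <- r_cl * sqrt(stats::runif(k))
          pts <- cbind(centre[1L] + rad * cos(ang), centre[2L] + rad * sin(ang))
          coords <- rbind(coords, pts)
          cls <- c(cls, rep(lab, k))
          placed <- placed + k
        }
      } else if (identical(spec, "paired")) {
        if (n %% 2L) warnf("odd count for paired class '%s'; last point placed solo", lab)
        placed <- 0L
        while (placed < n) {
          a <- place_far(hard_core + neighbor_radius)
          coords <- rbind(coords, a)
          cls <- c(cls, lab)
          placed <- placed + 1L
          if (placed < n) {
            ang <- stats::runif(1L, 0, 2 * pi)
            sep <- 0.4 * neighbor_radius
            b <- a + sep * c(cos(ang), sin(ang))
            coords <- rbind(coords, b)
            cls <- c(cls, lab)
            placed <- placed + 1L
          }
        }
      } else if (identical(spec, "scattered")) {
        for (i in seq_len(n)) {
          coords <- rbind(coords, place_far(hard_core))
          cls <- c(cls, lab)
        }
      } else stopf("unknown clustering mode for class '%s'", lab)
    }
    structure(list(coords = unname(coords), class = cls,
                   field = field, neighbor_radius = neighbor_radius),
              class = "point_pattern")
  })
}

#' Count neighbors within a fixed radius
#'
#' For each point, the number of other points (any class) within Euclidean
#' distance `radius`; scattered cells have fewer neighbors than cells in a
#' cluster. Also reports per-class median counts, the summary used to rank
#' how scattered each morphological class is.
#'
#' @param pattern a `point_pattern` (or a list with `coords` and `class`).
#' @param radius adjacency radius in µm (> 0).
#' @return list with `counts` (integer per point) and `medians` (named per
#'   class).
#' @export
neighbor_counts <- function(pattern, radius = 30) {
  if (!is_number(radius) || radius <= 0) stopf("radius must be > 0")
  coords <- as.matrix(pattern$coords)
  n <- nrow(coords)
  if (n == 1L) {
    counts <- 0L
  } else {
    d <- as.matrix(stats::dist(coords))
    counts <- as.integer(rowSums(d <= radius) - 1L)
  }
  medians <- vapply(split(counts, pattern$class), stats::median, 0)
  list(counts = counts, medians = medians)
}
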