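#' Coordinates for a set of taxa
#'
#' Lightweight validated container for one latitude/longitude pair per taxon
#' (decimal degrees, spherical earth).
#'
#' @param taxa Character vector of unique labels.
#' @param lat Latitudes in degrees, in \[-90, 90\].
#' @param lon Longitudes in degrees, in (-180, 180\].
#' @return A data frame of class `geo_points` with columns `taxon`, `lat`,
#'   `lon`.
#' @export
geo_points <- function(taxa, lat, lon) {
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) stop("duplicate taxa in coordinates")
  if (length(lat) != length(taxa) || length(lon) != length(taxa)) {
    stop("taxa, lat and lon must have equal length")
  }
  check_coords(lat, lon)
  structure(data.frame(taxon = taxa, lat = as.numeric(lat), lon = as.numeric(lon),
                       stringsAsFactors = FALSE),
            class = c("geo_points", "data.frame"))
}

check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon))) stop("non-finite coordinates")
  if (any(lat < -90 | lat > 90)) stop("latitude out of [-90, 90]")
  if (any(lon <= -180 | lon > 180)) stop("longitude out of (-180, 180]")
  invisible(TRUE)
}

#' Great-circle distance between two points
#'
#' Haversine great-circle distance on a sphere of the given radius.
#'
#' @param p1,p2 Numeric length-2 vectors `c(lat, lon)` in decimal degrees.
#' @param radius Sphere radius in kilometres (default 6371, the mean earth
#'   radius).
#' @return Distance in kilometres.
#' @examples
#' haversine_distance(c(90, 0), c(-90, 0))  # half great circle, ~20015 km
#' @export
haversine_distance <- function(p1, p2, radius = 6371) {
  check_coords(c(p1[1], p2[1]), c(p1[2], p2[2]))
  # geosphere expects (lon, lat) ordering and returns in the units of r
  geosphere::distHaversine(c(p1[2], p1[1]), c(p2[2], p2[1]), r = radius)
}

#' Pairwise great-circle distance matrix
#'
#' @param points A `geo_points` object (or data frame with `taxon`, `lat`,
#'   `lon`).
#' @param radius Sphere radius in kilometres.
#' @return Symmetric n x n matrix of distances in km, zero diagonal, with
#'   taxa as dimnames.
#' @export
distance_matrix <- function(points, radius = 6371) {
  if (!all(c("taxon", "lat", "lon") %in% names(points))) {
    stop("points must have columns taxon, lat, lon")
  }
  if (nrow(points) < 2) stop("need at least 2 points")
  if (anyDuplicated(points$taxon)) stop("duplicate taxa in coordinates")
  check_coords(points$lat, points$lon)
  xy <- cbind(points$lon, points$lat)
  d <- geosphere::distm(xy, fun = function(a, b) geosphere::distHaversine(a, b, r = radius))
  dimnames(d) <- list(points$taxon, points$taxon)
  d <- (d + t(d)) / 2  # enforce exact symmetry against rounding
  diag(d) <- 0
  d
}

#' Spatial similarity matrix from pairwise distances
#'
#' Converts a distance matrix into the similarity matrix W that plays the
#' role of a spatial covariance component. Raw distances cannot act as a
#' covariance (zero diagonal, values growing with separation), so a
#' decreasing transform with unit diagonal is applied:
#' \describe{
#'   \item{linear (default)}{`w = 1 - d / d_max`; the most distant pair maps
#'     to 0.}
#'   \item{exponential}{`w = exp(-d / rho)` with range parameter `rho` in km
#'     (default `d_max / 3`).}
#' }
#' `d_max` is always taken from the supplied matrix. Note W is not
#' guaranteed positive semidefinite; the model-fitting code treats grid
#' points where the combined covariance is not positive definite as
#' infeasible (see [profile_grid_fit()]).
#'
#' @param d Symmetric distance matrix (km) with zero diagonal.
#' @param transform `"linear"` or `"exponential"`.
#' @param rho Range parameter for the exponential transform, km.
#' @return An object of class `spatial_sim`: list with `taxa`, `w`, `d_max`,
#'   `transform`.
#' @export
spatial_similarity <- function(d, transform = c("linear", "exponential"), rho = NULL) {
  transform <- match.arg(transform)
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-6)) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have zero diagonal")
  if (any(d < 0)) stop("negative distances")
  d_max <- max(d)
  if (d_max <= 0) stop("all distances zero; no spatial structure (d_max = 0)")
  w <- switch(transform,
    linear = 1 - d / d_max,
    exponential = {
      if (is.null(rho)) rho <- d_max / 3
      if (rho <= 0) stop("rho must be positive")
      exp(-d / rho)
    }
  )
  diag(w) <- 1
  taxa <- rownames(d)
  if (is.null(taxa)) taxa <- as.character(seq_len(nrow(d)))
  dimnames(w) <- list(taxa, taxa)
  structure(list(taxa = taxa, w = w, d_max = d_max, transform = transform),
            class = "spatial_sim")
}

#' @export
print.spatial_sim <- function(x, ...) {
  cat("Spatial similarity: ", length(x$taxa), " taxa, ", x$transform,
      " transform, d_max = ", format(x$d_max, digits = 6), " km\n", sep = "")
  invisible(x)
}

#' Write a taxon-labelled matrix as TSV
#'
#' Writes a square matrix (distances, W, Sigma) with a taxon header row and
#' first column, the interchange format used for all matrix reports.
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
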