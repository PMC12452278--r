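#' Build a regular latitude-longitude world grid
#'
#' Cell centres on a uniform lat/lon lattice with cosine-latitude area
#' weights. The synthetic world is entirely ocean: every cell can be sampled
#' and every cell receives environmental fields.
#'
#' @param res Grid resolution in degrees (default 5). Must divide 180.
#' @return A tibble of class `world_grid` with one row per cell and columns
#'   `cell_id`, `lat`, `lon`, `area_w` (cos-latitude weight, strictly
#'   positive). Latitude and longitude vectors are stored as attributes
#'   `lat_centers` / `lon_centers`.
#' @examples
#' g <- world_grid(30)
#' nrow(g) # 6 x 12 cells
#' @export
world_grid <- function(res = 5) {
  stopifnot(is.numeric(res), length(res) == 1)
  if (res <= 0) stop("grid resolution must be positive")
  if (180 %% res != 0) stop("resolution must divide 180 degrees")
  lat <- seq(-90 + res / 2, 90 - res / 2, by = res)
  lon <- seq(-180 + res / 2, 180 - res / 2, by = res)
  cells <- tidyr::expand_grid(lat = lat, lon = lon)
  cells <- dplyr::mutate(cells,
    cell_id = seq_len(nrow(cells)),
    area_w = cos(lat * pi / 180)
  )
  cells <- dplyr::select(cells, "cell_id", "lat", "lon", "area_w")
  stopifnot(all(cells$area_w > 0))
  structure(cells,
    lat_centers = lat, lon_centers = lon, res = res,
    class = c("world_grid", class(cells))
  )
}

#' @keywords internal
assert_world_grid <- function(grid) {
  if (!inherits(grid, "world_grid")) stop("`grid` must be a world_grid")
  if (nrow(grid) == 0) stop("grid has no cells")
  invisible(grid)
}

# Deterministic per-stage seed derived from a global seed and a text tag.
# Plain 32-bit-safe integer arithmetic; keeps results < 2^31.
derive_seed <- function(seed, tag) {
  stopifnot(length(seed) == 1, is.finite(seed))
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(tag)) {
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer(h)
}

# Area-weighted mean with NA handling
weighted_mean_w <- function(x, w) {
  ok <- is.finite(x) & is.finite(w)
  if (!any(ok)) return(NA_real_)
  sum(x[ok] * w[ok]) / sum(w[ok])
}
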