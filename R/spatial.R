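#' Dual-resolution spatial grid
#'
#' The analysis region (the shelf around South Georgia and Shag Rocks,
#' 34-45 degrees W, 53-56 degrees S) is binned at two resolutions: coarse
#' half-degree-latitude by one-degree-longitude boxes for seasonal abundance
#' maps, and 10 km squares for catch-rate and depredation surfaces. The 10 km
#' squares live in a local equirectangular projection about `origin`; over a
#' three-degree latitudinal span the scale distortion of that projection is
#' below 2 percent, which is negligible against the 10 km cell size.
#'
#' All binning uses half-open intervals `[low, high)` with 0-based indices, so
#' a point exactly on a cell edge belongs to the larger-index cell.
#'
#' @param lat_step,lon_step Coarse box size in degrees (default 0.5 x 1).
#' @param km_cell Fine cell size in km (default 10).
#' @param origin Named vector `c(lat = , lon = )`, the projection origin; must
#'   lie inside `region`.
#' @param region List with `lat` and `lon` range vectors (degrees, south/west
#'   negative) bounding the study region.
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(lat_step = 0.5, lon_step = 1, km_cell = 10,
                      origin = c(lat = -54.5, lon = -39.5),
                      region = list(lat = c(-56, -53), lon = c(-45, -34))) {
  .assert_scalar_num(km_cell, "km_cell", min = 1e-6)
  stopifnot(origin[["lat"]] >= region$lat[1], origin[["lat"]] <= region$lat[2],
            origin[["lon"]] >= region$lon[1], origin[["lon"]] <= region$lon[2])
  structure(list(lat_step = lat_step, lon_step = lon_step, km_cell = km_cell,
                 origin = origin, region = region),
            class = "grid_spec")
}

# km per degree at the projection origin (spherical, local scale)
.KM_PER_DEG_LAT <- 110.574
.KM_PER_DEG_LON <- 111.320

.in_region <- function(lat, lon, region) {
  lat >= region$lat[1] & lat < region$lat[2] &
    lon >= region$lon[1] & lon < region$lon[2]
}

.check_region <- function(lat, lon, region, strict) {
  ok <- .in_region(lat, lon, region)
  if (strict && any(!ok)) {
    abort(sprintf("%d point(s) outside the region bounds", sum(!ok)))
  }
  ok
}

#' Great-circle distance in km
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorised over points.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE) ||
      any(abs(c(lon1, lon2)) > 180, na.rm = TRUE)) {
    abort("coordinates out of range: |lat| <= 90, |lon| <= 180 required")
  }
  as.numeric(geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                      r = 6371))
}

#' Assign points to half-degree boxes
#'
#' Floor-based binning of coordinates into the coarse 0.5 x 1 degree boxes,
#' indexed from the south-west corner of the region.
#'
#' @param lat,lon Coordinates in decimal degrees (vectorised).
#' @param grid A [grid_spec()].
#' @param strict If `TRUE` (default) out-of-region points are an error;
#'   otherwise they get `NA` indices.
#' @return Tibble with integer columns `box_i` (latitude row) and `box_j`
#'   (longitude column), 0-based.
#' @export
assign_halfdeg_box <- function(lat, lon, grid = grid_spec(), strict = TRUE) {
  ok <- .check_region(lat, lon, grid$region, strict)
  i <- floor((lat - grid$region$lat[1]) / grid$lat_step)
  j <- floor((lon - grid$region$lon[1]) / grid$lon_step)
  i[!ok] <- NA
  j[!ok] <- NA
  tibble::tibble(box_i = as.integer(i), box_j = as.integer(j))
}

# Local equirectangular projection about the grid origin, in km.
.project_km <- function(lat, lon, grid) {
  x <- (lon - grid$origin[["lon"]]) * .KM_PER_DEG_LON *
    cos(grid$origin[["lat"]] * pi / 180)
  y <- (lat - grid$origin[["lat"]]) * .KM_PER_DEG_LAT
  cbind(x = x, y = y)
}

.unproject_km <- function(x, y, grid) {
  lon <- grid$origin[["lon"]] +
    x / (.KM_PER_DEG_LON * cos(grid$origin[["lat"]] * pi / 180))
  lat <- grid$origin[["lat"]] + y / .KM_PER_DEG_LAT
  cbind(lat = lat, lon = lon)
}

#' Assign points to 10 km cells
#'
#' Projects coordinates into the grid's local equirectangular frame and bins
#' them into `km_cell`-sized squares (floor of x/size, y/size; indices can be
#' negative on the south/west side of the origin).
#'
#' @inheritParams assign_halfdeg_box
#' @return Tibble with integer columns `cell_i` (northing row) and `cell_j`
#'   (easting column).
#' @export
assign_km_cell <- function(lat, lon, grid = grid_spec(), strict = TRUE) {
  ok <- .check_region(lat, lon, grid$region, strict)
  p <- .project_km(lat, lon, grid)
  i <- floor(p[, "y"] / grid$km_cell)
  j <- floor(p[, "x"] / grid$km_cell)
  i[!ok] <- NA
  j[!ok] <- NA
  tibble::tibble(cell_i = as.integer(i), cell_j = as.integer(j))
}

#' Centre and bounds of a 10 km cell
#'
#' @param cell_i,cell_j Integer cell indices from [assign_km_cell()].
#' @param grid A [grid_spec()].
#' @return Tibble with the cell centroid (`lat`, `lon`) and its rectangle
#'   bounds (`lat_min`, `lat_max`, `lon_min`, `lon_max`) in degrees.
#' @export
km_cell_bounds <- function(cell_i, cell_j, grid = grid_spec()) {
  s <- grid$km_cell
  lo <- .unproject_km(cell_j * s, cell_i * s, grid)
  hi <- .unproject_km((cell_j + 1) * s, (cell_i + 1) * s, grid)
  mid <- .unproject_km((cell_j + 0.5) * s, (cell_i + 0.5) * s, grid)
  tibble::tibble(cell_i = as.integer(cell_i), cell_j = as.integer(cell_j),
                 lat = mid[, "lat"], lon = mid[, "lon"],
                 lat_min = lo[, "lat"], lat_max = hi[, "lat"],
                 lon_min = lo[, "lon"], lon_max = hi[, "lon"])
}

#' Five-area partition of the region
#'
#' The region is conventionally split into five named areas: Shag Rocks in the
#' west, and the remaining shelf around South Georgia quartered into
#' north-west, north-east, south-west and south-east. Published maps show the
#' areas without listing boundary coordinates, so the default boundaries here
#' are an explicit, configurable approximation of that layout: everything west
#' of `shag_lon` is Shag Rocks; the rest splits at `split_lat` (north/south)
#' and `split_lon` (west/east). Boundaries follow the same half-open
#' convention as the grids (a point on a boundary belongs to the
#' northern/eastern side).
#'
#' @param shag_lon Longitude (degrees) east of which South Georgia areas start.
#' @param split_lat Latitude separating north (>=) from south.
#' @param split_lon Longitude separating west (<) from east.
#' @param region Region bounds as in [grid_spec()].
#' @return A list of class `area_scheme`.
#' @export
area_scheme <- function(shag_lon = -40, split_lat = -54.4, split_lon = -36.5,
                        region = list(lat = c(-56, -53), lon = c(-45, -34))) {
  structure(list(shag_lon = shag_lon, split_lat = split_lat,
                 split_lon = split_lon, region = region),
            class = "area_scheme")
}

#' Area labels
#' @return Character vector of the five area names.
#' @export
area_labels <- function() {
  c("shag_rocks", "north_west", "north_east", "south_west", "south_east")
}

#' Assign points to named areas
#'
#' @param lat,lon Coordinates in decimal degrees (vectorised).
#' @param scheme An [area_scheme()].
#' @param strict If `TRUE` out-of-region points are an error, else `NA`.
#' @return Character vector of area labels (see [area_labels()]); every
#'   in-region point receives exactly one label.
#' @export
assign_area <- function(lat, lon, scheme = area_scheme(), strict = TRUE) {
  ok <- .check_region(lat, lon, scheme$region, strict)
  north <- lat >= scheme$split_lat
  west <- lon < scheme$split_lon
  lab <- ifelse(lon < scheme$shag_lon, "shag_rocks",
                ifelse(north,
                       ifelse(west, "north_west", "north_east"),
                       ifelse(west, "south_west", "south_east")))
  lab[!ok] <- NA
  lab
}

#' Attach spatial bins to observer records
#'
#' Adds the area label and both grid indices as columns, the form in which
#' binned tables are exported.
#'
#' @param sets Tibble of observer records.
#' @param grid A [grid_spec()].
#' @param scheme An [area_scheme()].
#' @param strict Passed to the assignment functions.
#' @return `sets` with columns `area`, `box_i`, `box_j`, `cell_i`, `cell_j`.
#' @export
bin_sets <- function(sets, grid = grid_spec(), scheme = area_scheme(),
                     strict = TRUE) {
  dplyr::bind_cols(
    sets,
    tibble::tibble(area = assign_area(sets$lat, sets$lon, scheme, strict)),
    assign_halfdeg_box(sets$lat, sets$lon, grid, strict),
    assign_km_cell(sets$lat, sets$lon, grid, strict)
  )
}
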