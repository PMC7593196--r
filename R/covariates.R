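#' WGS-84 ellipsoidal geodesic distance
#'
#' Distance in kilometers between points given as decimal-degree
#' latitude/longitude, on the WGS-84 ellipsoid (Karney's geodesic
#' algorithm via \pkg{geosphere}). Vectorized over \code{lat2}/\code{lon2}.
#' Differs from the great-circle (spherical) distance by up to about
#' 0.5%; e.g. one degree of longitude at the equator is ~111.3 km.
#'
#' @param lat1,lon1 first point, decimal degrees.
#' @param lat2,lon2 second point(s), decimal degrees.
#' @return distance(s) in km.
#' @export
geodesic_distance <- function(lat1, lon1, lat2, lon2) {
  co <- c(lat1, lon1, lat2, lon2)
  if (any(!is.finite(co))) stop("non-finite coordinates")
  if (any(abs(c(lat1, lat2)) > 90)) stop("latitude outside [-90, 90]")
  if (any(abs(c(lon1, lon2)) > 360)) stop("longitude outside plausible range")
  geosphere::distGeo(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}

# normalize longitudes to [-180, 180)
norm_lon <- function(lon) ((lon + 180) %% 360) - 180

#' Nearest grid record to a site
#'
#' Returns the value of the grid record geodesically nearest to the
#' site. Exact distance ties are broken deterministically: lowest
#' latitude first, then lowest longitude.
#'
#' @param lat,lon site coordinates, decimal degrees.
#' @param grid data.frame with columns \code{latitude},
#'   \code{longitude}, \code{value}.
#' @return list: \code{value}, \code{distance_km}, \code{index} (row of
#'   \code{grid} matched).
#' @export
nearest_match <- function(lat, lon, grid) {
  if (!is.data.frame(grid) || nrow(grid) == 0) stop("empty covariate grid")
  d <- geodesic_distance(lat, norm_lon(lon),
                         grid$latitude, norm_lon(grid$longitude))
  # order by distance, then latitude, then longitude: first row wins ties
  i <- order(d, grid$latitude, grid$longitude)[1]
  list(value = grid$value[i], distance_km = d[i], index = i)
}

#' Species abundances from assemblage records within a radius
#'
#' Collects all assemblage records within \code{radius_km} (closed
#' boundary, distance <= radius) of the site and returns the per-species
#' median relative abundance over those records. The default 300 km is
#' the maximum modelled postmortem drift of settling foraminifera
#' shells. If no record falls within the radius, the single nearest
#' record's abundances are returned with a warning, so the site stays
#' analyzable.
#'
#' @param lat,lon site coordinates, decimal degrees.
#' @param assemblage long-format data.frame with columns
#'   \code{latitude}, \code{longitude}, \code{species},
#'   \code{abundance}; rows sharing coordinates form one record.
#' @param radius_km search radius, km (> 0).
#' @return list: \code{abundance} (named per-species vector),
#'   \code{n_records} (assemblage records used),
#'   \code{nearest_km} (distance to the nearest record).
#' @export
radius_median_abundance <- function(lat, lon, assemblage, radius_km = 300) {
  if (!is.data.frame(assemblage) || nrow(assemblage) == 0)
    stop("empty assemblage table")
  if (!is.finite(radius_km) || radius_km <= 0) stop("radius_km must be > 0")

  key <- paste(assemblage$latitude, assemblage$longitude, sep = "\r")
  urec <- !duplicated(key)
  d_u <- geodesic_distance(lat, norm_lon(lon),
                           assemblage$latitude[urec],
                           norm_lon(assemblage$longitude[urec]))
  d <- d_u[match(key, key[urec])]

  use <- d <= radius_km
  if (!any(use)) {
    nearest_key <- key[which.min(d)]
    warning("no assemblage record within ", radius_km,
            " km; falling back to the nearest record at ",
            round(min(d), 1), " km")
    use <- key == nearest_key
  }
  sub <- assemblage[use, , drop = FALSE]
  ab <- tapply(sub$abundance, sub$species, stats::median)
  ab <- stats::setNames(as.numeric(ab), names(ab))
  list(
    abundance = ab[!is.na(ab)],
    n_records = length(unique(key[use])),
    nearest_km = min(d)
  )
}

#' Attach environmental and abundance covariates to sites
#'
#' For every site, matches the nearest SST and NPP grid records
#' (geodesic WGS-84 distance) and retrieves the focal species'
#' relative abundance both from the single nearest assemblage record
#' and as the median over records within \code{radius_km}.
#'
#' @param sites data.frame with \code{site_id}, \code{latitude},
#'   \code{longitude}.
#' @param grids named list of covariate grids (each latitude /
#'   longitude / value); typically \code{list(sst = ..., npp = ...)}.
#' @param assemblage long-format assemblage table (see
#'   [radius_median_abundance()]); may be NULL to skip abundance.
#' @param species focal species name(s) for abundance extraction; NULL
#'   = all species in the assemblage.
#' @param radius_km radius for the median-abundance variant.
#' @return data.frame, one row per site x species (or per site when
#'   assemblage is NULL): site_id, covariate values, match distances
#'   (km), abundance_nearest, abundance_radius, n_records_radius.
#' @export
match_covariates <- function(sites, grids, assemblage = NULL,
                             species = NULL, radius_km = 300) {
  stopifnot(is.data.frame(sites))
  env <- lapply(seq_len(nrow(sites)), function(i) {
    row <- list(site_id = sites$site_id[i])
    for (v in names(grids)) {
      m <- nearest_match(sites$latitude[i], sites$longitude[i], grids[[v]])
      row[[v]] <- m$value
      row[[paste0(v, "_dist_km")]] <- m$distance_km
    }
    row
  })
  env <- do.call(rbind, lapply(env, as.data.frame))

  if (is.null(assemblage)) return(env)
  if (is.null(species)) species <- sort(unique(assemblage$species))

  ab <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    rm <- radius_median_abundance(sites$latitude[i], sites$longitude[i],
                                  assemblage, radius_km)
    # nearest single record = radius shrunk to the nearest distance
    nr <- radius_median_abundance(sites$latitude[i], sites$longitude[i],
                                  assemblage, max(rm$nearest_km, 1e-9))
    data.frame(
      site_id = sites$site_id[i],
      species = species,
      abundance_nearest = unname(nr$abundance[species]),
      abundance_radius = unname(rm$abundance[species]),
      n_records_radius = rm$n_records,
      abundance_dist_km = rm$nearest_km,
      stringsAsFactors = FALSE
    )
  }))
  merge(env, ab, by = "site_id", sort = FALSE)
}
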