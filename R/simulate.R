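# Synthetic ground-truthed imagery.
#
# Two generators stand in for real acquisitions: a two-color STED-like
# field of nuclear pore complexes (ring-arranged gp210 subunit clusters in
# the red channel, one central pan-FG cluster per pore in the green
# channel), and a single-color SMLM-like field of active zones composed of
# adjacent molecule clusters.  Both emit exact ground truth so recovery can
# be measured, and both are bit-reproducible under a fixed seed.

#' Nuclear-pore field simulation parameters
#'
#' Defaults emulate a just-resolved STED regime: at 15 nm pixels a 40 nm
#' PSF (sigma ~1.13 px) against an 80 nm ring radius puts neighbouring
#' subunits of an 8-fold pore ~61 nm apart — about 1.5 PSF widths, so
#' individual subunits are separable but close, which is exactly the regime
#' that requires Gaussian fusion to see whole pores.
#'
#' @param image_size_px Square field edge length, pixels.
#' @param pixel_size_nm Physical pixel size, nm.
#' @param n_pores Number of pores to place.
#' @param ring_radius_nm Subunit ring radius (gp210 ring ~160 nm across).
#' @param subunits_per_pore Clusters on the ring (8 for the native pore).
#' @param psf_fwhm_nm PSF full width at half maximum, nm.
#' @param subunit_intensity_range Two-element range; each subunit's peak
#'   amplitude is drawn uniformly from it, modelling the per-cluster
#'   intensity variation of merged super-resolved objects.
#' @param pan_fg_intensity Peak amplitude of the central green cluster.
#' @param background_level Constant background added to both channels.
#' @param poisson_noise Resample every pixel as Poisson(intensity).
#' @param read_noise_sd Additive Gaussian read noise SD (clipped at 0).
#' @param min_pore_separation_nm Minimum centre-to-centre distance;
#'   default 3x the ring diameter so fusion never merges two pores.
#' @param angular_jitter_deg Per-subunit angular jitter SD, degrees.
#' @param seed Integer RNG seed; one seed governs every draw.
#' @return A list of class `sr_npc_params`.
#' @export
npc_simulation_params <- function(image_size_px = 512L,
                                  pixel_size_nm = 15,
                                  n_pores = 60L,
                                  ring_radius_nm = 80,
                                  subunits_per_pore = 8L,
                                  psf_fwhm_nm = 40,
                                  subunit_intensity_range = c(120, 220),
                                  pan_fg_intensity = 180,
                                  background_level = 10,
                                  poisson_noise = TRUE,
                                  read_noise_sd = 2,
                                  min_pore_separation_nm = 6 * ring_radius_nm,
                                  angular_jitter_deg = 4,
                                  seed = 1L) {
  p <- list(image_size_px = as.integer(image_size_px),
            pixel_size_nm = pixel_size_nm, n_pores = as.integer(n_pores),
            ring_radius_nm = ring_radius_nm,
            subunits_per_pore = as.integer(subunits_per_pore),
            psf_fwhm_nm = psf_fwhm_nm,
            subunit_intensity_range = subunit_intensity_range,
            pan_fg_intensity = pan_fg_intensity,
            background_level = background_level,
            poisson_noise = isTRUE(poisson_noise),
            read_noise_sd = read_noise_sd,
            min_pore_separation_nm = min_pore_separation_nm,
            angular_jitter_deg = angular_jitter_deg,
            seed = as.integer(seed))
  stopifnot(p$image_size_px >= 16L, p$pixel_size_nm > 0, p$n_pores >= 1L,
            p$ring_radius_nm > 0, p$subunits_per_pore >= 1L,
            p$psf_fwhm_nm > 0, length(p$subunit_intensity_range) == 2L,
            all(p$subunit_intensity_range > 0),
            diff(p$subunit_intensity_range) >= 0,
            p$background_level >= 0, p$read_noise_sd >= 0,
            p$min_pore_separation_nm > 0, p$angular_jitter_deg >= 0)
  class(p) <- "sr_npc_params"
  p
}

# Rejection-sample n points in [margin, size - margin]^2 (px) with pairwise
# separation >= min_sep_px; placement error after max_tries draws.
place_centers <- function(n, size_px, margin_px, min_sep_px, max_tries = 10000L) {
  centers <- matrix(NA_real_, n, 2L)
  placed <- 0L
  lo <- margin_px
  hi <- size_px - margin_px
  if (hi <= lo)
    stop_srseg("field too small for the requested geometry", "placement")
  for (try in seq_len(max_tries)) {
    cand <- stats::runif(2L, lo, hi)
    if (placed == 0L ||
        all((centers[seq_len(placed), 1L] - cand[1L])^2 +
            (centers[seq_len(placed), 2L] - cand[2L])^2 >= min_sep_px^2)) {
      placed <- placed + 1L
      centers[placed, ] <- cand
      if (placed == n) return(centers)
    }
  }
  stop_srseg(sprintf(
    "could not place %d objects with separation %.1f px in %d tries",
    n, min_sep_px, max_tries), "placement")
}

# Accumulate 2D Gaussian spots onto a field. spots: matrix (row, col,
# amplitude); sigma in px.  Window of 5 sigma per spot.
render_spots <- function(size_px, spots, sigma_px) {
  field <- matrix(0, size_px, size_px)
  if (is.null(spots) || nrow(spots) == 0L) return(field)
  w <- max(2L, as.integer(ceiling(5 * sigma_px)))
  for (i in seq_len(nrow(spots))) {
    r0 <- spots[i, 1L]; c0 <- spots[i, 2L]; A <- spots[i, 3L]
    rr <- max(1L, floor(r0 - w)):min(size_px, ceiling(r0 + w))
    cc <- max(1L, floor(c0 - w)):min(size_px, ceiling(c0 + w))
    g <- A * outer(exp(-(rr - r0)^2 / (2 * sigma_px^2)),
                   exp(-(cc - c0)^2 / (2 * sigma_px^2)))
    field[rr, cc] <- field[rr, cc] + g
  }
  field
}

apply_noise <- function(field, poisson, read_sd) {
  if (poisson) field <- matrix(stats::rpois(length(field), field),
                               nrow(field), ncol(field))
  if (read_sd > 0) {
    field <- field + matrix(stats::rnorm(length(field), 0, read_sd),
                            nrow(field), ncol(field))
    field[field < 0] <- 0
  }
  field
}

#' Simulate a two-color STED-like nuclear pore field
#'
#' Red channel: for each pore, `subunits_per_pore` Gaussian spots of FWHM
#' `psf_fwhm_nm` placed at equal angles (plus jitter) on a ring, each with
#' an independent uniform peak amplitude, over a constant background.
#' Green channel: one central Gaussian spot per pore.  Optional Poisson
#' resampling and additive read noise.  Deterministic under the seed.
#'
#' @param params An [npc_simulation_params()] object.
#' @return A list: `image` ([sr_multichannel] with channels `"red"`,
#'   `"green"`) and `truth` (list with `pore_centers_px` (n x 2 matrix,
#'   1-based row/col), `subunit_positions_px` (list of matrices),
#'   `pan_fg_positions_px`, `true_counts`, and the echoed `params`).
#' @export
simulate_npc_field <- function(params = npc_simulation_params()) {
  stopifnot(inherits(params, "sr_npc_params"))
  p <- params
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(p$seed)
  nm2px <- 1 / p$pixel_size_nm
  ring_px <- p$ring_radius_nm * nm2px
  sigma_px <- fwhm_to_sigma(p$psf_fwhm_nm * nm2px)
  margin <- ring_px + 5 * sigma_px + 1
  centers <- place_centers(p$n_pores, p$image_size_px, margin,
                           p$min_pore_separation_nm * nm2px)
  subunits <- vector("list", p$n_pores)
  spots <- NULL
  for (i in seq_len(p$n_pores)) {
    base <- stats::runif(1L, 0, 2 * pi)
    ang <- base + (seq_len(p$subunits_per_pore) - 1L) * 2 * pi / p$subunits_per_pore
    if (p$angular_jitter_deg > 0)
      ang <- ang + stats::rnorm(p$subunits_per_pore, 0,
                                p$angular_jitter_deg * pi / 180)
    amp <- stats::runif(p$subunits_per_pore,
                        p$subunit_intensity_range[1L],
                        p$subunit_intensity_range[2L])
    pos <- cbind(centers[i, 1L] + ring_px * sin(ang),
                 centers[i, 2L] + ring_px * cos(ang))
    subunits[[i]] <- pos
    spots <- rbind(spots, cbind(pos, amp))
  }
  red <- render_spots(p$image_size_px, spots, sigma_px) + p$background_level
  green <- render_spots(p$image_size_px,
                        cbind(centers, rep(p$pan_fg_intensity, p$n_pores)),
                        sigma_px) + p$background_level
  red <- apply_noise(red, p$poisson_noise, p$read_noise_sd)
  green <- apply_noise(green, p$poisson_noise, p$read_noise_sd)
  img <- sr_multichannel(
    list(sr_image(red, p$pixel_size_nm, "sim_npc_red"),
         sr_image(green, p$pixel_size_nm, "sim_npc_green")),
    c("red", "green"))
  truth <- list(pore_centers_px = centers,
                subunit_positions_px = subunits,
                pan_fg_positions_px = centers,
                true_counts = rep(p$subunits_per_pore, p$n_pores),
                params = p)
  list(image = img, truth = truth)
}

#' Active-zone field simulation parameters
#'
#' SMLM-like scene: well-separated zones, each a loose group of small
#' molecule clusters (e.g. Bruchpilot clusters at a fly neuromuscular
#' junction active zone).
#'
#' @param image_size_px,n_zones,clusters_per_zone Field edge, zone count,
#'   clusters per zone (scalar).
#' @param cluster_sigma_px Gaussian sigma of a single cluster, px.
#' @param zone_spread_px Clusters are placed uniformly in a disc of this
#'   radius around the zone centre.
#' @param zone_separation_px Minimum zone centre separation.
#' @param min_cluster_separation_px Minimum within-zone cluster separation
#'   (keeps clusters adjacent but individually resolvable).
#' @param intensity_range Uniform per-cluster peak amplitude range.
#' @param background_level,poisson_noise,read_noise_sd,seed As for
#'   [npc_simulation_params()].
#' @return A list of class `sr_az_params`.
#' @export
az_simulation_params <- function(image_size_px = 256L,
                                 n_zones = 2L,
                                 clusters_per_zone = 5L,
                                 cluster_sigma_px = 1.2,
                                 zone_spread_px = 8,
                                 zone_separation_px = 60,
                                 min_cluster_separation_px = 5,
                                 intensity_range = c(120, 220),
                                 background_level = 5,
                                 poisson_noise = FALSE,
                                 read_noise_sd = 0,
                                 seed = 1L) {
  p <- list(image_size_px = as.integer(image_size_px),
            n_zones = as.integer(n_zones),
            clusters_per_zone = as.integer(clusters_per_zone),
            cluster_sigma_px = cluster_sigma_px,
            zone_spread_px = zone_spread_px,
            zone_separation_px = zone_separation_px,
            min_cluster_separation_px = min_cluster_separation_px,
            intensity_range = intensity_range,
            background_level = background_level,
            poisson_noise = isTRUE(poisson_noise),
            read_noise_sd = read_noise_sd, seed = as.integer(seed))
  stopifnot(p$n_zones >= 1L, p$clusters_per_zone >= 1L,
            p$cluster_sigma_px > 0, p$zone_spread_px > 0,
            p$zone_separation_px > 0, all(p$intensity_range > 0))
  class(p) <- "sr_az_params"
  p
}

#' Simulate an SMLM-like active-zone field
#'
#' @param params An [az_simulation_params()] object.
#' @return A list: `image` ([sr_image]) and `truth` (list with
#'   `zone_centers_px`, `cluster_positions_px` (list of matrices, one per
#'   zone), `true_counts`, `params`).
#' @export
simulate_active_zones <- function(params = az_simulation_params()) {
  stopifnot(inherits(params, "sr_az_params"))
  p <- params
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(p$seed)
  margin <- p$zone_spread_px + 5 * p$cluster_sigma_px + 1
  centers <- place_centers(p$n_zones, p$image_size_px, margin,
                           p$zone_separation_px)
  clusters <- vector("list", p$n_zones)
  spots <- NULL
  for (i in seq_len(p$n_zones)) {
    pos <- place_centers(p$clusters_per_zone,
                         size_px = 2 * p$zone_spread_px,
                         margin_px = 0,
                         min_sep_px = p$min_cluster_separation_px)
    pos <- sweep(pos, 2L, c(p$zone_spread_px, p$zone_spread_px))  # centre
    pos <- sweep(pos, 2L, centers[i, ], "+")
    amp <- stats::runif(p$clusters_per_zone,
                        p$intensity_range[1L], p$intensity_range[2L])
    clusters[[i]] <- pos
    spots <- rbind(spots, cbind(pos, amp))
  }
  field <- render_spots(p$image_size_px, spots, p$cluster_sigma_px) +
    p$background_level
  field <- apply_noise(field, p$poisson_noise, p$read_noise_sd)
  list(image = sr_image(field, NA_real_, "sim_active_zones"),
       truth = list(zone_centers_px = centers,
                    cluster_positions_px = clusters,
                    true_counts = rep(p$clusters_per_zone, p$n_zones),
                    params = p))
}

# Save/restore the global RNG state so simulation seeds never leak into the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
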