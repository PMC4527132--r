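# YAML pipeline configuration: a small, flat, human-readable file with one
# section per stage.  Every omitted key falls back to the preset default
# and the fully resolved configuration is echoed into output provenance,
# from which it re-parses to an equal configuration.

seg_param_keys <- c("threshold_pre_smooth_px", "declump_method",
                    "suppression_distance_px", "min_diameter_px",
                    "max_diameter_px", "discard_border")

merge_seg_params <- function(base, override, section) {
  if (is.null(override)) return(base)
  unknown <- setdiff(names(override), seg_param_keys)
  if (length(unknown))
    stop_srseg(sprintf("unknown key '%s' in section '%s'", unknown[1L], section),
               "config")
  vals <- unclass(base)
  vals[names(override)] <- override
  do.call(segmentation_params, vals)
}

#' Parse a pipeline configuration file
#'
#' Reads a YAML file with optional sections `donut`, `clusters`, `panfg`
#' (each accepting the [segmentation_params()] keys plus, where relevant,
#' `fusion_diameter_px`, `smooth_px` or `preprocess`) and top-level keys
#' `pipeline` (`"npc"` or `"az"`) and `pixel_size_nm`.  Unknown keys are
#' rejected by name; all defaults are resolved at parse time.
#'
#' @param path Path to a YAML configuration file.
#' @return An [npc_pipeline_config()] or [az_pipeline_config()] object.
#' @export
parse_config <- function(path) {
  if (!file.exists(path))
    stop_srseg(sprintf("config file not found: %s", path), "io")
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  top_keys <- c("pipeline", "pixel_size_nm", "ring_radius_nm",
                "donut", "clusters", "panfg", "zones")
  unknown <- setdiff(names(raw), top_keys)
  if (length(unknown))
    stop_srseg(sprintf("unknown key '%s' in config", unknown[1L]), "config")
  kind <- if (is.null(raw$pipeline)) "npc" else raw$pipeline
  if (!kind %in% c("npc", "az"))
    stop_srseg(sprintf("unknown pipeline kind '%s' (npc or az)", kind), "config")
  if (kind == "az") {
    base <- az_pipeline_config()
    zo <- raw$zones; cl <- raw$clusters
    fus <- if (!is.null(zo$fusion_diameter_px)) zo$fusion_diameter_px
           else base$zone_fusion_diameter_px
    zo$fusion_diameter_px <- NULL
    return(az_pipeline_config(
      zone_fusion_diameter_px = fus,
      zone_params = merge_seg_params(base$zone_params, zo, "zones"),
      cluster_params = merge_seg_params(base$cluster_params, cl, "clusters")))
  }
  px <- if (is.null(raw$pixel_size_nm)) 15 else raw$pixel_size_nm
  rr <- if (is.null(raw$ring_radius_nm)) 80 else raw$ring_radius_nm
  base <- npc_pipeline_config(pixel_size_nm = px, ring_radius_nm = rr)
  don <- raw$donut; cl <- raw$clusters; pf <- raw$panfg
  fus <- if (!is.null(don$fusion_diameter_px)) don$fusion_diameter_px
         else base$donut_fusion_diameter_px
  don$fusion_diameter_px <- NULL
  pre <- if (!is.null(cl$preprocess)) cl$preprocess else "none"
  cl$preprocess <- NULL
  smo <- if (!is.null(pf$smooth_px)) pf$smooth_px else base$panfg_smooth_px
  pf$smooth_px <- NULL
  npc_pipeline_config(
    pixel_size_nm = px, ring_radius_nm = rr,
    donut_fusion_diameter_px = fus,
    donut_params = merge_seg_params(base$donut_params, don, "donut"),
    cluster_params = merge_seg_params(base$cluster_params, cl, "clusters"),
    panfg_smooth_px = smo,
    panfg_params = merge_seg_params(base$panfg_params, pf, "panfg"),
    cluster_preprocess = pre)
}

#' Serialise a pipeline configuration to YAML
#'
#' The provenance counterpart of [parse_config()]: `parse_config` on the
#' written file returns an equal configuration.
#'
#' @param cfg An `sr_npc_config` or `sr_az_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(cfg, path) {
  as_plain <- function(p) unclass(p)[seg_param_keys]
  out <- if (inherits(cfg, "sr_npc_config")) {
    don <- as_plain(cfg$donut_params)
    don$fusion_diameter_px <- cfg$donut_fusion_diameter_px
    cl <- as_plain(cfg$cluster_params)
    if (!identical(cfg$cluster_preprocess, "none"))
      cl$preprocess <- cfg$cluster_preprocess
    pf <- as_plain(cfg$panfg_params)
    pf$smooth_px <- cfg$panfg_smooth_px
    list(pipeline = "npc", donut = don, clusters = cl, panfg = pf)
  } else if (inherits(cfg, "sr_az_config")) {
    zo <- as_plain(cfg$zone_params)
    zo$fusion_diameter_px <- cfg$zone_fusion_diameter_px
    list(pipeline = "az", zones = zo,
         clusters = as_plain(cfg$cluster_params))
  } else stop_srseg("not a pipeline configuration", "type")
  yaml::write_yaml(out, path)
  invisible(path)
}
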