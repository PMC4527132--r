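# Example two-color nuclear-pore pipeline configuration.
# Any key may be omitted; omitted keys take the preset defaults shown here.
# All sizes are in pixels.

pipeline: npc

donut:                         # parent stage: Gaussian-fused pore rings
  fusion_diameter_px: 10.667   # artifact diameter (FWHM) fusing subunits;
                               # default = ring diameter / pixel size
  threshold_pre_smooth_px: 1.0 # MCT pre-smoothing sigma
  declump_method: shape        # fused parents declump by shape, not intensity
  suppression_distance_px: auto  # median equivalent radius of first-pass objects
  min_diameter_px: 6
  max_diameter_px: 60
  discard_border: true         # partial pores at the field edge are not countable

clusters:                      # child stage: subunit clusters in the raw image
  # preprocess: bandpass:3:40  # optional: none | smooth3x3 | bandpass:S:L
  threshold_pre_smooth_px: 1.0
  declump_method: intensity
  suppression_distance_px: 2.0 # ~ median radius of single-PSF clusters
  min_diameter_px: 1.5
  max_diameter_px: 12
  discard_border: false        # children inherit the border policy via parents

panfg:                         # central-channel stage (green)
  smooth_px: 5.0               # published pan-FG Gaussian
  declump_method: shape
  suppression_distance_px: auto
  min_diameter_px: 2
  max_diameter_px: 30
  discard_border: false
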