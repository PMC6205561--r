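# Example override config for conepercept::load_config().
# Only keys that differ from default_config() need to be listed.
mosaic:
  spacing: 1.2          # arcmin; sparser mosaic, e.g. slightly more eccentric
  s_fraction: 0.0       # L/M-only patch
session:
  intensities: [0.3, 0.6, 1.2]
observer:
  slope: 3.0
  locus_sd: 0.2
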