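{
  "seed": 7,
  "scene": {
    "rows": 64,
    "cols": 64,
    "pixel_size": 15,
    "lai_mean": 2.6,
    "lai_sd": 0.8,
    "plot_count": 51,
    "plot_radius": 8.5,
    "track_spacing": 300,
    "along_track_step": 100,
    "truth_variogram": {
      "kind": "spherical",
      "nugget": 0.05,
      "psill": 0.95,
      "range_a": 450
    }
  },
  "lag_width": 30,
  "max_lag": 450,
  "budget": 60
}
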