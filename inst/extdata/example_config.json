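{
  "geometry": {
    "source": "synthetic",
    "synthetic": {
      "n_frames": 16,
      "severity": 0.5,
      "sten_center": 4,
      "sten_extent": 3,
      "tort_amplitude": 0.3,
      "contour_noise": 0.02
    },
    "extensions": { "inlet_length": 4, "outlet_length": 6 }
  },
  "fluid": { "density_kg_m3": 1060, "viscosity_pa_s": 0.0035 },
  "waveform": { "type": "default", "u_mean": 0.1, "period": 0.4 },
  "grid": { "cells_per_diameter": 10, "margin_cells": 3 },
  "solver": { "cycles": 3, "discard": 1, "records_per_cycle": 50 },
  "species": [
    { "name": "neutrophil", "k_max": 2, "mode": "tracked" },
    { "name": "neutrophil", "k_max": 2, "mode": "uniform" }
  ],
  "output_dir": "results/run1",
  "seed": 1
}
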