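{
  "groups": {
    "WT": 5,
    "Tg": 8
  },
  "control": "WT",
  "seed": 1,
  "noise": true,
  "t_star": 20,
  "phantom": false,
  "presets": {
    "control": {
      "name": "control",
      "n_default": 5,
      "true_K1": 0.8,
      "true_k2": 0.15,
      "plasma_scale": 1,
      "noise_scale": 2,
      "idif_dilution": 1
    },
    "WT": {
      "name": "WT",
      "n_default": 5,
      "true_K1": 0.8,
      "true_k2": 0.15,
      "plasma_scale": 1,
      "noise_scale": 2,
      "idif_dilution": 1
    },
    "Tg": {
      "name": "Tg",
      "n_default": 8,
      "true_K1": 0.363636363636364,
      "true_k2": 0.15,
      "plasma_scale": 1.8,
      "noise_scale": 2,
      "idif_dilution": 1
    },
    "oct12_ko": {
      "name": "oct12_ko",
      "n_default": 4,
      "true_K1": 0.266666666666667,
      "true_k2": 0.15,
      "plasma_scale": 3,
      "noise_scale": 2,
      "idif_dilution": 1
    },
    "cimetidine": {
      "name": "cimetidine",
      "n_default": 5,
      "true_K1": 0.32,
      "true_k2": 0.15,
      "plasma_scale": 2.5,
      "noise_scale": 2,
      "idif_dilution": 1
    },
    "pyrimethamine": {
      "name": "pyrimethamine",
      "n_default": 4,
      "true_K1": 0.8,
      "true_k2": 0.15,
      "plasma_scale": 0.909090909090909,
      "noise_scale": 2,
      "idif_dilution": 1
    }
  },
  "schedule": {
    "frame_start_s": [0, 6, 12, 18, 24, 30, 36, 42, 48, 54, 60, 90, 120, 150, 180, 210, 240, 270, 300, 360, 420, 480, 540, 600, 900, 1200, 1500, 1800, 2400, 3000, 3600, 4200, 4800],
    "frame_duration_s": [6, 6, 6, 6, 6, 6, 6, 6, 6, 6, 30, 30, 30, 30, 30, 30, 30, 30, 60, 60, 60, 60, 60, 300, 300, 300, 300, 600, 600, 600, 600, 600, 600]
  },
  "reference_input": {
    "amplitude_kBq_mL": [3000, 400, 120],
    "rate_per_min": [8, 0.6, 0.02],
    "delay_min": 0.1
  },
  "zero_cortex": [],
  "fine_dt": 0.0025,
  "package_version": "0.1.0"
}
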