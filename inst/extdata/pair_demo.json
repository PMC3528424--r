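{
  "schema_version": 1,
  "tissue_area_mm2": 4096,
  "tumor_tissue_ratio": 0.3125,
  "conductivity_ratio": 1,
  "electrode_diameter_mm": 2,
  "groups": [
    {
      "voltage_V": 1300,
      "electrodes": [
        {
          "id": "a1",
          "x_mm": -8,
          "y_mm": 0,
          "polarity": "anode"
        },
        {
          "id": "c1",
          "x_mm": 8,
          "y_mm": 0,
          "polarity": "cathode"
        }
      ]
    }
  ],
  "thresholds": {
    "e_rev": 300,
    "e_irrev": 800,
    "unit": "V/cm"
  },
  "mesh": {
    "n_x": 400,
    "n_y": 400
  },
  "render": {
    "palette": "hot",
    "output_size": 400
  },
  "seed": 1
}
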