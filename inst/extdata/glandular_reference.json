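{
  "version": "1.0",
  "source": "synthetic standard tile (generateTile, size 256, no nuclei, seed 1000)",
  "centroid": [205.93942428035, 8.1712140175219, 4.14637046307885, 87.0884856070088, 7.10118898623279, 3.32127659574468, 215.530725907384, 4.15707133917397, 2.07590738423029],
  "feature_names": ["R_med", "R_iqr", "R_mad", "G_med", "G_iqr", "G_mad", "B_med", "B_iqr", "B_mad"]
}
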