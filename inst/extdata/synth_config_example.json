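{
  "peptide": "Ac-A{Nle}{R8}TYTGIF{S5}DQVLSVLK{Sar}ee|3-10",
  "n_pl": 40,
  "n_to": 32,
  "box": [6, 6, 10],
  "plane_z": 2,
  "depth": -0.3,
  "leaflet": "upper",
  "planted_contacts": 2,
  "hbond_fraction": 0.105,
  "jitter_sd": 0.05,
  "n_frames": 100,
  "seed": 1
}
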