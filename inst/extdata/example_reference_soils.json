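[
  {"RA": 108.79, "T2": 90.78, "T3": 78.55, "D250": 0.25, "Humus": 0.38, "pH": 8, "Clay": 6.7, "Sand": 90.4, "Sample Name": "sand"},
  {"RA": 101.09, "T2": 102.81, "T3": 86.81, "D250": 0.16, "Humus": 0.33, "pH": 7.9, "Clay": 5.9, "Sand": 85.4, "Sample Name": "sand"},
  {"RA": 101.09, "T2": 98.46, "T3": 71.99, "D250": 0.25, "Humus": 0.31, "pH": 8, "Clay": 6.3, "Sand": 88.7, "Sample Name": "sand"},
  {"RA": 104.95, "T2": 101.59, "T3": 71.93, "D250": 0.48, "Humus": 0.55, "pH": 5.3, "Clay": 8.5, "Sand": 81.7, "Sample Name": "light loam"}
]
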