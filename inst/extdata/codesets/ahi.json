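{
  "name": "ahi",
  "includes": [
    "X30", "X32",
    "T670", "T671", "T672", "T673", "T674",
    "T675", "T676", "T677", "T678", "T679",
    "E860", "E868",
    "N17",
    "R508", "R509",
    "M628", "T296", "G210",
    "E87", "E875",
    "R55"
  ],
  "excludes": ["W92"]
}
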