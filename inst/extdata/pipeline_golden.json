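{
  "seed": 5,
  "config_hash": "f1f225704c024ee746d04eff3ae45420",
  "scenes": {
    "direct": {
      "seed": 1005,
      "truth": {
        "r0": 20,
        "w0": 10
      },
      "r": 19.6542263060561,
      "sigma": 4.08878160684926,
      "w": 9.60863677609576,
      "ci95_r": 0.116008399198815,
      "ci95_w": 0.466992200678375,
      "n_sections": 20,
      "linkage_min": 2.34990791800825,
      "linkage_max": 11.958544694104
    },
    "indirect": {
      "seed": 2005,
      "truth": {
        "r0": 23,
        "w0": 16
      },
      "r": 23.2728942246336,
      "sigma": 6.23790098523065,
      "w": 14.659067315292,
      "ci95_r": 0.153093832241783,
      "ci95_w": 0.47831422675465,
      "n_sections": 20,
      "linkage_min": 3.44336056698759,
      "linkage_max": 18.1024278822796
    }
  },
  "comparison": {
    "conditions": ["direct", "indirect"],
    "r": {
      "F": 1363.43425175507,
      "df1": 1,
      "df2": 19,
      "p": 3.72911230097422e-19,
      "reconstruction": "ci-of-mean",
      "methodSensitive": true
    },
    "w": {
      "F": 219.276164566459,
      "df1": 1,
      "df2": 19,
      "p": 6.90261906973536e-12,
      "reconstruction": "ci-of-mean",
      "methodSensitive": true
    }
  }
}
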