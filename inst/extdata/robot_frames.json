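{
  "schema_version": "1.0",
  "frames": [
    {
      "segment": "pelvis",
      "origin": ["RASI", "LASI"],
      "primary": {
        "label": "z",
        "from": "LASI",
        "to": "RASI"
      },
      "secondary": {
        "label": "x",
        "from": ["RPSI", "LPSI"],
        "to": ["RASI", "LASI"]
      }
    },
    {
      "segment": "thigh_r",
      "origin": ["RKNL", "RKNM"],
      "primary": {
        "label": "z",
        "from": "RKNM",
        "to": "RKNL"
      },
      "secondary": {
        "label": "y",
        "from": ["RKNL", "RKNM"],
        "to": "R_HJC"
      }
    },
    {
      "segment": "shank_r",
      "origin": ["RANL", "RANM"],
      "primary": {
        "label": "z",
        "from": "RANM",
        "to": "RANL"
      },
      "secondary": {
        "label": "y",
        "from": ["RANL", "RANM"],
        "to": ["RKNL", "RKNM"]
      }
    },
    {
      "segment": "foot_r",
      "origin": "RHEE",
      "primary": {
        "label": "x",
        "from": "RHEE",
        "to": "RTOE"
      },
      "secondary": {
        "label": "y",
        "plane": ["RHEE", "RMT5", "RTOE"]
      }
    },
    {
      "segment": "thigh_l",
      "origin": ["LKNL", "LKNM"],
      "primary": {
        "label": "z",
        "from": "LKNL",
        "to": "LKNM"
      },
      "secondary": {
        "label": "y",
        "from": ["LKNL", "LKNM"],
        "to": "L_HJC"
      }
    },
    {
      "segment": "shank_l",
      "origin": ["LANL", "LANM"],
      "primary": {
        "label": "z",
        "from": "LANL",
        "to": "LANM"
      },
      "secondary": {
        "label": "y",
        "from": ["LANL", "LANM"],
        "to": ["LKNL", "LKNM"]
      }
    },
    {
      "segment": "foot_l",
      "origin": "LHEE",
      "primary": {
        "label": "x",
        "from": "LHEE",
        "to": "LTOE"
      },
      "secondary": {
        "label": "y",
        "plane": ["LHEE", "LTOE", "LMT5"]
      }
    }
  ],
  "virtual_points": {
    "R_HJC": {
      "segment": "pelvis",
      "local": [0, 0, 0.08]
    },
    "L_HJC": {
      "segment": "pelvis",
      "local": [0, 0, -0.08]
    }
  },
  "model_frames": {
    "pelvis": {
      "rotation": [
        [
          0.997458699830735,
          0.0712470499879096,
          0
        ],
        [
          -0.0712470499879096,
          0.997458699830735,
          0
        ],
        [
          0,
          0,
          1
        ]
      ],
      "translation": [
        0.07,
        0.02,
        0
      ]
    },
    "thigh_r": {
      "rotation": [
        [
          1,
          0,
          0
        ],
        [
          0,
          1,
          0
        ],
        [
          0,
          0,
          1
        ]
      ],
      "translation": [
        0,
        -0.26,
        0
      ]
    },
    "shank_r": {
      "rotation": [
        [
          1,
          0,
          0
        ],
        [
          0,
          1,
          0
        ],
        [
          0,
          0,
          1
        ]
      ],
      "translation": [
        0,
        -0.25,
        0
      ]
    },
    "foot_r": {
      "rotation": [
        [
          0.997458699830735,
          0,
          0.0712470499879096
        ],
        [
          0,
          1,
          0
        ],
        [
          -0.0712470499879096,
          0,
          0.997458699830735
        ]
      ],
      "translation": [
        -0.05,
        -0.03,
        0
      ]
    },
    "thigh_l": {
      "rotation": [
        [
          1,
          0,
          0
        ],
        [
          0,
          1,
          0
        ],
        [
          0,
          0,
          1
        ]
      ],
      "translation": [
        0,
        -0.26,
        0
      ]
    },
    "shank_l": {
      "rotation": [
        [
          1,
          0,
          0
        ],
        [
          0,
          1,
          0
        ],
        [
          0,
          0,
          1
        ]
      ],
      "translation": [
        0,
        -0.25,
        0
      ]
    },
    "foot_l": {
      "rotation": [
        [
          0.997458699830735,
          0,
          -0.0712470499879096
        ],
        [
          0,
          1,
          0
        ],
        [
          0.0712470499879096,
          0,
          0.997458699830735
        ]
      ],
      "translation": [
        -0.05,
        -0.03,
        0
      ]
    }
  }
}
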