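[
  {
    "name": "SLF1",
    "aggregation": "mean",
    "pairs": [
      [
        "superior parietal gyrus, left",
        "superior frontal gyrus (dorsal), left"
      ],
      [
        "superior parietal gyrus, left",
        "superior frontal gyrus (medial), left"
      ],
      [
        "superior parietal gyrus, left",
        "supplementary motor area, left"
      ]
    ]
  },
  {
    "name": "SLF2",
    "aggregation": "mean",
    "pairs": [
      [
        "inferior parietal lobule, left",
        "middle frontal gyrus, left"
      ],
      [
        "inferior parietal lobule, left",
        "superior frontal gyrus (dorsal), left"
      ]
    ]
  },
  {
    "name": "SLF3",
    "aggregation": "mean",
    "pairs": [
      [
        "supramarginal gyrus, left",
        "middle frontal gyrus, left"
      ],
      [
        "supramarginal gyrus, left",
        "superior frontal gyrus (dorsal), left"
      ],
      [
        "supramarginal gyrus, left",
        "inferior orbitofrontal cortex, left"
      ],
      [
        "supramarginal gyrus, left",
        "middle orbitofrontal cortex, left"
      ],
      [
        "supramarginal gyrus, left",
        "superior orbitofrontal cortex, left"
      ],
      [
        "supramarginal gyrus, left",
        "opercular inferior frontal gyrus, left"
      ],
      [
        "supramarginal gyrus, left",
        "triangular inferior frontal gyrus, left"
      ]
    ]
  },
  {
    "name": "ILF",
    "aggregation": "mean",
    "pairs": [
      [
        "fusiform gyrus, left",
        "superior temporal pole, left"
      ],
      [
        "fusiform gyrus, left",
        "middle temporal pole, left"
      ],
      [
        "superior occipital gyrus, left",
        "superior temporal pole, left"
      ],
      [
        "middle occipital gyrus, left",
        "superior temporal pole, left"
      ],
      [
        "inferior occipital gyrus, left",
        "superior temporal pole, left"
      ],
      [
        "superior occipital gyrus, left",
        "middle temporal pole, left"
      ],
      [
        "middle occipital gyrus, left",
        "middle temporal pole, left"
      ],
      [
        "inferior occipital gyrus, left",
        "middle temporal pole, left"
      ],
      [
        "lingual gyrus, left",
        "middle temporal gyrus, left"
      ],
      [
        "lingual gyrus, left",
        "middle temporal pole, left"
      ],
      [
        "cuneus, left",
        "middle temporal gyrus, left"
      ],
      [
        "cuneus, left",
        "middle temporal pole, left"
      ]
    ]
  },
  {
    "name": "AF",
    "aggregation": "mean",
    "pairs": [
      [
        "superior temporal gyrus, left",
        "opercular inferior frontal gyrus, left"
      ],
      [
        "superior temporal gyrus, left",
        "triangular inferior frontal gyrus, left"
      ],
      [
        "superior temporal gyrus, left",
        "inferior orbitofrontal cortex, left"
      ],
      [
        "middle temporal gyrus, left",
        "opercular inferior frontal gyrus, left"
      ],
      [
        "middle temporal gyrus, left",
        "triangular inferior frontal gyrus, left"
      ],
      [
        "middle temporal gyrus, left",
        "inferior orbitofrontal cortex, left"
      ]
    ]
  }
]
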