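{
  "seed": 99,
  "library": {
    "grid": {
      "from": 740,
      "to": 1060,
      "by": 8
    },
    "brands": [
      {
        "brand": "DemoBrand",
        "components": [
          {
            "name": "artesunate",
            "bands": [
              [
                820,
                9,
                0.7
              ],
              [
                930,
                9,
                0.6
              ],
              [
                1010,
                9,
                0.55
              ]
            ]
          },
          {
            "name": "excipient",
            "bands": [
              [
                780,
                35,
                0.3
              ],
              [
                920,
                55,
                0.4
              ],
              [
                1035,
                40,
                0.3
              ]
            ]
          }
        ],
        "nominal": {
          "artesunate": 1,
          "excipient": 1
        },
        "apis": [
          "artesunate"
        ]
      }
    ],
    "qa_batches": 2,
    "qa_samples": 4,
    "falsified_batches": 1,
    "falsified_samples": 1
  }
}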