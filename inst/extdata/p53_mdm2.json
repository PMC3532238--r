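{
  "genes": ["p53", "Mdm2"],
  "perturbation": 0,
  "periods": {},
  "functions": {
    "p53": [
      {
        "inputs": ["p53", "Mdm2"],
        "prob": 0.5,
        "table": [1, 1, 0, 0]
      },
      {
        "inputs": ["p53", "Mdm2"],
        "prob": 0.4,
        "table": [1, 1, 0, 1]
      },
      {
        "inputs": ["p53", "Mdm2"],
        "prob": 0.09,
        "table": [1, 0, 1, 1]
      },
      {
        "inputs": ["p53", "Mdm2"],
        "prob": 0.01,
        "table": [0, 0, 1, 1]
      }
    ],
    "Mdm2": [
      {
        "inputs": ["p53", "Mdm2"],
        "prob": 0.5,
        "table": [0, 0, 1, 1]
      },
      {
        "inputs": ["p53", "Mdm2"],
        "prob": 0.4,
        "table": [0, 0, 1, 0]
      },
      {
        "inputs": ["p53", "Mdm2"],
        "prob": 0.09,
        "table": [0, 1, 0, 0]
      },
      {
        "inputs": ["p53", "Mdm2"],
        "prob": 0.01,
        "table": [1, 1, 0, 0]
      }
    ]
  }
}
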