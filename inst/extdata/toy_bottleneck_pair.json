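{
  "id": "toy_bottleneck_pair",
  "metabolites": [
    {
      "id": "A",
      "compartment": "c"
    },
    {
      "id": "B",
      "compartment": "c"
    },
    {
      "id": "Z",
      "compartment": "c"
    }
  ],
  "reactions": [
    {
      "id": "EX_src",
      "metabolites": {
        "A": 1
      },
      "lower_bound": 0,
      "upper_bound": 10,
      "objective_coefficient": 0
    },
    {
      "id": "R1",
      "metabolites": {
        "A": -1,
        "B": 1
      },
      "lower_bound": 0,
      "upper_bound": "Inf",
      "objective_coefficient": 0
    },
    {
      "id": "R2",
      "metabolites": {
        "B": -1,
        "Z": 1
      },
      "lower_bound": 0,
      "upper_bound": "Inf",
      "objective_coefficient": 0
    },
    {
      "id": "BIO",
      "metabolites": {
        "Z": -1
      },
      "lower_bound": 0,
      "upper_bound": "Inf",
      "objective_coefficient": 1
    }
  ],
  "version": "1"
}
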