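{
  "schema_version": 1,
  "label": "OM-85 BV vs placebo, pediatric recurrent RTI",
  "parameters": [
    {
      "name": "p_repeat",
      "base": 0.2,
      "family": "beta",
      "sd": 0.05,
      "label": "probability of repeat RTI episode (6 months)"
    },
    {
      "name": "p_mort",
      "base": 0.008,
      "family": "beta",
      "sd": 0.001,
      "label": "mortality given repeat RTI episode"
    },
    {
      "name": "u_base",
      "base": 0.94,
      "family": "beta",
      "sd": 0.01,
      "label": "utility, no repeat episode"
    },
    {
      "name": "u_rti",
      "base": 0.87,
      "family": "beta",
      "sd": 0.2,
      "label": "utility, repeat RTI episode"
    },
    {
      "name": "c_rti",
      "base": 2022,
      "family": "gamma",
      "sd": 505,
      "label": "cost of repeat RTI episode (US$)"
    },
    {
      "name": "c_drug",
      "base": 74,
      "family": "gamma",
      "sd": 18.5,
      "label": "OM-85 BV, 3 cycles of 10 days (US$)"
    },
    {
      "name": "reduction",
      "base": 0.65,
      "family": "lognormal",
      "sd": 0.07,
      "dsa_low": 0.523607334888812,
      "dsa_high": 0.797651501524842,
      "unit_interval": true,
      "label": "relative reduction of repeat-RTI probability"
    }
  ],
  "tree": {
    "kind": "decision",
    "strategies": {
      "placebo": {
        "kind": "chance",
        "branches": [
          {
            "probability": "p_repeat",
            "node": {
              "kind": "chance",
              "branches": [
                {
                  "probability": "p_mort",
                  "node": {
                    "kind": "terminal",
                    "cost": "c_rti",
                    "utility": 0
                  },
                  "label": "die"
                },
                {
                  "probability": "1 - p_mort",
                  "node": {
                    "kind": "terminal",
                    "cost": "c_rti",
                    "utility": "u_rti"
                  },
                  "label": "survive"
                }
              ]
            },
            "label": "repeat_rti"
          },
          {
            "probability": "1 - p_repeat",
            "node": {
              "kind": "terminal",
              "cost": 0,
              "utility": "u_base"
            },
            "label": "no_repeat"
          }
        ]
      },
      "om85": {
        "kind": "chance",
        "branches": [
          {
            "probability": "p_repeat * (1 - reduction)",
            "node": {
              "kind": "chance",
              "branches": [
                {
                  "probability": "p_mort",
                  "node": {
                    "kind": "terminal",
                    "cost": "c_rti + c_drug",
                    "utility": 0
                  },
                  "label": "die"
                },
                {
                  "probability": "1 - p_mort",
                  "node": {
                    "kind": "terminal",
                    "cost": "c_rti + c_drug",
                    "utility": "u_rti"
                  },
                  "label": "survive"
                }
              ]
            },
            "label": "repeat_rti"
          },
          {
            "probability": "1 - p_repeat * (1 - reduction)",
            "node": {
              "kind": "terminal",
              "cost": "c_drug",
              "utility": "u_base"
            },
            "label": "no_repeat"
          }
        ]
      }
    }
  },
  "analysis": {
    "wtp": 5180,
    "n_psa": 10000,
    "dsa_fraction": 0.25,
    "reference": "placebo",
    "intervention": "om85",
    "horizon": "6 months"
  }
}
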