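{
  "children": {
    "C":  {"family": "lognormal", "meanlog": 2.8132347, "sdlog": 0.3873015, "lower": 7.8, "upper": 35.6},
    "IR": {"family": "lognormal", "meanlog": 0.0981436, "sdlog": 0.5},
    "EF": {"family": "uniform", "min": 180, "max": 365},
    "BW": {"family": "normal", "mean": 16.41, "sd": 2.4615, "lower": 5, "upper": 60}
  },
  "teenagers": {
    "C":  {"family": "lognormal", "meanlog": 2.8132347, "sdlog": 0.3873015, "lower": 7.8, "upper": 35.6},
    "IR": {"family": "lognormal", "meanlog": 0.3324248, "sdlog": 0.5},
    "EF": {"family": "uniform", "min": 180, "max": 365},
    "BW": {"family": "normal", "mean": 39.83, "sd": 5.9745, "lower": 12, "upper": 120}
  },
  "adults": {
    "C":  {"family": "lognormal", "meanlog": 2.8132347, "sdlog": 0.3873015, "lower": 7.8, "upper": 35.6},
    "IR": {"family": "lognormal", "meanlog": 0.5428294, "sdlog": 0.5},
    "EF": {"family": "uniform", "min": 180, "max": 365},
    "BW": {"family": "normal", "mean": 77.45, "sd": 11.6175, "lower": 25, "upper": 200}
  }
}
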