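{
  "fecal_coliform": {"unit": "CFU/100mL",     "nsf_weight": 0.16, "irwqi_weight": 0.140, "curve_id": "fecal_coliform"},
  "bod5":           {"unit": "mg/L",          "nsf_weight": 0.11, "irwqi_weight": 0.117, "curve_id": "bod5"},
  "no3":            {"unit": "mg/L",          "nsf_weight": 0.10, "irwqi_weight": 0.108, "curve_id": "no3"},
  "do_sat":         {"unit": "% saturation",  "nsf_weight": 0.17, "irwqi_weight": 0.097, "curve_id": "do_sat"},
  "ec":             {"unit": "uS/cm",         "nsf_weight": null, "irwqi_weight": 0.096, "curve_id": "ec"},
  "cod":            {"unit": "mg/L",          "nsf_weight": null, "irwqi_weight": 0.093, "curve_id": "cod"},
  "nh4":            {"unit": "mg/L",          "nsf_weight": null, "irwqi_weight": 0.090, "curve_id": "nh4"},
  "po4":            {"unit": "mg/L",          "nsf_weight": 0.10, "irwqi_weight": 0.087, "curve_id": "po4"},
  "turbidity":      {"unit": "NTU",           "nsf_weight": 0.08, "irwqi_weight": 0.062, "curve_id": "turbidity"},
  "th":             {"unit": "mg CaCO3/L",    "nsf_weight": null, "irwqi_weight": 0.059, "curve_id": "th"},
  "ph":             {"unit": "pH",            "nsf_weight": 0.11, "irwqi_weight": 0.051, "curve_id": "ph"},
  "temperature":    {"unit": "degC",          "nsf_weight": 0.10, "irwqi_weight": null,  "curve_id": "temperature"},
  "ts":             {"unit": "mg/L",          "nsf_weight": 0.07, "irwqi_weight": null,  "curve_id": "ts"}
}
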