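[
  {
    "metric_id": "pgtvtb_v_presc",
    "lower": 80,
    "upper": 95,
    "direction": "increasing",
    "s_min": 0,
    "s_max": 10
  },
  {
    "metric_id": "pgtvtb_ci",
    "lower": 0,
    "upper": 1,
    "direction": "increasing",
    "s_min": 0,
    "s_max": 10
  },
  {
    "metric_id": "pgtvtb_hi",
    "lower": 0,
    "upper": 0.2,
    "direction": "decreasing",
    "s_min": 0,
    "s_max": 10
  },
  {
    "metric_id": "gtvnd_v_presc",
    "lower": 80,
    "upper": 95,
    "direction": "increasing",
    "s_min": 0,
    "s_max": 10
  },
  {
    "metric_id": "gtvnd_ci",
    "lower": 0,
    "upper": 1,
    "direction": "increasing",
    "s_min": 0,
    "s_max": 10
  },
  {
    "metric_id": "gtvnd_hi",
    "lower": 0,
    "upper": 0.2,
    "direction": "decreasing",
    "s_min": 0,
    "s_max": 10
  },
  {
    "metric_id": "ptv_v_presc",
    "lower": 90,
    "upper": 95,
    "direction": "increasing",
    "s_min": 0,
    "s_max": 10
  },
  {
    "metric_id": "ptv_ci",
    "lower": 0.6,
    "upper": 1,
    "direction": "increasing",
    "s_min": 0,
    "s_max": 10
  },
  {
    "metric_id": "ptv_hi",
    "lower": 0,
    "upper": 0.3,
    "direction": "decreasing",
    "s_min": 0,
    "s_max": 10
  },
  {
    "metric_id": "brainstem_dmax",
    "lower": 25,
    "upper": 40,
    "direction": "decreasing",
    "s_min": 0,
    "s_max": 10
  },
  {
    "metric_id": "brainstem_prv_dmax",
    "lower": 30,
    "upper": 45,
    "direction": "decreasing",
    "s_min": 0,
    "s_max": 10
  },
  {
    "metric_id": "cord_dmax",
    "lower": 30,
    "upper": 40,
    "direction": "decreasing",
    "s_min": 0,
    "s_max": 10
  },
  {
    "metric_id": "cord_prv_dmax",
    "lower": 35,
    "upper": 45,
    "direction": "decreasing",
    "s_min": 0,
    "s_max": 10
  },
  {
    "metric_id": "parotids_dmean",
    "lower": 40,
    "upper": 55,
    "direction": "decreasing",
    "s_min": 0,
    "s_max": 10
  },
  {
    "metric_id": "nt_dmean",
    "lower": 10,
    "upper": 30,
    "direction": "decreasing",
    "s_min": 0,
    "s_max": 10
  }
]
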