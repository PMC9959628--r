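{
  "version": "pirads-2.1-rules-1",
  "comment": "Ordered decision lists encoding PI-RADS v2.1 sequence scoring and overall assessment over the CDE vocabulary. Within a sequence/zone block the first rule whose predicate holds determines the score; a rule predicate is a disjunction of conjunctive clauses ('when'), each clause a set of variable-in-values conditions. An empty clause list under 'otherwise' marks an explicit catch-all. The overall tables are written exhaustively and mutually exclusively, with no catch-all.",
  "sequences": {
    "t2w": {
      "PZ": [
        {"id": "pz-t2w-1-normal", "score": 1,
         "when": [{"t2w_abnormality": ["NO"]}]},
        {"id": "pz-t2w-5", "score": 5,
         "when": [
           {"t2w_abnormality": ["YES"], "t2w_signal_intensity_type": ["Hypointense"], "t2w_signal_intensity": ["Moderate", "Marked"], "t2w_uniformity": ["Homogeneous"], "t2w_focality": ["YES"], "t2w_margin_category": ["Circumscribed"], "lesion_dim_max": [">=15"]},
           {"t2w_abnormality": ["YES"], "t2w_signal_intensity_type": ["Hypointense"], "t2w_signal_intensity": ["Moderate", "Marked"], "t2w_uniformity": ["Homogeneous"], "t2w_focality": ["YES"], "t2w_margin_category": ["Circumscribed"], "t2w_invasive": ["YES"]}
         ]},
        {"id": "pz-t2w-4", "score": 4,
         "when": [
           {"t2w_abnormality": ["YES"], "t2w_signal_intensity_type": ["Hypointense"], "t2w_signal_intensity": ["Moderate", "Marked"], "t2w_uniformity": ["Homogeneous"], "t2w_focality": ["YES"], "t2w_margin_category": ["Circumscribed"]}
         ]},
        {"id": "pz-t2w-2", "score": 2,
         "when": [
           {"t2w_abnormality": ["YES"], "t2w_signal_intensity_type": ["Hypointense"], "t2w_shape_category": ["Linear"], "t2w_invasive": ["NO"]},
           {"t2w_abnormality": ["YES"], "t2w_signal_intensity_type": ["Hypointense"], "t2w_signal_intensity": ["Mild"], "t2w_invasive": ["NO"]}
         ]},
        {"id": "pz-t2w-3-otherwise", "score": 3, "otherwise": true}
      ],
      "TZ": [
        {"id": "tz-t2w-1-normal", "score": 1,
         "when": [{"t2w_abnormality": ["NO"]}]},
        {"id": "tz-t2w-5", "score": 5,
         "when": [
           {"t2w_abnormality": ["YES"], "t2w_signal_intensity_type": ["Hypointense"], "t2w_signal_intensity": ["Moderate", "Marked"], "t2w_uniformity": ["Homogeneous"], "t2w_focality": ["YES"], "t2w_margin_category": ["Non_Circumscribed"], "lesion_dim_max": [">=15"]},
           {"t2w_abnormality": ["YES"], "t2w_signal_intensity_type": ["Hypointense"], "t2w_signal_intensity": ["Moderate", "Marked"], "t2w_uniformity": ["Homogeneous"], "t2w_focality": ["YES"], "t2w_shape": ["Lenticular", "Water-Drop", "Tear-shaped"], "lesion_dim_max": [">=15"]},
           {"t2w_abnormality": ["YES"], "t2w_signal_intensity_type": ["Hypointense"], "t2w_signal_intensity": ["Moderate", "Marked"], "t2w_uniformity": ["Homogeneous"], "t2w_focality": ["YES"], "t2w_margin_category": ["Non_Circumscribed"], "t2w_invasive": ["YES"]},
           {"t2w_abnormality": ["YES"], "t2w_signal_intensity_type": ["Hypointense"], "t2w_signal_intensity": ["Moderate", "Marked"], "t2w_uniformity": ["Homogeneous"], "t2w_focality": ["YES"], "t2w_shape": ["Lenticular", "Water-Drop", "Tear-shaped"], "t2w_invasive": ["YES"]}
         ]},
        {"id": "tz-t2w-4", "score": 4,
         "when": [
           {"t2w_abnormality": ["YES"], "t2w_signal_intensity_type": ["Hypointense"], "t2w_signal_intensity": ["Moderate", "Marked"], "t2w_uniformity": ["Homogeneous"], "t2w_focality": ["YES"], "t2w_margin_category": ["Non_Circumscribed"]},
           {"t2w_abnormality": ["YES"], "t2w_signal_intensity_type": ["Hypointense"], "t2w_signal_intensity": ["Moderate", "Marked"], "t2w_uniformity": ["Homogeneous"], "t2w_focality": ["YES"], "t2w_shape": ["Lenticular", "Water-Drop", "Tear-shaped"]}
         ]},
        {"id": "tz-t2w-2-nodule", "score": 2,
         "when": [{"t2w_abnormality": ["YES"], "t2w_margin_category": ["Circumscribed"]}]},
        {"id": "tz-t2w-3-otherwise", "score": 3, "otherwise": true}
      ]
    },
    "dwi": {
      "ALL": [
        {"id": "dwi-1-normal", "score": 1,
         "when": [{"adc_abnormality": ["NO"], "dwi_abnormality": ["NO"]}]},
        {"id": "dwi-5", "score": 5,
         "when": [
           {"adc_abnormality": ["YES"], "adc_signal_intensity_type": ["Hypointense"], "adc_signal_intensity": ["Marked"], "adc_focality": ["YES"], "dwi_abnormality": ["YES"], "dwi_signal_intensity_type": ["Hyperintense"], "dwi_signal_intensity": ["Marked"], "lesion_dim_max": [">=15"]},
           {"adc_abnormality": ["YES"], "adc_signal_intensity_type": ["Hypointense"], "adc_signal_intensity": ["Marked"], "adc_focality": ["YES"], "dwi_abnormality": ["YES"], "dwi_signal_intensity_type": ["Hyperintense"], "dwi_signal_intensity": ["Marked"], "adc_invasive": ["YES"]},
           {"adc_abnormality": ["YES"], "adc_signal_intensity_type": ["Hypointense"], "adc_signal_intensity": ["Marked"], "adc_focality": ["YES"], "dwi_abnormality": ["YES"], "dwi_signal_intensity_type": ["Hyperintense"], "dwi_signal_intensity": ["Marked"], "dwi_invasive": ["YES"]}
         ]},
        {"id": "dwi-4", "score": 4,
         "when": [
           {"adc_abnormality": ["YES"], "adc_signal_intensity_type": ["Hypointense"], "adc_signal_intensity": ["Marked"], "adc_focality": ["YES"], "dwi_abnormality": ["YES"], "dwi_signal_intensity_type": ["Hyperintense"], "dwi_signal_intensity": ["Marked"]}
         ]},
        {"id": "dwi-2-linear", "score": 2,
         "when": [
           {"adc_abnormality": ["YES"], "adc_shape_category": ["Linear"], "adc_signal_intensity_type": ["Hypointense"]},
           {"dwi_abnormality": ["YES"], "dwi_shape_category": ["Linear"], "dwi_signal_intensity_type": ["Hyperintense"]}
         ]},
        {"id": "dwi-3-otherwise", "score": 3, "otherwise": true}
      ]
    },
    "dce": {
      "ALL": [
        {"id": "dce-x-unavailable", "result": "X",
         "when": [{"dce_present_and_adequate": ["NO"]}]},
        {"id": "dce-positive", "result": "Positive",
         "when": [
           {"dce_present_and_adequate": ["YES"], "dce_abnormality": ["YES"], "dce_enhancement": ["Positive_DCE"], "dce_corresponds_to": ["T2", "DWI"], "dce_bph_features": ["NO"]}
         ]},
        {"id": "dce-negative-otherwise", "result": "Negative", "otherwise": true}
      ]
    },
    "overall": {
      "PZ": [
        {"id": "pz-ov-1", "category": 1, "when": [{"dwi": [1]}]},
        {"id": "pz-ov-2", "category": 2, "when": [{"dwi": [2]}]},
        {"id": "pz-ov-3", "category": 3, "when": [{"dwi": [3], "dce": ["Negative", "X"]}]},
        {"id": "pz-ov-3-dce-upgrade", "category": 4, "when": [{"dwi": [3], "dce": ["Positive"]}]},
        {"id": "pz-ov-4", "category": 4, "when": [{"dwi": [4]}]},
        {"id": "pz-ov-5", "category": 5, "when": [{"dwi": [5]}]}
      ],
      "TZ": [
        {"id": "tz-ov-1", "category": 1, "when": [{"t2w": [1]}]},
        {"id": "tz-ov-2", "category": 2, "when": [{"t2w": [2], "dwi": [1, 2, 3]}]},
        {"id": "tz-ov-2-dwi-upgrade", "category": 3, "when": [{"t2w": [2], "dwi": [4, 5]}]},
        {"id": "tz-ov-3", "category": 3, "when": [{"t2w": [3], "dwi": [1, 2, 3, 4]}]},
        {"id": "tz-ov-3-dwi-upgrade", "category": 4, "when": [{"t2w": [3], "dwi": [5]}]},
        {"id": "tz-ov-4", "category": 4, "when": [{"t2w": [4]}]},
        {"id": "tz-ov-5", "category": 5, "when": [{"t2w": [5]}]}
      ]
    }
  }
}
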