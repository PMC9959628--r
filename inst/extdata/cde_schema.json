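{
  "version": "2.1-cde-1",
  "shape_dialects": {
    "table1": ["Linear", "Wedge", "Lenticular", "Water-Drop"],
    "lexicon": ["Round", "Oval", "Lenticular", "Lobulated", "Tear-shaped", "Wedge-shaped", "Linear", "Irregular"]
  },
  "variables": [
    {"name": "lesion_dim_max", "label": "Lesion max dimension (mm)", "radlex": "Diameter [RID13432]", "group": "GLOBAL", "domain": ["<5", ">=5", ">=15"], "ordinal": true},
    {"name": "lesion_location", "label": "Zone", "radlex": "Zone of prostate [RID38890]", "group": "GLOBAL", "domain": ["PZ", "TZ", "Not Available"]},

    {"name": "t2w_present_and_adequate", "label": "T2W present and adequate", "radlex": "Adequate [RID39308]", "group": "T2W", "domain": ["YES", "NO"]},
    {"name": "t2w_abnormality", "label": "T2W lesion present", "radlex": "Lesion [RID38780]", "group": "T2W", "domain": ["YES", "NO"], "applicability": [{"var": "t2w_present_and_adequate", "value": "YES"}]},
    {"name": "t2w_invasive", "label": "T2W Invasive", "radlex": "Invasive [RID5680]", "group": "T2W", "domain": ["YES", "NO"], "applicability": [{"var": "t2w_present_and_adequate", "value": "YES"}]},
    {"name": "t2w_signal_intensity_type", "label": "T2W signal intensity type", "radlex": "Signal characteristic [RID6049]", "group": "T2W", "domain": ["Hypointense", "Isointense", "Hyperintense"], "applicability": [{"var": "t2w_present_and_adequate", "value": "YES"}]},
    {"name": "t2w_signal_intensity", "label": "T2W signal intensity scale", "radlex": "Signal characteristic [RID6049]", "group": "T2W", "domain": ["Mild", "Moderate", "Marked"], "ordinal": true, "applicability": [{"var": "t2w_present_and_adequate", "value": "YES"}]},
    {"name": "t2w_uniformity", "label": "T2W lesion uniformity", "radlex": "Uniformity descriptor [RID43293]", "group": "T2W", "domain": ["Homogeneous", "Heterogeneous"], "applicability": [{"var": "t2w_present_and_adequate", "value": "YES"}]},
    {"name": "t2w_focality", "label": "T2W focality", "radlex": "Focal [RID5702]", "group": "T2W", "domain": ["YES", "NO"], "applicability": [{"var": "t2w_present_and_adequate", "value": "YES"}]},
    {"name": "t2w_shape", "label": "T2W shape", "radlex": "Morphologic descriptor [RID5863]", "group": "T2W", "domain_role": "shape", "applicability": [{"var": "t2w_present_and_adequate", "value": "YES"}]},
    {"name": "t2w_shape_category", "label": "T2W shape category", "radlex": "Morphologic descriptor [RID5863]", "group": "T2W", "domain": ["Linear", "Round", "Irregular"], "applicability": [{"var": "t2w_present_and_adequate", "value": "YES"}]},
    {"name": "t2w_margin", "label": "T2W margin", "radlex": "Margin [RID5972]", "group": "T2W", "domain": ["Indistinct", "Obscured", "Spiculated", "Erased charcoal sign", "Partly_Encapsulated", "Encapsulated", "Well_Defined"], "applicability": [{"var": "t2w_present_and_adequate", "value": "YES"}]},
    {"name": "t2w_margin_category", "label": "T2W margin category", "radlex": "Margin [RID5972]", "group": "T2W", "domain": ["Circumscribed", "Non_Circumscribed"], "applicability": [{"var": "t2w_present_and_adequate", "value": "YES"}]},

    {"name": "adc_present_and_adequate", "label": "ADC present and adequate", "radlex": "Adequate [RID39308]", "group": "ADC", "domain": ["YES", "NO"]},
    {"name": "adc_abnormality", "label": "ADC lesion present", "radlex": "Lesion [RID38780]", "group": "ADC", "domain": ["YES", "NO"], "applicability": [{"var": "adc_present_and_adequate", "value": "YES"}]},
    {"name": "adc_invasive", "label": "ADC invasive", "radlex": "Invasive [RID5680]", "group": "ADC", "domain": ["YES", "NO"], "applicability": [{"var": "adc_present_and_adequate", "value": "YES"}]},
    {"name": "adc_signal_intensity_type", "label": "ADC signal intensity type", "radlex": "Signal characteristic [RID6049]", "group": "ADC", "domain": ["Hypointense", "Isointense", "Hyperintense"], "aliases": {"Hypointensitivity": "Hypointense", "Isointensitivity": "Isointense", "Hyperintensitivity": "Hyperintense"}, "applicability": [{"var": "adc_present_and_adequate", "value": "YES"}]},
    {"name": "adc_signal_intensity", "label": "ADC signal intensity scale", "radlex": "Signal characteristic [RID6049]", "group": "ADC", "domain": ["Mild", "Moderate", "Marked"], "ordinal": true, "applicability": [{"var": "adc_present_and_adequate", "value": "YES"}]},
    {"name": "adc_focality", "label": "ADC focality", "radlex": "Focal [RID5702]", "group": "ADC", "domain": ["YES", "NO"], "applicability": [{"var": "adc_present_and_adequate", "value": "YES"}]},
    {"name": "adc_shape", "label": "ADC shape", "radlex": "Morphologic descriptor [RID5863]", "group": "ADC", "domain_role": "shape", "applicability": [{"var": "adc_present_and_adequate", "value": "YES"}]},
    {"name": "adc_shape_category", "label": "ADC shape category", "radlex": "Morphologic descriptor [RID5863]", "group": "ADC", "domain": ["Linear", "Round", "Irregular"], "applicability": [{"var": "adc_present_and_adequate", "value": "YES"}]},

    {"name": "dwi_present_and_adequate", "label": "DWI present and adequate", "radlex": "Adequate [RID39308]", "group": "DWI", "domain": ["YES", "NO"]},
    {"name": "dwi_abnormality", "label": "DWI lesion present", "radlex": "Lesion [RID38780]", "group": "DWI", "domain": ["YES", "NO"], "applicability": [{"var": "dwi_present_and_adequate", "value": "YES"}]},
    {"name": "dwi_invasive", "label": "DWI invasive", "radlex": "Invasive [RID5680]", "group": "DWI", "domain": ["YES", "NO"], "applicability": [{"var": "dwi_present_and_adequate", "value": "YES"}]},
    {"name": "dwi_signal_intensity_type", "label": "DWI signal intensity type", "radlex": "Signal characteristic [RID6049]", "group": "DWI", "domain": ["Hypointense", "Isointense", "Hyperintense"], "applicability": [{"var": "dwi_present_and_adequate", "value": "YES"}]},
    {"name": "dwi_signal_intensity", "label": "DWI signal intensity scale", "radlex": "Signal characteristic [RID6049]", "group": "DWI", "domain": ["Mild", "Moderate", "Marked"], "ordinal": true, "applicability": [{"var": "dwi_present_and_adequate", "value": "YES"}]},
    {"name": "dwi_focality", "label": "DWI focality", "radlex": "Focal [RID5702]", "group": "DWI", "domain": ["YES", "NO"], "applicability": [{"var": "dwi_present_and_adequate", "value": "YES"}]},
    {"name": "dwi_shape", "label": "DWI shape", "radlex": "Morphologic descriptor [RID5863]", "group": "DWI", "domain_role": "shape", "applicability": [{"var": "dwi_present_and_adequate", "value": "YES"}]},
    {"name": "dwi_shape_category", "label": "DWI shape category", "radlex": "Morphologic descriptor [RID5863]", "group": "DWI", "domain": ["Linear", "Round", "Irregular"], "applicability": [{"var": "dwi_present_and_adequate", "value": "YES"}]},

    {"name": "dce_present_and_adequate", "label": "Is DCE present and adequate?", "radlex": "Adequate [RID39308]", "group": "DCE", "domain": ["YES", "NO"]},
    {"name": "dce_abnormality", "label": "Does an abnormality appear on the DCE image?", "radlex": "Lesion [RID38780]", "group": "DCE", "domain": ["YES", "NO"], "applicability": [{"var": "dce_present_and_adequate", "value": "YES"}]},
    {"name": "dce_enhancement", "label": "Enhancement pattern", "radlex": "Enhancement pattern [RID6058]", "group": "DCE", "domain": ["Positive_DCE", "Negative_DCE"], "applicability": [{"var": "dce_present_and_adequate", "value": "YES"}]},
    {"name": "dce_corresponds_to", "label": "Corresponds to finding", "radlex": "MR tissue contrast attribute (Mr procedure attribute) [RID10791]", "group": "DCE", "domain": ["T2", "DWI", "Not_Available"], "applicability": [{"var": "dce_present_and_adequate", "value": "YES"}]},
    {"name": "dce_bph_features", "label": "BPH features on T2", "radlex": "Benign prostatic hyperplasia [RID3784]", "group": "DCE", "domain": ["YES", "NO"], "applicability": [{"var": "dce_present_and_adequate", "value": "YES"}]}
  ]
}
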