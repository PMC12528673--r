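crops:
- crop: Wheat
  t_min: 10.0
  t_max: 20.0
  h_min: 50.0
  h_max: 70.0
  p_min: 0.1
  p_max: 1.0
  salinity_tolerance: Low
  required_land_class: HIGH
- crop: Rice
  t_min: 20.0
  t_max: 30.0
  h_min: 70.0
  h_max: 90.0
  p_min: 3.0
  p_max: 10.0
  salinity_tolerance: Medium
  required_land_class: HIGH
- crop: Maize
  t_min: 18.0
  t_max: 27.0
  h_min: 60.0
  h_max: 80.0
  p_min: 1.0
  p_max: 3.0
  salinity_tolerance: Medium
  required_land_class: HIGH
- crop: Chickpea
  t_min: 15.0
  t_max: 25.0
  h_min: 40.0
  h_max: 60.0
  p_min: 0.0
  p_max: 1.0
  salinity_tolerance: High
  required_land_class: HIGH
- crop: Sugarcane
  t_min: 21.0
  t_max: 35.0
  h_min: 60.0
  h_max: 80.0
  p_min: 2.0
  p_max: 5.0
  salinity_tolerance: Medium
  required_land_class: HIGH
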