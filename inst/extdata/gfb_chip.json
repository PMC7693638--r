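{
  "fluid": {"viscosity_pa_s": 0.001, "density_kg_m3": 1000},
  "apical": {
    "width_mm": 6, "height_mm": 0.5, "length_mm": 35, "well_span_mm": 6,
    "well_offset_mm": 14.5,
    "via_length_in_mm": 3.175, "via_length_out_mm": 3.175,
    "via_radius_mm": 0.5
  },
  "basal": {
    "width_mm": 4.5, "height_mm": 0.5, "length_mm": 35, "well_span_mm": 6,
    "well_offset_mm": 14.5,
    "via_length_in_mm": 6.35, "via_length_out_mm": 6.35,
    "via_radius_mm": 0.5
  },
  "membrane": {
    "pore_radius_um": 1.5, "thickness_um": 10, "porosity": 0.14,
    "area_mm2": 27
  }
}
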