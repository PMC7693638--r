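# Shared fixtures: all built in code, no stored data.

ref_fluid <- function() water()

ref_membrane <- function(porosity = 0.14, thickness = 10e-6)
  membrane_spec(pore_radius = 1.5e-6, thickness = thickness,
                porosity = porosity, area = 27e-6)

ref_apical <- function() default_chip()$apical

ref_basal <- function() default_chip()$basal

# symmetric chip: both channels identical (apical geometry on both sides)
symmetric_chip <- function() {
  chip <- default_chip()
  chip$basal <- chip$apical
  chip
}

flows_config <- function(apical_ul_min, basal_ul_min, n_segments = 32)
  network_config(apical = inlet_flow(ul_min_to_m3_s(apical_ul_min)),
                 basal = inlet_flow(ul_min_to_m3_s(basal_ul_min)),
                 n_segments = n_segments)

solve_default <- function(chip = default_chip(), apical = 100, basal = 100,
                          n_segments = 32)
  solve_coupled_network(chip$apical, chip$basal, chip$membrane, chip$fluid,
                        flows_config(apical, basal, n_segments))
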