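# reference configuration used across tests: water-like culture medium,
# 250 um nozzle, 2 m/s droplets
water_spec <- function(U = 2) {
  fluid_jet_spec(viscosity = 1.0e-3, surface_tension = 0.0728,
                 density = 998, orifice_diameter = 250e-6,
                 droplet_velocity = U)
}

# random valid fluid/jet spec over wide physical ranges
random_spec <- function() {
  fluid_jet_spec(viscosity = runif(1, 1e-4, 1),
                 surface_tension = runif(1, 0.01, 0.1),
                 density = runif(1, 500, 2000),
                 orifice_diameter = runif(1, 10e-6, 1e-3),
                 droplet_velocity = runif(1, 0.01, 20))
}
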