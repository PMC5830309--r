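# shared fixtures: tiny geometries and fluids used across test files

base_geom <- function(blockage = 0.5, L = 0.07) {
  # throat at z = 2 cm: d + L0/2 = 0.02
  L0 <- 0.02824
  stenosis_geometry(R0 = 0.01, L_vessel = L, d = 0.02 - L0 / 2, L0 = L0,
                    delta = blockage * 0.01)
}

straight_geom <- function(R0 = 0.01, L = 0.07) {
  stenosis_geometry(R0 = R0, L_vessel = L, d = 0.02, L0 = 0.02, delta = 0)
}

blood_carreau <- function() carreau_params()
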