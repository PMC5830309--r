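# Example stenoflow scenario configuration.
#
# Every key is optional; omitted settings fall back to the base
# 50%-stenosis case (1 cm vessel radius, 7 cm length, 2.824 cm stenosis
# with its throat at z = 2 cm, whole-blood Carreau rheology, no applied
# field, 1 Hz pulsatile driving calibrated to Re ~ 100).  Quantities are
# strict SI numbers, or strings with an explicit unit suffix
# (m, cm, mm, s, Pa, kPa, mmHg, T, K, C).  Unknown keys are errors.

name: example_60pct_cooled

geometry:
  R0: 1 cm                 # unobstructed lumen radius
  L_vessel: 6 cm           # vessel length
  L0: 2.824 cm             # stenosis length
  blockage_fraction: 0.6   # stenosis height / R0, in [0, 1)
  # d: onset position; default places the throat at z = 2 cm
  # profile: linear_cosine (as-printed ramp+cosine) | cosine (symmetric)

fluid:
  rho: 1050                # density, kg/m^3
  cp: 3490                 # specific heat, J/(kg K)
  k: 0.5                   # thermal conductivity, W/(m K)
  sigma: 0.8               # electrical conductivity, S/m

rheology:
  model: carreau           # carreau | newtonian (then give mu)
  mu1: 0.056               # zero-shear viscosity, Pa s
  mu_inf: 0.036            # infinite-shear viscosity, Pa s
  lam: 3.313               # relaxation time, s
  n: 0.3568                # power index

magnetics:
  Ha: 1                    # give exactly one of Ha or B0 (Tesla)
  # z_on / z_off: magnetized region; default distal half of the vessel
  # ramp_len: envelope smoothing length; default 0.1 * L0
  # chi: magnetic susceptibility for the M = chi H Kelvin-force hook

pressure:
  Pm: 25.9 Pa              # mean inlet gauge pressure
  eps: 0.2                 # pulse amplitude ratio, < 1
  omega0: 6.283185307      # angular frequency, rad/s (1 Hz beat)

solver:
  dt: 0.01                 # time step, s
  t_end: 1                 # end time, s
  T_inlet: 310             # inlet blood temperature, K (300 for the
                           # literal boundary-condition variant)
  cooled_wall: true        # hold the distal stenosis wall at T_wall
  # T_wall defaults to T_inlet; relax_*/outer_tol/max_outer as documented

mesh:
  nz: 96                   # axial cells
  nr: 32                   # radial cells

outputs:
  snapshot_times: [0, 0.25, 0.5, 0.75, 1]
  probe_stations: [2 mm, 2 cm, 4 cm]
  # outdir: path for VTK snapshots, probe CSV and the run log
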