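# Scenario configuration: YAML parsing with unit conversion, validation
# that reports all problems at once, presets mirroring the study cases,
# and lossless save/load round-tripping.

.unit_table <- list(
  m = 1, cm = 1e-2, mm = 1e-3,
  s = 1, ms = 1e-3,
  pa = 1, kpa = 1e3, mmhg = 133.322387415,
  t = 1, mt = 1e-3,
  k = 1)

# numeric values pass through (SI); strings like "2.824 cm" or "80 mmHg"
# are converted; "37 C" converts Celsius to Kelvin
parse_quantity <- function(x, key = "") {
  if (is.numeric(x)) return(x)
  if (!is.character(x) || length(x) != 1)
    stop("cannot parse value for '", key, "'")
  m <- regmatches(x, regexec("^\\s*([-+0-9.eE]+)\\s*([A-Za-z]+)\\s*$", x))[[1]]
  if (length(m) != 3)
    stop("cannot parse quantity '", x, "' for '", key, "'")
  val <- as.numeric(m[2])
  unit <- tolower(m[3])
  if (unit == "c") return(val + 273.15)
  if (is.null(.unit_table[[unit]]))
    stop("unknown unit '", m[3], "' for '", key, "'")
  val * .unit_table[[unit]]
}

.known_keys <- list(
  top = c("name", "geometry", "fluid", "rheology", "magnetics", "pressure",
          "solver", "mesh", "outputs"),
  geometry = c("R0", "L_vessel", "d", "L0", "blockage_fraction", "profile"),
  fluid = c("rho", "cp", "k", "sigma"),
  rheology = c("model", "mu1", "mu_inf", "lam", "n", "mu"),
  magnetics = c("B0", "Ha", "z_on", "z_off", "ramp_len", "chi", "mu0_mag"),
  pressure = c("Pm", "eps", "omega0"),
  solver = c("dt", "t_end", "outer_tol", "du_tol", "max_outer", "relax_u",
             "relax_p", "relax_T", "relax_mu", "viscous_form", "T_inlet",
             "cooled_wall", "T_wall"),
  mesh = c("nz", "nr"),
  outputs = c("snapshot_times", "probe_stations", "outdir"))

.check_keys <- function(block, name, errs) {
  if (is.null(block)) return(errs)
  bad <- setdiff(names(block), .known_keys[[name]])
  if (length(bad))
    errs <- c(errs, paste0("unknown key(s) in '", name, "': ",
                           paste(bad, collapse = ", ")))
  errs
}

#' Assemble a scenario from configuration blocks
#'
#' Builds the validated scenario object used by [run_simulation()].  All
#' omitted settings fall back to the base 50%-stenosis case: a 1 cm-radius,
#' 7 cm-long vessel with a 2.824 cm stenosis whose throat sits at z = 2 cm,
#' whole-blood Carreau rheology, conductivity 0.8 S/m, density 1050 kg/m^3,
#' specific heat 3490 J/(kg K), no applied field, and a 1 Hz pulsatile
#' driving pressure calibrated so the unobstructed Newtonian mean flow has
#' Reynolds number about 100.
#'
#' @param name Scenario name.
#' @param geometry,fluid,rheology,magnetics,pressure,solver,mesh,outputs
#'   Named lists overriding individual defaults (the keys match the
#'   configuration-file schema; see [load_scenario()]).
#' @return An object of class `steno_scenario`.
#' @export
scenario <- function(name = "paper_case_50pct", geometry = list(),
                     fluid = list(), rheology = list(), magnetics = list(),
                     pressure = list(), solver = list(), mesh = list(),
                     outputs = list()) {
  errs <- character(0)
  for (blk in c("geometry", "fluid", "rheology", "magnetics", "pressure",
                "solver", "mesh", "outputs"))
    errs <- .check_keys(get(blk), blk, errs)

  q <- function(block, key, default) {
    v <- block[[key]]
    if (is.null(v)) default else parse_quantity(v, key)
  }

  ## geometry (defaults: Table-1-style base case, throat at z = 2 cm)
  R0 <- q(geometry, "R0", 0.01)
  L0 <- q(geometry, "L0", 0.02824)
  Lv <- q(geometry, "L_vessel", 0.07)
  d <- q(geometry, "d", 0.02 - L0 / 2)
  blk_frac <- q(geometry, "blockage_fraction", 0.5)
  profile <- geometry$profile %||% "linear_cosine"
  if (!is.numeric(blk_frac) || blk_frac < 0 || blk_frac >= 1)
    errs <- c(errs, sprintf(
      "geometry.blockage_fraction = %g outside [0, 1)", blk_frac))
  geom <- tryCatch(
    stenosis_geometry(R0, Lv, d, L0, delta = blk_frac * R0,
                      profile = profile),
    error = function(e) { errs <<- c(errs, conditionMessage(e)); NULL })

  ## rheology
  model <- rheology$model %||% "carreau"
  carreau <- tryCatch({
    if (identical(model, "newtonian"))
      newtonian_params(q(rheology, "mu", 0.0036))
    else
      carreau_params(mu1 = q(rheology, "mu1", 0.056),
                     mu_inf = q(rheology, "mu_inf", 0.036),
                     lam = q(rheology, "lam", 3.313),
                     n = q(rheology, "n", 0.3568))
  }, error = function(e) { errs <<- c(errs, conditionMessage(e)); NULL })

  ## fluid
  props <- tryCatch(
    fluid_props(rho = q(fluid, "rho", 1050), cp = q(fluid, "cp", 3490),
                k = q(fluid, "k", 0.5), sigma = q(fluid, "sigma", 0.8),
                carreau = carreau %||% carreau_params()),
    error = function(e) { errs <<- c(errs, conditionMessage(e)); NULL })

  ## magnetics: field imposed on the distal section by default
  if (!is.null(magnetics$B0) && !is.null(magnetics$Ha))
    errs <- c(errs, "magnetics: give exactly one of B0 and Ha")
  B0 <- if (is.null(magnetics$B0) && is.null(magnetics$Ha)) 0
  else if (!is.null(magnetics$B0)) parse_quantity(magnetics$B0, "B0")
  else NULL
  Ha <- if (!is.null(magnetics$Ha) && is.null(B0))
    parse_quantity(magnetics$Ha, "Ha") else NULL
  mag <- tryCatch(
    magnetic_config(
      B0 = B0, Ha = Ha,
      z_on = q(magnetics, "z_on", d + L0 / 2),
      z_off = q(magnetics, "z_off", Lv),
      ramp_len = q(magnetics, "ramp_len", 0.1 * L0),
      sigma = q(fluid, "sigma", 0.8),
      chi = q(magnetics, "chi", 0),
      mu0_mag = q(magnetics, "mu0_mag", 4e-7 * pi),
      R0 = R0,
      mu_ref = if (!is.null(carreau)) carreau$mu_inf else 0.036),
    error = function(e) { errs <<- c(errs, conditionMessage(e)); NULL })

  ## pulsatile pressure: Pm calibrated to Re ~= 100 unless given
  mu_ref <- if (!is.null(carreau)) carreau$mu_inf else 0.036
  rho <- q(fluid, "rho", 1050)
  u_bar <- 100 * mu_ref / (rho * 2 * R0)
  Pm_default <- 8 * mu_ref * Lv * u_bar / R0^2
  pp <- tryCatch(
    pulsatile_pressure(Pm = q(pressure, "Pm", Pm_default),
                       eps = q(pressure, "eps", 0.2),
                       omega0 = q(pressure, "omega0", 2 * pi)),
    error = function(e) { errs <<- c(errs, conditionMessage(e)); NULL })

  ## solver
  sv <- solver
  cfg <- tryCatch(
    solver_config(dt = q(sv, "dt", 0.01), t_end = q(sv, "t_end", 1),
                  outer_tol = q(sv, "outer_tol", 1e-6),
                  du_tol = q(sv, "du_tol", 1e-6),
                  max_outer = q(sv, "max_outer", 600),
                  relax_u = q(sv, "relax_u", 0.7),
                  relax_p = q(sv, "relax_p", 0.3),
                  relax_T = q(sv, "relax_T", 1.0),
                  relax_mu = q(sv, "relax_mu", 0.7),
                  viscous_form = sv$viscous_form %||% "full",
                  T_inlet = q(sv, "T_inlet", 310),
                  cooled_wall = isTRUE(sv$cooled_wall),
                  T_wall = q(sv, "T_wall", q(sv, "T_inlet", 310))),
    error = function(e) { errs <<- c(errs, conditionMessage(e)); NULL })

  nz <- q(mesh, "nz", 96); nr <- q(mesh, "nr", 32)

  t_end_res <- if (!is.null(cfg)) cfg$t_end else 1
  snap <- outputs$snapshot_times %||%
    (t_end_res * c(0, 0.25, 0.5, 0.75, 1))
  stations <- outputs$probe_stations %||% c(2e-3, 2e-2, 4e-2)
  snap <- vapply(snap, parse_quantity, 0, key = "snapshot_times")
  stations <- vapply(stations, parse_quantity, 0, key = "probe_stations")
  if (!is.null(cfg) && any(snap < 0 | snap > cfg$t_end + 1e-12))
    errs <- c(errs, "outputs.snapshot_times outside [0, t_end]")
  if (any(stations < 0 | stations > Lv))
    errs <- c(errs, "outputs.probe_stations outside [0, L_vessel]")

  if (length(errs))
    stop("invalid scenario configuration:\n  - ",
         paste(errs, collapse = "\n  - "))

  structure(list(name = name, geometry = geom, fluid = props,
                 magnetics = mag, pressure = pp, solver = cfg,
                 mesh = list(nz = as.integer(nz), nr = as.integer(nr)),
                 outputs = list(snapshot_times = snap,
                                probe_stations = stations,
                                outdir = outputs$outdir)),
            class = "steno_scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.steno_scenario <- function(x, ...) {
  cat(sprintf(
    "steno_scenario '%s': blockage %.0f%%, L = %g cm, Ha = %.3g, Pm = %.3g Pa, mesh %dx%d\n",
    x$name, 100 * x$geometry$delta / x$geometry$R0,
    100 * x$geometry$L_vessel, x$magnetics$Ha, x$pressure$Pm,
    x$mesh$nz, x$mesh$nr))
  invisible(x)
}

#' Load and validate a scenario configuration file
#'
#' Reads a YAML scenario description, applies the base-case defaults for
#' every omitted setting, converts unit-suffixed quantities (cm, mm, mmHg,
#' kPa, C, ...) to strict SI, and validates the result.  Unknown keys are
#' errors (no silent typos), and all validation failures are reported
#' together.  An empty file yields the default `paper_case_50pct`
#' scenario.
#'
#' @param path Path to a YAML configuration file.
#' @return A `steno_scenario`.
#' @export
load_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), .known_keys$top)
  if (length(bad))
    stop("invalid scenario configuration:\n  - unknown top-level key(s): ",
         paste(bad, collapse = ", "))
  scenario(name = raw$name %||% "paper_case_50pct",
           geometry = raw$geometry %||% list(),
           fluid = raw$fluid %||% list(),
           rheology = raw$rheology %||% list(),
           magnetics = raw$magnetics %||% list(),
           pressure = raw$pressure %||% list(),
           solver = raw$solver %||% list(),
           mesh = raw$mesh %||% list(),
           outputs = raw$outputs %||% list())
}

#' Save a scenario to a configuration file
#'
#' Writes the fully resolved scenario (strict SI numbers) as YAML;
#' [load_scenario()] of the result reproduces the scenario exactly.
#'
#' @param scn A `steno_scenario`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_scenario <- function(scn, path) {
  stopifnot(inherits(scn, "steno_scenario"))
  g <- scn$geometry; f <- scn$fluid; m <- scn$magnetics
  p <- scn$pressure; s <- scn$solver
  cr <- f$carreau
  out <- list(
    name = scn$name,
    geometry = list(R0 = g$R0, L_vessel = g$L_vessel, d = g$d, L0 = g$L0,
                    blockage_fraction = g$delta / g$R0,
                    profile = g$profile),
    fluid = list(rho = f$rho, cp = f$cp, k = f$k, sigma = f$sigma),
    rheology = if (cr$mu1 == cr$mu_inf)
      list(model = "newtonian", mu = cr$mu1)
    else
      list(model = "carreau", mu1 = cr$mu1, mu_inf = cr$mu_inf,
           lam = cr$lam, n = cr$n),
    magnetics = list(B0 = m$B0, z_on = m$z_on, z_off = m$z_off,
                     ramp_len = m$ramp_len, chi = m$chi,
                     mu0_mag = m$mu0_mag),
    pressure = list(Pm = p$Pm, eps = p$eps, omega0 = p$omega0),
    solver = list(dt = s$dt, t_end = s$t_end, outer_tol = s$outer_tol,
                  du_tol = s$du_tol, max_outer = s$max_outer,
                  relax_u = s$relax_u, relax_p = s$relax_p,
                  relax_T = s$relax_T, relax_mu = s$relax_mu,
                  viscous_form = s$viscous_form, T_inlet = s$T_inlet,
                  cooled_wall = s$cooled_wall, T_wall = s$T_wall),
    mesh = scn$mesh,
    outputs = list(
      snapshot_times = as.list(scn$outputs$snapshot_times),
      probe_stations = as.list(scn$outputs$probe_stations)))
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Study-case presets
#'
#' Named scenarios mirroring the cases explored in the study:
#' \describe{
#'   \item{`paper_case_50pct`}{base case: 50% blockage, 7 cm vessel, no
#'     applied field, pulsatile driving.}
#'   \item{`joule_60pct_lowdp`}{60% blockage, 6 cm vessel, Hartmann number
#'     1 over the distal section, quarter-strength driving pressure (the
#'     low-pressure-gradient regime that develops a post-throat
#'     recirculation), cooled distal stenosis wall.}
#'   \item{`ha_sweep`}{three otherwise-identical scenarios at Ha = 0, 0.1
#'     and 1.}
#'   \item{`blockage_sweep`}{seven scenarios spanning 20% to 85% blockage
#'     in a 6 cm vessel.}
#' }
#'
#' @param name Preset name.
#' @param nz,nr Optional mesh-size override applied to every returned
#'   scenario.
#' @return A `steno_scenario`, or a named list of them for the sweeps.
#' @export
preset <- function(name = c("paper_case_50pct", "joule_60pct_lowdp",
                            "ha_sweep", "blockage_sweep"),
                   nz = NULL, nr = NULL) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% c("paper_case_50pct", "joule_60pct_lowdp", "ha_sweep",
                   "blockage_sweep"))
    stop("unknown preset '", name, "'; available: paper_case_50pct, ",
         "joule_60pct_lowdp, ha_sweep, blockage_sweep")
  mesh <- list()
  if (!is.null(nz)) mesh$nz <- nz
  if (!is.null(nr)) mesh$nr <- nr
  base_Pm <- scenario()$pressure$Pm
  switch(name,
    paper_case_50pct = scenario(name = name, mesh = mesh),
    joule_60pct_lowdp = scenario(
      name = name,
      geometry = list(L_vessel = 0.06, blockage_fraction = 0.6),
      magnetics = list(Ha = 1),
      pressure = list(Pm = 0.75 * base_Pm),
      solver = list(cooled_wall = TRUE),
      mesh = mesh),
    ha_sweep = {
      out <- lapply(c(0, 0.1, 1), function(ha) scenario(
        name = sprintf("ha_sweep_Ha%g", ha),
        magnetics = list(Ha = ha), mesh = mesh))
      names(out) <- sprintf("Ha%g", c(0, 0.1, 1))
      out
    },
    blockage_sweep = {
      blks <- c(0.2, 0.4, 0.5, 0.6, 0.7, 0.8, 0.85)
      out <- lapply(blks, function(b) scenario(
        name = sprintf("blockage_sweep_%.0fpct", 100 * b),
        geometry = list(L_vessel = 0.06, blockage_fraction = b),
        mesh = mesh))
      names(out) <- sprintf("blk%.0f", 100 * blks)
      out
    })
}
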