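#' Simulation configuration
#'
#' Builds a validated set of mechanical, geometric, kinetic and run-control
#' parameters for the button-barcode pairing simulation. All quantities are in
#' dimensionless simulation units: the length unit is the rest bond length
#' (nominally 0.2 um of chromatin, see `length_unit_um`), the energy unit is
#' `kBT = 1`, the friction coefficient per node is `friction = 1`, and the time
#' unit is `friction * lu^2 / kBT`. The Langevin noise amplitude per step is
#' `sqrt(2 * kBT * dt / friction)`.
#'
#' Default stiffnesses are chosen so that the Euler--Maruyama update is stable:
#' the stiffest chain mode has eigenvalue about `4 * k_spring`, so we require
#' `dt * (4 * k_spring + 4 * k_bend + 2 * k_pair) / friction < 2`.
#'
#' @param n_pairs number of homolog pairs (two chains per pair).
#' @param nodes_per_arm beads per chain; node 0 is the centromere. The default
#'   of 28 is the smallest geometry that accommodates every preset layout
#'   (13 randomly placed buttons at minimum gap 2 need at least 25 nodes; the
#'   industrial 2-of-5 code spans 19 nodes, "most" of the arm; 12-node patches
#'   shifted distally by 12 nodes stay in range) while keeping the contour
#'   length (27 lu) close to the nuclear diameter (24 lu) so a tethered arm
#'   spans the nucleus in the Rabl orientation.
#' @param k_spring stretch spring constant between adjacent beads
#'   (energy/length^2).
#' @param k_bend bending rigidity: penalty on the deviation of each interior
#'   bead from the midpoint of its neighbours. `k_bend/4` approximates the
#'   persistence length in length units for unit bonds.
#' @param k_pair spring constant of a formed button--button bond (zero rest
#'   length).
#' @param k_confine harmonic penalty for beads outside the nuclear sphere.
#' @param k_tether harmonic penalty pulling each centromere to the nearest
#'   point of the envelope cap (Rabl patch).
#' @param friction drag coefficient per bead.
#' @param kBT thermal energy scale; 0 turns the dynamics into gradient descent.
#' @param dt integration time step.
#' @param nucleus_radius radius of the confining sphere (length units).
#' @param rabl_patch_radius chord radius of the spherical cap, centred on the
#'   +z pole, within which centromeres are tethered. A value of
#'   `2 * nucleus_radius` disables the Rabl constraint entirely.
#' @param capture_radius distance below which two free buttons may bond.
#' @param p_unpair per-iteration probability that an existing bond dissolves.
#' @param n_steps iterations per run.
#' @param record_every snapshot interval in steps.
#' @param burn_in steps at the start of the run during which pairing is
#'   disabled so the chain geometry can equilibrate; counted within `n_steps`.
#' @param seed RNG seed used by [run_simulation()].
#' @param rest_length rest length of the backbone springs (1 by convention).
#' @param length_unit_um documentation constant: micrometres per length unit.
#' @param steps_per_hour documentation constant: iterations corresponding to
#'   roughly one hour of nuclear time (a whole default run of 300,000 steps).
#'
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [read_config()], [run_simulation()]
#' @export
#' @examples
#' cfg <- sim_config(n_pairs = 2, n_steps = 1000)
#' cfg$p_unpair
sim_config <- function(n_pairs = 2,
                       nodes_per_arm = 28,
                       k_spring = 50,
                       k_bend = 20,
                       k_pair = 25,
                       k_confine = 50,
                       k_tether = 50,
                       friction = 1,
                       kBT = 1,
                       dt = 0.005,
                       nucleus_radius = 12,
                       rabl_patch_radius = 3,
                       capture_radius = 1,
                       p_unpair = 0.8,
                       n_steps = 300000,
                       record_every = 1000,
                       burn_in = 5000,
                       seed = 1,
                       rest_length = 1,
                       length_unit_um = 0.2,
                       steps_per_hour = 300000) {
  cfg <- list(
    n_pairs = as.integer(n_pairs),
    nodes_per_arm = as.integer(nodes_per_arm),
    k_spring = as.numeric(k_spring),
    k_bend = as.numeric(k_bend),
    k_pair = as.numeric(k_pair),
    k_confine = as.numeric(k_confine),
    k_tether = as.numeric(k_tether),
    friction = as.numeric(friction),
    kBT = as.numeric(kBT),
    dt = as.numeric(dt),
    nucleus_radius = as.numeric(nucleus_radius),
    rabl_patch_radius = as.numeric(rabl_patch_radius),
    capture_radius = as.numeric(capture_radius),
    p_unpair = as.numeric(p_unpair),
    n_steps = as.integer(n_steps),
    record_every = as.integer(record_every),
    burn_in = as.integer(burn_in),
    seed = as.integer(seed),
    rest_length = as.numeric(rest_length),
    length_unit_um = as.numeric(length_unit_um),
    steps_per_hour = as.numeric(steps_per_hour)
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the invariants of a `sim_config`: strictly positive stiffnesses,
#' radii, time step, friction and temperature scale; `p_unpair` in \[0, 1\];
#' and `rabl_patch_radius <= 2 * nucleus_radius`.
#'
#' @param cfg a `sim_config`.
#' @return `cfg`, invisibly; errors on violation.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  pos <- c("k_spring", "k_pair", "k_confine", "k_tether", "friction",
           "dt", "nucleus_radius", "rabl_patch_radius", "capture_radius",
           "rest_length", "length_unit_um")
  for (f in pos) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0) {
      stop(sprintf("config field '%s' must be strictly positive", f))
    }
  }
  if (!is.finite(cfg$k_bend) || cfg$k_bend < 0) {
    stop("config field 'k_bend' must be nonnegative")
  }
  if (!is.finite(cfg$kBT) || cfg$kBT < 0) {
    stop("config field 'kBT' must be nonnegative")
  }
  if (cfg$p_unpair < 0 || cfg$p_unpair > 1) {
    stop("p_unpair must lie in [0, 1]")
  }
  if (cfg$n_pairs < 1) stop("n_pairs must be >= 1")
  if (cfg$nodes_per_arm < 2) stop("nodes_per_arm must be >= 2")
  if (cfg$n_steps < 0) stop("n_steps must be >= 0")
  if (cfg$record_every < 1) stop("record_every must be >= 1")
  if (cfg$burn_in < 0) stop("burn_in must be >= 0")
  if (cfg$rabl_patch_radius > 2 * cfg$nucleus_radius) {
    stop("rabl_patch_radius must be <= 2 * nucleus_radius")
  }
  # adjacent cis buttons (minimum genomic gap 2) must rest outside capture range
  if (cfg$capture_radius >= 2 * cfg$rest_length) {
    stop("capture_radius must be < 2 * rest_length so adjacent cis buttons are not in permanent contact")
  }
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' The file is a flat key--value YAML mapping; every key must be a
#' `sim_config` field name (see [sim_config()]); unknown keys are an error.
#' Missing keys take the package defaults.
#'
#' @param path path to a YAML file.
#' @return a validated `sim_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  do.call(sim_config, raw)
}

#' Write a simulation configuration to a YAML file
#'
#' @param cfg a `sim_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d homolog pair(s), %d nodes per arm, %d steps (record every %d, burn-in %d)\n",
              x$n_pairs, x$nodes_per_arm, x$n_steps, x$record_every, x$burn_in))
  cat(sprintf("  mechanics: k_spring=%g k_bend=%g k_pair=%g k_confine=%g k_tether=%g\n",
              x$k_spring, x$k_bend, x$k_pair, x$k_confine, x$k_tether))
  cat(sprintf("  nucleus R=%g lu, Rabl patch radius=%g lu, capture radius=%g lu\n",
              x$nucleus_radius, x$rabl_patch_radius, x$capture_radius))
  cat(sprintf("  kinetics: p_unpair=%g; kBT=%g dt=%g friction=%g; seed=%d\n",
              x$p_unpair, x$kBT, x$dt, x$friction, x$seed))
  invisible(x)
}
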