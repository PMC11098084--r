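#' Initialize chains in a Rabl starting layout
#'
#' Each chain is placed with its centromere on the nuclear envelope inside the
#' Rabl patch (uniformly over the cap area) and successive nodes extended
#' toward -z at exact rest length with small random lateral jitter (amplitude
#' 0.1 lu). When the straight walk would exit the sphere the vertical
#' direction is reflected (serpentine placement), so all nodes start inside
#' the nucleus even when the contour length exceeds the nuclear diameter; the
#' burn-in phase of [run_simulation()] then relaxes the geometry before
#' adhesion begins. Deterministic given the RNG state.
#'
#' @param cfg a `sim_config`.
#' @param barcodes a list of length `n_pairs`; each element is either a single
#'   `barcode` (both homologs carry it — the default, homozygous case) or a
#'   list of two `barcode`s (heterozygous layouts, e.g. a shift on one
#'   homolog only).
#' @return list of `2 * n_pairs` `chain_state` objects; list position equals
#'   `chain_id`, chains ordered pair by pair.
#' @export
init_chains <- function(cfg, barcodes = NULL) {
  barcodes <- resolve_barcodes(cfg, barcodes)
  n <- cfg$nodes_per_arm
  R <- cfg$nucleus_radius
  theta_c <- 2 * asin(min(cfg$rabl_patch_radius / (2 * R), 1))
  chains <- vector("list", 2L * cfg$n_pairs)
  cid <- 0L
  for (h in seq_len(cfg$n_pairs)) {
    for (copy in 1:2) {
      cid <- cid + 1L
      bc <- barcodes[[h]][[copy]]
      if (bc$arm_length != n) stop("barcode arm_length must equal nodes_per_arm")
      # centromere uniform over the cap area
      cth <- stats::runif(1, cos(theta_c), 1)
      sth <- sqrt(1 - cth^2)
      phi <- stats::runif(1, 0, 2 * pi)
      x <- matrix(0, n, 3)
      x[1, ] <- R * c(sth * cos(phi), sth * sin(phi), cth)
      dz <- -1
      for (i in 2:n) {
        j <- stats::runif(2, -0.1, 0.1)
        dir <- c(j, dz)
        cand <- x[i - 1, ] + cfg$rest_length * dir / sqrt(sum(dir^2))
        if (sqrt(sum(cand^2)) > 0.98 * R) {
          dz <- -dz
          dir <- c(j, dz)
          cand <- x[i - 1, ] + cfg$rest_length * dir / sqrt(sum(dir^2))
          if (sqrt(sum(cand^2)) > 0.98 * R) {
            dir <- -x[i - 1, ]
            cand <- x[i - 1, ] + cfg$rest_length * dir / sqrt(sum(dir^2))
          }
        }
        x[i, ] <- cand
      }
      if (any(sqrt(rowSums(x^2)) > R * (1 + 1e-9))) stop("geometry infeasible")
      chains[[cid]] <- chain_state(x, bc$buttons, homolog_id = h, chain_id = cid)
    }
  }
  validate_chains(chains, cfg)
  chains
}

# Internal: normalise the `barcodes` argument to a list of n_pairs elements,
# each a list of two barcode objects (one per homolog copy).
resolve_barcodes <- function(cfg, barcodes) {
  if (is.null(barcodes)) {
    if (cfg$n_pairs != 2) {
      stop("barcodes must be supplied explicitly when n_pairs != 2")
    }
    barcodes <- list(uniform_barcode(3, cfg$nodes_per_arm),
                     uniform_barcode(4, cfg$nodes_per_arm))
  }
  if (length(barcodes) != cfg$n_pairs) {
    stop("barcodes must have one element per homolog pair")
  }
  lapply(barcodes, function(b) {
    if (inherits(b, "barcode")) return(list(b, b))
    if (is.list(b) && length(b) == 2 &&
        all(vapply(b, inherits, logical(1), "barcode"))) return(b)
    stop("each barcodes element must be a barcode or a list of two barcodes")
  })
}

#' One Euler--Maruyama step (reference implementation)
#'
#' Position update `x <- x + (dt/friction) * F_total + sqrt(2*kBT*dt/friction) * eta`
#' with `eta` independent standard normal 3-vectors, where `F_total` is the sum
#' of spring, bending, confinement, tether and pairing-bond forces. This pure-R
#' step is the reference against which the compiled engine is cross-checked;
#' production runs go through [run_simulation()].
#'
#' @param chains list of `chain_state`.
#' @param pairing a `pairing_state`.
#' @param cfg a `sim_config`.
#' @return list of `chain_state` with updated positions.
#' @export
bd_step <- function(chains, pairing, cfg) {
  f <- total_forces(chains, pairing, cfg)
  mob <- cfg$dt / cfg$friction
  sigma <- sqrt(2 * cfg$kBT * cfg$dt / cfg$friction)
  for (i in seq_along(chains)) {
    n <- nrow(chains[[i]]$positions)
    noise <- if (cfg$kBT > 0) {
      matrix(stats::rnorm(3 * n), n, 3) * sigma
    } else 0
    xnew <- chains[[i]]$positions + mob * f[[i]] + noise
    if (any(!is.finite(xnew))) stop("numerical blow-up: reduce dt")
    chains[[i]]$positions <- xnew
  }
  chains
}

#' Run a pairing simulation
#'
#' Seeds the RNG from `cfg$seed`, initializes the chains ([init_chains()]),
#' then alternates the pairing-kinetics update (break with probability
#' `p_unpair`, then greedy nearest-first formation within the capture radius)
#' with the overdamped Langevin position update for `n_steps` iterations,
#' recording a snapshot every `record_every` steps (plus the initial state).
#' Pairing is disabled during the first `burn_in` steps so the chain geometry
#' can equilibrate. Bit-reproducible for a fixed seed.
#'
#' @param cfg a `sim_config`.
#' @param barcodes see [init_chains()]; `NULL` gives the reference layout of
#'   uniform 3- vs 4-node spacing on the two pairs.
#' @param pairing_enabled set `FALSE` for calibration runs without adhesion
#'   (persistence length, Rabl correlation).
#' @return a `cp_trajectory`: list with elements `config`, `chain_meta`
#'   (data.frame of chain_id, homolog_id), `buttons` (per-chain 0-based
#'   indices), `steps` (recorded step indices) and `frames` (per frame: `step`,
#'   `pos` — an `(n_chains*n_nodes) x 3` matrix in chain-major row order — and
#'   `bonds` — an integer matrix `chain_a, node_a, chain_b, node_b`).
#' @export
#' @examples
#' cfg <- sim_config(n_steps = 500, record_every = 100, burn_in = 100, seed = 7)
#' traj <- run_simulation(cfg)
#' length(traj$frames)
run_simulation <- function(cfg, barcodes = NULL, pairing_enabled = TRUE) {
  validate_config(cfg)
  set.seed(cfg$seed)
  chains <- init_chains(cfg, barcodes)
  n_chains <- length(chains)
  pos0 <- do.call(rbind, lapply(chains, `[[`, "positions"))
  res <- .engine_run(pos0, n_chains, cfg$nodes_per_arm,
                     lapply(chains, `[[`, "buttons"),
                     matrix(integer(0), ncol = 4),
                     unclass(cfg),
                     cfg$n_steps, cfg$record_every, cfg$burn_in,
                     pairing_enabled)
  frames <- lapply(seq_along(res$steps), function(i) {
    list(step = res$steps[[i]], pos = res$positions[[i]],
         bonds = res$bonds[[i]])
  })
  structure(list(
    config = cfg,
    chain_meta = data.frame(
      chain_id = vapply(chains, `[[`, integer(1), "chain_id"),
      homolog_id = vapply(chains, `[[`, integer(1), "homolog_id")),
    buttons = lapply(chains, `[[`, "buttons"),
    steps = unlist(res$steps),
    frames = frames
  ), class = "cp_trajectory")
}

#' @export
print.cp_trajectory <- function(x, ...) {
  cat(sprintf("<cp_trajectory> %d chains x %d nodes, %d frames (steps %d..%d)\n",
              nrow(x$chain_meta), x$config$nodes_per_arm, length(x$frames),
              min(x$steps), max(x$steps)))
  invisible(x)
}

#' Positions of one chain in one recorded frame
#'
#' @param traj a `cp_trajectory`.
#' @param frame frame number (1-based).
#' @param chain_id chain id.
#' @return `nodes_per_arm x 3` matrix.
#' @export
frame_positions <- function(traj, frame, chain_id) {
  n <- traj$config$nodes_per_arm
  off <- (chain_id - 1L) * n
  traj$frames[[frame]]$pos[(off + 1L):(off + n), , drop = FALSE]
}

#' Reconstruct chain states from a recorded frame
#'
#' @param traj a `cp_trajectory`.
#' @param frame frame number (1-based).
#' @return list of `chain_state`.
#' @export
frame_chains <- function(traj, frame) {
  lapply(seq_len(nrow(traj$chain_meta)), function(c) {
    chain_state(frame_positions(traj, frame, c),
                traj$buttons[[c]],
                homolog_id = traj$chain_meta$homolog_id[c],
                chain_id = traj$chain_meta$chain_id[c])
  })
}
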