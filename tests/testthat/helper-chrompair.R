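# Shared test utilities: small configs, synthetic trajectories, and a
# finite-difference gradient of the elastic energy.

quick_cfg <- function(...) {
  args <- utils::modifyList(list(n_steps = 500L, record_every = 100L,
                                 burn_in = 100L), list(...))
  do.call(sim_config, args)
}

# strip the steps attribute for matrix comparisons
unattr <- function(m) {
  attr(m, "steps") <- NULL
  unname(m)
}

# Finite-difference gradient of elastic_energy with respect to every node
# coordinate; returns a list of n x 3 matrices like total_forces().
fd_gradient <- function(chains, pairing, cfg, h = 1e-6) {
  lapply(seq_along(chains), function(ci) {
    x <- chains[[ci]]$positions
    g <- matrix(0, nrow(x), 3)
    for (i in seq_len(nrow(x))) {
      for (k in 1:3) {
        cp <- chains; cm <- chains
        cp[[ci]]$positions[i, k] <- x[i, k] + h
        cm[[ci]]$positions[i, k] <- x[i, k] - h
        g[i, k] <- (elastic_energy(cp, pairing, cfg) -
                      elastic_energy(cm, pairing, cfg)) / (2 * h)
      }
    }
    g
  })
}

# Random small two-pair system with some bonds, for gradient checks.
random_system <- function(seed, n_nodes = 6, bonded = TRUE) {
  set.seed(seed)
  cfg <- sim_config(nodes_per_arm = n_nodes, rabl_patch_radius = 3,
                    nucleus_radius = 6)
  chains <- lapply(1:4, function(c) {
    base <- matrix(stats::rnorm(n_nodes * 3, sd = 1.5), n_nodes, 3)
    base[, 3] <- base[, 3] + 4   # keep near the top half, some nodes outside
    chain_state(base, buttons = c(0L, 2L, 4L),
                homolog_id = (c + 1L) %/% 2L, chain_id = c)
  })
  bonds <- if (bonded) {
    rbind(c(1L, 0L, 2L, 0L), c(1L, 2L, 3L, 4L), c(2L, 2L, 2L, 4L))
  } else matrix(integer(0), ncol = 4)
  list(cfg = cfg, chains = chains, pairing = pairing_state(bonds))
}

# Build a synthetic trajectory from a list of frames; each frame is a list of
# per-chain position matrices. Buttons default to all nodes.
synth_traj <- function(frames_pos, buttons = NULL, homolog_id = NULL,
                       steps = NULL, cfg = NULL, bonds = NULL) {
  n_chains <- length(frames_pos[[1]])
  n <- nrow(frames_pos[[1]][[1]])
  if (is.null(cfg)) {
    cfg <- sim_config(n_pairs = max(1L, n_chains %/% 2L), nodes_per_arm = n,
                      n_steps = length(frames_pos), record_every = 1,
                      burn_in = 0)
  }
  if (is.null(buttons)) buttons <- rep(list(0:(n - 1)), n_chains)
  if (is.null(homolog_id)) homolog_id <- rep(seq_len(ceiling(n_chains / 2)), each = 2)[seq_len(n_chains)]
  if (is.null(steps)) steps <- seq_along(frames_pos) - 1L
  frames <- lapply(seq_along(frames_pos), function(f) {
    list(step = steps[f], pos = do.call(rbind, frames_pos[[f]]),
         bonds = if (is.null(bonds)) matrix(integer(0), ncol = 4) else bonds[[f]])
  })
  structure(list(
    config = cfg,
    chain_meta = data.frame(chain_id = seq_len(n_chains), homolog_id = homolog_id),
    buttons = buttons,
    steps = steps,
    frames = frames
  ), class = "cp_trajectory")
}

# Two-pair chain metadata used by fidelity unit tests.
meta2 <- data.frame(chain_id = 1:4, homolog_id = c(1L, 1L, 2L, 2L))
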