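#' Pairing fidelity of one frame
#'
#' Fraction of buttons bonded to the correct partner. In `chromosome` mode a
#' button is correct when bonded to any button on its homolog; in `locus` mode
#' it must be bonded to the identically indexed node on the homolog. Unpaired
#' buttons, cis bonds and bonds to non-homologs all count as incorrect; the
#' denominator is the total number of buttons on all chains.
#'
#' @param bonds integer bond matrix (`chain_a, node_a, chain_b, node_b`).
#' @param chain_meta data.frame with columns `chain_id`, `homolog_id`.
#' @param buttons list of per-chain 0-based button indices.
#' @param mode `"locus"` or `"chromosome"`.
#' @return fraction in \[0, 1\].
#' @export
pairing_fidelity <- function(bonds, chain_meta, buttons, mode = c("locus", "chromosome")) {
  mode <- match.arg(mode)
  n_buttons <- sum(lengths(buttons))
  if (n_buttons == 0) stop("no buttons defined")
  if (is.null(bonds) || nrow(bonds) == 0) return(0)
  partner_of <- integer(nrow(chain_meta))
  for (c in chain_meta$chain_id) {
    h <- chain_meta$homolog_id[chain_meta$chain_id == c]
    partner_of[c] <- chain_meta$chain_id[chain_meta$homolog_id == h &
                                           chain_meta$chain_id != c]
  }
  trans_ok <- partner_of[bonds[, 1]] == bonds[, 3]
  correct <- if (mode == "locus") trans_ok & bonds[, 2] == bonds[, 4] else trans_ok
  # each correct bond satisfies both of its endpoints
  2 * sum(correct) / n_buttons
}

#' Classify pairing of one frame into fractions
#'
#' Returns the fraction of buttons that are correctly paired (locus and
#' chromosome modes), paired to a non-homolog (trans-incorrect), paired in cis,
#' and unpaired.
#'
#' @inheritParams pairing_fidelity
#' @return named numeric vector summing to 1 over
#'   `correct_chromosome + trans_incorrect + cis + unpaired`.
#' @export
pairing_fractions <- function(bonds, chain_meta, buttons) {
  n_buttons <- sum(lengths(buttons))
  if (n_buttons == 0) stop("no buttons defined")
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 4)
  partner_of <- integer(nrow(chain_meta))
  for (c in chain_meta$chain_id) {
    h <- chain_meta$homolog_id[chain_meta$chain_id == c]
    partner_of[c] <- chain_meta$chain_id[chain_meta$homolog_id == h &
                                           chain_meta$chain_id != c]
  }
  if (nrow(bonds) > 0) {
    trans_ok <- partner_of[bonds[, 1]] == bonds[, 3]
    locus_ok <- trans_ok & bonds[, 2] == bonds[, 4]
    cis <- bonds[, 1] == bonds[, 3]
    wrong <- !trans_ok & !cis
  } else {
    trans_ok <- locus_ok <- cis <- wrong <- logical(0)
  }
  c(correct_locus = 2 * sum(locus_ok) / n_buttons,
    correct_chromosome = 2 * sum(trans_ok) / n_buttons,
    trans_incorrect = 2 * sum(wrong) / n_buttons,
    cis = 2 * sum(cis) / n_buttons,
    unpaired = (n_buttons - 2 * nrow(bonds)) / n_buttons)
}

#' Chance baseline for correct pairing
#'
#' With `n_pairs` homolog pairs, every button choosing uniformly among its
#' candidate partners has one correct chromosome out of `2 * n_pairs` options:
#' the homolog, the `2 * n_pairs - 2` non-homologs, and its own chromosome
#' (cis). The expected correct fraction is therefore `1 / (2 * n_pairs)`
#' (0.25 for two pairs).
#'
#' @param n_pairs number of homolog pairs (>= 1).
#' @return fraction in (0, 0.5\].
#' @export
#' @examples
#' chance_baseline(2)  # 0.25
chance_baseline <- function(n_pairs) {
  if (length(n_pairs) != 1 || is.na(n_pairs) || n_pairs < 1) {
    stop("n_pairs must be >= 1")
  }
  1 / (2 * n_pairs)
}

#' Fidelity time course of a trajectory
#'
#' @param traj a `cp_trajectory`.
#' @param mode `"locus"` or `"chromosome"`.
#' @return numeric vector, one fidelity per recorded frame.
#' @export
fidelity_timecourse <- function(traj, mode = "locus") {
  vapply(traj$frames, function(fr) {
    pairing_fidelity(fr$bonds, traj$chain_meta, traj$buttons, mode)
  }, numeric(1))
}

#' Final pairing fidelity
#'
#' Mean fidelity over the last 10% of recorded frames (at least one frame).
#'
#' @inheritParams fidelity_timecourse
#' @return fraction in \[0, 1\].
#' @export
final_fidelity <- function(traj, mode = "locus") {
  tc <- fidelity_timecourse(traj, mode)
  k <- max(1L, ceiling(0.1 * length(tc)))
  mean(utils::tail(tc, k))
}

#' Homolog-distance kymograph
#'
#' Matrix with one row per node (locus) and one column per recorded frame;
#' entry (i, t) is the Euclidean distance between node i on the two homologs
#' of `homolog_id` at frame t, divided by the maximum such distance over all
#' loci and frames of the run, so values lie in \[0, 1\] and the maximum is
#' exactly 1 whenever any distance is nonzero.
#'
#' @param traj a `cp_trajectory`.
#' @param homolog_id which homolog pair to plot.
#' @return numeric matrix (`nodes x frames`) with attribute `steps`.
#' @export
kymograph <- function(traj, homolog_id = 1) {
  ids <- traj$chain_meta$chain_id[traj$chain_meta$homolog_id == homolog_id]
  if (length(ids) != 2) stop("homolog pair not found in trajectory")
  m <- vapply(seq_along(traj$frames), function(f) {
    a <- frame_positions(traj, f, ids[1])
    b <- frame_positions(traj, f, ids[2])
    sqrt(rowSums((a - b)^2))
  }, numeric(traj$config$nodes_per_arm))
  m <- matrix(m, nrow = traj$config$nodes_per_arm)
  mx <- max(m)
  if (mx > 0) m <- m / mx
  attr(m, "steps") <- traj$steps
  m
}

#' Rabl correlation coefficient
#'
#' Pearson correlation between genomic position (node index, increasing away
#' from the centromere toward the telomere) and vertical position (z
#' coordinate, +z being the centromere pole), pooled over all chains and all
#' recorded frames after burn-in. With this orientation a strong Rabl
#' configuration gives r near -1 (loci far from the centromere sit low in the
#' nucleus); no Rabl organisation gives r near 0. Intended for trajectories
#' run with pairing disabled, as in the calibration runs.
#'
#' @param traj a `cp_trajectory`.
#' @return Pearson correlation coefficient.
#' @export
rabl_correlation <- function(traj) {
  n <- traj$config$nodes_per_arm
  if (n < 2) stop("need at least 2 distinct node indices")
  keep <- which(traj$steps >= traj$config$burn_in)
  if (length(keep) == 0) keep <- seq_along(traj$frames)
  n_chains <- nrow(traj$chain_meta)
  idx <- rep(0:(n - 1), times = n_chains)
  zs <- unlist(lapply(keep, function(f) traj$frames[[f]]$pos[, 3]))
  stats::cor(rep(idx, times = length(keep)), zs)
}

#' Persistence length from bond-orientation correlations
#'
#' Computes the mean cosine between unit bond vectors separated by `s` bonds,
#' `C(s)`, averaged over all chains and all post-burn-in frames, and fits
#' `log C(s) = -s / Lp` by least squares through the origin over the
#' separations with `C(s) > 0.1`. Two degenerate regimes are flagged via the
#' `"flag"` attribute: if `C(1) <= 0.1` the chain is at the freely jointed
#' floor and the theoretical value 0.5 length units (half the link length) is
#' returned with flag `"free_chain_floor"` and a warning; if the fitted decay
#' is flat the chain is effectively rigid and a value at least the contour
#' length is returned with flag `"rigid"`.
#'
#' @param traj a `cp_trajectory` (pairing disabled for meaningful results).
#' @return persistence length in length units, with attribute `flag`
#'   (`"ok"`, `"free_chain_floor"` or `"rigid"`).
#' @export
estimate_persistence_length <- function(traj) {
  cc <- bond_cosine_decay(traj)
  persistence_from_decay(cc, contour = traj$config$nodes_per_arm - 1)
}

#' Mean bond-orientation cosine by separation
#'
#' `C(s) = <u_i . u_{i+s}>` for unit bond vectors, averaged over all chains
#' and post-burn-in frames.
#'
#' @param traj a `cp_trajectory`.
#' @return numeric vector indexed by separation `s = 1, 2, ...`.
#' @export
bond_cosine_decay <- function(traj) {
  n <- traj$config$nodes_per_arm
  if (n < 3) stop("need at least 2 bonds per chain")
  keep <- which(traj$steps >= traj$config$burn_in)
  if (length(keep) == 0) keep <- seq_along(traj$frames)
  n_chains <- nrow(traj$chain_meta)
  smax <- n - 2
  acc <- numeric(smax); cnt <- numeric(smax)
  for (f in keep) {
    for (c in seq_len(n_chains)) {
      x <- frame_positions(traj, f, c)
      u <- x[-1, , drop = FALSE] - x[-n, , drop = FALSE]
      u <- u / sqrt(rowSums(u^2))
      nb <- nrow(u)
      for (s in seq_len(smax)) {
        i <- seq_len(nb - s)
        acc[s] <- acc[s] + sum(rowSums(u[i, , drop = FALSE] * u[i + s, , drop = FALSE]))
        cnt[s] <- cnt[s] + length(i)
      }
    }
  }
  acc / cnt
}

# Internal: through-origin exponential-decay fit shared by the estimator and
# the synthetic-chain tests.
persistence_from_decay <- function(cc, contour) {
  if (!is.finite(cc[1]) || cc[1] <= 0.1) {
    warning("bond orientations decorrelate within one link; reporting the freely jointed floor of 0.5 length units")
    return(structure(0.5, flag = "free_chain_floor"))
  }
  s <- which(cc > 0.1)
  s <- s[seq_len(match(FALSE, cc > 0.1, nomatch = length(s) + 1L) - 1L)] # leading run
  lc <- log(cc[s])
  slope <- sum(s * lc) / sum(s^2)
  if (slope >= -1 / (100 * contour)) {
    return(structure(max(contour, if (slope < 0) -1 / slope else contour),
                     flag = "rigid"))
  }
  lp <- -1 / slope
  if (lp >= contour) return(structure(lp, flag = "rigid"))
  structure(lp, flag = "ok")
}

#' Time to reach a pairing-fidelity threshold
#'
#' First recorded step at which the fidelity reaches `threshold`; later frames
#' are not re-checked. Returns `NA` ("not reached") if the threshold is never
#' crossed in the recorded frames.
#'
#' @param traj a `cp_trajectory`.
#' @param threshold fidelity threshold (default 0.9).
#' @param mode `"locus"` or `"chromosome"`.
#' @return integer step index, or `NA_integer_` if not reached.
#' @export
time_to_fraction_paired <- function(traj, threshold = 0.9, mode = "locus") {
  tc <- fidelity_timecourse(traj, mode)
  hit <- which(tc >= threshold)
  if (length(hit) == 0) return(NA_integer_)
  as.integer(traj$steps[hit[1]])
}

#' Discrimination energy between two barcodes
#'
#' The mechanical basis of barcode selectivity: the elastic-energy difference
#' between enforced incorrect pairing and correct pairing. Two two-chain
#' systems are relaxed by noiseless gradient descent (to force tolerance
#' `tol`) in free space (no confinement or tether, so the result measures the
#' intrinsic chain-deformation cost): in the correct system both chains carry
#' `bc_a` and same-index buttons are bonded; in the incorrect system the
#' chains carry `bc_a` and `bc_b` and buttons are bonded by rank order (any
#' surplus buttons on the longer code are left unbonded). Returns
#' `E(incorrect) - E(correct)` in kBT units; zero for identical codes,
#' positive whenever the incorrect alignment requires deformation.
#'
#' @param cfg a `sim_config` (mechanics are taken from it).
#' @param bc_a,bc_b `barcode` objects on the same arm length.
#' @param tol force tolerance for the relaxation (default 1e-6).
#' @param max_iter descent iteration cap.
#' @return energy difference in kBT, with attribute `energies` (named vector
#'   of the two relaxed energies).
#' @export
discrimination_energy <- function(cfg, bc_a, bc_b, tol = 1e-6, max_iter = 500000) {
  if (bc_a$arm_length != bc_b$arm_length) stop("barcodes must share arm_length")
  n <- bc_a$arm_length
  free_cfg <- cfg
  free_cfg$nucleus_radius <- 1e9
  free_cfg$rabl_patch_radius <- 2e9
  relaxed_energy <- function(b1, b2) {
    # straight chains along -z; second chain offset laterally by one unit
    x1 <- cbind(0, 0, -(0:(n - 1)))
    x2 <- cbind(1, 0, -(0:(n - 1)))
    k <- min(length(b1$buttons), length(b2$buttons))
    bond_rows <- cbind(b1$buttons[seq_len(k)], n + b2$buttons[seq_len(k)])
    step_max <- 4 * cfg$k_spring + 4 * cfg$k_bend + 2 * cfg$k_pair
    res <- .engine_relax(rbind(x1, x2), 2L, n, bond_rows, unclass(cfg),
                         step_size = 1 / step_max, tol = tol,
                         max_iter = as.integer(max_iter), confined = FALSE)
    chains <- list(
      chain_state(res$positions[1:n, , drop = FALSE], b1$buttons, 1L, 1L),
      chain_state(res$positions[(n + 1):(2 * n), , drop = FALSE], b2$buttons, 1L, 2L))
    bonds <- cbind(1L, b1$buttons[seq_len(k)], 2L, b2$buttons[seq_len(k)])
    elastic_energy(chains, pairing_state(bonds), free_cfg)
  }
  e_correct <- relaxed_energy(bc_a, bc_a)
  e_incorrect <- relaxed_energy(bc_a, bc_b)
  structure(e_incorrect - e_correct,
            energies = c(correct = e_correct, incorrect = e_incorrect))
}

#' Run an ensemble of independent simulations
#'
#' Runs `n_runs` simulations with per-run seeds `base_seed + 0:(n_runs-1)` and
#' collects the run-level metrics so that ensemble means and standard errors
#' can be recomputed from the per-run values.
#'
#' @param cfg a `sim_config` (its `seed` field is overridden per run).
#' @param barcodes see [init_chains()].
#' @param n_runs ensemble size.
#' @param base_seed first seed.
#' @param threshold fidelity threshold for the pairing-time metric.
#' @return data.frame with one row per run: `run`, `seed`, `fidelity_locus`,
#'   `fidelity_chromosome`, `trans_incorrect`, `time_to_threshold`.
#' @export
run_ensemble <- function(cfg, barcodes = NULL, n_runs = 30,
                         base_seed = cfg$seed, threshold = 0.9) {
  rows <- lapply(seq_len(n_runs), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer(base_seed + i - 1L)
    traj <- run_simulation(cfg_i, barcodes)
    k <- max(1L, ceiling(0.1 * length(traj$frames)))
    last <- utils::tail(seq_along(traj$frames), k)
    fr <- rowMeans(vapply(last, function(f) {
      pairing_fractions(traj$frames[[f]]$bonds, traj$chain_meta, traj$buttons)
    }, numeric(5)))
    data.frame(run = i, seed = cfg_i$seed,
               fidelity_locus = fr[["correct_locus"]],
               fidelity_chromosome = fr[["correct_chromosome"]],
               trans_incorrect = fr[["trans_incorrect"]],
               time_to_threshold = time_to_fraction_paired(traj, threshold))
  })
  do.call(rbind, rows)
}

#' Summarise an ensemble
#'
#' @param ens data.frame from [run_ensemble()].
#' @param metric column to summarise.
#' @return named vector with `mean`, `sem`, `median`, `min`, `max`, `n`.
#' @export
ensemble_summary <- function(ens, metric = "fidelity_locus") {
  x <- ens[[metric]]
  c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)),
    median = stats::median(x), min = min(x), max = max(x), n = length(x))
}

#' Metrics report for a single run
#'
#' Bundles the per-run metrics: fidelity time courses (both modes), final
#' fidelity, the kymograph for the first homolog pair, the Rabl correlation,
#' the persistence-length estimate and the time to 90% locus pairing.
#'
#' @param traj a `cp_trajectory`.
#' @return a `metrics_report` list.
#' @export
metrics_report <- function(traj) {
  km <- kymograph(traj, homolog_id = 1)
  rep <- list(
    steps = traj$steps,
    fidelity_locus = fidelity_timecourse(traj, "locus"),
    fidelity_chromosome = fidelity_timecourse(traj, "chromosome"),
    final_fidelity_locus = final_fidelity(traj, "locus"),
    final_fidelity_chromosome = final_fidelity(traj, "chromosome"),
    kymograph = km,
    rabl_correlation = rabl_correlation(traj),
    persistence_length = suppressWarnings(as.numeric(estimate_persistence_length(traj))),
    time_to_90pct = time_to_fraction_paired(traj, 0.9)
  )
  class(rep) <- "metrics_report"
  rep
}

#' Write a metrics report as JSON
#'
#' @param rep a `metrics_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(rep, path) {
  out <- unclass(rep)
  out$kymograph <- NULL   # written separately as a CSV matrix
  out$time_to_90pct <- if (is.na(out$time_to_90pct)) "not reached" else out$time_to_90pct
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
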