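test_that("pairing fidelity distinguishes locus and chromosome conventions", {
  buttons <- rep(list(c(0L, 3L)), 4)  # 8 buttons over two homolog pairs
  # all bonded to the same-index button on the homolog
  b_perfect <- rbind(c(1L, 0L, 2L, 0L), c(1L, 3L, 2L, 3L),
                     c(3L, 0L, 4L, 0L), c(3L, 3L, 4L, 3L))
  expect_equal(pairing_fidelity(b_perfect, meta2, buttons, "locus"), 1)
  expect_equal(pairing_fidelity(b_perfect, meta2, buttons, "chromosome"), 1)
  # no bonds at all
  none <- matrix(integer(0), ncol = 4)
  expect_equal(pairing_fidelity(none, meta2, buttons, "locus"), 0)
  # all bonds to non-homologs
  b_wrong <- rbind(c(1L, 0L, 3L, 0L), c(1L, 3L, 3L, 3L),
                   c(2L, 0L, 4L, 0L), c(2L, 3L, 4L, 3L))
  expect_equal(pairing_fidelity(b_wrong, meta2, buttons, "chromosome"), 0)
  # homolog bonds but index-shifted: chromosome-correct, locus-incorrect
  b_shift <- rbind(c(1L, 0L, 2L, 3L), c(1L, 3L, 2L, 0L))
  expect_equal(pairing_fidelity(b_shift, meta2, buttons, "chromosome"), 0.5)
  expect_equal(pairing_fidelity(b_shift, meta2, buttons, "locus"), 0)
  expect_error(pairing_fidelity(b_perfect, meta2, list(), "locus"), "no buttons")
})

test_that("pairing fractions partition every button exactly once", {
  buttons <- rep(list(c(0L, 3L)), 4)
  bonds <- rbind(c(1L, 0L, 2L, 0L),   # correct locus
                 c(1L, 3L, 3L, 3L),   # trans incorrect
                 c(4L, 0L, 4L, 3L))   # cis
  fr <- pairing_fractions(bonds, meta2, buttons)
  expect_equal(unname(fr["correct_locus"]), 0.25)
  expect_equal(unname(fr["correct_chromosome"]), 0.25)
  expect_equal(unname(fr["trans_incorrect"]), 0.25)
  expect_equal(unname(fr["cis"]), 0.25)
  expect_equal(unname(fr["unpaired"]), 0.25)
  expect_equal(unname(fr["correct_chromosome"] + fr["trans_incorrect"] +
                        fr["cis"] + fr["unpaired"]), 1)
})

test_that("chance baseline is 1 / (2 * n_pairs)", {
  expect_identical(chance_baseline(2), 0.25)
  expect_identical(chance_baseline(1), 0.5)
  expect_identical(chance_baseline(5), 0.1)
  expect_error(chance_baseline(0), "n_pairs")
})

test_that("kymograph normalizes homolog distances to the run maximum", {
  # hand-built 2-frame, 2-node trajectory
  f1 <- list(rbind(c(0, 0, 0), c(0, 0, 1)), rbind(c(3, 0, 0), c(0, 4, 1)))
  f2 <- list(rbind(c(0, 0, 0), c(0, 0, 1)), rbind(c(1, 0, 0), c(0, 0, 1)))
  traj <- synth_traj(list(f1, f2))
  km <- kymograph(traj, 1)
  # distances: frame1 (3, 4), frame2 (1, 0); max = 4
  expect_equal(unattr(km), rbind(c(3, 1), c(4, 0)) / 4)
  expect_equal(max(km), 1)
  # identical homolog coordinates give the all-zero matrix
  same <- synth_traj(list(list(f1[[1]], f1[[1]])))
  expect_equal(unattr(kymograph(same, 1)), matrix(0, 2, 1))
})

test_that("Rabl correlation recovers exact and null orderings", {
  n <- 20
  perfect <- lapply(1:3, function(f) {
    x <- cbind(0, 0, -(0:(n - 1)))
    list(x, x)
  })
  traj <- synth_traj(perfect)
  expect_equal(abs(rabl_correlation(traj)), 1)
  # z independent of index: |r| small at 1e4 pooled points
  set.seed(8)
  null_frames <- lapply(1:250, function(f) {
    list(cbind(0, 0, rnorm(n)), cbind(0, 0, rnorm(n)))
  })
  traj0 <- synth_traj(null_frames)
  expect_lt(abs(rabl_correlation(traj0)), 0.05)
})

test_that("persistence length estimator matches a known angle model", {
  # synthetic chain with independent bond turns: cos(theta) has known mean;
  # closed form Lp = -1 / log(<cos theta>)
  set.seed(10)
  n <- 40
  kappa <- 8  # wrapped-normal-ish turning angle scale via small gaussians
  frames <- lapply(1:400, function(f) {
    u <- c(0, 0, 1)
    x <- matrix(0, n, 3)
    for (i in 2:n) {
      # perturb direction by independent gaussian of variance 1/kappa per axis
      u <- u + rnorm(3, sd = sqrt(1 / kappa))
      u <- u / sqrt(sum(u^2))
      x[i, ] <- x[i - 1, ] + u
    }
    list(x, x)
  })
  traj <- synth_traj(frames)
  # oracle: mean cosine between successive bonds measured directly
  mean_cos <- mean(vapply(frames, function(fr) {
    x <- fr[[1]]
    u <- x[-1, ] - x[-n, ]
    u <- u / sqrt(rowSums(u^2))
    mean(rowSums(u[-1, ] * u[-(n - 1), ]))
  }, numeric(1)))
  lp_closed <- -1 / log(mean_cos)
  lp <- estimate_persistence_length(traj)
  expect_equal(attr(lp, "flag"), "ok")
  expect_equal(as.numeric(lp), lp_closed, tolerance = 0.1)
})

test_that("persistence length flags the rigid and freely jointed regimes", {
  n <- 12
  rigid <- synth_traj(lapply(1:3, function(f) {
    x <- cbind(0, 0, 0:(n - 1)); list(x, x)
  }))
  lp <- estimate_persistence_length(rigid)
  expect_equal(attr(lp, "flag"), "rigid")
  expect_gte(as.numeric(lp), n - 1)
  # freely jointed: independent random unit bonds
  set.seed(11)
  fj <- synth_traj(lapply(1:200, function(f) {
    u <- matrix(rnorm(3 * (n - 1)), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    x <- rbind(0, apply(u, 2, cumsum))
    list(x, x)
  }))
  expect_warning(lp0 <- estimate_persistence_length(fj), "freely jointed")
  expect_identical(as.numeric(lp0), 0.5)
  expect_equal(attr(lp0, "flag"), "free_chain_floor")
})

test_that("time to threshold takes the first crossing and never re-checks", {
  buttons <- rep(list(c(0L, 1L)), 4)
  full <- rbind(c(1L, 0L, 2L, 0L), c(1L, 1L, 2L, 1L),
                c(3L, 0L, 4L, 0L), c(3L, 1L, 4L, 1L))
  half <- full[c(1, 3), ]
  none <- matrix(integer(0), ncol = 4)
  pos <- lapply(1:4, function(c) cbind(0, 0, 0:1))
  mk <- function(bond_seq, steps) {
    synth_traj(rep(list(pos), length(bond_seq)), buttons = buttons,
               steps = steps, bonds = bond_seq)
  }
  # fidelities 0.1-like, 0.95-like, 0.8-like -> the second frame's step
  traj <- mk(list(none, full, half), steps = c(0L, 100L, 200L))
  expect_identical(time_to_fraction_paired(traj, 0.9), 100L)
  # starts fully paired -> first recorded step
  traj2 <- mk(list(full, half), steps = c(0L, 100L))
  expect_identical(time_to_fraction_paired(traj2, 0.9), 0L)
  # never crosses -> not reached (NA)
  traj3 <- mk(list(none, half), steps = c(0L, 100L))
  expect_identical(time_to_fraction_paired(traj3, 0.9), NA_integer_)
})

test_that("discrimination energy is zero iff codes are identical", {
  cfg <- sim_config()
  b3 <- barcode(3 * (0:4), 28)
  b4 <- barcode(4 * (0:4), 28)
  de0 <- discrimination_energy(cfg, b3, b3, tol = 1e-6)
  expect_equal(as.numeric(de0), 0, tolerance = 1e-9)
  de <- discrimination_energy(cfg, b3, b4, tol = 1e-6)
  expect_gt(as.numeric(de), 0.5)
  # regression fixture for the relaxation oracle (recorded magnitude)
  expect_equal(as.numeric(de), 8.63, tolerance = 0.05)
  # surplus buttons on the longer code are left unbonded, no error
  b2 <- barcode(c(0L, 5L), 28)
  expect_no_error(discrimination_energy(cfg, b3, b2, tol = 1e-5))
})

test_that("ensembles store per-run values so SEM is recomputable", {
  cfg <- quick_cfg(n_steps = 2000, record_every = 200, burn_in = 200, seed = 1)
  ens <- run_ensemble(cfg, n_runs = 4, base_seed = 11)
  expect_identical(nrow(ens), 4L)
  expect_identical(ens$seed, 11:14)
  s <- ensemble_summary(ens, "fidelity_chromosome")
  expect_equal(unname(s["sem"]),
               sd(ens$fidelity_chromosome) / 2)
  expect_gte(unname(s["sem"]), 0)
  expect_true(all(ens$fidelity_locus >= 0 & ens$fidelity_locus <= 1))
})
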