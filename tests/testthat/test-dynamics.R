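test_that("initialization satisfies the bookkeeping and geometry contract", {
  cfg <- quick_cfg(seed = 5)
  set.seed(cfg$seed)
  chains <- init_chains(cfg)
  expect_length(chains, 4)
  hom <- vapply(chains, `[[`, integer(1), "homolog_id")
  expect_identical(sort(unique(hom)), c(1L, 2L))
  expect_true(all(table(hom) == 2))
  # deterministic given the seed
  set.seed(cfg$seed)
  chains2 <- init_chains(cfg)
  expect_identical(chains, chains2)
  for (ch in chains) {
    x <- ch$positions
    d <- sqrt(rowSums((x[-1, ] - x[-nrow(x), ])^2))
    expect_true(all(abs(d - cfg$rest_length) <= 0.1 * cfg$rest_length))
    expect_true(all(sqrt(rowSums(x^2)) <= cfg$nucleus_radius * (1 + 1e-6)))
    # centromere starts on the envelope inside the Rabl cap
    cent <- x[1, ]
    expect_equal(sqrt(sum(cent^2)), cfg$nucleus_radius, tolerance = 1e-9)
    chord <- sqrt(sum((cent - c(0, 0, cfg$nucleus_radius))^2))
    expect_lte(chord, cfg$rabl_patch_radius + 1e-9)
  }
})

test_that("heterozygous layouts give the two homologs different codes", {
  cfg <- quick_cfg()
  a <- reference_patch_code("primary")
  b <- shift_barcode(a, 12)
  set.seed(1)
  chains <- init_chains(cfg, list(list(a, b), reference_patch_code("secondary")))
  expect_identical(chains[[1]]$buttons, a$buttons)
  expect_identical(chains[[2]]$buttons, b$buttons)
  expect_identical(chains[[3]]$buttons, chains[[4]]$buttons)
})

test_that("a rest-length straight chain far from constraints is a fixed point", {
  cfg <- sim_config(nodes_per_arm = 6, kBT = 0, nucleus_radius = 100,
                    rabl_patch_radius = 200)
  x <- cbind(0, 0, 10 - (0:5))
  chains <- list(chain_state(x, 0L, 1L, 1L), chain_state(x + 5, 0L, 1L, 2L))
  out <- bd_step(chains, pairing_state(), cfg)
  expect_equal(out[[1]]$positions, x)
  # a single displaced node moves strictly down the force direction
  x2 <- x; x2[3, 1] <- 0.4
  ch2 <- list(chain_state(x2, 0L, 1L, 1L), chain_state(x + 5, 0L, 1L, 2L))
  f <- total_forces(ch2, pairing_state(), cfg)[[1]][3, ]
  out2 <- bd_step(ch2, pairing_state(), cfg)
  disp <- out2[[1]]$positions[3, ] - x2[3, ]
  expect_equal(disp / sqrt(sum(disp^2)), f / sqrt(sum(f^2)), tolerance = 1e-12)
})

test_that("runs are reproducible and n_steps = 0 keeps only the initial frame", {
  cfg <- quick_cfg(seed = 9)
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(t1$frames, t2$frames)
  cfg0 <- quick_cfg(n_steps = 0, seed = 9)
  t0 <- run_simulation(cfg0)
  expect_length(t0$frames, 1)
  expect_identical(t0$frames[[1]]$step, 0L)
})

test_that("the compiled engine matches the reference R step at kBT = 0", {
  cfg <- sim_config(nodes_per_arm = 8, kBT = 0, n_steps = 1, record_every = 1,
                    burn_in = 0, seed = 3)
  set.seed(3)
  chains <- init_chains(cfg)
  traj <- run_simulation(cfg, pairing_enabled = FALSE)
  # same initial chains (same seed), stepped once by the R reference
  ref <- bd_step(chains, pairing_state(), cfg)
  for (c in seq_along(chains)) {
    expect_equal(frame_positions(traj, 2, c), unname(ref[[c]]$positions),
                 tolerance = 1e-12)
  }
})

test_that("centre-of-mass diffusion obeys the Einstein relation", {
  # the COM of an N-bead chain feels no internal force and diffuses with
  # D = kBT / (N * friction); time-averaged MSD over a long free run
  cfg <- sim_config(nodes_per_arm = 2, kBT = 1, friction = 1, dt = 0.005,
                    nucleus_radius = 1e6, rabl_patch_radius = 2e6,
                    n_steps = 200000, record_every = 20, burn_in = 0, seed = 21)
  traj <- run_simulation(cfg, barcodes = list(barcode(0L, 2), barcode(0L, 2)),
                         pairing_enabled = FALSE)
  com <- t(vapply(seq_along(traj$frames),
                  function(f) colMeans(frame_positions(traj, f, 1)),
                  numeric(3)))
  lag <- 5
  d <- com[-(1:lag), ] - com[seq_len(nrow(com) - lag), ]
  msd <- mean(rowSums(d^2))
  expected <- 6 * (cfg$kBT / (2 * cfg$friction)) * lag * cfg$record_every * cfg$dt
  expect_equal(msd, expected, tolerance = 0.15)
})

test_that("equilibrium bond lengths follow the Boltzmann distribution", {
  # 2-node chain: stationary bond-length density ~ d^2 exp(-k (d-d0)^2 / 2kBT);
  # small k*dt so the Euler-Maruyama bias is below KS resolution
  k <- 10
  cfg <- sim_config(nodes_per_arm = 2, k_spring = k, kBT = 1, dt = 0.001,
                    nucleus_radius = 1e6, rabl_patch_radius = 2e6,
                    n_steps = 2e6, record_every = 200, burn_in = 0, seed = 31)
  traj <- run_simulation(cfg, barcodes = list(barcode(0L, 2), barcode(0L, 2)),
                         pairing_enabled = FALSE)
  d <- vapply(seq_along(traj$frames), function(f) {
    x <- frame_positions(traj, f, 1)
    sqrt(sum((x[2, ] - x[1, ])^2))
  }, numeric(1))
  d <- d[-(1:50)]   # discard relaxation from the jittered start
  dens <- function(r) r^2 * exp(-k * (r - 1)^2 / 2)
  Z <- stats::integrate(dens, 0, Inf)$value
  cdf <- function(q) vapply(q, function(qq)
    stats::integrate(dens, 0, qq)$value / Z, numeric(1))
  ks <- suppressWarnings(stats::ks.test(d, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("tethered chains develop the Rabl z-gradient", {
  cfg <- sim_config(n_steps = 30000, record_every = 500, seed = 13)
  traj <- run_simulation(cfg, pairing_enabled = FALSE)
  expect_lt(rabl_correlation(traj), -0.5)
})

test_that("numerical blow-up is reported, not silently propagated", {
  cfg <- quick_cfg(dt = 5, n_steps = 5000, record_every = 5000, burn_in = 0,
                   seed = 2)
  expect_error(run_simulation(cfg), "numerical blow-up")
})
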