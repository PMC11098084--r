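test_that("formation is greedy nearest-first with one-to-one exclusivity", {
  # three free buttons: A-B at 0.5, A-C at 0.7, B-C out of range
  cfg <- quick_cfg(nodes_per_arm = 4, p_unpair = 0)
  xa <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  xb <- xa; xb[1, ] <- c(0.5, 0, 0)   # B on chain 2
  xc <- xa + 10; xc[1, ] <- c(-0.7, 0, 0)  # C on chain 3... needs 4 chains
  xd <- xa + 20
  chains <- list(
    chain_state(xa, 0L, 1L, 1L),
    chain_state(xb, 0L, 1L, 2L),
    chain_state(xc, 0L, 2L, 3L),
    chain_state(xd, 0L, 2L, 4L))
  upd <- update_pairing(chains, pairing_state(), cfg)
  expect_identical(nrow(upd$bonds), 1L)
  expect_identical(unname(upd$bonds[1, ]), c(1L, 0L, 2L, 0L))  # A-B wins; C stays free
})

test_that("pairing kinetics respects p_unpair limits", {
  cfg <- quick_cfg(nodes_per_arm = 4, p_unpair = 0)
  x1 <- cbind(0:3, 0, 0)
  chains <- list(chain_state(x1, c(0L, 2L), 1L, 1L),
                 chain_state(x1 + rep(c(0, 0.4, 0), each = 4), c(0L, 2L), 1L, 2L))
  p <- update_pairing(chains, pairing_state(), cfg)
  expect_identical(nrow(p$bonds), 2L)
  set.seed(1)
  for (i in 1:50) {  # p_unpair = 0: bonds never break
    p <- update_pairing(chains, p, cfg)
    expect_identical(nrow(p$bonds), 2L)
  }
  # p_unpair = 1: every bond enters the formation phase free each iteration,
  # yet the endpoints remain near each other and immediately re-bond
  cfg$p_unpair <- 1
  p2 <- update_pairing(chains, p, cfg)
  expect_identical(attr(p2, "n_broken"), 2L)
  expect_identical(nrow(p2$bonds), 2L)
})

test_that("bond lifetimes are geometric with mean 1/p_unpair", {
  # hold two bonded buttons at a distance beyond the capture radius so the
  # bond cannot re-form; iterate the break phase and count survival times
  x1 <- cbind(0:3, 0, 0)
  chains <- list(chain_state(x1, 0L, 1L, 1L),
                 chain_state(x1 + rep(c(2, 0, 0), each = 4), 0L, 1L, 2L))
  set.seed(99)
  for (p in c(0.2, 0.8)) {
    cfg <- quick_cfg(nodes_per_arm = 4, p_unpair = p)
    n_trials <- 1500
    lifetimes <- vapply(seq_len(n_trials), function(i) {
      bond <- pairing_state(matrix(c(1L, 0L, 2L, 0L), 1))
      t <- 0L
      while (nrow(bond$bonds) > 0) {
        t <- t + 1L
        bond <- update_pairing(chains, bond, cfg)
      }
      t
    }, integer(1))
    mu <- 1 / p
    sem <- sqrt((1 - p) / p^2) / sqrt(n_trials)
    expect_lt(abs(mean(lifetimes) - mu), 3 * sem + 1e-9)
  }
})

test_that("one-to-one exclusivity holds under randomized clustered geometries", {
  cfg <- quick_cfg(nodes_per_arm = 10, p_unpair = 0.5)
  set.seed(7)
  for (rep in 1:30) {
    chains <- lapply(1:4, function(c) {
      # clustered positions so many candidate pairs fall within capture range
      x <- matrix(rnorm(30, sd = 0.8), 10, 3)
      chain_state(x, seq(0L, 8L, 2L), homolog_id = (c + 1L) %/% 2L, chain_id = c)
    })
    p <- pairing_state()
    for (it in 1:3) p <- update_pairing(chains, p, cfg)
    ends <- rbind(p$bonds[, 1:2], p$bonds[, 3:4])
    expect_identical(anyDuplicated(ends), 0L)
    # brute-force check: every bond formed was within capture at formation,
    # endpoints are declared buttons
    for (r in seq_len(nrow(p$bonds))) {
      expect_true(p$bonds[r, 2] %in% chains[[p$bonds[r, 1]]]$buttons)
      expect_true(p$bonds[r, 4] %in% chains[[p$bonds[r, 3]]]$buttons)
    }
  }
})

test_that("greedy matching agrees with a brute-force reference", {
  # independent oracle: recompute the greedy matching from scratch on the
  # distance list and compare bond sets (p_unpair = 0, single update)
  cfg <- quick_cfg(nodes_per_arm = 6, p_unpair = 0)
  set.seed(17)
  for (rep in 1:20) {
    chains <- lapply(1:4, function(c) {
      chain_state(matrix(rnorm(18, sd = 0.7), 6, 3), c(0L, 2L, 4L),
                  homolog_id = (c + 1L) %/% 2L, chain_id = c)
    })
    got <- update_pairing(chains, pairing_state(), cfg)$bonds
    # oracle
    tab <- do.call(rbind, lapply(chains, function(ch)
      cbind(ch$chain_id, ch$buttons)))
    pos <- do.call(rbind, lapply(chains, function(ch)
      ch$positions[ch$buttons + 1, ]))
    cand <- list()
    for (i in seq_len(nrow(tab) - 1)) {
      for (j in (i + 1):nrow(tab)) {
        d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
        if (d < cfg$capture_radius) cand[[length(cand) + 1]] <- c(d, i, j)
      }
    }
    exp_bonds <- matrix(integer(0), ncol = 4)
    if (length(cand) > 0) {
      cm <- do.call(rbind, cand)
      cm <- cm[order(cm[, 1], cm[, 2], cm[, 3]), , drop = FALSE]
      used <- rep(FALSE, nrow(tab))
      for (r in seq_len(nrow(cm))) {
        i <- cm[r, 2]; j <- cm[r, 3]
        if (!used[i] && !used[j]) {
          used[i] <- used[j] <- TRUE
          exp_bonds <- rbind(exp_bonds, c(tab[i, ], tab[j, ]))
        }
      }
    }
    o <- function(m) m[order(m[, 1], m[, 2]), , drop = FALSE]
    expect_equal(unname(o(got)), unname(o(matrix(as.integer(exp_bonds), ncol = 4))))
  }
})

test_that("cis bonds are permitted and counted", {
  cfg <- quick_cfg(nodes_per_arm = 6, p_unpair = 0)
  # fold one chain so its two buttons touch; keep the other pair far away
  x <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0.3, 0, 0), c(2, 5, 0), c(3, 5, 0))
  chains <- list(chain_state(x, c(0L, 3L), 1L, 1L),
                 chain_state(x + 50, c(0L, 3L), 1L, 2L),
                 chain_state(x - 50, c(0L, 3L), 2L, 3L),
                 chain_state(x + 100, c(0L, 3L), 2L, 4L))
  p <- update_pairing(chains, pairing_state(), cfg)
  cis <- p$bonds[p$bonds[, 1] == p$bonds[, 3], , drop = FALSE]
  expect_identical(nrow(cis), 4L)  # one cis bond per folded chain
})

test_that("pairing-bond forces are zero-rest-length Hookean pairs", {
  cfg <- quick_cfg(nodes_per_arm = 4)
  x <- cbind(0:3, 0, 0)
  chains <- list(chain_state(x, 0L, 1L, 1L),
                 chain_state(x, 0L, 1L, 2L))        # coincident buttons
  bonds <- pairing_state(matrix(c(1L, 0L, 2L, 0L), 1))
  f <- pairing_forces(chains, bonds, 50)
  expect_equal(f[[1]], matrix(0, 4, 3))
  chains[[2]]$positions[1, ] <- c(0, 1, 0)          # distance 1
  f <- pairing_forces(chains, bonds, 50)
  expect_equal(f[[1]][1, ], c(0, 50, 0))
  expect_equal(f[[2]][1, ], c(0, -50, 0))
  expect_equal(Reduce(`+`, lapply(f, colSums)), c(0, 0, 0))
})
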