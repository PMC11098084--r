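#' Backbone spring forces
#'
#' Hookean springs between adjacent nodes: for a bond of length `d` the force
#' has magnitude `k_spring * (d - rest_length)` along the bond, attractive when
#' stretched, equal and opposite on the two nodes, so the net force over the
#' chain is zero.
#'
#' @param chain a `chain_state` (or bare `n x 3` matrix).
#' @param k_spring spring constant.
#' @param rest_length rest bond length (> 0).
#' @return numeric `n x 3` matrix of per-node forces.
#' @export
spring_forces <- function(chain, k_spring, rest_length = 1) {
  x <- chain_positions(chain)
  if (nrow(x) < 2) stop("degenerate chain")
  if (rest_length <= 0) stop("rest_length must be > 0")
  n <- nrow(x)
  f <- matrix(0, n, 3)
  u <- x[-1, , drop = FALSE] - x[-n, , drop = FALSE]   # bond vectors i -> i+1
  d <- sqrt(rowSums(u^2))
  ok <- d > 0
  scale <- ifelse(ok, k_spring * (d - rest_length) / pmax(d, .Machine$double.eps), 0)
  fb <- u * scale                                       # force on node i (toward i+1 when stretched)
  f[-n, ] <- f[-n, , drop = FALSE] + fb
  f[-1, ] <- f[-1, , drop = FALSE] - fb
  f
}

#' Bending forces (worm-like-chain straightening)
#'
#' For each interior node `i`, a restoring force
#' `-k_bend * (x_i - midpoint(x_{i-1}, x_{i+1}))` is applied to node `i`, with
#' reaction `+k_bend * (x_i - midpoint)/2` on each neighbour; this is exactly
#' the negative gradient of the midpoint-deviation energy
#' `0.5 * k_bend * |x_i - midpoint|^2`, so internal forces sum to zero and the
#' chain is pushed toward a straight line.
#'
#' @inheritParams spring_forces
#' @param k_bend bending rigidity.
#' @return numeric `n x 3` matrix of per-node forces.
#' @export
bending_forces <- function(chain, k_bend) {
  x <- chain_positions(chain)
  n <- nrow(x)
  if (n < 2) stop("degenerate chain")
  f <- matrix(0, n, 3)
  if (n < 3 || k_bend == 0) return(f)
  i <- 2:(n - 1)
  v <- x[i, , drop = FALSE] -
    0.5 * (x[i - 1, , drop = FALSE] + x[i + 1, , drop = FALSE])
  f[i, ] <- f[i, , drop = FALSE] - k_bend * v
  f[i - 1, ] <- f[i - 1, , drop = FALSE] + 0.5 * k_bend * v
  f[i + 1, ] <- f[i + 1, , drop = FALSE] + 0.5 * k_bend * v
  f
}

#' Nuclear confinement forces
#'
#' Zero force for nodes inside the sphere of radius `nucleus_radius` centred at
#' the origin; an inward radial force of magnitude `k_confine * (|x| - R)` for
#' nodes outside.
#'
#' @param x numeric `n x 3` matrix of node positions (any chains concatenated).
#' @param nucleus_radius sphere radius.
#' @param k_confine penalty constant.
#' @return numeric `n x 3` matrix of per-node forces.
#' @export
confinement_forces <- function(x, nucleus_radius, k_confine) {
  x <- chain_positions(x)
  r <- sqrt(rowSums(x^2))
  f <- matrix(0, nrow(x), 3)
  out <- r > nucleus_radius
  if (any(out)) {
    mag <- k_confine * (r[out] - nucleus_radius) / r[out]
    f[out, ] <- -x[out, , drop = FALSE] * mag
  }
  f
}

# Internal: nearest point of the Rabl cap (spherical cap on the sphere of
# radius R centred at the origin, around the +z pole, with chord radius rp)
# for each row of x. Returns an n x 3 matrix.
nearest_cap_point <- function(x, nucleus_radius, rabl_patch_radius) {
  R <- nucleus_radius
  theta_c <- 2 * asin(min(rabl_patch_radius / (2 * R), 1))
  rho <- sqrt(x[, 1]^2 + x[, 2]^2)
  theta <- atan2(rho, x[, 3])
  tp <- pmin(theta, theta_c)
  # azimuth: preserve when defined, else arbitrary meridian (x-z plane)
  cx <- ifelse(rho > 0, x[, 1] / rho, 1)
  cy <- ifelse(rho > 0, x[, 2] / rho, 0)
  cbind(R * sin(tp) * cx, R * sin(tp) * cy, R * cos(tp))
}

#' Centromere tether (Rabl patch) forces
#'
#' Each centromere is pulled toward the nearest point of the envelope cap
#' centred on the +z pole with chord radius `rabl_patch_radius`:
#' `F = k_tether * (nearest cap point - x)`, zero when the centromere sits on
#' the cap. Setting `rabl_patch_radius = 2 * nucleus_radius` disables the
#' constraint entirely (no Rabl configuration).
#'
#' @param x numeric `n x 3` matrix of centromere positions.
#' @param nucleus_radius sphere radius.
#' @param rabl_patch_radius chord radius of the cap.
#' @param k_tether penalty constant.
#' @return numeric `n x 3` matrix of forces.
#' @export
tether_forces <- function(x, nucleus_radius, rabl_patch_radius, k_tether) {
  x <- chain_positions(x)
  if (rabl_patch_radius >= 2 * nucleus_radius) {
    return(matrix(0, nrow(x), 3))
  }
  p <- nearest_cap_point(x, nucleus_radius, rabl_patch_radius)
  k_tether * (p - x)
}

#' Pairing-bond forces
#'
#' Each bond is a zero-rest-length Hookean spring between the two bonded
#' buttons: `F = -k_pair * (x_a - x_b)` on endpoint a, equal and opposite on b.
#'
#' @param chains list of `chain_state` (indexed by chain id).
#' @param pairing a `pairing_state`.
#' @param k_pair bond spring constant.
#' @return list of `n x 3` force matrices, one per chain.
#' @export
pairing_forces <- function(chains, pairing, k_pair) {
  f <- lapply(chains, function(ch) matrix(0, nrow(ch$positions), 3))
  b <- pairing$bonds
  if (nrow(b) > 0) {
    for (r in seq_len(nrow(b))) {
      ca <- b[r, 1]; ia <- b[r, 2] + 1L
      cb <- b[r, 3]; ib <- b[r, 4] + 1L
      d <- chains[[ca]]$positions[ia, ] - chains[[cb]]$positions[ib, ]
      f[[ca]][ia, ] <- f[[ca]][ia, ] - k_pair * d
      f[[cb]][ib, ] <- f[[cb]][ib, ] + k_pair * d
    }
  }
  f
}

#' Total force on every node
#'
#' Sum of backbone spring, bending, confinement, tether and pairing-bond
#' forces; the negative gradient of [elastic_energy()].
#'
#' @param chains list of `chain_state`.
#' @param pairing a `pairing_state`.
#' @param cfg a `sim_config`.
#' @return list of `n x 3` force matrices, one per chain.
#' @export
total_forces <- function(chains, pairing, cfg) {
  f <- pairing_forces(chains, pairing, cfg$k_pair)
  for (i in seq_along(chains)) {
    ch <- chains[[i]]
    f[[i]] <- f[[i]] +
      spring_forces(ch, cfg$k_spring, cfg$rest_length) +
      bending_forces(ch, cfg$k_bend) +
      confinement_forces(ch$positions, cfg$nucleus_radius, cfg$k_confine)
    cent <- ch$centromere_index + 1L
    f[[i]][cent, ] <- f[[i]][cent, ] +
      tether_forces(ch$positions[cent, , drop = FALSE],
                    cfg$nucleus_radius, cfg$rabl_patch_radius, cfg$k_tether)
  }
  f
}

#' Total elastic energy of the system
#'
#' Sum of stretch (`0.5*k_spring*(d - rest)^2` per bond), bending
#' (`0.5*k_bend*|x_i - midpoint|^2` per interior node), pairing-bond
#' (`0.5*k_pair*d^2` per bond), confinement and tether penalty terms, in kBT
#' units. Zero for straight rest-length chains inside the nucleus with
#' centromeres on the Rabl cap and no strained bonds. Forces are the negative
#' gradient of this function.
#'
#' @param chains list of `chain_state`.
#' @param pairing a `pairing_state`.
#' @param cfg a `sim_config`.
#' @return nonnegative scalar energy.
#' @export
elastic_energy <- function(chains, pairing, cfg) {
  e <- 0
  for (ch in chains) {
    x <- ch$positions
    n <- nrow(x)
    u <- x[-1, , drop = FALSE] - x[-n, , drop = FALSE]
    d <- sqrt(rowSums(u^2))
    e <- e + 0.5 * cfg$k_spring * sum((d - cfg$rest_length)^2)
    if (n >= 3 && cfg$k_bend > 0) {
      i <- 2:(n - 1)
      v <- x[i, , drop = FALSE] -
        0.5 * (x[i - 1, , drop = FALSE] + x[i + 1, , drop = FALSE])
      e <- e + 0.5 * cfg$k_bend * sum(v^2)
    }
    r <- sqrt(rowSums(x^2))
    out <- r > cfg$nucleus_radius
    if (any(out)) {
      e <- e + 0.5 * cfg$k_confine * sum((r[out] - cfg$nucleus_radius)^2)
    }
    if (cfg$rabl_patch_radius < 2 * cfg$nucleus_radius) {
      cent <- x[ch$centromere_index + 1L, , drop = FALSE]
      p <- nearest_cap_point(cent, cfg$nucleus_radius, cfg$rabl_patch_radius)
      e <- e + 0.5 * cfg$k_tether * sum((p - cent)^2)
    }
  }
  b <- pairing$bonds
  if (nrow(b) > 0) {
    for (r in seq_len(nrow(b))) {
      d <- chains[[b[r, 1]]]$positions[b[r, 2] + 1L, ] -
        chains[[b[r, 3]]]$positions[b[r, 4] + 1L, ]
      e <- e + 0.5 * cfg$k_pair * sum(d^2)
    }
  }
  e
}

# Internal: accept either a chain_state or a bare matrix of positions.
chain_positions <- function(chain) {
  if (inherits(chain, "chain_state")) chain$positions else as.matrix(chain)
}
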