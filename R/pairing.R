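#' One iteration of reversible pairing kinetics
#'
#' Two phases per iteration, matching the engine's update order:
#'
#' * Break phase: every existing bond dissolves independently with probability
#'   `p_unpair` (one uniform draw per bond, in canonical bond order).
#' * Formation phase: over all unordered pairs of free buttons whose 3D
#'   distance is below `capture_radius` (any chains; cis pairs included),
#'   bonds are formed greedily in order of increasing distance, skipping pairs
#'   whose endpoints have already been taken; ties are broken by
#'   `(chain_id, button_index)` lexicographic order of the pair. There is no
#'   specificity of any kind: homologous and non-homologous buttons bond under
#'   identical rules. A pair that dissolves in the break phase re-enters the
#'   formation pool immediately: since the endpoints are still adjacent they
#'   usually re-bond at once, so unbinding only changes the configuration
#'   when a nearer free button is available -- the error-correction channel
#'   that makes reversibility essential.
#'
#' @param chains list of `chain_state` (list position == chain id).
#' @param pairing a `pairing_state`.
#' @param cfg a `sim_config` (uses `p_unpair`, `capture_radius`).
#' @param form if `FALSE`, run the break phase only (used to measure bond
#'   lifetimes).
#' @return updated `pairing_state`. The integer attribute `n_broken` records
#'   how many bonds dissolved in the break phase.
#' @export
update_pairing <- function(chains, pairing, cfg, form = TRUE) {
  b <- pairing$bonds
  n_broken <- 0L
  if (nrow(b) > 0) {
    broken <- stats::runif(nrow(b)) < cfg$p_unpair
    n_broken <- sum(broken)
    b <- b[!broken, , drop = FALSE]
  }
  if (form) {
    # global button table: chain, node, position
    tab <- do.call(rbind, lapply(chains, function(ch) {
      cbind(chain = ch$chain_id, node = ch$buttons)
    }))
    pos <- do.call(rbind, lapply(chains, function(ch) {
      ch$positions[ch$buttons + 1L, , drop = FALSE]
    }))
    key <- paste(tab[, 1], tab[, 2])
    taken <- key %in% c(paste(b[, 1], b[, 2]), paste(b[, 3], b[, 4]))
    free <- which(!taken)
    if (length(free) >= 2) {
      fp <- pos[free, , drop = FALSE]
      dm <- as.matrix(stats::dist(fp))
      cand <- which(upper.tri(dm) & dm < cfg$capture_radius, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        i1 <- free[cand[, 1]]; i2 <- free[cand[, 2]]
        # canonical endpoint order within each candidate pair
        swap <- tab[i1, 1] > tab[i2, 1] |
          (tab[i1, 1] == tab[i2, 1] & tab[i1, 2] > tab[i2, 2])
        a <- ifelse(swap, i2, i1); z <- ifelse(swap, i1, i2)
        d <- dm[cand]
        ord <- order(d, tab[a, 1], tab[a, 2], tab[z, 1], tab[z, 2])
        used <- rep(FALSE, nrow(tab))
        new_bonds <- list()
        for (r in ord) {
          if (!used[a[r]] && !used[z[r]]) {
            used[a[r]] <- TRUE; used[z[r]] <- TRUE
            new_bonds[[length(new_bonds) + 1L]] <-
              c(tab[a[r], 1], tab[a[r], 2], tab[z[r], 1], tab[z[r], 2])
          }
        }
        if (length(new_bonds) > 0) {
          b <- rbind(b, do.call(rbind, new_bonds))
        }
      }
    }
  }
  out <- pairing_state(b)
  attr(out, "n_broken") <- n_broken
  out
}
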