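#' Chain state
#'
#' One chromosome arm: an `n x 3` matrix of node coordinates, the centromere
#' node (node 0, stored as the first matrix row), the 0-based button indices
#' (its barcode), a homolog id shared by exactly two chains, and a unique
#' chain id.
#'
#' @param positions numeric `n x 3` matrix of node coordinates (length units).
#' @param buttons strictly increasing 0-based node indices that are adhesive.
#' @param homolog_id integer homolog-pair identifier.
#' @param chain_id unique integer chain identifier.
#' @param centromere_index 0-based index of the tethered node (default 0).
#' @return an object of class `chain_state`.
#' @export
chain_state <- function(positions, buttons, homolog_id, chain_id,
                        centromere_index = 0) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an n x 3 matrix")
  if (nrow(positions) < 2) stop("degenerate chain")
  buttons <- as.integer(buttons)
  if (any(buttons < 0L) || any(buttons >= nrow(positions))) {
    stop("button indices out of range")
  }
  if (is.unsorted(buttons, strictly = TRUE)) {
    stop("button indices must be strictly increasing")
  }
  structure(list(positions = positions,
                 buttons = buttons,
                 homolog_id = as.integer(homolog_id),
                 chain_id = as.integer(chain_id),
                 centromere_index = as.integer(centromere_index)),
            class = "chain_state")
}

#' @export
print.chain_state <- function(x, ...) {
  cat(sprintf("<chain_state> chain %d (homolog %d): %d nodes, %d buttons\n",
              x$chain_id, x$homolog_id, nrow(x$positions), length(x$buttons)))
  invisible(x)
}

#' Pairing state
#'
#' The current one-to-one bonds between buttons. Stored as an integer matrix
#' with columns `chain_a, node_a, chain_b, node_b` (chain ids as in the chain
#' list, node indices 0-based), one row per bond, each row canonicalised so
#' that `(chain_a, node_a) <= (chain_b, node_b)` lexicographically. Cis bonds
#' (same chain, different buttons) are permitted.
#'
#' @param bonds integer matrix with 4 columns (may have zero rows).
#' @return an object of class `pairing_state`.
#' @export
pairing_state <- function(bonds = matrix(integer(0), ncol = 4)) {
  bonds <- matrix(as.integer(bonds), ncol = 4,
                  dimnames = list(NULL, c("chain_a", "node_a", "chain_b", "node_b")))
  if (nrow(bonds) > 0) {
    swap <- bonds[, 1] > bonds[, 3] |
      (bonds[, 1] == bonds[, 3] & bonds[, 2] > bonds[, 4])
    bonds[swap, ] <- bonds[swap, c(3, 4, 1, 2)]
    ends <- rbind(bonds[, 1:2], bonds[, 3:4])
    if (anyDuplicated(ends)) {
      stop("a button endpoint appears in more than one bond")
    }
    if (any(bonds[, 1] == bonds[, 3] & bonds[, 2] == bonds[, 4])) {
      stop("a bond cannot join a button to itself")
    }
  }
  structure(list(bonds = bonds), class = "pairing_state")
}

#' @export
print.pairing_state <- function(x, ...) {
  cat(sprintf("<pairing_state> %d bond(s)\n", nrow(x$bonds)))
  invisible(x)
}

#' Validate a chain list against a configuration
#'
#' Checks bookkeeping invariants: every chain has `nodes_per_arm` nodes, every
#' homolog id is carried by exactly two chains, and chain ids are unique.
#'
#' @param chains list of `chain_state`.
#' @param cfg a `sim_config`.
#' @return `chains`, invisibly.
#' @export
validate_chains <- function(chains, cfg) {
  stopifnot(all(vapply(chains, inherits, logical(1), "chain_state")))
  n <- vapply(chains, function(ch) nrow(ch$positions), integer(1))
  if (any(n != cfg$nodes_per_arm)) stop("chain length mismatch with config")
  ids <- vapply(chains, `[[`, integer(1), "chain_id")
  if (anyDuplicated(ids)) stop("chain ids must be unique")
  hom <- vapply(chains, `[[`, integer(1), "homolog_id")
  if (any(table(hom) != 2)) stop("each homolog_id must be carried by exactly two chains")
  invisible(chains)
}

# Internal: partner chain id of chain `cid` (the other chain sharing its
# homolog id).
homolog_partner <- function(chains, cid) {
  hom <- vapply(chains, `[[`, integer(1), "homolog_id")
  ids <- vapply(chains, `[[`, integer(1), "chain_id")
  h <- hom[ids == cid]
  ids[hom == h & ids != cid]
}
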