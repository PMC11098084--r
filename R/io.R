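#' Write a trajectory as CSV
#'
#' One row per node per recorded frame with columns `step, chain_id,
#' node_index, x, y, z, is_button, partner_chain, partner_button`; the partner
#' fields are empty when the node is not a bonded button. Node indices are
#' 0-based. [read_trajectory_csv()] reads the format back for analysis.
#'
#' @param traj a `cp_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  n <- traj$config$nodes_per_arm
  n_chains <- nrow(traj$chain_meta)
  rows <- lapply(seq_along(traj$frames), function(f) {
    fr <- traj$frames[[f]]
    df <- data.frame(
      step = fr$step,
      chain_id = rep(traj$chain_meta$chain_id, each = n),
      node_index = rep(0:(n - 1), times = n_chains),
      x = fr$pos[, 1], y = fr$pos[, 2], z = fr$pos[, 3],
      is_button = FALSE,
      partner_chain = NA_integer_,
      partner_button = NA_integer_
    )
    for (c in seq_len(n_chains)) {
      df$is_button[(c - 1) * n + traj$buttons[[c]] + 1L] <- TRUE
    }
    b <- fr$bonds
    if (!is.null(b) && nrow(b) > 0) {
      for (r in seq_len(nrow(b))) {
        ia <- (b[r, 1] - 1L) * n + b[r, 2] + 1L
        ib <- (b[r, 3] - 1L) * n + b[r, 4] + 1L
        df$partner_chain[ia] <- b[r, 3]; df$partner_button[ia] <- b[r, 4]
        df$partner_chain[ib] <- b[r, 1]; df$partner_button[ib] <- b[r, 2]
      }
    }
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trajectory CSV
#'
#' Reconstructs a `cp_trajectory` from a file written by
#' [write_trajectory_csv()]. Homolog identities are recovered from the
#' supplied config convention (consecutive chain pairs) unless `chain_meta`
#' is given.
#'
#' @param path CSV path.
#' @param cfg optional `sim_config` describing the run; inferred dimensions
#'   are used if omitted.
#' @return a `cp_trajectory`.
#' @export
read_trajectory_csv <- function(path, cfg = NULL) {
  df <- utils::read.csv(path)
  n <- max(df$node_index) + 1L
  chain_ids <- sort(unique(df$chain_id))
  n_chains <- length(chain_ids)
  if (is.null(cfg)) {
    cfg <- sim_config(n_pairs = n_chains %/% 2L, nodes_per_arm = n,
                      n_steps = max(df$step),
                      record_every = max(1L, as.integer(diff(sort(unique(df$step)))[1])))
  }
  steps <- sort(unique(df$step))
  df <- df[order(df$step, df$chain_id, df$node_index), ]
  buttons <- lapply(chain_ids, function(c) {
    sub <- df[df$step == steps[1] & df$chain_id == c, ]
    sub$node_index[sub$is_button %in% c(TRUE, "TRUE", "True")]
  })
  frames <- lapply(steps, function(s) {
    sub <- df[df$step == s, ]
    pos <- as.matrix(sub[, c("x", "y", "z")])
    bonded <- sub[!is.na(sub$partner_chain), , drop = FALSE]
    bonds <- if (nrow(bonded) > 0) {
      b <- cbind(bonded$chain_id, bonded$node_index,
                 bonded$partner_chain, bonded$partner_button)
      keep <- b[, 1] < b[, 3] | (b[, 1] == b[, 3] & b[, 2] < b[, 4])
      matrix(as.integer(b[keep, , drop = FALSE]), ncol = 4)
    } else matrix(integer(0), ncol = 4)
    list(step = s, pos = pos, bonds = bonds)
  })
  structure(list(
    config = cfg,
    chain_meta = data.frame(chain_id = chain_ids,
                            homolog_id = rep(seq_len(n_chains %/% 2L), each = 2)),
    buttons = buttons,
    steps = steps,
    frames = frames
  ), class = "cp_trajectory")
}

#' Write a multi-frame XYZ file for molecular viewers
#'
#' Each recorded frame becomes one XYZ block; buttons are labelled `B` and
#' plain nodes `C`, so viewers can colour adhesive sites differently.
#'
#' @param traj a `cp_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  n <- traj$config$nodes_per_arm
  n_chains <- nrow(traj$chain_meta)
  elem <- rep("C", n * n_chains)
  for (c in seq_len(n_chains)) {
    elem[(c - 1) * n + traj$buttons[[c]] + 1L] <- "B"
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in traj$frames) {
    writeLines(as.character(n * n_chains), con)
    writeLines(sprintf("step %d", fr$step), con)
    writeLines(sprintf("%s %.5f %.5f %.5f", elem,
                       fr$pos[, 1], fr$pos[, 2], fr$pos[, 3]), con)
  }
  invisible(path)
}

#' Write a kymograph matrix as CSV
#'
#' @param km matrix from [kymograph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kymograph_csv <- function(km, path) {
  df <- as.data.frame(km)
  names(df) <- paste0("step_", attr(km, "steps"))
  utils::write.csv(cbind(node = 0:(nrow(km) - 1), df), path, row.names = FALSE)
  invisible(path)
}
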