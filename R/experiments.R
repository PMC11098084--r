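# Preset scenario runner: each figure-level experiment is a named registry of
# conditions (a config + a barcode layout per condition), run as seeded
# ensembles with per-run metrics, an ensemble summary, and a figure-style
# plot.

# Internal: evaluate expr with a temporary RNG seed, restoring the caller's
# RNG state afterwards. Used for the fixed-seed preset barcodes.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Preset reference barcode patches
#'
#' The short five-button centromere-proximal patch codes used by the shift,
#' constrained-random and translocation scenarios: five buttons within the
#' 12-node patch at the centromeric end of the arm (nodes 0--11), so the
#' whole patch can be shifted distally by up to 12 nodes. They are generated
#' from fixed, documented seeds (`"primary"` = 101, `"secondary"` = 102) so
#' each preset is a stable named fixture.
#'
#' @param which `"primary"` or `"secondary"`.
#' @param arm_length nodes per arm (default 28).
#' @return a `barcode`.
#' @export
reference_patch_code <- function(which = c("primary", "secondary"),
                                 arm_length = 28) {
  which <- match.arg(which)
  seed <- switch(which, primary = 101, secondary = 102)
  with_seed(seed, random_barcode(5, c(0, 11), arm_length))
}

# Internal: the preset whole-arm random five-button codes shared by the fig4
# and fig7 scenarios (code i comes from seed 1500 + i), so the two-pair fig7
# condition is exactly the first fig4 five-button condition.
preset_five_button_code <- function(i, arm_length) {
  with_seed(1500 + i, random_barcode(5, c(0, arm_length - 1), arm_length))
}

#' Available scenario names
#'
#' @return character vector of registered scenario names.
#' @export
list_scenarios <- function() {
  c("fig2", "fig3b", "fig3c", "fig3d", "fig4", "fig5a", "fig5b",
    "fig6", "fig7", "fig8d", "fig8e")
}

# Internal: condition list for a scenario. Each condition is
# list(label, x (numeric or NA), cfg, barcodes, calibrate (logical)).
scenario_conditions <- function(name, cfg) {
  arm <- cfg$nodes_per_arm
  tract <- function(spacing, start) {
    barcode(start + spacing * (0:4), arm, min_gap = 2)
  }
  switch(
    name,
    fig3b = {
      grid <- c(0, 2, 5, 10, 20, 40, 70)
      mid <- arm %/% 2
      conds <- list()
      for (kb in grid) {
        cfg_k <- cfg; cfg_k$k_bend <- kb
        # aligned: both five-button tracts centred on the same mid-arm node
        conds[[length(conds) + 1]] <- list(
          label = sprintf("aligned_kbend_%g", kb), x = kb, cfg = cfg_k,
          group = "aligned", calibrate = TRUE,
          barcodes = list(tract(3, mid - 6), tract(4, mid - 8)))
        # offset: tract starts 11 nodes apart (centromere- vs telomere-proximal)
        conds[[length(conds) + 1]] <- list(
          label = sprintf("offset_kbend_%g", kb), x = kb, cfg = cfg_k,
          group = "offset", calibrate = TRUE,
          barcodes = list(tract(4, 0), tract(3, 11)))
      }
      conds
    },
    fig3c = {
      lapply(c(0, 0.2, 0.4, 0.6, 0.8, 1.0), function(p) {
        cfg_p <- cfg; cfg_p$p_unpair <- p
        list(label = sprintf("p_unpair_%g", p), x = p, cfg = cfg_p,
             group = "scan", calibrate = FALSE,
             barcodes = list(uniform_barcode(3, arm), uniform_barcode(4, arm)))
      })
    },
    fig3d = {
      lapply(c(3, 6, 9, 12, 16, 24), function(rp) {
        cfg_r <- cfg; cfg_r$rabl_patch_radius <- rp
        list(label = sprintf("rabl_radius_%g", rp), x = rp, cfg = cfg_r,
             group = "scan", calibrate = TRUE,
             barcodes = list(uniform_barcode(3, arm), uniform_barcode(4, arm)))
      })
    },
    fig4 = {
      conds <- list()
      for (nb in c(5, 8, 13)) {
        for (j in 1:2) {
          if (nb == 5) {
            bc1 <- preset_five_button_code(2 * j - 1, arm)
            bc2 <- preset_five_button_code(2 * j, arm)
          } else {
            bc1 <- with_seed(1000 + 100 * nb + 2 * j - 1,
                             random_barcode(nb, c(0, arm - 1), arm))
            bc2 <- with_seed(1000 + 100 * nb + 2 * j,
                             random_barcode(nb, c(0, arm - 1), arm))
          }
          conds[[length(conds) + 1]] <- list(
            label = sprintf("random_%db_%d", nb, j), x = nb, cfg = cfg,
            group = sprintf("%d buttons", nb), calibrate = FALSE,
            barcodes = list(bc1, bc2))
        }
      }
      conds
    },
    fig5a = {
      ref <- reference_patch_code("primary", arm)
      alt <- reference_patch_code("secondary", arm)
      lapply(seq(0, 12, by = 2), function(off) {
        list(label = sprintf("shift_%d", off), x = off, cfg = cfg,
             group = "shift", calibrate = FALSE,
             barcodes = list(shift_barcode(ref, off), shift_barcode(alt, off)))
      })
    },
    fig5b = {
      ref <- reference_patch_code("primary", arm)
      alt <- reference_patch_code("secondary", arm)
      conds <- list(list(label = "reference", x = 0, cfg = cfg,
                         group = "reference", calibrate = FALSE,
                         barcodes = list(ref, alt)))
      for (j in 1:5) {
        bc1 <- with_seed(200 + 2 * j - 1, random_barcode(5, c(0, 12), arm))
        bc2 <- with_seed(200 + 2 * j, random_barcode(5, c(0, 12), arm))
        conds[[length(conds) + 1]] <- list(
          label = sprintf("constrained_%d", j), x = j, cfg = cfg,
          group = "constrained", calibrate = FALSE,
          barcodes = list(bc1, bc2))
      }
      conds
    },
    fig6 = {
      digit_pair <- function(d1, d2) {
        list(gaps_to_barcode(encode_2of5(d1), arm),
             gaps_to_barcode(encode_2of5(d2), arm))
      }
      conds <- list(
        list(label = "2of5_0v1", x = NA, cfg = cfg, group = "2of5",
             calibrate = FALSE, barcodes = digit_pair(0, 1)),
        list(label = "2of5_3v7", x = NA, cfg = cfg, group = "2of5",
             calibrate = FALSE, barcodes = digit_pair(3, 7)),
        list(label = "2of5_4v8", x = NA, cfg = cfg, group = "2of5",
             calibrate = FALSE, barcodes = digit_pair(4, 8)))
      for (j in 1:3) {
        bc1 <- with_seed(300 + 2 * j - 1,
                         random_barcode(6, c(0, 18), arm, fix_endpoints = TRUE))
        bc2 <- with_seed(300 + 2 * j,
                         random_barcode(6, c(0, 18), arm, fix_endpoints = TRUE))
        conds[[length(conds) + 1]] <- list(
          label = sprintf("random_sameends_%d", j), x = NA, cfg = cfg,
          group = "random", calibrate = FALSE, barcodes = list(bc1, bc2))
      }
      conds
    },
    fig7 = {
      codes <- lapply(1:10, function(i) preset_five_button_code(i, arm))
      lapply(c(2, 3, 4, 5, 6, 8, 10), function(np) {
        cfg_n <- cfg; cfg_n$n_pairs <- as.integer(np)
        list(label = sprintf("pairs_%d", np), x = np, cfg = cfg_n,
             group = "scan", calibrate = FALSE, barcodes = codes[seq_len(np)])
      })
    },
    fig8d = {
      ref <- reference_patch_code("primary", arm)
      alt <- reference_patch_code("secondary", arm)
      shifted <- shift_barcode(ref, 12)
      list(
        list(label = "wildtype", x = NA, cfg = cfg, group = "fig8d",
             calibrate = FALSE, barcodes = list(ref, alt)),
        list(label = "heterozygous_shift12", x = NA, cfg = cfg, group = "fig8d",
             calibrate = FALSE, barcodes = list(list(ref, shifted), alt)),
        list(label = "homozygous_shift12", x = NA, cfg = cfg, group = "fig8d",
             calibrate = FALSE, barcodes = list(shifted, alt)))
    },
    fig8e = {
      pa <- reference_patch_code("primary", arm)
      pb <- reference_patch_code("secondary", arm)
      conds <- list(list(label = "wildtype", x = NA, cfg = cfg, group = "fig8e",
                         calibrate = FALSE, barcodes = list(pa, pb)))
      quarters <- list(c(0, 2), c(3, 5), c(6, 8), c(9, 11))
      for (q in seq_along(quarters)) {
        tr <- reciprocal_translocation(pa, pb, quarters[[q]], quarters[[q]])
        conds[[length(conds) + 1]] <- list(
          label = sprintf("quarter_%d", q), x = q, cfg = cfg, group = "fig8e",
          calibrate = FALSE, barcodes = list(tr$a, tr$b))
      }
      full <- reciprocal_translocation(pa, pb, c(0, 11), c(0, 11))
      conds[[length(conds) + 1]] <- list(
        label = "full_patch", x = NA, cfg = cfg, group = "fig8e",
        calibrate = FALSE, barcodes = list(full$a, full$b))
      conds
    },
    stop("unknown scenario '", name, "'; available: ",
         paste(list_scenarios(), collapse = ", "))
  )
}

#' Run a preset figure scenario
#'
#' Runs the registered ensemble experiment for `name` (see
#' [list_scenarios()]), with per-run seeds `base_seed + run index`. Overrides
#' may rescale the run (`n_steps`, `record_every`, any `sim_config` field).
#' When `out_dir` is given, per-run metrics, the ensemble summary and a
#' figure-style plot (fidelity curve for numeric scans, box/beeswarm
#' otherwise) are written there.
#'
#' `fig2` is special-cased as the single representative run: it writes the
#' trajectory CSV, an XYZ export and the kymograph (CSV and PNG) and returns
#' the trajectory and metrics report.
#'
#' @param name scenario name.
#' @param overrides named list of `sim_config` fields to override.
#' @param n_runs runs per condition (default 30).
#' @param base_seed seed for run 1; run i uses `base_seed + i - 1`.
#' @param out_dir optional output directory.
#' @param fidelity_mode which fidelity convention the scenario's `fidelity`
#'   column uses. The default follows each figure's wording: `"chromosome"`
#'   (fraction of buttons bonded to any button of the correct homolog) for
#'   all scenarios except the multi-chromosome scan `fig7`, which counts
#'   buttons paired to the corresponding (same-index) button (`"locus"`).
#' @return a `cp_scenario` list: `name`, `results` (per-run rows), `summary`
#'   (per-condition mean/SEM/median), `calibration` (if applicable), `plot`.
#' @export
run_scenario <- function(name, overrides = list(), n_runs = 30,
                         base_seed = 1, out_dir = NULL,
                         fidelity_mode = if (name == "fig7") "locus" else "chromosome") {
  if (!name %in% list_scenarios()) {
    stop("unknown scenario '", name, "'; available: ",
         paste(list_scenarios(), collapse = ", "))
  }
  base_cfg <- do.call(sim_config, overrides)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  if (name == "fig2") {
    cfg <- base_cfg; cfg$seed <- as.integer(base_seed)
    traj <- run_simulation(cfg)  # default 3- vs 4-node uniform layout
    rep <- metrics_report(traj)
    km <- rep$kymograph
    if (!is.null(out_dir)) {
      write_trajectory_csv(traj, file.path(out_dir, "fig2_trajectory.csv"))
      write_xyz(traj, file.path(out_dir, "fig2_trajectory.xyz"))
      write_kymograph_csv(km, file.path(out_dir, "fig2_kymograph.csv"))
      ggplot2::ggsave(file.path(out_dir, "fig2_kymograph.png"),
                      plot_kymograph(km), width = 7, height = 4, dpi = 150)
      write_metrics_json(rep, file.path(out_dir, "fig2_metrics.json"))
    }
    return(structure(list(name = name, trajectory = traj, report = rep,
                          plot = plot_kymograph(km)),
                     class = "cp_scenario"))
  }

  conds <- scenario_conditions(name, base_cfg)
  results <- list()
  calib <- list()
  for (cond in conds) {
    message(sprintf("[%s] condition %s (%d runs)", name, cond$label, n_runs))
    ens <- run_ensemble(cond$cfg, cond$barcodes, n_runs = n_runs,
                        base_seed = base_seed)
    ens$label <- cond$label
    ens$group <- cond$group
    ens$x <- cond$x
    ens$fidelity <- if (fidelity_mode == "locus") ens$fidelity_locus else ens$fidelity_chromosome
    results[[length(results) + 1]] <- ens
    if (isTRUE(cond$calibrate)) {
      cfg_cal <- cond$cfg; cfg_cal$seed <- as.integer(base_seed + 90000L)
      cal <- run_simulation(cfg_cal, cond$barcodes, pairing_enabled = FALSE)
      calib[[cond$label]] <- c(
        rabl_correlation = rabl_correlation(cal),
        persistence_length = suppressWarnings(
          as.numeric(estimate_persistence_length(cal))))
    }
  }
  results <- do.call(rbind, results)
  summary <- do.call(rbind, lapply(split(results, results$label), function(d) {
    data.frame(label = d$label[1], group = d$group[1], x = d$x[1],
               n = nrow(d),
               mean_fidelity = mean(d$fidelity),
               sem_fidelity = stats::sd(d$fidelity) / sqrt(nrow(d)),
               median_fidelity = stats::median(d$fidelity),
               min_fidelity = min(d$fidelity),
               mean_trans_incorrect = mean(d$trans_incorrect))
  }))
  summary <- summary[order(match(summary$label, vapply(conds, `[[`, "", "label"))), ]
  rownames(summary) <- NULL

  plt <- if (all(!is.na(results$x)) && length(unique(results$x)) > 2 &&
             length(unique(results$group)) == 1) {
    plot_fidelity_curve(results, xlab = name)
  } else {
    plot_fidelity_swarm(results)
  }

  if (!is.null(out_dir)) {
    utils::write.csv(results, file.path(out_dir, paste0(name, "_runs.csv")),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, paste0(name, "_summary.csv")),
                     row.names = FALSE)
    if (length(calib) > 0) {
      utils::write.csv(
        data.frame(label = names(calib), do.call(rbind, calib)),
        file.path(out_dir, paste0(name, "_calibration.csv")),
        row.names = FALSE)
    }
    ggplot2::ggsave(file.path(out_dir, paste0(name, "_plot.png")), plt,
                    width = 7, height = 4.5, dpi = 150)
  }

  structure(list(name = name, results = results, summary = summary,
                 calibration = calib, plot = plt),
            class = "cp_scenario")
}

#' @export
print.cp_scenario <- function(x, ...) {
  cat(sprintf("<cp_scenario> %s\n", x$name))
  if (!is.null(x$summary)) print(x$summary, digits = 3)
  invisible(x)
}
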