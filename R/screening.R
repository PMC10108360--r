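#' Trim the equilibration prefix from a trajectory
#'
#' Drops every frame closer than `trim_time` to the first frame time, so all
#' statistics are computed on the equilibrated span only. The discarded and
#' analyzed spans are reported (frames x time-per-frame).
#'
#' @param traj A [trajectory()].
#' @param trim_time Duration to discard from the start, ps.
#' @return List with `trajectory` (trimmed), `total_span`, `discarded_span`,
#'   `analyzed_span` (ps).
#' @export
trim_equilibration <- function(traj, trim_time = 0) {
  times <- frame_times(traj)
  dt <- if (length(times) > 1L) stats::median(diff(times)) else 0
  total <- length(times) * dt
  keep <- times - times[1L] >= trim_time
  if (!any(keep)) {
    stop("empty analyzed span: trim_time removes every frame", call. = FALSE)
  }
  trimmed <- trajectory(traj$atoms, traj$frames[keep])
  list(trajectory = trimmed, total_span = total,
       discarded_span = sum(!keep) * dt, analyzed_span = sum(keep) * dt)
}

default_screening_config <- function() {
  list(
    trim_time = 0,
    theta_bin = 5, depth_bin = 0.05,
    theta_ok = 60, depth_ok = 1.4, theta_bad = 120, depth_bad = 1.2,
    density_bin = 0.1,
    hbond_r_da_max = 0.35, hbond_angle_max = 30,
    sasa_probe = 0.14, sasa_dots = 960L, sasa_stride = 5L,
    cluster_cutoff = 0.4,
    n_blocks = 5L,
    plots = FALSE
  )
}

#' Run the full membrane-orientation screening pipeline
#'
#' Executes, per candidate, the fixed stage order orientation -> density ->
#' hydrogen bonds -> SASA -> clusters on the equilibration-trimmed
#' trajectory, classifies the candidate's orientation against the
#' correct/incorrect reference populations, and writes a machine-readable
#' JSON report plus CSV tables (and optionally plots). Every threshold,
#' cutoff, bin width and seed is echoed into the report so any number in it
#' can be regenerated from the inputs plus the echo. A stage failing for one
#' candidate is recorded as an error in the report; the remaining stages and
#' candidates still run.
#'
#' @param config Either a named list or a path to a YAML file. Recognized
#'   keys: `scenario` (a scenario name from [reference_scenarios()] or a
#'   list of [scenario_config()] overrides), or `gro` + `ndx` (+ optional
#'   `ligand` spec list) for file input; analysis keys `trim_time` (ps),
#'   `theta_bin`, `depth_bin`, `theta_ok`, `depth_ok`, `theta_bad`,
#'   `depth_bad`, `density_bin`, `hbond_r_da_max`, `hbond_angle_max`,
#'   `sasa_probe`, `sasa_dots`, `sasa_stride`, `cluster_cutoff`, `n_blocks`,
#'   `seed`, `plots`.
#' @param outdir Output directory for the report and artifacts; `NULL`
#'   computes the report without writing files.
#' @return The screening report (list), invisibly when `outdir` is given.
#'   `report$candidates[[name]]$verdict$label` is the authoritative
#'   machine-readable outcome.
#' @export
run_screening <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_screening_config(), config)

  if (!is.null(cfg$scenario)) {
    seed <- if (!is.null(cfg$seed)) cfg$seed else 1L
    scen_cfg <- if (is.character(cfg$scenario)) {
      nf <- if (is.null(cfg$n_frames)) 200L else cfg$n_frames
      ref <- reference_scenarios(n_frames = nf, seed = seed)
      if (!cfg$scenario %in% names(ref)) {
        stop("unknown reference scenario: ", cfg$scenario, call. = FALSE)
      }
      ref[[cfg$scenario]]
    } else {
      do.call(scenario_config, c(cfg$scenario, list(seed = seed)))
    }
    scen <- generate_scenario(scen_cfg)
    candidate_name <- if (is.character(cfg$scenario)) cfg$scenario else
      scen$spec$resname
    traj <- scen$trajectory
    groups <- scen$groups
    spec <- scen$spec
  } else if (!is.null(cfg$gro)) {
    traj <- read_gro(cfg$gro)
    groups <- read_index_groups(cfg$ndx, traj$atoms)
    if (is.null(cfg$ligand)) {
      stop("file input needs a 'ligand' spec definition", call. = FALSE)
    }
    spec <- do.call(ligand_spec, cfg$ligand)
    candidate_name <- spec$resname
  } else {
    stop("config must name a 'scenario' or provide 'gro'/'ndx' paths",
         call. = FALSE)
  }

  tr <- trim_equilibration(traj, cfg$trim_time)
  traj <- tr$trajectory
  crit <- hbond_criterion(cfg$hbond_r_da_max, cfg$hbond_angle_max)
  sset <- sasa_settings(cfg$sasa_probe, cfg$sasa_dots)

  cand <- list(errors = list())
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cand$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  # orientation
  orient <- run_stage("orientation", {
    samples <- orientation_samples(traj, spec, groups$lipids)
    hm <- accumulate_heatmap(samples, cfg$theta_bin, cfg$depth_bin)
    list(heatmap = hm,
         verdict = classify_orientation(hm, cfg$theta_ok, cfg$depth_ok,
                                        cfg$theta_bad, cfg$depth_bad))
  })
  hm <- orient$heatmap
  cand$verdict <- orient$verdict

  # density + interface
  dens <- run_stage("density", {
    prof <- list(
      lipid = partial_density(traj, groups$lipids, cfg$density_bin,
                              groups$lipids, label = "lipid"),
      water = partial_density(traj, groups$water, cfg$density_bin,
                              groups$lipids, label = "water"))
    lig_idx <- unlist(lapply(seq_len(spec$n_copies), function(k) {
      resolve_ligand_atoms(traj$atoms, spec, k, "all")
    }), use.names = FALSE)
    prof$ligand <- partial_density(traj, lig_idx, cfg$density_bin,
                                   groups$lipids, label = "ligand")
    if (!is.null(spec$oh_group)) {
      oh_idx <- unlist(lapply(seq_len(spec$n_copies), function(k) {
        resolve_ligand_atoms(traj$atoms, spec, k, "oh")
      }), use.names = FALSE)
      prof$oh <- partial_density(traj, oh_idx, cfg$density_bin,
                                 groups$lipids, label = "oh")
    }
    interface <- tryCatch(locate_interface(prof$water, prof$lipid),
                          error = function(e) NULL)
    list(profiles = prof, interface = interface)
  })

  # hydrogen bonds (Table-1-style)
  hb <- run_stage("hbonds", {
    combos <- expand.grid(group = c("oh", "oono"),
                          partner = c("water", "lipid"),
                          stringsAsFactors = FALSE)
    if (is.null(spec$oh_group)) combos <- combos[combos$group != "oh", ]
    out <- list()
    for (i in seq_len(nrow(combos))) {
      key <- paste(combos$group[i], combos$partner[i], sep = "_")
      out[[key]] <- hbond_block_stats(
        traj, spec, combos$group[i], combos$partner[i],
        water_group = groups$water, lipid_group = groups$lipids,
        crit = crit, n_blocks = cfg$n_blocks)
    }
    out
  })

  # SASA (Table-2-style)
  sasa <- run_stage("sasa", {
    out <- list()
    for (g in c("oh", "oono")) {
      if (g == "oh" && is.null(spec$oh_group)) next
      out[[g]] <- group_sasa_block_stats(traj, spec, g, sset,
                                         n_blocks = cfg$n_blocks,
                                         stride = cfg$sasa_stride)
    }
    out
  })

  # clusters
  clusters <- run_stage("clusters", {
    cluster_timeseries(traj, spec, cfg$cluster_cutoff)
  })

  cand$heatmap <- hm
  cand$density <- dens
  cand$hbonds <- hb
  cand$sasa <- sasa
  cand$clusters <- clusters

  report <- list(
    candidates = stats::setNames(list(cand), candidate_name),
    spans = tr[c("total_span", "discarded_span", "analyzed_span")],
    config_echo = cfg
  )
  class(report) <- "screening_report"

  if (!is.null(outdir)) {
    write_screening_report(report, outdir)
    return(invisible(report))
  }
  report
}

block_row <- function(ba) {
  if (is.null(ba)) return(NULL)
  list(mean = ba$grand_mean, sd = ba$sd, n_blocks = ba$n_blocks,
       block_length = ba$block_length)
}

#' Write a screening report to disk
#'
#' Emits `report.json` (machine-readable, authoritative), `report.txt`
#' (human-readable summary) and per-candidate CSV artifacts (heat map,
#' density profiles, cluster time series), plus PNG plots when the config
#' echo requests them.
#'
#' @param report A `screening_report` from [run_screening()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_screening_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  json <- list(spans = report$spans,
               config_echo = report$config_echo[
                 !vapply(report$config_echo, is.list, logical(1))],
               candidates = list())
  txt <- c("membscreen screening report", "===========================", "")
  txt <- c(txt, sprintf(
    "trajectory span: %.0f ps total, %.0f ps discarded (equilibration), %.0f ps analyzed",
    report$spans$total_span, report$spans$discarded_span,
    report$spans$analyzed_span), "")
  for (nm in names(report$candidates)) {
    cand <- report$candidates[[nm]]
    entry <- list()
    if (!is.null(cand$verdict)) {
      v <- cand$verdict
      entry$verdict <- list(
        label = v$label, mode_theta = v$mode_theta,
        mode_depth = v$mode_depth,
        secondary_population_fraction = v$secondary_population_fraction,
        thresholds = as.list(v$thresholds))
      txt <- c(txt, sprintf(
        "%s: %s (mode theta %.1f deg, mode depth %.2f nm, secondary %.1f%%)",
        nm, toupper(v$label), v$mode_theta, v$mode_depth,
        100 * v$secondary_population_fraction))
    }
    entry$hbonds <- lapply(cand$hbonds, block_row)
    entry$sasa <- lapply(cand$sasa, block_row)
    if (!is.null(cand$clusters)) {
      entry$clusters <- cand$clusters[c("clustered_frame_fraction",
                                        "mean_largest_cluster_size")]
    }
    if (!is.null(cand$density$interface)) {
      entry$interface <- as.list(cand$density$interface)
    }
    entry$errors <- cand$errors
    json$candidates[[nm]] <- entry

    if (!is.null(cand$heatmap)) {
      heatmap_table(cand$heatmap,
                    file.path(outdir, paste0(nm, "_heatmap.csv")))
      entry_path <- file.path(outdir, paste0(nm, "_heatmap.png"))
      if (isTRUE(report$config_echo$plots)) {
        ggplot2::ggsave(entry_path, plot_heatmap(cand$heatmap),
                        width = 6, height = 4, dpi = 120)
      }
    }
    if (!is.null(cand$density)) {
      density_table(cand$density$profiles,
                    file.path(outdir, paste0(nm, "_density.csv")))
      if (isTRUE(report$config_echo$plots)) {
        ggplot2::ggsave(file.path(outdir, paste0(nm, "_density.png")),
                        plot_density_profiles(cand$density$profiles,
                                              cand$density$interface),
                        width = 6, height = 4, dpi = 120)
      }
    }
    if (!is.null(cand$clusters)) {
      utils::write.csv(cand$clusters$timeseries,
                       file.path(outdir, paste0(nm, "_clusters.csv")),
                       row.names = FALSE)
    }
    for (err in names(cand$errors)) {
      txt <- c(txt, sprintf("  [stage error] %s: %s", err,
                            cand$errors[[err]]))
    }
  }
  jsonlite::write_json(json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(txt, file.path(outdir, "report.txt"))
  invisible(outdir)
}

#' @export
print.screening_report <- function(x, ...) {
  for (nm in names(x$candidates)) {
    v <- x$candidates[[nm]]$verdict
    if (!is.null(v)) {
      cat(nm, ": ", v$label, "\n", sep = "")
    } else {
      cat(nm, ": orientation stage failed\n", sep = "")
    }
  }
  invisible(x)
}
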