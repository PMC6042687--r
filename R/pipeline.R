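# Pipeline orchestration: simulate -> segment -> measure -> report as
# file-based stages, so any stage can be re-run or audited on its own and a
# fixed (config, seed) reproduces every output byte-for-byte.

#' Simulate stage: write synthetic cells with ground truth
#'
#' Writes per-cell OME-TIFF stacks (`stacks/`), per-cell 8-bit truth masks
#' (`truth/`) and `truth.csv` (true overlaps, pairing, configuration).
#'
#' @param config a [read_run_config()] result (or path).
#' @param out_dir output directory root.
#' @param seed population seed (overrides the config's).
#' @param n_cells number of cells (overrides the config's).
#' @param write_images write stacks and truth masks (the truth table is
#'   always written)?
#' @return invisible tibble: the truth table.
#' @export
stage_simulate <- function(config, out_dir, seed = NULL, n_cells = NULL,
                           write_images = TRUE) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  seed <- seed %||% cfg$seed
  n_cells <- n_cells %||% cfg$n_cells
  params <- cfg$simulation
  dir.create(file.path(out_dir, "stacks"), recursive = TRUE, showWarnings = FALSE)
  if (write_images) {
    dir.create(file.path(out_dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  }
  rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    pi <- params
    pi$seed <- derive_seed(seed, i)
    id <- sprintf("cell_%03d", i)
    truth <- simulate_cell(pi)
    stack <- render_microscopy(truth, cell_id = id)
    if (write_images) {
      write_stack(stack, file.path(out_dir, "stacks", paste0(id, ".ome.tif")))
      write_mask(truth$nucleus, file.path(out_dir, "truth",
                                          paste0(id, "_nucleus.tif")),
                 params$voxel_spacing, paste0(id, "_nucleus"))
      for (ch in names(truth$masks)) {
        write_mask(truth$masks[[ch]],
                   file.path(out_dir, "truth", paste0(id, "_", ch, ".tif")),
                   params$voxel_spacing, paste0(id, "_", ch))
      }
    } else {
      saveRDS(stack, file.path(out_dir, "stacks", paste0(id, ".rds")))
    }
    row <- list(cell_id = id)
    nm <- rownames(truth$overlap)
    for (a in nm) for (b in nm) if (a != b) {
      row[[paste0("true_ovf_", a, "_given_", b)]] <- truth$overlap[a, b]
    }
    for (a in nm) row[[paste0("true_paired_", a)]] <- unname(truth$pairing[a])
    if (!is.null(truth$configuration)) {
      row$true_cfg_state <- truth$configuration$state_id
      row$true_cfg_closed <- truth$configuration$closed
    }
    rows[[i]] <- tibble::as_tibble(row)
  }
  truth_tbl <- dplyr::bind_rows(rows)
  readr::write_csv(truth_tbl, file.path(out_dir, "truth.csv"))
  invisible(truth_tbl)
}

#' Segment stage: nucleus + territory masks for every stack in a directory
#'
#' Reads each stack under `in_dir/stacks`, writes per-cell label TIFFs under
#' `out_dir/masks` and `provenance.json` (thresholds per cell and channel,
#' border flags).
#'
#' @param config a [read_run_config()] result (or path).
#' @param in_dir directory containing `stacks/`.
#' @param out_dir output root (may equal `in_dir`).
#' @return invisible list of `ct_cell` objects.
#' @export
stage_segment <- function(config, in_dir, out_dir = in_dir) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  mask_dir <- file.path(out_dir, "masks")
  dir.create(mask_dir, recursive = TRUE, showWarnings = FALSE)
  files <- sort(list.files(file.path(in_dir, "stacks"),
                           pattern = "\\.(ome\\.tif|rds)$", full.names = TRUE))
  if (length(files) == 0L) stop("segment stage: no stacks found in ", in_dir,
                                call. = FALSE)
  cells <- vector("list", length(files))
  prov <- list()
  for (fi in seq_along(files)) {
    stack <- if (grepl("\\.rds$", files[fi])) readRDS(files[fi])
             else read_stack(files[fi])
    if (!cfg$dna_channel %in% stack$channels) {
      stop(sprintf("segment stage: DNA channel '%s' not in stack channels (%s)",
                   cfg$dna_channel, paste(stack$channels, collapse = ", ")),
           call. = FALSE)
    }
    cell <- segment_cell(stack, dna_channel = cfg$dna_channel,
                         thresholds = cfg$thresholds,
                         min_volume = cfg$min_volume,
                         relative_min = cfg$relative_min)
    cells[[fi]] <- cell
    id <- cell$cell_id
    write_mask(cell$nucleus, file.path(mask_dir, paste0(id, "_nucleus.tif")),
               cell$spacing, paste0(id, "_nucleus"))
    for (ch in names(cell$territories)) {
      tt <- cell$territories[[ch]]
      lab <- if (is.null(tt)) array(0L, dim(cell$nucleus)) else tt$labels
      write_mask(lab, file.path(mask_dir, paste0(id, "_", ch, ".tif")),
                 cell$spacing, paste0(id, "_", ch))
    }
    prov[[id]] <- cell$provenance
  }
  jsonlite::write_json(prov, file.path(mask_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(cells)
}

# rebuild a ct_cell from label masks on disk
cell_from_masks <- function(mask_dir, id, channels, spacing, provenance) {
  nuc <- read_mask(file.path(mask_dir, paste0(id, "_nucleus.tif")))
  sp <- provenance$spacing %||% nuc$spacing %||% spacing
  territories <- setNames(vector("list", length(channels)), channels)
  for (ch in channels) {
    mm <- read_mask(file.path(mask_dir, paste0(id, "_", ch, ".tif")))
    lab <- mm$labels
    if (max(lab) > 0L) {
      sizes <- tabulate(lab[lab > 0L])
      territories[[ch]] <- structure(
        list(labels = lab,
             volumes = tibble::tibble(label = seq_along(sizes),
                                      n_voxels = as.integer(sizes),
                                      volume = sizes * prod(sp)),
             low = NA_real_, high = NA_real_, spacing = sp),
        class = "ct_components")
    }
  }
  structure(list(nucleus = nuc$mask, territories = territories, spacing = sp,
                 cell_id = id, provenance = provenance),
            class = "ct_cell")
}

#' Measure stage: per-cell metrics table
#'
#' Consumes segmented cells (in memory from [stage_segment()], or label
#' masks under `in_dir/masks`) and writes `cells.csv`. Border-touching
#' nuclei are excluded from the table and logged.
#'
#' @param config a [read_run_config()] result (or path).
#' @param in_dir directory containing `masks/` (ignored when `cells` given).
#' @param out_csv output CSV path.
#' @param cells optional list of `ct_cell` objects.
#' @return invisible tibble of measurements (excluded cells dropped);
#'   attribute `excluded` lists cell ids and reasons.
#' @export
stage_measure <- function(config, in_dir = NULL, out_csv = file.path(in_dir, "cells.csv"),
                          cells = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  if (is.null(cells)) {
    mask_dir <- file.path(in_dir, "masks")
    prov_all <- jsonlite::read_json(file.path(mask_dir, "provenance.json"))
    nuc_files <- sort(list.files(mask_dir, pattern = "_nucleus\\.tif$"))
    ids <- sub("_nucleus\\.tif$", "", nuc_files)
    all_files <- list.files(mask_dir, pattern = "\\.tif$")
    cells <- lapply(ids, function(id) {
      chs <- sub("\\.tif$", "",
                 sub(paste0("^", id, "_"), "",
                     grep(paste0("^", id, "_"), all_files, value = TRUE)))
      chs <- setdiff(chs, "nucleus")
      pv <- prov_all[[id]] %||% list()
      pv$relative_min <- pv$relative_min %||% cfg$relative_min
      cell_from_masks(mask_dir, id, chs, cfg$simulation$voxel_spacing, pv)
    })
  }
  measured <- measure_cells(cells, contact_mode = cfg$contact_mode)
  excluded <- measured[measured$border_touching, "cell_id", drop = FALSE]
  kept <- measured[!measured$border_touching, , drop = FALSE]
  if (nrow(kept) == 0L) stop("measure stage: all cells excluded", call. = FALSE)
  readr::write_csv(kept, out_csv)
  attr(kept, "excluded") <- excluded$cell_id
  invisible(kept)
}

#' Report stage: population summaries
#'
#' Writes `overlap_heatmap.csv`, `contact_heatmap.csv`, `shell_profiles.csv`,
#' `config_frequencies.csv` (when configurations are present),
#' `translocation_screen.csv` (when >= 3 channel pairs) and `summary.json`;
#' optionally PNG heatmap/shell plots.
#'
#' @param cells_csv path to `cells.csv` (or a measurements tibble).
#' @param out_dir report output directory.
#' @param plots also write PNG figures?
#' @return invisible `ct_summary`.
#' @export
stage_report <- function(cells_csv, out_dir, plots = FALSE) {
  cells <- if (is.character(cells_csv)) {
    readr::read_csv(cells_csv, show_col_types = FALSE)
  } else cells_csv
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summ <- aggregate_cells(cells)
  wm <- function(m, path) {
    df <- as.data.frame(m)
    df <- cbind(channel = rownames(m), df)
    readr::write_csv(tibble::as_tibble(df), path)
  }
  wm(summ$overlap, file.path(out_dir, "overlap_heatmap.csv"))
  wm(summ$contact, file.path(out_dir, "contact_heatmap.csv"))
  if (!is.null(summ$shell_profiles)) {
    readr::write_csv(summ$shell_profiles, file.path(out_dir, "shell_profiles.csv"))
  }
  if (!is.null(summ$config)) {
    readr::write_csv(summ$config$frequencies,
                     file.path(out_dir, "config_frequencies.csv"))
  }
  screen <- if (length(summ$channels) >= 3L) translocation_screen(summ) else NULL
  if (!is.null(screen)) {
    readr::write_csv(screen, file.path(out_dir, "translocation_screen.csv"))
  }
  jsonlite::write_json(
    c(as.list(glance(summ)),
      list(flagged_pairs = if (is.null(screen)) character(0)
           else paste(screen$channel_a, screen$channel_b, sep = "-")[screen$flagged])),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA
  )
  if (plots) {
    ggplot2::ggsave(file.path(out_dir, "overlap_heatmap.png"),
                    autoplot(summ, "overlap"), width = 5, height = 4, dpi = 150)
    ggplot2::ggsave(file.path(out_dir, "contact_heatmap.png"),
                    autoplot(summ, "contact"), width = 5, height = 4, dpi = 150)
    if (!is.null(summ$shell_profiles)) {
      ggplot2::ggsave(file.path(out_dir, "shell_profiles.png"),
                      autoplot(summ, "shells"), width = 5, height = 3.5, dpi = 150)
    }
  }
  invisible(summ)
}

#' Run the full pipeline
#'
#' simulate -> segment -> measure -> report, with a `manifest.json`
#' recording the package version, seed, per-stage parameters and per-cell
#' exclusions. Outputs are a pure function of `(config, seed)`.
#'
#' @param config YAML path or config list (see [read_run_config()]).
#' @param out_dir output root.
#' @param seed population seed (overrides the config's).
#' @param n_cells overrides the config's cell count.
#' @param write_images write stacks/truth/label TIFFs (in-memory when
#'   `FALSE`; `cells.csv`, `truth.csv` and reports are always written).
#' @return invisible list: `cells` (measurements tibble), `summary`
#'   (`ct_summary`), `truth` (truth table).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, n_cells = NULL,
                         write_images = TRUE) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  seed <- seed %||% cfg$seed
  n_cells <- n_cells %||% cfg$n_cells
  nm <- vapply(cfg$simulation$channels, `[[`, "", "name")
  if (cfg$dna_channel %in% nm) {
    stop("config error [simulate]: DNA channel name collides with a paint channel",
         call. = FALSE)
  }
  if (cfg$dna_channel != "dna") {
    stop(sprintf(paste0("config error [simulate]: DNA channel '%s' will not be ",
                        "present in simulated stacks (the simulator names the ",
                        "counterstain 'dna')"), cfg$dna_channel), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- stage_simulate(cfg, out_dir, seed = seed, n_cells = n_cells,
                          write_images = write_images)
  cells_seg <- stage_segment(cfg, out_dir, out_dir)
  measured <- stage_measure(cfg, in_dir = out_dir,
                            out_csv = file.path(out_dir, "cells.csv"),
                            cells = cells_seg)
  summ <- stage_report(file.path(out_dir, "cells.csv"),
                       file.path(out_dir, "report"),
                       plots = isTRUE(cfg$report$plots))
  manifest <- list(
    package = "ctfish",
    version = as.character(utils::packageVersion("ctfish")),
    seed = seed, n_cells = n_cells,
    parameters = list(
      confinement = cfg$simulation$confinement,
      pairing_prob = cfg$simulation$pairing_prob,
      grid_dim = cfg$simulation$grid_dim,
      voxel_spacing = cfg$simulation$voxel_spacing,
      channels = nm, dna_channel = cfg$dna_channel,
      min_volume = cfg$min_volume, relative_min = cfg$relative_min,
      contact_mode = cfg$contact_mode
    ),
    excluded_cells = attr(measured, "excluded")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cells = measured, summary = summ, truth = truth))
}
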