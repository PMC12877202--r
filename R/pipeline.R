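#' Pipeline configuration with the method's fixed constants
#'
#' Collects every stage parameter with its default: 30 px bins and a 20x
#' mean threshold for the prevalent-barcode filter; 100 px localization
#' bins with unique/major ratio thresholds 10 and 2; 30 um neighborhood and
#' colocalization radius; 100 um ligand-receptor radius; 100 / 1000
#' permutations for PCCF / ligand-receptor screening; embedding learning
#' rate 0.001, 150 epochs, tau 0.3, lam 0.3, dropout 0.25; pixel pitch
#' 0.265 um/px; one global seed.
#'
#' @param ... overrides of individual fields.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    pixel_pitch_um = PIXEL_PITCH_UM,
    filter_bin_px = 30, filter_k = 20, filter_max_iter = 100,
    localize_bin_px = 100, unique_ratio = 10, major_ratio = 2,
    neighborhood_radius_um = 30, pccf_radius_um = 30, pccf_n_perm = 100,
    ligrec_radius_um = 100, ligrec_n_perm = 1000, ligrec_alpha = 0.005,
    embed_lr = 0.001, embed_epochs = 150, embed_tau = 0.3, embed_lam = 0.3,
    embed_dropout = 0.25, leiden_resolution = 0.1,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `path` (write) or the configuration (read).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the simulate-to-statistics pipeline on synthetic data
#'
#' End-to-end driver: simulate a chip and tissue, attach and correct
#' barcodes, filter prevalent barcodes, localize nuclei, benchmark against
#' the simulated truth, assign districts, and compute colocalization
#' statistics. Each stage's outputs are written under `outdir` along with
#' the resolved configuration (`run_config.yaml`) and a JSON report.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param chip a [chip_spec()].
#' @param tissue a [tissue_spec()].
#' @param stages character vector of stages to run, in pipeline order.
#' @param verbose print stage progress to stderr.
#' @return (invisibly) a list with the per-stage results and the report.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("nuclocate_"),
                         chip = chip_spec(seed = config$seed),
                         tissue = tissue_spec(seed = config$seed + 1L),
                         stages = c("simulate", "attach", "filter", "localize",
                                    "evaluate", "districts", "colocalize"),
                         verbose = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, file.path(outdir, "run_config.yaml"))
  say <- function(stage, msg) {
    if (verbose) message(sprintf("[%s] %s", stage, msg))
  }
  res <- list()
  report <- list(seed = config$seed)
  run_stage <- function(stage, fn) {
    if (!stage %in% stages) return(invisible(NULL))
    say(stage, "running")
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  run_stage("simulate", function() {
    cm <- make_chip(chip)
    cap <- simulate_capture(cm, tissue)
    res$chip <<- cm
    res$capture <<- cap
    write_chip_map(cm, file.path(outdir, "chip_map.tsv"))
    write.table(cap$counts, file.path(outdir, "barcode_counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.csv(cap$truth, file.path(outdir, "truth.csv"), row.names = FALSE)
    expr <- simulate_expression(cap$truth, seed = config$seed + 2L)
    Matrix::writeMM(expr, file.path(outdir, "expression.mtx"))
    writeLines(rownames(expr), file.path(outdir, "genes.tsv"))
    writeLines(colnames(expr), file.path(outdir, "cells.tsv"))
    res$expression <<- expr
    niche_labels <- vapply(tissue$niches, `[[`, "", "label")
    if (length(niche_labels) >= 2L) {
      clono <- simulate_clonotypes(cap$truth, route = niche_labels,
                                   seed = config$seed + 3L)
      write.csv(clono, file.path(outdir, "clonotypes.csv"), row.names = FALSE)
      res$clonotypes <<- clono
    }
    report$n_nuclei <<- nrow(cap$truth)
    report$n_capture_events <<- cap$n_capture_events
  })
  run_stage("attach", function() {
    dd <- dedup_chip_barcodes(res$chip)
    pos <- attach_coordinates(res$capture$counts, dd$map, correct = TRUE)
    res$positioned <<- pos
    report$chip_barcodes_deduplicated <<- dd$n_removed
    report$count_rows_dropped <<- attr(pos, "n_dropped")
  })
  run_stage("filter", function() {
    fl <- filter_prevalent_barcodes(res$positioned, bin_px = config$filter_bin_px,
                                    k = config$filter_k,
                                    max_iter = config$filter_max_iter)
    res$filtered <<- fl$counts
    report$filter <<- list(iterations = fl$report$iterations,
                           cells_removed = length(fl$report$cells_removed))
  })
  run_stage("localize", function() {
    loc <- localize_all(res$filtered, bin_px = config$localize_bin_px,
                        unique_ratio = config$unique_ratio,
                        major_ratio = config$major_ratio,
                        pixel_pitch_um = config$pixel_pitch_um)
    res$localized <<- loc
    write.csv(loc, file.path(outdir, "localized.csv"), row.names = FALSE)
    report$localization <<- as.list(attr(loc, "summary"))
  })
  run_stage("evaluate", function() {
    truth <- res$capture$truth
    loc <- res$localized
    ok <- loc[!is.na(loc$x_um), ]
    mr <- match_nearest(
      data.frame(id = ok$cell_id, x = ok$x_um, y = ok$y_um),
      data.frame(id = truth$cell_id, x = truth$x_um, y = truth$y_um))
    res$match <<- mr
    report$offset_um <<- list(mean = mean(mr$pairs$offset_um),
                              median = median(mr$pairs$offset_um))
  })
  run_stage("districts", function() {
    truth <- res$capture$truth
    loc <- res$localized
    ok <- loc[!is.na(loc$x_um), ]
    ct <- truth$cell_type[match(ok$cell_id, truth$cell_id)]
    cells <- data.frame(cell_id = ok$cell_id, x = ok$x_um, y = ok$y_um,
                        cell_type = ct, stringsAsFactors = FALSE)
    cells <- cells[!is.na(cells$cell_type), ]
    res$cells <<- cells
    cfg <- embed_config(lr = config$embed_lr, epochs = config$embed_epochs,
                        tau = config$embed_tau, lam = config$embed_lam,
                        dropout_p = config$embed_dropout, seed = config$seed)
    da <- find_districts(cells, radius_um = config$neighborhood_radius_um,
                         config = cfg, resolution = config$leiden_resolution)
    res$districts <<- da
    merged <- merge(cells, da, by = "cell_id")
    write.csv(merged, file.path(outdir, "cells_districts.csv"), row.names = FALSE)
    report$n_districts <<- length(unique(da$district))
  })
  run_stage("colocalize", function() {
    cells <- res$cells
    tys <- sort(unique(cells$cell_type))
    if (length(tys) >= 2L) {
      pr <- pccf(cells, tys[1], tys[2], radius_um = config$pccf_radius_um,
                 n_perm = config$pccf_n_perm, seed = config$seed)
      res$pccf <<- pr
      report$pccf <<- list(pair = paste(tys[1], tys[2], sep = "|"),
                           value = pr$pccf, p = pr$p_value)
    }
  })
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$report <- report
  res$outdir <- outdir
  invisible(res)
}
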