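# File formats -----------------------------------------------------------------
#
# Images travel as 16-bit multi-page TIFF plus a JSON sidecar carrying the
# micron calibration and channel names (the tiff package cannot write
# resolution tags). Boundaries travel as a tidy CSV dialect or as ImageJ
# .roi / RoiSet .zip files; counts as MatrixMarket + TSVs or dense CSV.

sidecar_path <- function(path) paste0(path, ".meta.json")

#' Write one or more image channels as 16-bit TIFF
#'
#' Intensities are rounded to integers and stored as 16-bit unsigned TIFF
#' pages (values must fit 0..65535); pixel size and channel names go to a
#' `<path>.meta.json` sidecar. Integer-valued images round-trip bit-exactly.
#'
#' @param channels An [image_channel()] or list of them (shared grid).
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_image <- function(channels, path) {
  if (inherits(channels, "image_channel")) channels <- list(channels)
  grid <- channels[[1]]$grid
  pages <- lapply(channels, function(ch) {
    stopifnot(inherits(ch, "image_channel"))
    if (max(ch$data) > 65535)
      oq_abort("intensities exceed the 16-bit range.", "parameter")
    round(ch$data) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(pixel_size_um = grid$pixel_size_um,
         channels = vapply(channels, `[[`, "", "channel")),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read image channels from a TIFF file
#'
#' Calibration comes from the JSON sidecar written by [write_image()] or from
#' the `pixel_size_um` override; with neither, reading errors.
#'
#' @param path `.tif` path.
#' @param pixel_size_um Optional calibration override (microns per pixel).
#' @param channels Optional channel names override (one per page).
#' @return List of [image_channel()]s (length = number of pages).
#' @export
read_image <- function(path, pixel_size_um = NULL, channels = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- if (file.exists(sidecar_path(path)))
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE) else NULL
  px <- pixel_size_um %||% meta$pixel_size_um
  if (is.null(px))
    oq_abort("no pixel-size calibration: no sidecar and no override.",
             "parameter")
  nms <- channels %||% meta$channels %||% sprintf("ch%02d", seq_along(pages))
  purrr::map2(pages, rep_len(nms, length(pages)), function(p, nm)
    image_channel(round(p * 65535), px, nm))
}

# --- boundary polylines -------------------------------------------------------

#' Write rosette boundaries to the tidy CSV dialect
#'
#' Columns: `rosette_id`, `role` (`outer` / `inner`), `vertex_index`,
#' `x_um`, `y_um`.
#'
#' @param boundaries Named list: per rosette id, a list with `outer` and
#'   `inner` [boundary_polyline()]s.
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_boundaries <- function(boundaries, path) {
  rows <- purrr::imap_dfr(boundaries, function(pair, id)
    purrr::imap_dfr(pair[c("outer", "inner")], function(b, role)
      tibble(rosette_id = id, role = role,
             vertex_index = seq_along(b$x), x_um = b$x, y_um = b$y)))
  utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read rosette boundaries (CSV or ImageJ RoiSet zip)
#'
#' CSV follows the [write_boundaries()] dialect. A `.zip` is an ImageJ RoiSet
#' whose entries are named `<rosette_id>_outer.roi` / `<rosette_id>_inner.roi`
#' (polygon or freehand ROIs; pixel coordinates are converted with
#' `pixel_size_um`). Every rosette id must carry both roles.
#'
#' @param path `.csv` or `.zip` path.
#' @param pixel_size_um Calibration for `.zip` input (ignored for CSV, whose
#'   coordinates are already in microns).
#' @return Named list: per rosette id, `list(outer =, inner =)` boundary
#'   polylines.
#' @export
read_boundaries <- function(path, pixel_size_um = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("rosette_id", "role", "vertex_index", "x_um", "y_um")
    if (!all(need %in% names(d)))
      oq_abort("boundary CSV header mismatch.", "parameter")
    pairs <- split(d, d$rosette_id)
    out <- lapply(pairs, function(dd) {
      roles <- split(dd, dd$role)
      if (!all(c("outer", "inner") %in% names(roles)))
        oq_abort(sprintf("rosette '%s' is missing an outer or inner boundary.",
                         dd$rosette_id[1]), "parameter")
      lapply(roles[c("outer", "inner")], function(r) {
        r <- r[order(r$vertex_index), ]
        boundary_polyline(r$x_um, r$y_um)
      })
    })
    return(out)
  }
  if (ext == "zip") {
    if (is.null(pixel_size_um))
      oq_abort("reading ImageJ ROIs needs `pixel_size_um`.", "parameter")
    tmp <- tempfile("roiset")
    files <- unzip(path, exdir = tmp)
    on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
    ids <- sub("_(outer|inner)\\.roi$", "", basename(files))
    roles <- sub("^.*_(outer|inner)\\.roi$", "\\1", basename(files))
    if (any(!roles %in% c("outer", "inner")))
      oq_abort("RoiSet entries must be named <id>_outer.roi / <id>_inner.roi.",
               "parameter")
    out <- lapply(split(seq_along(files), ids), function(ix) {
      rl <- setNames(files[ix], roles[ix])
      if (!all(c("outer", "inner") %in% names(rl)))
        oq_abort("unpaired boundary in RoiSet.", "parameter")
      lapply(as.list(rl[c("outer", "inner")]),
             read_imagej_roi, pixel_size_um = pixel_size_um)
    })
    return(out)
  }
  oq_abort("unsupported boundary format (use .csv or .zip).", "parameter")
}

#' Read a single ImageJ .roi file (polygon / freehand)
#'
#' Minimal reader for the ImageJ ROI binary format, supporting the polygon
#' (type 0) and freehand (type 7) shapes with integer pixel coordinates.
#'
#' @param path `.roi` path.
#' @param pixel_size_um Microns per pixel used to convert the stored pixel
#'   coordinates.
#' @return A closed [boundary_polyline()] in microns.
#' @export
read_imagej_roi <- function(path, pixel_size_um) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "Iout"))
    oq_abort("not an ImageJ ROI file.", "parameter")
  readBin(con, "integer", 1, 2, endian = "big")          # version
  type <- readBin(con, "integer", 1, 1, signed = FALSE)
  readBin(con, "integer", 1, 1, signed = FALSE)          # unused
  if (!type %in% c(0L, 7L))
    oq_abort("only polygon/freehand ImageJ ROIs are supported.", "parameter")
  top <- readBin(con, "integer", 1, 2, endian = "big")
  left <- readBin(con, "integer", 1, 2, endian = "big")
  readBin(con, "integer", 2, 2, endian = "big")          # bottom, right
  n <- readBin(con, "integer", 1, 2, endian = "big")
  seek(con, 64)
  xs <- readBin(con, "integer", n, 2, endian = "big")
  ys <- readBin(con, "integer", n, 2, endian = "big")
  boundary_polyline((left + xs) * pixel_size_um, (top + ys) * pixel_size_um)
}

#' Write a boundary polyline as an ImageJ .roi polygon
#'
#' @param boundary A closed [boundary_polyline()] in microns.
#' @param path Output `.roi` path.
#' @param pixel_size_um Microns per pixel; vertices are rounded to integer
#'   pixel coordinates (ImageJ stores shorts).
#' @return `path`, invisibly.
#' @export
write_imagej_roi <- function(boundary, path, pixel_size_um) {
  xs <- as.integer(round(boundary$x / pixel_size_um))
  ys <- as.integer(round(boundary$y / pixel_size_um))
  left <- min(xs); top <- min(ys)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("Iout", con, 4, eos = NULL)
  writeBin(c(227L), con, 2, endian = "big")               # version
  writeBin(as.raw(c(0L, 0L)), con)                        # type polygon, pad
  writeBin(as.integer(c(top, left, max(ys) + 1, max(xs) + 1, length(xs))),
           con, 2, endian = "big")
  writeBin(raw(64 - 18), con)                             # rest of the header
  writeBin(as.integer(c(xs - left, ys - top)), con, 2, endian = "big")
  invisible(path)
}

# --- count matrices -----------------------------------------------------------

#' Write a count matrix as MatrixMarket + TSVs
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and, when present,
#' `clusters.csv` (`cell,cluster`) and `mito_genes.txt` into `dir`.
#'
#' @param m A [count_matrix()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_counts <- function(m, dir) {
  stopifnot(inherits(m, "count_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(m$counts), file.path(dir, "barcodes.tsv"))
  if (!is.null(m$clusters))
    utils::write.csv(data.frame(cell = names(m$clusters),
                                cluster = unname(m$clusters)),
                     file.path(dir, "clusters.csv"), row.names = FALSE)
  if (length(m$mito_genes))
    writeLines(m$mito_genes, file.path(dir, "mito_genes.txt"))
  writeLines(m$sample, file.path(dir, "sample.txt"))
  invisible(dir)
}

#' Read a count matrix (MatrixMarket directory or dense CSV)
#'
#' A directory must contain `matrix.mtx`, `genes.tsv`, `barcodes.tsv`
#' (optionally `clusters.csv`, `mito_genes.txt`, `sample.txt`). A `.csv` is a
#' dense genes x cells table whose first column holds gene ids.
#'
#' @param path Directory or `.csv` path.
#' @param sample Sample label (overrides any stored label).
#' @param mito_pattern Regex identifying mitochondrial genes when no explicit
#'   list is stored (default `"^MT-"`).
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, sample = NULL, mito_pattern = "^MT-") {
  if (dir.exists(path)) {
    need <- file.path(path, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
    if (!all(file.exists(need)))
      oq_abort("count directory must contain matrix.mtx, genes.tsv, barcodes.tsv.",
               "parameter")
    x <- Matrix::readMM(need[1])
    genes <- readLines(need[2])
    cells <- readLines(need[3])
    if (nrow(x) != length(genes) || ncol(x) != length(cells))
      oq_abort("matrix dimensions do not match genes.tsv/barcodes.tsv.",
               "parameter")
    dimnames(x) <- list(genes, cells)
    clusters <- NULL
    clp <- file.path(path, "clusters.csv")
    if (file.exists(clp)) {
      cl <- utils::read.csv(clp, stringsAsFactors = FALSE)
      clusters <- cl$cluster[match(cells, cl$cell)]
    }
    mtp <- file.path(path, "mito_genes.txt")
    mito <- if (file.exists(mtp)) readLines(mtp) else grep(mito_pattern, genes,
                                                           value = TRUE)
    smp <- file.path(path, "sample.txt")
    label <- sample %||% (if (file.exists(smp)) readLines(smp)[1] else "sample")
    return(count_matrix(x, label, clusters, mito))
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- d[[1]]
  x <- as.matrix(d[, -1, drop = FALSE])
  rownames(x) <- genes
  count_matrix(x, sample %||% "sample",
               mito_genes = grep(mito_pattern, genes, value = TRUE))
}

# --- run configuration and pipeline driver -----------------------------------

#' Pipeline run configuration
#'
#' All physical parameters are in microns and every default equals the
#' method's stated value: 1.8 um erosion/dilation, 54 um top-hat radius, QC
#' cutoffs 8000 / 200 / 50000 / 20%, 6400-cell downsampling, pseudocount
#' 0.01, log2 fold-change cutoff 1, NES cutoff 7.5. Configs round-trip
#' losslessly through YAML via [write_run_config()] / [read_run_config()].
#'
#' @param stage One of `"simulate"`, `"rosette-quant"`, `"marker-quant"`,
#'   `"coloc"`, `"screen"`, `"stats"`, `"run-all"`.
#' @param inputs Named list of input paths (stage-dependent).
#' @param outdir Output directory.
#' @param seed Integer seed for all randomness.
#' @param ... Parameter overrides (see Defaults).
#' @return An `oq_run_config` list.
#' @export
run_config <- function(stage, inputs = list(), outdir = "out", seed = 1L, ...) {
  defaults <- list(
    erosion_um = 1.8, dilation_um = 1.8, refine = FALSE,
    tophat_radius_um = 54,
    max_nFeature = 8000, min_nFeature = 200, max_nCount = 50000,
    max_pct_mito = 20, downsample_n = 6400, pseudocount = 0.01,
    fc_threshold = 1, nes_cutoff = 7.5,
    pixel_size_um = NULL,
    coloc_method = "otsu", coloc_fixed_t = NULL,
    doublet_rate_metadata = 0.008,  # upstream multiplet rate, provenance only
    simulate = list(n_per_group = 8, group_ribbon_means = list(control = 300,
                                                               edited = 200))
  )
  overrides <- list(...)
  if (!is.null(overrides$simulate$group_ribbon_means))
    overrides$simulate$group_ribbon_means <-
      as.list(overrides$simulate$group_ribbon_means)
  params <- defaults
  for (nm in names(overrides)) params[nm] <- list(overrides[[nm]])
  structure(list(stage = stage, inputs = inputs, outdir = outdir,
                 seed = as.integer(seed), params = params),
            class = "oq_run_config")
}

#' @rdname run_config
#' @param config An `oq_run_config`.
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config(raw$stage, raw$inputs %||% list(), raw$outdir, raw$seed)
  # overlay stored parameters, preserving explicit NULLs and default order
  for (nm in names(raw$params)) cfg$params[nm] <- list(raw$params[[nm]])
  cfg
}

write_parameters_json <- function(config, dir) {
  jsonlite::write_json(
    list(stage = config$stage, seed = config$seed, params = config$params,
         package_version = as.character(utils::packageVersion("organoidquant"))),
    file.path(dir, "parameters.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
}

write_csv_stable <- function(d, path) {
  utils::write.csv(as.data.frame(d), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
}

#' Run a pipeline stage
#'
#' Thin driver binding the stages to the file formats above. Every run writes
#' its outputs plus a `parameters.json` recording the full parameter set and
#' package version; reruns with identical config and seed are byte-identical.
#'
#' Stages and their inputs:
#' * `simulate`: writes seeded rosette scenes per group (`image_*.tif`,
#'   `boundaries.csv`, `truth.json`).
#' * `rosette-quant`: `inputs$images` (directory of TIFFs) +
#'   `inputs$boundaries` (CSV) -> `rosette_measurements.csv`.
#' * `marker-quant`: `inputs$images` -> `marker_quant.csv`.
#' * `coloc`: `inputs$stacks` (directory of multi-page TIFFs with channel
#'   sidecars) + `inputs$regions` (CSV `file,region`) -> `coloc_tvc.csv`.
#' * `screen`: `inputs$sample_a`, `inputs$sample_b` (count directories) ->
#'   `cell_qc.csv`, `cluster_ratios.csv`, `de_genes.csv`.
#' * `stats`: `inputs$measurements` (CSV `group,value`) -> `anova.json`,
#'   `tukey.csv`, `normality.csv`.
#' * `run-all`: simulate, then rosette-quant and stats on the simulated set.
#'
#' @param config An [run_config()] object.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "oq_run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  need_input <- function(key) {
    p <- config$inputs[[key]]
    if (is.null(p) || !file.exists(p))
      oq_abort(sprintf("stage '%s': missing input '%s'.", config$stage, key),
               "parameter")
    p
  }
  p <- config$params
  switch(
    config$stage,
    "simulate" = {
      sim <- p$simulate
      bnds <- list()
      truth <- list()
      i <- 0
      for (g in names(sim$group_ribbon_means)) {
        for (j in seq_len(sim$n_per_group)) {
          i <- i + 1
          sc <- make_rosette_scene(rosette_scene_params(
            ribbon_mean = sim$group_ribbon_means[[g]],
            seed = config$seed * 10000L + i))
          id <- sprintf("%s_%02d", g, j)
          write_image(sc$image, file.path(config$outdir,
                                          sprintf("image_%s.tif", id)))
          bnds[[id]] <- list(outer = sc$truth$outer, inner = sc$truth$inner)
          truth[[id]] <- list(group = g,
                              region_means = as.list(sc$truth$region_means))
        }
      }
      write_boundaries(bnds, file.path(config$outdir, "boundaries.csv"))
      jsonlite::write_json(truth, file.path(config$outdir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
    },
    "rosette-quant" = {
      imgs <- need_input("images")
      bnds <- read_boundaries(need_input("boundaries"))
      files <- sort(list.files(imgs, pattern = "\\.tif$", full.names = TRUE))
      rows <- purrr::map_dfr(files, function(f) {
        id <- sub("^image_", "", sub("\\.tif$", "", basename(f)))
        if (!id %in% names(bnds))
          oq_abort(sprintf("stage 'rosette-quant': no boundaries for '%s'.", id),
                   "parameter")
        ch <- read_image(f, pixel_size_um = p$pixel_size_um)[[1]]
        measure_rosette(ch, bnds[[id]]$outer, bnds[[id]]$inner,
                        rosette_id = id, group = sub("_[0-9]+$", "", id),
                        erosion_um = p$erosion_um, dilation_um = p$dilation_um,
                        refine = p$refine)
      })
      write_csv_stable(rows, file.path(config$outdir,
                                       "rosette_measurements.csv"))
    },
    "marker-quant" = {
      imgs <- need_input("images")
      files <- sort(list.files(imgs, pattern = "\\.tif$", full.names = TRUE))
      rows <- purrr::map_dfr(files, function(f) {
        ch <- read_image(f, pixel_size_um = p$pixel_size_um)[[1]]
        dplyr::mutate(quantify_marker(ch, p$tophat_radius_um),
                      image = basename(f), channel = ch$channel, .before = 1)
      })
      write_csv_stable(rows, file.path(config$outdir, "marker_quant.csv"))
    },
    "coloc" = {
      stacks_dir <- need_input("stacks")
      regions <- utils::read.csv(need_input("regions"), stringsAsFactors = FALSE)
      stacks <- lapply(regions$file, function(f) {
        chs <- read_image(file.path(stacks_dir, f))
        arrs <- lapply(chs, `[[`, "data")
        names(arrs) <- vapply(chs, `[[`, "", "channel")
        volume_stack(arrs, rep(chs[[1]]$grid$pixel_size_um, 3))
      })
      rep <- coloc_report(stacks, regions$region, method = p$coloc_method,
                          t = p$coloc_fixed_t)
      write_csv_stable(rep$table, file.path(config$outdir, "coloc_tvc.csv"))
    },
    "screen" = {
      a <- read_counts(need_input("sample_a"), sample = "A")
      b <- read_counts(need_input("sample_b"), sample = "B")
      res <- lapply(list(A = a, B = b), function(m) {
        qc <- compute_cell_qc(m)
        keep <- qc_filter(qc, p$max_nFeature, p$min_nFeature, p$max_nCount,
                          p$max_pct_mito)
        m2 <- count_matrix(m$counts[, keep, drop = FALSE], m$sample,
                           if (!is.null(m$clusters)) m$clusters[keep],
                           m$mito_genes)
        if (ncol(m2$counts) > p$downsample_n)
          m2 <- downsample_cells(m2, p$downsample_n, seed = config$seed)
        list(qc = qc, m = m2)
      })
      write_csv_stable(dplyr::bind_rows(A = res$A$qc, B = res$B$qc,
                                        .id = "sample"),
                       file.path(config$outdir, "cell_qc.csv"))
      ratios <- cluster_aggregate_log2ratio(res$A$m, res$B$m,
                                            pseudocount = p$pseudocount)
      write_csv_stable(ratios, file.path(config$outdir, "cluster_ratios.csv"))
      write_csv_stable(select_de_genes(ratios, p$fc_threshold),
                       file.path(config$outdir, "de_genes.csv"))
    },
    "stats" = {
      d <- utils::read.csv(need_input("measurements"), stringsAsFactors = FALSE)
      rep <- group_report(d)
      jsonlite::write_json(as.list(glance(rep$anova)),
                           file.path(config$outdir, "anova.json"),
                           auto_unbox = TRUE, digits = NA)
      write_csv_stable(rep$tukey, file.path(config$outdir, "tukey.csv"))
      write_csv_stable(rep$normality, file.path(config$outdir,
                                                "normality.csv"))
    },
    "run-all" = {
      simdir <- file.path(config$outdir, "simulated")
      run_pipeline(run_config("simulate", outdir = simdir, seed = config$seed,
                              simulate = p$simulate))
      qdir <- file.path(config$outdir, "quant")
      cfg_q <- run_config("rosette-quant",
                          inputs = list(images = simdir,
                                        boundaries = file.path(simdir,
                                                               "boundaries.csv")),
                          outdir = qdir, seed = config$seed)
      cfg_q$params <- modifyList(cfg_q$params, p[c("erosion_um", "dilation_um",
                                                   "refine")])
      run_pipeline(cfg_q)
      meas <- utils::read.csv(file.path(qdir, "rosette_measurements.csv"),
                              stringsAsFactors = FALSE)
      sdir <- file.path(config$outdir, "stats")
      dir.create(sdir, showWarnings = FALSE)
      write_csv_stable(data.frame(group = meas$group, value = meas$mean_ribbon),
                       file.path(sdir, "measurements.csv"))
      run_pipeline(run_config("stats",
                              inputs = list(measurements =
                                              file.path(sdir,
                                                        "measurements.csv")),
                              outdir = sdir, seed = config$seed))
    },
    oq_abort(sprintf("unknown stage '%s'.", config$stage), "parameter")
  )
  write_parameters_json(config, config$outdir)
  invisible(config$outdir)
}
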