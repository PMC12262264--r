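#' Read point patterns from a CSV table
#'
#' Expects columns `x`, `y`, `cell_type`, `image_id` and optionally
#' `patient_id`, `group_id` (micron units, header required). Window side
#' lengths come from a per-image metadata CSV with columns `image_id`,
#' `xmin`, `xmax`, `ymin`, `ymax` (or `width`/`height` for origin-0
#' windows); when absent, each image's bounding box is used and a warning is
#' issued.
#'
#' @param file Path to the point CSV.
#' @param meta_file Optional path to the window metadata CSV.
#' @return List with `patterns` (named list of multitype `point_pattern`s)
#'   and `meta` (a [study_design()], when patient/group columns exist).
#' @export
read_patterns <- function(file, meta_file = NULL) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("x", "y", "cell_type", "image_id")
  if (!all(need %in% names(df))) {
    stopf("point CSV must have columns: %s", paste(need, collapse = ", "))
  }
  windows <- NULL
  if (!is.null(meta_file)) {
    wm <- read.csv(meta_file, stringsAsFactors = FALSE)
    if (all(c("width", "height") %in% names(wm))) {
      wm$xmin <- 0; wm$xmax <- wm$width; wm$ymin <- 0; wm$ymax <- wm$height
    }
    windows <- wm
  } else {
    warnf("no window metadata supplied; inferring windows from bounding boxes")
  }
  ids <- unique(df$image_id)
  patterns <- lapply(ids, function(id) {
    sub <- df[df$image_id == id, ]
    w <- if (!is.null(windows)) {
      row <- windows[windows$image_id == id, ]
      if (!nrow(row)) stopf("no window metadata for image '%s'", id)
      shade_window(c(row$xmin[1], row$xmax[1]), c(row$ymin[1], row$ymax[1]))
    } else {
      shade_window(range(sub$x), range(sub$y))
    }
    point_pattern(sub$x, sub$y, sub$cell_type, w)
  })
  names(patterns) <- as.character(ids)
  meta <- NULL
  if (all(c("patient_id", "group_id") %in% names(df))) {
    per_img <- unique(df[, c("image_id", "patient_id", "group_id")])
    meta <- study_design(per_img$image_id, per_img$patient_id,
                         per_img$group_id)
  }
  list(patterns = patterns, meta = meta)
}

#' Write a simulated study as CSV point tables plus truth JSON
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (m in seq_along(study$images)) {
    im <- study$images[[m]]
    id <- study$meta$image_id[m]
    for (nm in names(im$sources)) {
      s <- im$sources[[nm]]
      if (length(s$x)) {
        rows[[length(rows) + 1]] <- data.frame(
          x = s$x, y = s$y, cell_type = nm, image_id = id,
          patient_id = study$meta$patient_id[m],
          group_id = study$meta$group_id[m])
      }
    }
    t <- im$targets
    if (length(t$x)) {
      rows[[length(rows) + 1]] <- data.frame(
        x = t$x, y = t$y, cell_type = "target", image_id = id,
        patient_id = study$meta$patient_id[m],
        group_id = study$meta$group_id[m])
    }
  }
  pts <- file.path(dir, "points.csv")
  write.csv(do.call(rbind, rows), pts, row.names = FALSE)
  wtab <- data.frame(image_id = study$meta$image_id, xmin = 0,
                     xmax = study$config$window_side, ymin = 0,
                     ymax = study$config$window_side)
  wfile <- file.path(dir, "windows.csv")
  write.csv(wtab, wfile, row.names = FALSE)
  tfile <- file.path(dir, "truth.json")
  jsonlite::write_json(list(psi = study$truth$psi, gamma = study$truth$gamma,
                            delta = study$truth$delta,
                            design = as.data.frame(study$meta)),
                       tfile, digits = NA)
  invisible(c(pts, wfile, tfile))
}

#' Export posterior draws in long format
#'
#' @param fit A `shade_fit`.
#' @param file Optional CSV path; when `NULL` the data frame is returned.
#' @return Data frame with columns `param`, `chain`, `draw`, `value`.
#' @export
draws_table <- function(fit, file = NULL) {
  con <- fit$draws
  S <- length(con$chain)
  per_chain <- S / fit$sampler$chains
  rows <- list()
  grab <- function(name, v) {
    rows[[length(rows) + 1]] <<- data.frame(
      param = name, chain = con$chain,
      draw = rep(seq_len(per_chain), fit$sampler$chains), value = v)
  }
  walk <- function(arr, name) {
    d <- dim(arr)
    for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
      grab(sprintf("%s[%d,%d]", name, i, j), arr[, i, j])
    }
  }
  walk(con$delta, "delta")
  walk(con$beta, "beta")
  if (!is.null(con$psi)) {
    walk(con$psi, "psi"); walk(con$gamma, "gamma")
    for (k in 1:3) {
      grab(c("sigma_cohort", "sigma_patient", "sigma_image")[k],
           con$sigma[, k])
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(file)) {
    write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Export a curve's tidy summary
#'
#' @param curve A `sic_curve`.
#' @param file Optional CSV path.
#' @return Data frame `level`, `unit`, `source`, `distance`, `median`,
#'   `lo95`, `hi95`.
#' @export
sic_table <- function(curve, file = NULL) {
  out <- cbind(data.frame(level = curve$level, unit = curve$unit,
                          source = curve$source), curve$summary)
  if (!is.null(file)) {
    write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Write an intensity map as a plain-text ASCII grid
#'
#' ESRI-style header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`) followed by rows of node values, top row first.
#'
#' @param map An [intensity_map()].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_ascii_grid <- function(map, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", length(map$x)),
               sprintf("nrows %d", length(map$y)),
               sprintf("xllcorner %g", map$x[1] - map$grid_spacing / 2),
               sprintf("yllcorner %g", map$y[1] - map$grid_spacing / 2),
               sprintf("cellsize %g", map$grid_spacing)), con)
  for (i in rev(seq_along(map$y))) {
    writeLines(paste(signif(map$values[i, ], 7), collapse = " "), con)
  }
  invisible(file)
}
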