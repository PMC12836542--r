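# End-to-end orchestration: run configuration, plate quantification and
# dose-response fitting over standard-format files.

.RUN_DEFAULTS <- list(
  stacks_dir = ".",            # directory of {well_id}_d{day}.tif stacks
  plate_map = "plate_map.csv",
  output_dir = "results",
  pixel_size = 3,              # um/px
  tile_size = 32,              # projection tile, px
  polarity = "dark_objects",
  threshold_k = 3,
  min_area = pi * 20^2,        # um^2; 40 um-diameter disk
  max_area = NA,               # um^2; NA = no upper cut
  exclude_border = FALSE,
  anchor_policy = "first_imaged_day",
  dose_min = 0.1, dose_max = 1000, dose_fold = 10,
  fit_readouts = "relative_total_area",
  fit_days = NA,               # NA = every day after each well's anchor day
  seed = 1)

#' Run configuration for the quantification pipeline
#'
#' Builds a validated run configuration from defaults, an optional flat
#' key = value config file, and direct overrides (in that order of
#' precedence, overrides last). Unknown keys are an error, guarding against
#' silent typos. The configuration is serialized verbatim into every output
#' directory for provenance.
#'
#' Config file format: one \code{key = value} pair per line; \code{#} starts
#' a comment; comma-separated values make vectors.
#'
#' @param path optional config file.
#' @param ... direct overrides of the documented keys.
#' @return object of class \code{run_config} (named list).
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- .RUN_DEFAULTS
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L) stop("malformed config line: ", ln)
      key <- trimws(kv[1L]); val <- trimws(kv[2L])
      if (!key %in% names(cfg)) stop("unknown config key: ", key)
      cfg[[key]] <- .parse_config_value(val, cfg[[key]])
    }
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$pixel_size <= 0) stop("pixel_size must be > 0")
  if (cfg$tile_size < 8) stop("tile_size must be >= 8")
  if (!cfg$polarity %in% c("dark_objects", "bright_objects"))
    stop("polarity must be dark_objects or bright_objects")
  if (cfg$min_area < 0) stop("min_area must be >= 0")
  structure(cfg, class = "run_config")
}

.parse_config_value <- function(val, template) {
  parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
  if (is.character(template)) return(if (length(parts) > 1L) parts else val)
  if (is.logical(template)) return(as.logical(toupper(parts)))
  num <- suppressWarnings(as.numeric(parts))
  if (any(is.na(num) & toupper(parts) != "NA")) return(parts)
  num
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (k in names(x)) cat(sprintf("  %s = %s\n", k, paste(x[[k]], collapse = ", ")))
  invisible(x)
}

.write_config <- function(cfg, dir) {
  lines <- vapply(names(cfg), function(k)
    sprintf("%s = %s", k, paste(cfg[[k]], collapse = ", ")), character(1))
  writeLines(lines, file.path(dir, "run_config.txt"))
}

.stack_path <- function(dir, well_id, day) {
  # days may be written as e.g. "5" or "5.0"; match on the canonical form
  file.path(dir, sprintf("%s_d%g.tif", well_id, day))
}

#' Quantify a plate: stacks -> per-object and per-well readout tables
#'
#' For every (well, day) stack found under the plate map, runs best-focus
#' projection, image-specific global thresholding, hole-filled binarization,
#' 8-connected particle extraction with debris filtering, and per-object
#' morphometrics; then aggregates the seven per-well readouts with intra-well
#' anchoring. Wells or days that cannot be processed (missing/unreadable
#' stack, degenerate image, zero anchor area) are skipped with a logged
#' reason and the run continues.
#'
#' @param config a [run_config()].
#' @param write write per_object.csv, per_well.csv, run_log.csv and the
#'   serialized config into \code{config$output_dir}?
#' @return list with \code{per_object}, \code{per_well} (both data.frames)
#'   and \code{log} (data.frame of well/day exclusions with reasons).
#' @export
quantify_plate <- function(config, write = TRUE) {
  stopifnot(inherits(config, "run_config"))
  pm <- read.csv(config$plate_map, stringsAsFactors = FALSE)
  need <- c("well_id", "sample_id", "drug", "concentration_nM", "replicate",
            "is_vehicle")
  if (!all(need %in% names(pm)))
    stop("plate map must have columns: ", paste(need, collapse = ", "))
  files <- list.files(config$stacks_dir, pattern = "_d[0-9.]+\\.tif$")
  log <- list(); per_object <- list(); per_well <- list()
  max_area <- if (is.na(config$max_area)) NULL else config$max_area
  for (w in seq_len(nrow(pm))) {
    wid <- pm$well_id[w]
    wfiles <- files[startsWith(files, paste0(wid, "_d"))]
    if (!length(wfiles)) {
      log[[length(log) + 1L]] <- data.frame(well_id = wid, day = NA_real_,
                                            reason = "no_images", stringsAsFactors = FALSE)
      warning("no images for well ", wid)
      next
    }
    days <- sort(as.numeric(sub("\\.tif$", "", sub(paste0(wid, "_d"), "", wfiles))))
    objs_well <- NULL
    for (day in days) {
      path <- .stack_path(config$stacks_dir, wid, day)
      res <- tryCatch({
        st <- read_zstack(path, pixel_size = config$pixel_size,
                          well_id = wid, day = day)
        proj <- best_focus_project(st, tile_size = config$tile_size)
        thr <- select_threshold(proj, polarity = config$polarity,
                                k = config$threshold_k)
        mask <- binarize(proj, thr)
        label_and_filter(mask, pixel_size = config$pixel_size,
                         min_area = config$min_area, max_area = max_area,
                         exclude_border = config$exclude_border)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        log[[length(log) + 1L]] <- data.frame(well_id = wid, day = day,
                                              reason = conditionMessage(res),
                                              stringsAsFactors = FALSE)
        next
      }
      if (nrow(res)) {
        res$well_id <- wid; res$day <- day
        objs_well <- rbind(objs_well, res)
        per_object[[length(per_object) + 1L]] <-
          data.frame(res[, c("well_id", "day", "label", "area_um2",
                             "perimeter_um", "diameter_um", "circularity",
                             "cx", "cy", "touches_border")],
                     stringsAsFactors = FALSE)
      }
    }
    if (is.null(objs_well))
      objs_well <- data.frame(day = numeric(0), area_um2 = numeric(0),
                              diameter_um = numeric(0),
                              perimeter_um = numeric(0),
                              circularity = numeric(0))
    ok_days <- setdiff(days, unlist(lapply(log, function(l)
      if (l$well_id == wid) l$day else NULL)))
    if (!length(ok_days)) next
    wr <- well_readouts(objs_well, days = ok_days)
    if (isTRUE(attr(wr, "unusable"))) {
      log[[length(log) + 1L]] <- data.frame(well_id = wid, day = NA_real_,
                                            reason = "zero_anchor_area",
                                            stringsAsFactors = FALSE)
    }
    meta <- pm[w, need, drop = FALSE]
    per_well[[length(per_well) + 1L]] <- data.frame(
      meta[rep(1, nrow(wr)), , drop = FALSE], wr,
      anchor_day = attr(wr, "anchor_day"),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  per_object <- if (length(per_object)) do.call(rbind, per_object) else
    data.frame()
  per_well <- if (length(per_well)) do.call(rbind, per_well) else data.frame()
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(well_id = character(0), day = numeric(0), reason = character(0))
  out <- list(per_object = per_object, per_well = per_well, log = log)
  if (write) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(per_object, file.path(config$output_dir, "per_object.csv"),
              row.names = FALSE)
    write.csv(per_well, file.path(config$output_dir, "per_well.csv"),
              row.names = FALSE)
    write.csv(log, file.path(config$output_dir, "run_log.csv"),
              row.names = FALSE)
    .write_config(config, config$output_dir)
  }
  out
}

#' Fit dose-response models across a quantified plate
#'
#' Normalizes treated wells to the vehicle mean per (sample, day, readout),
#' fits a 5PL model per combination, and derives ED50, GI50 and sensitivity
#' rankings. Results are written as one JSON record per fit, a tidy CSV of
#' fitted curve evaluations, and a ranking report.
#'
#' @param config a [run_config()]; \code{fit_readouts} and \code{fit_days}
#'   select what is fitted.
#' @param per_well per-well readout table (from [quantify_plate()]); read
#'   from \code{output_dir/per_well.csv} when NULL.
#' @param write write fits.json, curves.csv and ranking.csv to
#'   \code{config$output_dir}?
#' @return list with \code{fits} (named list of [fit_ll5()] objects, names
#'   \code{sample/day/readout}), \code{fit_table} (data.frame of parameters
#'   and derived doses), \code{curves}, \code{ranking}.
#' @export
fit_plate <- function(config, per_well = NULL, write = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(per_well))
    per_well <- read.csv(file.path(config$output_dir, "per_well.csv"),
                         stringsAsFactors = FALSE)
  if (!nrow(per_well)) stop("no per-well data to fit")
  if (!any(!per_well$is_vehicle)) stop("no treated wells")
  fits <- list(); fit_rows <- list(); curve_rows <- list()
  for (readout in config$fit_readouts) {
    days <- if (all(is.na(config$fit_days))) {
      anch <- max(per_well$anchor_day)
      sort(unique(per_well$day[per_well$day > anch]))
    } else config$fit_days
    pts_all <- normalize_to_control(per_well, readout = readout, days = days)
    for (s in unique(pts_all$sample_id)) for (d in unique(pts_all$day)) {
      pts <- pts_all[pts_all$sample_id == s & pts_all$day == d, , drop = FALSE]
      if (nrow(pts) < 4L) next
      fit <- tryCatch(fit_ll5(response ~ concentration_nM, pts),
                      error = function(e) e)
      key <- paste(s, d, readout, sep = "/")
      if (inherits(fit, "error")) {
        fit_rows[[length(fit_rows) + 1L]] <- data.frame(
          sample_id = s, day = d, readout = readout, error = conditionMessage(fit),
          stringsAsFactors = FALSE)
        next
      }
      fits[[key]] <- fit
      cf <- coef(fit)
      fit_rows[[length(fit_rows) + 1L]] <- data.frame(
        sample_id = s, day = d, readout = readout,
        b = cf["b"], c = cf["c"], d = cf["d"], e = cf["e"], f = cf["f"],
        ed50 = suppressWarnings(ed50(fit)), gi50 = gi50(fit),
        rss = fit$rss, n_points = fit$n_points, converged = fit$converged,
        four_param = fit$four_param, error = NA_character_,
        row.names = NULL, stringsAsFactors = FALSE)
      xs <- exp(seq(log(min(pts$concentration_nM)),
                    log(max(pts$concentration_nM)), length.out = 50))
      curve_rows[[length(curve_rows) + 1L]] <- data.frame(
        sample_id = s, day = d, readout = readout, concentration_nM = xs,
        fitted_response = predict(fit, xs), stringsAsFactors = FALSE)
    }
  }
  if (!length(fits)) stop("no condition yielded a usable dose-response fit")
  fit_table <- do.call(rbind, lapply(fit_rows, function(r) {
    miss <- setdiff(c("b","c","d","e","f","ed50","gi50","rss","n_points",
                      "converged","four_param","error"), names(r))
    for (m in miss) r[[m]] <- NA
    r[, c("sample_id","day","readout","b","c","d","e","f","ed50","gi50",
          "rss","n_points","converged","four_param","error")]
  }))
  curves <- do.call(rbind, curve_rows)

  # ranking on the latest fitted day of the primary readout
  ranking <- NULL
  prim <- config$fit_readouts[1L]
  sub <- fit_table[fit_table$readout == prim & is.na(fit_table$error), , drop = FALSE]
  if (nrow(sub)) {
    last_day <- max(sub$day)
    keys <- paste(sub$sample_id[sub$day == last_day], last_day, prim, sep = "/")
    day_fits <- fits[keys]
    names(day_fits) <- sub$sample_id[sub$day == last_day]
    if (length(day_fits) >= 2L) {
      ranking <- do.call(rbind, lapply(c("max_inhibition", "ed50", "gi50"),
        function(cr) {
          r <- rank_sensitivity(day_fits, cr)
          r$criterion <- cr; r$day <- last_day; r$readout <- prim
          r
        }))
    }
  }
  out <- list(fits = fits, fit_table = fit_table, curves = curves,
              ranking = ranking)
  if (write) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    json <- lapply(split(fit_table, seq_len(nrow(fit_table))), as.list)
    names(json) <- paste(fit_table$sample_id, fit_table$day,
                         fit_table$readout, sep = "/")
    jsonlite::write_json(json, file.path(config$output_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    write.csv(curves, file.path(config$output_dir, "curves.csv"),
              row.names = FALSE)
    if (!is.null(ranking))
      write.csv(ranking, file.path(config$output_dir, "ranking.csv"),
                row.names = FALSE)
  }
  out
}
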