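# Per-well time-series readouts, intra-well day-1 normalization, replicate
# summaries and readout correlations.

.READOUTS <- c("total_area_um2", "relative_total_area", "count",
               "mean_size_um2", "mean_diameter_um", "mean_perimeter_um",
               "mean_circularity")

#' Intra-well normalization of total area to the anchor day
#'
#' Divides a well's total-area series by its value on the first imaged
#' (anchor) day, the anchor mapping to exactly 1. This self-normalization
#' removes well-to-well differences in seeding density and absolute growth,
#' and is invariant under any global rescaling of the well's areas. A zero
#' anchor value makes the readout undefined for the whole well (all NA, with
#' an attribute recording the reason).
#'
#' @param total_area numeric vector of per-day total areas (um^2), in day
#'   order; the first element is the anchor day.
#' @return numeric vector of the same length; attribute \code{"anchor_index"}
#'   gives the anchor position, attribute \code{"unusable"} is TRUE when the
#'   anchor area was 0.
#' @examples
#' relative_total_area(c(1000, 2000, 4000)) # 1 2 4
#' @export
relative_total_area <- function(total_area) {
  if (length(total_area) == 0L) return(total_area)
  anchor <- total_area[1L]
  if (is.na(anchor) || anchor <= 0) {
    out <- rep(NA_real_, length(total_area))
    attr(out, "anchor_index") <- 1L
    attr(out, "unusable") <- TRUE
    return(out)
  }
  out <- total_area / anchor
  out[1L] <- 1
  attr(out, "anchor_index") <- 1L
  attr(out, "unusable") <- FALSE
  out
}

#' Per-well time-series readouts from measured objects
#'
#' Aggregates per-object morphometrics of one well into the seven per-day
#' readouts: total covered area, relative total area (anchored at the first
#' imaged day), object count, and the per-object means of size, diameter,
#' perimeter and circularity. Days with no objects get total area and count
#' 0 and missing means.
#'
#' @param objects data.frame of measured objects for one well, with columns
#'   \code{day}, \code{area_um2}, \code{diameter_um}, \code{perimeter_um},
#'   \code{circularity} (e.g. rows of [label_and_filter()] output plus a
#'   \code{day} column).
#' @param days imaging days to report (defaults to the days present); days
#'   without rows are reported as empty.
#' @return data.frame with one row per day and columns \code{day} plus the
#'   seven readouts; attribute \code{"anchor_day"} records the normalization
#'   anchor.
#' @export
well_readouts <- function(objects, days = sort(unique(objects$day))) {
  days <- sort(days)
  agg <- function(day) {
    o <- objects[objects$day == day, , drop = FALSE]
    n <- nrow(o)
    data.frame(day = day,
               total_area_um2 = if (n) sum(o$area_um2) else 0,
               count = n,
               mean_size_um2 = if (n) mean(o$area_um2) else NA_real_,
               mean_diameter_um = if (n) mean(o$diameter_um) else NA_real_,
               mean_perimeter_um = if (n) mean(o$perimeter_um) else NA_real_,
               mean_circularity = if (n) mean(o$circularity) else NA_real_)
  }
  out <- do.call(rbind, lapply(days, agg))
  rel <- relative_total_area(out$total_area_um2)
  out$relative_total_area <- as.numeric(rel)
  out <- out[, c("day", .READOUTS)]
  attr(out, "anchor_day") <- days[attr(rel, "anchor_index")]
  attr(out, "unusable") <- isTRUE(attr(rel, "unusable"))
  out
}

#' Replicate summary: mean, SEM and n per condition, day and readout
#'
#' Summarizes technical-replicate wells of the same condition. SEM is the
#' sample standard deviation (n - 1 denominator) over replicate wells divided
#' by sqrt(n); it is undefined (NA) for a single well. Wells with a missing
#' value are excluded per readout, with n adjusted accordingly.
#'
#' @param wells data.frame of per-well, per-day readouts with condition
#'   columns \code{sample_id}, \code{drug}, \code{concentration_nM},
#'   \code{day} and the readout columns of [well_readouts()].
#' @param readouts readout column names to summarize.
#' @return long data.frame: condition columns, \code{readout}, \code{mean},
#'   \code{sem}, \code{n}.
#' @export
replicate_stats <- function(wells, readouts = intersect(.READOUTS, names(wells))) {
  key <- interaction(wells$sample_id, wells$drug, wells$concentration_nM,
                     wells$day, drop = TRUE)
  out <- list()
  for (g in levels(key)) {
    sub <- wells[key == g, , drop = FALSE]
    for (r in readouts) {
      v <- sub[[r]]
      v <- v[!is.na(v)]
      n <- length(v)
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sub$sample_id[1L], drug = sub$drug[1L],
        concentration_nM = sub$concentration_nM[1L], day = sub$day[1L],
        readout = r,
        mean = if (n) mean(v) else NA_real_,
        sem = if (n > 1L) sd(v) / sqrt(n) else NA_real_,
        n = n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Pearson correlations between imaging readouts
#'
#' Correlation matrix of readouts (count excluded by default, matching its
#' weak coupling to the size-related readouts) over (well, day) observations,
#' using pairwise-complete observations. Zero-variance readouts yield NA for
#' their pairs.
#'
#' @param wells per-well, per-day readout data.frame (see [replicate_stats()]).
#' @param readouts readout columns to correlate; requires >= 3 paired
#'   observations overall.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
readout_correlations <- function(wells,
                                 readouts = setdiff(intersect(.READOUTS, names(wells)),
                                                    "count")) {
  m <- as.matrix(wells[, readouts, drop = FALSE])
  if (sum(complete.cases(m)) < 3L)
    stop("need at least 3 complete observations to correlate readouts")
  suppressWarnings(r <- cor(m, use = "pairwise.complete.obs"))
  diag(r) <- 1
  r
}
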