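# Index-selection procedure: range screening, bimodality screening, then
# ranking by per-class spread.

#' Select the classification index from diagnostics of all nine indices
#'
#' Implements the three-stage screening used to pick the visible-band index
#' for vegetation classification:
#' \enumerate{
#'   \item discard indices with any observed value outside the theoretical
#'     range;
#'   \item discard indices whose gray histogram shows no double peak
#'     (fewer than two major peaks, see [bimodality()]);
#'   \item rank the survivors by ascending mean per-class standard deviation.
#' }
#' Ties in stage (iii) are broken by the fixed index-name order of
#' [vi_names()].
#'
#' @param stats Named list (all nine indices) of [class_error_stats()] tables.
#' @param hists Named list of [vi_histogram()] objects for the same indices.
#' @param observed_ranges Named list of length-2 observed value ranges; by
#'   default recovered from each histogram's occupied bins.
#' @param prominence_frac,min_separation_frac Peak-detection parameters passed
#'   to [bimodality()].
#' @return Object of class `index_selection`: list with `chosen`, `ranking`
#'   (data frame over surviving indices) and `audit` (per-index data frame
#'   with range/bimodality verdicts and mean class sd).
#' @export
select_index <- function(stats, hists, observed_ranges = NULL,
                         prominence_frac = 0.05, min_separation_frac = 0.1) {
  need <- vi_names()
  if (!all(need %in% names(stats)) || !all(need %in% names(hists))) {
    stop("stats and hists must cover all nine indices: ",
         paste(setdiff(need, intersect(names(stats), names(hists))),
               collapse = ", "))
  }
  audit <- do.call(rbind, lapply(need, function(nm) {
    h <- hists[[nm]]
    rng <- vi_theoretical_range(nm)
    obs <- if (!is.null(observed_ranges)) observed_ranges[[nm]] else {
      nz <- which(h$counts > 0)
      c(h$bin_edges[min(nz)], h$bin_edges[max(nz) + 1])
    }
    in_range <- obs[1] >= rng[1] - 1e-12 && obs[2] <= rng[2] + 1e-12
    bm <- bimodality(h, prominence_frac, min_separation_frac)
    data.frame(index = nm,
               obs_min = obs[1], obs_max = obs[2], in_range = in_range,
               n_major_peaks = bm$n_major_peaks,
               double_peaks = bm$n_major_peaks >= 2L,
               mean_class_sd = mean(stats[[nm]]$sd))
  }))
  audit$survives <- audit$in_range & audit$double_peaks
  surv <- audit[audit$survives, , drop = FALSE]
  if (!nrow(surv)) {
    msg <- paste0(
      "all indices eliminated; diagnostics:\n",
      paste(sprintf("  %s: in_range=%s, major_peaks=%d", audit$index,
                    audit$in_range, audit$n_major_peaks), collapse = "\n"))
    stop(msg)
  }
  o <- order(surv$mean_class_sd, match(surv$index, need))
  ranking <- surv[o, c("index", "mean_class_sd", "n_major_peaks")]
  rownames(ranking) <- NULL
  structure(list(chosen = ranking$index[1], ranking = ranking, audit = audit),
            class = "index_selection")
}

#' @export
print.index_selection <- function(x, ...) {
  cat("<index_selection> chosen:", x$chosen, "\n")
  cat("ranking of survivors (ascending mean per-class sd):\n")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}

#' Run the full index-selection diagnostics on a labeled RGB raster
#'
#' Convenience wrapper: computes all nine index rasters, per-class error
#' statistics, gray histograms, observed ranges, and calls [select_index()].
#'
#' @param raster An [rgb_raster()].
#' @param labels Class raster aligned with it (character matrix or coded
#'   integer matrix with a `levels` attribute).
#' @param ... Passed to [select_index()].
#' @return An `index_selection` object with an extra `stats` element.
#' @export
select_index_for <- function(raster, labels, ...) {
  vis <- lapply(vi_names(), function(nm) compute_index(raster, nm))
  names(vis) <- vi_names()
  stats <- lapply(vis, class_error_stats, labels = labels)
  hists <- lapply(vis, vi_histogram)
  obs <- lapply(vis, function(v) range(v$values, na.rm = TRUE))
  sel <- select_index(stats, hists, observed_ranges = obs, ...)
  sel$stats <- stats
  sel
}
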