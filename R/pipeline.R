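#' Scan-level null distribution for sweep-statistic peaks
#'
#' Simulates whole neutral loci of the scanned length, applies the same
#' sliding-window scan and peak identification as the observed data, and
#' collects the per-replicate peak Zeng's E, minimum standardized Fay-Wu H
#' and minimum Tajima's D.  Comparing observed peaks against this null
#' accounts for the selection of the most extreme window, so the
#' end-to-end false-positive rate stays at the nominal level -- unlike a
#' comparison of a scanned peak against a single-window null.
#'
#' @param n,theta_site,rho_site neutral model parameters (per site).
#' @param length_bp scanned locus length.
#' @param window_bp,step_bp scan geometry.
#' @param reps replicates (default 1000).
#' @return object of class `scan_null`: sorted vectors `E_max`, `H_min`,
#'   `D_min` over replicates with at least one defined window.
#' @export
scan_null_distribution <- function(n = 22L, theta_site = 7.6e-3,
                                   rho_site = 2.5e-1, length_bp = 6000L,
                                   window_bp = 2000L, step_bp = 1000L,
                                   reps = 1000L) {
  L <- as.integer(length_bp)
  raw <- .sim_arg_cpp(n, theta_site * L, rho_site * L, as.integer(reps),
                      detail = FALSE)
  starts <- seq.int(0L, L - window_bp, by = step_bp)
  peaks <- vapply(raw, function(x) {
    bp <- x$pos * L
    ok <- FALSE
    best <- c(E = -Inf, H = Inf, D = Inf)
    for (s in starts) {
      cnt <- x$count[bp >= s & bp < s + window_bp]
      if (!length(cnt)) next
      sfs <- sfs_from_counts(n, cnt)
      e <- zengs_e(sfs); h <- fay_wu_h_std(sfs); d <- tajimas_d(sfs)
      if (is.na(e)) next
      ok <- TRUE
      best["E"] <- max(best["E"], e)
      best["H"] <- min(best["H"], h)
      best["D"] <- min(best["D"], d)
    }
    if (ok) best else c(E = NA_real_, H = NA_real_, D = NA_real_)
  }, numeric(3))
  def <- !is.na(peaks["E", ])
  structure(list(E_max = sort(peaks["E", def]),
                 H_min = sort(peaks["H", def]),
                 D_min = sort(peaks["D", def]),
                 n_defined = sum(def),
                 params = list(n = n, theta_site = theta_site,
                               rho_site = rho_site, length_bp = L,
                               window_bp = window_bp, step_bp = step_bp,
                               reps = reps)),
            class = "scan_null")
}

#' Run the sweep-detection pipeline on one locus
#'
#' Sliding-window scan, peak identification, empirical probabilities of the
#' observed peaks against a scan-level neutral null, and the significance
#' rule (`P(Sim <= Obs) >= 0.95` for E; `< 0.05` for H and D).  The locus is
#' called swept when at least two of the three statistics are significant: a
#' majority vote over the panel, robust to the fact that the statistics peak
#' at different sweep ages (H immediately after fixation, E later during
#' recovery, D with the excess of rare recovering variants).
#'
#' @param locus a [haplotype_window()] (for example read with
#'   [read_haplotype_fasta()] or generated by [gen_sweep_locus()]).
#' @param null a `scan_null` from [scan_null_distribution()] matching the
#'   scan geometry; if `NULL` one is simulated (slow -- prefer building it
#'   once and reusing it across loci).
#' @param window_bp,step_bp scan geometry (defaults 2000 / 1000).
#' @param null_reps replicates when `null` must be built here.
#' @param out_dir optional directory: writes `scan.bed`, `peaks.tsv` and
#'   `report.json`.
#' @return list of class `sweep_report`: `track`, `peaks`, `call`
#'   (a `sweep_call`), `sweep_detected`.
#' @export
run_sweep_pipeline <- function(locus, null = NULL, window_bp = 2000L,
                               step_bp = 1000L, null_reps = 1000L,
                               out_dir = NULL) {
  track <- sliding_scan(locus, window_bp, step_bp)
  peaks <- find_peaks(track)
  if (is.null(null)) {
    null <- scan_null_distribution(
      n = length(locus$sequences),
      length_bp = locus$end - locus$start,
      window_bp = window_bp, step_bp = step_bp, reps = null_reps)
  }
  call <- call_significance(
    p_E = empirical_p(null$E_max, peaks$E$value),
    p_H = empirical_p(null$H_min, peaks$H$value),
    p_D = empirical_p(null$D_min, peaks$D$value))
  n_sig <- sum(call$significant_E, call$significant_H, call$significant_D)
  report <- structure(list(track = track, peaks = peaks, call = call,
                           n_significant = n_sig,
                           sweep_detected = n_sig >= 2L),
                      class = "sweep_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_bed(track, file.path(out_dir, "scan.bed"),
              header = sprintf("window=%d step=%d", window_bp, step_bp))
    pk <- do.call(rbind, Map(cbind, stat = names(peaks), peaks))
    utils::write.table(pk, file.path(out_dir, "peaks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(p_E = call$p_E, p_H = call$p_H, p_D = call$p_D,
           significant_E = call$significant_E,
           significant_H = call$significant_H,
           significant_D = call$significant_D,
           sweep_detected = report$sweep_detected),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.sweep_report <- function(x, ...) {
  cat("sweep_report:\n")
  cat(sprintf("  E peak %.3f at [%d, %d)\n", x$peaks$E$value,
              x$peaks$E$start, x$peaks$E$end))
  cat(sprintf("  H peak %.3f at [%d, %d)\n", x$peaks$H$value,
              x$peaks$H$start, x$peaks$H$end))
  cat(sprintf("  D peak %.3f at [%d, %d)\n", x$peaks$D$value,
              x$peaks$D$start, x$peaks$D$end))
  print(x$call)
  cat(sprintf("  sweep detected: %s\n", x$sweep_detected))
  invisible(x)
}
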