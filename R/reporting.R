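#' Root-mean-square deviation between two sampled curves
#'
#' `sqrt(mean((a - b)^2))` over samples taken on the same flexion grid.
#'
#' @param curve_a,curve_b Equal-length numeric vectors.
#' @return Nonnegative scalar in the curves' units.
#' @export
rmsd <- function(curve_a, curve_b) {
  if (length(curve_a) != length(curve_b))
    stop("curves must have the same length")
  sqrt(mean((curve_a - curve_b)^2))
}

#' Percent reduction of a deviation
#'
#' `100 * (baseline - optimized) / baseline`; displayed values are
#' conventionally rounded to one decimal.
#'
#' @param baseline Baseline deviation (> 0).
#' @param optimized Post-optimization deviation.
#' @return Percent reduction (negative if the deviation grew).
#' @export
percent_reduction <- function(baseline, optimized) {
  if (any(!is.finite(baseline)) || any(baseline <= 0))
    stop("baseline must be > 0")
  100 * (baseline - optimized) / baseline
}

#' RMSD report between a post-operative and a pre-diseased trace
#'
#' Per-variable kinematic RMSDs (ap/lm/pd in mm, ei/vv in degrees; flexion
#' is the driven coordinate and is excluded), per-ligament strain RMSDs in
#' percent (over the ligaments common to both traces, i.e. excluding the
#' resected ACL when comparing against an implanted knee), and the conventional
#' summaries: translations mean +/- sd over {ap, lm, pd} and rotations
#' mean +/- sd over {ei, vv}, both with the sample (n-1) standard deviation.
#'
#' @param pre_trace,post_trace `simulation_trace`s on the same flexion grid.
#' @return List of class `rmsd_report`: `kinematic` (named, mm / deg),
#'   `strain_pct` (named, percent), `translation_mean`, `translation_sd`,
#'   `rotation_mean`, `rotation_sd`.
#' @export
build_report <- function(pre_trace, post_trace) {
  check_same_grid(pre_trace, post_trace)
  kin <- vapply(KIN_VARS, function(v)
    rmsd(post_trace$pose[[v]], pre_trace$pose[[v]]), numeric(1))
  ligs <- intersect(pre_trace$ligaments, post_trace$ligaments)
  strain <- vapply(ligs, function(lg)
    100 * rmsd(post_trace$strain[, lg], pre_trace$strain[, lg]), numeric(1))
  tr <- kin[c("ap", "lm", "pd")]
  ro <- kin[c("ei", "vv")]
  structure(list(kinematic = kin, strain_pct = strain,
                 translation_mean = mean(tr), translation_sd = stats::sd(tr),
                 rotation_mean = mean(ro), rotation_sd = stats::sd(ro)),
            class = "rmsd_report")
}

#' @export
print.rmsd_report <- function(x, ...) {
  cat(sprintf("RMSD vs pre-diseased: %.1f +/- %.1f mm (translations), %.1f +/- %.1f deg (rotations)\n",
              x$translation_mean, x$translation_sd,
              x$rotation_mean, x$rotation_sd))
  cat("  per-variable:",
      paste(sprintf("%s %.2f", names(x$kinematic), x$kinematic), collapse = ", "),
      "\n")
  cat("  strains (%):",
      paste(sprintf("%s %.2f", names(x$strain_pct), x$strain_pct), collapse = ", "),
      "\n")
  invisible(x)
}

#' Serialize an RMSD report to a one-row data frame / CSV
#'
#' Columns: each kinematic variable (`rmsd_ap_mm`, ...), each ligament
#' (`rmsd_<name>_pct`), and the four summary fields. [report_from_row()]
#' restores the report losslessly.
#'
#' @param report An `rmsd_report`.
#' @param label Row label (e.g. `"MA"`, `"ST1"`).
#' @return Data frame with one row.
#' @export
report_to_row <- function(report, label = NA_character_) {
  stopifnot(inherits(report, "rmsd_report"))
  kin <- as.list(stats::setNames(report$kinematic,
    sprintf("rmsd_%s_%s", names(report$kinematic),
            ifelse(names(report$kinematic) %in% c("ei", "vv"), "deg", "mm"))))
  st <- as.list(stats::setNames(report$strain_pct,
    sprintf("rmsd_%s_pct", names(report$strain_pct))))
  data.frame(c(list(label = label), kin, st,
               list(translation_mean = report$translation_mean,
                    translation_sd = report$translation_sd,
                    rotation_mean = report$rotation_mean,
                    rotation_sd = report$rotation_sd)),
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname report_to_row
#' @param row One row of the data frame written by [report_to_row()].
#' @export
report_from_row <- function(row) {
  nm <- names(row)
  kin_cols <- grep("^rmsd_(ap|lm|pd|ei|vv)_", nm, value = TRUE)
  st_cols <- grep("^rmsd_[A-Za-z]+_pct$", nm, value = TRUE)
  kin <- stats::setNames(as.numeric(row[kin_cols]),
                         sub("^rmsd_([a-z]+)_.*$", "\\1", kin_cols))
  st <- stats::setNames(as.numeric(row[st_cols]),
                        sub("^rmsd_([A-Za-z]+)_pct$", "\\1", st_cols))
  structure(list(kinematic = kin, strain_pct = st,
                 translation_mean = as.numeric(row[["translation_mean"]]),
                 translation_sd = as.numeric(row[["translation_sd"]]),
                 rotation_mean = as.numeric(row[["rotation_mean"]]),
                 rotation_sd = as.numeric(row[["rotation_sd"]])),
            class = "rmsd_report")
}

#' Kinematic and strain curve overlays
#'
#' ggplot2 overlays of the pre-diseased, MA and optimized traces (one facet
#' per kinematic coordinate or per ligament), mirroring the standard way
#' such extension trials are reported. Requires ggplot2.
#'
#' @param traces Named list of `simulation_trace`s (e.g.
#'   `list(pre_diseased = ..., MA = ..., ST5 = ...)`).
#' @param what `"kinematics"` or `"strains"`.
#' @return A ggplot object.
#' @export
plot_trace_overlay <- function(traces, what = c("kinematics", "strains")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_trace_overlay requires ggplot2")
  what <- match.arg(what)
  long <- do.call(rbind, lapply(names(traces), function(nm) {
    tr <- traces[[nm]]
    if (what == "kinematics") {
      do.call(rbind, lapply(KIN_VARS, function(v)
        data.frame(model = nm, flexion = tr$pose$fe, variable = v,
                   value = tr$pose[[v]])))
    } else {
      do.call(rbind, lapply(tr$ligaments, function(lg)
        data.frame(model = nm, flexion = tr$pose$fe, variable = lg,
                   value = 100 * tr$strain[, lg])))
    }
  }))
  ylab <- if (what == "kinematics") "translation (mm) / rotation (deg)"
          else "strain (%)"
  ggplot2::ggplot(long, ggplot2::aes(x = flexion, y = value,
                                     colour = model)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "knee flexion (deg)", y = ylab, colour = NULL)
}
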