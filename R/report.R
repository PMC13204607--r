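# Reporting: error bars per index/mode and repeatability-threshold flags.

#' Spirometry repeatability thresholds
#'
#' The between-maneuver agreement limits used as error benchmarks:
#' 0.15 L for FVC and FEV1 (ATS/ERS repeatability criterion) and
#' 0.67 L/s for PEF (earlier guideline).
#'
#' @return Named numeric vector over `fvc_ref`, `fev1_ref`, `pef_ref`.
#' @export
repeatability_thresholds <- function() {
  c(fvc_ref = 0.15, fev1_ref = 0.15, pef_ref = 0.67)
}

#' Assemble the evaluation report
#'
#' Collects subject-level error summaries per spirometric index and
#' breathing mode into a flag table (does each LOSO RMSE meet the
#' repeatability threshold for its index?) and a bar chart of RMSE/MAE
#' with standard-error bars. Regeneration from the same inputs is
#' deterministic.
#'
#' @param summaries data.frame with columns `index`, `mode`, `stage`,
#'   `rmse`, `mae`, `se_rmse`, `se_mae` (one row per index/mode/stage), or
#'   a list of [summarize_errors()] objects with `index`/`mode` attached.
#' @param mixed_results Optional list of [compare_modes()] results.
#' @return List of class `spiro_report`: `table` (flag table), `mixed`
#'   (mode-comparison p-values), `plot` (ggplot object).
#' @export
build_report <- function(summaries, mixed_results = NULL) {
  df <- if (is.data.frame(summaries)) summaries else
    do.call(rbind, lapply(summaries, function(s) {
      data.frame(index = s$index %||% NA_character_,
                 mode = s$mode %||% NA_character_,
                 stage = s$stage, rmse = s$mean_rmse, mae = s$mean_mae,
                 se_rmse = s$se_rmse, se_mae = s$se_mae,
                 stringsAsFactors = FALSE)
    }))
  thr <- repeatability_thresholds()
  df$threshold <- unname(thr[df$index])
  df$meets_threshold <- df$rmse <= df$threshold
  mixed <- if (!is.null(mixed_results))
    data.frame(
      index = vapply(mixed_results, function(m) m$index, character(1)),
      mode_effect = vapply(mixed_results, function(m)
        m$fixed_effect_mode[["estimate"]], numeric(1)),
      p_value = vapply(mixed_results, function(m) m$p_value, numeric(1)),
      stringsAsFactors = FALSE)
  else NULL
  structure(list(table = df, mixed = mixed, plot = report_plot(df)),
            class = "spiro_report")
}

report_plot <- function(df) {
  long <- rbind(
    data.frame(index = df$index, mode = df$mode, stage = df$stage,
               metric = "RMSE", value = df$rmse, se = df$se_rmse),
    data.frame(index = df$index, mode = df$mode, stage = df$stage,
               metric = "MAE", value = df$mae, se = df$se_mae))
  ggplot2::ggplot(long, ggplot2::aes(x = index, y = value, fill = metric)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = value - se, ymax = value + se),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::facet_grid(stage ~ mode) +
    ggplot2::scale_fill_manual(values = c(RMSE = "#1f4e79", MAE = "#9dc3e6")) +
    ggplot2::labs(x = NULL, y = "Error (L or L/s)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
print.spiro_report <- function(x, ...) {
  cat("<spiro_report>\n")
  tab <- x$table
  for (k in seq_len(nrow(tab)))
    cat(sprintf("  %-9s %-10s %-8s RMSE %.3f / MAE %.3f  [thr %.2f: %s]\n",
                tab$index[k], tab$mode[k], tab$stage[k], tab$rmse[k],
                tab$mae[k], tab$threshold[k],
                if (isTRUE(tab$meets_threshold[k])) "pass" else "fail"))
  if (!is.null(x$mixed))
    for (k in seq_len(nrow(x$mixed)))
      cat(sprintf("  mode effect on %s: %.4g (p = %.3f)\n",
                  x$mixed$index[k], x$mixed$mode_effect[k],
                  x$mixed$p_value[k]))
  invisible(x)
}
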