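# CSV/JSON dialects shared by the pipeline. All text output is UTF-8 with
# '.' decimal separator and LF line endings.

write_lf_csv <- function(df, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read and write RTCA traces
#'
#' On-disk dialect: CSV with header `time_h,nci`, where `nci` is the
#' normalized cell index (1.0 at time 0).
#'
#' @param path CSV path.
#' @param df `data.frame(time_h, nci)`.
#' @return `read_rtca_csv` returns the data frame; writers return `path`
#'   invisibly.
#' @export
read_rtca_csv <- function(path) {
  if (!file.exists(path)) stop_invalid_input(paste0("input not found: ", path))
  df <- utils::read.csv(path)
  if (!all(c("time_h", "nci") %in% names(df))) {
    stop_invalid_input("RTCA CSV must have columns time_h,nci")
  }
  if (any(!is.finite(df$time_h)) || any(!is.finite(df$nci)) || any(df$nci < 0)) {
    stop_invalid_input("RTCA CSV contains non-finite or negative values")
  }
  df[c("time_h", "nci")]
}

#' @rdname read_rtca_csv
#' @export
write_rtca_csv <- function(df, path) write_lf_csv(df[c("time_h", "nci")], path)

#' Extract an RTCA fit series from a trace
#'
#' Picks the rows of a `time_h,nci` trace at the requested fit times
#' (default the standard five: 24/36/48/60/72 h) and returns them as a
#' percent-viability series (`nci * 100`).
#'
#' @param df `data.frame(time_h, nci)`.
#' @param times Fit times in hours.
#' @return A [viability_series] with modality `"RTCA"`.
#' @export
rtca_fit_series <- function(df, times = rtca_fit_times()) {
  idx <- match_times(times, df$time_h)
  viability_series(times, 100 * df$nci[idx], modality = "RTCA")
}

#' Read and write flow-cytometry snapshots
#'
#' On-disk dialect: CSV with header
#' `time_h,viable_pct,early_pct,late_pct,necrosis_pct`; each row's four
#' fractions must sum to 100 (tolerance 1e-6 on file input, to absorb
#' decimal formatting).
#'
#' @param path CSV path.
#' @param fractions A list of [flow_fractions].
#' @return `read_flow_csv` returns a list of [flow_fractions]; the writer
#'   returns `path` invisibly.
#' @export
read_flow_csv <- function(path) {
  if (!file.exists(path)) stop_invalid_input(paste0("input not found: ", path))
  df <- utils::read.csv(path)
  need <- c("time_h", "viable_pct", "early_pct", "late_pct", "necrosis_pct")
  if (!all(need %in% names(df))) {
    stop_invalid_input(paste0("flow CSV must have columns ",
                              paste(need, collapse = ",")))
  }
  sums <- rowSums(df[need[-1]])
  if (any(abs(sums - 100) > 1e-6)) {
    stop_invalid_input(sprintf(
      "flow fractions must sum to 100 in every row (worst row sums to %.6g)",
      sums[which.max(abs(sums - 100))]))
  }
  lapply(seq_len(nrow(df)), function(i) {
    fr <- df[i, ]
    # renormalize away formatting round-off before the strict constructor
    tot <- sum(fr$viable_pct, fr$early_pct, fr$late_pct, fr$necrosis_pct)
    flow_fractions(fr$time_h, 100 * fr$viable_pct / tot,
                   100 * fr$early_pct / tot, 100 * fr$late_pct / tot,
                   100 * fr$necrosis_pct / tot)
  })
}

#' @rdname read_flow_csv
#' @export
write_flow_csv <- function(fractions, path) {
  df <- do.call(rbind, lapply(fractions, function(x) {
    data.frame(time_h = x$t, viable_pct = x$viable_pct,
               early_pct = x$early_pct, late_pct = x$late_pct,
               necrosis_pct = x$necrosis_pct)
  }))
  write_lf_csv(df, path)
}

#' Pooled viability series from flow snapshots
#'
#' @param fractions A list of [flow_fractions].
#' @return A [viability_series] with modality `"flow"`.
#' @export
flow_series <- function(fractions) {
  viability_series(vapply(fractions, `[[`, numeric(1), "t"),
                   vapply(fractions, pooled_viability, numeric(1)),
                   modality = "flow")
}

#' Write an estimation result as JSON
#'
#' Serializes parameters, final SE, relative changes, bounds, seed and
#' optimizer diagnostics (full double precision; deterministic byte output
#' for identical results).
#'
#' @param result An `estimation_result`.
#' @param path Output path.
#' @param extra Optional named list merged into the JSON (e.g. a config
#'   echo).
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, path, extra = NULL) {
  obj <- list(
    params = unclass(result$params),
    se = result$se,
    free = result$free,
    frozen = as.list(result$frozen_values),
    rel_change_pct = if (is.null(result$rel_change_pct)) NULL else
      as.list(result$rel_change_pct),
    bounds = lapply(result$bounds, as.list),
    stage1 = list(seed = result$stage1$seed,
                  n_starts = result$stage1$n_starts,
                  best_start = result$stage1$best_start,
                  values = result$stage1$values,
                  convergence = result$stage1$convergence),
    stage2 = result$stage2,
    n_eval = result$n_eval)
  if (!is.null(extra)) obj <- c(obj, extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
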