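# Residue screening: detection counts, concentration summaries over the
# detected samples, and strict (> MRL) exceedance screening, laid out one
# row per pesticide as in regulatory survey tables.

#' Summarize residues of one pesticide across samples
#'
#' Statistics are computed over *detected* samples only (survey tables
#' report ranges and means of detects); detection and exceedance
#' percentages are relative to all samples. Both the SD and the standard
#' error of the mean are reported, since published survey tables are often
#' ambiguous about which accompanies the mean.
#'
#' @param records a residue table (data frame with columns `sample_id`,
#'   `pesticide`, `concentration_ug_per_kg`, `detected`).
#' @param pesticide pesticide name; must occur in `records`.
#' @return an object of class `residue_summary`: list with `pesticide`,
#'   `n_total`, `n_detected`, `detection_pct`, `min`, `max`, `mean`, `sd`,
#'   `se` (all ug/kg; NA when there are no detects).
#' @examples
#' rt <- data.frame(sample_id = sprintf("S%d", 1:5), pesticide = "x",
#'                  concentration_ug_per_kg = c(2, 4, 6, NA, NA),
#'                  detected = c(1, 1, 1, 0, 0))
#' summarize_residues(rt, "x")
#' @export
summarize_residues <- function(records, pesticide) {
  check_residue_table(records)
  rows <- records[records$pesticide == pesticide, ]
  if (nrow(rows) == 0) stop("unknown pesticide: ", pesticide)
  det <- rows$concentration_ug_per_kg[rows$detected == 1]
  n_tot <- nrow(rows)
  n_det <- length(det)
  s <- if (n_det > 0) {
    list(min = min(det), max = max(det), mean = mean(det),
         sd = if (n_det > 1) stats::sd(det) else 0)
  } else {
    list(min = NA_real_, max = NA_real_, mean = NA_real_, sd = NA_real_)
  }
  structure(
    list(pesticide = pesticide, n_total = n_tot, n_detected = n_det,
         detection_pct = 100 * n_det / n_tot,
         min = s$min, max = s$max, mean = s$mean, sd = s$sd,
         se = if (n_det > 0) s$sd / sqrt(n_det) else NA_real_),
    class = "residue_summary")
}

#' Screen one pesticide's residues against its MRL
#'
#' A sample is flagged iff its concentration strictly exceeds the MRL
#' (regulatory convention: a residue *at* the limit complies). Non-detects
#' never exceed. The exceedance percentage is returned at full precision;
#' display rounding to one decimal is applied by [render_summary()] only.
#'
#' @param records a residue table (see [summarize_residues()]).
#' @param mrl_table named numeric vector, pesticide -> MRL (ug/kg, > 0).
#' @param pesticide pesticide name; must be present in `mrl_table`.
#' @return list with `flags` (logical per sample of this pesticide, named
#'   by `sample_id`), `n_above`, `pct_above` (percent of all samples).
#' @examples
#' rt <- data.frame(sample_id = c("a", "b"), pesticide = "x",
#'                  concentration_ug_per_kg = c(12, 10), detected = c(1, 1))
#' mrl_exceedances(rt, c(x = 10), "x")$n_above  # 1: exactly-at-MRL complies
#' @export
mrl_exceedances <- function(records, mrl_table, pesticide) {
  check_residue_table(records)
  if (!pesticide %in% names(mrl_table))
    stop("no MRL available for pesticide: ", pesticide)
  mrl <- mrl_table[[pesticide]]
  if (mrl <= 0) stop("MRL must be > 0")
  rows <- records[records$pesticide == pesticide, ]
  if (nrow(rows) == 0) stop("unknown pesticide: ", pesticide)
  flags <- rows$detected == 1 & !is.na(rows$concentration_ug_per_kg) &
    rows$concentration_ug_per_kg > mrl
  names(flags) <- rows$sample_id
  list(flags = flags, n_above = sum(flags),
       pct_above = 100 * sum(flags) / nrow(rows))
}

#' Survey summary table, one row per pesticide
#'
#' Combines [summarize_residues()] and [mrl_exceedances()] into a single
#' machine-readable table in the row order of `mrl_table` (pesticides in
#' `records` but absent from `mrl_table` raise an error, so MRL coverage is
#' checked up front).
#'
#' @param records a residue table.
#' @param mrl_table named numeric vector, pesticide -> MRL (ug/kg).
#' @return data frame of class `residue_summary_table` with columns
#'   `pesticide`, `n_total`, `n_detected`, `detection_pct`, `n_above_mrl`,
#'   `pct_above_mrl`, `min`, `max`, `mean`, `sd`, `se`, `mrl`.
#' @export
build_summary_table <- function(records, mrl_table) {
  check_residue_table(records)
  present <- unique(records$pesticide)
  missing_mrl <- setdiff(present, names(mrl_table))
  if (length(missing_mrl))
    stop("no MRL for pesticide(s): ", paste(missing_mrl, collapse = ", "))
  order_ <- intersect(names(mrl_table), present)
  rows <- lapply(order_, function(p) {
    s <- summarize_residues(records, p)
    e <- mrl_exceedances(records, mrl_table, p)
    data.frame(pesticide = p, n_total = s$n_total, n_detected = s$n_detected,
               detection_pct = s$detection_pct, n_above_mrl = e$n_above,
               pct_above_mrl = e$pct_above, min = s$min, max = s$max,
               mean = s$mean, sd = s$sd, se = s$se, mrl = mrl_table[[p]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("residue_summary_table", "data.frame")
  out
}

check_residue_table <- function(records) {
  need <- c("sample_id", "pesticide", "concentration_ug_per_kg", "detected")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("residue table is missing column(s): ", paste(miss, collapse = ", "))
  bad <- records$detected == 1 &
    (is.na(records$concentration_ug_per_kg) | records$concentration_ug_per_kg <= 0)
  if (any(bad))
    stop("detected records must carry a positive concentration (rows: ",
         paste(utils::head(which(bad), 5), collapse = ", "), ")")
  invisible(records)
}
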