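#' Cell-in-cell rate
#'
#' The CIC rate is the percentage quotient of CIC structures over all viable
#' cells in the sample (hosts included): `100 * n_cic / n_viable`.
#'
#' @param n_cic number of accepted CIC structures (>= 0).
#' @param n_viable number of viable cells (>= 0).
#' @return Percentage; `NA` (undefined) when `n_viable` is 0 - a sample with
#'   no viable cells has no rate, not a zero rate.
#' @export
cic_rate <- function(n_cic, n_viable) {
  if (any(n_cic < 0) || any(n_viable < 0))
    stop("counts must be >= 0", call. = FALSE)
  ifelse(n_viable > 0, 100 * n_cic / n_viable, NA_real_)
}

#' Cell-in-cell density
#'
#' CIC structures per square millimetre of tissue. The denominator is the
#' nominal core area by default (pi/4 mm^2 for the standard 1-mm spot); see
#' [core_area_mm2()].
#'
#' @param n_cic number of CIC structures (>= 0).
#' @param area_mm2 evaluated area in mm^2 (> 0).
#' @return Events per mm^2.
#' @export
cic_density <- function(n_cic, area_mm2) {
  if (any(n_cic < 0)) stop("counts must be >= 0", call. = FALSE)
  if (any(area_mm2 <= 0)) stop("area_mm2 must be > 0", call. = FALSE)
  n_cic / area_mm2
}

#' Summarize one sample (image or core)
#'
#' Counts objects and accepted events and fills the mode-appropriate
#' statistic: CIC rate (%) for co-incubation images, CIC/mm^2 for tissue
#' cores. Viable counts include host cells and dead counts include engulfed
#' cells, matching the convention that the rate divides by *all* viable
#' cells.
#'
#' @param sample_id identifier.
#' @param mode `"coincubation"` or `"tissue"`.
#' @param n_viable,n_dead,n_cic counts; in fluorescence mode derive them as
#'   `length(viable)`, `length(dead)`, `sum(events$accepted)`.
#' @param area_mm2 evaluated area (tissue mode).
#' @param ecad_score,t_stage,n_stage,m_stage optional tissue annotations.
#' @return A one-row data frame (a `SampleSummary`).
#' @export
summarize_sample <- function(sample_id, mode = c("coincubation", "tissue"),
                             n_viable = NA_integer_, n_dead = NA_integer_,
                             n_cic = 0L, area_mm2 = NA_real_,
                             ecad_score = NA_integer_,
                             t_stage = NA_character_, n_stage = NA_character_,
                             m_stage = NA_character_) {
  mode <- match.arg(mode)
  if (!is.na(n_dead) && n_cic > n_dead)
    stop("n_cic cannot exceed n_dead (every CIC structure is a dead cell)",
         call. = FALSE)
  data.frame(sample_id = as.character(sample_id), mode = mode,
             n_viable = n_viable, n_dead = n_dead, n_cic = n_cic,
             cic_rate_percent = if (mode == "coincubation" && !is.na(n_viable))
               cic_rate(n_cic, n_viable) else NA_real_,
             area_mm2 = area_mm2,
             cic_per_mm2 = if (mode == "tissue" && !is.na(area_mm2))
               cic_density(n_cic, area_mm2) else NA_real_,
             ecad_score = ecad_score, t_stage = t_stage, n_stage = n_stage,
             m_stage = m_stage, stringsAsFactors = FALSE)
}

#' Summarize a scene analysis
#'
#' Convenience wrapper building a `SampleSummary` from an [analyze_scene()]
#' result.
#'
#' @param sample_id identifier.
#' @param analysis result of [analyze_scene()].
#' @return A one-row data frame.
#' @export
summarize_scene <- function(sample_id, analysis) {
  summarize_sample(sample_id, "coincubation",
                   n_viable = length(analysis$viable),
                   n_dead = length(analysis$dead),
                   n_cic = sum(analysis$events$accepted))
}

#' Summarize a tissue core from its truth record or manual counts
#'
#' @param sample_id identifier.
#' @param truth the `truth` element of [generate_tissue_core()], or any list
#'   with `n_cic`, `area_mm2`, `ecad_level` and stage labels.
#' @param ecad_score optional measured score overriding the generating level.
#' @return A one-row data frame.
#' @export
summarize_core <- function(sample_id, truth, ecad_score = NULL) {
  area <- truth$area_mm2 %||%
    (if (!is.null(truth$core_diameter_mm)) core_area_mm2(truth$core_diameter_mm)
     else NA_real_)
  summarize_sample(sample_id, "tissue",
                   n_viable = truth$n_cells %||% NA_integer_,
                   n_dead = NA_integer_, n_cic = truth$n_cic,
                   area_mm2 = area,
                   ecad_score = ecad_score %||% truth$ecad_level,
                   t_stage = truth$t_stage %||% NA_character_,
                   n_stage = truth$n_stage %||% NA_character_,
                   m_stage = truth$m_stage %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

MIN_GROUP_FOR_SIGNIFICANCE <- 5L

#' Aggregate per-core summaries by a grouping label
#'
#' Mean and sample SD of CIC/mm^2 per group, the fraction of samples with at
#' least one CIC structure (the percent-of-biopsies statistic), and the
#' significance-eligibility flag: groups with fewer than 5 samples are never
#' entered into significance testing. Unknown stages form their own group.
#'
#' @param summaries data frame of `SampleSummary` rows (tissue mode).
#' @param group_key column name to group by (e.g. `"n_stage"`,
#'   `"ecad_score"`).
#' @return A data frame with one row per group: `group`, `n_samples`,
#'   `mean_cic_per_mm2`, `sd_cic_per_mm2`, `fraction_with_cic`,
#'   `significance_eligible`.
#' @export
aggregate_groups <- function(summaries, group_key) {
  if (!group_key %in% names(summaries))
    stop("no column '", group_key, "' in summaries", call. = FALSE)
  g <- as.character(summaries[[group_key]])
  g[is.na(g)] <- "unknown"
  out <- lapply(split(seq_len(nrow(summaries)), g), function(k) {
    dens <- summaries$cic_per_mm2[k]
    data.frame(group = g[k[1L]], n_samples = length(k),
               mean_cic_per_mm2 = mean(dens),
               sd_cic_per_mm2 = if (length(k) > 1L) stats::sd(dens) else NA_real_,
               fraction_with_cic = mean(summaries$n_cic[k] >= 1),
               significance_eligible = length(k) >= MIN_GROUP_FOR_SIGNIFICANCE,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out[order(names(out))])
  rownames(res) <- NULL
  res
}

#' Aggregate cell-line results for one culture condition
#'
#' Reports both the unweighted mean and SD of the per-line CIC rates (the
#' mean-of-lines statistic usually quoted for adherent vs suspension
#' comparisons) and the pooled totals with the pooled rate. The two
#' deliberately stay side by side: they answer different questions and can
#' disagree when line sizes are unbalanced.
#'
#' @param lines data frame with one row per cell line: `line`, `n_viable`,
#'   `n_dead`, `n_cic`.
#' @param condition label, e.g. `"adherent"` or `"suspension"`.
#' @return A list with `condition`, `n_lines`, `mean_rate`, `sd_rate`
#'   (unweighted over lines; SD is `NA` for a single line), per-line means
#'   of the counts, `pooled` (summed counts and the pooled rate), and the
#'   per-line `rates`.
#' @export
aggregate_cell_lines <- function(lines, condition) {
  need <- c("line", "n_viable", "n_dead", "n_cic")
  if (!all(need %in% names(lines)))
    stop("lines must have columns ", paste(need, collapse = ", "), call. = FALSE)
  rates <- cic_rate(lines$n_cic, lines$n_viable)
  pooled <- list(n_viable = sum(lines$n_viable), n_dead = sum(lines$n_dead),
                 n_cic = sum(lines$n_cic))
  pooled$rate <- cic_rate(pooled$n_cic, pooled$n_viable)
  list(condition = condition, n_lines = nrow(lines),
       mean_rate = mean(rates, na.rm = TRUE),
       sd_rate = if (nrow(lines) > 1L) stats::sd(rates, na.rm = TRUE) else NA_real_,
       mean_viable_per_line = pooled$n_viable / nrow(lines),
       mean_dead_per_line = pooled$n_dead / nrow(lines),
       mean_cic_per_line = pooled$n_cic / nrow(lines),
       pooled = pooled, rates = stats::setNames(rates, lines$line))
}
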