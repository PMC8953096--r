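component_cols <- c(
  "short T2" = "t2_short", "long T2" = "t2_long",
  "short fraction" = "frac_short", "long fraction" = "frac_long"
)

#' Two-group comparison of every structure and component
#'
#' For each structure and each of the four components (short/long T2,
#' short/long fraction), compares the displacement and no-displacement
#' groups with a two-sample Student t-test on subject-level ROI means
#' (pooled variance by default), checks per-group normality with
#' Shapiro-Wilk, and flags results against the Bonferroni-corrected
#' threshold `family_alpha / m` (default 0.05 / 4 = 0.0125). P-values in
#' [threshold, 0.05) are flagged as a trend toward significance.
#'
#' @param cohort tibble as returned by [make_cohort()] (columns `subject`,
#'   `group`, `structure`, `t2_short`, `t2_long`, `frac_short`,
#'   `frac_long`).
#' @param family_alpha family-wise error rate (default 0.05).
#' @param m comparisons per Bonferroni family (default 4, the four
#'   components of one structure).
#' @param welch use Welch's unequal-variance t-test instead of pooling.
#' @return A tibble shaped like a reference results table: one row per
#'   structure x component with per-group mean/SD/n, `t`, `df`, `p`,
#'   `normality_p_displacement`, `normality_p_no_displacement`,
#'   `significant` (p < threshold) and `trend` (threshold <= p < 0.05).
#' @export
group_analysis <- function(cohort, family_alpha = 0.05, m = 4L,
                           welch = FALSE) {
  needed <- c("group", "structure", unname(component_cols))
  if (!all(needed %in% names(cohort))) {
    stop("cohort is missing columns: ",
         paste(setdiff(needed, names(cohort)), collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("displacement", "no_displacement") %in% cohort$group)) {
    stop("cohort must contain both groups", call. = FALSE)
  }
  threshold <- bonferroni_alpha(family_alpha, m)

  long <- tidyr::pivot_longer(cohort, cols = dplyr::all_of(unname(component_cols)),
                              names_to = "component_col", values_to = "value")
  long$component <- names(component_cols)[match(long$component_col,
                                                component_cols)]

  safe_shapiro <- function(v) {
    if (length(unique(v)) < 3L) return(NA_real_)
    tryCatch(shapiro_wilk(v)$p, error = function(e) NA_real_)
  }

  res <- long |>
    dplyr::group_by(.data$structure, .data$component) |>
    dplyr::group_modify(function(d, key) {
      a <- d$value[d$group == "displacement"]
      b <- d$value[d$group == "no_displacement"]
      tt <- pooled_t_test(mean(a), stats::sd(a), length(a),
                          mean(b), stats::sd(b), length(b), welch = welch)
      tibble::tibble(
        mean_displacement = mean(a), sd_displacement = stats::sd(a),
        n_displacement = length(a),
        mean_no_displacement = mean(b), sd_no_displacement = stats::sd(b),
        n_no_displacement = length(b),
        t = tt$t, df = tt$df, p = tt$p,
        normality_p_displacement = safe_shapiro(a),
        normality_p_no_displacement = safe_shapiro(b)
      )
    }) |>
    dplyr::ungroup()

  res$significant <- res$p < threshold
  res$trend <- res$p >= threshold & res$p < 0.05
  # keep the reference row order: structure as encountered, component fixed
  res$component <- factor(res$component, levels = names(component_cols))
  res$structure <- factor(res$structure, levels = unique(cohort$structure))
  res <- dplyr::arrange(res, .data$structure, .data$component)
  res$component <- as.character(res$component)
  res$structure <- as.character(res$structure)
  res
}
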