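#' Reference tissue parameters for the stomatognathic system
#'
#' Across-study means and standard deviations of the short and long T2
#' components (ms) and the short fraction for seven stomatognathic
#' structures, split by temporomandibular-disk status (disk displacement
#' vs. no displacement; 18 vs. 32 studies). These are the generative
#' defaults of the phantom and cohort simulators. The long fraction is
#' always taken as `1 - frac_short` because per-voxel fractions sum to 1
#' by definition.
#'
#' @return A tibble with one row per structure x group, columns
#'   `structure`, `group`, `mean_t2_short`, `sd_t2_short`, `mean_t2_long`,
#'   `sd_t2_long`, `mean_frac_short`, `sd_frac_short`.
#' @export
tissue_reference <- function() {
  tribble_rows <- list(
    # structure,            group,             t2s,  sd,  t2l,   sd,  fs,    sd
    list("disk",                "displacement",    13.3, 4.5, 105.9, 15.5, 0.708, 0.043),
    list("disk",                "no_displacement", 12.9, 2.1, 107.8, 16.6, 0.718, 0.033),
    list("retrodiscal_tissue",  "displacement",    22.6, 5.2, 105.7, 12.4, 0.637, 0.039),
    list("retrodiscal_tissue",  "no_displacement", 17.6, 3.0, 105.3, 12.0, 0.666, 0.030),
    list("bone_marrow",         "displacement",    37.8, 7.3, 123.7, 19.6, 0.411, 0.042),
    list("bone_marrow",         "no_displacement", 42.4, 5.3, 114.4,  7.4, 0.392, 0.033),
    list("masseter",            "displacement",    25.3, 4.8,  94.9, 11.6, 0.606, 0.043),
    list("masseter",            "no_displacement", 23.6, 3.3,  92.0,  6.5, 0.614, 0.020),
    list("pterygoid_lateralis", "displacement",    25.9, 3.1,  98.8,  7.9, 0.583, 0.027),
    list("pterygoid_lateralis", "no_displacement", 26.5, 2.6,  99.3,  6.4, 0.589, 0.024),
    list("pterygoid_medialis",  "displacement",    25.3, 2.0,  99.5,  7.7, 0.604, 0.021),
    list("pterygoid_medialis",  "no_displacement", 22.3, 2.1,  97.1,  5.0, 0.607, 0.019),
    list("pulp",                "displacement",    26.8, 4.8, 146.7, 16.8, 0.773, 0.051),
    list("pulp",                "no_displacement", 21.6, 3.2, 147.0, 11.1, 0.489, 0.053)
  )
  tibble::tibble(
    structure      = vapply(tribble_rows, `[[`, character(1), 1L),
    group          = vapply(tribble_rows, `[[`, character(1), 2L),
    mean_t2_short  = vapply(tribble_rows, `[[`, numeric(1), 3L),
    sd_t2_short    = vapply(tribble_rows, `[[`, numeric(1), 4L),
    mean_t2_long   = vapply(tribble_rows, `[[`, numeric(1), 5L),
    sd_t2_long     = vapply(tribble_rows, `[[`, numeric(1), 6L),
    mean_frac_short = vapply(tribble_rows, `[[`, numeric(1), 7L),
    sd_frac_short  = vapply(tribble_rows, `[[`, numeric(1), 8L)
  )
}

#' Look up one tissue specification
#'
#' @param structure one of `"disk"`, `"retrodiscal_tissue"`, `"bone_marrow"`,
#'   `"masseter"`, `"pterygoid_lateralis"`, `"pterygoid_medialis"`, `"pulp"`.
#' @param group `"displacement"` or `"no_displacement"`.
#' @param zero_sd if `TRUE`, all SD fields are set to 0 (every draw returns
#'   the configured means exactly) — the noiseless-phantom configuration.
#' @return A one-row tissue spec (list) with the fields of
#'   [tissue_reference()].
#' @export
tissue_spec <- function(structure, group = c("no_displacement", "displacement"),
                        zero_sd = FALSE) {
  group <- match.arg(group)
  ref <- tissue_reference()
  row <- ref[ref$structure == structure & ref$group == group, ]
  if (nrow(row) != 1L) {
    stop("unknown structure '", structure, "'; see tissue_reference()",
         call. = FALSE)
  }
  spec <- as.list(row)
  if (zero_sd) {
    spec$sd_t2_short <- 0
    spec$sd_t2_long <- 0
    spec$sd_frac_short <- 0
  }
  spec
}

validate_tissue_spec <- function(spec) {
  needed <- c("mean_t2_short", "sd_t2_short", "mean_t2_long", "sd_t2_long",
              "mean_frac_short", "sd_frac_short")
  if (!all(needed %in% names(spec))) {
    stop("tissue spec is missing fields: ",
         paste(setdiff(needed, names(spec)), collapse = ", "), call. = FALSE)
  }
  if (spec$mean_t2_short <= 0 || spec$mean_t2_long <= 0) {
    stop("tissue spec means must be positive", call. = FALSE)
  }
  if (spec$mean_t2_short >= spec$mean_t2_long) {
    stop("tissue spec requires mean_t2_short < mean_t2_long", call. = FALSE)
  }
  if (spec$sd_t2_short < 0 || spec$sd_t2_long < 0 || spec$sd_frac_short < 0) {
    stop("tissue spec SDs must be non-negative", call. = FALSE)
  }
  if (spec$mean_frac_short <= 0 || spec$mean_frac_short >= 1) {
    stop("tissue spec short fraction must lie in (0, 1)", call. = FALSE)
  }
  invisible(spec)
}
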