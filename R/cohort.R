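#' Cohort specification
#'
#' A two-group study design: subjects with and without disk displacement.
#' Default group sizes are 18 (displacement) and 32 (no displacement).
#' Between-subject variability of each subject's ROI-mean parameters comes
#' from the across-study SD columns of [tissue_reference()].
#'
#' @param n_displacement,n_no_displacement group sizes (>= 1).
#' @param structures character vector of structures to simulate; default all
#'   seven reference structures.
#' @param seed integer RNG seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_displacement = 18L, n_no_displacement = 32L,
                        structures = unique(tissue_reference()$structure),
                        seed = 1L) {
  if (n_displacement < 1L || n_no_displacement < 1L) {
    stop("both group sizes must be >= 1", call. = FALSE)
  }
  ref_structures <- unique(tissue_reference()$structure)
  if (!all(structures %in% ref_structures)) {
    stop("unknown structures: ",
         paste(setdiff(structures, ref_structures), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(n_displacement = as.integer(n_displacement),
         n_no_displacement = as.integer(n_no_displacement),
         structures = structures, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Simulate a two-group cohort of subject-level ROI parameters
#'
#' For every subject and structure, one set of ROI-mean biexponential
#' parameters is drawn from the structure's group-specific reference
#' distribution (subject-to-subject scatter = the across-study SD columns).
#' This is the observation unit of the group analysis: one ROI mean per
#' subject per structure, as in a study of 18 vs. 32 joints.
#'
#' @param spec a [cohort_spec()].
#' @param tissue_overrides optional named list mapping structure name to a
#'   two-element list `list(displacement = <tissue spec>, no_displacement =
#'   <tissue spec>)` replacing the reference rows (used, e.g., for null
#'   simulations where both groups share one distribution).
#' @return A tibble with columns `subject`, `group`, `structure`,
#'   `t2_short`, `t2_long`, `frac_short`, `frac_long`.
#' @export
make_cohort <- function(spec, tissue_overrides = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(spec$seed)

  groups <- c(rep("displacement", spec$n_displacement),
              rep("no_displacement", spec$n_no_displacement))
  subjects <- sprintf("S%03d", seq_along(groups))

  rows <- vector("list", length(groups) * length(spec$structures))
  k <- 0L
  for (i in seq_along(groups)) {
    for (st in spec$structures) {
      tis <- if (!is.null(tissue_overrides) && st %in% names(tissue_overrides)) {
        tissue_overrides[[st]][[groups[i]]]
      } else {
        tissue_spec(st, groups[i])
      }
      p <- sample_voxel_params(tis)
      fr <- fractions(p$amp_short, p$amp_long)
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        subject = subjects[i], group = groups[i], structure = st,
        t2_short = p$t2_short, t2_long = p$t2_long,
        frac_short = fr[["frac_short"]], frac_long = fr[["frac_long"]]
      )
    }
  }
  dplyr::bind_rows(rows)
}
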