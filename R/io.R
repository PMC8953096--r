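sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write a multi-echo volume (plus label mask and truth maps) to NIfTI
#'
#' The 4-D volume goes to `<stem>.nii.gz` with a JSON sidecar
#' `<stem>.json` carrying the echo times (NIfTI has no standard
#' TE-per-volume field), the seed and any label names; the label mask and
#' truth maps, when present, are written alongside.
#'
#' @param phantom result of [make_phantom()] (or any list with `volume`,
#'   `tes`, optional `label` and `truth`).
#' @param stem output path stem (directories are created).
#' @return Invisibly, the named character vector of files written.
#' @export
write_multiecho <- function(phantom, stem) {
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  files <- c(volume = paste0(stem, ".nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(phantom$volume), files[["volume"]])
  sidecar <- list(echo_times_ms = phantom$tes)
  if (!is.null(phantom$spec)) {
    sidecar$seed <- phantom$spec$seed
    sidecar$noise <- phantom$spec$noise
    sidecar$labels <- lapply(phantom$spec$rois, function(r) {
      list(label = r$label, structure = r$structure)
    })
  }
  jsonlite::write_json(sidecar, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  files <- c(files, sidecar = paste0(stem, ".json"))
  if (!is.null(phantom$label)) {
    files <- c(files, label = paste0(stem, "_label.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(phantom$label), files[["label"]])
  }
  if (!is.null(phantom$truth)) {
    for (nm in names(phantom$truth)) {
      f <- paste0(stem, "_truth_", nm, ".nii.gz")
      files <- c(files, stats::setNames(f, paste0("truth_", nm)))
      RNifti::writeNifti(RNifti::asNifti(phantom$truth[[nm]]), f)
    }
  }
  invisible(files)
}

#' Read a multi-echo volume and its echo times
#'
#' Expects a 4-D NIfTI whose echo times come from a JSON sidecar
#' (`<stem>.json`, field `echo_times_ms`) or the `tes` argument; an
#' explicit `tes` overrides the sidecar. The echo count must match the 4th
#' dimension and the grid must be strictly increasing.
#'
#' @param path path to the 4-D NIfTI file.
#' @param tes optional echo times (ms) overriding the sidecar.
#' @return list with `volume` (4-D array) and `tes`.
#' @export
read_multiecho <- function(path, tes = NULL) {
  img <- RNifti::readNifti(path)
  volume <- array(as.numeric(img), dim = dim(img))
  if (length(dim(volume)) != 4L) {
    stop("expected a 4-D multi-echo volume; got ",
         length(dim(volume)), "-D", call. = FALSE)
  }
  if (is.null(tes)) {
    sc <- sidecar_path(path)
    if (!file.exists(sc)) {
      stop("no echo times: provide `tes` or a sidecar JSON at ", sc,
           call. = FALSE)
    }
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    tes <- as.numeric(meta$echo_times_ms)
  }
  validate_echo_times(tes)
  if (length(tes) != dim(volume)[4]) {
    stop("echo count mismatch: volume has ", dim(volume)[4],
         " echoes but ", length(tes), " echo times were given", call. = FALSE)
  }
  list(volume = volume, tes = tes)
}

#' Write a reconstructed map stack to a directory
#'
#' One 3-D NIfTI per map plus the validity mask (0/1) and a JSON
#' provenance file recording echo times, software version and any extra
#' metadata (e.g. the seed). Files are written to a temporary directory
#' first and moved into place, so a failure never leaves a partial map
#' set.
#'
#' @param stack a `map_stack` from [reconstruct_volume()].
#' @param dir output directory (created if needed).
#' @param metadata named list merged into the provenance JSON.
#' @return Invisibly, the character vector of files written.
#' @export
write_maps <- function(stack, dir, metadata = list()) {
  stopifnot(inherits(stack, "map_stack"))
  staging <- tempfile("maps_")
  dir.create(staging, recursive = TRUE)
  maps <- c("t2_short", "t2_long", "amp_short", "amp_long",
            "frac_short", "frac_long", "mse_biexp", "mse_mono")
  written <- character(0)
  for (nm in maps) {
    f <- file.path(staging, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(stack[[nm]]), f)
    written <- c(written, basename(f))
  }
  f <- file.path(staging, "validity.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(stack$validity),
                                           dim = dim(stack$validity))), f)
  written <- c(written, basename(f))
  prov <- c(list(echo_times_ms = stack$tes,
                 package = "biexpT2",
                 version = as.character(utils::packageVersion("biexpT2")),
                 n_valid_voxels = sum(stack$validity)),
            metadata)
  jsonlite::write_json(prov, file.path(staging, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  written <- c(written, "provenance.json")

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ok <- file.copy(file.path(staging, written), file.path(dir, written),
                  overwrite = TRUE)
  unlink(staging, recursive = TRUE)
  if (!all(ok)) stop("failed to move map set into ", dir, call. = FALSE)
  invisible(file.path(dir, written))
}

#' Read a map stack written by [write_maps()]
#'
#' @param dir directory containing the map NIfTIs and provenance JSON.
#' @return A `map_stack` list (sentinel `NA` voxels preserved).
#' @export
read_maps <- function(dir) {
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"),
                              simplifyVector = TRUE)
  maps <- c("t2_short", "t2_long", "amp_short", "amp_long",
            "frac_short", "frac_long", "mse_biexp", "mse_mono")
  pad3 <- function(dm) c(dm, rep(1L, max(0L, 3L - length(dm))))
  out <- lapply(maps, function(nm) {
    img <- RNifti::readNifti(file.path(dir, paste0(nm, ".nii.gz")))
    array(as.numeric(img), dim = pad3(dim(img)))
  })
  names(out) <- maps
  val <- RNifti::readNifti(file.path(dir, "validity.nii.gz"))
  out$validity <- array(as.integer(val) == 1L, dim = pad3(dim(val)))
  out$model <- NULL
  out$tes <- as.numeric(prov$echo_times_ms)
  out$provenance <- prov
  class(out) <- "map_stack"
  out
}

#' Read a phantom or cohort configuration from YAML
#'
#' The YAML mirrors the [phantom_spec()] / [cohort_spec()] fields. A
#' `kind:` key selects which spec is built (`"phantom"` or `"cohort"`).
#' Tissue parameters may be given by reference (`structure` + `group`,
#' optionally `zero_sd`) or in full.
#'
#' @param path YAML file path.
#' @return A `phantom_spec` or `cohort_spec`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  kind <- cfg$kind
  if (is.null(kind) || !kind %in% c("phantom", "cohort")) {
    stop("config must set kind: phantom or kind: cohort", call. = FALSE)
  }
  if (kind == "cohort") {
    return(cohort_spec(
      n_displacement = cfg$n_displacement %||% 18L,
      n_no_displacement = cfg$n_no_displacement %||% 32L,
      structures = cfg$structures %||% unique(tissue_reference()$structure),
      seed = cfg$seed %||% 1L
    ))
  }
  rois <- lapply(cfg$rois, function(r) {
    tissue <- if (!is.null(r$tissue)) {
      r$tissue
    } else {
      tissue_spec(r$structure, r$group %||% "no_displacement",
                  zero_sd = isTRUE(r$zero_sd))
    }
    region <- r$region
    # YAML 1.1 reads a bare `y:` key as boolean TRUE; undo that
    names(region)[names(region) == "TRUE"] <- "y"
    list(label = r$label, structure = r$structure, tissue = tissue,
         region = region)
  })
  phantom_spec(
    dim = as.integer(cfg$dim %||% c(32L, 32L, 1L)),
    tes = as.numeric(cfg$tes %||% default_echo_times()),
    rois = rois,
    noise = cfg$noise %||% "none",
    sigmas = as.numeric(cfg$sigmas %||% 0),
    seed = cfg$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
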