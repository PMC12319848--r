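#' Read and write NIfTI volumes
#'
#' Thin wrappers around RNifti used by the pipeline's file interfaces:
#' 4D BOLD runs with their mask, 3D beta / Bayes-factor maps. Missing
#' values in statistical maps are stored as NaN.
#'
#' @param run a [bold_run()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `write_bold_nifti()` returns `path` invisibly.
#' @export
write_bold_nifti <- function(run, path) {
  stopifnot(inherits(run, "bold_run"))
  img <- RNifti::asNifti(run$data)
  RNifti::pixdim(img) <- c(abs(diag(run$affine)[1:3]), run$tr)
  RNifti::writeNifti(img, path)
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(run$mask), dim(run$mask))),
                     mask_path(path))
  invisible(path)
}

mask_path <- function(path) sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)

#' @rdname write_bold_nifti
#' @param tr repetition time to attach when reading.
#' @export
read_bold_nifti <- function(path, tr = NULL) {
  img <- RNifti::readNifti(path)
  pd <- attr(img, "pixdim")
  tr <- tr %||% if (length(pd) >= 4) pd[4] else abort("TR not stored; pass `tr`.")
  mask <- RNifti::readNifti(mask_path(path))
  affine <- default_affine(pd[1])
  bold_run(array(as.numeric(img), dim(img)), tr = tr,
           mask = array(as.numeric(mask) > 0.5, dim(mask)[1:3]),
           affine = affine)
}

#' Write a statistical volume (beta or BF map) as NIfTI
#'
#' @param vol 3D numeric array (NA allowed; stored as NaN).
#' @param path output path.
#' @param voxel_mm voxel size for the header.
#' @return `path`, invisibly.
#' @export
write_stat_nifti <- function(vol, path, voxel_mm = 3.75) {
  v <- array(as.numeric(vol), dim(vol)[1:3])
  v[is.na(v)] <- NaN
  img <- RNifti::asNifti(v)
  RNifti::pixdim(img) <- rep(voxel_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_stat_nifti
#' @export
read_stat_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  v <- array(as.numeric(img), dim(img)[1:3])
  v[is.nan(v)] <- NA_real_
  v
}

#' Write a synthetic study to a self-contained directory
#'
#' Lays out a dataset the way the file-based pipeline entry points expect
#' it: per-subject BOLD runs and events tables
#' (`sub-XX/run-R_bold.nii.gz`, `sub-XX/run-R_events.tsv`), a shared mask,
#' the lexicon (TSV + embeddings TSV + MFCC JSON), per-subject model RDM
#' TSVs, and a JSON manifest recording seeds, plant specifications and the
#' achieved planted correlations.
#'
#' @param dataset a `synthetic_dataset` (with BOLD retained).
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_study <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_lexicon(dataset$lexicon, file.path(dir, "lexicon.tsv"))
  write_stat_nifti(array(as.numeric(dataset$mask), dim(dataset$mask)),
                   file.path(dir, "mask.nii.gz"))
  for (subj in dataset$subjects) {
    sd_dir <- file.path(dir, sprintf("sub-%02d", subj$id))
    dir.create(sd_dir, showWarnings = FALSE)
    if (!is.null(subj$runs)) {
      for (r in seq_along(subj$runs)) {
        write_bold_nifti(subj$runs[[r]],
                         file.path(sd_dir, sprintf("run-%d_bold.nii.gz", r)))
      }
    }
    for (r in seq_along(subj$events)) {
      readr::write_tsv(subj$events[[r]],
                       file.path(sd_dir, sprintf("run-%d_events.tsv", r)))
    }
    for (cond in names(subj$models)) {
      for (mdl in names(subj$models[[cond]])) {
        write_rdm_tsv(subj$models[[cond]][[mdl]],
                      file.path(sd_dir, sprintf("model_%s_%s.tsv", cond, mdl)))
      }
    }
  }
  manifest <- list(
    seed = dataset$seed,
    design = dataset$design,
    n_subjects = length(dataset$subjects),
    dims = dataset$geometry$dim,
    plants = lapply(dataset$plant_specs, function(ps) {
      list(model = ps$model, rho_target = ps$rho_target,
           conditions = ps$conditions, region_voxels = sum(ps$region))
    }),
    achieved = dataset$achieved
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write per-subject beta maps as NIfTI files
#'
#' Files are named `{subject}_{condition}_{model}_beta.nii.gz`.
#'
#' @param betas a `beta_maps` object.
#' @param subject subject label.
#' @param dir output directory.
#' @return Character vector of written paths, invisibly.
#' @export
write_beta_maps <- function(betas, subject, dir) {
  stopifnot(inherits(betas, "beta_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cond <- paste(betas$condition, collapse = "-")
  paths <- vapply(names(betas$maps), function(mdl) {
    p <- file.path(dir, sprintf("%s_%s_%s_beta.nii.gz", subject, cond, mdl))
    write_stat_nifti(betas$maps[[mdl]], p,
                     voxel_mm = abs(betas$geometry$affine[1, 1]))
    p
  }, character(1))
  invisible(paths)
}
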