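#' Write a simulated measurement to disk
#'
#' Writes the 4D phase-resolved image and the four 3D masks as NIfTI
#' (\code{.nii.gz}, voxel size in the header), the navigator as a CSV of
#' (timestamp, amplitude), and a ground-truth summary (true tidal volume,
#' breathing frequency, in-mask mean true RVent, phase indices) as JSON.
#'
#' @param meas A \code{\linkS4class{SyntheticMeasurement}}.
#' @param dir Output directory (created if missing).
#' @param prefix File prefix; defaults to
#'   \code{subject_scanner_m<measurement>}.
#' @return Invisibly, the named vector of written paths.
#' @export
writeMeasurement <- function(meas, dir, prefix = NULL) {
  if (is.null(prefix))
    prefix <- sprintf("%s_%s_m%d", meas@subjectId, meas@scanner,
                      meas@measurementIndex)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- voxelSize(meas@images)
  p <- function(suffix) file.path(dir, paste0(prefix, "_", suffix))
  paths <- c(images = p("images.nii.gz"), parenchyma = p("parenchyma.nii.gz"),
             vessel = p("vessel.nii.gz"), insp = p("insp.nii.gz"),
             exp = p("exp.nii.gz"), navigator = p("navigator.csv"),
             truth = p("truth.json"))
  RNifti::writeNifti(asNiftiWithPixdim(meas@images@data, c(vs, 1)),
                     paths["images"])
  for (nm in c("parenchyma", "vessel", "insp", "exp")) {
    arr <- switch(nm, parenchyma = meas@parenchymaMask,
                  vessel = meas@vesselMask, insp = meas@inspMask,
                  exp = meas@expMask)
    RNifti::writeNifti(asNiftiWithPixdim(array(as.integer(arr), dim(arr)),
                                         vs), paths[nm])
  }
  write.csv(data.frame(timestamp = timestamps(meas@navigator),
                       amplitude = amplitude(meas@navigator)),
            paths["navigator"], row.names = FALSE)
  gt <- meas@groundTruth
  mask <- analysisMask(meas)
  jsonlite::write_json(list(
    subject_id = meas@subjectId, scanner = meas@scanner,
    measurement = meas@measurementIndex,
    exp_idx = expIndex(meas@images), insp_idx = inspIndex(meas@images),
    phase_u = meas@images@phaseU,
    true_tidal_volume = gt@trueTidalVolume,
    true_breathing_frequency = gt@trueBreathingFrequency,
    true_mean_rvent = mean(gt@rventTrueField[mask])),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

asNiftiWithPixdim <- function(arr, pd) {
  n <- RNifti::asNifti(arr)
  RNifti::`pixdim<-`(n, pd)
}

#' Read a measurement written by \code{writeMeasurement}
#'
#' Reconstructs the images, masks and navigator from the on-disk files; the
#' full voxel-wise ground truth is not round-tripped (only its JSON
#' summary), so the returned object carries a placeholder ground truth with
#' the true scalars.
#'
#' @param dir Directory holding the files.
#' @param prefix File prefix used at write time.
#' @return A \code{\linkS4class{SyntheticMeasurement}}.
#' @export
readMeasurement <- function(dir, prefix) {
  p <- function(suffix) file.path(dir, paste0(prefix, "_", suffix))
  img <- RNifti::readNifti(p("images.nii.gz"))
  vs <- RNifti::pixdim(img)[1:3]
  truth <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  readMask <- function(suffix) {
    a <- RNifti::readNifti(p(suffix))
    array(as.array(a) > 0.5, dim(a))
  }
  nav <- read.csv(p("navigator.csv"))
  dimsImg <- dim(img)
  svZero <- array(0, dimsImg[1:3])
  gt <- new("GroundTruth", svField = svZero, rventTrueField = svZero,
            defectMask = array(FALSE, dimsImg[1:3]),
            cycleWaveform = numeric(0),
            trueTidalVolume = truth$true_tidal_volume,
            trueBreathingFrequency = truth$true_breathing_frequency)
  new("SyntheticMeasurement",
      images = PhaseResolvedImage(array(as.vector(img), dim(img)), vs,
                                  truth$exp_idx, truth$insp_idx,
                                  truth$phase_u),
      parenchymaMask = readMask("parenchyma.nii.gz"),
      vesselMask = readMask("vessel.nii.gz"),
      inspMask = readMask("insp.nii.gz"), expMask = readMask("exp.nii.gz"),
      navigator = GatingSeries(nav$timestamp, nav$amplitude),
      groundTruth = gt, subjectId = truth$subject_id,
      scanner = truth$scanner, measurementIndex = truth$measurement,
      seed = NA_integer_)
}

#' Read a study configuration from YAML
#'
#' Reads a YAML study configuration and fills unspecified fields from
#' \code{\link{defaultStudyConfig}}. Validates that every profile referenced
#' by a center is defined.
#'
#' @param path YAML file path.
#' @return A configuration list.
#' @export
readStudyConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  ## YAML 1.1 parses a bare `n` key as a boolean; restore it
  cfg$centers <- lapply(cfg$centers, function(ctr) {
    names(ctr)[names(ctr) %in% c("FALSE", "no")] <- "n"
    ctr
  })
  cfg <- mergeConfig(defaultStudyConfig(), cfg)
  validateStudyConfig(cfg)
  cfg
}

## recursive default-filling: named lists merge key-wise, anything else
## (vectors, unnamed lists such as profiles/centers) replaces wholesale
mergeConfig <- function(base, override) {
  if (!is.list(base) || !is.list(override) ||
      is.null(names(base)) || is.null(names(override)))
    return(override)
  for (nm in names(override))
    base[[nm]] <- if (nm %in% names(base))
      mergeConfig(base[[nm]], override[[nm]]) else override[[nm]]
  base
}

validateStudyConfig <- function(config) {
  needed <- c("seed", "grid", "n_phases", "navigator", "profiles",
              "centers", "demographics", "perturbation")
  missing <- setdiff(needed, names(config))
  if (length(missing))
    stop("config error: missing keys: ", paste(missing, collapse = ", "))
  studyProfiles(config)  # errors on undefined profile references
  invisible(config)
}
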