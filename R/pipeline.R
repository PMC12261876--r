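#' Default study configuration
#'
#' Fixture-scale defaults for the end-to-end synthetic studies: two centers,
#' Center 1 carrying a 1.5-T and a 3-T profile, Center 2 one 3-T profile;
#' two measurements per subject and scanner. The grid (24^3 voxels of 10 mm)
#' and 12 respiratory phases keep a full study in seconds; demographics and
#' breathing parameters are drawn from healthy-volunteer ranges (age 18-65,
#' 70\% female, 9-18 breaths/min, tidal volume 280-700 mL). Scanner
#' profiles encode the field-strength contrast as lower parenchymal SNR and
#' higher ventilation heterogeneity at 3 T.
#'
#' @param n1,n2 Subjects at Center 1 / Center 2.
#' @param seed Root seed.
#' @param gridDim,voxelSize Grid descriptor.
#' @param nPhases Respiratory phases per cycle.
#' @return Configuration list understood by \code{\link{generateCohort}} and
#'   the study runners.
#' @export
defaultStudyConfig <- function(n1 = 4, n2 = 4, seed = 20260101,
                               gridDim = c(24, 24, 24),
                               voxelSize = c(10, 10, 10), nPhases = 12) {
  list(
    seed = as.integer(seed),
    grid = list(dim = gridDim, voxel_size = voxelSize),
    n_phases = nPhases,
    navigator = list(duration = 60, dt = 0.1, noise_sd = 0.05),
    profiles = list(
      list(label = "Center1-1.5T", field_strength = 1.5, snr = 250,
           heterogeneity_scale = 1.0, signal_scale = 100),
      list(label = "Center1-3T", field_strength = 3.0, snr = 100,
           heterogeneity_scale = 1.3, signal_scale = 100),
      list(label = "Center2-3T", field_strength = 3.0, snr = 100,
           heterogeneity_scale = 1.3, signal_scale = 100)),
    centers = list(
      list(name = "Center1", n = n1,
           profiles = c("Center1-1.5T", "Center1-3T")),
      list(name = "Center2", n = n2, profiles = c("Center2-3T"))),
    demographics = list(
      age_range = c(18, 65), female_fraction = 0.7,
      bf_range = c(9, 18), tv_range = c(280, 700),
      sv_mean_range = c(0.2, 0.3), sv_correlation_length = 30,
      lung_semiaxes = c(50, 60, 95), defect_fraction = 0),
    perturbation = list(tidalFactor = 1, frequencyFactor = 1),
    physiology = list(amp_sd = 0.10, spatial_sd = 0.14, lag_sd = 0.03,
                      lag_logsd = 0.25, freq_sd = 0.05),
    analysis = list(vvp_rvent_fraction = 0.4, vvp_fvlcm_threshold = 0.9))
}

#' Simulate and summarise a whole cohort
#'
#' Streams through the configured cohort: each measurement is simulated,
#' mapped and reduced to its scalar summary and binary ventilated-volume
#' maps before the next is generated, so full image series are never all in
#' memory at once.
#'
#' @param config Study configuration.
#' @return List with \code{summaries} (data.frame, one row per measurement)
#'   and \code{vvMaps} (named list of lists \code{vvRVent}, \code{vvFVLCM},
#'   \code{mask}).
#' @export
studySummaries <- function(config) {
  subjects <- cohortSubjects(config)
  profiles <- studyProfiles(config)
  rows <- list(); vvMaps <- list()
  for (ctr in config$centers) {
    for (sub in subjects) {
      if (sub@center != ctr$name) next
      for (plab in ctr$profiles) {
        for (m in 1:2) {
          meas <- simulateMeasurement(
            sub, profiles[[plab]], measurementIndex = m,
            perturbation = config$perturbation,
            gridDim = config$grid$dim, voxelSize = config$grid$voxel_size,
            nPhases = config$n_phases,
            navDuration = config$navigator$duration,
            navDt = config$navigator$dt,
            navNoiseSd = config$navigator$noise_sd,
            physiology = config$physiology %||% list())
          res <- summarizeMeasurement(meas, keepMaps = TRUE)
          key <- sprintf("%s_%s_m%d", sub@subjectId, plab, m)
          rows[[key]] <- cbind(
            data.frame(subject_id = sub@subjectId, age = sub@age,
                       sex = sub@sex, center = ctr$name, scanner = plab,
                       field_strength = profiles[[plab]]@fieldStrength,
                       measurement = m, stringsAsFactors = FALSE),
            as.data.frame(res$summary),
            data.frame(true_mean_rvent =
                         mean(groundTruth(meas)@rventTrueField[
                           analysisMask(meas)])))
          vvMaps[[key]] <- list(vvRVent = res$maps$vvRVent,
                                vvFVLCM = res$maps$vvFVLCM,
                                mask = res$maps$mask)
        }
      }
    }
  }
  list(summaries = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       vvMaps = vvMaps)
}

#' Run the repeatability study
#'
#' For every scanner: the full repeatability table (bias, limits of
#' agreement, Wilcoxon p, median between-measurement CoV, ICC(2,1) with
#' label, Cohen's d with label, per parameter) plus the median (IQR) spatial
#' overlap of the binary ventilated-volume maps between the two
#' measurements.
#'
#' @param config Study configuration, or the result of
#'   \code{\link{studySummaries}} to reuse simulated data.
#' @return List with \code{table}, \code{overlap} (per scanner), and
#'   \code{summaries}.
#' @export
runRepeatabilityStudy <- function(config) {
  ss <- if (!is.null(config$summaries)) config else studySummaries(config)
  tab <- buildTables(ss$summaries, "repeatability")
  ov <- list()
  for (sc in unique(ss$summaries$scanner)) {
    s <- ss$summaries[ss$summaries$scanner == sc & ss$summaries$measurement == 1, ]
    rows <- lapply(s$subject_id, function(id) {
      k1 <- sprintf("%s_%s_m1", id, sc); k2 <- sprintf("%s_%s_m2", id, sc)
      if (is.null(ss$vvMaps[[k1]]) || is.null(ss$vvMaps[[k2]])) return(NULL)
      data.frame(
        subject_id = id, scanner = sc,
        overlap_rvent = spatialOverlap(ss$vvMaps[[k1]]$vvRVent,
                                       ss$vvMaps[[k2]]$vvRVent,
                                       ss$vvMaps[[k1]]$mask),
        overlap_fvlcm = spatialOverlap(ss$vvMaps[[k1]]$vvFVLCM,
                                       ss$vvMaps[[k2]]$vvFVLCM,
                                       ss$vvMaps[[k1]]$mask))
    })
    ov[[sc]] <- do.call(rbind, rows)
  }
  list(table = tab, overlap = ov, summaries = ss$summaries)
}

#' Run the intercenter consistency study
#'
#' Age-matches the two centers' subjects and compares the 3-T parameters per
#' measurement (bias and Wilcoxon p per parameter); exclusions from the
#' matching are reported.
#'
#' @inheritParams runRepeatabilityStudy
#' @return List with \code{table}, \code{matching}, \code{summaries}.
#' @export
runIntercenterStudy <- function(config) {
  ss <- if (!is.null(config$summaries)) config else studySummaries(config)
  tab <- buildTables(ss$summaries, "intercenter")
  list(table = tab, matching = attr(tab, "matching"),
       summaries = ss$summaries)
}

#' Run the field-strength comparison study
#'
#' Compares 3-T against 1.5-T measurements of the center that carries both
#' profiles: per measurement and parameter, bias (1.5 T minus 3 T), percent
#' change of the 3-T mean against the 1.5-T mean, Wilcoxon p, and Cohen's d
#' with label.
#'
#' @inheritParams runRepeatabilityStudy
#' @return List with \code{table} and \code{summaries}.
#' @export
runFieldStrengthStudy <- function(config) {
  ss <- if (!is.null(config$summaries)) config else studySummaries(config)
  s <- ss$summaries
  ctr <- names(which(sapply(split(s$field_strength, s$center),
                            function(f) length(unique(f)) == 2)))
  if (!length(ctr))
    stop("config error: no center carries two field strengths")
  tab <- buildTables(s[s$center == ctr[1], ], "field_strength")
  list(table = tab, summaries = ss$summaries)
}

#' Run all study sections
#'
#' Simulates the cohort once and produces every comparison the configuration
#' supports: repeatability per scanner, intercenter consistency (two centers
#' sharing a field strength), and the field-strength comparison (one center
#' with two profiles). A run manifest records the seed, configuration hash
#' and package version.
#'
#' @param config Study configuration (see \code{\link{defaultStudyConfig}}).
#' @return A study report list with elements \code{repeatability},
#'   \code{intercenter}, \code{field_strength} (as supported),
#'   \code{summaries} and \code{manifest}.
#' @export
runStudy <- function(config) {
  ss <- studySummaries(config)
  s <- ss$summaries
  report <- list(summaries = s)
  report$repeatability <- runRepeatabilityStudy(ss)[c("table", "overlap")]
  fsPerCenter <- split(s$field_strength, s$center)
  common <- Reduce(intersect, fsPerCenter)
  if (length(fsPerCenter) == 2 && length(common))
    report$intercenter <- runIntercenterStudy(ss)[c("table", "matching")]
  if (any(sapply(fsPerCenter, function(f) length(unique(f)) == 2)))
    report$field_strength <- runFieldStrengthStudy(ss)["table"]
  report$manifest <- list(
    seed = config$seed, config_hash = hashConfig(config),
    package_version = as.character(utils::packageVersion("preful3d")),
    n_measurements = nrow(s), timestamp = format(Sys.time(), "%Y-%m-%d"))
  report
}

## ---- file-based stages -----------------------------------------------------

#' Pipeline stages on disk
#'
#' File-based counterparts of the in-memory study runners, for running the
#' pipeline in separate steps: \code{stageSimulate} writes every measurement
#' (NIfTI images and masks, navigator CSV, ground-truth JSON) plus the
#' cohort table; \code{stageMap} reads them back, writes the static RVent,
#' FVL-CM and binary ventilated-volume maps as NIfTI and the per-measurement
#' summaries as CSV; \code{stageStats} builds the report tables and writes
#' them as CSV and JSON with a run manifest. \code{runAll} chains the three.
#'
#' @param config Study configuration.
#' @param dir Working directory of the study run.
#' @return Each stage invisibly returns the paths it wrote; \code{runAll}
#'   returns the report list.
#' @name stages
NULL

#' @rdname stages
#' @export
stageSimulate <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generateCohort(config)
  for (key in names(cohort$measurements))
    writeMeasurement(cohort$measurements[[key]], file.path(dir, "measurements"),
                     prefix = key)
  write.csv(cohort$cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(file.path(dir, "cohort.csv"))
}

#' @rdname stages
#' @export
stageMap <- function(dir) {
  cohortPath <- file.path(dir, "cohort.csv")
  if (!file.exists(cohortPath))
    stop("file error: ", cohortPath, " not found; run stageSimulate first")
  cohort <- read.csv(cohortPath)
  mdir <- file.path(dir, "measurements")
  odir <- file.path(dir, "maps")
  dir.create(odir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    key <- sprintf("%s_%s_m%d", cohort$subject_id[i], cohort$scanner[i],
                   cohort$measurement[i])
    if (!file.exists(file.path(mdir, paste0(key, "_images.nii.gz"))))
      stop("file error: missing images for ", key, " under ", mdir)
    meas <- readMeasurement(mdir, key)
    res <- summarizeMeasurement(meas, keepMaps = TRUE)
    vs <- voxelSize(meas@images)
    for (nm in c("rventStatic", "fvlcm", "vvRVent", "vvFVLCM")) {
      arr <- res$maps[[nm]]
      if (is.logical(arr)) arr <- array(as.integer(arr), dim(arr))
      nif <- RNifti::asNifti(arr)
      RNifti::pixdim(nif) <- vs
      RNifti::writeNifti(nif,
                         file.path(odir, sprintf("%s_%s.nii.gz", key, nm)))
    }
    rows[[key]] <- cbind(cohort[i, c("subject_id", "age", "sex", "center",
                                     "scanner", "field_strength",
                                     "measurement")],
                         as.data.frame(res$summary))
  }
  summaries <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  write.csv(summaries, file.path(dir, "summaries.csv"), row.names = FALSE)
  invisible(file.path(dir, "summaries.csv"))
}

#' @rdname stages
#' @export
stageStats <- function(dir, config) {
  sumPath <- file.path(dir, "summaries.csv")
  if (!file.exists(sumPath))
    stop("file error: ", sumPath, " not found; run stageMap first")
  summaries <- read.csv(sumPath, stringsAsFactors = FALSE)
  odir <- file.path(dir, "maps")
  readVV <- function(key, nm) {
    a <- RNifti::readNifti(file.path(odir, sprintf("%s_%s.nii.gz", key, nm)))
    array(as.array(a) > 0.5, dim(a))
  }
  vvMaps <- list()
  for (i in seq_len(nrow(summaries))) {
    key <- sprintf("%s_%s_m%d", summaries$subject_id[i],
                   summaries$scanner[i], summaries$measurement[i])
    vvMaps[[key]] <- list(vvRVent = readVV(key, "vvRVent"),
                          vvFVLCM = readVV(key, "vvFVLCM"),
                          mask = analysisMaskFromFiles(dir, key))
  }
  ss <- list(summaries = summaries, vvMaps = vvMaps)
  report <- list(repeatability = runRepeatabilityStudy(ss)[c("table",
                                                             "overlap")])
  fsPerCenter <- split(summaries$field_strength, summaries$center)
  if (length(fsPerCenter) == 2 &&
      length(Reduce(intersect, fsPerCenter)))
    report$intercenter <- runIntercenterStudy(ss)[c("table", "matching")]
  if (any(sapply(fsPerCenter, function(f) length(unique(f)) == 2))) {
    ctr <- names(which(sapply(fsPerCenter,
                              function(f) length(unique(f)) == 2)))[1]
    report$field_strength <- list(
      table = buildTables(summaries[summaries$center == ctr, ],
                          "field_strength"))
  }
  report$manifest <- list(
    seed = config$seed, config_hash = hashConfig(config),
    package_version = as.character(utils::packageVersion("preful3d")),
    n_measurements = nrow(summaries))
  writeReport(report, dir)
  invisible(report)
}

## analysis mask of a written measurement: parenchyma minus vessels
analysisMaskFromFiles <- function(dir, key) {
  mdir <- file.path(dir, "measurements")
  rd <- function(suffix) {
    a <- RNifti::readNifti(file.path(mdir, paste0(key, "_", suffix)))
    array(as.array(a) > 0.5, dim(a))
  }
  rd("parenchyma.nii.gz") & !rd("vessel.nii.gz")
}

writeReport <- function(report, dir) {
  tdir <- file.path(dir, "tables")
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$repeatability$table))
    write.csv(report$repeatability$table,
              file.path(tdir, "repeatability.csv"), row.names = FALSE)
  if (!is.null(report$intercenter$table))
    write.csv(report$intercenter$table,
              file.path(tdir, "intercenter.csv"), row.names = FALSE)
  if (!is.null(report$field_strength$table))
    write.csv(report$field_strength$table,
              file.path(tdir, "field_strength.csv"), row.names = FALSE)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  invisible(file.path(dir, "report.json"))
}

#' @rdname stages
#' @export
runAll <- function(config, dir) {
  stageSimulate(config, dir)
  stageMap(dir)
  stageStats(dir, config)
}
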