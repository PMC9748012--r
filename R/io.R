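#' Read a 3D image volume from NIfTI or MetaImage
#'
#' Voxel values are interpreted as count rates (cps per voxel); voxel
#' spacing (mm) is read from the header.  NIfTI is handled by RNifti;
#' MetaImage (`.mhd` header + `.raw`, or single-file `.mha`) is parsed
#' directly.
#'
#' @param path file path (`.nii`, `.nii.gz`, `.mha`, `.mhd`).
#' @param duration acquisition duration in seconds to attach as metadata
#'   (not stored in either format).
#' @return An [image_volume].
#' @export
read_volume <- function(path, duration = NA_real_) {
  if (!file.exists(path)) stop("no such file: ", path)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    a <- array(as.numeric(img), dim(img))
    if (length(dim(a)) != 3L) stop("expected a 3D volume, got ", length(dim(a)), "D")
    sp <- RNifti::pixdim(img)[1:3]
    image_volume(a, spacing = sp, duration = duration)
  } else if (grepl("\\.mhd?a?$", lower) && grepl("\\.(mha|mhd)$", lower)) {
    read_metaimage(path, duration = duration)
  } else {
    stop("unknown image format (expected .nii, .nii.gz, .mha or .mhd): ", path)
  }
}

#' Write an image volume to NIfTI or MetaImage
#'
#' @param image an [image_volume].
#' @param path output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_volume <- function(image, path) {
  stopifnot(inherits(image, "image_volume"))
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::asNifti(image$voxels)
    RNifti::pixdim(img) <- image$spacing
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.(mha|mhd)$", lower)) {
    write_metaimage(image, path)
  } else {
    stop("unknown image format for output: ", path)
  }
  invisible(path)
}

metaimage_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
                     MET_SHORT = "integer", MET_USHORT = "integer",
                     MET_INT = "integer", MET_UINT = "integer",
                     MET_FLOAT = "double", MET_DOUBLE = "double")
metaimage_sizes <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_SHORT = 2L,
                     MET_USHORT = 2L, MET_INT = 4L, MET_UINT = 4L,
                     MET_FLOAT = 4L, MET_DOUBLE = 8L)

read_metaimage <- function(path, duration = NA_real_) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("corrupted MetaImage header: no ElementDataFile")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("corrupted MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  ndims <- as.integer(hdr[["NDims"]] %||% "3")
  if (is.na(ndims) || ndims != 3L) stop("only 3D MetaImage volumes are supported")
  d <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  if (length(d) != 3L || any(is.na(d))) stop("corrupted MetaImage header: DimSize")
  sp <- as.numeric(strsplit(hdr[["ElementSpacing"]] %||% "1 1 1", "\\s+")[[1]])
  type <- hdr[["ElementType"]] %||% "MET_FLOAT"
  if (!type %in% names(metaimage_types))
    stop("unsupported MetaImage ElementType: ", type)
  msb <- toupper(hdr[["BinaryDataByteOrderMSB"]] %||% "FALSE") == "TRUE"
  n <- prod(d)
  datafile <- hdr[["ElementDataFile"]]
  if (toupper(datafile) == "LOCAL") {
    raw <- readBin(con, metaimage_types[[type]], n = n,
                   size = metaimage_sizes[[type]],
                   endian = if (msb) "big" else "little",
                   signed = !type %in% c("MET_UCHAR", "MET_USHORT"))
  } else {
    rawpath <- file.path(dirname(path), datafile)
    if (!file.exists(rawpath)) stop("MetaImage data file not found: ", rawpath)
    con2 <- file(rawpath, "rb")
    on.exit(close(con2), add = TRUE)
    raw <- readBin(con2, metaimage_types[[type]], n = n,
                   size = metaimage_sizes[[type]],
                   endian = if (msb) "big" else "little",
                   signed = !type %in% c("MET_UCHAR", "MET_USHORT"))
  }
  if (length(raw) != n) stop("corrupted MetaImage: expected ", n,
                             " voxels, read ", length(raw))
  image_volume(array(as.numeric(raw), d), spacing = sp, duration = duration)
}

write_metaimage <- function(image, path) {
  d <- dim(image$voxels)
  local_data <- grepl("\\.mha$", tolower(path))
  datafile <- if (local_data) "LOCAL" else
    paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(d, collapse = " ")),
           paste("ElementSpacing =", paste(format(image$spacing, digits = 15),
                                           collapse = " ")),
           "ElementType = MET_DOUBLE",
           paste("ElementDataFile =", datafile))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (local_data) {
    writeBin(as.numeric(image$voxels), con, size = 8L, endian = "little")
  } else {
    con2 <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(con2), add = TRUE)
    writeBin(as.numeric(image$voxels), con2, size = 8L, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Persist and restore a calibration record
#'
#' JSON with fields `sensitivity_cps_per_MBq`, `u_sensitivity`, `nuclide`,
#' `half_life_h`, `reference_time`.
#'
#' @param cal a [calibration] object.
#' @param path JSON file path.
#' @return `write_calibration`: `path` invisibly; `read_calibration`: a
#'   [calibration].
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "calibration"))
  jsonlite::write_json(
    list(sensitivity_cps_per_MBq = cal$sensitivity,
         u_sensitivity = cal$u_sensitivity, nuclide = cal$nuclide,
         half_life_h = cal$half_life_h, reference_time = cal$reference_time),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration(sensitivity = x$sensitivity_cps_per_MBq,
              u_sensitivity = x$u_sensitivity %||% 0,
              nuclide = x$nuclide %||% "I-131",
              half_life_h = x$half_life_h %||% I131_HALF_LIFE_H,
              reference_time = x$reference_time %||% NA_character_)
}

#' Read time-activity samples from CSV
#'
#' Expected columns: `time_h`, `activity_MBq` and optionally
#' `u_activity_MBq`.
#'
#' @param path CSV file path.
#' @return Data frame of samples.
#' @export
read_tac_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_h", "activity_MBq") %in% names(x)))
    stop("time-activity CSV needs columns time_h, activity_MBq")
  x
}

#' Read recovery-curve observations from CSV
#'
#' Expected columns: `volume_ml`, `count_rate_cps`, `activity_MBq` (or a
#' pre-computed `recovery` column).
#'
#' @param path CSV file path.
#' @return Data frame with columns `volume`, `count_rate`, `activity`
#'   (and/or `recovery`) ready for [fit_recovery_curve()].
#' @export
read_recovery_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  ren <- c(volume_ml = "volume", count_rate_cps = "count_rate",
           activity_MBq = "activity")
  for (old in names(ren)) if (old %in% names(x))
    names(x)[names(x) == old] <- ren[[old]]
  if (!"volume" %in% names(x) ||
      !("recovery" %in% names(x) || all(c("count_rate", "activity") %in% names(x))))
    stop("recovery CSV needs volume_ml plus count_rate_cps & activity_MBq (or recovery)")
  x
}

#' Persist and restore a fitted recovery curve
#'
#' JSON with fields `b1_ml`, `b2` and the 2x2 parameter `covariance`.
#'
#' @param curve a [fit_recovery_curve()] result.
#' @param path JSON file path.
#' @export
write_recovery_curve <- function(curve, path) {
  stopifnot(inherits(curve, "recovery_curve"))
  jsonlite::write_json(
    list(b1_ml = curve$b1, b2 = curve$b2,
         covariance = unclass(curve$covariance)),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_recovery_curve
#' @export
read_recovery_curve <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cv <- matrix(as.numeric(x$covariance), 2, 2,
               dimnames = list(c("b1", "b2"), c("b1", "b2")))
  structure(list(b1 = x$b1_ml, b2 = x$b2, covariance = cv,
                 observations = NULL, fitted = NULL, residuals = NULL,
                 nls = NULL),
            class = "recovery_curve")
}

#' Read a dose-factor table from CSV
#'
#' Expected columns: `mass_g`, `factor_Gy_per_MBqh`.
#'
#' @param path CSV file path.
#' @return Data frame for [dose_factor_from_table()].
#' @export
read_dose_factor_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("mass_g", "factor_Gy_per_MBqh") %in% names(x)))
    stop("dose-factor CSV needs columns mass_g, factor_Gy_per_MBqh")
  x
}
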