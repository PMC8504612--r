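#' Read a 3D volume from NIfTI or MetaImage
#'
#' Reads `.nii`/`.nii.gz` (via RNifti) or `.mhd` + `.raw` MetaImage files.
#' Spacing and origin are taken from the header. Masks are binarized with a
#' `> 0.5` threshold.
#'
#' @param path file path; format is chosen by extension.
#' @param kind `"image"` or `"mask"`.
#' @return an [lw_volume()].
#' @export
read_volume <- function(path, kind = c("image", "mask")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    raw <- read_nifti_raw(path)
  } else if (grepl("\\.mhd$", lower)) {
    raw <- read_mhd_raw(path)
  } else {
    stop("unsupported volume format (expected .nii, .nii.gz or .mhd): ", path,
         call. = FALSE)
  }
  data <- raw$data
  d <- dim(data)
  # tolerate trailing singleton dimensions (e.g. 3D stored as X x Y x Z x 1)
  while (length(d) > 3L && d[length(d)] == 1L) {
    d <- d[-length(d)]
    dim(data) <- d
  }
  if (length(d) != 3L)
    stop(sprintf("expected a 3D payload, got %d dimensions in %s",
                 length(d), path), call. = FALSE)
  is_mask <- kind == "mask"
  if (is_mask) data <- (data > 0.5) * 1
  lw_volume(data, spacing = raw$spacing, origin = raw$origin, is_mask = is_mask)
}

#' Write a volume to NIfTI or MetaImage
#'
#' The written header carries the volume's spacing and origin; reading the
#' file back reproduces data, spacing and origin (bit-exactly for integer
#' payloads).
#'
#' @param v an [lw_volume()].
#' @param path output path ending in `.nii`, `.nii.gz` or `.mhd` (the `.raw`
#'   payload file is placed next to the `.mhd` header).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "lw_volume"))
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    write_nifti_raw(v$data, v$spacing, v$origin, path)
  } else if (grepl("\\.mhd$", lower)) {
    write_mhd_raw(v$data, v$spacing, v$origin, path)
  } else {
    stop("unsupported output format: ", path, call. = FALSE)
  }
  invisible(path)
}

read_nifti_raw <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file: ", path,
                                           "\n  ", conditionMessage(e),
                                           call. = FALSE))
  hdr <- RNifti::niftiHeader(img)
  pd <- hdr$pixdim[-1]
  list(data = array(as.numeric(img), dim(img)),
       spacing = abs(pd[1:3]),
       origin = c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z))
}

write_nifti_raw <- function(arr, spacing, origin, path) {
  img <- RNifti::asNifti(arr)
  xf <- rbind(cbind(diag(spacing), origin), c(0, 0, 0, 1))
  img <- RNifti::`qform<-`(img, structure(xf, code = 2L))
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(spacing, rep(1, max(0, nd - 3)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# --- MetaImage (.mhd + .raw) ------------------------------------------------
# Plain-text header, one `Key = value` per line, binary payload in a separate
# raw file. Only the uncompressed, separate-data-file layout is supported.

mhd_types <- list(
  MET_UCHAR  = list(size = 1L, what = "integer", signed = FALSE),
  MET_CHAR   = list(size = 1L, what = "integer", signed = TRUE),
  MET_USHORT = list(size = 2L, what = "integer", signed = FALSE),
  MET_SHORT  = list(size = 2L, what = "integer", signed = TRUE),
  MET_UINT   = list(size = 4L, what = "integer", signed = FALSE),
  MET_INT    = list(size = 4L, what = "integer", signed = TRUE),
  MET_FLOAT  = list(size = 4L, what = "numeric", signed = TRUE),
  MET_DOUBLE = list(size = 8L, what = "numeric", signed = TRUE)
)

read_mhd_raw <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed MetaImage header line: ", ln,
                                call. = FALSE)
    kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  ndims <- as.integer(kv$NDims %||% "3")
  if (is.na(ndims) || ndims != 3L)
    stop(sprintf("expected a 3D payload, got NDims = %s in %s",
                 kv$NDims %||% "?", path), call. = FALSE)
  dims <- as.integer(strsplit(kv$DimSize, "\\s+")[[1]])
  if (length(dims) != 3L || any(is.na(dims)))
    stop("bad DimSize in MetaImage header: ", path, call. = FALSE)
  spacing <- as.numeric(strsplit(kv$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  origin_key <- kv$Offset %||% kv$Origin %||% kv$Position %||% "0 0 0"
  origin <- as.numeric(strsplit(origin_key, "\\s+")[[1]])
  if (toupper(kv$CompressedData %||% "FALSE") == "TRUE")
    stop("compressed MetaImage data is not supported: ", path, call. = FALSE)
  type <- mhd_types[[kv$ElementType %||% ""]]
  if (is.null(type))
    stop("unsupported MetaImage ElementType: ", kv$ElementType, call. = FALSE)
  datafile <- kv$ElementDataFile
  if (is.null(datafile) || toupper(datafile) == "LOCAL")
    stop("MetaImage with embedded (LOCAL) data is not supported: ", path,
         call. = FALSE)
  if (!grepl("^(/|[A-Za-z]:)", datafile))
    datafile <- file.path(dirname(path), datafile)
  if (!file.exists(datafile))
    stop("MetaImage data file not found: ", datafile, call. = FALSE)
  msb <- toupper(kv$BinaryDataByteOrderMSB %||% kv$ElementByteOrderMSB %||% "FALSE") == "TRUE"
  n <- prod(dims)
  con <- file(datafile, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = type$what, n = n, size = type$size,
                  signed = type$signed, endian = if (msb) "big" else "little")
  if (length(vals) != n)
    stop("MetaImage payload shorter than DimSize implies: ", datafile,
         call. = FALSE)
  list(data = array(as.double(vals), dims), spacing = spacing, origin = origin)
}

write_mhd_raw <- function(arr, spacing, origin, path) {
  rawfile <- sub("\\.mhd$", ".raw", path, ignore.case = TRUE)
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("DimSize = %s", paste(dim(arr), collapse = " ")),
    sprintf("ElementSpacing = %s", paste(format(spacing, digits = 17), collapse = " ")),
    sprintf("Offset = %s", paste(format(origin, digits = 17), collapse = " ")),
    "ElementType = MET_DOUBLE",
    sprintf("ElementDataFile = %s", basename(rawfile))
  )
  writeLines(header, path)
  con <- file(rawfile, "wb")
  on.exit(close(con))
  writeBin(as.double(arr), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a landmark file
#'
#' One triple of voxel indices per line, whitespace- or comma-separated, as
#' distributed with DIR-Lab-style datasets. Input indices default to 1-based
#' (the DIR-Lab convention) and are converted to the package's 0-based
#' internal convention.
#'
#' @param path landmark text file.
#' @param frame `"fixed"` or `"moving"`.
#' @param one_based logical: are on-disk indices 1-based? Default `TRUE`.
#' @return an [lw_landmarks()].
#' @export
read_landmarks <- function(path, frame = c("fixed", "moving"),
                           one_based = TRUE) {
  frame <- match.arg(frame)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty landmark file: ", path, call. = FALSE)
  rows <- lapply(lines, function(ln) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[,[:space:]]+")[[1]]))
    if (length(v) != 3L || any(is.na(v)))
      stop("malformed landmark row (need 3 numeric fields): '", ln, "'",
           call. = FALSE)
    v
  })
  pts <- do.call(rbind, rows)
  if (one_based) pts <- pts - 1
  lw_landmarks(pts, frame)
}

#' Write a landmark file
#'
#' Mirrors [read_landmarks()]: internal 0-based coordinates are written
#' 1-based by default.
#' @param lms an [lw_landmarks()].
#' @param path output path.
#' @param one_based write 1-based indices (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lms, path, one_based = TRUE) {
  stopifnot(inherits(lms, "lw_landmarks"))
  pts <- lms$points + if (one_based) 1 else 0
  writeLines(apply(pts, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE), collapse = " ")), path)
  invisible(path)
}

#' Read/write a displacement field as 4D NIfTI
#'
#' Fields are stored as X x Y x Z x 3 NIfTI volumes, last axis = component
#' (x, y, z), in voxel units on the fixed grid — the package's canonical
#' on-disk field format.
#' @param path NIfTI path.
#' @return `read_field`: a 4D array; `write_field`: `path` invisibly.
#' @export
read_field <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) != 4L || dim(arr)[4] != 3L)
    stop("expected a X x Y x Z x 3 displacement field in ", path, call. = FALSE)
  as_field(arr)
}

#' @rdname read_field
#' @param field 4D array (X x Y x Z x 3), finite, voxel units.
#' @param spacing voxel spacing recorded in the header (mm).
#' @export
write_field <- function(field, path, spacing = c(1, 1, 1)) {
  field <- as_field(field)
  write_nifti_raw(field, spacing, c(0, 0, 0), path)
}

# validate a displacement field array
as_field <- function(field) {
  if (!is.array(field) || length(dim(field)) != 4L || dim(field)[4] != 3L)
    stop("displacement field must be a X x Y x Z x 3 array", call. = FALSE)
  if (any(!is.finite(field)))
    stop("displacement field contains non-finite values", call. = FALSE)
  storage.mode(field) <- "double"
  field
}
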