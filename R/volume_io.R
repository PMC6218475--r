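# Containers and file I/O for volumetric data.
#
# Axis convention throughout the package: data[z, y, x], i.e. the first
# array index is the slice index. voxel_size_um is stored per axis in the
# same (z, y, x) order.

#' Default voxel edge length in micrometers
#'
#' Isotropic reconstructed micro-CT voxel size assumed when a file carries no
#' spacing metadata. Typical desktop micro-CT scans of murine hindfeet are
#' reconstructed at 4-4.5 um; 4.5 um is the package default.
#' @export
DEFAULT_VOXEL_SIZE_UM <- 4.5

.check_spacing <- function(voxel_size_um) {
  v <- as.numeric(voxel_size_um)
  if (length(v) == 1L) v <- rep(v, 3L)
  if (length(v) != 3L || any(!is.finite(v)) || any(v <= 0)) {
    stop("voxel_size_um must be one or three strictly positive finite values")
  }
  v
}

.check_dim3 <- function(data) {
  d <- dim(data)
  if (is.null(d) || length(d) != 3L || any(d < 1L)) {
    stop("data must be a 3D array with all dimensions >= 1")
  }
  d
}

#' Construct a voxel volume
#'
#' A 3D grayscale scalar field with voxel-size metadata, representing a
#' reconstructed micro-CT scan. Axis order is (z, y, x): `data[s, , ]` is
#' slice `s`.
#'
#' @param data 3D numeric array, axis order (z, y, x).
#' @param voxel_size_um voxel edge length(s) in micrometers; a scalar is
#'   recycled to the three axes. Must be strictly positive.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, voxel_size_um = DEFAULT_VOXEL_SIZE_UM) {
  .check_dim3(data)
  if (!is.numeric(data)) stop("volume data must be numeric")
  structure(list(data = data, voxel_size_um = .check_spacing(voxel_size_um)),
            class = "voxel_volume")
}

#' Construct a binary bone mask
#'
#' @param data 3D logical array (TRUE = bone), axis order (z, y, x).
#' @inheritParams voxel_volume
#' @return An object of class `bone_mask`.
#' @export
bone_mask <- function(data, voxel_size_um = DEFAULT_VOXEL_SIZE_UM) {
  .check_dim3(data)
  if (!is.logical(data)) {
    if (is.numeric(data)) data <- array(data != 0, dim = dim(data))
    else stop("mask data must be logical")
  }
  if (anyNA(data)) stop("mask data must not contain NA")
  structure(list(data = data, voxel_size_um = .check_spacing(voxel_size_um)),
            class = "bone_mask")
}

#' Default murine hindfoot bone numbering
#'
#' Label-to-name table for individual tarsal/metatarsal bones of the mouse
#' hindfoot: 1 talus, 2 calcaneus, 3 navicular, 4-6 cuneiforms I-III,
#' 7 cuboid, 8 metatarsal V, 9 metatarsal IV, 10 fibula, 11 tibia,
#' 12-14 metatarsals I-III.
#'
#' @return Named character vector; names are the integer labels as strings.
#' @export
tarsal_bone_names <- function() {
  c(`1` = "Talus", `2` = "Calcaneus", `3` = "Navicular",
    `4` = "Cuneiform I", `5` = "Cuneiform II", `6` = "Cuneiform III",
    `7` = "Cuboid", `8` = "Metatarsal V", `9` = "Metatarsal IV",
    `10` = "Fibula", `11` = "Tibia", `12` = "Metatarsal I",
    `13` = "Metatarsal II", `14` = "Metatarsal III")
}

#' Construct a per-bone label volume
#'
#' Integer labels assign voxels to individual bones; 0 is background. Labels
#' without an explicit name fall back to the standard hindfoot numbering
#' ([tarsal_bone_names()]), then to `"bone_<label>"`.
#'
#' @param data 3D non-negative integer array, axis order (z, y, x).
#' @param label_names named character vector mapping label (as name) to bone
#'   name; may be `NULL`.
#' @inheritParams voxel_volume
#' @return An object of class `labeled_bones`.
#' @export
labeled_bones <- function(data, voxel_size_um = DEFAULT_VOXEL_SIZE_UM,
                          label_names = NULL) {
  .check_dim3(data)
  if (!is.numeric(data)) stop("label data must be integer-valued")
  if (anyNA(data) || any(data < 0) || any(data != round(data))) {
    stop("labels must be non-negative integers with no NA")
  }
  data <- array(as.integer(data), dim = dim(data))
  present <- sort(unique(data[data > 0L]))
  nm <- character(0)
  if (!is.null(label_names)) {
    if (is.null(names(label_names))) stop("label_names must be named by label")
    nm <- stats::setNames(as.character(label_names), names(label_names))
  }
  defaults <- tarsal_bone_names()
  for (l in present) {
    key <- as.character(l)
    if (!key %in% names(nm)) {
      nm[key] <- if (key %in% names(defaults)) defaults[[key]]
                 else paste0("bone_", key)
    }
  }
  structure(list(data = data, voxel_size_um = .check_spacing(voxel_size_um),
                 label_names = nm[order(as.integer(names(nm)))]),
            class = "labeled_bones")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume> %s voxels, voxel size %s um, range [%g, %g]\n",
              paste(dim(x$data), collapse = " x "),
              paste(signif(x$voxel_size_um, 4), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.bone_mask <- function(x, ...) {
  cat(sprintf("<bone_mask> %s voxels, %d foreground, voxel size %s um\n",
              paste(dim(x$data), collapse = " x "), sum(x$data),
              paste(signif(x$voxel_size_um, 4), collapse = " x ")))
  invisible(x)
}

#' @export
print.labeled_bones <- function(x, ...) {
  cat(sprintf("<labeled_bones> %s voxels, labels: %s\n",
              paste(dim(x$data), collapse = " x "),
              paste(sprintf("%s=%s", names(x$label_names), x$label_names),
                    collapse = ", ")))
  invisible(x)
}

# relative per-axis spacing used for distance computations in voxel units;
# isotropic scans give (1, 1, 1)
rel_spacing <- function(x) {
  v <- x$voxel_size_um
  v / min(v)
}

.sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".labels.json")
}

.infer_format <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(format, c("nrrd", "mhd")))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         nrrd = "nrrd",
         nhdr = "nrrd",
         mhd = "mhd",
         stop("cannot infer volume format from extension '", ext,
              "'; supported: nrrd, mhd"))
}

.nrrd_type <- function(kind) {
  switch(kind, volume = "double", mask = "unsigned char", labels = "int")
}

.object_kind <- function(x) {
  if (inherits(x, "voxel_volume")) "volume"
  else if (inherits(x, "bone_mask")) "mask"
  else if (inherits(x, "labeled_bones")) "labels"
  else stop("expected a voxel_volume, bone_mask or labeled_bones object")
}

.raw_payload <- function(x, kind) {
  if (kind == "volume") {
    writeBin(as.numeric(x$data), raw(), size = 8, endian = "little")
  } else if (kind == "mask") {
    writeBin(as.integer(x$data), raw(), size = 1, endian = "little")
  } else {
    writeBin(as.integer(x$data), raw(), size = 4, endian = "little")
  }
}

#' Write a volume, mask or label map to disk
#'
#' Supported formats: NRRD (single file, raw little-endian payload) and
#' MHD/RAW (text header plus `.raw` payload next to it). Label maps write
#' their label-name table to a JSON sidecar (`<stem>.labels.json`) so the
#' image file stays standard. Round-trips exactly through [read_volume()].
#'
#' @param x a `voxel_volume`, `bone_mask` or `labeled_bones` object.
#' @param path output file path (`.nrrd` or `.mhd`).
#' @param format `"nrrd"` or `"mhd"`; inferred from the extension if `NULL`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, format = NULL) {
  kind <- .object_kind(x)
  fmt <- .infer_format(path, format)
  .check_spacing(x$voxel_size_um)
  d <- dim(x$data)
  payload <- .raw_payload(x, kind)

  if (fmt == "nrrd") {
    header <- c(
      "NRRD0004",
      paste0("type: ", .nrrd_type(kind)),
      "dimension: 3",
      paste0("sizes: ", paste(d, collapse = " ")),
      paste0("spacings: ", paste(format(x$voxel_size_um, digits = 17),
                                 collapse = " ")),
      "endian: little",
      "encoding: raw",
      paste0("content: osteoerode-", kind),
      "")
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeLines(header, con, sep = "\n")
    writeBin(payload, con)
  } else {
    raw_name <- paste0(basename(tools::file_path_sans_ext(path)), ".raw")
    mtype <- switch(kind, volume = "MET_DOUBLE", mask = "MET_UCHAR",
                    labels = "MET_INT")
    header <- c(
      "ObjectType = Image",
      "NDims = 3",
      "BinaryData = True",
      "BinaryDataByteOrderMSB = False",
      paste0("DimSize = ", paste(d, collapse = " ")),
      paste0("ElementSpacing = ", paste(format(x$voxel_size_um, digits = 17),
                                        collapse = " ")),
      paste0("ElementType = ", mtype),
      paste0("Content = osteoerode-", kind),
      paste0("ElementDataFile = ", raw_name))
    writeLines(header, path)
    writeBin(payload, file.path(dirname(path), raw_name))
  }

  if (kind == "labels") {
    jsonlite::write_json(as.list(x$label_names), .sidecar_path(path),
                         auto_unbox = TRUE)
  }
  invisible(path)
}

.decode_payload <- function(raw_data, type, n) {
  spec <- switch(type,
    "unsigned char" = , "uchar" = , "uint8" = list(what = integer(), size = 1,
                                                   signed = FALSE),
    "short" = , "int16" = list(what = integer(), size = 2, signed = TRUE),
    "unsigned short" = , "uint16" = list(what = integer(), size = 2,
                                         signed = FALSE),
    "int" = , "int32" = list(what = integer(), size = 4, signed = TRUE),
    "float" = list(what = numeric(), size = 4, signed = TRUE),
    "double" = list(what = numeric(), size = 8, signed = TRUE),
    stop("unsupported element type '", type, "'"))
  if (length(raw_data) < n * spec$size) {
    stop("payload too short: expected ", n * spec$size, " bytes, got ",
         length(raw_data))
  }
  readBin(raw_data, what = spec$what, n = n, size = spec$size,
          signed = spec$signed, endian = "little")
}

.assemble <- function(values, d, spacing, kind, path) {
  arr <- array(values, dim = d)
  if (kind == "mask") {
    bone_mask(arr != 0, spacing)
  } else if (kind == "labels") {
    nm <- NULL
    sc <- .sidecar_path(path)
    if (file.exists(sc)) {
      nm <- unlist(jsonlite::read_json(sc))
    }
    labeled_bones(arr, spacing, label_names = nm)
  } else {
    voxel_volume(arr + 0.0, spacing)
  }
}

#' Read a volume, mask or label map from disk
#'
#' Reads NRRD or MHD/RAW files written by [write_volume()] or by standard
#' tools (raw encoding, little-endian). Files written by this package carry a
#' content tag and come back as the object they were (`bone_mask` /
#' `labeled_bones`, with names recovered from the JSON sidecar); foreign
#' files come back as a `voxel_volume`. Missing spacing metadata falls back
#' to the documented 4.5 um default with a warning.
#'
#' @param path input file path.
#' @param format `"nrrd"` or `"mhd"`; inferred from the extension if `NULL`.
#' @return A `voxel_volume`, `bone_mask` or `labeled_bones` object.
#' @export
read_volume <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- .infer_format(path, format)
  if (fmt == "nrrd") .read_nrrd(path) else .read_mhd(path)
}

.spacing_or_default <- function(spacing, path) {
  if (is.null(spacing)) {
    warning("no voxel spacing metadata in '", basename(path),
            "'; assuming isotropic ", DEFAULT_VOXEL_SIZE_UM, " um")
    rep(DEFAULT_VOXEL_SIZE_UM, 3L)
  } else {
    spacing
  }
}

.read_nrrd <- function(path) {
  bytes <- readBin(path, raw(), n = file.size(path))
  # header ends at the first blank line
  nl <- which(bytes == as.raw(10L))
  split_at <- NA_integer_
  for (i in seq_along(nl)[-1]) {
    if (nl[i] == nl[i - 1] + 1L) { split_at <- nl[i]; break }
  }
  if (is.na(split_at)) stop("malformed NRRD: no header terminator in ", path)
  header <- strsplit(rawToChar(bytes[seq_len(split_at - 2L)]), "\n",
                     fixed = TRUE)[[1]]
  if (!grepl("^NRRD", header[1])) stop("not an NRRD file: ", path)
  fields <- list()
  for (line in header[-1]) {
    if (grepl("^\\s*#", line) || !grepl(":", line, fixed = TRUE)) next
    kv <- sub(":=", ":", line, fixed = TRUE)
    key <- tolower(trimws(sub(":.*$", "", kv)))
    val <- trimws(sub("^[^:]*:", "", kv))
    fields[[key]] <- val
  }
  if (is.null(fields$encoding) || fields$encoding != "raw") {
    stop("unsupported NRRD encoding '", fields$encoding, "' (raw only)")
  }
  if (!is.null(fields$endian) && fields$endian != "little") {
    stop("unsupported NRRD endianness '", fields$endian, "'")
  }
  d <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(d) != 3L) stop("only 3D NRRD volumes are supported")
  spacing <- NULL
  if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  }
  spacing <- .spacing_or_default(spacing, path)
  values <- .decode_payload(bytes[(split_at + 1L):length(bytes)],
                            fields$type, prod(d))
  kind <- "volume"
  if (!is.null(fields$content) && grepl("^osteoerode-", fields$content)) {
    kind <- sub("^osteoerode-", "", fields$content)
  }
  .assemble(values, d, spacing, kind, path)
}

.read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fields <- list()
  for (line in lines) {
    if (!grepl("=", line, fixed = TRUE)) next
    key <- trimws(sub("=.*$", "", line))
    val <- trimws(sub("^[^=]*=", "", line))
    fields[[key]] <- val
  }
  if (!identical(fields$NDims, "3")) stop("only 3D MHD volumes are supported")
  if (!is.null(fields$BinaryDataByteOrderMSB) &&
      tolower(fields$BinaryDataByteOrderMSB) == "true") {
    stop("big-endian MHD payloads are not supported")
  }
  d <- as.integer(strsplit(fields$DimSize, "\\s+")[[1]])
  spacing <- NULL
  if (!is.null(fields$ElementSpacing)) {
    spacing <- as.numeric(strsplit(fields$ElementSpacing, "\\s+")[[1]])
  }
  spacing <- .spacing_or_default(spacing, path)
  type <- switch(fields$ElementType,
                 MET_UCHAR = "unsigned char", MET_SHORT = "short",
                 MET_USHORT = "unsigned short", MET_INT = "int",
                 MET_FLOAT = "float", MET_DOUBLE = "double",
                 stop("unsupported MHD ElementType '", fields$ElementType, "'"))
  raw_path <- file.path(dirname(path), fields$ElementDataFile)
  if (!file.exists(raw_path)) stop("MHD payload not found: ", raw_path)
  values <- .decode_payload(readBin(raw_path, raw(), n = file.size(raw_path)),
                            type, prod(d))
  kind <- "volume"
  if (!is.null(fields$Content) && grepl("^osteoerode-", fields$Content)) {
    kind <- sub("^osteoerode-", "", fields$Content)
  }
  .assemble(values, d, spacing, kind, path)
}
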