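# Minimal single-frame monochrome DICOM (Part 10, Explicit VR Little
# Endian) writer and reader. Scope is deliberately narrow: 16-bit unsigned
# single-channel images with rescale slope/intercept, which is all the
# thermal workflow needs. Acquisition metadata travel as a JSON string in
# ImageComments plus PatientID for the cow identifier.

UID_TRANSFER_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_SECONDARY_CAPTURE <- "1.2.840.10008.5.1.4.1.1.7"
UID_IMPL_CLASS <- "2.25.840422871257491127"

.uid_counter <- new.env(parent = emptyenv())

new_uid <- function() {
  if (is.null(.uid_counter$n)) .uid_counter$n <- 0L
  .uid_counter$n <- .uid_counter$n + 1L
  stamp <- gsub("[^0-9]", "", format(Sys.time(), "%Y%m%d%H%M%OS3"))
  sprintf("2.25.%s%d.%d", stamp, Sys.getpid() %% 100000L, .uid_counter$n)
}

uint16_bytes <- function(x) {
  x <- as.integer(x)
  writeBin(ifelse(x > 32767L, x - 65536L, x), raw(), size = 2,
           endian = "little")
}

uint32_bytes <- function(x) {
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

tag_bytes <- function(group, element) {
  c(uint16_bytes(group), uint16_bytes(element))
}

# One data element, explicit VR little endian
dicom_element <- function(group, element, vr, value) {
  if (vr %in% c("UI", "CS", "DA", "TM", "LO", "LT", "SH", "DS", "IS", "PN")) {
    bytes <- charToRaw(as.character(value))
    if (length(bytes) %% 2L == 1L)
      bytes <- c(bytes, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  } else if (vr == "US") {
    bytes <- uint16_bytes(value)
  } else if (vr == "UL") {
    bytes <- uint32_bytes(value)
  } else if (vr %in% c("OB", "OW")) {
    bytes <- value
    if (length(bytes) %% 2L == 1L) bytes <- c(bytes, as.raw(0L))
  } else stop("unsupported VR: ", vr)
  header <- c(tag_bytes(group, element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "SQ", "UT", "UN")) {
    header <- c(header, as.raw(c(0L, 0L)), uint32_bytes(length(bytes)))
  } else {
    header <- c(header, uint16_bytes(length(bytes)))
  }
  c(header, bytes)
}

#' Write a temperature map as a single-frame DICOM file
#'
#' Writes a monochrome 16-bit unsigned image (Explicit VR Little Endian,
#' secondary-capture SOP class) with RescaleSlope 0.1 and RescaleIntercept
#' 0 declared, so conformant viewers display degrees Celsius directly
#' (stored 312 -> 31.2 degC). Acquisition metadata are serialized to JSON
#' in ImageComments; the cow identifier is also placed in PatientID. The
#' round trip through [read_dicom()] is bit-exact.
#'
#' @param tmap a [temperature_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(tmap, path) {
  stopifnot(inherits(tmap, "temperature_map"))
  if (any(tmap$pixels > 65535L))
    stop("stored values exceed 16-bit unsigned range")
  sop_uid <- new_uid()

  meta_elements <- c(
    dicom_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dicom_element(0x0002, 0x0002, "UI", UID_SECONDARY_CAPTURE),
    dicom_element(0x0002, 0x0003, "UI", sop_uid),
    dicom_element(0x0002, 0x0010, "UI", UID_TRANSFER_EXPLICIT_LE),
    dicom_element(0x0002, 0x0012, "UI", UID_IMPL_CLASS)
  )
  meta <- c(dicom_element(0x0002, 0x0000, "UL", length(meta_elements)),
            meta_elements)

  cow <- tmap$meta$cow_id
  if (is.null(cow) || is.na(cow)) cow <- "UNKNOWN"
  comments <- jsonlite::toJSON(tmap$meta, auto_unbox = TRUE, null = "null")
  # row-major pixel order as DICOM requires
  pix_bytes <- uint16_bytes(as.vector(t(tmap$pixels)))

  body <- c(
    dicom_element(0x0008, 0x0016, "UI", UID_SECONDARY_CAPTURE),
    dicom_element(0x0008, 0x0018, "UI", sop_uid),
    dicom_element(0x0008, 0x0060, "CS", "OT"),
    dicom_element(0x0010, 0x0020, "LO", cow),
    dicom_element(0x0020, 0x4000, "LT", as.character(comments)),
    dicom_element(0x0028, 0x0002, "US", 1L),
    dicom_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dicom_element(0x0028, 0x0010, "US", nrow(tmap$pixels)),
    dicom_element(0x0028, 0x0011, "US", ncol(tmap$pixels)),
    dicom_element(0x0028, 0x0100, "US", 16L),
    dicom_element(0x0028, 0x0101, "US", 16L),
    dicom_element(0x0028, 0x0102, "US", 15L),
    dicom_element(0x0028, 0x0103, "US", 0L),
    dicom_element(0x0028, 0x1052, "DS", "0"),
    dicom_element(0x0028, 0x1053, "DS", "0.1"),
    dicom_element(0x0028, 0x1054, "LO", "CEL"),
    dicom_element(0x7FE0, 0x0010, "OW", pix_bytes)
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

read_uint16 <- function(raw, offset) {
  as.integer(raw[offset + 1L]) + 256L * as.integer(raw[offset + 2L])
}

read_uint32 <- function(raw, offset) {
  sum(as.numeric(raw[offset + 1:4]) * c(1, 256, 65536, 16777216))
}

#' Read a single-frame monochrome DICOM file
#'
#' Parses the Explicit VR Little Endian encoding produced by
#' [write_dicom()] (and by other writers using that transfer syntax),
#' applying no rescaling to the stored pixels: the returned
#' [temperature_map()] carries the raw stored integers and the file must
#' declare RescaleSlope 0.1 (or omit it, in which case 0.1 is assumed for
#' files produced by this package's writer).
#'
#' @param path DICOM file path.
#' @return a [temperature_map()].
#' @export
read_dicom <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 160 ||
      rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM Part 10 file: ", path)
  pos <- 132L
  elems <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 8L <= length(bytes)) {
    group <- read_uint16(bytes, pos)
    element <- read_uint16(bytes, pos + 2L)
    vr <- rawToChar(bytes[(pos + 5L):(pos + 6L)])
    if (vr %in% long_vrs) {
      len <- read_uint32(bytes, pos + 8L)
      val_start <- pos + 12L
    } else {
      len <- read_uint16(bytes, pos + 6L)
      val_start <- pos + 8L
    }
    key <- sprintf("%04X%04X", group, element)
    elems[[key]] <- list(vr = vr, start = val_start, len = len)
    pos <- val_start + as.integer(len)
  }
  get_str <- function(key) {
    e <- elems[[key]]
    if (is.null(e)) return(NULL)
    b <- bytes[(e$start + 1L):(e$start + e$len)]
    trimws(rawToChar(b[b != as.raw(0L)]))
  }
  get_us <- function(key) {
    e <- elems[[key]]
    if (is.null(e)) return(NULL)
    read_uint16(bytes, e$start)
  }
  rows <- get_us("00280010"); cols <- get_us("00280011")
  bits <- get_us("00280100")
  pix <- elems[["7FE00010"]]
  if (is.null(rows) || is.null(cols) || is.null(pix))
    stop("file lacks required pixel attributes (Rows/Columns/PixelData)")
  if (!is.null(bits) && bits != 16L)
    stop("only 16-bit images are supported")
  slope <- get_str("00281053")
  if (!is.null(slope) && abs(as.numeric(slope) - 0.1) > 1e-12)
    stop("unexpected rescale slope: ", slope)
  n <- rows * cols
  if (pix$len < 2 * n) stop("truncated pixel data")
  con <- rawConnection(bytes[(pix$start + 1L):(pix$start + 2L * n)])
  vals <- readBin(con, "integer", n = n, size = 2, signed = FALSE,
                  endian = "little")
  close(con)
  meta <- list()
  comments <- get_str("00204000")
  if (!is.null(comments) && nzchar(comments))
    meta <- tryCatch(jsonlite::fromJSON(comments), error = function(e) list())
  cow <- get_str("00100020")
  if (!is.null(cow) && is.null(meta$cow_id)) meta$cow_id <- cow
  temperature_map(matrix(vals, nrow = rows, ncol = cols, byrow = TRUE),
                  meta = meta)
}
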