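# Minimal DICOM reader for axial CT series: Part 10 files, little-endian
# explicit or implicit VR, uncompressed single-frame slices. Covers the tags
# a CT stack needs (geometry, rescale, pixel data); sequences and encapsulated
# transfer syntaxes are rejected.

dcm_tag <- function(group, element) sprintf("%04X,%04X", group, element)

# Parse one DICOM file into a named list of the elements we care about.
dcm_parse_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 132L || rawToChar(raw[129:132]) != "DICM") {
    stop("not a DICOM Part 10 file: ", path)
  }
  pos <- 133L  # 1-based offset of first meta element
  u16 <- function(at) readBin(raw[at:(at + 1L)], "integer", size = 2,
                              endian = "little", signed = FALSE)
  u32 <- function(at) {
    v <- readBin(raw[at:(at + 3L)], "integer", size = 4, endian = "little")
    if (v < 0) stop("unsupported undefined/huge element length in ", path)
    v
  }
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  elements <- list()
  explicit <- TRUE  # meta group is always explicit VR little endian
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    if (explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- u32(pos + 4L); hdr <- 8L
    }
    if (!is.na(vr) && vr == "SQ") stop("DICOM sequences are not supported: ", path)
    val_at <- pos + hdr
    if (val_at + len - 1L > n) stop("truncated DICOM element in ", path)
    key <- dcm_tag(group, element)
    elements[[key]] <- list(vr = vr, raw = raw[seq.int(val_at, length.out = len)])
    pos <- val_at + len
    # Transfer syntax decides VR mode for the main dataset (group > 0002)
    if (key == "0002,0010") {
      ts <- dcm_string(elements[[key]])
      if (ts == "1.2.840.10008.1.2") {
        explicit_next <- FALSE
      } else if (ts %in% c("1.2.840.10008.1.2.1")) {
        explicit_next <- TRUE
      } else {
        stop("unsupported DICOM transfer syntax ", ts, " in ", path)
      }
      attr(elements, "ts_explicit") <- explicit_next
    }
    if (group > 0x0002 && !is.null(attr(elements, "ts_explicit"))) {
      explicit <- attr(elements, "ts_explicit")
    }
  }
  elements
}

dcm_string <- function(el) {
  if (is.null(el)) return(NULL)
  s <- rawToChar(el$raw[el$raw != as.raw(0)])  # strip NUL padding
  sub("\\s+$", "", s)
}

dcm_numbers <- function(el) {
  s <- dcm_string(el)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_uint16 <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el$raw, "integer", size = 2, endian = "little", signed = FALSE)
}

# Decode one slice to a Rows x Cols HU matrix (row-major on disk).
dcm_slice_matrix <- function(elements, path) {
  rows <- dcm_uint16(elements[["0028,0010"]])
  cols <- dcm_uint16(elements[["0028,0011"]])
  bits <- dcm_uint16(elements[["0028,0100"]])
  if (is.null(rows) || is.null(cols)) stop("missing Rows/Columns in ", path)
  if (is.null(bits) || bits != 16L) stop("only 16-bit pixel data supported: ", path)
  signed <- identical(dcm_uint16(elements[["0028,0103"]]), 1L)
  px <- elements[["7FE0,0010"]]
  if (is.null(px)) stop("missing PixelData in ", path)
  vals <- readBin(px$raw, "integer", n = rows * cols, size = 2,
                  endian = "little", signed = signed)
  if (length(vals) != rows * cols) stop("short PixelData in ", path)
  slope <- dcm_numbers(elements[["0028,1053"]]); if (is.null(slope)) slope <- 1
  inter <- dcm_numbers(elements[["0028,1052"]]); if (is.null(inter)) inter <- 0
  hu <- slope * vals + inter
  matrix(hu, nrow = rows, ncol = cols, byrow = TRUE)
}

# Read a directory holding one coherent axial series into a ct_volume.
read_dicom_series <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in DICOM directory: ", path)
  parsed <- lapply(files, dcm_parse_file)

  uids <- vapply(parsed, function(e) {
    u <- dcm_string(e[["0020,000E"]])
    if (is.null(u)) "" else u
  }, character(1))
  if (length(unique(uids)) > 1L) {
    stop("mixed series: directory contains ", length(unique(uids)),
         " different SeriesInstanceUIDs")
  }

  # physical slice position: ImagePositionPatient z, else SliceLocation,
  # else InstanceNumber
  zpos <- vapply(seq_along(parsed), function(i) {
    e <- parsed[[i]]
    ipp <- dcm_numbers(e[["0020,0032"]])
    if (!is.null(ipp) && length(ipp) >= 3) return(ipp[3])
    sl <- dcm_numbers(e[["0020,1041"]])
    if (!is.null(sl)) return(sl[1])
    inum <- dcm_numbers(e[["0020,0013"]])
    if (!is.null(inum)) return(inum[1])
    stop("cannot order slice ", files[i], ": no position tags")
  }, numeric(1))
  ord <- order(zpos)
  parsed <- parsed[ord]; zpos <- zpos[ord]

  slices <- lapply(seq_along(parsed), function(i)
    dcm_slice_matrix(parsed[[i]], files[ord[i]]))
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("inconsistent slice dimensions across series")
  }

  if (length(parsed) > 1L) {
    dz <- diff(zpos)
    if (any(dz <= 0)) stop("duplicate or unordered slice positions")
    if ((max(dz) - min(dz)) > 0.01 * mean(dz)) {
      stop(sprintf("nonuniform slice spacing (%.4g-%.4g mm) beyond 1%% tolerance",
                   min(dz), max(dz)))
    }
    slice_sp <- mean(dz)
  } else {
    st <- dcm_numbers(parsed[[1]][["0018,0050"]])
    slice_sp <- if (!is.null(st)) st[1] else 1
  }

  ps <- dcm_numbers(parsed[[1]][["0028,0030"]])  # "row\col" spacing
  if (is.null(ps) || length(ps) < 2) ps <- c(1, 1)

  vox <- array(NA_real_, c(length(slices), dims[1, 1], dims[2, 1]))
  for (i in seq_along(slices)) vox[i, , ] <- slices[[i]]
  ct_volume(vox, spacing = c(slice_sp, ps[1], ps[2]),
            id = if (nzchar(uids[1])) uids[1] else basename(path))
}
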