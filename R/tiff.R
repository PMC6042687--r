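# Minimal baseline TIFF support: uncompressed, grayscale, little-endian,
# multi-page, 8/16-bit unsigned (32-bit uint and float32 accepted on read).
# OME-XML metadata (voxel spacing, channel names) rides in the first page's
# ImageDescription tag. This is deliberately the smallest dialect every
# scientific TIFF reader understands; no installed R package reads TIFF.

.u16le <- function(v) {
  v <- as.integer(v)
  ifelse(v > 32767L, v - 65536L, v)
}

.wr_entry <- function(con, tag, type, count, value_raw4) {
  writeBin(.u16le(tag), con, size = 2, endian = "little")
  writeBin(.u16le(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  writeBin(value_raw4, con)
}

.raw4_long <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
.raw4_short <- function(x) {
  c(writeBin(.u16le(x), raw(), size = 2, endian = "little"), as.raw(c(0, 0)))
}

#' Write a multi-page grayscale TIFF
#'
#' @param pages 3D array `(z, y, x)`: one page per z-plane, or a list of 2D
#'   matrices `(y, x)`.
#' @param path output file.
#' @param bits 8 or 16 (unsigned).
#' @param description optional character scalar stored in the first page's
#'   ImageDescription tag (used for OME-XML).
#' @return `path`, invisibly.
#' @keywords internal
write_tiff <- function(pages, path, bits = 16L, description = NULL) {
  if (is.array(pages) && length(dim(pages)) == 3L) {
    pages <- lapply(seq_len(dim(pages)[1]), function(k) pages[k, , , drop = TRUE])
  }
  stopifnot(is.list(pages), length(pages) >= 1L, bits %in% c(8L, 16L))
  np <- length(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  bpp <- bits / 8L
  page_bytes <- as.integer(w * h * bpp)
  desc <- if (is.null(description)) NULL else c(charToRaw(description), as.raw(0))
  if (!is.null(desc) && length(desc) %% 2L == 1L) desc <- c(desc, as.raw(0))

  data_off <- 8L
  desc_off <- data_off + np * page_bytes
  ifd_off0 <- desc_off + if (is.null(desc)) 0L else length(desc)
  n_entries <- function(p) if (p == 1L && !is.null(desc)) 11L else 10L
  ifd_size <- function(p) 2L + 12L * n_entries(p) + 4L
  ifd_offs <- ifd_off0 + cumsum(c(0L, vapply(seq_len(np - 1L), ifd_size, 1L)))

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw("II"), con)
  writeBin(.u16le(42L), con, size = 2, endian = "little")
  writeBin(as.integer(ifd_off0), con, size = 4, endian = "little")
  for (p in seq_len(np)) {
    m <- pages[[p]]
    if (nrow(m) != h || ncol(m) != w) stop("pages must share one shape", call. = FALSE)
    v <- as.integer(round(t(m)))            # row-major: x fastest
    v[v < 0L] <- 0L
    top <- if (bits == 8L) 255L else 65535L
    v[v > top] <- top
    if (bits == 8L) {
      writeBin(as.raw(v), con)
    } else {
      writeBin(.u16le(v), con, size = 2, endian = "little")
    }
  }
  if (!is.null(desc)) writeBin(desc, con)
  for (p in seq_len(np)) {
    writeBin(.u16le(n_entries(p)), con, size = 2, endian = "little")
    .wr_entry(con, 256L, 4L, 1L, .raw4_long(w))
    .wr_entry(con, 257L, 4L, 1L, .raw4_long(h))
    .wr_entry(con, 258L, 3L, 1L, .raw4_short(bits))
    .wr_entry(con, 259L, 3L, 1L, .raw4_short(1L))   # no compression
    .wr_entry(con, 262L, 3L, 1L, .raw4_short(1L))   # BlackIsZero
    if (p == 1L && !is.null(desc)) {
      .wr_entry(con, 270L, 2L, length(desc), .raw4_long(desc_off))
    }
    .wr_entry(con, 273L, 4L, 1L, .raw4_long(data_off + (p - 1L) * page_bytes))
    .wr_entry(con, 277L, 3L, 1L, .raw4_short(1L))
    .wr_entry(con, 278L, 4L, 1L, .raw4_long(h))
    .wr_entry(con, 279L, 4L, 1L, .raw4_long(page_bytes))
    .wr_entry(con, 339L, 3L, 1L, .raw4_short(1L))   # unsigned int
    nxt <- if (p < np) ifd_offs[p + 1L] else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

.rd_int <- function(raw, off, size, endian) {
  # readBin only supports unsigned for 1/2-byte sizes; 4-byte offsets in our
  # files stay far below 2^31, so signed 32-bit reads are lossless
  readBin(raw[off:(off + size - 1L)], "integer", n = 1L, size = size,
          endian = endian, signed = size > 2L)
}

.rd_vals <- function(raw, off, type, count, endian) {
  # type: 1 BYTE, 2 ASCII, 3 SHORT, 4 LONG, 11 FLOAT
  size <- c(1L, 1L, 2L, 4L, NA, NA, NA, NA, NA, NA, 4L)[type]
  total <- size * count
  src_off <- if (total <= 4L) off else .rd_int(raw, off, 4L, endian) + 1L
  bytes <- raw[src_off:(src_off + total - 1L)]
  if (type == 2L) {
    return(rawToChar(bytes[bytes != as.raw(0)]))
  }
  if (type == 11L) {
    return(readBin(bytes, "double", n = count, size = 4L, endian = endian))
  }
  readBin(bytes, "integer", n = count, size = size, endian = endian,
          signed = size > 2L)
}

#' Read a multi-page grayscale TIFF
#'
#' @param path TIFF file.
#' @return list with `pages` (3D array `(page, y, x)`) and `description`
#'   (character or `NULL`).
#' @keywords internal
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file: ", path, call. = FALSE)
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    stop("not a TIFF file: ", path, call. = FALSE)
  off <- .rd_int(raw, 5L, 4L, endian) + 1L
  pages <- list()
  description <- NULL
  while (off > 1L) {
    n <- .rd_int(raw, off, 2L, endian)
    tags <- list()
    for (e in seq_len(n)) {
      eo <- off + 2L + (e - 1L) * 12L
      tag <- .rd_int(raw, eo, 2L, endian)
      type <- .rd_int(raw, eo + 2L, 2L, endian)
      count <- .rd_int(raw, eo + 4L, 4L, endian)
      tags[[as.character(tag)]] <- list(type = type, count = count, voff = eo + 8L)
    }
    gettag <- function(id, default = NULL) {
      t <- tags[[as.character(id)]]
      if (is.null(t)) return(default)
      .rd_vals(raw, t$voff, t$type, t$count, endian)
    }
    w <- gettag(256L); h <- gettag(257L)
    bits <- gettag(258L, 1L)[1]
    comp <- gettag(259L, 1L)
    fmt <- gettag(339L, 1L)[1]
    if (comp != 1L) stop("only uncompressed TIFF is supported", call. = FALSE)
    if (is.null(description)) description <- gettag(270L)
    offs <- gettag(273L); counts <- gettag(279L)
    bytes <- unlist(lapply(seq_along(offs), function(s) {
      raw[(offs[s] + 1L):(offs[s] + counts[s])]
    }))
    vals <- if (fmt == 3L) {
      readBin(bytes, "double", n = w * h, size = bits / 8L, endian = endian)
    } else if (bits == 8L) {
      as.integer(bytes)
    } else if (bits %in% c(16L, 32L)) {
      v <- readBin(bytes, "integer", n = w * h, size = bits / 8L,
                   endian = endian, signed = bits > 16L)
      as.numeric(v)
    } else stop("unsupported bit depth: ", bits, call. = FALSE)
    pages[[length(pages) + 1L]] <- t(matrix(vals, nrow = w, ncol = h))
    off <- .rd_int(raw, off + 2L + n * 12L, 4L, endian) + 1L
  }
  np <- length(pages)
  arr <- array(0, c(np, nrow(pages[[1]]), ncol(pages[[1]])))
  for (p in seq_len(np)) arr[p, , ] <- pages[[p]]
  list(pages = arr, description = description)
}

ome_xml <- function(dims_zyx, channels, spacing, type = "uint16", name = "cell") {
  ch <- paste(sprintf('<Channel ID="Channel:0:%d" Name="%s" SamplesPerPixel="1"/>',
                      seq_along(channels) - 1L, channels), collapse = "")
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    sprintf('<Image ID="Image:0" Name="%s">', name),
    sprintf(paste0('<Pixels ID="Pixels:0" DimensionOrder="XYZCT" Type="%s" ',
                   'SizeX="%d" SizeY="%d" SizeZ="%d" SizeC="%d" SizeT="1" ',
                   'PhysicalSizeX="%.17g" PhysicalSizeY="%.17g" PhysicalSizeZ="%.17g">'),
            type, dims_zyx[3], dims_zyx[2], dims_zyx[1], length(channels),
            spacing[3], spacing[2], spacing[1]),
    ch, "</Pixels></Image></OME>"
  )
}

parse_ome <- function(description) {
  if (is.null(description) || !grepl("<OME", description, fixed = TRUE)) return(NULL)
  out <- tryCatch({
    doc <- xml2::read_xml(description)
    xml2::xml_ns_strip(doc)
    px <- xml2::xml_find_first(doc, ".//Pixels")
    att <- function(a) xml2::xml_attr(px, a)
    chn <- xml2::xml_attr(xml2::xml_find_all(doc, ".//Channel"), "Name")
    list(
      size = c(z = as.integer(att("SizeZ")), c = as.integer(att("SizeC")),
               y = as.integer(att("SizeY")), x = as.integer(att("SizeX"))),
      spacing = as.numeric(c(att("PhysicalSizeZ"), att("PhysicalSizeY"),
                             att("PhysicalSizeX"))),
      channels = chn,
      name = xml2::xml_attr(xml2::xml_find_first(doc, ".//Image"), "Name")
    )
  }, error = function(e) NULL)
  out
}

#' Read an image stack from a (OME-)TIFF file
#'
#' Pages are interpreted in `XYZCT` order (z fastest, then channel). Voxel
#' spacing and channel names are taken from OME-XML metadata when present;
#' values supplied in `config` win over metadata (with a warning on
#' disagreement), matching the rule that the experimenter's configuration is
#' authoritative.
#'
#' @param path TIFF or OME-TIFF file.
#' @param config optional list with any of `channels` (character),
#'   `spacing` (numeric `(z, y, x)` um), `cell_id`.
#' @return A [ct_stack()].
#' @export
read_stack <- function(path, config = NULL) {
  tf <- read_tiff(path)
  np <- dim(tf$pages)[1]
  ome <- parse_ome(tf$description)
  channels <- config$channels
  if (is.null(channels)) {
    channels <- if (!is.null(ome) && length(ome$channels) &&
                    !anyNA(ome$channels)) ome$channels
    else stop("no channel names in config or OME metadata: ", path, call. = FALSE)
  } else if (!is.null(ome) && length(ome$channels) == length(channels) &&
             !anyNA(ome$channels) && !identical(as.character(ome$channels),
                                                as.character(channels))) {
    warning(sprintf("channel names in config (%s) differ from OME metadata (%s); config wins",
                    paste(channels, collapse = ","), paste(ome$channels, collapse = ",")))
  }
  nc <- length(channels)
  if (np %% nc != 0L) {
    stop(sprintf("%s: %d pages cannot hold %d channels (page count must be z * channels)",
                 path, np, nc), call. = FALSE)
  }
  if (!is.null(ome) && !is.na(ome$size["c"]) && ome$size["c"] != nc) {
    stop(sprintf("%s: OME metadata has %d channels but config names %d",
                 path, ome$size["c"], nc), call. = FALSE)
  }
  nz <- np %/% nc
  spacing <- config$spacing
  if (is.null(spacing)) {
    if (is.null(ome) || anyNA(ome$spacing)) {
      stop("no voxel spacing in config or OME metadata: ", path, call. = FALSE)
    }
    spacing <- ome$spacing
  } else if (!is.null(ome) && !anyNA(ome$spacing) &&
             max(abs(as.numeric(spacing) - ome$spacing)) > 1e-9) {
    warning(sprintf("voxel spacing in config (%s) differs from OME metadata (%s); config wins",
                    paste(signif(spacing, 6), collapse = ","),
                    paste(signif(ome$spacing, 6), collapse = ",")))
  }
  vox <- array(0, c(nz, dim(tf$pages)[2], dim(tf$pages)[3], nc))
  for (ci in seq_len(nc)) {
    vox[, , , ci] <- tf$pages[(ci - 1L) * nz + seq_len(nz), , , drop = FALSE]
  }
  cell_id <- config$cell_id
  if (is.null(cell_id)) {
    cell_id <- if (!is.null(ome) && !is.na(ome$name)) ome$name
    else sub("\\.(ome\\.)?tiff?$", "", basename(path), ignore.case = TRUE)
  }
  ct_stack(vox, spacing = spacing, channels = channels, cell_id = cell_id)
}

#' Write an image stack to OME-TIFF
#'
#' 16-bit unsigned, one page per z-plane, z fastest then channel (`XYZCT`);
#' spacing and channel names are embedded as OME-XML.
#'
#' @param stack a [ct_stack()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ct_stack"))
  d <- dim(stack$voxels)
  pages <- vector("list", d[1] * d[4])
  p <- 0L
  for (ci in seq_len(d[4])) {
    for (k in seq_len(d[1])) {
      p <- p + 1L
      pages[[p]] <- stack$voxels[k, , , ci, drop = TRUE]
    }
  }
  desc <- ome_xml(d[1:3], stack$channels, stack$spacing, "uint16", stack$cell_id)
  write_tiff(pages, path, bits = 16L, description = desc)
}

#' Write a binary mask as 8-bit TIFF
#'
#' Foreground is 255, background 0; voxel spacing is embedded as OME-XML so
#' masks round-trip losslessly with their physical calibration.
#'
#' @param mask 3D logical array `(z, y, x)`, or integer label array (written
#'   as labels, 8-bit, values clamped at 255).
#' @param path output file.
#' @param spacing voxel spacing `(z, y, x)` um.
#' @param name identifier stored in the metadata.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, spacing = c(1, 1, 1), name = "mask") {
  stopifnot(length(dim(mask)) == 3L)
  vox <- if (is.logical(mask)) array(as.integer(mask) * 255L, dim(mask))
         else array(as.integer(mask), dim(mask))
  desc <- ome_xml(dim(mask), name, .spacing_check(spacing), "uint8", name)
  write_tiff(vox, path, bits = 8L, description = desc)
}

#' Read a binary or label mask written by [write_mask()]
#'
#' @param path 8-bit TIFF file.
#' @return list with `mask` (logical array: voxels > 0), `labels` (integer
#'   array of the raw values) and `spacing` (or `NULL` if no metadata).
#' @export
read_mask <- function(path) {
  tf <- read_tiff(path)
  ome <- parse_ome(tf$description)
  labels <- array(as.integer(tf$pages), dim(tf$pages))
  list(mask = labels > 0L, labels = labels,
       spacing = if (!is.null(ome)) ome$spacing else NULL)
}
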