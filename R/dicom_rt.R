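# Minimal DICOM RT structure set writer/reader. One ROI per structure,
# CLOSED_PLANAR contours, even-odd hole semantics (no keyhole). The file
# meta group is explicit VR little endian; the dataset uses the implicit VR
# little endian transfer syntax (1.2.840.10008.1.2). Only the elements the
# round trip needs are written/parsed; geometry is supplied externally on
# read (as a reference CT geometry stub).

RTSTRUCT_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.481.3"
IMPLICIT_VR_LE <- "1.2.840.10008.1.2"

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
u32_undef <- function() as.raw(c(0xFF, 0xFF, 0xFF, 0xFF))

pad_even <- function(r, pad = as.raw(0x20)) {
  if (length(r) %% 2 == 1) c(r, pad) else r
}

str_raw <- function(s, ui = FALSE) {
  pad_even(charToRaw(s), pad = if (ui) as.raw(0) else as.raw(0x20))
}

elem <- function(group, element, value) {
  c(u16(group), u16(element), u32(length(value)), value)
}

elem_explicit <- function(group, element, vr, value) {
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT"))
    c(u16(group), u16(element), charToRaw(vr), as.raw(c(0, 0)),
      u32(length(value)), value)
  else
    c(u16(group), u16(element), charToRaw(vr),
      writeBin(as.integer(length(value)), raw(), size = 2,
               endian = "little"), value)
}

seq_undef <- function(group, element, items) {
  body <- do.call(c, c(lapply(items, function(it)
    c(u16(0xFFFE), u16(0xE000), u32_undef(), it,
      u16(0xFFFE), u16(0xE00D), u32(0))), list(raw(0))))
  c(u16(group), u16(element), u32_undef(), body,
    u16(0xFFFE), u16(0xE0DD), u32(0))
}

#' Write contour sets as a DICOM RT structure set
#'
#' Writes one ROI per \code{\link{contour_set}} as CLOSED_PLANAR contours
#' (vertices in world mm, patient LPS, formatted to 1e-4 mm).
#'
#' @param contour_sets a \code{contour_set} or list of them.
#' @param path output file path.
#' @param label structure set label.
#' @return The path, invisibly.
#' @export
write_rtstruct <- function(contour_sets, path, label = "btvseg") {
  if (inherits(contour_sets, "contour_set"))
    contour_sets <- list(contour_sets)
  stopifnot(all(vapply(contour_sets, inherits, logical(1), "contour_set")))
  sop_instance <- "2.25.1"
  roi_items <- contour_items <- list()
  for (i in seq_along(contour_sets)) {
    cs <- contour_sets[[i]]
    roi_items[[i]] <- c(
      elem(0x3006, 0x0022, str_raw(as.character(i))),
      elem(0x3006, 0x0026, str_raw(cs$name)))
    polys <- lapply(cs$contours, function(cn) {
      pts <- t(cn$points)
      data <- paste(sprintf("%.4f", as.numeric(pts)), collapse = "\\")
      c(elem(0x3006, 0x0042, str_raw("CLOSED_PLANAR")),
        elem(0x3006, 0x0046, str_raw(as.character(nrow(cn$points)))),
        elem(0x3006, 0x0050, str_raw(data)))
    })
    contour_items[[i]] <- c(
      elem(0x3006, 0x0084, str_raw(as.character(i))),
      seq_undef(0x3006, 0x0040, polys))
  }
  dataset <- c(
    elem(0x0008, 0x0016, str_raw(RTSTRUCT_SOP_CLASS, ui = TRUE)),
    elem(0x0008, 0x0018, str_raw(sop_instance, ui = TRUE)),
    elem(0x0008, 0x0060, str_raw("RTSTRUCT")),
    elem(0x3006, 0x0002, str_raw(label)),
    seq_undef(0x3006, 0x0020, roi_items),
    seq_undef(0x3006, 0x0039, contour_items))
  meta_body <- c(
    elem_explicit(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    elem_explicit(0x0002, 0x0002, "UI", str_raw(RTSTRUCT_SOP_CLASS,
                                                ui = TRUE)),
    elem_explicit(0x0002, 0x0003, "UI", str_raw(sop_instance, ui = TRUE)),
    elem_explicit(0x0002, 0x0010, "UI", str_raw(IMPLICIT_VR_LE, ui = TRUE)))
  meta <- c(elem_explicit(0x0002, 0x0000, "UL", u32(length(meta_body))),
            meta_body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, dataset), con)
  invisible(path)
}

# --- reader ----------------------------------------------------------------

rt_sequence_tags <- c("3006,0020", "3006,0039", "3006,0040")

tag_str <- function(group, element) sprintf("%04x,%04x", group, element)

read_u16 <- function(bytes, pos) {
  readBin(bytes[pos:(pos + 1)], "integer", size = 2, endian = "little",
          signed = FALSE)
}

read_u32 <- function(bytes, pos) {
  v <- readBin(bytes[pos:(pos + 3)], "integer", size = 4, endian = "little")
  if (v == -1L) NA_integer_ else v  # NA marks undefined length
}

# parse implicit-VR elements in bytes[pos..end]; returns list(values, pos).
# sequences (known RTSTRUCT tags or undefined-length values) recurse.
parse_implicit <- function(bytes, pos, end) {
  out <- list()
  while (pos <= end) {
    if (pos + 7 > length(bytes) + 1)
      stop(sprintf("truncated DICOM element at byte offset %d", pos))
    group <- read_u16(bytes, pos); element <- read_u16(bytes, pos + 2)
    len <- read_u32(bytes, pos + 4)
    pos <- pos + 8
    tag <- tag_str(group, element)
    if (group == 0xFFFE && element == 0xE0DD) break        # sequence end
    if (group == 0xFFFE && element == 0xE00D) break        # item end
    if (tag %in% rt_sequence_tags) {
      items <- list()
      seq_end <- if (is.na(len)) length(bytes) else pos + len - 1
      while (pos <= seq_end) {
        g2 <- read_u16(bytes, pos); e2 <- read_u16(bytes, pos + 2)
        l2 <- read_u32(bytes, pos + 4)
        pos <- pos + 8
        if (g2 == 0xFFFE && e2 == 0xE0DD) break
        if (!(g2 == 0xFFFE && e2 == 0xE000))
          stop(sprintf("malformed sequence %s: expected item tag, got %s",
                       tag, tag_str(g2, e2)))
        item_end <- if (is.na(l2)) length(bytes) else pos + l2 - 1
        parsed <- parse_implicit(bytes, pos, item_end)
        items[[length(items) + 1L]] <- parsed$values
        pos <- parsed$pos
        if (!is.na(l2)) pos <- item_end + 1
      }
      out[[tag]] <- c(out[[tag]], list(items))
    } else {
      if (is.na(len))
        stop(sprintf("element %s has undefined length but is not a known ",
                     tag), "sequence")
      if (pos + len - 1 > length(bytes))
        stop(sprintf("element %s runs past end of file", tag))
      out[[tag]] <- if (len > 0) bytes[pos:(pos + len - 1)] else raw(0)
      pos <- pos + len
    }
  }
  list(values = out, pos = pos)
}

value_string <- function(raw_val) {
  while (length(raw_val) > 0 &&
         raw_val[length(raw_val)] %in% as.raw(c(0x00, 0x20)))
    raw_val <- raw_val[-length(raw_val)]
  rawToChar(raw_val)
}

#' Read a DICOM RT structure set
#'
#' Parses the structures written by \code{\link{write_rtstruct}} (implicit
#' VR little endian dataset) back into contour sets. The reference geometry
#' is supplied by the caller, as RTSTRUCT files reference a CT series rather
#' than carrying a grid; slice membership of each contour is recomputed from
#' that geometry (a contour off its slice planes surfaces later as a
#' geometry-mismatch error in \code{\link{contours_to_mask}}).
#'
#' @param path RTSTRUCT file path.
#' @param geometry reference \code{image_geometry} (the planning-CT grid).
#' @return Named list of \code{\link{contour_set}}s.
#' @export
read_rtstruct <- function(path, geometry) {
  stopifnot(inherits(geometry, "image_geometry"))
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 132 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM file: missing DICM magic")
  pos <- 133
  g <- read_u16(bytes, pos); e <- read_u16(bytes, pos + 2)
  if (g != 2L || e != 0L)
    stop("malformed file meta: expected element 0002,0000 first")
  # explicit VR UL: vr(2) + len16(2) + 4-byte value
  meta_len <- readBin(bytes[(pos + 8):(pos + 11)], "integer", size = 4,
                      endian = "little")
  pos <- pos + 12 + meta_len
  ds <- parse_implicit(bytes, pos, length(bytes))$values
  rois <- ds[["3006,0020"]][[1]]
  if (is.null(rois)) stop("missing element 3006,0020 (StructureSetROISequence)")
  roi_names <- vapply(rois, function(it)
    value_string(it[["3006,0026"]]), character(1))
  roi_numbers <- vapply(rois, function(it)
    value_string(it[["3006,0022"]]), character(1))
  names(roi_names) <- roi_numbers
  contour_blocks <- ds[["3006,0039"]][[1]]
  if (is.null(contour_blocks))
    stop("missing element 3006,0039 (ROIContourSequence)")
  out <- list()
  for (blk in contour_blocks) {
    num <- value_string(blk[["3006,0084"]])
    nm <- roi_names[[num]]
    contours <- lapply(blk[["3006,0040"]][[1]], function(it) {
      vals <- as.numeric(strsplit(value_string(it[["3006,0050"]]),
                                  "\\", fixed = TRUE)[[1]])
      if (length(vals) %% 3 != 0)
        stop("element 3006,0050 (ContourData) length is not a multiple of 3")
      pts <- matrix(vals, ncol = 3, byrow = TRUE)
      k <- round_half_up(world_to_voxel(geometry, pts[1, ])[3])
      list(slice_k = as.integer(k), points = pts)
    })
    out[[nm]] <- contour_set(nm, contours, geometry)
  }
  out
}
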