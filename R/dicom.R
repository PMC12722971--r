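# Minimal DICOM codec: Explicit VR Little Endian, part-10 files, with
# sequence support (defined and undefined lengths).  Covers the subset
# needed for brachy RT Plans and RT Structure Sets; everything else is
# carried opaquely through read/write round trips.
#
# Element representation: list(group, element, vr, value) where value is
#   - list of datasets (each a list of elements)     for VR "SQ"
#   - character scalar (multi-values joined by "\\") for string VRs
#   - integer vector                                  for US / UL / SS / SL
#   - raw vector                                      otherwise (OB, UN, ...)

DCM_STRING_VRS <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT",
                    "PN", "SH", "ST", "TM", "UC", "UI", "UR", "UT")
DCM_LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

dcm_element <- function(group, element, vr, value) {
  list(group = group, element = element, vr = vr, value = value)
}

u16le <- function(v) as.raw(c(v %% 256, (v %/% 256) %% 256))
u32le <- function(v) as.raw(c(v %% 256, (v %/% 256) %% 256,
                              (v %/% 65536) %% 256, (v %/% 16777216) %% 256))
r_u16 <- function(b, i) as.integer(b[i]) + 256L * as.integer(b[i + 1])
r_u32 <- function(b, i) {
  as.numeric(b[i]) + 256 * as.numeric(b[i + 1]) +
    65536 * as.numeric(b[i + 2]) + 16777216 * as.numeric(b[i + 3])
}

# shortest decimal string (<= 16 chars, DICOM DS limit) reproducing x to
# 1e-9 absolute
ds_format <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) stop("non-finite value in DS field")
    for (d in 1:15) {
      s <- formatC(v, digits = d, format = "g", width = 1)
      if (nchar(s) <= 16 && abs(as.numeric(s) - v) <= 1e-9) return(s)
    }
    s <- formatC(v, digits = 10, format = "g", width = 1)
    if (nchar(s) > 16) stop("DS value does not fit in 16 characters: ", v)
    s
  }, character(1))
}

dcm_encode_value <- function(vr, value) {
  if (vr == "SQ") stop("SQ handled separately")
  if (vr %in% DCM_STRING_VRS) {
    s <- paste(as.character(value), collapse = "\\")
    b <- charToRaw(s)
    if (length(b) %% 2 == 1)
      b <- c(b, if (vr == "UI") as.raw(0) else charToRaw(" "))
    return(b)
  }
  if (vr %in% c("US", "SS")) return(do.call(c, lapply(value, u16le)))
  if (vr %in% c("UL", "SL")) return(do.call(c, lapply(value, u32le)))
  if (vr %in% c("FL")) return(writeBin(as.numeric(value), raw(), size = 4,
                                       endian = "little"))
  if (vr %in% c("FD")) return(writeBin(as.numeric(value), raw(), size = 8,
                                       endian = "little"))
  b <- as.raw(value)
  if (length(b) %% 2 == 1) b <- c(b, as.raw(0))
  b
}

dcm_serialize_element <- function(el) {
  if (el$vr == "SQ") {
    items <- lapply(el$value, function(item) {
      body <- dcm_serialize_dataset(item)
      c(u16le(0xFFFE), u16le(0xE000), u32le(length(body)), body)
    })
    body <- if (length(items)) do.call(c, items) else raw(0)
    return(c(u16le(el$group), u16le(el$element), charToRaw("SQ"),
             as.raw(c(0, 0)), u32le(length(body)), body))
  }
  b <- dcm_encode_value(el$vr, el$value)
  if (el$vr %in% DCM_LONG_VRS)
    c(u16le(el$group), u16le(el$element), charToRaw(el$vr),
      as.raw(c(0, 0)), u32le(length(b)), b)
  else
    c(u16le(el$group), u16le(el$element), charToRaw(el$vr),
      u16le(length(b)), b)
}

dcm_serialize_dataset <- function(elements) {
  ord <- order(vapply(elements, function(e) e$group * 65536 + e$element,
                      numeric(1)))
  parts <- lapply(elements[ord], dcm_serialize_element)
  if (length(parts)) do.call(c, parts) else raw(0)
}

dcm_decode_value <- function(vr, b) {
  if (vr %in% DCM_STRING_VRS) {
    s <- rawToChar(b[b != as.raw(0)])
    return(sub("[ ]+$", "", s))
  }
  if (vr %in% c("US", "SS")) {
    n <- length(b) %/% 2
    return(vapply(seq_len(n), function(i) r_u16(b, 2 * i - 1), integer(1)))
  }
  if (vr %in% c("UL", "SL")) {
    n <- length(b) %/% 4
    return(vapply(seq_len(n), function(i) r_u32(b, 4 * i - 3), numeric(1)))
  }
  if (vr == "FL") return(readBin(b, numeric(), n = length(b) %/% 4,
                                 size = 4, endian = "little"))
  if (vr == "FD") return(readBin(b, numeric(), n = length(b) %/% 8,
                                 size = 8, endian = "little"))
  b
}

# parse one dataset from bytes b over [pos, end]; returns list(elements, pos)
dcm_parse_dataset <- function(b, pos, end) {
  elements <- list()
  while (pos + 7 <= end + 1 && pos <= end) {
    group <- r_u16(b, pos); element <- r_u16(b, pos + 2)
    if (group == 0xFFFE && element == 0xE00D) {        # item delimiter
      pos <- pos + 8
      return(list(elements = elements, pos = pos, delimited = TRUE))
    }
    vr <- rawToChar(b[(pos + 4):(pos + 5)])
    if (vr %in% DCM_LONG_VRS) {
      len <- r_u32(b, pos + 8); pos <- pos + 12
    } else if (grepl("^[A-Z]{2}$", vr)) {
      len <- r_u16(b, pos + 6); pos <- pos + 8
    } else stop(sprintf("unrecognized VR at tag (%04X,%04X)", group, element))
    if (vr == "SQ") {
      sq_end <- if (len == 4294967295) end else pos + len - 1
      items <- list()
      while (pos <= sq_end) {
        ig <- r_u16(b, pos); ie <- r_u16(b, pos + 2)
        ilen <- r_u32(b, pos + 4); pos <- pos + 8
        if (ig == 0xFFFE && ie == 0xE0DD) break       # sequence delimiter
        if (!(ig == 0xFFFE && ie == 0xE000))
          stop("malformed sequence item tag")
        if (ilen == 4294967295) {
          r <- dcm_parse_dataset(b, pos, end)
          items[[length(items) + 1]] <- r$elements; pos <- r$pos
        } else {
          r <- dcm_parse_dataset(b, pos, pos + ilen - 1)
          items[[length(items) + 1]] <- r$elements; pos <- pos + ilen
        }
      }
      elements[[length(elements) + 1]] <-
        dcm_element(group, element, "SQ", items)
    } else {
      if (pos + len - 1 > end) stop("truncated DICOM element value")
      val <- if (len > 0) b[pos:(pos + len - 1)] else raw(0)
      elements[[length(elements) + 1]] <-
        dcm_element(group, element, vr, dcm_decode_value(vr, val))
      pos <- pos + len
    }
  }
  list(elements = elements, pos = pos, delimited = FALSE)
}

#' Read a DICOM part-10 file (Explicit VR Little Endian)
#'
#' @param path File path.
#' @return A list with `meta` and `dataset` element lists.
#' @keywords internal
dcm_read <- function(path) {
  b <- readBin(path, raw(), n = file.info(path)$size)
  if (length(b) < 140 || rawToChar(b[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133
  # file meta group (always explicit LE)
  meta <- list()
  while (pos + 7 <= length(b) && r_u16(b, pos) == 0x0002) {
    group <- r_u16(b, pos); element <- r_u16(b, pos + 2)
    vr <- rawToChar(b[(pos + 4):(pos + 5)])
    if (vr %in% DCM_LONG_VRS) {
      len <- r_u32(b, pos + 8); pos <- pos + 12
    } else {
      len <- r_u16(b, pos + 6); pos <- pos + 8
    }
    val <- if (len > 0) b[pos:(pos + len - 1)] else raw(0)
    pos <- pos + len
    meta[[length(meta) + 1]] <-
      dcm_element(group, element, vr,
                  if (vr == "OB") val else dcm_decode_value(vr, val))
  }
  ts <- el_string(meta, 0x0002, 0x0010)
  if (!is.null(ts) && ts != "1.2.840.10008.1.2.1")
    stop("unsupported transfer syntax: ", ts,
         " (only Explicit VR Little Endian)")
  ds <- dcm_parse_dataset(b, pos, length(b))
  list(meta = meta, dataset = ds$elements)
}

#' Write a DICOM part-10 file (Explicit VR Little Endian)
#'
#' @param dataset List of elements.
#' @param path Output path.
#' @param sop_class_uid,sop_instance_uid UIDs for the file meta header.
#' @keywords internal
dcm_write <- function(dataset, path, sop_class_uid, sop_instance_uid) {
  meta <- list(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_element(0x0002, 0x0002, "UI", sop_class_uid),
    dcm_element(0x0002, 0x0003, "UI", sop_instance_uid),
    dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    dcm_element(0x0002, 0x0012, "UI", EMTRECON_UID_ROOT)
  )
  meta_bytes <- dcm_serialize_dataset(meta)
  gl <- dcm_serialize_element(
    dcm_element(0x0002, 0x0000, "UL", length(meta_bytes)))
  body <- dcm_serialize_dataset(dataset)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), gl, meta_bytes, body), con)
  invisible(path)
}

EMTRECON_UID_ROOT <- "1.2.826.0.1.3680043.10.1457"

el_find <- function(elements, group, element) {
  for (e in elements)
    if (e$group == group && e$element == element) return(e)
  NULL
}

el_string <- function(elements, group, element) {
  e <- el_find(elements, group, element)
  if (is.null(e)) NULL else as.character(e$value)
}

el_numbers <- function(elements, group, element) {
  e <- el_find(elements, group, element)
  if (is.null(e)) return(NULL)
  if (is.character(e$value))
    as.numeric(strsplit(e$value, "\\", fixed = TRUE)[[1]])
  else as.numeric(e$value)
}

el_require <- function(elements, group, element, what) {
  e <- el_find(elements, group, element)
  if (is.null(e))
    stop(sprintf("missing DICOM element (%04X,%04X): %s",
                 group, element, what))
  e
}

el_drop <- function(elements, tags) {
  keep <- vapply(elements, function(e)
    !any(vapply(tags, function(tg)
      e$group == tg[1] && e$element == tg[2], logical(1))), logical(1))
  elements[keep]
}
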