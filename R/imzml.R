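# imzML 1.1 reading and writing (continuous and processed binary modes).
#
# The format is an mzML-style XML index file (.imzML) plus an external
# binary file (.ibd) whose first 16 bytes are a UUID echoed in the XML.
# Only uncompressed 32/64-bit float and 32/64-bit integer arrays are
# supported, which covers the files this package writes and the common
# converter output.

.ims_cv <- c(
  continuous = "IMS:1000030", processed = "IMS:1000031",
  uuid = "IMS:1000080", md5 = "IMS:1000090",
  offset = "IMS:1000102", length = "IMS:1000103", encoded_length = "IMS:1000104",
  pos_x = "IMS:1000050", pos_y = "IMS:1000051",
  max_x = "IMS:1000042", max_y = "IMS:1000043",
  pixel_x = "IMS:1000046", pixel_y = "IMS:1000047")

# md5 of a raw vector, via a temp file (tools::md5sum is file-based)
.raw_md5 <- function(bytes) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(bytes, tf)
  unname(tools::md5sum(tf))
}

#' Write an IMS dataset as imzML
#'
#' Writes a continuous-mode imzML 1.1 file pair (`.imzML` + `.ibd`) with
#' uncompressed 64-bit float arrays. The ibd UUID is derived from the MD5 of
#' the binary payload, so identical datasets produce byte-identical files.
#'
#' @param dataset An [ims_dataset()].
#' @param path Output path; the `.imzML` extension is added if absent and the
#'   `.ibd` file is written alongside.
#' @return Invisibly, the `.imzML` path.
#' @export
write_imzml <- function(dataset, path) {
  stopifnot(inherits(dataset, "ims_dataset"))
  path <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  ibd_path <- paste0(path, ".ibd")
  xml_path <- paste0(path, ".imzML")

  n_px <- nrow(dataset$coords)
  n_mz <- length(dataset$mz)

  # binary payload: shared mz axis then one intensity block per pixel
  con <- rawConnection(raw(0), "wb")
  writeBin(dataset$mz, con, size = 8, endian = "little")
  for (i in seq_len(n_px))
    writeBin(as.numeric(dataset$intensities[i, ]), con, size = 8,
             endian = "little")
  payload <- rawConnectionValue(con)
  close(con)

  uuid_bytes <- as.raw(strtoi(substring(.raw_md5(payload),
                                        seq(1, 31, 2), seq(2, 32, 2)),
                              base = 16L))
  ibd <- c(uuid_bytes, payload)
  writeBin(ibd, ibd_path)
  uuid <- paste0("{", paste(
    vapply(list(1:4, 5:6, 7:8, 9:10, 11:16),
           function(ix) paste(format(uuid_bytes[ix]), collapse = ""),
           character(1)), collapse = "-"), "}")
  ibd_md5 <- toupper(.raw_md5(ibd))

  cv <- function(acc, name, value = NULL, ref = NULL) {
    ref <- if (is.null(ref)) strsplit(acc, ":")[[1]][1] else ref
    v <- if (is.null(value)) "" else sprintf(' value="%s"', value)
    sprintf('<cvParam cvRef="%s" accession="%s" name="%s"%s/>',
            ref, acc, name, v)
  }

  mz_off <- 16
  int_len <- n_mz * 8L
  int_off <- mz_off + int_len + (seq_len(n_px) - 1L) * int_len

  spectra <- vapply(seq_len(n_px), function(i) {
    paste0(
      sprintf('<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
              i - 1L, i, n_mz),
      '<scanList count="1"><scan>',
      cv(.ims_cv["pos_x"], "position x", dataset$coords$x[i] + 1L),
      cv(.ims_cv["pos_y"], "position y", dataset$coords$y[i] + 1L),
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      cv(.ims_cv["length"], "external array length", n_mz),
      cv(.ims_cv["encoded_length"], "external encoded length", int_len),
      cv(.ims_cv["offset"], "external offset", mz_off),
      "<binary/></binaryDataArray>",
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      cv(.ims_cv["length"], "external array length", n_mz),
      cv(.ims_cv["encoded_length"], "external encoded length", int_len),
      cv(.ims_cv["offset"], "external offset", int_off[i]),
      "<binary/></binaryDataArray>",
      "</binaryDataArrayList></spectrum>")
  }, character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="3">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    cv(.ims_cv["continuous"], "continuous"),
    cv(.ims_cv["uuid"], "universally unique identifier", uuid),
    cv(.ims_cv["md5"], "ibd MD5", ibd_md5),
    cv("MS:1000294", "mass spectrum"),
    "</fileContent></fileDescription>",
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    cv("MS:1000514", "m/z array"),
    cv("MS:1000523", "64-bit float"),
    cv("MS:1000576", "no compression"),
    "</referenceableParamGroup>",
    '<referenceableParamGroup id="intensityArray">',
    cv("MS:1000515", "intensity array"),
    cv("MS:1000523", "64-bit float"),
    cv("MS:1000576", "no compression"),
    "</referenceableParamGroup>",
    "</referenceableParamGroupList>",
    '<scanSettingsList count="1"><scanSettings id="scanSettings1">',
    cv(.ims_cv["max_x"], "max count of pixel x", max(dataset$coords$x) + 1L),
    cv(.ims_cv["max_y"], "max count of pixel y", max(dataset$coords$y) + 1L),
    cv(.ims_cv["pixel_x"], "pixel size x", dataset$pixel_pitch),
    cv(.ims_cv["pixel_y"], "pixel size y", dataset$pixel_pitch),
    "</scanSettings></scanSettingsList>",
    sprintf('<run id="%s"><spectrumList count="%d">',
            if (is.null(dataset$metadata$id)) "run1" else dataset$metadata$id,
            n_px),
    paste(spectra, collapse = ""),
    "</spectrumList></run></mzML>\n")
  writeLines(xml, xml_path, sep = "")
  invisible(xml_path)
}

.cv_value <- function(node, accession) {
  p <- xml2::xml_find_first(
    node, sprintf(".//d1:cvParam[@accession='%s']", accession))
  if (inherits(p, "xml_missing")) NA_character_ else xml2::xml_attr(p, "value")
}

.read_ibd_array <- function(con, offset, length, what, size) {
  seek(con, where = offset, origin = "start")
  readBin(con, what = what, n = length, size = size, endian = "little")
}

#' Read an imzML file
#'
#' Accepts continuous and processed binary modes; processed-mode spectra on
#' differing axes are linearly interpolated onto the first spectrum's axis so
#' the in-memory representation is always a shared-axis [ims_dataset()].
#'
#' @param path Path to the `.imzML` file (the `.ibd` must sit alongside).
#' @return An [ims_dataset()].
#' @export
read_imzml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("imzML parse error in '", path,
                                           "': ", conditionMessage(e)))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "d1")

  mode_node <- xml2::xml_find_first(
    doc, sprintf("//d1:fileContent/d1:cvParam[@accession='%s']",
                 .ims_cv["continuous"]), ns)
  continuous <- !inherits(mode_node, "xml_missing")

  # data type per referenceable param group
  grp_type <- function(id) {
    grp <- xml2::xml_find_first(
      doc, sprintf("//d1:referenceableParamGroup[@id='%s']", id), ns)
    if (inherits(grp, "xml_missing")) return(c("double", 8))
    accs <- xml2::xml_attr(xml2::xml_find_all(grp, ".//d1:cvParam", ns),
                           "accession")
    if ("MS:1000521" %in% accs) c("double", 4)        # 32-bit float
    else if ("MS:1000522" %in% accs) c("integer", 8)  # 64-bit integer
    else if ("MS:1000519" %in% accs) c("integer", 4)  # 32-bit integer
    else c("double", 8)
  }
  mz_type <- grp_type("mzArray"); int_type <- grp_type("intensityArray")

  pitch <- .cv_value(doc |> xml2::xml_find_first("//d1:scanSettings", ns),
                     .ims_cv[["pixel_x"]])
  pitch <- if (is.na(pitch)) 70 else as.numeric(pitch)

  spectra <- xml2::xml_find_all(doc, "//d1:spectrum", ns)
  if (!length(spectra)) stop("imzML parse error in '", path,
                             "': no spectrum elements")

  ibd_path <- paste0(sub("\\.imzML$", "", path, ignore.case = TRUE), ".ibd")
  if (!file.exists(ibd_path)) stop("missing ibd file: ", ibd_path)
  ibd_size <- file.size(ibd_path)
  con <- file(ibd_path, "rb")
  on.exit(close(con))

  parse_spectrum <- function(sp, idx) {
    x <- .cv_value(sp, .ims_cv[["pos_x"]])
    y <- .cv_value(sp, .ims_cv[["pos_y"]])
    arrays <- xml2::xml_find_all(sp, ".//d1:binaryDataArray", ns)
    if (length(arrays) < 2L || is.na(x) || is.na(y))
      stop("imzML parse error in '", path, "': spectrum ", idx,
           " lacks position or binary array metadata")
    get <- function(arr, type) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(arr, ".//d1:referenceableParamGroupRef", ns),
        "ref")
      off <- as.numeric(.cv_value(arr, .ims_cv[["offset"]]))
      len <- as.numeric(.cv_value(arr, .ims_cv[["length"]]))
      size <- as.numeric(type[2])
      if (is.na(off) || is.na(len) || off + len * size > ibd_size)
        stop("imzML parse error in '", path, "': spectrum ", idx,
             " array '", ref, "' offset/length outside ibd (offset=", off,
             ", length=", len, ")")
      .read_ibd_array(con, off, len, type[1], size)
    }
    refs <- vapply(arrays, function(a) xml2::xml_attr(
      xml2::xml_find_first(a, ".//d1:referenceableParamGroupRef", ns), "ref"),
      character(1))
    mz_arr <- arrays[[match("mzArray", refs)]]
    int_arr <- arrays[[match("intensityArray", refs)]]
    list(x = as.integer(x) - 1L, y = as.integer(y) - 1L,
         mz = as.numeric(get(mz_arr, mz_type)),
         intensity = as.numeric(get(int_arr, int_type)))
  }

  parsed <- lapply(seq_along(spectra),
                   function(i) parse_spectrum(spectra[[i]], i))
  axis <- parsed[[1]]$mz
  ints <- matrix(0, nrow = length(parsed), ncol = length(axis))
  for (i in seq_along(parsed)) {
    p <- parsed[[i]]
    ints[i, ] <- if (continuous || identical(p$mz, axis)) p$intensity
      else stats::approx(p$mz, p$intensity, xout = axis, rule = 2)$y
  }
  coords <- data.frame(x = vapply(parsed, `[[`, integer(1), "x"),
                       y = vapply(parsed, `[[`, integer(1), "y"))
  ims_dataset(coords, axis, ints, pixel_pitch = pitch,
              metadata = list(source = path,
                              mode = if (continuous) "continuous" else "processed"))
}

#' Write / read ROI definitions
#'
#' ROIs are stored in a versioned JSON sidecar (imzML has no ROI standard):
#' an object with `schema_version` and a `rois` array whose members carry
#' `pixels` (1-based indices into the dataset pixel list), `region`,
#' `hemisphere`, `section_id`, `animal_id` and `dataset_id`.
#'
#' @param rois List of [ims_roi()] objects.
#' @param path JSON file path.
#' @return `write_rois` invisibly returns `path`; `read_rois` returns a
#'   validated list of [ims_roi()] objects.
#' @export
write_rois <- function(rois, path) {
  payload <- list(schema_version = 1L,
                  rois = lapply(rois, function(r) unclass(r)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  if (is.null(payload$schema_version) || is.null(payload$rois))
    stop("ROI file '", path, "' lacks schema_version/rois")
  rois <- lapply(seq_along(payload$rois), function(i) {
    r <- payload$rois[[i]]
    tryCatch(
      ims_roi(r$pixels, r$region, r$hemisphere, r$section_id, r$animal_id,
              if (is.null(r$dataset_id)) NA_character_ else r$dataset_id),
      error = function(e) stop("invalid ROI #", i, " in '", path, "': ",
                               conditionMessage(e)))
  })
  keys <- vapply(rois, roi_key, character(1))
  if (anyDuplicated(keys))
    stop("duplicate (animal, section, hemisphere, region) ROI: ",
         keys[duplicated(keys)][1])
  rois
}

#' Write / read simulation ground truth
#'
#' @param truth Ground-truth list as produced by [simulate_study()].
#' @param path JSON file path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
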