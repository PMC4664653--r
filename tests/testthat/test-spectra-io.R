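test_that("container constructors enforce their invariants", {
  expect_error(mass_spectrum(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(mass_spectrum(c(2, 1), c(1, 1)), "increasing")
  expect_error(mass_spectrum(c(1, 2), c(-1, 1)), ">= 0")
  expect_error(ims_dataset(data.frame(x = c(0, 0), y = c(0, 0)),
                           1:3, matrix(1, 2, 3)), "unique")
  expect_error(ims_roi(integer(0), "r", "left", "S1", "A01"), "at least one")
  expect_error(ims_roi(1L, "r", "middle", "S1", "A01"), "hemisphere")
  expect_error(ims_roi(1L, "", "left", "S1", "A01"), "non-empty")
})

test_that("imzML round trip preserves coordinates and intensities", {
  set.seed(42)
  mz <- seq(1500, 1600, by = 0.5)
  n <- 100
  coords <- expand.grid(x = 0:9, y = 0:9)
  ints <- matrix(abs(rnorm(n * length(mz), 10, 3)), n)
  ds <- ims_dataset(coords, mz, ints, pixel_pitch = 70)
  path <- file.path(tempdir(), "roundtrip")
  write_imzml(ds, path)
  back <- read_imzml(paste0(path, ".imzML"))
  expect_identical(back$coords, ds$coords)
  expect_identical(back$mz, ds$mz)
  expect_lt(max(abs(back$intensities - ds$intensities) /
                  pmax(abs(ds$intensities), 1e-12)), 1e-6)
  expect_equal(back$pixel_pitch, 70)
})

test_that("identical datasets write byte-identical imzML files", {
  set.seed(7)
  ds <- ims_dataset(data.frame(x = 0:3, y = rep(0L, 4)),
                    seq(1, 10, 0.5), matrix(runif(4 * 19), 4))
  p1 <- file.path(tempdir(), "w1"); p2 <- file.path(tempdir(), "w2")
  write_imzml(ds, p1); write_imzml(ds, p2)
  expect_identical(unname(tools::md5sum(paste0(p1, ".ibd"))),
                   unname(tools::md5sum(paste0(p2, ".ibd"))))
  expect_identical(readLines(paste0(p1, ".imzML")),
                   readLines(paste0(p2, ".imzML")))
})

test_that("malformed imzML is rejected without a partial dataset", {
  set.seed(1)
  ds <- ims_dataset(data.frame(x = 0:1, y = c(0L, 0L)),
                    1:5, matrix(runif(10), 2))
  p <- file.path(tempdir(), "trunc")
  write_imzml(ds, p)
  xml <- readChar(paste0(p, ".imzML"), file.size(paste0(p, ".imzML")))
  writeChar(substr(xml, 1, nchar(xml) %/% 2),
            file.path(tempdir(), "trunc_bad.imzML"))
  file.copy(paste0(p, ".ibd"), file.path(tempdir(), "trunc_bad.ibd"),
            overwrite = TRUE)
  expect_error(read_imzml(file.path(tempdir(), "trunc_bad.imzML")),
               "parse error")
  # truncated binary: offsets beyond the ibd end must be refused
  ibd <- readBin(paste0(p, ".ibd"), "raw", file.size(paste0(p, ".ibd")))
  file.copy(paste0(p, ".imzML"), file.path(tempdir(), "short.imzML"),
            overwrite = TRUE)
  writeBin(ibd[1:40], file.path(tempdir(), "short.ibd"))
  expect_error(read_imzml(file.path(tempdir(), "short.imzML")),
               "outside ibd")
  expect_error(read_imzml(file.path(tempdir(), "nonexistent.imzML")),
               "no such file")
})

test_that("processed-mode imzML reads into the shared-axis representation", {
  # hand-built two-pixel processed file: per-spectrum m/z arrays
  dir <- tempdir()
  ibd_path <- file.path(dir, "proc.ibd")
  mz1 <- c(1500, 1501, 1502, 1503); int1 <- c(1, 5, 2, 1)
  mz2 <- c(1500.5, 1501.5, 1502.5); int2 <- c(2, 4, 2)
  con <- file(ibd_path, "wb")
  writeBin(as.raw(rep(0, 16)), con)
  for (v in list(mz1, int1, mz2, int2)) writeBin(v, con, size = 8,
                                                 endian = "little")
  close(con)
  off <- 16 + c(0, cumsum(8 * lengths(list(mz1, int1, mz2))))
  sp <- function(i, x, y, n, omz, oint) sprintf(paste0(
    '<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
    '<scanList count="1"><scan>',
    '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>',
    '</scan></scanList><binaryDataArrayList count="2">',
    '<binaryDataArray encodedLength="0">',
    '<referenceableParamGroupRef ref="mzArray"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>',
    '<binary/></binaryDataArray><binaryDataArray encodedLength="0">',
    '<referenceableParamGroupRef ref="intensityArray"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>',
    '<binary/></binaryDataArray></binaryDataArrayList></spectrum>'),
    i - 1, i, n, x, y, n, omz, n, oint)
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="IMS" accession="IMS:1000031" name="processed"/>',
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '</referenceableParamGroup></referenceableParamGroupList>',
    '<run id="r"><spectrumList count="2">',
    sp(1, 1, 1, 4, off[1], off[2]),
    sp(2, 2, 1, 3, off[3], off[4]),
    '</spectrumList></run></mzML>')
  writeLines(xml, file.path(dir, "proc.imzML"))
  ds <- read_imzml(file.path(dir, "proc.imzML"))
  expect_equal(ds$mz, mz1)                 # first spectrum's axis is shared
  expect_equal(ds$intensities[1, ], int1)
  # second spectrum resampled onto the shared axis
  expect_equal(ds$intensities[2, 2],
               approx(mz2, int2, xout = 1501)$y)
  expect_equal(ds$coords$x, c(0L, 1L))     # converted to 0-based
})

test_that("ROI JSON round trip preserves tuples and validates schema", {
  rois <- list(
    ims_roi(1:4, "CC", "left", "S1", "A01", "A01_S1"),
    ims_roi(5:8, "CC", "right", "S1", "A01", "A01_S1"))
  p <- file.path(tempdir(), "rois.json")
  write_rois(rois, p)
  back <- read_rois(p)
  expect_equal(lapply(back, unclass), lapply(rois, unclass))

  bad <- list(list(pixels = list(), region = "CC", hemisphere = "left",
                   section_id = "S1", animal_id = "A01"))
  jsonlite::write_json(list(schema_version = 1, rois = bad),
                       file.path(tempdir(), "bad_roi.json"),
                       auto_unbox = TRUE)
  expect_error(read_rois(file.path(tempdir(), "bad_roi.json")),
               "invalid ROI #1")

  dup <- c(rois, rois[1])
  write_rois(dup, file.path(tempdir(), "dup_roi.json"))
  expect_error(read_rois(file.path(tempdir(), "dup_roi.json")), "duplicate")
})

test_that("simulated ROI sets survive the JSON round trip unchanged", {
  cfg <- tiny_config(list(r1 = list(total = 50, ratio = 2)))
  st <- simulate_study(cfg, build_phantom("single", c(8, 8), labels = "r1"))
  p <- file.path(tempdir(), "sim_rois.json")
  write_rois(st$rois, p)
  back <- read_rois(p)
  expect_equal(lapply(back, unclass), lapply(st$rois, unclass))
})
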