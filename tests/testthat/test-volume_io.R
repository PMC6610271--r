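test_that("image_volume and kidney_mask enforce their invariants", {
  expect_error(image_volume(matrix(0, 2, 2), c(1, 1), 1), "3D")
  expect_error(image_volume(array(0, c(2, 2, 2)), c(0, 1), 1), "positive")
  expect_error(image_volume(array(0, c(2, 2, 2)), c(1, 1), -1), "positive")
  expect_error(image_volume(array(0, c(2, 2, 2)), c(1, 1), 1,
                            axis_labels = c("a", "b", "c")), "permutation")
  v <- image_volume(array(1, c(3, 4, 5)), c(0.68, 0.68), 4)
  expect_equal(n_coronal(v), 4L)
  expect_equal(dim(coronal_slice(v, 2)), c(3L, 5L))
  expect_error(kidney_mask(array(2, c(2, 2, 2))), "binary")
  m <- kidney_mask(array(1L, c(2, 2, 2)), side = "right")
  expect_s3_class(m, "kidney_mask")
})

test_that("NIfTI round trip preserves voxels, spacing and axis order", {
  ph <- fx_phantom_small()
  vol <- ph$clean
  vol$voxels <- round(vol$voxels)
  path <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(vol, path)
  back <- read_nifti(path)
  expect_equal(back$voxels, vol$voxels, ignore_attr = TRUE)
  expect_equal(back$spacing_inplane, vol$spacing_inplane)
  expect_equal(back$slice_thickness, vol$slice_thickness)
  expect_equal(back$axis_labels, c("sagittal", "coronal", "axial"))
})

test_that("NIfTI reader restores canonical order from a permuted file", {
  arr <- array(seq_len(3 * 4 * 5), c(3, 4, 5))
  pd <- c(1.5, 4, 1.5)
  # store in (coronal, sagittal, axial) order with a matching sform
  perm <- c(2, 1, 3)
  img <- RNifti::asNifti(aperm(arr, perm))
  RNifti::pixdim(img) <- pd[perm]
  xf <- diag(4) * 0
  xf[4, 4] <- 1
  xf[1, 2] <- pd[1]; xf[2, 1] <- pd[2]; xf[3, 3] <- pd[3]
  img <- RNifti::`sform<-`(img, structure(xf, code = 1L))
  path <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, path)
  back <- read_nifti(path)
  expect_equal(dim(back$voxels), c(3L, 4L, 5L))
  expect_equal(back$voxels, arr, ignore_attr = TRUE)
  expect_equal(back$slice_thickness, 4)
})

test_that("NIfTI reader rejects missing files and non-3D payloads", {
  expect_error(read_nifti(tempfile()), "no such file")
  img4 <- RNifti::asNifti(array(0, c(4, 4, 4, 2)))
  p4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img4, p4)
  expect_error(read_nifti(p4), "3D")
})

test_that("DICOM series round trip is voxel-identical and matches NIfTI", {
  ph <- fx_phantom_small()
  vol <- ph$clean
  vol$voxels <- round(vol$voxels)
  dcm_dir <- file.path(tempfile(), "series")
  write_dicom_series(vol, dcm_dir)
  from_dcm <- read_dicom_series(dcm_dir)
  expect_equal(from_dcm$voxels, vol$voxels, ignore_attr = TRUE)
  expect_equal(from_dcm$spacing_inplane, vol$spacing_inplane)
  expect_equal(from_dcm$slice_thickness, vol$slice_thickness)

  nii <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(vol, nii)
  from_nii <- read_nifti(nii)
  expect_equal(from_dcm$voxels, from_nii$voxels, ignore_attr = TRUE)
  expect_equal(from_dcm$spacing_inplane, from_nii$spacing_inplane)
})

test_that("single-slice DICOM directory yields a stack of one", {
  vol <- image_volume(array(round(runif(20 * 30, 0, 100)), c(20, 1, 30)),
                      c(0.68, 0.68), 4)
  d <- file.path(tempfile(), "one")
  write_dicom_series(vol, d)
  back <- read_dicom_series(d)
  expect_equal(dim(back$voxels)[2], 1L)
  expect_equal(back$voxels, vol$voxels, ignore_attr = TRUE)
})

test_that("DICOM reader errors on empty dirs, mixed series and bad spacing", {
  empty <- tempfile(); dir.create(empty)
  expect_error(read_dicom_series(empty), "empty")

  vol <- image_volume(array(1, c(8, 2, 8)), c(1, 1), 4)
  d <- file.path(tempfile(), "mixed")
  write_dicom_series(vol, d, series_uid = "1.2.3.1")
  p <- write_dicom_series(vol, tempfile(), series_uid = "1.2.3.2")
  file.copy(p[1], file.path(d, "other.dcm"))
  expect_error(read_dicom_series(d), "multiple DICOM series")

  d2 <- file.path(tempfile(), "nospacing")
  write_dicom_series(vol, d2)
  # strip the PixelSpacing element from each file
  for (f in list.files(d2, full.names = TRUE)) {
    buf <- readBin(f, raw(), file.size(f))
    tag <- as.raw(c(0x28, 0x00, 0x30, 0x00))
    hit <- NULL
    for (i in seq_len(length(buf) - 8)) {
      if (buf[i] == tag[1] && buf[i + 1] == tag[2] &&
          buf[i + 2] == tag[3] && buf[i + 3] == tag[4]) { hit <- i; break }
    }
    len <- as.integer(buf[hit + 6]) + 256L * as.integer(buf[hit + 7])
    buf <- buf[-(hit:(hit + 7L + len))]
    writeBin(buf, f)
  }
  expect_error(read_dicom_series(d2), "PixelSpacing")

  expect_error(read_dicom_series(tempfile()), "no such directory")
})

test_that("a non-DICOM file is rejected with a clear error", {
  f <- tempfile()
  writeBin(as.raw(rep(0, 200)), f)
  d <- dirname(f)
  expect_error(tkvtools:::read_dicom_file(f), "DICM")
})

test_that("mask writing round-trips voxels and records the side", {
  ph <- fx_phantom_small()
  path <- tempfile(fileext = ".nii.gz")
  write_mask(ph$masks[[1]], path, method = "phantom-truth")
  expect_true(file.exists(paste0(path, ".json")))
  sc <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(sc$side, ph$masks[[1]]$side)
  expect_equal(sc$method, "phantom-truth")
  back <- read_mask(path)
  expect_equal(back$voxels, ph$masks[[1]]$voxels, ignore_attr = TRUE)
  expect_equal(back$side, ph$masks[[1]]$side)

  # empty mask writes a zero-sum file
  empty <- kidney_mask(array(0L, dim(ph$masks[[1]]$voxels)), side = "left",
                       spacing_inplane = c(1.5, 1.5), slice_thickness = 4)
  p2 <- tempfile(fileext = ".nii.gz")
  write_mask(empty, p2)
  expect_equal(sum(read_mask(p2)$voxels), 0)
})
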