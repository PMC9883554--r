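## Minimal NIfTI-1 volume I/O (uncompressed .nii, single file).
##
## Only what the package needs for interoperability with external
## segmentations and viewers: 3-D integer or float volumes, isotropic or
## anisotropic spacing, sform affine with a translation. No NIfTI R package
## is available in the target environment, so the 348-byte header is
## written/parsed directly.

nifti_datatype <- function(storage) {
  switch(storage,
         int16 = list(code = 4L, size = 2L, what = "integer"),
         int32 = list(code = 8L, size = 4L, what = "integer"),
         float32 = list(code = 16L, size = 4L, what = "double"),
         float64 = list(code = 64L, size = 8L, what = "double"),
         stop("unsupported NIfTI storage type: ", storage))
}

#' Write a 3-D volume as NIfTI-1
#'
#' @param vol 3-D numeric or integer array.
#' @param path Output path ending in `.nii` (uncompressed).
#' @param spacing Voxel edge lengths, mm (length 1 or 3).
#' @param origin Physical coordinate of the center of voxel `[1,1,1]`, mm.
#' @param storage One of `"int16"`, `"int32"`, `"float32"`, `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, spacing = 1, origin = c(0, 0, 0),
                        storage = if (is.integer(vol)) "int32" else "float32") {
  stopifnot(length(dim(vol)) == 3L)
  spacing <- rep_len(spacing, 3L)
  dt <- nifti_datatype(storage)
  con <- file(path, "wb")
  on.exit(close(con))
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_i32(348L)                                   # sizeof_hdr
  w_raw(36L)                                    # data_type..dim_info
  w_i16(c(3L, dim(vol), 1L, 1L, 1L, 1L))        # dim[8]
  w_f32(c(0, 0, 0))                             # intent_p1..p3
  w_i16(0L)                                     # intent_code
  w_i16(dt$code)                                # datatype
  w_i16(dt$size * 8L)                           # bitpix
  w_i16(0L)                                     # slice_start
  w_f32(c(1, spacing, 0, 0, 0, 0))              # pixdim[8]
  w_f32(352)                                    # vox_offset
  w_f32(c(1, 0))                                # scl_slope, scl_inter
  w_i16(0L); w_raw(1L); w_raw(1L)               # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0))                             # cal_max, cal_min, slice_duration
  w_f32(0)                                      # toffset
  w_i32(c(0L, 0L))                              # glmax, glmin
  w_raw(80L); w_raw(24L)                        # descrip, aux_file
  w_i16(0L); w_i16(1L)                          # qform_code, sform_code
  w_f32(c(0, 0, 0, 0, 0, 0))                    # quatern_b..qoffset_z
  w_f32(c(spacing[1], 0, 0, origin[1]))         # srow_x
  w_f32(c(0, spacing[2], 0, origin[2]))         # srow_y
  w_f32(c(0, 0, spacing[3], origin[3]))         # srow_z
  w_raw(16L)                                    # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con) # magic
  w_i32(0L)                                     # 4-byte extension flag
  if (dt$what == "integer") {
    writeBin(as.integer(vol), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(vol), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Reads uncompressed single-file `.nii` volumes with datatypes int16,
#' int32, float32 or float64 (sufficient for label volumes and exported
#' field maps).
#'
#' @param path Path to a `.nii` file.
#' @return A list: `vol` (3-D array), `spacing` (mm, length 3), `origin`
#'   (mm, from the sform translation).
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!identical(hdr_size, 348L)) {
    stop("not an uncompressed NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  seek(con, 40L)
  dims <- readBin(con, "integer", 8L, size = 2L, endian = "little")
  seek(con, 70L)
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  seek(con, 76L)
  pixdim <- readBin(con, "double", 8L, size = 4L, endian = "little")
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = "little")
  scl <- readBin(con, "double", 2L, size = 4L, endian = "little")
  seek(con, 344L)
  magic <- rawToChar(readBin(con, "raw", 3L))
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic in ", path)
  seek(con, 280L)   # srow_x/y/z: 3 x 4 floats
  srows <- readBin(con, "double", 12L, size = 4L, endian = "little")
  nd <- dims[1]
  if (nd < 3L) stop("expected a 3-D volume in ", path)
  shape <- dims[2:4]
  n <- prod(shape)
  seek(con, as.integer(vox_offset))
  vol <- switch(as.character(datatype),
    `4`  = readBin(con, "integer", n, size = 2L, endian = "little"),
    `8`  = readBin(con, "integer", n, size = 4L, endian = "little"),
    `16` = readBin(con, "double", n, size = 4L, endian = "little"),
    `64` = readBin(con, "double", n, size = 8L, endian = "little"),
    stop("unsupported NIfTI datatype code: ", datatype))
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0)) {
    vol <- vol * scl[1] + scl[2]
  }
  dim(vol) <- shape
  list(vol = vol,
       spacing = pixdim[2:4],
       origin = srows[c(4, 8, 12)])
}

#' Export a phantom label volume as NIfTI
#'
#' Integer label codes follow the package convention (0 outside, 1 scalp,
#' 2 skull, 3 gray matter, 4 white matter, 5 CSF, 6 tumor shell,
#' 7 tumor core, 8 hydrogel, 9 electrode, 10 air).
#'
#' @param ph A `voxel_phantom`.
#' @param path Output `.nii` path.
#' @return `path`, invisibly.
#' @export
write_phantom_nifti <- function(ph, path) {
  write_nifti(ph$labels, path, spacing = ph$spacing, origin = ph$origin,
              storage = "int16")
}

#' Import a label volume as a phantom
#'
#' Wraps a user-supplied NIfTI label volume (package label codes) in a
#' `voxel_phantom` so it can be fed to the solver. Requires isotropic
#' spacing.
#'
#' @param path Path to a `.nii` label volume.
#' @param cfg Optional `phantom_config` to attach (for array parameters).
#' @return A `voxel_phantom`.
#' @export
read_phantom_nifti <- function(path, cfg = phantom_config()) {
  nii <- read_nifti(path)
  sp <- nii$spacing
  if (max(abs(sp - sp[1])) > 1e-6 * sp[1]) {
    stop("phantom label volumes must have isotropic spacing")
  }
  lab <- nii$vol
  storage.mode(lab) <- "integer"
  structure(
    list(labels = lab, spacing = sp[1], origin = nii$origin,
         defect_mask = NULL, tid = NULL, arrays = NULL,
         insulation = rep(FALSE, 18L), cfg = cfg),
    class = "voxel_phantom"
  )
}
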