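#' Write / read an image frame as TIFF with a YAML sidecar
#'
#' The pixel data go to `<path>` as a single-page grayscale TIFF; the pixel
#' size and the embedded ground truth (when present) go to `<path>.yaml`.
#'
#' @param frame An `image_frame` from [render_micrograph()].
#' @param path Output TIFF path.
#' @return `write_frame_tiff` returns `path` invisibly; `read_frame_tiff`
#'   returns an `image_frame`.
#' @export
write_frame_tiff <- function(frame, path) {
  stopifnot(inherits(frame, "image_frame"))
  tiff::writeTIFF(frame$pixels, path, bits.per.sample = 16)
  meta <- list(pixel_size_um = frame$pixel_size_um, truth = frame$truth)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_frame_tiff
#' @export
read_frame_tiff <- function(path) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  sidecar <- paste0(path, ".yaml")
  if (!file.exists(sidecar)) {
    stop("missing sidecar metadata file: ", sidecar,
         " (pixel size is required)")
  }
  meta <- yaml::read_yaml(sidecar)
  structure(list(pixels = px, pixel_size_um = meta$pixel_size_um,
                 truth = meta$truth),
            class = "image_frame")
}

#' Write / read a Z-stack as multi-page TIFFs with a YAML sidecar
#'
#' Each channel (cell, nucleus, beads) is written as one multi-page TIFF
#' (`<prefix>_cell.tif`, ...); voxel geometry and ground truth go to
#' `<prefix>.yaml`.
#'
#' @param stack A `zstack` from [render_zstack()].
#' @param prefix Output path prefix.
#' @return `write_zstack_tiff` returns `prefix` invisibly; `read_zstack_tiff`
#'   returns a `zstack`.
#' @export
write_zstack_tiff <- function(stack, prefix) {
  stopifnot(inherits(stack, "zstack"))
  for (ch in c("cell", "nucleus", "beads")) {
    pages <- lapply(seq_len(dim(stack[[ch]])[3]),
                    function(k) stack[[ch]][, , k])
    tiff::writeTIFF(pages, paste0(prefix, "_", ch, ".tif"),
                    bits.per.sample = 8)
  }
  yaml::write_yaml(list(pixel_size_um = stack$pixel_size_um,
                        z_step_um = stack$z_step_um, truth = stack$truth),
                   paste0(prefix, ".yaml"))
  invisible(prefix)
}

#' @rdname write_zstack_tiff
#' @export
read_zstack_tiff <- function(prefix) {
  sidecar <- paste0(prefix, ".yaml")
  if (!file.exists(sidecar)) stop("missing sidecar metadata file: ", sidecar)
  meta <- yaml::read_yaml(sidecar)
  chans <- lapply(c(cell = "cell", nucleus = "nucleus", beads = "beads"),
                  function(ch) {
                    pages <- tiff::readTIFF(paste0(prefix, "_", ch, ".tif"),
                                            all = TRUE)
                    array(unlist(pages), c(dim(pages[[1]]), length(pages)))
                  })
  structure(c(chans, list(pixel_size_um = meta$pixel_size_um,
                          z_step_um = meta$z_step_um, truth = meta$truth)),
            class = "zstack")
}
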