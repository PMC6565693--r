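# File I/O: projections and volumes as multi-frame TIFF with plain-text
# sidecars, DVFs as per-node TIFF stacks plus a JSON header.  TIFF storage
# is 32-bit with a recorded affine value range, so round trips are exact to
# single-precision quantization (~2e-10 of the dynamic range).

range_encode <- function(a) {
  lo <- min(a); hi <- max(a)
  if (hi == lo) hi <- lo + 1
  list(img = (a - lo) / (hi - lo), lo = lo, hi = hi)
}

write_tiff_stack <- function(a, path) {
  enc <- range_encode(a)
  n3 <- dim(a)[3]
  # frames are detector/grid planes; tiff expects row-major matrices
  frames <- lapply(seq_len(n3), function(k) t(enc$img[, , k]))
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, compression = "none")
  c(lo = enc$lo, hi = enc$hi)
}

read_tiff_stack <- function(path, lo, hi) {
  frames <- tiff::readTIFF(path, all = TRUE)
  a <- vapply(frames, function(m) t(m), matrix(0, ncol(frames[[1]]),
                                               nrow(frames[[1]])))
  a * (hi - lo) + lo
}

#' Write / read a projection stack (TIFF + CSV sidecar)
#'
#' The images go into a multi-frame 32-bit TIFF; the sidecar CSV holds one
#' row per projection with columns `index, angle_deg, time, subtomo, du, dv`
#' (angles in degrees on disk, radians in memory) plus the affine value
#' range of the TIFF encoding.
#'
#' @param proj an [projection_stack()].
#' @param path base path; `.tif` and `.csv` are appended.
#' @return `write_projections` returns `path` invisibly; `read_projections`
#'   returns an [projection_stack()].
#' @export
write_projections <- function(proj, path) {
  rg <- write_tiff_stack(proj$images, paste0(path, ".tif"))
  meta <- data.frame(index = seq_along(proj$angles),
                     angle_deg = proj$angles * 180 / pi,
                     time = proj$times, subtomo = proj$subtomo,
                     du = proj$shifts[, 1], dv = proj$shifts[, 2],
                     value_lo = unname(rg["lo"]), value_hi = unname(rg["hi"]))
  write.csv(meta, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_projections
#' @export
read_projections <- function(path) {
  csv <- paste0(path, ".csv")
  if (!file.exists(csv)) stop("missing metadata sidecar: ", csv)
  meta <- read.csv(csv)
  need <- c("index", "angle_deg", "time", "subtomo", "du", "dv")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata is missing column(s): ",
                         paste(miss, collapse = ", "))
  img <- read_tiff_stack(paste0(path, ".tif"),
                         meta$value_lo[1], meta$value_hi[1])
  if (dim(img)[3] != nrow(meta))
    stop(sprintf("count mismatch: %d TIFF frames vs %d metadata rows",
                 dim(img)[3], nrow(meta)))
  projection_stack(img, meta$angle_deg * pi / 180, meta$time, meta$subtomo,
                   cbind(meta$du, meta$dv))
}

#' Write / read a volume (TIFF z-slice stack + JSON sidecar)
#'
#' @param vol an [volume3d()] or array.
#' @param path base path; `.tif` and `.json` are appended.
#' @export
write_volume <- function(vol, path) {
  a <- as_vol_array(vol)
  rg <- write_tiff_stack(a, paste0(path, ".tif"))
  vs <- if (inherits(vol, "nct_volume")) vol$voxel_size else 1
  jsonlite::write_json(list(shape = dim(a), voxel_size = vs,
                            value_lo = rg[["lo"]], value_hi = rg[["hi"]]),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  a <- read_tiff_stack(paste0(path, ".tif"), hdr$value_lo, hdr$value_hi)
  volume3d(array(a, hdr$shape), hdr$voxel_size)
}

#' Write / read a deformation field (per-node TIFF stacks + JSON header)
#'
#' Each node's three displacement components are stored as consecutive
#' frames of one TIFF stack per node; the JSON header records node times,
#' spatial step, grid shape and the per-node value ranges.
#'
#' @param dvf an [dvf4d()].
#' @param path base path; `_node<k>.tif` and `.json` are appended.
#' @export
write_dvf <- function(dvf, path) {
  m <- dim(dvf$nodes[[1]])
  rgs <- lapply(seq_along(dvf$nodes), function(k) {
    a <- array(dvf$nodes[[k]], c(m[1], m[2], m[3] * 3))
    write_tiff_stack(a, sprintf("%s_node%d.tif", path, k))
  })
  jsonlite::write_json(
    list(node_times = dvf$node_times, spatial_step = dvf$spatial_step,
         grid_shape = dvf$grid_shape, grid_dim = m[1:3],
         value_lo = vapply(rgs, `[[`, 0, "lo"),
         value_hi = vapply(rgs, `[[`, 0, "hi")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dvf
#' @export
read_dvf <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- hdr$grid_dim
  nodes <- lapply(seq_along(hdr$node_times), function(k) {
    a <- read_tiff_stack(sprintf("%s_node%d.tif", path, k),
                         hdr$value_lo[k], hdr$value_hi[k])
    array(a, c(m, 3))
  })
  # the boundary node is zero by construction; restore it exactly
  nodes[[1]][] <- 0
  dvf4d(hdr$node_times, nodes, hdr$spatial_step, hdr$grid_shape)
}
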