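# Readers and writers. Amplitude images are stored as 16-bit grayscale
# TIFF (or PNG); volumes as 32-bit float multi-page TIFF stacks with a JSON
# sidecar holding axis metadata; paired datasets as directories of TIFF
# pairs plus a JSON manifest. All formats are plain files readable by
# standard imaging tools.

img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext == "png") return("png")
  stop("unsupported image format: '", ext, "' (use TIFF or PNG)")
}

#' Read / write 2-D amplitude images
#'
#' `[0, 1]` float images are quantized to 16 bits on TIFF write (max
#' round-trip error 2^-16; PNG output is 8-bit); multi-channel files are
#' collapsed to their channel mean with a warning.
#'
#' @param path file path ending in .tif/.tiff/.png.
#' @param image numeric matrix in `[0, 1]`.
#' @param bits bits per sample for TIFF output (8 or 16).
#' @return `read_image`: numeric matrix in `[0, 1]`; `write_image`: `path`,
#'   invisibly.
#' @export
read_image <- function(path) {
  fmt <- img_format(path)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- if (fmt == "tiff") tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(img)) == 3L) {
    warning("multi-channel image collapsed to channel mean")
    img <- apply(img, c(1, 2), mean)
  }
  img
}

#' @rdname read_image
#' @export
write_image <- function(path, image, bits = 16L) {
  stopifnot_image(image)
  fmt <- img_format(path)
  image <- clamp01(image)
  # snap to the quantization grid so the writer's truncation is exact
  levels <- if (fmt == "tiff") 2^as.integer(bits) - 1 else 255
  image <- round(image * levels) / levels
  if (fmt == "tiff") tiff::writeTIFF(image, path, bits.per.sample = as.integer(bits))
  else png::writePNG(image, path)
  invisible(path)
}

#' Read / write A-scan volumes
#'
#' Volumes are stored as multi-page 32-bit float TIFF stacks, one en-face
#' (y, x) page per depth sample, with a `<path>.json` sidecar recording
#' axis order, spacings and acquisition mode.
#'
#' @param path TIFF path; metadata goes to `paste0(path, ".json")`.
#' @param volume an [as_ascan_volume()] object.
#' @return `read_volume`: an `ascan_volume`; `write_volume`: `path`,
#'   invisibly.
#' @export
write_volume <- function(path, volume) {
  if (!inherits(volume, "ascan_volume")) stop("expected an ascan_volume")
  d <- dim(volume$amplitudes)
  pages <- lapply(seq_len(d[1]), function(z) t(volume$amplitudes[z, , ]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(axes = "zxy", dim = d,
                            spacing_um = volume$spacing_um, mode = volume$mode),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop("missing volume metadata sidecar: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (key in c("dim", "spacing_um", "mode"))
    if (is.null(meta[[key]])) stop("volume metadata missing key: ", key)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- as.integer(meta$dim)
  if (length(pages) != d[1] || any(dim(pages[[1]]) != d[c(3, 2)]))
    stop("volume metadata inconsistent with declared shape")
  vol <- array(0, d)
  for (z in seq_len(d[1])) vol[z, , ] <- t(pages[[z]])
  as_ascan_volume(vol, spacing_um = meta$spacing_um, mode = meta$mode)
}

#' Write / read a paired dataset directory
#'
#' Pairs are written as `input_%04d.tif` / `target_%04d.tif` (16-bit) plus
#' a `manifest.json` carrying seeds, geometry, jitter configuration, crop
#' offsets and per-line lag records, sufficient to reload or regenerate the
#' dataset.
#'
#' @param dataset a `paired_dataset` from [generate_paired_dataset()].
#' @param dir output directory (created if needed).
#' @return `write_paired_dataset`: `dir` invisibly; `read_paired_dataset`:
#'   a `paired_dataset`.
#' @export
write_paired_dataset <- function(dataset, dir) {
  if (!inherits(dataset, "paired_dataset")) stop("expected a paired_dataset")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(dataset$pairs)) {
    write_image(file.path(dir, sprintf("input_%04d.tif", i)),
                dataset$pairs[[i]]$input_img)
    write_image(file.path(dir, sprintf("target_%04d.tif", i)),
                dataset$pairs[[i]]$target_img)
  }
  manifest <- dataset$manifest
  manifest$jitter_records <- lapply(dataset$pairs, function(p)
    as.list(p$jitter_record))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_paired_dataset
#' @export
read_paired_dataset <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) stop("missing dataset manifest: ", mp)
  manifest <- jsonlite::read_json(mp, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  n <- manifest$n_pairs
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- if (!is.null(manifest$jitter_records))
      as.data.frame(manifest$jitter_records[[i]]) else NULL
    pairs[[i]] <- structure(
      list(input_img = read_image(file.path(dir, sprintf("input_%04d.tif", i))),
           target_img = read_image(file.path(dir, sprintf("target_%04d.tif", i))),
           jitter_record = rec,
           scene_seed = manifest$scene_seeds[i],
           crop_offset = manifest$crop_offsets[i, ]),
      class = "paired_sample")
  }
  manifest$jitter_records <- NULL
  structure(list(pairs = pairs, manifest = manifest), class = "paired_dataset")
}

#' Save / load a trained checkpoint
#'
#' Checkpoints bundle the generator (and discriminator) weights with their
#' architecture and training configurations and the training log, so a
#' saved file is self-describing.
#'
#' @param checkpoint a `biraster_checkpoint`.
#' @param path output `.rds` path.
#' @return `save_checkpoint`: `path` invisibly; `load_checkpoint`: the
#'   checkpoint.
#' @export
save_checkpoint <- function(checkpoint, path) {
  if (!inherits(checkpoint, "biraster_checkpoint")) stop("expected a checkpoint")
  # environments are serialized by value; rebuild graphs as plain lists
  pack_net <- function(nw) {
    if (is.null(nw)) return(NULL)
    list(nodes = nw$graph$nodes, out = nw$graph$out, config = nw$config,
         type = nw$type)
  }
  obj <- list(generator = pack_net(checkpoint$generator),
              discriminator = pack_net(checkpoint$discriminator),
              config = checkpoint$config, log = checkpoint$log,
              best_epoch = checkpoint$best_epoch,
              best_val_ssim = checkpoint$best_val_ssim)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- readRDS(path)
  unpack_net <- function(pk) {
    if (is.null(pk)) return(NULL)
    net <- nn_new()
    net$nodes <- pk$nodes
    net$out <- pk$out
    structure(list(graph = net, config = pk$config, type = pk$type),
              class = "biraster_net")
  }
  structure(list(generator = unpack_net(obj$generator),
                 discriminator = unpack_net(obj$discriminator),
                 config = obj$config, log = obj$log,
                 best_epoch = obj$best_epoch,
                 best_val_ssim = obj$best_val_ssim),
            class = "biraster_checkpoint")
}

#' Write a depth-encoded rendering to PNG
#'
#' @param encoded a [depth_encode()] result.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_depth_png <- function(encoded, path) {
  if (!inherits(encoded, "depth_encoded_image")) stop("expected a depth_encoded_image")
  png::writePNG(encoded$rgb, path)
  invisible(path)
}
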