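#' Paired training sample
#'
#' One (LR, HR) slice pair with provenance. Invariants (dims, range,
#' divisibility) are checked at construction.
#'
#' @param hr HR slice matrix in `[0, 1]`.
#' @param lr LR slice matrix in `[0, 1]`, dims exactly `dim(hr) / scale`.
#' @param volume_id,slice_index provenance.
#' @param scale decimation factor.
#' @return object of class `slice_pair`.
#' @export
slice_pair <- function(hr, lr, volume_id = "vol", slice_index = 1L, scale = 2L) {
  stopifnot(is.matrix(hr), is.matrix(lr))
  if (!all(dim(lr) * scale == dim(hr)))
    stop("lr dims must be hr dims / scale exactly")
  rng <- range(hr, lr)
  if (rng[1] < 0 || rng[2] > 1) stop("slice_pair intensities must lie in [0, 1]")
  structure(list(hr = hr, lr = lr, volume_id = as.character(volume_id),
                 slice_index = as.integer(slice_index), scale = as.integer(scale)),
            class = "slice_pair")
}

#' Build LR/HR pairs from HR slices
#'
#' Degrades each HR slice with [degrade()] and records provenance.
#'
#' @param hr_images list of HR matrices (or a single matrix), all with dims
#'   divisible by the scale.
#' @param scale decimation factor.
#' @param deg_cfg degradation operator; defaults to the published protocol
#'   (3x3 Gaussian, sigma 1, bicubic) at `scale`.
#' @param volume_ids,slice_indices optional provenance vectors recycled over
#'   the images.
#' @return list of [slice_pair()] objects, one per input image.
#' @export
build_pairs <- function(hr_images, scale = 2L,
                        deg_cfg = degradation_config(scale = scale),
                        volume_ids = NULL, slice_indices = NULL) {
  if (is.matrix(hr_images)) hr_images <- list(hr_images)
  bad <- which(vapply(hr_images, function(m)
    nrow(m) %% scale != 0L || ncol(m) %% scale != 0L, logical(1)))
  if (length(bad))
    stop("image dims not divisible by scale ", scale, " at indices: ",
         paste(bad, collapse = ", "))
  if (is.null(volume_ids)) volume_ids <- sprintf("img%03d", seq_along(hr_images))
  if (is.null(slice_indices)) slice_indices <- seq_along(hr_images)
  volume_ids <- rep_len(volume_ids, length(hr_images))
  slice_indices <- rep_len(slice_indices, length(hr_images))
  lapply(seq_along(hr_images), function(i) {
    hr <- hr_images[[i]]
    slice_pair(hr, degrade(hr, deg_cfg), volume_ids[i], slice_indices[i], scale)
  })
}

#' Volume-level train/validation/test split
#'
#' Splits at the volume (subject) level so adjacent slices of one volume
#' never straddle a split boundary. Seeded shuffle; disjoint and exhaustive.
#'
#' @param volume_ids character vector of distinct volume identifiers.
#' @param fractions length-3 nonnegative fractions summing to 1
#'   (default `c(0.7, 0.1, 0.2)`).
#' @param seed shuffle seed.
#' @param manifest optional CSV path; when given, a `volume_id,split` table
#'   is written there.
#' @return list with elements `train`, `val`, `test`.
#' @examples
#' split_dataset(sprintf("v%02d", 1:10), seed = 1)
#' @export
split_dataset <- function(volume_ids, fractions = c(0.7, 0.1, 0.2), seed = 1L,
                          manifest = NULL) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (anyDuplicated(volume_ids)) stop("volume_ids must be distinct")
  n <- length(volume_ids)
  if (n < sum(fractions > 0))
    stop("fewer volumes (", n, ") than nonzero fractions")
  sizes <- floor(fractions * n)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(fractions * n - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  perm <- with_preserved_rng(seed, sample(volume_ids))
  ends <- cumsum(sizes)
  out <- list(train = perm[seq_len(sizes[1])],
              val = if (sizes[2] > 0) perm[(ends[1] + 1):ends[2]] else character(),
              test = if (sizes[3] > 0) perm[(ends[2] + 1):ends[3]] else character())
  if (!is.null(manifest)) {
    tab <- data.frame(volume_id = unlist(out, use.names = FALSE),
                      split = rep(names(out), lengths(out)))
    write.csv(tab, manifest, row.names = FALSE)
  }
  out
}

#' Read an MRI volume or a directory of 2D slices
#'
#' NIfTI files (`.nii`, `.nii.gz`) are read with RNifti; a directory is read
#' as a stack of grayscale PNG slices (sorted by name). Slices iterate along
#' the last axis. Intensities are returned as stored; pass the result
#' through [normalize_intensity()] before degradation.
#'
#' @param path NIfTI file or directory of PNG slices.
#' @param modality optional tag (`"T1"`, `"T2"`, `"PD"`, `"other"`).
#' @return list with `data` (3D array) and `record`
#'   (path, shape, modality).
#' @export
read_volume <- function(path, modality = "other") {
  modality <- match.arg(modality, c("T1", "T2", "PD", "other"))
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) stop("no PNG slices found in ", path)
    slices <- lapply(files, read_image)
    d <- dim(slices[[1L]])
    arr <- array(0, c(d, length(slices)))
    for (i in seq_along(slices)) arr[, , i] <- slices[[i]]
  } else {
    if (!file.exists(path)) stop("cannot read volume: ", path, " does not exist")
    arr <- tryCatch(as.array(RNifti::readNifti(path)),
                    error = function(e) stop("unreadable NIfTI file ", path,
                                             ": ", conditionMessage(e)))
    arr <- array(as.numeric(arr), dim(arr))   # drop NIfTI header attributes
    if (length(dim(arr)) != 3L)
      stop("expected a 3D NIfTI volume, got ", length(dim(arr)), " axes in ", path)
  }
  list(data = arr,
       record = list(path = path, shape = dim(arr), modality = modality))
}

#' Extract 2D slices from a volume
#' @param volume 3D array (or the list returned by [read_volume()]).
#' @return list of matrices, one per index of the last axis.
#' @export
volume_slices <- function(volume) {
  if (is.list(volume)) volume <- volume$data
  stopifnot(length(dim(volume)) == 3L)
  lapply(seq_len(dim(volume)[3L]), function(i) volume[, , i])
}

#' Read/write 2D grayscale images and NIfTI volumes
#'
#' PNG images are written 16-bit grayscale; NIfTI via RNifti. Values are
#' expected in `[0, 1]`.
#'
#' @param x matrix (PNG) or 3D array (NIfTI).
#' @param path destination; format chosen by extension (`.png`, `.nii`,
#'   `.nii.gz`).
#' @export
write_image <- function(x, path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (tolower(tools::file_ext(path)) == "png") {
    png::writePNG(pmin(pmax(x, 0), 1), path, dpi = NULL)
  } else if (ext == "nii") {
    RNifti::writeNifti(RNifti::asNifti(x), path)
  } else stop("unsupported image format: ", path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, " does not exist")
  if (tolower(tools::file_ext(path)) == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    return(img)
  }
  stop("unsupported image format: ", path)
}

#' Write a pairing manifest
#'
#' One line per pair: hr path, lr path, scale, blur sigma, kernel size and
#' bicubic dialect — enough to re-run the degradation.
#'
#' @param rows data.frame with columns `hr`, `lr`.
#' @param deg_cfg the [degradation_config()] used.
#' @param path destination CSV.
#' @export
write_pair_manifest <- function(rows, deg_cfg, path) {
  rows$scale <- deg_cfg$scale
  rows$sigma <- deg_cfg$sigma
  rows$kernel <- deg_cfg$kernel_size
  rows$bicubic_a <- deg_cfg$bicubic_a
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
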