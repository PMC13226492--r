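# ---------------------------------------------------------------------------
# Dataset ingestion, preprocessing and patient-level splitting.
# ---------------------------------------------------------------------------

#' Preprocess an image for the network
#'
#' Converts to grayscale (luminance weights) if needed, resizes bilinearly
#' to `size` x `size`, and linearly min-max scales intensities to `[0, 1]`.
#' Constant images map to all zeros (degenerate-range guard).
#'
#' @param image matrix (H,W) or array (H,W,3).
#' @param size target side length.
#' @return matrix (size, size) with values in `[0, 1]`.
#' @export
preprocess <- function(image, size = 256L) {
  d <- dim(image)
  if (is.null(d) || length(d) < 2 || d[1] < 1 || d[2] < 1)
    stop("unreadable or zero-area image")
  if (length(d) == 3 && d[3] >= 3) {
    image <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  } else if (length(d) == 3) {
    image <- image[, , 1]
  }
  x <- array(as.numeric(image), c(dim(image), 1L, 1L))
  y <- resize_bilinear_array(x, size, size)[, , 1, 1]
  rng <- range(y)
  if (rng[2] > rng[1]) (y - rng[1]) / (rng[2] - rng[1]) else y * 0
}

#' Preprocess a segmentation mask
#'
#' Nearest-neighbor resize followed by re-binarization (threshold 0.5 on the
#' `[0,1]` scale, i.e. >127 for 8-bit masks).
#'
#' @param mask matrix with values in `[0,1]` (or 0/255 scaled).
#' @param size target side length.
#' @return binary matrix (size, size) with values in `{0, 1}`.
#' @export
preprocess_mask <- function(mask, size = 256L) {
  d <- dim(mask)
  if (length(d) == 3) mask <- mask[, , 1]
  if (max(mask) > 1) mask <- mask / 255
  ridx <- pmin(pmax(ceiling((seq_len(size) - 0.5) * nrow(mask) / size), 1),
               nrow(mask))
  cidx <- pmin(pmax(ceiling((seq_len(size) - 0.5) * ncol(mask) / size), 1),
               ncol(mask))
  (mask[ridx, cidx, drop = FALSE] > 0.5) * 1L
}

#' Parse a patient id from a file stem
#'
#' Stems of the form `<patient>_<index>` map to `<patient>`; stems without
#' an underscore are their own patient (one image per patient).
#' @param stem character vector of file stems.
#' @return character vector of patient ids.
#' @export
parse_patient_id <- function(stem) {
  ifelse(grepl("_[^_]+$", stem), sub("_[^_]+$", "", stem), stem)
}

#' Patient-level train/test split
#'
#' Patients are shuffled with the seed and assigned greedily to the training
#' set until the training fraction first reaches `ratio`; the remainder goes
#' to the test set.  All images of one patient always share a split.
#'
#' @param entries data.frame with at least a `patient_id` column, one row
#'   per image.
#' @param ratio target training fraction.
#' @param seed shuffle seed.
#' @return the data.frame with a `split` column (`"train"`/`"test"`), class
#'   `dataset_manifest`.
#' @export
patient_split <- function(entries, ratio = 0.7, seed = 1L) {
  stopifnot(is.data.frame(entries), "patient_id" %in% names(entries))
  patients <- unique(entries$patient_id)
  with_seed(derive_seed(seed, "split"), {
    patients <- sample(patients)
  })
  sizes <- table(entries$patient_id)[patients]
  n <- nrow(entries)
  test_budget <- n - ceiling(ratio * n)
  assigned <- character(length(patients))
  n_train <- 0
  for (i in seq_along(patients)) {
    if (n_train / n < ratio) {
      assigned[i] <- "train"
      n_train <- n_train + sizes[i]
    } else {
      if (sizes[i] > test_budget) {
        warning("patient ", patients[i],
                " has more images than the test budget; assigned to train")
        assigned[i] <- "train"
        n_train <- n_train + sizes[i]
      } else assigned[i] <- "test"
    }
  }
  names(assigned) <- patients
  entries$split <- unname(assigned[entries$patient_id])
  class(entries) <- c("dataset_manifest", "data.frame")
  entries
}

#' Validate a split manifest for patient-level leakage
#'
#' @param manifest data.frame with `patient_id` and `split` columns.
#' @return `TRUE` invisibly; errors if any patient straddles the two splits.
#' @export
validate_manifest <- function(manifest) {
  bad <- tapply(manifest$split, manifest$patient_id,
                function(s) length(unique(s)) > 1)
  if (any(bad))
    stop("patient-level leakage: ",
         paste(names(bad)[bad], collapse = ", "),
         " appear in both subsets")
  invisible(TRUE)
}

#' Load a paired images/masks dataset directory
#'
#' Expects the layout written by [write_dataset()]: `images/` and `masks/`
#' subdirectories with matching PNG stems.  Images are run through
#' [preprocess()], masks through [preprocess_mask()].  Unpaired files are
#' reported in the `mismatches` attribute.
#'
#' @param dir dataset directory.
#' @param size target side length for preprocessing.
#' @param normalize apply per-image min-max scaling to `[0,1]`; with
#'   `FALSE`, raw 8-bit intensities are kept on the `[0,1]` scale, which
#'   makes reading back a written dataset exact up to quantization.
#' @return list of `phantom_sample`-like lists, with attribute `mismatches`.
#' @export
load_dataset <- function(dir, size = 256L, normalize = TRUE) {
  img_dir <- file.path(dir, "images"); msk_dir <- file.path(dir, "masks")
  imgs <- sort(list.files(img_dir, pattern = "\\.png$"))
  msks <- sort(list.files(msk_dir, pattern = "\\.png$"))
  if (!length(imgs)) stop("no images found under ", img_dir)
  stems_i <- sub("\\.png$", "", imgs); stems_m <- sub("\\.png$", "", msks)
  common <- intersect(stems_i, stems_m)
  mismatches <- c(setdiff(stems_i, stems_m), setdiff(stems_m, stems_i))
  manifest_pid <- NULL
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) {
    man <- jsonlite::read_json(mf)
    manifest_pid <- vapply(man$entries, function(e) e$patient_id, character(1))
    names(manifest_pid) <- vapply(man$entries, function(e) e$stem, character(1))
  }
  out <- lapply(common, function(st) {
    img <- png::readPNG(file.path(img_dir, paste0(st, ".png")))
    msk <- png::readPNG(file.path(msk_dir, paste0(st, ".png")))
    pid <- if (!is.null(manifest_pid) && st %in% names(manifest_pid))
      manifest_pid[[st]] else parse_patient_id(st)
    if (length(dim(img)) == 3) img <- img[, , 1]
    s <- list(image = if (normalize) preprocess(img, size) else
                resize_bilinear_array(array(img, c(dim(img), 1L, 1L)),
                                      size, size)[, , 1, 1],
              mask = preprocess_mask(msk, size),
              patient_id = pid, stem = st)
    class(s) <- "phantom_sample"
    s
  })
  attr(out, "mismatches") <- mismatches
  out
}

#' Stack a list of samples into network input arrays
#' @param samples list of samples with `image`/`mask` matrices.
#' @return list with `images` (H,W,1,N) and `masks` (H,W,N).
#' @export
stack_samples <- function(samples) {
  H <- nrow(samples[[1]]$image); W <- ncol(samples[[1]]$image)
  n <- length(samples)
  images <- array(0, c(H, W, 1L, n))
  masks <- array(0, c(H, W, n))
  for (i in seq_len(n)) {
    images[, , 1, i] <- samples[[i]]$image
    masks[, , i] <- samples[[i]]$mask
  }
  list(images = images, masks = masks)
}
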