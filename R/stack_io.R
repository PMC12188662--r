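REPORT_SCHEMA_VERSION <- "1"

#' Calibrated multi-channel image stack
#'
#' The package-wide container for a z-stack: a 4D array in fixed
#' `(channel, z, y, x)` order with strictly positive voxel spacing in
#' micrometres. All modules rely on this axis convention.
#'
#' @param data numeric 4D array `(channel, z, y, x)`.
#' @param voxel_spacing_um (z, y, x) voxel pitch in micrometres.
#' @param channel_names character vector, one name per channel.
#' @param source_id opaque stack identifier used in reports and file names.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(data, voxel_spacing_um, channel_names,
                        source_id = "stack") {
  d <- dim(data)
  if (is.null(d) || length(d) != 4L) {
    stop("data must be a 4D (channel, z, y, x) array", call. = FALSE)
  }
  if (any(d[2:4] < 1L)) stop("all spatial dims must be >= 1", call. = FALSE)
  voxel_spacing_um <- check_spacing(voxel_spacing_um)
  channel_names <- as.character(channel_names)
  if (length(channel_names) != d[1]) {
    stop(sprintf("channel mismatch: %d channels in data but %d names",
                 d[1], length(channel_names)), call. = FALSE)
  }
  structure(list(data = data, voxel_spacing_um = voxel_spacing_um,
                 channel_names = channel_names,
                 source_id = as.character(source_id)),
            class = "image_stack")
}

#' Extract one channel of a stack as a 3D (z, y, x) array
#' @param stack an `image_stack`.
#' @param channel channel name or index.
#' @return numeric 3D array.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(channel)) {
    k <- match(channel, stack$channel_names)
    if (is.na(k)) stop(sprintf("no channel named '%s'", channel), call. = FALSE)
  } else k <- as.integer(channel)
  if (k < 1L || k > dim(stack$data)[1]) stop("channel index out of range",
                                             call. = FALSE)
  array(stack$data[k, , , ], dim = dim(stack$data)[2:4])
}

# structured I/O log: one line per file touched, with an md5 checksum.
# Printed when options(voxquant.verbose = TRUE); appended to
# options(voxquant.log_file =) when set.
log_io <- function(action, path) {
  sum <- tryCatch(unname(tools::md5sum(path)), error = function(e) NA_character_)
  line <- sprintf("%s\t%s\t%s\t%s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), action, path, sum)
  if (isTRUE(getOption("voxquant.verbose"))) message(line)
  lf <- getOption("voxquant.log_file")
  if (!is.null(lf)) cat(line, "\n", sep = "", file = lf, append = TRUE)
  invisible(line)
}

stack_metadata_json <- function(stack) {
  jsonlite::toJSON(list(
    format = "voxquant-stack", version = 1L,
    channel_names = stack$channel_names,
    voxel_spacing_um = stack$voxel_spacing_um,
    shape = dim(stack$data)[2:4],
    source_id = stack$source_id), auto_unbox = FALSE, digits = NA)
}

metadata_sidecar_path <- function(path) paste0(path, ".json")

#' Write an image stack as a multi-page 16-bit TIFF with a metadata sidecar
#'
#' Pages are stored channel-major (all z of channel 1, then channel 2, ...).
#' Calibration, channel names and the source id are written to a JSON
#' sidecar (`<path>.json`) so [read_stack()] round-trips voxel- and
#' metadata-exactly. Intensities must lie in `[0, 65535]` and are stored as
#' 16-bit integers.
#'
#' @param stack an `image_stack`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  if (min(stack$data) < 0 || max(stack$data) > 65535) {
    stop("stack intensities must be within [0, 65535]", call. = FALSE)
  }
  pages <- vector("list", d[1] * d[2])
  k <- 0L
  for (ch in seq_len(d[1])) for (z in seq_len(d[2])) {
    k <- k + 1L
    pages[[k]] <- matrix(stack$data[ch, z, , ], d[3], d[4]) / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  writeLines(as.character(stack_metadata_json(stack)),
             metadata_sidecar_path(path))
  log_io("write_stack", path)
  invisible(path)
}

#' Read a calibrated image stack from TIFF
#'
#' Reads a multi-page TIFF written by [write_stack()] (metadata in the JSON
#' sidecar `<path>.json`) or a plain TIFF with calibration supplied through
#' `spacing_override`/`channel_names`. A stack with no calibration in its
#' metadata and no override is an error: volumes in um^3 are the headline
#' output and a silently guessed pitch would corrupt them.
#'
#' @param path TIFF file path.
#' @param spacing_override optional (z, y, x) um triple overriding (or
#'   supplying) calibration; its use is logged.
#' @param channel_names optional channel names for files without metadata;
#'   page count must be divisible by the channel count.
#' @return an `image_stack`.
#' @export
read_stack <- function(path, spacing_override = NULL, channel_names = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- NULL
  sidecar <- metadata_sidecar_path(path)
  if (file.exists(sidecar)) {
    meta <- tryCatch(jsonlite::fromJSON(sidecar), error = function(e) NULL)
    if (!is.null(meta) && !identical(meta$format, "voxquant-stack")) meta <- NULL
  }
  if (!is.null(meta)) {
    ch <- as.character(meta$channel_names)
    spacing <- as.numeric(meta$voxel_spacing_um)
    source_id <- as.character(meta$source_id)
    if (!is.null(channel_names) && length(channel_names) != length(ch)) {
      stop(sprintf("channel mismatch: file has %d channels but %d names given",
                   length(ch), length(channel_names)), call. = FALSE)
    }
    if (!is.null(channel_names)) ch <- as.character(channel_names)
  } else {
    ch <- if (is.null(channel_names)) "channel1" else as.character(channel_names)
    spacing <- NULL
    source_id <- tools::file_path_sans_ext(basename(path))
  }
  if (!is.null(spacing_override)) {
    spacing <- check_spacing(spacing_override)
    log_io("spacing_override", path)
  }
  if (is.null(spacing)) {
    stop(paste0("no voxel calibration: file carries none and no ",
                "spacing_override was supplied"), call. = FALSE)
  }
  n_pages <- length(pages)
  n_ch <- length(ch)
  if (n_pages %% n_ch != 0L) {
    stop(sprintf("channel mismatch: %d pages not divisible by %d channels",
                 n_pages, n_ch), call. = FALSE)
  }
  nz <- n_pages %/% n_ch
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  data <- array(0, dim = c(n_ch, nz, ny, nx))
  k <- 0L
  for (c in seq_len(n_ch)) for (z in seq_len(nz)) {
    k <- k + 1L
    data[c, z, , ] <- round(pages[[k]] * 65535)
  }
  log_io("read_stack", path)
  image_stack(data, voxel_spacing_um = spacing, channel_names = ch,
              source_id = source_id)
}

#' Write / read a 3D integer label volume as 16-bit TIFF
#'
#' @param labels integer 3D (z, y, x) array, background 0, labels <= 65535.
#' @param path file path.
#' @return `write_labels`: `path` invisibly; `read_labels`: integer array.
#' @export
write_labels <- function(labels, path) {
  if (is.list(labels) && !is.null(labels$data)) labels <- labels$data
  d <- dim(labels)
  stopifnot(length(d) == 3L)
  if (min(labels) < 0 || max(labels) > 65535) {
    stop("labels must be integers in [0, 65535]", call. = FALSE)
  }
  pages <- lapply(seq_len(d[1]), function(z) matrix(labels[z, , ], d[2], d[3]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  log_io("write_labels", path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  out <- array(0L, dim = c(length(pages), ny, nx))
  for (z in seq_along(pages)) out[z, , ] <- as.integer(round(pages[[z]] * 65535))
  log_io("read_labels", path)
  out
}

#' Write a binary ROI mask as 8-bit 0/255 TIFF
#' @param mask logical 3D (z, y, x) array.
#' @param path file path.
#' @export
write_roi_mask <- function(mask, path) {
  d <- dim(mask)
  stopifnot(length(d) == 3L, is.logical(mask))
  pages <- lapply(seq_len(d[1]), function(z) matrix(mask[z, , ] * 1, d[2], d[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  log_io("write_roi_mask", path)
  invisible(path)
}

#' Read and validate region-of-interest masks for a stack
#'
#' Masks must be binary (0/255 8-bit), co-registered with the stack (equal
#' spatial shape) and, when both the "SNc" and "SNc+SNr" masks are present,
#' nested: every SNc voxel must also be in SNc+SNr.
#'
#' @param paths named character vector of TIFF paths; names are ROI names
#'   (at minimum "SNc" and "SNc+SNr" in the midbrain workflow).
#' @param stack the `image_stack` the masks belong to.
#' @return named list of logical 3D arrays of class `roi_mask_set`.
#' @export
read_roi_masks <- function(paths, stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    stop("paths must be a named vector of ROI mask files", call. = FALSE)
  }
  shape <- dim(stack$data)[2:4]
  masks <- lapply(paths, function(p) {
    pages <- tiff::readTIFF(p, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    vals <- round(unlist(lapply(pages, as.numeric)) * 255)
    if (!all(vals %in% c(0, 255))) {
      stop(sprintf("ROI mask is not binary (0/255): %s", p), call. = FALSE)
    }
    m <- array(FALSE, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (z in seq_along(pages)) m[z, , ] <- round(pages[[z]] * 255) == 255
    log_io("read_roi_mask", p)
    m
  })
  for (nm in names(masks)) {
    if (!identical(dim(masks[[nm]]), as.integer(shape))) {
      stop(sprintf("ROI mask '%s' shape (%s) does not match stack (%s)",
                   nm, paste(dim(masks[[nm]]), collapse = "x"),
                   paste(shape, collapse = "x")), call. = FALSE)
    }
  }
  validate_roi_set(masks)
  structure(masks, class = "roi_mask_set")
}

# nesting invariant shared by file-based and in-memory ROI sets
validate_roi_set <- function(masks) {
  if (all(c("SNc", "SNc+SNr") %in% names(masks))) {
    if (any(masks[["SNc"]] & !masks[["SNc+SNr"]])) {
      stop("ROI consistency error: 'SNc' is not contained in 'SNc+SNr'",
           call. = FALSE)
    }
  }
  invisible(masks)
}

#' Write a per-stack report table to CSV
#'
#' Adds a `schema_version` column so cohort merges can reject mixed
#' schemas. One row per stack x ROI.
#'
#' @param report data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(is.data.frame(report))
  if (is.null(report$schema_version)) {
    report$schema_version <- REPORT_SCHEMA_VERSION
  }
  write.csv(report, path, row.names = FALSE)
  log_io("write_report", path)
  invisible(path)
}

#' Combine per-stack report CSVs into one cohort table
#'
#' Mirrors the study's combine step in which every analysed z-stack emits a
#' separate CSV that a second script merges for statistics. Files must share
#' a schema version and column set; the merge is order-independent (rows are
#' sorted canonically). Duplicate `stack_id` values are kept but flagged
#' with a warning.
#'
#' @param paths character vector of CSV paths.
#' @return combined data.frame.
#' @export
combine_reports <- function(paths) {
  stopifnot(length(paths) >= 1L)
  tabs <- lapply(paths, function(p) {
    t <- read.csv(p, stringsAsFactors = FALSE)
    log_io("read_report", p)
    if (!is.null(t$schema_version)) {
      t$schema_version <- as.character(t$schema_version)
    }
    t
  })
  vers <- unique(unlist(lapply(tabs, function(t) unique(as.character(t$schema_version)))))
  if (length(vers) != 1L) {
    stop(sprintf("schema-version clash across reports: %s",
                 paste(vers, collapse = ", ")), call. = FALSE)
  }
  cols <- lapply(tabs, names)
  if (length(unique(vapply(cols, paste, character(1), collapse = "|"))) != 1L) {
    stop("reports do not share one column schema", call. = FALSE)
  }
  out <- do.call(rbind, tabs)
  if (!is.null(out$stack_id) && !is.null(out$roi_name)) {
    key <- paste(out$stack_id, out$roi_name)
    if (anyDuplicated(key)) {
      warning(sprintf("duplicate stack_id/roi rows kept in combined table: %s",
                      paste(unique(key[duplicated(key)]), collapse = "; ")),
              call. = FALSE)
    }
    out <- out[order(out$stack_id, out$roi_name), , drop = FALSE]
  } else if (!is.null(out$stack_id)) {
    if (anyDuplicated(out$stack_id)) {
      warning("duplicate stack_id rows kept in combined table", call. = FALSE)
    }
    out <- out[order(out$stack_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
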