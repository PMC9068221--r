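#' Labeled CT volume
#'
#' A `label_volume` is a 3D integer array with physical geometry attached:
#' per-axis voxel spacing (mm), the world position of the center of voxel
#' (1,1,1) (mm) and an anatomical orientation code.  The world coordinate of
#' voxel index `(i,j,k)` (1-based) is `origin + (i-1, j-1, k-1) * spacing`
#' under the voxel-center convention used throughout the package: a voxel is
#' "in" a region if and only if its center is.
#'
#' The canonical internal orientation is RAS: +x left-to-right, +y
#' posterior-to-anterior, +z inferior-to-superior.  Files whose headers
#' declare a different (axis-aligned) orientation are reoriented on read.
#'
#' @param labels 3D integer array of voxel labels.
#' @param spacing Numeric length-3, voxel size in mm per axis; all > 0.
#' @param origin Numeric length-3, world mm position of the first voxel
#'   center.
#' @param orientation Three-letter orientation code (default "RAS").
#' @param scheme Optional [label_scheme()]; when given, label values are
#'   validated against it.
#' @return An object of class `label_volume`.
#' @examples
#' vol <- label_volume(array(0L, c(8, 8, 8)), spacing = c(1, 1, 1))
#' dim(vol$labels)
#' @export
label_volume <- function(labels, spacing, origin = c(0, 0, 0),
                         orientation = "RAS", scheme = NULL) {
  if (length(dim(labels)) != 3L) stop("`labels` must be a 3D array")
  if (is.double(labels)) {
    if (any(labels != round(labels), na.rm = TRUE)) {
      stop("non-integer data: label volumes must hold integer labels")
    }
    storage.mode(labels) <- "integer"
  }
  if (!is.integer(labels)) stop("non-integer data: label volumes must hold integer labels")
  if (anyNA(labels)) stop("labels contain missing values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("missing/zero spacing: `spacing` must be 3 positive values in mm")
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin))) stop("`origin` must be 3 finite values")
  vol <- structure(list(labels = labels, spacing = spacing, origin = origin,
                        orientation = orientation),
                   class = "label_volume")
  if (!is.null(scheme)) validate_labels(vol, scheme)
  vol
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d x %d x %d voxels, spacing %s mm, origin %s mm, %s\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", "),
              x$orientation))
  tab <- table(x$labels)
  cat("  labels:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                         collapse = ", "), "\n")
  invisible(x)
}

validate_labels <- function(vol, scheme) {
  vals <- scheme_values(assert_scheme(scheme))
  seen <- unique(as.integer(vol$labels))
  bad <- setdiff(seen, vals)
  if (length(bad)) {
    stop(sprintf("unknown label value(s) %s not in scheme {%s}",
                 paste(bad, collapse = ", "), paste(vals, collapse = ", ")))
  }
  invisible(vol)
}

assert_volume <- function(vol) {
  if (!inherits(vol, "label_volume")) stop("`vol` must be a label_volume")
  vol
}

# world coordinates of the voxel-center bounding box, half-voxel padded so it
# is the physical extent of the volume
volume_box <- function(vol) {
  d <- dim(vol$labels)
  list(lo = vol$origin - vol$spacing / 2,
       hi = vol$origin + (d - 1) * vol$spacing + vol$spacing / 2)
}

#' Read a labeled volume from NIfTI or NRRD
#'
#' Reads an integer label volume with spacing metadata from a `.nii`,
#' `.nii.gz` or `.nrrd` file, reorients it to the canonical RAS axes when the
#' header declares an axis-aligned orientation, and validates all label
#' values against the scheme.
#'
#' @param path Path to the volume file.
#' @param scheme A [label_scheme()] used to validate label values.
#' @return A [label_volume()].
#' @seealso [write_labelmap()]
#' @export
read_labelmap <- function(path, scheme = label_scheme()) {
  if (!file.exists(path)) stop(sprintf("unreadable file: '%s' does not exist", path))
  assert_scheme(scheme)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    vol <- read_nifti_labels(path)
  } else if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    vol <- read_nrrd_labels(path)
  } else {
    stop(sprintf("unreadable file: unsupported extension in '%s' (want .nii, .nii.gz or .nrrd)", path))
  }
  validate_labels(vol, scheme)
  vol
}

read_nifti_labels <- function(path) {
  img <- RNifti::readNifti(path)
  ort <- try(RNifti::orientation(img), silent = TRUE)
  if (!inherits(ort, "try-error") && is.character(ort) && !identical(ort, "RAS")) {
    RNifti::orientation(img) <- "RAS"
  }
  aff <- RNifti::xform(img)
  dat <- as.array(img)
  if (length(dim(dat)) == 4L && dim(dat)[4] == 1L) dat <- dat[, , , 1, drop = TRUE]
  if (length(dim(dat)) != 3L) stop("expected a 3D volume")
  if (any(dat != round(dat))) stop("non-integer data: label volumes must hold integer labels")
  dat <- array(as.integer(round(dat)), dim = dim(dat))
  sp <- sqrt(colSums(aff[1:3, 1:3]^2))
  rot <- sweep(aff[1:3, 1:3], 2, sp, "/")
  if (max(abs(rot - diag(3))) > 1e-3) {
    stop("volume affine is not axis-aligned after reorientation; oblique acquisitions are not supported")
  }
  label_volume(dat, spacing = sp, origin = aff[1:3, 4], orientation = "RAS")
}

#' Write a labeled volume to NIfTI or NRRD
#'
#' The format is chosen from the file extension.  Writing then reading back
#' is voxel-exact for integer labels and preserves spacing and origin.
#'
#' @param vol A [label_volume()].
#' @param path Output path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return `path`, invisibly.
#' @export
write_labelmap <- function(vol, path) {
  assert_volume(vol)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(vol$labels, datatype = "int32")
    aff <- diag(4)
    diag(aff)[1:3] <- vol$spacing
    aff[1:3, 4] <- vol$origin
    RNifti::sform(img) <- structure(aff, code = 2L)
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    write_nrrd_labels(vol, path)
  } else {
    stop(sprintf("unsupported extension in '%s' (want .nii, .nii.gz or .nrrd)", path))
  }
  invisible(path)
}

# ---- minimal NRRD support --------------------------------------------------
# No NRRD reader is available to this package's dependencies, so a small
# reader/writer for the subset this package emits is included: 3D integer
# volumes, attached header, raw / gzip / ascii encodings, diagonal axis-
# aligned space directions.

read_nrrd_labels <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic)) stop("unreadable file: not an NRRD file")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unreadable file: truncated NRRD header")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    if (length(kv) != 2L) next
    fields[[tolower(trimws(kv[1]))]] <- trimws(kv[2])
  }
  if (is.null(fields$dimension) || as.integer(fields$dimension) != 3L) {
    stop("only 3D NRRD volumes are supported")
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  type <- fields$type
  rtype <- switch(type,
    "signed char" = , "int8" = , "int8_t" = list(what = "integer", size = 1L, signed = TRUE),
    "uchar" = , "unsigned char" = , "uint8" = , "uint8_t" = list(what = "integer", size = 1L, signed = FALSE),
    "short" = , "short int" = , "signed short" = , "int16" = , "int16_t" = list(what = "integer", size = 2L, signed = TRUE),
    "ushort" = , "unsigned short" = , "uint16" = , "uint16_t" = list(what = "integer", size = 2L, signed = FALSE),
    "int" = , "signed int" = , "int32" = , "int32_t" = list(what = "integer", size = 4L, signed = TRUE),
    "float" = list(what = "double", size = 4L, signed = TRUE),
    "double" = list(what = "double", size = 8L, signed = TRUE),
    stop(sprintf("unsupported NRRD type '%s'", type))
  )
  endian <- if (!is.null(fields$endian) && fields$endian == "big") "big" else "little"
  n <- prod(sizes)
  enc <- tolower(fields$encoding %||% "raw")
  if (enc %in% c("raw")) {
    vals <- readBin(con, what = rtype$what, n = n, size = rtype$size,
                    signed = rtype$signed, endian = endian)
  } else if (enc %in% c("gzip", "gz")) {
    comp <- readBin(con, what = "raw", n = file.size(path))
    vals <- readBin(memDecompress(comp, type = "gzip"), what = rtype$what,
                    n = n, size = rtype$size, signed = rtype$signed, endian = endian)
  } else if (enc %in% c("ascii", "text", "txt")) {
    txt <- readLines(con)
    vals <- as.numeric(scan(text = paste(txt, collapse = " "), quiet = TRUE))
  } else {
    stop(sprintf("unsupported NRRD encoding '%s'", enc))
  }
  if (length(vals) != n) stop("unreadable file: NRRD data shorter than header promises")

  spacing <- c(1, 1, 1)
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space directions"]])) {
    dirs <- parse_nrrd_vectors(fields[["space directions"]])
    if (nrow(dirs) != 3L) stop("expected 3 space directions")
    offdiag <- dirs; diag(offdiag) <- 0
    if (max(abs(offdiag)) > 1e-6) stop("only axis-aligned NRRD space directions are supported")
    spacing <- abs(diag(dirs))
    flip <- diag(dirs) < 0
  } else {
    if (!is.null(fields$spacings)) spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
    flip <- c(FALSE, FALSE, FALSE)
  }
  if (!is.null(fields[["space origin"]])) {
    origin <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]), ",")[[1]])
  }
  arr <- array(as.integer(round(vals)), dim = sizes)
  if (any(abs(vals - round(vals)) > 1e-9)) stop("non-integer data in NRRD label volume")
  # fold negative directions into a flip so internal axes are positive
  for (a in which(flip)) {
    idx <- rev(seq_len(sizes[a]))
    arr <- switch(a, arr[idx, , , drop = FALSE], arr[, idx, , drop = FALSE],
                  arr[, , idx, drop = FALSE])
    origin[a] <- origin[a] - (sizes[a] - 1) * spacing[a]
  }
  label_volume(arr, spacing = spacing, origin = origin, orientation = "RAS")
}

parse_nrrd_vectors <- function(s) {
  m <- gregexpr("\\(([^)]*)\\)", s)[[1]]
  parts <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
  do.call(rbind, lapply(parts, function(p) {
    as.numeric(strsplit(gsub("[()]", "", p), ",")[[1]])
  }))
}

write_nrrd_labels <- function(vol, path) {
  d <- dim(vol$labels)
  hdr <- c(
    "NRRD0004",
    "# generated by nasoplan",
    "type: int32",
    "dimension: 3",
    "space: right-anterior-superior",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("space directions: (%.9g,0,0) (0,%.9g,0) (0,0,%.9g)",
            vol$spacing[1], vol$spacing[2], vol$spacing[3]),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: gzip",
    sprintf("space origin: (%.9g,%.9g,%.9g)",
            vol$origin[1], vol$origin[2], vol$origin[3]),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  payload <- writeBin(as.integer(vol$labels), raw(), size = 4L, endian = "little")
  writeBin(memCompress(payload, type = "gzip"), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resample a label volume onto an isotropic grid
#'
#' Nearest-neighbor resampling of the categorical labels onto a grid with
#' equal spacing on all axes.  The physical extent and center of the volume
#' are preserved to within one voxel; labels are never interpolated.
#' Anisotropic acquisitions (e.g. CT stacks with coarser slice thickness)
#' should be regularized this way before any metric corridor geometry.
#'
#' @param vol A [label_volume()].
#' @param target_spacing Isotropic output spacing in mm (> 0).  Defaults to
#'   the smallest input spacing so no axis is downsampled.
#' @return A [label_volume()] with spacing `c(t, t, t)`.
#' @export
resample_isotropic <- function(vol, target_spacing = min(vol$spacing)) {
  assert_volume(vol)
  t <- as.numeric(target_spacing)
  if (length(t) != 1L || !is.finite(t) || t <= 0) stop("`target_spacing` must be a single positive number")
  d <- dim(vol$labels)
  if (all(abs(vol$spacing - t) < 1e-12)) return(vol)
  out_dim <- pmax(1L, as.integer(round(d * vol$spacing / t)))
  center <- vol$origin + (d - 1) * vol$spacing / 2
  out_origin <- center - (out_dim - 1) * t / 2
  # separable nearest-neighbor index lookup per axis
  idx <- lapply(1:3, function(a) {
    w <- out_origin[a] + (seq_len(out_dim[a]) - 1) * t
    i <- round((w - vol$origin[a]) / vol$spacing[a]) + 1
    pmin(pmax(as.integer(i), 1L), d[a])
  })
  label_volume(vol$labels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
               spacing = c(t, t, t), origin = out_origin,
               orientation = vol$orientation)
}

#' Allowed-region mask
#'
#' Logical mask that is `TRUE` exactly where the corridor may pass: air,
#' surgical space and target voxels.  Its complement is the forbidden
#' (non-surgical) voxel set; together they partition the grid.
#'
#' @param vol A [label_volume()].
#' @param scheme A [label_scheme()].
#' @return Logical 3D array with the volume's dimensions.
#' @export
allowed_mask <- function(vol, scheme = label_scheme()) {
  assert_volume(vol)
  assert_scheme(scheme)
  array(vol$labels %in% c(scheme$air, scheme$surgical, scheme$target),
        dim = dim(vol$labels))
}

#' Forbidden-region mask
#'
#' Complement of [allowed_mask()]: `TRUE` exactly on non-surgical voxels.
#'
#' @inheritParams allowed_mask
#' @return Logical 3D array.
#' @export
forbidden_mask <- function(vol, scheme = label_scheme()) {
  assert_volume(vol)
  assert_scheme(scheme)
  array(vol$labels == scheme$non_surgical, dim = dim(vol$labels))
}
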