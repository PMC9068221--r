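#' Label scheme for segmented surgical scenes
#'
#' Maps the four semantic roles of a segmented CT volume to integer label
#' values: `air` (background outside the skull), `surgical` (the confined
#' surgical space, e.g. the nasal corridor), `non_surgical` (tissue the tool
#' must never touch) and `target` (the marked surgical target, e.g. the
#' anterior wall of the optic canal).
#'
#' A corridor is feasible when every voxel it sweeps is air, surgical space
#' or target; only `non_surgical` voxels are forbidden.  Target voxels are
#' allowed because the corridor must touch the target by construction.
#'
#' @param air,surgical,non_surgical,target Integer label values; must be
#'   four distinct integers.
#' @return An object of class `label_scheme`.
#' @examples
#' label_scheme()
#' @export
label_scheme <- function(air = 0L, surgical = 1L, non_surgical = 2L, target = 3L) {
  vals <- c(air = air, surgical = surgical, non_surgical = non_surgical,
            target = target)
  if (any(vals != round(vals))) stop("label values must be integers")
  vals <- setNames(as.integer(round(vals)), names(vals))
  if (anyDuplicated(vals)) stop("label values must be distinct")
  structure(as.list(vals), class = "label_scheme")
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("<label_scheme>",
      sprintf("air=%d surgical=%d non_surgical=%d target=%d\n",
              x$air, x$surgical, x$non_surgical, x$target))
  invisible(x)
}

scheme_values <- function(scheme) {
  unlist(scheme[c("air", "surgical", "non_surgical", "target")])
}

assert_scheme <- function(scheme) {
  if (!inherits(scheme, "label_scheme")) stop("`scheme` must be a label_scheme")
  scheme
}
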