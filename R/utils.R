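#' Construct a 3D binary mask with voxel spacing
#'
#' The unit that all segmentation-quality metrics and ROI constructions
#' operate on: a logical 3D array plus the physical voxel spacing in mm.
#'
#' @param voxels logical (or coercible) 3D array.
#' @param spacing_mm numeric length-3 (or scalar, recycled), mm per voxel
#'   along each axis; must be strictly positive.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing_mm = c(0.5, 0.5, 0.5)) {
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  stopifnot(length(dim(voxels)) == 3, length(spacing_mm) == 3)
  if (any(spacing_mm <= 0)) stop("spacing_mm must be strictly positive")
  storage.mode(voxels) <- "logical"
  structure(list(voxels = voxels, spacing_mm = as.numeric(spacing_mm)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, %d foreground, spacing %s mm\n",
              paste(dim(x$voxels), collapse = "x"), sum(x$voxels),
              paste(format(x$spacing_mm), collapse = "x")))
  invisible(x)
}

mask_volume_cc <- function(mask) {
  # foreground voxel count times voxel volume; mm^3 -> cm^3
  sum(mask$voxels) * prod(mask$spacing_mm) / 1000
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop("masks have different grid shapes")
  if (!isTRUE(all.equal(a$spacing_mm, b$spacing_mm)))
    stop("masks have different voxel spacings")
  invisible(TRUE)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals do not disturb the
#' caller's RNG stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic child seeds below 2^31, derived from a parent seed
child_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h + 1)
}

voxel_coords <- function(voxels) {
  # n x 3 integer matrix of foreground voxel indices (1-based)
  which(voxels, arr.ind = TRUE)
}

#' Connected-component labelling of a binary array
#'
#' @param voxels logical 2D or 3D array.
#' @param connectivity 6 or 26 for 3D arrays; for 2D input these correspond
#'   to 4- and 8-connectivity.
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(voxels, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 26))
  d <- dim(voxels)
  if (length(d) == 2) d <- c(d, 1L)
  lab <- .cpp_label_components(as.logical(voxels), as.integer(d),
                               as.integer(connectivity))
  dim(lab) <- dim(voxels)
  lab
}

largest_component <- function(voxels, connectivity = 6) {
  lab <- label_components(voxels, connectivity)
  if (!any(lab > 0)) return(voxels & FALSE)
  tab <- tabulate(lab[lab > 0])
  lab == which.max(tab)
}

boundary_voxels <- function(mask) {
  d <- dim(mask$voxels)
  b <- .cpp_boundary_mask(as.logical(mask$voxels), as.integer(d))
  dim(b) <- d
  b
}
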