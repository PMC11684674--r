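## 3D resampling and rotation about the rotation axis y, used to align
## pole-cell stacks before counting.

#' Resample a stack to isotropic voxels
#'
#' Linearly interpolates the stack onto a grid with equal voxel edge
#' lengths along z, y and x. Rigid 3D rotation assumes isotropic voxels,
#' so anisotropic stacks are passed through this first.
#'
#' @param stack an [ImageStack-class] with a known voxel size, or a bare
#'   3D array plus `voxelSize`.
#' @param voxelSize micrometres per voxel `c(z, y, x)` (taken from the
#'   stack when omitted).
#' @param target target isotropic voxel edge length; defaults to the
#'   smallest input voxel dimension.
#' @return An [ImageStack-class] with isotropic `voxelSize`.
#' @export
resampleIsotropic <- function(stack, voxelSize = NULL, target = NULL) {
  if (is(stack, "ImageStack")) {
    if (is.null(voxelSize)) voxelSize <- stack@voxelSize
    a <- stack@data
  } else a <- stack
  if (is.null(voxelSize) || any(is.na(voxelSize)))
    stop("voxel size required for resampling")
  vs <- setNames(as.numeric(voxelSize), c("z", "y", "x"))
  if (is.null(target)) target <- min(vs)
  d <- dim(a)
  ## array axes are [row (y), col (x), slice (z)]
  axVox <- c(vs["y"], vs["x"], vs["z"])
  for (axis in 1:3) {
    if (isTRUE(all.equal(axVox[axis], target))) next
    a <- .interpAxis(a, axis, axVox[axis], target)
  }
  out <- ImageStack(a, voxelSize = c(z = target, y = target, x = target))
  if (is(stack, "ImageStack")) {
    out@datasetId <- stack@datasetId
    out@timepointId <- stack@timepointId
  }
  out
}

## linear interpolation along one array axis (old spacing -> new spacing)
.interpAxis <- function(a, axis, vOld, vNew) {
  d <- dim(a)
  n <- d[axis]
  posOld <- (seq_len(n) - 1) * vOld
  posNew <- seq(0, posOld[n], by = vNew)
  f <- pmin(pmax(posNew / vOld, 0), n - 1)
  i0 <- pmin(floor(f) + 1, n - 1L)
  w <- f - (i0 - 1)
  W <- matrix(0, length(posNew), n)
  W[cbind(seq_along(posNew), i0)] <- 1 - w
  W[cbind(seq_along(posNew), pmin(i0 + 1L, n))] <-
    W[cbind(seq_along(posNew), pmin(i0 + 1L, n))] + w
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- W %*% matrix(ap, nrow = n)
  dNew <- c(length(posNew), d[setdiff(1:3, axis)])
  out <- array(m, dNew)
  aperm(out, order(perm))
}

#' Rigid rotation of a stack about the rotation axis y
#'
#' Rotates every (z, x) plane of the stack by `angle` degrees about the
#' *y* axis using bilinear interpolation; the output canvas is enlarged
#' to contain the whole rotated volume and padded with zeros. Anisotropic
#' stacks are resampled to isotropic voxels first (with a message).
#' Counter-rotating by `-angle` restores the original volume up to
#' interpolation error. Per-dataset alignment angles for the reference
#' pole-cell recordings are -40, -7, +41 and +13 degrees.
#'
#' @param stack an [ImageStack-class], or a 3D array (assumed isotropic).
#' @param angle rotation angle in degrees; positive angles rotate z
#'   towards x.
#' @return An [ImageStack-class].
#' @export
rotateAboutY <- function(stack, angle) {
  if (is(stack, "ImageStack")) {
    vs <- stack@voxelSize
    if (!any(is.na(vs)) && diff(range(vs)) > 1e-9 * min(vs)) {
      message("anisotropic voxels: resampling to isotropic before rotation")
      stack <- resampleIsotropic(stack)
    }
    a <- stack@data
  } else {
    a <- stack
    stack <- ImageStack(a)
  }
  d <- dim(a)
  if (angle %% 360 == 0) return(stack)
  th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  nz <- d[3]; nx <- d[2]
  ## rotated extent of the (z, x) plane
  cz <- (nz + 1) / 2; cx <- (nx + 1) / 2
  hz <- (nz - 1) / 2; hx <- (nx - 1) / 2
  nzOut <- as.integer(ceiling(2 * (abs(ct) * hz + abs(st) * hx))) + 1L
  nxOut <- as.integer(ceiling(2 * (abs(st) * hz + abs(ct) * hx))) + 1L
  czO <- (nzOut + 1) / 2; cxO <- (nxOut + 1) / 2
  grid <- expand.grid(x = seq_len(nxOut), z = seq_len(nzOut))
  dz <- grid$z - czO; dx <- grid$x - cxO
  ## inverse mapping: source = R(-theta) %*% dest
  zs <- ct * dz + st * dx + cz
  xs <- -st * dz + ct * dx + cx
  valid <- zs >= 1 & zs <= nz & xs >= 1 & xs <= nx
  z0 <- pmin(floor(zs), nz - 1L); x0 <- pmin(floor(xs), nx - 1L)
  wz <- zs - z0; wx <- xs - x0
  out <- array(0, c(d[1], nxOut, nzOut))
  vidx <- which(valid)
  z0v <- z0[vidx]; x0v <- x0[vidx]; wzv <- wz[vidx]; wxv <- wx[vidx]
  for (y in seq_len(d[1])) {
    plane <- a[y, , ]                     # [x, z]
    vals <- (1 - wxv) * (1 - wzv) * plane[cbind(x0v, z0v)] +
            wxv * (1 - wzv) * plane[cbind(x0v + 1L, z0v)] +
            (1 - wxv) * wzv * plane[cbind(x0v, z0v + 1L)] +
            wxv * wzv * plane[cbind(x0v + 1L, z0v + 1L)]
    slab <- numeric(nxOut * nzOut)
    slab[vidx] <- vals
    out[y, , ] <- slab
  }
  res <- ImageStack(pmax(out, 0), voxelSize = stack@voxelSize,
                    datasetId = stack@datasetId,
                    timepointId = stack@timepointId)
  res
}
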