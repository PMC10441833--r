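#' Construct a phantom specification
#'
#' Defaults render a 128 x 128 short-axis slice stack whose myocardial ring
#' has moderate tissue heterogeneity and a focal scar sector, roughly the
#' regime in which LGE entropy of a 128-bin histogram falls in the 5.5-6.5
#' bit range seen clinically.
#'
#' @param gridSize pixels per side.
#' @param innerRadius,outerRadius annulus bounds in pixels.
#' @param nSlices number of slices to stack.
#' @param spacing mm per pixel.
#' @param baseIntensity mean myocardial signal (arbitrary units).
#' @param heterogeneitySigma SD of myocardial intensity variation.
#' @param scarFraction fraction of myocardial pixels given scar intensity.
#' @param scarIntensityMultiplier scar intensity multiple of the base.
#' @param scarMode "sector" for one contiguous angular sector (default;
#'   the focal morphology the FWHM rule assumes) or "scattered".
#' @param noiseModel "none", "gaussian", or "rician" (MR magnitude noise).
#' @param noiseSd noise SD.
#' @param seed integer seed.
#' @return a [PhantomSpec-class] object.
#' @examples
#' spec <- phantomSpec(heterogeneitySigma = 0, scarFraction = 0,
#'                     noiseModel = "none", seed = 1)
#' img <- generatePhantom(spec)
#' @export
phantomSpec <- function(gridSize = 128L, innerRadius = 20, outerRadius = 30,
                        nSlices = 1L, spacing = 1.4, baseIntensity = 100,
                        heterogeneitySigma = 20, scarFraction = 0.1,
                        scarIntensityMultiplier = 3, scarMode = "sector",
                        noiseModel = "gaussian", noiseSd = 5, seed = 1L) {
  new("PhantomSpec",
      gridSize = as.integer(gridSize), innerRadius = innerRadius,
      outerRadius = outerRadius, nSlices = as.integer(nSlices),
      spacing = spacing, baseIntensity = baseIntensity,
      heterogeneitySigma = heterogeneitySigma, scarFraction = scarFraction,
      scarIntensityMultiplier = scarIntensityMultiplier,
      scarMode = scarMode, noiseModel = noiseModel, noiseSd = noiseSd,
      seed = as.integer(seed))
}

# Geometry of one slice: radius and angle of every pixel centre relative to
# the grid centre. Masks are half-open in radius: myocardium is
# innerRadius <= r < outerRadius, blood pool r < innerRadius.
sliceGeometry <- function(gridSize, innerRadius, outerRadius) {
  ctr <- (gridSize + 1) / 2
  xs <- seq_len(gridSize) - ctr
  r <- sqrt(outer(xs^2, xs^2, "+"))
  theta <- atan2(matrix(xs, gridSize, gridSize, byrow = TRUE),
                 matrix(xs, gridSize, gridSize))
  list(myo = r >= innerRadius & r < outerRadius,
       blood = r < innerRadius,
       theta = theta)
}

#' Generate a synthetic LGE phantom
#'
#' Renders the ring/blood-pool geometry of \code{spec}: the annulus between
#' the radii is myocardium, the disk inside the inner radius is blood pool
#' at a fixed bright intensity (2.5 x base, as blood is hyperintense on
#' LGE), a contiguous angular sector (or scattered pixels) covering
#' approximately \code{scarFraction} of the myocardium gets
#' \code{baseIntensity * scarIntensityMultiplier}, the remaining myocardium
#' is Normal(base, sigma) truncated at 0, and the chosen noise model is
#' applied last to the whole image.
#'
#' The same spec (including seed) reproduces a bit-identical phantom.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [PhantomImage-class] (2D matrix for one slice, 3D array
#'   otherwise), with myocardium, blood-pool and scar truth masks.
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  g <- spec@gridSize
  geo <- sliceGeometry(g, spec@innerRadius, spec@outerRadius)
  nMyo <- sum(geo$myo)
  if (nMyo == 0L) lgeError("annulus contains no pixels", "emptyRegionError")

  withSeed(spec@seed, {
    dims <- c(g, g, spec@nSlices)
    pixels <- array(0, dims)
    scarMask <- array(FALSE, dims)
    for (s in seq_len(spec@nSlices)) {
      sl <- matrix(0, g, g)
      sl[geo$blood] <- spec@baseIntensity * 2.5
      sl[geo$myo] <- pmax(0, rnorm(nMyo, spec@baseIntensity,
                                   spec@heterogeneitySigma))
      nScar <- round(spec@scarFraction * nMyo)
      if (nScar > 0) {
        idxMyo <- which(geo$myo)
        if (spec@scarMode == "sector") {
          # contiguous angular run starting at a random angle
          start <- runif(1, -pi, pi)
          d <- (geo$theta[idxMyo] - start) %% (2 * pi)
          pick <- idxMyo[order(d)[seq_len(nScar)]]
        } else {
          pick <- sample(idxMyo, nScar)
        }
        sl[pick] <- spec@baseIntensity * spec@scarIntensityMultiplier
        sm <- matrix(FALSE, g, g)
        sm[pick] <- TRUE
        scarMask[, , s] <- sm
      }
      if (spec@noiseModel == "gaussian" && spec@noiseSd > 0) {
        sl <- pmax(0, sl + matrix(rnorm(g * g, 0, spec@noiseSd), g, g))
      } else if (spec@noiseModel == "rician" && spec@noiseSd > 0) {
        n1 <- matrix(rnorm(g * g, 0, spec@noiseSd), g, g)
        n2 <- matrix(rnorm(g * g, 0, spec@noiseSd), g, g)
        sl <- sqrt((sl + n1)^2 + n2^2)
      }
      pixels[, , s] <- sl
    }
    myoMask <- array(rep(geo$myo, spec@nSlices), dims)
    bloodMask <- array(rep(geo$blood, spec@nSlices), dims)
    if (spec@nSlices == 1L) {
      dim(pixels) <- dim(myoMask) <- dim(bloodMask) <- dim(scarMask) <-
        c(g, g)
    }
    new("PhantomImage", pixels = pixels, spacing = spec@spacing,
        myocardiumMask = myoMask, bloodpoolMask = bloodMask,
        scarTruthMask = scarMask)
  })
}

#' Read/write a phantom as NIfTI image plus label map
#'
#' The label map encodes 0 background, 1 myocardium, 2 blood pool, 3 scar
#' (scar pixels are also myocardium; label 3 takes precedence).
#'
#' @param image a [PhantomImage-class].
#' @param imagePath,labelPath output NIfTI paths (.nii or .nii.gz).
#' @return \code{writePhantom} returns the paths invisibly;
#'   \code{readPhantom} returns a [PhantomImage-class] (scar truth taken
#'   from label 3).
#' @export
writePhantom <- function(image, imagePath, labelPath) {
  stopifnot(is(image, "PhantomImage"))
  labels <- array(0L, dim(image@pixels))
  labels[image@myocardiumMask] <- 1L
  labels[image@bloodpoolMask] <- 2L
  labels[image@scarTruthMask] <- 3L
  pd <- rep(image@spacing, min(3L, length(dim(image@pixels))))
  RNifti::writeNifti(RNifti::asNifti(image@pixels, pixdim = pd), imagePath)
  RNifti::writeNifti(RNifti::asNifti(labels, pixdim = pd), labelPath)
  invisible(c(imagePath, labelPath))
}

#' @rdname writePhantom
#' @export
readPhantom <- function(imagePath, labelPath) {
  img <- RNifti::readNifti(imagePath)
  lab <- RNifti::readNifti(labelPath)
  if (!identical(dim(img), dim(lab)))
    lgeError("image and label map dimensions differ", "alignmentError")
  pix <- array(as.numeric(img), dim(img))
  lab <- array(as.integer(round(as.numeric(lab))), dim(img))
  sp <- RNifti::pixdim(img)[1]
  new("PhantomImage", pixels = pix, spacing = as.numeric(sp),
      myocardiumMask = lab == 1L | lab == 3L,
      bloodpoolMask = lab == 2L,
      scarTruthMask = lab == 3L)
}
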