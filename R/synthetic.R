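# Synthetic field scenes with known ground truth.
#
# The generator emulates the class-mixture statistics of four-texture field
# photographs (green plants, dried plants, an intermediate state, dark
# shadow): a blob-structured role map cut from a smooth random field at the
# target area fractions, per-class mean colours under a multiplicative
# illumination ramp, and additive Gaussian pixel noise. It makes no attempt
# at photometric realism (leaf morphology, specularities, mixed pixels).

.defaultPalette <- function() {
  data.frame(role = c("GO", "DO", "HD", "SG"),
             R = c(50, 180, 120, 25),
             G = c(110, 170, 130, 30),
             B = c(40, 80, 60, 25),
             fraction = c(0.35, 0.25, 0.2, 0.2),
             stringsAsFactors = FALSE)
}

#' Specify a synthetic field scene
#'
#' Defaults describe a 512 x 512 scene with the four damage-survey textures
#' (green oat, dried oat, half-dried, shady ground) at fractions
#' 0.35/0.25/0.2/0.2, additive noise of 5 digital numbers (well below the
#' ~76 DN minimum inter-class colour distance of the default palette), a
#' +/-5% illumination ramp and ~32 px blobs.
#'
#' @param width,height image size in pixels
#' @param palette data.frame with columns role, R, G, B, fraction
#' @param noiseSd additive per-channel Gaussian noise sd (8-bit DN)
#' @param gradientAmplitude illumination ramp amplitude (0 = flat)
#' @param patchScale characteristic blob size in pixels
#' @param seed integer random seed
#' @return a \linkS4class{SceneSpec}
#' @export
sceneSpec <- function(width = 512, height = 512, palette = .defaultPalette(),
                      noiseSd = 5, gradientAmplitude = 0.05, patchScale = 32,
                      seed = 1) {
  new("SceneSpec", width = as.integer(width), height = as.integer(height),
      palette = palette, noiseSd = as.numeric(noiseSd),
      gradientAmplitude = as.numeric(gradientAmplitude),
      patchScale = as.numeric(patchScale), seed = as.integer(seed))
}

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.bilinearUpsample <- function(g, nr, nc) {
  ri <- seq(1, nrow(g), length.out = nr)
  ci <- seq(1, ncol(g), length.out = nc)
  r0 <- pmin(floor(ri), nrow(g) - 1L); fr <- ri - r0
  c0 <- pmin(floor(ci), ncol(g) - 1L); fc <- ci - c0
  outer(1 - fr, 1 - fc) * g[r0, c0] + outer(fr, 1 - fc) * g[r0 + 1L, c0] +
    outer(1 - fr, fc) * g[r0, c0 + 1L] + outer(fr, fc) * g[r0 + 1L, c0 + 1L]
}

#' Generate a synthetic field scene with ground truth
#'
#' Each class gets its own smooth random field (coarse Gaussian noise,
#' bilinearly upsampled, summed over two spatial scales); every pixel takes
#' the class whose shifted field is largest, with the per-class shifts
#' calibrated iteratively so the realized area fractions match the targets
#' (within 2% for images of 256 x 256 and up). This yields compact
#' interlocking blobs for every class, including the intermediate ones.
#' Pixel colours are the role's mean RGB scaled by a linear illumination
#' ramp across columns, plus additive Gaussian noise, clipped to [0, 255].
#' Output is reproducible from the spec's seed.
#'
#' @param spec a \linkS4class{SceneSpec}
#' @return list with \code{rgb} (height x width x 3 array, 0..255),
#'   \code{roles} (character matrix of ground-truth roles),
#'   \code{classIndex} (integer matrix, row index into the palette),
#'   \code{spec}
#' @export
generateScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  nr <- spec@height; nc <- spec@width
  pal <- spec@palette
  K <- nrow(pal)
  .withSeed(spec@seed, {
    coarse <- function(scale) {
      g <- matrix(stats::rnorm((max(2L, ceiling(nr / scale)) + 1L) *
                               (max(2L, ceiling(nc / scale)) + 1L)),
                  nrow = max(2L, ceiling(nr / scale)) + 1L)
      .bilinearUpsample(g, nr, nc)
    }
    fields <- vapply(seq_len(K), function(k)
      as.vector(coarse(spec@patchScale) + 0.4 * coarse(spec@patchScale / 4)),
      numeric(nr * nc))
    # calibrate per-class shifts so argmax areas hit the target fractions
    offsets <- numeric(K)
    for (it in 1:100) {
      idx <- max.col(sweep(fields, 2L, offsets, `+`), ties.method = "first")
      frac <- tabulate(idx, K) / (nr * nc)
      err <- frac - pal$fraction
      if (max(abs(err)) < 0.005) break
      offsets <- offsets - 1.5 * err
      offsets <- offsets - mean(offsets)
    }
    classIndex <- matrix(idx, nrow = nr)
    roles <- matrix(pal$role[classIndex], nrow = nr)

    ramp <- 1 + spec@gradientAmplitude *
      (if (nc > 1) (2 * (seq_len(nc) - 1) / (nc - 1) - 1) else 0)
    rgb <- array(0, dim = c(nr, nc, 3L))
    for (ch in 1:3) {
      base <- matrix(pal[[c("R", "G", "B")[ch]]][classIndex], nrow = nr)
      plane <- sweep(base, 2L, ramp, `*`)
      if (spec@noiseSd > 0)
        plane <- plane + matrix(stats::rnorm(nr * nc, sd = spec@noiseSd), nrow = nr)
      rgb[, , ch] <- pmin(pmax(plane, 0), 255)
    }
    list(rgb = rgb, roles = roles, classIndex = classIndex, spec = spec)
  })
}

#' Generate pure reference polygons from a ground-truth role map
#'
#' Places axis-aligned square polygons fully inside single-role regions
#' (with a safety margin to the region boundary), emulating the homogeneous
#' sample units an expert would delineate. Polygons do not overlap. If fewer
#' than the requested number can be placed for some class a warning is
#' issued and the partial result returned.
#'
#' @param roles character matrix of ground-truth roles
#' @param perClass polygons to place per class
#' @param sizeRange integer(2), min and max square side in pixels
#' @param margin pure-region margin around each polygon, in pixels
#' @param seed integer random seed
#' @return list of \linkS4class{PolygonSample}
#' @export
generatePolygons <- function(roles, perClass = 5, sizeRange = c(8, 16),
                             margin = 2, seed = 1) {
  nr <- nrow(roles); nc <- ncol(roles)
  sat <- function(m) {
    s <- apply(m, 2L, cumsum)
    s <- t(apply(s, 1L, cumsum))
    cbind(0, rbind(0, s))
  }
  blockSum <- function(S, r, c, s) S[r + s, c + s] - S[r, c + s] - S[r + s, c] + S[r, c]
  used <- matrix(FALSE, nr, nc)
  polys <- list()
  .withSeed(seed, {
    for (role in unique(as.vector(roles))) {
      mask <- roles == role
      S <- sat(mask * 1)
      placed <- 0L
      attempts <- 0L
      while (placed < perClass && attempts < 400L * perClass) {
        attempts <- attempts + 1L
        side <- sample(sizeRange[1L]:sizeRange[2L], 1L)
        blk <- side + 2L * margin
        if (blk > nr || blk > nc) next
        r <- sample(nr - blk + 1L, 1L)
        c <- sample(nc - blk + 1L, 1L)
        if (blockSum(S, r, c, blk) != blk^2) next
        rr <- (r + margin):(r + margin + side - 1L)
        cc <- (c + margin):(c + margin + side - 1L)
        if (any(used[rr, cc])) next
        used[rr, cc] <- TRUE
        placed <- placed + 1L
        polys[[length(polys) + 1L]] <- polygonSample(
          sprintf("%s_%02d", role, placed), role,
          x = c(cc[1L] - 0.5, cc[length(cc)] + 0.5,
                cc[length(cc)] + 0.5, cc[1L] - 0.5),
          y = c(rr[1L] - 0.5, rr[1L] - 0.5,
                rr[length(rr)] + 0.5, rr[length(rr)] + 0.5))
      }
      if (placed < perClass)
        warning(sprintf("placed %d of %d polygons for class %s",
                        placed, perClass, role))
    }
  })
  polys
}
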