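# Synthetic vertebra phantoms with analytic ground truth.
#
# A phantom vertebral body is a superellipse cylinder |x/a|^n + |y/b|^n <= 1,
# |z| <= h/2 in its own (untilted) frame, optionally tilted about the
# horizontal axis, carrying an analytic PDFF field defined on normalized
# coordinates (u, v, w) = (x/a, y/b, 2 z/h) of that frame. Because the field
# lives in normalized body coordinates, two phantoms of different size but
# identical field specs are ground-truth-identical after standardization,
# which is what makes the shape-independence of the template mapping testable.

#' Analytic PDFF field specification
#'
#' The field is `base + gradient . (u, v, w) + radialAmplitude * (u^2 + v^2)`
#' on normalized body coordinates `u, v, w` in `[-1, 1]`. Validity of the
#' spec (field within [0, 100] percent everywhere on the body) is checked at
#' construction from the closed-form extrema over the corner set.
#'
#' @param base Baseline PDFF, percent.
#' @param gradient Length-3 numeric, percent per unit normalized coordinate
#'   along (horizontal, dorsoventral, longitudinal).
#' @param radialAmplitude Coefficient of the in-plane radial term
#'   `u^2 + v^2`, percent.
#' @return A `FieldSpec` list.
#' @export
fieldSpec <- function(base, gradient = c(0, 0, 0), radialAmplitude = 0) {
  stopifnot(length(gradient) == 3L, is.finite(base))
  linRange <- sum(abs(gradient))
  hi <- base + linRange + max(2 * radialAmplitude, 0)
  lo <- base - linRange + min(2 * radialAmplitude, 0)
  if (lo < 0 || hi > 100)
    stop(sprintf(paste0("field spec can leave [0, 100] %% on the unit body ",
                        "(extrema %.1f .. %.1f)"), lo, hi))
  structure(list(base = base, gradient = as.numeric(gradient),
                 radialAmplitude = radialAmplitude), class = "FieldSpec")
}

#' Evaluate an analytic field at normalized coordinates
#'
#' @param field A [fieldSpec()].
#' @param u,v,w Normalized coordinates in `[-1, 1]` (vectorized).
#' @return PDFF values, percent.
#' @export
evaluateField <- function(field, u, v, w) {
  stopifnot(inherits(field, "FieldSpec"))
  if (any(abs(u) > 1 + 1e-9) || any(abs(v) > 1 + 1e-9) || any(abs(w) > 1 + 1e-9))
    stop("normalized coordinates must lie in [-1, 1]")
  field$base + field$gradient[1] * u + field$gradient[2] * v +
    field$gradient[3] * w + field$radialAmplitude * (u^2 + v^2)
}

#' One phantom vertebra
#'
#' @param semiAxisA,semiAxisB Horizontal / dorsoventral semi-axes, mm.
#' @param heightMm Body height, mm.
#' @param exponent Superellipse exponent (>= 2; 2 = ellipse, larger values
#'   approximate the rounded-rectangular cross-section of a vertebral body).
#' @param inclinationDeg Tilt about the horizontal axis, degrees
#'   (|angle| < 45; positive tilts the ventral end inferiorly).
#' @param field A [fieldSpec()].
#' @return A `VertebraSpec` list.
#' @export
vertebraSpec <- function(semiAxisA, semiAxisB, heightMm, exponent = 2.5,
                         inclinationDeg = 0, field = fieldSpec(40)) {
  stopifnot(semiAxisA > 0, semiAxisB > 0, heightMm > 0, exponent >= 2,
            abs(inclinationDeg) < 45)
  structure(list(a = semiAxisA, b = semiAxisB, h = heightMm, n = exponent,
                 inclinationDeg = inclinationDeg, field = field),
            class = "VertebraSpec")
}

#' Phantom volume specification
#'
#' @param vertebrae List of [vertebraSpec()]s, ordered superior to inferior
#'   (the first entry is the topmost vertebra).
#' @param spacing Voxel spacing in mm; the default matches a typical
#'   chemical-shift-encoded lumbar acquisition (1.2 x 1.2 mm in-plane,
#'   3 mm sections).
#' @param gapMm Intervertebral gap between the tilted z-extents, mm.
#' @param noiseSd Additive Gaussian noise SD on PDFF, percent.
#' @param seed RNG seed for the noise (NULL = use current RNG state).
#' @param labels Integer label values, one per vertebra; default `1:K`
#'   (so with 5 vertebrae and [defaultLabelMap()], the topmost is L1).
#' @param marginMm In-plane and longitudinal background margin, mm.
#' @return A `PhantomSpec` list.
#' @export
phantomSpec <- function(vertebrae, spacing = c(1.2, 1.2, 3.0), gapMm = 6,
                        noiseSd = 0, seed = NULL, labels = NULL,
                        marginMm = 6) {
  if (inherits(vertebrae, "VertebraSpec")) vertebrae <- list(vertebrae)
  stopifnot(length(vertebrae) >= 1L, all(spacing > 0), gapMm > 0,
            noiseSd >= 0, marginMm >= 0)
  if (is.null(labels)) labels <- seq_along(vertebrae)
  stopifnot(length(labels) == length(vertebrae), !anyDuplicated(labels))
  structure(list(vertebrae = vertebrae, spacing = as.numeric(spacing),
                 gapMm = gapMm, noiseSd = noiseSd, seed = seed,
                 labels = as.integer(labels), marginMm = marginMm),
            class = "PhantomSpec")
}

#' Rasterize a phantom specification
#'
#' Each vertebra is rasterized as a (possibly tilted) superellipse cylinder;
#' scalar voxels inside a mask take the analytic field evaluated at the
#' voxel's normalized pre-tilt body coordinates, plus seeded Gaussian noise.
#' Background voxels are 0 % so that any mask-leakage bug depresses masked
#' statistics detectably.
#'
#' @param spec A [phantomSpec()].
#' @param labelMap Label naming convention for the output label volume.
#' @return List with elements `scalar` ([ScalarVolume3D]), `labels`
#'   ([LabelVolume3D]) and `spec`.
#' @export
generatePhantom <- function(spec, labelMap = NULL) {
  stopifnot(inherits(spec, "PhantomSpec"))
  if (!is.null(spec$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      oldSeed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
    }
    set.seed(spec$seed)
  }
  sp <- spec$spacing
  K <- length(spec$vertebrae)
  th <- vapply(spec$vertebrae, function(v) v$inclinationDeg * pi / 180, 0)
  a <- vapply(spec$vertebrae, `[[`, 0, "a")
  b <- vapply(spec$vertebrae, `[[`, 0, "b")
  h <- vapply(spec$vertebrae, `[[`, 0, "h")
  # effective half-extents of the tilted body along y and z
  yHalf <- b * abs(cos(th)) + h / 2 * abs(sin(th))
  zHalf <- b * abs(sin(th)) + h / 2 * abs(cos(th))

  nx <- ceiling(2 * (max(a) + spec$marginMm) / sp[1])
  ny <- ceiling(2 * (max(yHalf) + spec$marginMm) / sp[2])
  cx <- nx * sp[1] / 2
  cy <- ny * sp[2] / 2
  # nominal height-band stacking, superior (first entry) to inferior; the
  # tilt is applied about each centroid afterwards, so strongly tilted
  # bodies can collide across a small gap (detected below)
  pos <- numeric(K)
  for (i in seq_len(K)[-1])
    pos[i] <- pos[i - 1] - h[i - 1] / 2 - spec$gapMm - h[i] / 2
  zBot <- min(pos - zHalf)
  zTop <- max(pos + zHalf)
  nz <- ceiling((zTop - zBot + 2 * spec$marginMm) / sp[3])
  cz <- pos - zBot + spec$marginMm

  scalar <- array(0, c(nx, ny, nz))
  lab <- array(0L, c(nx, ny, nz))
  xs <- (seq_len(nx) - 0.5) * sp[1]
  ys <- (seq_len(ny) - 0.5) * sp[2]
  zs <- (seq_len(nz) - 0.5) * sp[3]

  for (i in seq_len(K)) {
    vb <- spec$vertebrae[[i]]
    ix <- which(abs(xs - cx) <= vb$a + sp[1])
    iy <- which(abs(ys - cy) <= yHalf[i] + sp[2])
    iz <- which(abs(zs - cz[i]) <= zHalf[i] + sp[3])
    if (!length(ix) || !length(iy) || !length(iz))
      stop("vertebra ", i, " does not intersect the phantom grid")
    X <- xs[ix] - cx
    Y <- ys[iy] - cy
    Z <- zs[iz] - cz[i]
    cth <- cos(th[i]); sth <- sin(th[i])
    # body-frame (untilt) coordinates; rotation mixes y and z only
    yb <- outer(Y * cth, Z * sth, "+")          # y' = y cos + z sin
    zb <- outer(-Y * sth, Z * cth, "+")         # z' = -y sin + z cos
    u <- X / vb$a
    vMat <- yb / vb$b
    wMat <- zb / (vb$h / 2)
    inPlane <- abs(vMat)^vb$n
    inside <- outer(abs(u)^vb$n, inPlane, "+") <= 1 &
      outer(rep(TRUE, length(ix)), abs(wMat) <= 1, "&")
    if (!any(inside)) stop("vertebra ", i, " rasterized to zero voxels")
    val <- outer(vb$field$gradient[1] * u + vb$field$radialAmplitude * u^2,
                 vb$field$gradient[2] * vMat + vb$field$gradient[3] * wMat +
                   vb$field$radialAmplitude * vMat^2, "+") + vb$field$base
    sub <- lab[ix, iy, iz, drop = FALSE]
    if (any(sub[inside] != 0L))
      stop("vertebrae overlap after tilt (vertebra ", i,
           "); increase gapMm or reduce inclination")
    vals <- val[inside]
    if (spec$noiseSd > 0)
      vals <- vals + stats::rnorm(length(vals), 0, spec$noiseSd)
    vals <- pmin(pmax(vals, 0), 100)
    subS <- scalar[ix, iy, iz, drop = FALSE]
    subS[inside] <- vals
    scalar[ix, iy, iz] <- subS
    sub[inside] <- spec$labels[i]
    lab[ix, iy, iz] <- sub
  }

  if (is.null(labelMap))
    labelMap <- stats::setNames(paste0("L", spec$labels),
                                as.character(spec$labels))
  list(scalar = suppressMessages(scalarVolume(scalar, sp)),
       labels = labelVolume(lab, labelMap, sp),
       spec = spec)
}

#' Reproducible synthetic cohort
#'
#' Draws `nSubjects` five-vertebra phantom specifications from documented
#' ranges chosen to echo healthy lumbar bone marrow: semi-axes 13--18 /
#' 9--14 mm, heights 25--32 mm, inclinations up to 12 degrees, field
#' baselines 30--42 %, gradients up to 12 % per unit normalized coordinate,
#' radial amplitudes up to 12 % and noise 2.5--4 %, so that per-vertebra SDs
#' span roughly 4--11 % and maxima reach roughly 50--90 %.
#'
#' @param nSubjects Number of subjects (>= 1).
#' @param seed Integer RNG seed; the whole cohort is reproducible from it.
#' @param noiseless If TRUE, noise and sampling are kept but `noiseSd = 0`
#'   (useful for analytic-oracle tests).
#' @return List of length `nSubjects`; each element as [generatePhantom()].
#' @export
cohortFixture <- function(nSubjects, seed, noiseless = FALSE) {
  stopifnot(nSubjects >= 1)
  specs <- cohortSpecs(nSubjects, seed, noiseless = noiseless)
  lapply(specs, generatePhantom)
}

#' Cohort phantom specifications without rasterization
#'
#' @inheritParams cohortFixture
#' @return List of [phantomSpec()]s (one per subject).
#' @export
cohortSpecs <- function(nSubjects, seed, noiseless = FALSE) {
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  }
  set.seed(seed)
  lapply(seq_len(nSubjects), function(s) {
    verts <- lapply(1:5, function(k) {
      grad <- c(stats::runif(1, -6, 6), stats::runif(1, -6, 6),
                sample(c(-1, 1), 1) * stats::runif(1, 4, 12))
      vertebraSpec(
        semiAxisA = stats::runif(1, 13, 18),
        semiAxisB = stats::runif(1, 9, 14),
        heightMm = stats::runif(1, 25, 32),
        exponent = stats::runif(1, 2, 4),
        inclinationDeg = stats::runif(1, -12, 12),
        field = fieldSpec(base = stats::runif(1, 30, 42), gradient = grad,
                          radialAmplitude = stats::runif(1, 0, 12))
      )
    })
    phantomSpec(verts, noiseSd = if (noiseless) 0 else stats::runif(1, 2.5, 4),
                seed = sample.int(.Machine$integer.max - 1L, 1))
  })
}
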