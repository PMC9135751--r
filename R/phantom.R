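#' Segmentation label dictionary
#'
#' Tissue classes carried by phantom segmentation volumes: cortical gray
#' matter (CGM), white matter (WM), deep gray matter (DGM), cerebellum,
#' brainstem, hippocampus, and ventricles; 0 is background.
#'
#' @return Named integer vector of segmentation labels.
#' @export
segmentation_labels <- function() {
  c(cgm = 1L, wm = 2L, dgm = 3L, cerebellum = 4L, brainstem = 5L,
    hippocampus = 6L, ventricles = 7L)
}

#' Parcellation region dictionary
#'
#' Ten regions per hemisphere: the four lobes (frontal, parietal, temporal,
#' occipital), anterior/posterior cingulate, insula, corpus callosum, deep
#' gray matter, and ventricles. Left-hemisphere regions carry ids 1-10,
#' right-hemisphere ids 11-20.
#'
#' @return Named integer vector of left-hemisphere region ids; add
#'   `hemisphere_offset()` for the right hemisphere.
#' @export
parcellation_regions <- function() {
  c(frontal = 1L, parietal = 2L, temporal = 3L, occipital = 4L,
    ant_cingulate = 5L, post_cingulate = 6L, insula = 7L,
    corpus_callosum = 8L, dgm = 9L, ventricles = 10L)
}

#' @rdname parcellation_regions
#' @export
hemisphere_offset <- function() 10L

#' The four lobar regions used for cortical features
#' @return Character vector of lobe names.
#' @export
lobe_names <- function() c("frontal", "parietal", "temporal", "occipital")

#' Phantom specification
#'
#' Describes an analytic brain phantom: a white-matter core whose boundary is
#' a radially perturbed sphere
#' `r(theta, phi) = wm_radius * (1 + fold_amplitude * sin(f * theta) * sin(f * phi))`
#' (`f = fold_frequency`), wrapped in a cortical gray matter shell of constant
#' thickness, with disjoint ellipsoidal accessory structures (DGM, paired
#' ventricles and hippocampi inside the core; cerebellum and brainstem below
#' it). All structure volumes have closed forms at `fold_amplitude = 0`
#' (see [phantom_analytic_volumes()]).
#'
#' @param wm_radius Base radius of the white-matter core, mm.
#' @param fold_amplitude Dimensionless folding amplitude, >= 0.
#' @param fold_frequency Integer angular wavenumber of the folding pattern.
#' @param cgm_thickness Cortical shell thickness, mm.
#' @param spacing Voxel spacing, mm (length 3).
#' @param grid_shape Optional voxel counts per axis; computed to fit the
#'   phantom when `NULL`.
#' @param structures Optional list overriding the accessory-structure layout;
#'   see [phantom_structures()].
#' @param pit Optional radial pit: `list(depth, angular_radius, direction)`.
#'   The pit carves `depth * cos^2(pi * psi / (2 * angular_radius))` out of
#'   the core radius for angles `psi < angular_radius` from `direction`,
#'   giving an exact planar rim so the expected hull distance of the pit
#'   bottom is `depth - wm_radius * (1 - cos(angular_radius))`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(wm_radius = 30, fold_amplitude = 0,
                         fold_frequency = 6L, cgm_thickness = 3,
                         spacing = c(1, 1, 1), grid_shape = NULL,
                         structures = NULL, pit = NULL) {
  spec <- list(
    wm_radius = wm_radius,
    fold_amplitude = fold_amplitude,
    fold_frequency = as.integer(fold_frequency),
    cgm_thickness = cgm_thickness,
    spacing = as.numeric(spacing),
    grid_shape = grid_shape,
    structures = structures %||% phantom_structures(wm_radius),
    pit = pit
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default accessory-structure layout
#'
#' Ellipsoid centers (mm, relative to the brain center) and semi-axes (mm)
#' for the accessory structures, scaled from the white-matter core radius.
#' Internal structures (DGM, paired ventricles and hippocampi) stay inside
#' `0.8 * wm_radius`; the cerebellum and brainstem sit below the cerebrum,
#' clear of the maximal cortical envelope.
#'
#' @param wm_radius White-matter core radius, mm.
#' @return Named list of `list(center, semi)` entries; paired structures have
#'   `center_left`/`center_right`.
#' @export
phantom_structures <- function(wm_radius) {
  R <- wm_radius
  list(
    dgm = list(center = c(0, 0, 0), semi = c(0.28, 0.22, 0.22) * R),
    ventricles = list(
      center_left = c(-0.48, 0, 0.28) * R,
      center_right = c(0.48, 0, 0.28) * R,
      semi = c(0.11, 0.22, 0.11) * R
    ),
    hippocampus = list(
      center_left = c(-0.45, -0.38, -0.28) * R,
      center_right = c(0.45, -0.38, -0.28) * R,
      semi = c(0.09, 0.14, 0.09) * R
    ),
    cerebellum = list(center = c(0, -0.8, -1.65) * R,
                      semi = c(0.5, 0.38, 0.32) * R),
    brainstem = list(center = c(0, 0.3, -1.5) * R,
                     semi = c(0.12, 0.12, 0.2) * R)
  )
}

structure_extent <- function(st) {
  # bounding box corners over all ellipsoids of one structure
  centers <- st[grepl("^center", names(st))]
  do.call(rbind, lapply(centers, function(ce) {
    rbind(ce - st$semi, ce + st$semi)
  }))
}

validate_phantom_spec <- function(spec) {
  if (!is.numeric(spec$wm_radius) || spec$wm_radius <= 0) {
    stop("wm_radius must be positive", call. = FALSE)
  }
  if (spec$fold_amplitude < 0) {
    stop("fold_amplitude must be >= 0", call. = FALSE)
  }
  if (spec$fold_frequency < 1L) {
    stop("fold_frequency must be a positive integer", call. = FALSE)
  }
  if (spec$cgm_thickness <= 0) stop("cgm_thickness must be positive", call. = FALSE)
  if (any(spec$spacing <= 0) || length(spec$spacing) != 3L) {
    stop("spacing must be three positive mm values", call. = FALSE)
  }
  if (!is.null(spec$pit)) {
    if (spec$pit$depth < 0 || spec$pit$angular_radius <= 0) {
      stop("pit depth must be >= 0 and angular_radius > 0", call. = FALSE)
    }
  }

  # extents needed around the brain center
  r_max <- spec$wm_radius * (1 + spec$fold_amplitude) + spec$cgm_thickness
  ext <- rbind(matrix(rep(c(-r_max, r_max), each = 3), ncol = 3, byrow = TRUE),
               do.call(rbind, lapply(spec$structures, structure_extent)))
  margin <- 2 * max(spec$spacing) + 2  # room for smoothing + padding
  lo <- apply(ext, 2, min) - margin
  hi <- apply(ext, 2, max) + margin

  if (is.null(spec$grid_shape)) {
    spec$grid_shape <- as.integer(ceiling((hi - lo) / spec$spacing)) + 1L
    spec$center <- -lo
  } else {
    spec$grid_shape <- as.integer(spec$grid_shape)
    spec$center <- spec$center %||% ((spec$grid_shape - 1) * spec$spacing / 2)
    fit_lo <- all(spec$center + lo + margin - 2 >= 0)
    fit_hi <- all(spec$center + hi - margin + 2 <=
                    (spec$grid_shape - 1) * spec$spacing)
    if (!fit_lo || !fit_hi) {
      stop("phantom does not fit inside grid_shape: ",
           "wm_radius*(1+fold_amplitude)+cgm_thickness and accessory ",
           "structures must fit with a margin", call. = FALSE)
    }
  }
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> R =", x$wm_radius, "mm, amplitude =", x$fold_amplitude,
      ", f =", x$fold_frequency, ", shell =", x$cgm_thickness, "mm\n")
  cat("  grid", paste(x$grid_shape, collapse = "x"), "@",
      paste(x$spacing, collapse = "x"), "mm\n")
  invisible(x)
}

ellipsoid_inside <- function(X, Y, Z, center, semi) {
  ((X - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 +
    ((Z - center[3]) / semi[3])^2 <= 1
}

#' Generate segmentation and parcellation label volumes for a phantom
#'
#' Digitizes the analytic phantom onto the voxel grid (a voxel takes the label
#' of the structure containing its center). The segmentation volume carries
#' tissue classes ([segmentation_labels()]); the parcellation volume carries
#' the 10 regions x 2 hemispheres ([parcellation_regions()]), with cortical
#' sectors defined by angular wedges so every surface vertex has an exact
#' ground-truth region. Generation is deterministic: the same spec always
#' yields bit-identical grids (`seed` is accepted for interface stability).
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer; kept for interface stability (generation is
#'   deterministic given `spec`).
#' @return List with `segmentation` and `parcellation`, both [label_volume()]s.
#' @export
make_phantom <- function(spec, seed = 0L) {
  spec <- validate_phantom_spec(spec)
  d <- spec$grid_shape
  sp <- spec$spacing
  cen <- spec$center

  x <- (seq_len(d[1]) - 1) * sp[1] - cen[1]
  y <- (seq_len(d[2]) - 1) * sp[2] - cen[2]
  z <- (seq_len(d[3]) - 1) * sp[3] - cen[3]
  X <- array(rep(x, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(z, each = d[1] * d[2]), dim = d)

  r <- sqrt(X^2 + Y^2 + Z^2)
  theta <- acos(pmin(1, pmax(-1, ifelse(r > 0, Z / pmax(r, 1e-12), 1))))
  phi <- atan2(Y, X)
  phi[phi < 0] <- phi[phi < 0] + 2 * pi

  f <- spec$fold_frequency
  r_wm <- spec$wm_radius * (1 + spec$fold_amplitude * sin(f * theta) * sin(f * phi))
  if (!is.null(spec$pit)) {
    dir <- spec$pit$direction / sqrt(sum(spec$pit$direction^2))
    cospsi <- (X * dir[1] + Y * dir[2] + Z * dir[3]) / pmax(r, 1e-12)
    psi <- acos(pmin(1, pmax(-1, cospsi)))
    carve <- ifelse(psi < spec$pit$angular_radius,
                    spec$pit$depth * cos(pi * psi / (2 * spec$pit$angular_radius))^2,
                    0)
    r_wm <- r_wm - carve
  }

  labs <- segmentation_labels()
  seg <- array(0L, dim = d)
  in_core <- r <= r_wm
  seg[in_core] <- labs[["wm"]]
  seg[!in_core & r <= r_wm + spec$cgm_thickness] <- labs[["cgm"]]

  st <- spec$structures
  put <- function(seg, st_one, lab) {
    for (nm in names(st_one)[grepl("^center", names(st_one))]) {
      inside <- ellipsoid_inside(X, Y, Z, st_one[[nm]], st_one$semi)
      seg[inside] <- lab
    }
    seg
  }
  # precedence: later assignments overwrite; internal structures carve the core
  seg <- put(seg, st$cerebellum, labs[["cerebellum"]])
  seg <- put(seg, st$brainstem, labs[["brainstem"]])
  seg <- put(seg, st$hippocampus, labs[["hippocampus"]])
  seg <- put(seg, st$dgm, labs[["dgm"]])
  seg <- put(seg, st$ventricles, labs[["ventricles"]])

  # parcellation: cortical sectors for cerebrum voxels, DGM/ventricles kept
  regs <- parcellation_regions()
  sector <- cortical_sector(X, Y, Z, theta)
  parc <- array(0L, dim = d)
  cerebrum <- seg == labs[["cgm"]] | seg == labs[["wm"]] | seg == labs[["hippocampus"]]
  parc[cerebrum] <- sector[cerebrum]
  hemi_off <- ifelse(X > 0, hemisphere_offset(), 0L)
  parc[seg == labs[["dgm"]]] <- regs[["dgm"]] + hemi_off[seg == labs[["dgm"]]]
  parc[seg == labs[["ventricles"]]] <-
    regs[["ventricles"]] + hemi_off[seg == labs[["ventricles"]]]

  list(
    segmentation = label_volume(seg, sp, labels = labs),
    parcellation = label_volume(parc, sp)
  )
}

# Angular-sector region id (left ids 1..8, right 11..18) for cerebrum points.
# Polar caps: theta < pi/8 -> anterior/posterior cingulate (split front/back);
# theta > 7pi/8 -> insula / corpus callosum. Otherwise four equal wedges of
# the front-to-back angle alpha = atan2(|x|, y): frontal, parietal, temporal,
# occipital. The mid-sagittal plane (x = 0) belongs to the left hemisphere.
cortical_sector <- function(X, Y, Z, theta) {
  regs <- parcellation_regions()
  alpha <- atan2(abs(X), Y)  # 0 = front (+y), pi = back (-y)
  sector <- regs[["frontal"]] + pmin(3L, as.integer(floor(alpha / (pi / 4))))
  top <- theta < pi / 8
  bot <- theta > 7 * pi / 8
  sector[top] <- ifelse(Y[top] >= 0, regs[["ant_cingulate"]], regs[["post_cingulate"]])
  sector[bot] <- ifelse(Y[bot] >= 0, regs[["insula"]], regs[["corpus_callosum"]])
  sector <- sector + ifelse(X > 0, hemisphere_offset(), 0L)
  array(as.integer(sector), dim = dim(X))
}

#' Closed-form structure volumes of a phantom
#'
#' Analytic volumes in mm^3. Exact for every ellipsoidal structure at any
#' fold amplitude; exact for WM and CGM at `fold_amplitude = 0` (WM core =
#' sphere minus the internal structures; CGM = spherical shell). For
#' `fold_amplitude > 0` the WM core volume acquires a factor
#' `1 + 3 A^2 E[s^2]` (the odd moments of the product-of-sines perturbation
#' vanish), which this function includes, so it remains exact for pit-free
#' phantoms at any amplitude.
#'
#' @param spec A [phantom_spec()].
#' @return Tibble with columns `tissue` and `volume_mm3`.
#' @export
phantom_analytic_volumes <- function(spec) {
  spec <- validate_phantom_spec(spec)
  st <- spec$structures
  ell <- function(st_one) {
    npair <- sum(grepl("^center", names(st_one)))
    npair * 4 / 3 * pi * prod(st_one$semi)
  }
  R <- spec$wm_radius
  A <- spec$fold_amplitude
  f <- spec$fold_frequency
  # E[sin^2(f theta) sin^2(f phi)] over the sphere
  es2_phi <- 0.5
  int_theta <- stats::integrate(function(t) sin(f * t)^2 * sin(t), 0, pi)$value
  es2 <- (int_theta / 2) * es2_phi
  core <- 4 / 3 * pi * R^3 * (1 + 3 * A^2 * es2)
  # shell over the perturbed core: E[(r+t)^3 - r^3] = 3t E[r^2] + 3t^2 E[r] + t^3
  # with E[r] = R (odd moments vanish) and E[r^2] = R^2 (1 + A^2 E[s^2])
  t <- spec$cgm_thickness
  er2 <- R^2 * (1 + A^2 * es2)
  shell <- 4 * pi / 3 * (3 * t * er2 + 3 * t^2 * R + t^3)
  tibble::tibble(
    tissue = c("cgm", "wm", "dgm", "cerebellum", "brainstem", "hippocampus",
               "ventricles"),
    volume_mm3 = c(
      shell,
      core - ell(st$dgm) - ell(st$ventricles) - ell(st$hippocampus),
      ell(st$dgm), ell(st$cerebellum), ell(st$brainstem),
      ell(st$hippocampus), ell(st$ventricles)
    )
  )
}
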