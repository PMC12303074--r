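#' Circular-inclusion phantom specifications
#'
#' Parameterised simple targets on a square domain: circular speed-of-sound
#' inclusions in a constant background, an optional water-bath frame, an
#' optional rectangular bone-like inclusion, and per-dataset sets of
#' circular initial-pressure inclusions.  The shipped geometries use a loose
#' 3 x 3 arrangement of nine sound-speed inclusions (variants
#' `"low_contrast"`, `"water_bath"`, `"high_contrast"`) or a three-inclusion
#' arrangement (`"three_inclusion"`) for reduced-scale studies; all
#' coordinates are fractions of the domain side so the same specification
#' rasterises on any grid.
#'
#' @param variant phantom family.
#' @param extent domain side length in metres (default 20 mm).
#' @param n_datasets number of initial-pressure distributions (1 to 4).
#' @return object of class `pat_phantom_spec`.
#' @export
simple_phantom_spec <- function(variant = c("low_contrast", "water_bath",
                                            "high_contrast",
                                            "three_inclusion"),
                                extent = 20e-3, n_datasets = 4L) {
  variant <- match.arg(variant)
  f <- function(...) extent * c(...)
  nine <- data.frame(
    cx = f(0.25, 0.50, 0.75, 0.25, 0.50, 0.75, 0.25, 0.50, 0.75),
    cy = f(0.25, 0.25, 0.25, 0.50, 0.50, 0.50, 0.75, 0.75, 0.75),
    r  = f(0.075, 0.06, 0.09, 0.06, 0.075, 0.06, 0.09, 0.06, 0.075),
    c  = 1580)
  three <- data.frame(cx = f(0.30, 0.65, 0.60), cy = f(0.50, 0.30, 0.70),
                      r = f(0.10, 0.09, 0.08), c = 1580)
  p0_sets <- list(
    data.frame(cx = f(0.30, 0.70, 0.50), cy = f(0.30, 0.65, 0.80),
               r = f(0.075, 0.06, 0.05), amplitude = 10),
    data.frame(cx = f(0.70, 0.30, 0.50), cy = f(0.30, 0.65, 0.15),
               r = f(0.06, 0.075, 0.05), amplitude = 10),
    data.frame(cx = f(0.50, 0.20, 0.80), cy = f(0.50, 0.80, 0.80),
               r = f(0.075, 0.05, 0.06), amplitude = 10),
    data.frame(cx = f(0.50, 0.20, 0.80, 0.40), cy = f(0.30, 0.20, 0.50, 0.70),
               r = f(0.05, 0.06, 0.075, 0.05), amplitude = 10))
  spec <- list(
    extent = extent,
    background_c = 1430,
    inclusions = if (variant == "three_inclusion") three else nine,
    water_bath = if (variant == "water_bath")
      list(width = 0.10 * extent, c = 1482) else NULL,
    bone = if (variant == "high_contrast")
      list(xmin = 0.65 * extent, xmax = 0.85 * extent,
           ymin = 0.20 * extent, ymax = 0.80 * extent, c = 2500) else NULL,
    p0_sets = p0_sets[seq_len(n_datasets)],
    variant = variant)
  class(spec) <- "pat_phantom_spec"
  spec
}

#' Rasterise a simple phantom onto a grid
#'
#' Pixel membership is decided by the centre-inside-shape test.  The
#' sound-speed map extends the background value into the sensor and PML
#' margins; initial pressures are zero outside their inclusions.
#'
#' @param spec a `pat_phantom_spec`.
#' @param grid a `pat_grid` whose target extent matches the spec.
#' @return list with `medium` (a `pat_medium` on the full grid) and `p0`
#'   (list of target-domain initial-pressure matrices).
#' @export
build_simple_phantom <- function(spec, grid) {
  scl <- grid$extent / spec$extent
  if (abs(scl - 1) > 0.1) {
    stop("grid target extent does not match the phantom specification")
  }
  # geometry scales with the grid extent (discretisations cannot always hit
  # the nominal domain size exactly)
  spec$inclusions[c("cx", "cy", "r")] <- spec$inclusions[c("cx", "cy", "r")] * scl
  spec$p0_sets <- lapply(spec$p0_sets, function(s) {
    s[c("cx", "cy", "r")] <- s[c("cx", "cy", "r")] * scl
    s
  })
  if (!is.null(spec$water_bath)) spec$water_bath$width <- spec$water_bath$width * scl
  if (!is.null(spec$bone)) {
    spec$bone[c("xmin", "xmax", "ymin", "ymax")] <-
      lapply(spec$bone[c("xmin", "xmax", "ymin", "ymax")], `*`, scl)
  }
  cc <- grid_coords(grid, "target")
  X <- matrix(cc$x, grid$n_interior, grid$n_interior)
  Y <- matrix(cc$y, grid$n_interior, grid$n_interior, byrow = TRUE)
  ext <- spec$extent * scl
  inside_domain <- function(cx, cy, r) {
    all(cx - r >= 0, cx + r <= ext, cy - r >= 0, cy + r <= ext)
  }

  cmap <- matrix(spec$background_c, grid$n_interior, grid$n_interior)
  if (!is.null(spec$water_bath)) {
    w <- spec$water_bath$width
    band <- X < w | X > ext - w | Y < w | Y > ext - w
    cmap[band] <- spec$water_bath$c
  }
  for (j in seq_len(nrow(spec$inclusions))) {
    inc <- spec$inclusions[j, ]
    if (!inside_domain(inc$cx, inc$cy, inc$r)) stop("sound-speed inclusion outside domain")
    cmap[(X - inc$cx)^2 + (Y - inc$cy)^2 <= inc$r^2] <- inc$c
  }
  if (!is.null(spec$bone)) {
    b <- spec$bone
    cmap[X >= b$xmin & X <= b$xmax & Y >= b$ymin & Y <= b$ymax] <- b$c
  }

  p0 <- lapply(spec$p0_sets, function(set) {
    m <- matrix(0, grid$n_interior, grid$n_interior)
    for (j in seq_len(nrow(set))) {
      d <- set[j, ]
      if (!inside_domain(d$cx, d$cy, d$r)) stop("initial-pressure inclusion outside domain")
      m[(X - d$cx)^2 + (Y - d$cy)^2 <= d$r^2] <- d$amplitude
    }
    m
  })

  medium <- make_medium(embed_field(cmap, grid, fill = spec$background_c) ,
                        grid)
  # margins keep the background (or water) value
  if (!is.null(spec$water_bath)) {
    full <- medium$c
    idx <- target_indices(grid)
    full[-idx, ] <- spec$water_bath$c
    full[, -idx] <- spec$water_bath$c
    full[idx, idx] <- cmap
    medium <- make_medium(full, grid)
  }
  list(medium = medium, p0 = p0, c_target = cmap)
}

#' Continuous-wave diffusion-approximation fluence
#'
#' Solves `-div(kappa grad Phi) + mu_a Phi = 0` with
#' `kappa = 1 / (2 (mu_a + mu_s'))` (2D convention) by a cell-centred
#' finite-volume discretisation with harmonic-mean face diffusivities and
#' Robin boundary conditions `Phi / 2 + kappa dPhi/dn = q_in`, where the
#' inward flux `q_in` is 1 on illuminated sides and 0 elsewhere.
#'
#' @param mu_a absorption coefficient field, 1/mm (target-domain matrix).
#' @param mu_s reduced scattering coefficient field, 1/mm.
#' @param illuminated character vector among `"top"`, `"bottom"`, `"left"`,
#'   `"right"`.
#' @param dx_mm pixel size in millimetres.
#' @return fluence field (same shape), non-negative.
#' @export
diffusion_fluence <- function(mu_a, mu_s, illuminated, dx_mm) {
  if (any(mu_a <= 0) || any(mu_s <= 0)) stop("optical coefficients must be positive")
  illuminated <- match.arg(illuminated,
                           c("top", "bottom", "left", "right"),
                           several.ok = TRUE)
  n1 <- nrow(mu_a); n2 <- ncol(mu_a)
  h <- dx_mm
  kap <- 1 / (2 * (mu_a + mu_s))
  idx <- function(i, j) (j - 1L) * n1 + i
  N <- n1 * n2

  diag_acc <- as.vector(mu_a) * h^2
  b <- numeric(N)

  # interior faces, harmonic-mean diffusivity (conductance kf/h * face h)
  gx <- expand.grid(i = seq_len(n1 - 1L), j = seq_len(n2))
  ax <- idx(gx$i, gx$j); bx <- idx(gx$i + 1L, gx$j)
  gy <- expand.grid(i = seq_len(n1), j = seq_len(n2 - 1L))
  ay <- idx(gy$i, gy$j); by <- idx(gy$i, gy$j + 1L)
  kv <- as.vector(kap)
  wx <- 2 / (1 / kv[ax] + 1 / kv[bx])
  wy <- 2 / (1 / kv[ay] + 1 / kv[by])
  fa <- c(ax, ay); fb <- c(bx, by); fw <- c(wx, wy)
  ii <- c(fa, fb); jj <- c(fb, fa); vv <- c(-fw, -fw)
  dacc <- tapply(c(fw, fw), c(fa, fb), sum)
  diag_acc[as.integer(names(dacc))] <- diag_acc[as.integer(names(dacc))] + dacc

  # Robin boundary faces: eliminate the face value from
  # Phi_f / 2 + kf (Phi_f - Phi_c) / (h/2) = q_in
  side_cells <- list(
    left   = idx(rep(1L, n2), seq_len(n2)),
    right  = idx(rep(n1, n2), seq_len(n2)),
    bottom = idx(seq_len(n1), rep(1L, n1)),
    top    = idx(seq_len(n1), rep(n2, n1)))
  for (s in names(side_cells)) {
    cells <- side_cells[[s]]
    kf <- kv[cells]
    g2 <- 2 * kf / h
    denom <- 0.5 + g2
    diag_acc[cells] <- diag_acc[cells] + g2 * (1 - g2 / denom) * h
    if (s %in% illuminated) b[cells] <- b[cells] + g2 / denom * h
  }

  A <- Matrix::sparseMatrix(i = c(ii, seq_len(N)),
                            j = c(jj, seq_len(N)),
                            x = c(vv, diag_acc),
                            dims = c(N, N))
  phi <- Matrix::solve(A, b)
  phi <- matrix(as.vector(phi), n1, n2)
  if (any(!is.finite(phi))) stop("diffusion solve failed: non-finite fluence")
  pmax(phi, 0)
}

#' Initial pressure from absorbed optical energy
#'
#' `p0 = Gamma * mu_a * Phi` with a dimensionless photoacoustic-efficiency
#' (Grueneisen) scale; the absolute scale of `p0` is arbitrary in a linear
#' acoustic model.
#'
#' @param mu_a absorption field, 1/mm.
#' @param fluence fluence field on the same pixels.
#' @param gruneisen_scale scalar efficiency (default 1).
#' @return initial pressure field.
#' @export
p0_from_fluence <- function(mu_a, fluence, gruneisen_scale = 1) {
  if (!all(dim(mu_a) == dim(fluence))) stop("field dimensions differ")
  gruneisen_scale * mu_a * fluence
}

#' Load the bundled chromophore absorption table
#'
#' A small representative table of absorption coefficients (1/mm at unit
#' volume fraction) for oxy-/deoxyhaemoglobin (whole-blood basis), water and
#' fat over 600-1000 nm, synthesised from typical literature magnitudes for
#' demonstration phantoms; supply your own table for quantitative work.
#'
#' @param path CSV with columns `wavelength_nm`, `HbO2`, `HHb`, `water`,
#'   `fat`; defaults to the bundled table.
#' @return data.frame.
#' @export
load_chromophore_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "chromophore_spectra_synthetic.csv",
                        package = "patjrec")
  }
  utils::read.csv(path)
}

#' Absorption map from chromophore volume fractions
#'
#' `mu_a(lambda) = sum_k V_k * mu_a,k(lambda) + baseline`, with the per-
#' chromophore coefficients linearly interpolated in wavelength from the
#' table.
#'
#' @param fractions list with fields `V_HbO2`, `V_HHb`, `V_water`, `V_fat`
#'   (matrices or scalars).
#' @param wavelength wavelength in nm (must lie within the table range).
#' @param spectra_table table from [load_chromophore_table()].
#' @param baseline additive background absorption, 1/mm.
#' @return absorption coefficient field, 1/mm.
#' @export
spectral_mu_a <- function(fractions, wavelength, spectra_table = NULL,
                          baseline = 0) {
  if (is.null(spectra_table)) spectra_table <- load_chromophore_table()
  wl <- spectra_table$wavelength_nm
  if (wavelength < min(wl) || wavelength > max(wl)) {
    stop(sprintf("wavelength %g nm outside table support [%g, %g]",
                 wavelength, min(wl), max(wl)))
  }
  at <- function(col) stats::approx(wl, spectra_table[[col]], wavelength)$y
  fractions$V_HbO2 * at("HbO2") + fractions$V_HHb * at("HHb") +
    fractions$V_water * at("water") + fractions$V_fat * at("fat") + baseline
}

#' Overwrite absorption inside exogenous absorber disks
#'
#' @param mu_a absorption field, 1/mm (target domain).
#' @param absorbers data.frame with `cx`, `cy`, `r` (metres) and optional
#'   `mu_a` (default 0.3 / mm).
#' @param grid the `pat_grid` the field lives on.
#' @return modified absorption field.
#' @export
add_exogenous_absorbers <- function(mu_a, absorbers, grid) {
  if (is.null(absorbers) || nrow(absorbers) == 0) return(mu_a)
  cc <- grid_coords(grid, "target")
  X <- matrix(cc$x, grid$n_interior, grid$n_interior)
  Y <- matrix(cc$y, grid$n_interior, grid$n_interior, byrow = TRUE)
  for (j in seq_len(nrow(absorbers))) {
    a <- absorbers[j, ]
    if (a$cx < 0 || a$cx > grid$extent || a$cy < 0 || a$cy > grid$extent) {
      stop("absorber position outside the target domain")
    }
    val <- if ("mu_a" %in% names(absorbers)) a$mu_a else 0.3
    mu_a[(X - a$cx)^2 + (Y - a$cy)^2 <= a$r^2] <- val
  }
  mu_a
}

#' Procedural tissue-mimicking optical and acoustic phantom
#'
#' A structured 2D stand-in for a soft-tissue cross-section: smooth
#' background chromophore fractions, vessel-like curvilinear absorbers with
#' elevated blood fractions, two elliptical sound-speed lobes and faster
#' vessels.  Deterministic (no RNG): the geometry is fixed in domain-
#' fraction coordinates.
#'
#' @param grid a `pat_grid`.
#' @return list with volume-fraction fields `V_HbO2`, `V_HHb`, `V_water`,
#'   `V_fat`, reference reduced scattering `mu_s_ref` (1/mm at
#'   `lambda_ref_nm = 800`), and the sound-speed map `c_target`.
#' @export
make_tissue_phantom <- function(grid) {
  n <- grid$n_interior
  cc <- grid_coords(grid, "target")
  ext <- grid$extent
  X <- matrix(cc$x, n, n) / ext
  Y <- matrix(cc$y, n, n, byrow = TRUE) / ext

  vessel_mask <- matrix(FALSE, n, n)
  vessel <- function(x0, y0, amp, freq, width, vertical = FALSE) {
    if (vertical) d <- abs(X - (x0 + amp * sin(2 * pi * freq * (Y - y0))))
    else d <- abs(Y - (y0 + amp * sin(2 * pi * freq * (X - x0))))
    vessel_mask <<- vessel_mask | (d < width)
  }
  vessel(0.0, 0.30, 0.08, 1.2, 0.018)
  vessel(0.1, 0.62, 0.06, 0.9, 0.022)
  vessel(0.45, 0.1, 0.07, 1.0, 0.016, vertical = TRUE)
  vessel(0.78, 0.0, 0.05, 1.4, 0.014, vertical = TRUE)

  lobe <- function(cx, cy, rx, ry) ((X - cx) / rx)^2 + ((Y - cy) / ry)^2 <= 1
  lobe1 <- lobe(0.35, 0.62, 0.22, 0.16)
  lobe2 <- lobe(0.68, 0.32, 0.18, 0.14)

  V_HbO2 <- 0.01 + 0.005 * sin(2 * pi * X) * cos(2 * pi * Y)
  V_HHb <- 0.005 + 0.002 * cos(2 * pi * (X + Y))
  V_HbO2[vessel_mask] <- 0.15   # blood-dominated absorption in vessels
  V_HHb[vessel_mask] <- 0.10
  V_water <- 0.6 + 0.05 * lobe1 - 0.05 * lobe2
  V_fat <- 0.25 + 0.075 * lobe2 - 0.05 * lobe1

  mu_s_ref <- matrix(1.0, n, n) + 0.4 * lobe2 - 0.2 * lobe1  # 1/mm at 800 nm

  c_target <- matrix(1480, n, n)
  c_target[lobe1] <- 1540
  c_target[lobe2] <- 1440
  c_target[vessel_mask] <- 1560

  list(V_HbO2 = V_HbO2, V_HHb = V_HHb, V_water = V_water, V_fat = V_fat,
       mu_s_ref = mu_s_ref, lambda_ref_nm = 800, c_target = c_target)
}

#' Reduced scattering at a wavelength
#'
#' Power-law wavelength dependence
#' `mu_s'(lambda) = mu_s_ref * (lambda / lambda_ref)^(-b)`.
#'
#' @param mu_s_ref reference reduced scattering field, 1/mm.
#' @param wavelength wavelength, nm.
#' @param lambda_ref reference wavelength, nm.
#' @param b scattering power (default 1.2).
#' @return reduced scattering field, 1/mm.
#' @export
scale_mu_s <- function(mu_s_ref, wavelength, lambda_ref = 800, b = 1.2) {
  mu_s_ref * (wavelength / lambda_ref)^(-b)
}

#' Generate tissue-mimicking initial-pressure sets
#'
#' Builds the I initial pressures for the three multi-dataset designs:
#' `"illumination"` (one wavelength, planar illumination from each of the
#' four sides in turn), `"wavelength"` (four wavelengths, fixed top+left
#' illumination) and `"absorber"` (fixed wavelength and top+left
#' illumination; datasets 2-4 add four exogenous absorber disks at varying
#' positions).
#'
#' @param phantom output of [make_tissue_phantom()].
#' @param grid the `pat_grid`.
#' @param approach dataset-generation design.
#' @param wavelengths wavelengths (nm) used by the `"wavelength"` design.
#' @param gruneisen_scale passed to [p0_from_fluence()].
#' @param p0_scale multiplier applied to all p0 maps (sets the pressure
#'   scale, which is arbitrary in a linear model).
#' @return list with `p0` (list of I fields), `mu_a` (list of absorption
#'   maps used) and `c_target`.
#' @export
tissue_p0_sets <- function(phantom, grid,
                           approach = c("illumination", "wavelength",
                                        "absorber"),
                           wavelengths = c(650, 750, 850, 950),
                           gruneisen_scale = 1, p0_scale = 10) {
  approach <- match.arg(approach)
  dx_mm <- grid$dx * 1e3
  ext <- grid$extent
  frac <- list(V_HbO2 = phantom$V_HbO2, V_HHb = phantom$V_HHb,
               V_water = phantom$V_water, V_fat = phantom$V_fat)
  fluence_for <- function(mu_a, mu_s, sides) {
    diffusion_fluence(mu_a, mu_s, sides, dx_mm)
  }
  if (approach == "illumination") {
    mu_a <- spectral_mu_a(frac, 800)
    mu_s <- phantom$mu_s_ref
    sides <- list("top", "left", "bottom", "right")
    p0 <- lapply(sides, function(s) {
      p0_from_fluence(mu_a, fluence_for(mu_a, mu_s, s), gruneisen_scale)
    })
    mu_a_list <- rep(list(mu_a), 4)
  } else if (approach == "wavelength") {
    maps <- lapply(wavelengths, function(wl) {
      list(mu_a = spectral_mu_a(frac, wl),
           mu_s = scale_mu_s(phantom$mu_s_ref, wl, phantom$lambda_ref_nm))
    })
    p0 <- lapply(maps, function(m) {
      p0_from_fluence(m$mu_a, fluence_for(m$mu_a, m$mu_s, c("top", "left")),
                      gruneisen_scale)
    })
    mu_a_list <- lapply(maps, `[[`, "mu_a")
  } else {
    wl <- wavelengths[1]
    mu_a0 <- spectral_mu_a(frac, wl)
    mu_s <- scale_mu_s(phantom$mu_s_ref, wl, phantom$lambda_ref_nm)
    absorber_sets <- list(
      NULL,
      data.frame(cx = ext * c(0.08, 0.92, 0.08, 0.92),
                 cy = ext * c(0.08, 0.08, 0.92, 0.92), r = 0.04 * ext),
      data.frame(cx = ext * c(0.50, 0.08, 0.92, 0.50),
                 cy = ext * c(0.06, 0.50, 0.50, 0.94), r = 0.04 * ext),
      data.frame(cx = ext * c(0.25, 0.75, 0.25, 0.75),
                 cy = ext * c(0.06, 0.06, 0.94, 0.94), r = 0.04 * ext))
    mu_a_list <- lapply(absorber_sets, function(ab) {
      if (is.null(ab)) mu_a0 else add_exogenous_absorbers(mu_a0, ab, grid)
    })
    p0 <- lapply(mu_a_list, function(m) {
      p0_from_fluence(m, fluence_for(m, mu_s, c("top", "left")),
                      gruneisen_scale)
    })
  }
  peak <- max(vapply(p0, max, numeric(1)))
  p0 <- lapply(p0, function(m) m * (p0_scale / peak))
  list(p0 = p0, mu_a = mu_a_list, c_target = phantom$c_target)
}

#' Add measurement noise to sensor data
#'
#' Zero-mean Gaussian noise with standard deviation equal to a fraction of
#' the clean dataset's peak-to-peak amplitude; reproducible under a fixed
#' seed (the global RNG state is restored afterwards).
#'
#' @param data a `pat_sensor_data` (clean).
#' @param level noise level as a fraction of peak-to-peak amplitude.
#' @param seed integer seed; `NULL` uses (and advances) the current RNG.
#' @return noisy `pat_sensor_data` with attribute `sigma_target`.
#' @export
add_noise <- function(data, level, seed = NULL) {
  if (level < 0) stop("noise level must be non-negative")
  if (level == 0) return(data)
  sd <- level * (max(data$y) - min(data$y))
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
  }
  out <- data
  out$y <- data$y + matrix(stats::rnorm(length(data$y), sd = sd),
                           nrow(data$y))
  attr(out, "sigma_target") <- sd
  out
}
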