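#' Phantom geometry specifications
#'
#' A `phantom_spec` is a declarative description of a fillable image-quality
#' phantom: a torso-shaped body compartment holding a set of hollow spheres
#' (hot or cold), an optional low-density lung insert on the central axis,
#' and an optional CT low-contrast module bolted onto the end of the body.
#' All lengths are millimetres in a right-handed frame with the phantom
#' centre at the origin; activity concentrations are kBq/mL.
#'
#' Two builders return ready-made phantoms:
#' * [build_nim_phantom()] — the NIM PET/CT phantom: the six NEMA sphere
#'   sizes plus extra 4 mm and 7 mm micro-lesion spheres, a lung insert, and
#'   a 150 mm x 20 mm CT module carrying three low-contrast inserts
#'   (0.5 / 1.0 / 1.5 %, i.e. 5 / 10 / 15 HU).
#' * [build_nema_iec_phantom()] — the NEMA IEC body phantom: spheres
#'   {10, 13, 17, 22, 28, 37} mm, lung insert, no CT module.
#'
#' In both, the 28 mm and 37 mm spheres are cold (filled with water, zero
#' activity) and the rest are hot at `hot_activity` kBq/mL. Defaults follow
#' the standard acquisition: background 6.6 kBq/mL, hot 26.4 kBq/mL
#' (sphere-to-background ratio R = 4).
#'
#' @param overrides Named list of overrides for declared fields
#'   (`background_activity`, `hot_activity`, `spheres`, `lung`, `ct_module`,
#'   `body`). Unknown names are an error. Overriding sphere geometry is
#'   re-validated (overlap / containment).
#' @return A `phantom_spec` object.
#' @examples
#' ph <- build_nim_phantom()
#' ph$spheres
#' activity_ratio(ph)
#' @name phantom_builders
NULL

# signed distance to a rounded rectangle (2D), negative inside
sdf_rounded_rect <- function(x, y, half_w, half_h, corner_r) {
  qx <- abs(x) - (half_w - corner_r)
  qy <- abs(y) - (half_h - corner_r)
  sqrt(pmax(qx, 0)^2 + pmax(qy, 0)^2) + pmin(pmax(qx, qy), 0) - corner_r
}

default_body <- function() {
  list(half_width = 150, half_height = 115, corner_radius = 77, length = 180)
}

default_lung <- function() {
  list(diameter = 50, density = 0.30)
}

#' NEMA-style sphere layout on a circle
#'
#' Sphere centres at equal angular spacing on a circle in the central
#' transverse plane (default radius 57.2 mm, the standard NEMA sphere
#' circle). When a 7 mm sphere is present it is anchored at the 10-o'clock
#' angle (150 degrees), where it appears in the phantom's reference images.
#' Spheres of 28 and 37 mm are assigned the cold role, all others hot.
#'
#' @param diameters Sphere inner diameters in mm.
#' @param ring_radius Radius of the sphere-centre circle, mm.
#' @return A tibble with columns `diameter`, `x`, `y`, `z`, `role`.
#' @export
sphere_ring <- function(diameters, ring_radius = 57.2) {
  n <- length(diameters)
  step <- 360 / n
  i7 <- match(7, diameters)
  anchor <- if (!is.na(i7)) i7 else 1L
  angles <- (150 + step * (seq_len(n) - anchor)) %% 360
  tibble(
    diameter = diameters,
    x = ring_radius * cospi(angles / 180),
    y = ring_radius * sinpi(angles / 180),
    z = 0,
    role = ifelse(diameters %in% c(28, 37), "cold", "hot")
  )
}

default_ct_module <- function() {
  azim <- c(90, 210, 330)
  list(
    diameter = 150,
    thickness = 20,
    center_z = 100,
    # radius of the nominal interface between the water-equivalent
    # background material and the injected purified water; chosen to keep
    # 8 boundary ROIs clear of the inserts (50 mm outer reach) and the rim
    water_boundary_radius = 58,
    inserts = tibble(
      contrast_pct = c(0.5, 1.0, 1.5),
      hu_delta = 10 * c(0.5, 1.0, 1.5),
      diameter = 20,
      x = 40 * cospi(azim / 180),
      y = 40 * sinpi(azim / 180)
    )
  )
}

new_phantom_spec <- function(name, body, spheres, lung, ct_module,
                             background_activity, hot_activity) {
  spec <- structure(
    list(
      name = name, body = body, spheres = spheres, lung = lung,
      ct_module = ct_module,
      background_activity = background_activity,
      hot_activity = hot_activity
    ),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  sp <- spec$spheres
  if (nrow(sp) > 0) {
    if (any(sp$diameter <= 0)) abort("sphere inner diameters must be > 0")
    if (!all(sp$role %in% c("hot", "cold"))) {
      abort("sphere role must be 'hot' or 'cold'")
    }
    # pairwise overlap (3D)
    if (nrow(sp) > 1) {
      d <- as.matrix(dist(cbind(sp$x, sp$y, sp$z)))
      rsum <- outer(sp$diameter / 2, sp$diameter / 2, `+`)
      diag(d) <- Inf
      if (any(d < rsum)) {
        bad <- which(d < rsum, arr.ind = TRUE)[1, ]
        abort(sprintf(
          "geometry error: spheres %.0f mm and %.0f mm overlap",
          sp$diameter[bad[1]], sp$diameter[bad[2]]
        ))
      }
    }
    # containment in the body outline (eroded by the sphere radius)
    b <- spec$body
    sd2 <- sdf_rounded_rect(sp$x, sp$y, b$half_width, b$half_height,
                            b$corner_radius)
    if (any(sd2 + sp$diameter / 2 > 0) ||
        any(abs(sp$z) + sp$diameter / 2 > b$length / 2)) {
      abort("geometry error: sphere extends outside the body outline")
    }
    if (!is.null(spec$lung)) {
      dr <- sqrt(sp$x^2 + sp$y^2) - sp$diameter / 2
      if (any(dr < spec$lung$diameter / 2)) {
        abort("geometry error: sphere overlaps the lung insert")
      }
    }
  }
  if (!is.null(spec$lung)) {
    dens <- spec$lung$density
    if (dens < 0.20 || dens > 0.40) {
      warn(sprintf(
        "lung insert density %.2f g/mL outside the nominal 0.30 +/- 0.10 band",
        dens
      ))
    }
  }
  if (spec$background_activity < 0 || spec$hot_activity < 0) {
    abort("activity concentrations must be non-negative")
  }
  invisible(spec)
}

apply_overrides <- function(defaults, overrides) {
  if (is.null(overrides)) return(defaults)
  if (!is.list(overrides)) abort("overrides must be a named list")
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown override field(s): ", paste(unknown, collapse = ", ")))
  }
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]]) &&
        !is.data.frame(defaults[[nm]]) && !is.data.frame(overrides[[nm]])) {
      defaults[[nm]] <- apply_overrides(defaults[[nm]], overrides[[nm]])
    } else {
      defaults[nm] <- list(overrides[[nm]])  # keeps explicit NULLs
    }
  }
  defaults
}

#' @rdname phantom_builders
#' @export
build_nim_phantom <- function(overrides = NULL) {
  fields <- list(
    name = "nim_petct",
    body = default_body(),
    spheres = sphere_ring(c(4, 7, 10, 13, 17, 22, 28, 37)),
    lung = default_lung(),
    ct_module = default_ct_module(),
    background_activity = 6.6,
    hot_activity = 26.4
  )
  fields <- apply_overrides(fields, overrides)
  do.call(new_phantom_spec, fields)
}

#' @rdname phantom_builders
#' @export
build_nema_iec_phantom <- function(overrides = NULL) {
  fields <- list(
    name = "nema_iec",
    body = default_body(),
    spheres = sphere_ring(c(10, 13, 17, 22, 28, 37)),
    lung = default_lung(),
    ct_module = NULL,
    background_activity = 6.6,
    hot_activity = 26.4
  )
  fields <- apply_overrides(fields, overrides)
  do.call(new_phantom_spec, fields)
}

#' True sphere-to-background activity concentration ratio R
#' @param spec A `phantom_spec`.
#' @return The ratio `hot_activity / background_activity`.
#' @export
activity_ratio <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  spec$hot_activity / spec$background_activity
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec: %s>\n", x$name))
  cat(sprintf("  body: %.0f x %.0f mm rounded-rect, length %.0f mm\n",
              2 * x$body$half_width, 2 * x$body$half_height, x$body$length))
  if (nrow(x$spheres) > 0) {
    cat(sprintf("  spheres (mm): %s  [cold: %s]\n",
                paste(x$spheres$diameter, collapse = ", "),
                paste(x$spheres$diameter[x$spheres$role == "cold"],
                      collapse = ", ")))
  } else cat("  spheres: none\n")
  cat(if (is.null(x$lung)) "  lung insert: none\n" else
    sprintf("  lung insert: %.0f mm, density %.2f g/mL\n",
            x$lung$diameter, x$lung$density))
  cat(if (is.null(x$ct_module)) "  CT module: none\n" else
    sprintf("  CT module: %.0f x %.0f mm, inserts %s %%\n",
            x$ct_module$diameter, x$ct_module$thickness,
            paste(x$ct_module$inserts$contrast_pct, collapse = "/")))
  cat(sprintf("  activity: background %.1f, hot %.1f kBq/mL (R = %.1f)\n",
              x$background_activity, x$hot_activity, activity_ratio(x)))
  invisible(x)
}

#' Serialize a phantom specification to/from YAML
#'
#' The on-disk layout mirrors the `phantom_spec` fields with explicit units
#' in the key names. Two presets ship with the package
#' (`system.file("extdata", "presets", package = "petctiq")`).
#'
#' @param spec A `phantom_spec`.
#' @param path File path.
#' @return `write_phantom_yaml()` returns `path` invisibly;
#'   `read_phantom_yaml()` returns a validated `phantom_spec`.
#' @export
write_phantom_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  obj <- list(
    name = spec$name,
    units = list(length = "mm", activity = "kBq/mL"),
    body = spec$body,
    spheres = lapply(seq_len(nrow(spec$spheres)), function(i) {
      as.list(spec$spheres[i, ])
    }),
    lung = spec$lung,
    ct_module = if (!is.null(spec$ct_module)) {
      m <- spec$ct_module
      m$inserts <- lapply(seq_len(nrow(m$inserts)), function(i) {
        as.list(m$inserts[i, ])
      })
      m
    },
    background_activity = spec$background_activity,
    hot_activity = spec$hot_activity
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_phantom_yaml
#' @export
read_phantom_yaml <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  obj <- yaml::read_yaml(path)
  ct <- obj$ct_module
  if (!is.null(ct)) ct$inserts <- bind_rows(ct$inserts)
  new_phantom_spec(
    name = obj$name %||% "phantom",
    body = obj$body,
    spheres = bind_rows(obj$spheres),
    lung = obj$lung,
    ct_module = ct,
    background_activity = obj$background_activity,
    hot_activity = obj$hot_activity
  )
}
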