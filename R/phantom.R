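#' Material property set for a phantom region
#'
#' Bundles the three per-pixel physical properties of a sample region:
#' optical absorption coefficient, thermal diffusivity and volumetric heat
#' capacity, together with a region label.
#'
#' @param label Region tag, one of `"water"`, `"axon_bundle"`,
#'   `"surrounding_tissue"`, `"feature"`, `"background"`.
#' @param absorption Absorption coefficient (1/m), strictly positive.
#' @param diffusivity Thermal diffusivity alpha (m^2/s), strictly positive.
#' @param heat_capacity Volumetric heat capacity C_V (J m^-3 K^-1),
#'   strictly positive.
#' @param loss Optional first-order out-of-plane loss rate (1/s) for the
#'   region, standing in for heat escape normal to the imaging plane (finite
#'   water-layer thickness between the sample windows). `NULL` defers to the
#'   phantom-level scalar.
#' @return A `material_props` list.
#' @seealso [phantom_materials()] for the packaged defaults.
#' @export
material_props <- function(label, absorption, diffusivity, heat_capacity,
                           loss = NULL) {
  label <- match.arg(label, c("water", "axon_bundle", "surrounding_tissue",
                              "feature", "background"))
  check_scalar_pos(absorption, "absorption")
  check_scalar_pos(diffusivity, "diffusivity")
  check_scalar_pos(heat_capacity, "heat_capacity")
  if (!is.null(loss) && (!is.numeric(loss) || length(loss) != 1L || loss < 0))
    stop_bad("'loss' must be a single non-negative number or NULL")
  structure(list(label = label, absorption = absorption,
                 diffusivity = diffusivity, heat_capacity = heat_capacity,
                 loss = loss),
            class = "material_props")
}

#' Default material properties
#'
#' Water uses textbook constants (alpha = 1.4e-7 m^2/s, C_V = 4.18e6
#' J m^-3 K^-1) and an Amide-I-band absorption of 1e5 1/m (i.e. 1000 1/cm).
#' Axon-bundle tissue is protein-rich soft matter (alpha = 1.1e-7, C_V =
#' 3.6e6) absorbing about 2.2x more strongly than the water bath, matching
#' the observed amplitude ratio between bundle and saline. Surrounding
#' tissue shares the bundle's thermal constants at intermediate absorption.
#'
#' @return Named list of [material_props()] objects
#'   (`water`, `axon_bundle`, `surrounding_tissue`, `feature`).
#' @export
phantom_materials <- function() {
  list(
    water = material_props("water", 1.0e5, 1.4e-7, 4.18e6),
    axon_bundle = material_props("axon_bundle", 2.2e5, 1.1e-7, 3.6e6),
    surrounding_tissue = material_props("surrounding_tissue", 1.6e5, 1.1e-7, 3.6e6),
    feature = material_props("feature", 2.6e5, 1.0e-7, 3.4e6)
  )
}

#' Construct a thermal phantom
#'
#' A phantom is the simulated sample: aligned 2-D maps of absorption,
#' thermal diffusivity and volumetric heat capacity plus a region label per
#' pixel. Rows index y, columns index x; pixel (1,1) is the top-left corner
#' and pixel centres sit at `(i - 0.5) * pixel_size`.
#'
#' @param absorption_map,diffusivity_map,heat_capacity_map Numeric matrices
#'   of identical shape, strictly positive.
#' @param label_map Character matrix of region tags, same shape.
#' @param pixel_size Pixel pitch (m), default 200 nm.
#' @param out_of_plane_loss First-order loss rate (1/s) standing in for heat
#'   escape normal to the imaging plane; default 0 (purely in-plane
#'   diffusion). Either a single rate or a per-pixel matrix (regions with
#'   different out-of-plane geometry relax at different rates).
#' @return A `thermal_phantom` object.
#' @export
thermal_phantom <- function(absorption_map, diffusivity_map, heat_capacity_map,
                            label_map, pixel_size = 200e-9,
                            out_of_plane_loss = 0) {
  check_scalar_pos(pixel_size, "pixel_size")
  if (!is.numeric(out_of_plane_loss) || any(!is.finite(out_of_plane_loss)) ||
      any(out_of_plane_loss < 0) ||
      !(length(out_of_plane_loss) == 1L ||
        (is.matrix(out_of_plane_loss) &&
         identical(dim(out_of_plane_loss), dim(absorption_map)))))
    stop_bad("'out_of_plane_loss' must be a non-negative scalar or a matrix matching the maps")
  maps <- list(absorption_map = absorption_map, diffusivity_map = diffusivity_map,
               heat_capacity_map = heat_capacity_map)
  dims <- dim(absorption_map)
  for (nm in names(maps)) {
    m <- maps[[nm]]
    if (!is.matrix(m) || !is.numeric(m)) stop_bad(sprintf("'%s' must be a numeric matrix", nm))
    if (!identical(dim(m), dims)) stop_bad("all phantom maps must share one shape")
    if (any(!is.finite(m)) || any(m <= 0)) stop_bad(sprintf("'%s' must be strictly positive everywhere", nm))
  }
  if (!is.matrix(label_map) || !identical(dim(label_map), dims))
    stop_bad("'label_map' must be a matrix matching the physical maps")
  structure(list(absorption_map = absorption_map,
                 diffusivity_map = diffusivity_map,
                 heat_capacity_map = heat_capacity_map,
                 label_map = label_map,
                 pixel_size = pixel_size,
                 out_of_plane_loss = out_of_plane_loss),
            class = "thermal_phantom")
}

#' @export
print.thermal_phantom <- function(x, ...) {
  d <- dim(x$absorption_map)
  cat(sprintf("thermal_phantom: %d x %d pixels at %.0f nm (%.1f x %.1f um)\n",
              d[1], d[2], x$pixel_size * 1e9,
              d[2] * x$pixel_size * 1e6, d[1] * x$pixel_size * 1e6))
  tab <- table(x$label_map)
  cat("regions:", paste(sprintf("%s (%d px)", names(tab), as.integer(tab)), collapse = ", "), "\n")
  cat(sprintf("alpha range: %.3g - %.3g m^2/s; out-of-plane loss: %.3g - %.3g 1/s\n",
              min(x$diffusivity_map), max(x$diffusivity_map),
              min(x$out_of_plane_loss), max(x$out_of_plane_loss)))
  invisible(x)
}

#' Build a two-region interface phantom with optional disc features
#'
#' Creates a straight vertical absorber/water-style interface: pixels with
#' centre x-coordinate below `interface_position` take `side_a_props`, the
#' rest `side_b_props`. Optional disc features are stamped on top;
#' a pixel belongs to a disc when its centre lies within the disc radius.
#'
#' @param field_size Physical field extent `c(width, height)` in m
#'   (default 15 x 15 um).
#' @param pixel_size Pixel pitch (m), default 200 nm.
#' @param interface_position x-position of the interface (m).
#' @param side_a_props,side_b_props [material_props()] for the left (x <
#'   interface) and right sides.
#' @param features List of features, each
#'   `list(center = c(x, y) (m), radius (m), props = material_props)`.
#' @param out_of_plane_loss Passed to [thermal_phantom()].
#' @return A [thermal_phantom()] with labels from the side/feature props.
#' @examples
#' mats <- phantom_materials()
#' ph <- build_interface_phantom(side_a_props = mats$axon_bundle,
#'                               side_b_props = mats$water)
#' dim(ph$label_map)  # 75 x 75
#' @export
build_interface_phantom <- function(field_size = c(15e-6, 15e-6),
                                    pixel_size = 200e-9,
                                    interface_position = field_size[1] / 2,
                                    side_a_props, side_b_props,
                                    features = list(),
                                    out_of_plane_loss = 0) {
  check_scalar_pos(pixel_size, "pixel_size")
  nx <- round(field_size[1] / pixel_size)
  ny <- round(field_size[2] / pixel_size)
  if (nx < 32 || ny < 32)
    stop_bad("field must span at least 32 x 32 pixels at the configured pixel size")
  xc <- (seq_len(nx) - 0.5) * pixel_size
  yc <- (seq_len(ny) - 0.5) * pixel_size
  left <- matrix(xc < interface_position, ny, nx, byrow = TRUE)

  fill <- function(a, b) { m <- matrix(b, ny, nx); m[left] <- a; m }
  absorption <- fill(side_a_props$absorption, side_b_props$absorption)
  diffusivity <- fill(side_a_props$diffusivity, side_b_props$diffusivity)
  heat_capacity <- fill(side_a_props$heat_capacity, side_b_props$heat_capacity)
  labels <- matrix(side_b_props$label, ny, nx)
  labels[left] <- side_a_props$label
  any_loss <- !is.null(side_a_props$loss) || !is.null(side_b_props$loss) ||
    any(vapply(features, function(f) !is.null(f$props$loss), logical(1)))
  loss <- if (any_loss)
    fill(side_a_props$loss %||% out_of_plane_loss,
         side_b_props$loss %||% out_of_plane_loss)
  else out_of_plane_loss

  claimed <- matrix(FALSE, ny, nx)
  for (f in features) {
    r <- f$radius
    if (!is.numeric(r) || length(r) != 1L || r <= 0)
      stop_bad("feature radius must be a single positive number")
    ctr <- f$center
    if (ctr[1] - r < 0 || ctr[1] + r > field_size[1] ||
        ctr[2] - r < 0 || ctr[2] + r > field_size[2])
      stop_bad("feature lies outside the field")
    inside <- outer((yc - ctr[2])^2, (xc - ctr[1])^2, `+`) <= r^2
    if (any(inside & claimed))
      stop_bad(sprintf("feature at (%.2g, %.2g) m overlaps a previous feature", ctr[1], ctr[2]))
    claimed <- claimed | inside
    p <- f$props
    absorption[inside] <- p$absorption
    diffusivity[inside] <- p$diffusivity
    heat_capacity[inside] <- p$heat_capacity
    labels[inside] <- p$label
    if (is.matrix(loss)) loss[inside] <- p$loss %||% out_of_plane_loss
  }
  thermal_phantom(absorption, diffusivity, heat_capacity, labels,
                  pixel_size = pixel_size, out_of_plane_loss = loss)
}

#' Lumped-capacitance decay-time prediction for a feature
#'
#' Fourier's-law scaling of the characteristic thermal decay time of a small
#' absorber coupled to its environment: tau = C_V * V / (h * A), with C_V
#' the volumetric heat capacity, V the feature volume, h the heat transfer
#' coefficient to the surroundings and A the contact surface area. For a
#' sphere of radius r this reduces to C_V * r / (3 h): smaller features
#' (smaller volume-to-surface ratio) decay faster.
#'
#' @param c_v Volumetric heat capacity (J m^-3 K^-1).
#' @param volume Feature volume (m^3).
#' @param h Heat transfer coefficient (W m^-2 K^-1).
#' @param area Contact surface area (m^2).
#' @return Predicted decay time (s).
#' @examples
#' predict_feature_tau(4e6, volume = 4 / 3 * pi * (0.5e-6)^3,
#'                     h = 1e5, area = 4 * pi * (0.5e-6)^2)
#' @export
predict_feature_tau <- function(c_v, volume, h, area) {
  check_scalar_pos(c_v, "c_v"); check_scalar_pos(volume, "volume")
  check_scalar_pos(h, "h"); check_scalar_pos(area, "area")
  c_v * volume / (h * area)
}
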