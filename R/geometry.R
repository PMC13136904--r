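#' Hard-cylinder geometry of one G-quadruplex unit
#'
#' Each G4 unit is represented as an impenetrable solid cylinder.  The
#' defaults are the dimensions that best reproduce experimental SAXS
#' profiles of telomeric dimers: radius 1.26 nm and height 2.64 nm.
#'
#' @param radius Cylinder radius R_HC in nm (> 0).
#' @param height Cylinder height H in nm (> 0).
#' @return An object of class `"cylinder_geometry"`.
#' @examples
#' geom <- cylinder_geometry()
#' geom$radius
#' @export
cylinder_geometry <- function(radius = 1.26, height = 2.64) {
  if (!is_number(radius) || radius <= 0) stop("radius must be a positive number")
  if (!is_number(height) || height <= 0) stop("height must be a positive number")
  structure(list(radius = radius, height = height), class = "cylinder_geometry")
}

#' Interaction patches of the dimer model
#'
#' Two spherical patch types decorate each cylinder: a linker patch of radius
#' R0 on the rim of one base, whose centers interact through an infinite
#' square well of width 2*R0 (the hard constraint standing in for the TTA
#' linker), and a stacking patch of radius R1 at the center of each base,
#' whose centers interact through a finite square well of width 2*R1 and
#' depth u0.  All energies are expressed in units of u0.
#'
#' @param linker_radius Linker patch radius R0 in nm (default 0.53).
#' @param stacking_radius Stacking patch radius R1 in nm (default 0.265);
#'   must be smaller than `linker_radius`.
#' @return An object of class `"patch_spec"`.
#' @export
patch_spec <- function(linker_radius = 0.53, stacking_radius = 0.265) {
  if (!is_number(linker_radius) || linker_radius <= 0)
    stop("linker_radius must be positive")
  if (!is_number(stacking_radius) || stacking_radius <= 0)
    stop("stacking_radius must be positive")
  if (stacking_radius >= linker_radius)
    stop("stacking_radius must be smaller than linker_radius")
  structure(list(linker_radius = linker_radius, stacking_radius = stacking_radius),
            class = "patch_spec")
}

#' Position and orientation of one cylinder
#'
#' A pose holds the configurational degrees of freedom of one hard cylinder:
#' its center, its unit axis, and an azimuth fixing the rotation about the
#' axis.  The azimuth matters because the rim-mounted linker patch breaks
#' azimuthal symmetry; azimuth 0 points along the first vector of the
#' deterministic frame perpendicular to the axis (x-hat for a z-aligned
#' cylinder).
#'
#' @param center Numeric length-3 center (nm).
#' @param axis Numeric length-3 axis; normalized internally (must be nonzero).
#' @param azimuth Rotation about the axis in radians; wrapped into [0, 2*pi).
#' @return An object of class `"cylinder_pose"`.
#' @export
cylinder_pose <- function(center = c(0, 0, 0), axis = c(0, 0, 1), azimuth = 0) {
  if (length(center) != 3 || !all(is.finite(center))) stop("center must be a finite 3-vector")
  if (length(axis) != 3 || !all(is.finite(axis))) stop("axis must be a finite 3-vector")
  if (!is_number(azimuth)) stop("azimuth must be a number")
  structure(list(center = as.numeric(center), axis = unitize(as.numeric(axis)),
                 azimuth = azimuth %% (2 * pi)),
            class = "cylinder_pose")
}

#' Patch center positions for a posed cylinder
#'
#' Stacking patches sit at the centers of both bases, `center +/- (H/2)*axis`.
#' The linker patch sits on the rim of one designated base, at
#' `center + s*(H/2)*axis + R_HC * radial(azimuth)` where `s` is the
#' `linker_base` sign.  Which base carries the linker patch is a fixed
#' per-cylinder convention: in a [dimer_state()] cylinder A uses its +axis
#' base and cylinder B its -axis base, so that a single junction faces the
#' partner.
#'
#' @param pose A [cylinder_pose()].
#' @param geometry A [cylinder_geometry()].
#' @param patches A [patch_spec()] (patch radii are not needed for the
#'   positions, but the argument keeps call sites explicit about the model).
#' @param linker_base Which base carries the linker patch: -1 (default) or +1.
#' @return A list with `linker` (3-vector) and `stacking` (2 x 3 matrix,
#'   rows for the -axis and +axis base centers).
#' @examples
#' pc <- patch_centers(cylinder_pose(), cylinder_geometry())
#' pc$stacking   # (0, 0, -1.32) and (0, 0, 1.32)
#' pc$linker     # (1.26, 0, -1.32)
#' @export
patch_centers <- function(pose, geometry, patches = patch_spec(), linker_base = -1) {
  stopifnot(inherits(pose, "cylinder_pose"), inherits(geometry, "cylinder_geometry"))
  if (!linker_base %in% c(-1, 1)) stop("linker_base must be -1 or +1")
  h <- geometry$height / 2
  fr <- perp_frame(pose$axis)
  radial <- cos(pose$azimuth) * fr$e1 + sin(pose$azimuth) * fr$e2
  base_m <- pose$center - h * pose$axis
  base_p <- pose$center + h * pose$axis
  linker <- (if (linker_base < 0) base_m else base_p) + geometry$radius * radial
  list(linker = linker, stacking = rbind(minus = base_m, plus = base_p))
}

#' Do two hard cylinders intersect?
#'
#' Exact intersection test for two solid finite cylinders of common radius
#' and height, covering all contact cases (lateral-lateral, cap-lateral,
#' cap-cap, rim contacts).  Implemented as a GJK test on the convex bodies
#' using the cylinder support function; configurations touching exactly at
#' the boundary (zero-volume contact) are classified as non-overlapping.
#'
#' @param pose_a,pose_b [cylinder_pose()] objects.
#' @param geometry A [cylinder_geometry()]; degenerate (non-positive)
#'   dimensions are an error.
#' @return `TRUE` if the closed cylinders share interior volume.
#' @export
cylinders_overlap <- function(pose_a, pose_b, geometry) {
  stopifnot(inherits(pose_a, "cylinder_pose"), inherits(pose_b, "cylinder_pose"))
  if (!inherits(geometry, "cylinder_geometry"))
    stop("geometry must be a cylinder_geometry")
  cyl_overlap_cpp(pose_a$center, pose_a$axis, pose_b$center, pose_b$axis,
                  geometry$radius, geometry$height)
}

#' State of one dimer
#'
#' Bundles the poses of the two cylinders with the geometry and patch
#' parameters.  Cylinder A carries its linker patch on its +axis base and
#' cylinder B on its -axis base; the stacking interaction acts between the
#' facing base centers (A's +axis base, B's -axis base), reproducing a
#' single well-defined junction.
#'
#' @param pose_a,pose_b [cylinder_pose()] objects for cylinders A and B.
#' @param geometry A [cylinder_geometry()].
#' @param patches A [patch_spec()].
#' @return An object of class `"dimer_state"`.
#' @export
dimer_state <- function(pose_a, pose_b, geometry = cylinder_geometry(),
                        patches = patch_spec()) {
  stopifnot(inherits(pose_a, "cylinder_pose"), inherits(pose_b, "cylinder_pose"),
            inherits(geometry, "cylinder_geometry"), inherits(patches, "patch_spec"))
  structure(list(pose_a = pose_a, pose_b = pose_b, geometry = geometry,
                 patches = patches), class = "dimer_state")
}

# patch centers relevant to the junction of a dimer_state
junction_points <- function(d) {
  pa <- patch_centers(d$pose_a, d$geometry, d$patches, linker_base = +1)
  pb <- patch_centers(d$pose_b, d$geometry, d$patches, linker_base = -1)
  list(linker_a = pa$linker, linker_b = pb$linker,
       stack_a = pa$stacking["plus", ], stack_b = pb$stacking["minus", ])
}

#' Pair energy of a dimer in units of u0
#'
#' `+Inf` when the cylinders overlap or the linker patch centers are farther
#' apart than 2*R0 (the infinite square well is violated); `-1` when the
#' facing stacking patch centers are within 2*R1 of each other; `0`
#' otherwise.
#'
#' @param d A [dimer_state()].
#' @return A single number: `-1`, `0`, or `+Inf`.
#' @export
pair_energy <- function(d) {
  stopifnot(inherits(d, "dimer_state"))
  jp <- junction_points(d)
  if (vnorm(jp$linker_a - jp$linker_b) > 2 * d$patches$linker_radius) return(Inf)
  if (cylinders_overlap(d$pose_a, d$pose_b, d$geometry)) return(Inf)
  if (vnorm(jp$stack_a - jp$stack_b) <= 2 * d$patches$stacking_radius) -1 else 0
}

#' Is a dimer in the stacked conformation?
#'
#' A dimer is stacked when the facing stacking patch centers are within the
#' square well, i.e. their distance is at most 2*R1 (equivalently, when
#' [pair_energy()] is -1 for a feasible configuration).
#'
#' @param d A [dimer_state()].
#' @return `TRUE`/`FALSE`.
#' @export
is_stacked <- function(d) {
  stopifnot(inherits(d, "dimer_state"))
  jp <- junction_points(d)
  vnorm(jp$stack_a - jp$stack_b) <= 2 * d$patches$stacking_radius
}

# ---- conversions between pose objects and flat MC state rows ----
# row layout (18): cA(3) uA(3) wA(3) cB(3) uB(3) wB(3);
# w is the rim (linker) direction, i.e. radial(azimuth) in the world frame.

pose_to_half_row <- function(pose) {
  fr <- perp_frame(pose$axis)
  w <- cos(pose$azimuth) * fr$e1 + sin(pose$azimuth) * fr$e2
  c(pose$center, pose$axis, w)
}

half_row_to_pose <- function(r9) {
  axis <- unitize(r9[4:6])
  w <- r9[7:9]
  fr <- perp_frame(axis)
  cylinder_pose(center = r9[1:3], axis = axis,
                azimuth = atan2(sum(w * fr$e2), sum(w * fr$e1)))
}

dimer_to_row <- function(d) c(pose_to_half_row(d$pose_a), pose_to_half_row(d$pose_b))

row_to_dimer <- function(row, geometry, patches) {
  dimer_state(half_row_to_pose(row[1:9]), half_row_to_pose(row[10:18]),
              geometry, patches)
}
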