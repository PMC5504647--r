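# The sampler's state for docking: a rigid receptor plus a ligand carried
# as (conformer index, rotation, centre).  Ligand coordinates are derived,
# so rigid moves preserve intramolecular geometry exactly.

#' Construct a docking pose
#'
#' A pose holds the (rigid) receptor atom table, an ordered ligand
#' conformer library of local coordinates, and the ligand rigid-body
#' placement: current coordinates are
#' `conformers[[conformer]] %*% t(rotation) + center`.  Conformer local
#' coordinates should be centred on the origin so rotations pivot about
#' the ligand centroid.
#'
#' @param receptor receptor atom table ([atom_records()]); an `eps` column
#'   (attractive well-depth multiplier) defaults to 1.
#' @param conformers list of `n x 3` local coordinate matrices sharing
#'   atom identity and order.
#' @param elements length-`n` element symbols of the ligand atoms.
#' @param conformer index of the active conformer.
#' @param rotation 3x3 proper rotation matrix.
#' @param center ligand centroid position, Angstrom.
#' @param is_hydrogen optional logical flags (default `elements == "H"`).
#' @return an object of class `dock_pose`.
#' @export
new_pose <- function(receptor, conformers, elements,
                     conformer = 1L, rotation = diag(3),
                     center = c(0, 0, 0), is_hydrogen = NULL) {
  stopifnot(is.data.frame(receptor), is.list(conformers),
            length(conformers) >= 1L)
  n <- nrow(conformers[[1]])
  for (cf in conformers)
    stopifnot(is.matrix(cf), nrow(cf) == n, ncol(cf) == 3)
  stopifnot(length(elements) == n, conformer >= 1L,
            conformer <= length(conformers))
  if (is.null(receptor$eps)) receptor$eps <- 1
  if (is.null(is_hydrogen)) is_hydrogen <- elements == "H"
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be a proper rotation (det = +1)")
  rec_xyz <- .atom_xyz(receptor)
  rec_polar <- receptor$element %in% c("N", "O") & !receptor$is_hydrogen
  structure(list(
    receptor = receptor,
    rec_xyz = rec_xyz,
    rec_norm2 = rowSums(rec_xyz * rec_xyz),
    rec_eps = receptor$eps,
    rec_role = receptor$role,
    rec_polar = rec_polar,
    rec_polar_bb = rec_polar & receptor$role == "receptor-backbone",
    rec_polar_sc = rec_polar & receptor$role == "receptor-sidechain",
    lig_polar = elements %in% c("N", "O") & !(is_hydrogen),
    conformers = conformers,
    lig_elements = elements,
    lig_is_h = is_hydrogen,
    conformer = as.integer(conformer),
    rotation = rotation,
    center = as.numeric(center)), class = "dock_pose")
}

#' Current ligand coordinates of a pose
#' @param pose a [new_pose()].
#' @return an `n x 3` matrix in Angstrom.
#' @export
ligand_coords <- function(pose) {
  l <- pose$conformers[[pose$conformer]] %*% t(pose$rotation)
  l + matrix(pose$center, nrow(l), 3, byrow = TRUE)
}

#' Ligand atom table of a pose
#' @param pose a [new_pose()].
#' @return an [atom_records()] data frame with `role = "ligand"`.
#' @export
ligand_atoms <- function(pose) {
  xyz <- ligand_coords(pose)
  atom_records(xyz[, 1], xyz[, 2], xyz[, 3],
               element = pose$lig_elements, name = pose$lig_elements,
               role = "ligand", is_hydrogen = pose$lig_is_h)
}

#' Rigidly translate the ligand of a pose
#' @param pose a [new_pose()].
#' @param dxyz length-3 translation, Angstrom.
#' @return the translated pose (input unmodified).
#' @export
translate_pose <- function(pose, dxyz) {
  pose$center <- pose$center + as.numeric(dxyz)
  pose
}

#' @export
print.dock_pose <- function(x, ...) {
  cat(sprintf(
    "<dock_pose> receptor %d atoms | ligand %d atoms (%d conformers, active %d)\n",
    nrow(x$receptor), length(x$lig_elements), length(x$conformers),
    x$conformer))
  cat(sprintf("  center (%.2f, %.2f, %.2f) A\n",
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

# compact numeric snapshot (used internally when dumping archives)
.pose_snapshot <- function(pose) {
  c(pose$conformer, as.numeric(pose$rotation), pose$center)
}
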