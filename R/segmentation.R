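#' Extract the lower two-thirds of the face
#'
#' Three successive watertight cuts: keep the region below the Frankfort
#' plane, anterior of the bi-porion coronal plane, and above the mandibular
#' base plane. This is the domain over which the four facial slabs are
#' measured.
#'
#' @param mesh watertight head `vc_mesh`.
#' @param stack `vc_plane_stack` (validated; see [validate_plane_stack()]).
#' @return watertight `vc_mesh`.
#' @export
extract_lower_two_thirds <- function(mesh, stack) {
  stopifnot(inherits(stack, "vc_plane_stack"))
  m <- cut_mesh(mesh, stack$fh)$below
  if (!mesh_is_empty(m)) m <- cut_mesh(m, stack$coronal_porion)$above
  if (!mesh_is_empty(m)) m <- cut_mesh(m, stack$mandibular_base)$above
  if (mesh_is_empty(m)) {
    stop("extract_lower_two_thirds(): empty result; landmarks inconsistent with mesh")
  }
  m
}

#' Partition the lower two-thirds into the four facial slabs
#'
#' Cut tree: the palatal plane separates the malar slab from the rest; the
#' occlusal plane separates the maxillary slab; the mental-foramina plane
#' separates the mandibular slab (above) from the chin (below, down to the
#' mandibular base). Because every piece is produced by successive cuts of
#' one mesh the partition is exact by construction: slab volumes sum to the
#' lower-two-thirds volume to machine precision.
#'
#' @param lower watertight lower-two-thirds `vc_mesh`.
#' @param stack `vc_plane_stack`.
#' @param lm `vc_landmarks` used for the stack (for validation).
#' @param force skip plane-stack validation failures (default `FALSE`).
#' @return `vc_slabs`: list with watertight meshes `malar`, `maxillary`,
#'   `mandibular`, `chin`, plus `lower_two_thirds` and `flags` (names of
#'   empty slabs).
#' @export
partition_slabs <- function(lower, stack, lm = NULL, force = FALSE) {
  stopifnot(inherits(stack, "vc_plane_stack"))
  if (!is.null(lm) && !force) {
    diag <- validate_plane_stack(stack, lm)
    if (!all(diag$pass)) {
      bad <- diag$constraint[!diag$pass]
      stop("partition_slabs(): plane-stack validation failed: ",
           paste(bad, collapse = ", "),
           " (use force = TRUE to segment anyway)")
    }
  }
  c1 <- cut_mesh(lower, stack$palatal)
  malar <- c1$above
  c2 <- if (mesh_is_empty(c1$below)) {
    list(above = empty_mesh(), below = empty_mesh())
  } else cut_mesh(c1$below, stack$occlusal)
  maxillary <- c2$above
  c3 <- if (mesh_is_empty(c2$below)) {
    list(above = empty_mesh(), below = empty_mesh())
  } else cut_mesh(c2$below, stack$foramina)
  mandibular <- c3$above
  chin <- c3$below
  slabs <- list(malar = malar, maxillary = maxillary,
                mandibular = mandibular, chin = chin,
                lower_two_thirds = lower)
  empty <- names(which(vapply(slabs[1:4], mesh_is_empty, TRUE)))
  if (length(empty) > 0L) {
    warning("empty slab(s): ", paste(empty, collapse = ", "))
  }
  structure(c(slabs, list(flags = empty)), class = "vc_slabs")
}

#' Measure slab volumes
#'
#' @param slabs `vc_slabs` from [partition_slabs()].
#' @return `vc_profile`; see [volume_profile()].
#' @export
slab_volumes <- function(slabs) {
  stopifnot(inherits(slabs, "vc_slabs"))
  volume_profile(
    v_malar = mesh_volume(slabs$malar),
    v_maxillary = mesh_volume(slabs$maxillary),
    v_mandibular = mesh_volume(slabs$mandibular),
    v_chin = mesh_volume(slabs$chin)
  )
}

#' Export slabs as STL files
#'
#' Writes each slab next to `base_path` with suffixes `_malar`,
#' `_maxillary`, `_mandibular`, `_chin` (ASCII STL).
#'
#' @param slabs `vc_slabs`.
#' @param base_path path prefix; files get `<base>_<slab>.stl`.
#' @return invisibly, the written paths.
#' @export
write_slabs <- function(slabs, base_path) {
  stopifnot(inherits(slabs, "vc_slabs"))
  paths <- character(0)
  for (nm in c("malar", "maxillary", "mandibular", "chin")) {
    p <- paste0(base_path, "_", nm, ".stl")
    write_stl(slabs[[nm]], p, binary = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
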