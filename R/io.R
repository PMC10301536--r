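#' Read an STL surface mesh
#'
#' Reads binary or ASCII STL (dialect auto-detected), merges duplicate
#' vertices within `merge_tol` mm to restore connectivity (STL stores a
#' triangle soup), drops zero-area faces, repairs global orientation if the
#' signed volume is negative, and errors with boundary-edge diagnostics if
#' the result is not watertight. STL carries no units; coordinates are
#' taken to be mm by convention.
#'
#' @param path STL file path.
#' @param merge_tol vertex-merge tolerance in mm (default 1e-6).
#' @return watertight, outward-oriented `vc_mesh`.
#' @export
read_stl <- function(path, merge_tol = 1e-6) {
  if (!file.exists(path)) stop("read_stl(): no such file: ", path)
  con <- file(path, "rb")
  header <- readBin(con, "raw", 80L)
  n_tri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  size <- file.size(path)
  is_binary <- length(n_tri) == 1L && !is.na(n_tri) &&
    size == 84 + 50 * as.numeric(n_tri)
  close(con)
  tri <- if (is_binary) read_stl_binary(path, n_tri) else read_stl_ascii(path)
  if (nrow(tri) == 0L) stop("read_stl(): no facets in ", path)
  nv <- nrow(tri)
  soup <- trimesh(tri, matrix(seq_len(nv), ncol = 3L, byrow = TRUE))
  m <- mesh_merge_vertices(soup, tol = merge_tol)
  areas <- mesh_face_areas(m)
  if (any(areas <= 1e-12)) {
    m <- mesh_compact(trimesh(m$vertices, m$faces[areas > 1e-12, , drop = FALSE]))
  }
  be <- mesh_boundary_edges(m)
  if (nrow(be) > 0L) {
    stop(sprintf("read_stl(): mesh is not watertight: %d boundary edges (first at vertex pair %d-%d)",
                 nrow(be), be[1, 1L], be[1, 2L]))
  }
  mesh_repair_orientation(m)
}

read_stl_binary <- function(path, n_tri) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 84L)
  rec <- readBin(con, "raw", 50L * n_tri)
  # each record: 12 floats (normal + 3 vertices) + uint16 attribute
  idx <- rep(seq_len(n_tri) - 1L, each = 48L) * 50L + rep(seq_len(48L), n_tri)
  floats <- readBin(rec[idx], "numeric", n = 12L * n_tri, size = 4L,
                    endian = "little")
  m <- matrix(floats, ncol = 12L, byrow = TRUE)
  v <- m[, 4:12, drop = FALSE]  # skip the stored normal
  matrix(t(v), ncol = 3L, byrow = TRUE)
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vl) %% 3L != 0L) stop("read_stl(): malformed ASCII STL (vertex count not multiple of 3)")
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"), function(p) as.numeric(p[2:4]),
                   numeric(3)))
  nums
}

#' Write an STL surface mesh
#'
#' @param mesh `vc_mesh`.
#' @param path output path.
#' @param binary write binary STL (default) or ASCII.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  stopifnot(inherits(mesh, "vc_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  cc <- v[f[, 3L], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  nrm <- cbind(
    e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
    e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
    e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  )
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    dat <- cbind(nrm, a, b, cc)
    for (k in seq_len(nrow(f))) {
      writeBin(as.numeric(dat[k, ]), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    fmt <- function(x) sprintf("%.9g", x)
    lines <- character(7L * nrow(f) + 2L)
    lines[1L] <- "solid volcephalo"
    for (k in seq_len(nrow(f))) {
      o <- 1L + (k - 1L) * 7L
      lines[o + 1L] <- sprintf("  facet normal %s %s %s", fmt(nrm[k, 1]),
                               fmt(nrm[k, 2]), fmt(nrm[k, 3]))
      lines[o + 2L] <- "    outer loop"
      lines[o + 3L] <- sprintf("      vertex %s %s %s", fmt(a[k, 1]), fmt(a[k, 2]), fmt(a[k, 3]))
      lines[o + 4L] <- sprintf("      vertex %s %s %s", fmt(b[k, 1]), fmt(b[k, 2]), fmt(b[k, 3]))
      lines[o + 5L] <- sprintf("      vertex %s %s %s", fmt(cc[k, 1]), fmt(cc[k, 2]), fmt(cc[k, 3]))
      lines[o + 6L] <- "    endloop"
      lines[o + 7L] <- "  endfacet"
    }
    lines[length(lines)] <- "endsolid volcephalo"
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a landmark file (JSON or CSV)
#'
#' JSON: an object mapping landmark names to `[x, y, z]` arrays in mm.
#' CSV: columns `name`, `x`, `y`, `z`. Missing required names are reported
#' all at once; unknown names are preserved but ignored downstream.
#'
#' @param path file path (`.json` or `.csv`).
#' @return `vc_landmarks`.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("read_landmarks(): no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  pts <- if (ext == "json") {
    lapply(jsonlite::read_json(path), function(p) as.numeric(unlist(p)))
  } else if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("name", "x", "y", "z")
    if (!all(need %in% names(df))) {
      stop("read_landmarks(): CSV needs columns name,x,y,z")
    }
    stats::setNames(lapply(seq_len(nrow(df)),
                           function(i) c(df$x[i], df$y[i], df$z[i])), df$name)
  } else {
    stop("read_landmarks(): unsupported extension .", ext, " (use .json or .csv)")
  }
  landmark_set(pts)
}

#' Write a landmark set as JSON
#' @param lm `vc_landmarks`.
#' @param path output `.json` path.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "vc_landmarks"))
  jsonlite::write_json(lapply(unclass(lm), function(p) as.numeric(p)), path,
                       digits = NA)
  invisible(path)
}

#' Measurement run configuration
#'
#' @param decimals_share,decimals_ratio rounding for reported shares/ratios.
#' @param cutoff jury-score selection cutoff (default 8.5).
#' @param reference `"female"`, `"male"`, or `NA` for no comparison.
#' @param reference_variant passed to [normative_reference()].
#' @param force proceed on plane-stack validation failure.
#' @param voxel_mm voxel-oracle spacing for optional cross-checks.
#' @param seed integer seed recorded in outputs.
#' @export
run_config <- function(decimals_share = 1, decimals_ratio = 2, cutoff = 8.5,
                       reference = NA_character_,
                       reference_variant = "volume_consistent",
                       force = FALSE, voxel_mm = 1, seed = 1L) {
  stopifnot(cutoff >= 1)  # values above 10 are allowed and select nobody
  structure(list(
    decimals_share = decimals_share, decimals_ratio = decimals_ratio,
    cutoff = cutoff, reference = reference,
    reference_variant = reference_variant, force = isTRUE(force),
    voxel_mm = voxel_mm, seed = as.integer(seed)
  ), class = "vc_config")
}

config_hash <- function(config) {
  s <- paste(names(config), vapply(config, function(x) paste(format(x), collapse = ","), ""),
             sep = "=", collapse = ";")
  # small stable polynomial hash; avoids a digest dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Measure one subject end-to-end
#'
#' Full measurement run: read mesh and landmarks, build and validate the
#' plane stack, extract the lower two-thirds, partition into the four
#' slabs, and report volumes, shares, ratio, and (optionally) the
#' deviation from a normative reference. Written as JSON and CSV when
#' `out_prefix` is given.
#'
#' @param mesh_path STL path (or a `vc_mesh`).
#' @param landmarks_path landmark JSON/CSV path (or a `vc_landmarks`).
#' @param config `vc_config`.
#' @param out_prefix optional path prefix; writes `<prefix>.json` and
#'   `<prefix>.csv`.
#' @return report list (invisible when writing).
#' @export
run_measure <- function(mesh_path, landmarks_path, config = run_config(),
                        out_prefix = NULL) {
  mesh <- if (inherits(mesh_path, "vc_mesh")) mesh_path else read_stl(mesh_path)
  lm <- if (inherits(landmarks_path, "vc_landmarks")) landmarks_path else
    read_landmarks(landmarks_path)
  stack <- build_plane_stack(lm)
  diagnostics <- validate_plane_stack(stack, lm)
  if (!all(diagnostics$pass) && !config$force) {
    stop("run_measure(): plane-stack validation failed: ",
         paste(diagnostics$constraint[!diagnostics$pass], collapse = ", "))
  }
  lower <- extract_lower_two_thirds(mesh, stack)
  slabs <- partition_slabs(lower, stack, lm = lm, force = config$force)
  profile <- slab_volumes(slabs)
  report <- list(
    tool = "volcephalo",
    version = vc_version(),
    config_hash = config_hash(config),
    diagnostics = diagnostics,
    volumes_mm3 = c(malar = profile$v_malar, maxillary = profile$v_maxillary,
                    mandibular = profile$v_mandibular, chin = profile$v_chin,
                    total = profile$total),
    shares_pct = round_half_away(
      c(malar = profile$share_malar, maxillary = profile$share_maxillary,
        mandibular = profile$share_mandibular, chin = profile$share_chin),
      config$decimals_share),
    mm_ratio = round_half_away(profile$mm_ratio, config$decimals_ratio),
    empty_slabs = slabs$flags
  )
  if (!is.na(config$reference)) {
    ref <- normative_reference(config$reference, config$reference_variant)
    report$reference <- ref$source
    report$comparison <- compare_to_reference(profile, ref)
  }
  if (!is.null(out_prefix)) {
    jsonlite::write_json(report, paste0(out_prefix, ".json"), digits = NA,
                         auto_unbox = TRUE, dataframe = "rows")
    utils::write.csv(
      data.frame(region = names(report$volumes_mm3),
                 volume_mm3 = unname(report$volumes_mm3),
                 share_pct = c(unname(report$shares_pct), 100)),
      paste0(out_prefix, ".csv"), row.names = FALSE)
    return(invisible(report))
  }
  report
}

#' Run the cohort stage end-to-end
#'
#' Per-subject measurement from a manifest CSV (`subject_id`, `gender`,
#' `mesh_path`, `landmarks_path`), jury-score selection at the configured
#' cutoff, per-judge test-retest repeatability, per-gender/per-region
#' Shapiro-Wilk normality, gender-stratified summary, and deviation of each
#' gender's summary from the normative reference. Per-subject failures are
#' logged and excluded with a final count.
#'
#' @param manifest data.frame or CSV path.
#' @param scores `vc_scores`, data.frame, or CSV path.
#' @param config `vc_config`.
#' @param out_prefix optional path prefix for JSON + CSV output.
#' @return summary list.
#' @export
run_cohort <- function(manifest, scores, config = run_config(),
                       out_prefix = NULL) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (is.character(scores)) scores <- utils::read.csv(scores, stringsAsFactors = FALSE)
  scores <- jury_scores(scores)
  need <- c("subject_id", "gender", "mesh_path", "landmarks_path")
  if (!all(need %in% names(manifest))) {
    stop("run_cohort(): manifest needs columns ", paste(need, collapse = ", "))
  }
  rows <- list()
  failures <- character(0)
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[i]
    rep_i <- tryCatch(
      run_measure(manifest$mesh_path[i], manifest$landmarks_path[i], config),
      error = function(e) e
    )
    if (inherits(rep_i, "error")) {
      warning(sprintf("subject %s failed: %s", sid, conditionMessage(rep_i)))
      failures <- c(failures, sid)
      next
    }
    v <- rep_i$volumes_mm3
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = sid, gender = manifest$gender[i],
      v_malar = v[["malar"]], v_maxillary = v[["maxillary"]],
      v_mandibular = v[["mandibular"]], v_chin = v[["chin"]]
    )
  }
  cohort <- do.call(rbind, rows)
  if (is.null(cohort)) stop("run_cohort(): every subject failed")

  selected <- select_attractive(scores, cutoff = config$cutoff)
  if (length(selected) == 0L) {
    warning("run_cohort(): no subject reaches the cutoff ", config$cutoff)
  }
  repeatability <- if (any(scores$session == 2L)) judge_repeatability(scores) else NULL
  normality <- list()
  for (g in intersect(c("female", "male"), unique(cohort$gender))) {
    sub <- cohort[cohort$gender == g, ]
    if (nrow(sub) >= 3L) {
      normality[[g]] <- lapply(
        c(malar = "v_malar", maxillary = "v_maxillary",
          mandibular = "v_mandibular", chin = "v_chin"),
        function(col) normality_check(sub[[col]])
      )
    }
  }
  summary <- cohort_summary(cohort)
  deviations <- list()
  for (g in names(summary)) {
    ref <- normative_reference(g, config$reference_variant)
    prof <- volume_profile(summary[[g]]$mean_volumes[["malar"]],
                           summary[[g]]$mean_volumes[["maxillary"]],
                           summary[[g]]$mean_volumes[["mandibular"]],
                           summary[[g]]$mean_volumes[["chin"]])
    deviations[[g]] <- compare_to_reference(prof, ref)
  }
  out <- list(
    tool = "volcephalo",
    version = vc_version(),
    config_hash = config_hash(config),
    n_measured = nrow(cohort), n_failed = length(failures),
    failed_subjects = failures,
    per_subject = cohort,
    selected = selected,
    mean_scores = as.list(mean_scores(scores)),
    repeatability = repeatability,
    normality = normality,
    gender_summary = summary,
    reference_deviations = deviations
  )
  if (!is.null(out_prefix)) {
    jsonlite::write_json(out, paste0(out_prefix, ".json"), digits = NA,
                         auto_unbox = TRUE, dataframe = "rows")
    utils::write.csv(cohort, paste0(out_prefix, ".csv"), row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Write a simulated cohort to disk
#'
#' Per subject: ASCII STL + landmark JSON; plus a manifest CSV, a scores
#' CSV, and a provenance JSON recording the cohort spec and seed.
#'
#' @param cohort result of [generate_cohort()] (with meshes kept).
#' @param scores `vc_scores` for the same subjects.
#' @param dir output directory (created if needed).
#' @param cspec the `vc_cohortspec` used (recorded as provenance).
#' @return invisibly, the manifest data.frame.
#' @export
write_cohort <- function(cohort, scores, dir, cspec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- cohort$table
  mesh_paths <- character(nrow(tab))
  lm_paths <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    sid <- tab$subject_id[i]
    subj <- cohort$subjects[[sid]]
    if (is.null(subj$mesh)) stop("write_cohort(): meshes were not kept")
    mesh_paths[i] <- file.path(dir, paste0(sid, ".stl"))
    lm_paths[i] <- file.path(dir, paste0(sid, "_landmarks.json"))
    write_stl(subj$mesh, mesh_paths[i], binary = FALSE)
    write_landmarks(subj$landmarks, lm_paths[i])
  }
  manifest <- data.frame(subject_id = tab$subject_id, gender = tab$gender,
                         mesh_path = mesh_paths, landmarks_path = lm_paths)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(scores), file.path(dir, "scores.csv"),
                   row.names = FALSE)
  prov <- list(tool = "volcephalo",
               version = vc_version(),
               cohort_spec = if (!is.null(cspec)) unclass(cspec) else NULL)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

vc_version <- function() {
  tryCatch(as.character(utils::packageVersion("volcephalo")),
           error = function(e) "dev")
}
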