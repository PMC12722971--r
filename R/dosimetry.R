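# TG-43 style 1D point-source dose engine and DVH metrics.
#
# Voxel dose (Gy) = sum over dwells of
#   S_K * Lambda * (r0 / r)^2 * g(r) * phi_an * t / 3600 / 100
# with S_K the reference air-kerma rate (uGy m^2/h = U), Lambda the
# dose-rate constant (cGy / (h U)), r0 = 1 cm, g(r) the radial dose
# function (log-linear interpolation in r) and phi_an a constant anisotropy
# factor.  Distances below 0.5 mm are capped at the 0.5 mm value.

#' TG-43 point-source model
#'
#' @param g_table Data frame with columns `r_cm`, `g`, or a path to a TSV
#'   with those columns; default is the packaged generic HDR Ir-192-like
#'   curve (synthetic, for plan comparison).
#' @param Lambda Dose-rate constant, cGy h^-1 U^-1.
#' @param phi_an Constant anisotropy factor (dimensionless).
#' @param sk Source strength: reference air-kerma rate, uGy m^2/h (= U).
#' @return An object of class `"source_model"`.
#' @export
source_model <- function(g_table = NULL, Lambda = 1.109, phi_an = 0.98,
                         sk = 40820) {
  if (is.null(g_table))
    g_table <- system.file("extdata", "ir192_generic_gr.tsv",
                           package = "emtrecon")
  if (is.character(g_table))
    g_table <- utils::read.table(g_table, header = TRUE, sep = "\t",
                                 comment.char = "#")
  stopifnot(all(c("r_cm", "g") %in% names(g_table)))
  if (any(g_table$g <= 0)) stop("radial dose function must be positive")
  i1 <- which.min(abs(g_table$r_cm - 1))
  if (abs(g_table$g[i1] - 1) > 0.01)
    stop("g(r) not normalized at the 1 cm reference distance")
  gfun <- stats::approxfun(log(g_table$r_cm), g_table$g, rule = 2)
  structure(list(Lambda = Lambda, phi_an = phi_an, sk = sk,
                 g_table = g_table, g = function(r_cm) gfun(log(r_cm))),
            class = "source_model")
}

#' An empty dose grid
#'
#' Voxel \[1,1,1\] is centered at `origin`; spacing is isotropic.
#'
#' @param origin Center of the first voxel, mm.
#' @param spacing Isotropic voxel spacing, mm (> 0).
#' @param dims Integer vector (nx, ny, nz).
#' @param prescription_gy Prescription dose, Gy (required for V100).
#' @return An object of class `"dose_grid"`.
#' @export
dose_grid <- function(origin, spacing, dims, prescription_gy) {
  if (spacing <= 0) stop("grid spacing must be > 0")
  dims <- as.integer(dims)
  if (any(dims < 1)) stop("zero-extent dose grid")
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 values = array(0, dim = dims),
                 prescription_gy = prescription_gy),
            class = "dose_grid")
}

grid_axes <- function(grid) {
  lapply(1:3, function(a)
    grid$origin[a] + grid$spacing * (seq_len(grid$dims[a]) - 1))
}

#' Compute the dose grid for a set of dwells
#'
#' @param dwell_list List per channel of `list(positions = <n x 3 mm>,
#'   times = <n, s>)`; the output of [plan_dwells()] is accepted directly.
#' @param src A [source_model()].
#' @param grid A [dose_grid()] (its values are overwritten).
#' @return The grid with voxel doses in Gy.
#' @export
compute_dose <- function(dwell_list, src, grid) {
  stopifnot(inherits(src, "source_model"), inherits(grid, "dose_grid"))
  ax <- grid_axes(grid)
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  dose <- array(0, dim = grid$dims)
  # squared distances via separable per-axis tables
  for (ch in dwell_list) {
    pos <- if (!is.null(ch$dwells)) ch$dwells$positions else ch$positions
    times <- ch$times
    if (any(times < 0)) stop("negative dwell time")
    for (j in seq_len(nrow(pos))) {
      if (times[j] == 0) next
      dx2 <- (ax[[1]] - pos[j, 1])^2
      dy2 <- (ax[[2]] - pos[j, 2])^2
      dz2 <- (ax[[3]] - pos[j, 3])^2
      r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
      r_mm <- pmax(sqrt(r2), 0.5)
      r_cm <- r_mm / 10
      dose <- dose + array(
        src$sk * src$Lambda * src$g(r_cm) * src$phi_an /
          r_cm^2 * times[j] / 3600 / 100,
        dim = grid$dims)
    }
  }
  grid$values <- dose
  grid
}

#' Rasterize a planar-contour structure onto a dose grid
#'
#' Even-odd polygon fill per contour plane, voxel-center inclusion; each
#' contour plane claims the half-open z slab \[z - dz/2, z + dz/2) where dz
#' is the plane spacing of the structure (or the grid spacing for a single
#' plane).
#'
#' @param struct One structure entry of a [structure_set_model()].
#' @param grid A [dose_grid()].
#' @return A logical array over the grid.
#' @export
rasterize_structure <- function(struct, grid) {
  ax <- grid_axes(grid)
  mask <- array(FALSE, dim = grid$dims)
  zs <- vapply(struct$contours, `[[`, numeric(1), "z")
  dz <- if (length(zs) > 1) stats::median(diff(sort(zs))) else grid$spacing
  xy <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]]))
  for (ct in struct$contours) {
    kz <- which(ax[[3]] >= ct$z - dz / 2 & ax[[3]] < ct$z + dz / 2)
    if (!length(kz)) next
    inside <- matrix(mgcv::in.out(rbind(ct$xy, ct$xy[1, ]), xy),
                     nrow = grid$dims[1])
    for (k in kz) mask[, , k] <- mask[, , k] | inside
  }
  mask
}

#' DVH metrics of a structure on a dose grid
#'
#' `v100_pct` is the percentage of the structure volume receiving at least
#' the prescription dose.  `DXcm3` is the minimum dose of the hottest X cm^3
#' (voxel-volume weighted, linearly interpolated at the cut boundary).
#'
#' @param grid A computed [dose_grid()].
#' @param struct A structure entry (or a precomputed logical mask).
#' @param volumes_cm3 Hot-spot volumes to evaluate, cm^3.
#' @return A list of class `"dvh_metrics"`: `v100_pct`, `d_gy` (named
#'   vector, Gy), `volume_cm3` (structure volume), `n_voxels`.
#' @export
dvh_metrics <- function(grid, struct, volumes_cm3 = c(0.1, 1, 2)) {
  mask <- if (is.array(struct) && is.logical(struct)) struct
  else rasterize_structure(struct, grid)
  n <- sum(mask)
  if (n == 0) stop("structure rasterizes to zero voxels on this grid")
  doses <- sort(grid$values[mask], decreasing = TRUE)
  vox_cm3 <- (grid$spacing / 10)^3
  v100 <- 100 * mean(doses >= grid$prescription_gy)
  cumvol <- seq_along(doses) * vox_cm3
  dx <- vapply(volumes_cm3, function(v) {
    if (v <= cumvol[1]) return(doses[1])
    if (v >= cumvol[n]) return(doses[n])
    i <- findInterval(v, cumvol)
    w <- (v - cumvol[i]) / vox_cm3
    doses[i] * (1 - w) + doses[i + 1] * w
  }, numeric(1))
  names(dx) <- sprintf("D%gcm3", volumes_cm3)
  structure(list(v100_pct = v100, d_gy = dx, volume_cm3 = n * vox_cm3,
                 n_voxels = n),
            class = "dvh_metrics")
}

#' DVH metric differences between two plans
#'
#' Computes dose on a common grid for both plans and reports, per structure,
#' the deltas in the conventional units: V100 as percentage points of the
#' structure volume, and hot-spot D metrics as percent of the prescription
#' dose (A minus B).
#'
#' @param dwells_a,dwells_b Dwell lists (see [compute_dose()]).
#' @param structs A [structure_set_model()].
#' @param src A [source_model()].
#' @param grid A [dose_grid()] template.
#' @return A data frame with columns `structure`, `role`, `metric`,
#'   `value_a`, `value_b`, `delta`, `unit`.
#' @export
metric_difference <- function(dwells_a, dwells_b, structs, src, grid) {
  ga <- compute_dose(dwells_a, src, grid)
  gb <- compute_dose(dwells_b, src, grid)
  rows <- list()
  for (s in structs$structures) {
    mask <- rasterize_structure(s, grid)
    ma <- dvh_metrics(ga, mask)
    mb <- dvh_metrics(gb, mask)
    rows[[length(rows) + 1]] <- data.frame(
      structure = s$name, role = s$role, metric = "V100",
      value_a = ma$v100_pct, value_b = mb$v100_pct,
      delta = ma$v100_pct - mb$v100_pct, unit = "% of structure volume")
    for (m in names(ma$d_gy)) {
      rows[[length(rows) + 1]] <- data.frame(
        structure = s$name, role = s$role, metric = m,
        value_a = ma$d_gy[[m]], value_b = mb$d_gy[[m]],
        delta = 100 * (ma$d_gy[[m]] - mb$d_gy[[m]]) / grid$prescription_gy,
        unit = "% of prescription")
    }
  }
  do.call(rbind, rows)
}

#' @export
print.dvh_metrics <- function(x, ...) {
  cat(sprintf("DVH: V100 = %.1f%%, %s (volume %.1f cm3)\n", x$v100_pct,
              paste(sprintf("%s = %.2f Gy", names(x$d_gy), x$d_gy),
                    collapse = ", "), x$volume_cm3))
  invisible(x)
}
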