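# Tissue construction: fibrosis label grids, ACh patches, diffusion maps.

#' 2D atrial tissue model
#'
#' A square lattice of nodes, each a myocyte or a fibroblast, with an
#' acetylcholine concentration map, a patch registry holding the ground-truth
#' geometry, and the scalars needed to build the anisotropic heterogeneous
#' diffusion map. Node (i, j) sits at coordinates `x = (j-1)*dx`,
#' `y = (i-1)*dx` (cm), origin at the tissue corner; fibers run parallel to
#' the y axis.
#'
#' @param nx,ny Node counts (default 251 x 251, i.e. 5 x 5 cm at `dx` 0.02).
#' @param dx Space step (cm).
#' @param d_long Longitudinal (fiber-direction) diffusion coefficient
#'   (cm^2/ms): 0.003 for non-AF/PxAF, 0.002 for PsAF.
#' @param anisotropy_ratio Transverse-to-longitudinal conductivity ratio.
#' @param fibro_coupling_factor Diffusion reduction factor on lattice edges
#'   touching a fibroblast.
#' @param label Optional integer matrix (`ny` x `nx`; 0 myocyte,
#'   1 fibroblast), e.g. from [uniform_fibrosis()].
#' @param condition Label recording the substrate (`"nonAF"`, `"PxAF"`,
#'   `"PsAF"`); informational.
#' @return An object of class `achmap_tissue`.
#' @export
#' @examples
#' tis <- tissue_model(nx = 63, ny = 63, dx = 0.04)
#' dim(tis$label)
tissue_model <- function(nx = 251, ny = 251, dx = 0.02, d_long = 0.003,
                         anisotropy_ratio = 0.5, fibro_coupling_factor = 0.25,
                         label = NULL, condition = "nonAF") {
  if (dx <= 0 || d_long <= 0) stop("dx and d_long must be positive")
  if (is.null(label)) label <- matrix(0L, ny, nx)
  stopifnot(nrow(label) == ny, ncol(label) == nx,
            all(label %in% c(0L, 1L)))
  structure(list(nx = as.integer(nx), ny = as.integer(ny), dx = dx,
                 d_long = d_long, anisotropy_ratio = anisotropy_ratio,
                 fibro_coupling_factor = fibro_coupling_factor,
                 fiber_axis = "y", label = label,
                 ach = matrix(0, ny, nx),
                 registry = tibble::tibble(kind = character(), x = numeric(),
                                           y = numeric(), r = numeric(),
                                           dose = numeric()),
                 condition = condition),
            class = "achmap_tissue")
}

#' @export
print.achmap_tissue <- function(x, ...) {
  cat(sprintf(paste0("<achmap_tissue %d x %d nodes, dx %.3g cm (%.2f x %.2f cm), ",
                     "%s, %.1f%% fibroblasts, %d ACh patch(es)>\n"),
              x$nx, x$ny, x$dx, (x$nx - 1) * x$dx, (x$ny - 1) * x$dx,
              x$condition, 100 * mean(x$label), sum(x$registry$kind == "ACh")))
  invisible(x)
}

node_coords <- function(tissue) {
  list(x = (seq_len(tissue$nx) - 1) * tissue$dx,
       y = (seq_len(tissue$ny) - 1) * tissue$dx)
}

# distance-to-center test, inclusive boundary (<= r)
in_circle <- function(xg, yg, cx, cy, r) {
  outer(yg, xg, function(y, x) sqrt((x - cx)^2 + (y - cy)^2) <= r)
}

#' Uniform diffuse fibrosis labels
#'
#' Each node independently becomes a fibroblast with probability `density`.
#'
#' @param nx,ny Grid dimensions.
#' @param density Fibroblast probability in `[0, 1]`.
#' @param seed Optional RNG seed for reproducibility.
#' @return Integer matrix (`ny` x `nx`; 0 myocyte, 1 fibroblast).
#' @export
uniform_fibrosis <- function(nx, ny, density, seed = NULL) {
  if (!is.finite(density) || density < 0 || density > 1)
    stop("density must lie in [0, 1]")
  with_seed(seed, matrix(rbinom(nx * ny, 1L, density), ny, nx))
}

#' Non-uniform (patchy) diffuse fibrosis labels
#'
#' Diffuse fibrosis of the given density confined to the union of circular
#' patches; pure myocardium outside.
#'
#' @param nx,ny Grid dimensions; `dx` space step (cm).
#' @param patches Data frame / tibble with columns `x`, `y`, `r` (cm).
#' @param density Fibroblast probability inside the patches.
#' @param seed Optional RNG seed.
#' @return Integer matrix (`ny` x `nx`).
#' @export
patchy_fibrosis <- function(nx, ny, dx, patches, density, seed = NULL) {
  if (!is.finite(density) || density < 0 || density > 1)
    stop("density must lie in [0, 1]")
  if (is.null(patches) || nrow(patches) == 0)
    stop("at least one fibrotic patch is required")
  xg <- (seq_len(nx) - 1) * dx
  yg <- (seq_len(ny) - 1) * dx
  inside <- Reduce(`|`, lapply(seq_len(nrow(patches)), function(k)
    in_circle(xg, yg, patches$x[k], patches$y[k], patches$r[k])))
  lab <- matrix(0L, ny, nx)
  n_in <- sum(inside)
  lab[inside] <- with_seed(seed, rbinom(n_in, 1L, density))
  lab
}

#' Place circular acetylcholine-release patches
#'
#' Draws circle centers uniformly at random inside `region` (by default the
#' whole tissue inset by the largest radius so circles fit), rejecting
#' overlaps, and rasterizes the resulting dose map. The registry records the
#' true geometry for ground-truth labeling.
#'
#' @param tissue [tissue_model()].
#' @param radii Circle radii (cm), e.g. `c(0.5)` or mixed `c(0.5, 0.24)`.
#' @param n_per_radius Circle count per radius (recycled against `radii`).
#' @param dose ACh concentration inside the circles (micromolar).
#' @param region Optional `c(xmin, xmax, ymin, ymax)` (cm) constraining the
#'   circle centers, e.g. the electrode-mapped area.
#' @param min_separation Minimal gap between circle rims (cm).
#' @param seed Optional RNG seed.
#' @param max_tries Placement attempts per circle before giving up.
#' @return The tissue with `ach` map and `registry` filled in.
#' @export
place_ach_patches <- function(tissue, radii, n_per_radius = 1, dose = 0.1,
                              region = NULL, min_separation = 0,
                              seed = NULL, max_tries = 200) {
  stopifnot(inherits(tissue, "achmap_tissue"))
  if (any(radii <= 0)) stop("radii must be positive")
  n_per_radius <- rep(n_per_radius, length.out = length(radii))
  lx <- (tissue$nx - 1) * tissue$dx
  ly <- (tissue$ny - 1) * tissue$dx
  if (any(2 * radii > c(lx, ly))) stop("patch does not fit in the domain")
  todo <- rep(radii, n_per_radius)
  todo <- sort(todo, decreasing = TRUE)  # large circles first eases packing
  one_layout <- function() {
    acc <- list()
    for (r in todo) {
      lo_x <- max(r, if (is.null(region)) r else region[1])
      hi_x <- min(lx - r, if (is.null(region)) lx - r else region[2])
      lo_y <- max(r, if (is.null(region)) r else region[3])
      hi_y <- min(ly - r, if (is.null(region)) ly - r else region[4])
      if (lo_x > hi_x || lo_y > hi_y) stop("patch does not fit in the domain")
      ok <- FALSE
      for (k in seq_len(max_tries)) {
        cx <- runif(1, lo_x, hi_x)
        cy <- runif(1, lo_y, hi_y)
        clear <- all(vapply(acc, function(p)
          sqrt((p$x - cx)^2 + (p$y - cy)^2) > p$r + r + min_separation,
          logical(1)))
        if (clear) { acc[[length(acc) + 1]] <- list(x = cx, y = cy, r = r); ok <- TRUE; break }
      }
      if (!ok) return(NULL)   # dead-end layout, restart from scratch
    }
    acc
  }
  placed <- with_seed(seed, {
    acc <- NULL
    for (rep in 1:100) {
      acc <- one_layout()
      if (!is.null(acc)) break
    }
    if (is.null(acc)) stop("could not place ACh patches without overlap; ",
                           "reduce count/radii or min_separation")
    acc
  })
  reg <- tibble::tibble(kind = "ACh",
                        x = vapply(placed, `[[`, numeric(1), "x"),
                        y = vapply(placed, `[[`, numeric(1), "y"),
                        r = vapply(placed, `[[`, numeric(1), "r"),
                        dose = dose)
  tissue$registry <- dplyr::bind_rows(tissue$registry, reg)
  tissue$ach <- rasterize_ach(tissue)
  tissue
}

#' Rasterize the ACh patch registry into a dose map
#'
#' @param tissue [tissue_model()] with a filled registry.
#' @return Matrix (`ny` x `nx`) of ACh doses (micromolar).
#' @export
rasterize_ach <- function(tissue) {
  g <- node_coords(tissue)
  ach <- matrix(0, tissue$ny, tissue$nx)
  reg <- tissue$registry[tissue$registry$kind == "ACh", , drop = FALSE]
  for (k in seq_len(nrow(reg)))
    ach[in_circle(g$x, g$y, reg$x[k], reg$y[k], reg$r[k])] <- reg$dose[k]
  ach
}

#' Register fibrotic patch geometry (for ground truth)
#'
#' Adds fibrosis circles to the registry and replaces the label grid with
#' diffuse fibrosis confined to them.
#'
#' @param tissue [tissue_model()].
#' @param patches Tibble with `x`, `y`, `r` (cm).
#' @param density Fibroblast probability inside the patches.
#' @param seed Optional RNG seed.
#' @return Updated tissue.
#' @export
add_fibrotic_patches <- function(tissue, patches, density, seed = NULL) {
  stopifnot(inherits(tissue, "achmap_tissue"))
  tissue$label <- patchy_fibrosis(tissue$nx, tissue$ny, tissue$dx,
                                  patches, density, seed)
  tissue$registry <- dplyr::bind_rows(
    tissue$registry,
    tibble::tibble(kind = "fibrosis", x = patches$x, y = patches$y,
                   r = patches$r, dose = density))
  tissue
}

#' Preset non-uniform fibrosis patch layouts
#'
#' Two named circular-patch layouts for non-uniform diffuse fibrosis,
#' expressed in fractional tissue coordinates so they scale with domain size:
#' `Fnu1` has two large patches, `Fnu2` four smaller ones.
#'
#' @param tissue [tissue_model()] (used for its physical size).
#' @param layout `"Fnu1"` or `"Fnu2"`.
#' @return Tibble with `x`, `y`, `r` in cm.
#' @export
fnu_preset <- function(tissue, layout = c("Fnu1", "Fnu2")) {
  layout <- match.arg(layout)
  lx <- (tissue$nx - 1) * tissue$dx
  frac <- switch(layout,
    Fnu1 = tibble::tibble(x = c(0.32, 0.68), y = c(0.36, 0.68),
                          r = c(0.24, 0.21)),
    Fnu2 = tibble::tibble(x = c(0.28, 0.70, 0.34, 0.72),
                          y = c(0.30, 0.38, 0.72, 0.74),
                          r = c(0.15, 0.13, 0.14, 0.15)))
  tibble::tibble(x = frac$x * lx, y = frac$y * lx, r = frac$r * lx)
}

#' Edge-wise anisotropic heterogeneous diffusion map
#'
#' Each lattice edge carries `d_long` if parallel to the fiber axis (y) or
#' `anisotropy_ratio * d_long` if perpendicular, multiplied by
#' `fibro_coupling_factor` when either endpoint is a fibroblast (the 4-fold
#' coupling reduction at myocyte-fibroblast and fibroblast-fibroblast
#' contacts).
#'
#' @param tissue [tissue_model()].
#' @return List with matrices `Dx` (`ny` x `nx-1`, edges along x) and `Dy`
#'   (`ny-1` x `nx`, edges along y), cm^2/ms.
#' @export
build_diffusion <- function(tissue) {
  stopifnot(inherits(tissue, "achmap_tissue"))
  lab <- tissue$label
  d_t <- tissue$anisotropy_ratio * tissue$d_long   # transverse (x edges)
  d_l <- tissue$d_long                             # longitudinal (y edges)
  fib <- lab == 1L
  nx <- tissue$nx; ny <- tissue$ny
  Dx <- matrix(d_t, ny, nx - 1)
  red_x <- fib[, -nx, drop = FALSE] | fib[, -1, drop = FALSE]
  Dx[red_x] <- d_t * tissue$fibro_coupling_factor
  Dy <- matrix(d_l, ny - 1, nx)
  red_y <- fib[-ny, , drop = FALSE] | fib[-1, , drop = FALSE]
  Dy[red_y] <- d_l * tissue$fibro_coupling_factor
  list(Dx = Dx, Dy = Dy)
}

#' Write / read a tissue model as plain text
#'
#' The label and ACh maps go to CSV, scalars and the patch registry to JSON.
#'
#' @param tissue [tissue_model()].
#' @param path Directory to write into (created if needed).
#' @return `write_tissue` returns `path` invisibly; `read_tissue` the tissue.
#' @export
write_tissue <- function(tissue, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write.csv(tissue$label, file.path(path, "label.csv"), row.names = FALSE)
  write.csv(tissue$ach, file.path(path, "ach.csv"), row.names = FALSE)
  meta <- tissue[c("nx", "ny", "dx", "d_long", "anisotropy_ratio",
                   "fibro_coupling_factor", "fiber_axis", "condition")]
  meta$registry <- tissue$registry
  jsonlite::write_json(meta, file.path(path, "tissue.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tissue
#' @export
read_tissue <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "tissue.json"),
                              simplifyVector = TRUE)
  lab <- as.matrix(read.csv(file.path(path, "label.csv")))
  dimnames(lab) <- NULL
  tis <- tissue_model(nx = meta$nx, ny = meta$ny, dx = meta$dx,
                      d_long = meta$d_long,
                      anisotropy_ratio = meta$anisotropy_ratio,
                      fibro_coupling_factor = meta$fibro_coupling_factor,
                      label = matrix(as.integer(lab), meta$ny, meta$nx),
                      condition = meta$condition)
  tis$registry <- tibble::as_tibble(meta$registry)
  ach <- as.matrix(read.csv(file.path(path, "ach.csv")))
  dimnames(ach) <- NULL
  tis$ach <- ach
  tis
}
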