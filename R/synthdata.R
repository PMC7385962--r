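#' Specification of a synthetic mIHC patch
#'
#' The generator emulates a high-density tumor region of a brightfield mIHC
#' section: near-circular lymphocytes (CD3/CD4/CD8/CD20), irregular
#' elliptical CD16 myeloid cells, and K17 tumor nests built from merged
#' irregular blobs with hematoxylin nuclei "holes" (the nuclear-exclusion
#' failure mode of colour-based segmentation). All randomness is fixed by
#' `seed`.
#'
#' @param height,width patch size in pixels (defaults 256 x 256).
#' @param pixel_size microns per pixel (default 0.175, the 40x scan
#'   resolution the panel was designed for).
#' @param n_cells named integer vector of cell counts per class
#'   (`CD3`, `CD4`, `CD8`, `CD20`, `CD16`); the default profile is
#'   imbalanced (myeloid-rich, B-cell-poor) as in PDAC tissue.
#' @param n_nests number of K17 tumor nests.
#' @param cell_radius_um named list of radius ranges (microns) per class.
#' @param nest_radius_um radius range (microns) of individual nest blobs.
#' @param nest_blobs range of blob counts merged into one nest.
#' @param nucleus_fraction fraction of a cell's area occupied by its
#'   hematoxylin-stained nucleus (default 0.35).
#' @param n_stroma_nuclei count of hematoxylin-only stromal nuclei placed on
#'   background (label 0).
#' @param conc_range stain concentration range per cell.
#' @param hema_conc_range hematoxylin concentration range in nuclei.
#' @param bg_conc constant background-channel concentration (grey cast).
#' @param hole_stain_factor residual K17 concentration inside nuclear holes.
#' @param noise_sd additive intensity noise of the renderer.
#' @param overlap_frac probability that a cell placement is allowed to
#'   partially overlap cells of other classes (capped at 25% of its area).
#' @param max_tries placement retry budget per object.
#' @param seed integer RNG seed.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(height = 256L, width = 256L, pixel_size = 0.175,
                       n_cells = c(CD3 = 2L, CD4 = 2L, CD8 = 1L, CD20 = 1L,
                                   CD16 = 2L),
                       n_nests = 1L,
                       cell_radius_um = list(CD3 = c(3.5, 5.25),
                                             CD4 = c(3.5, 5.25),
                                             CD8 = c(3.5, 5.25),
                                             CD20 = c(3.5, 5.25),
                                             CD16 = c(4, 6.5)),
                       nest_radius_um = c(4, 8), nest_blobs = c(2L, 4L),
                       nucleus_fraction = 0.35, n_stroma_nuclei = 3L,
                       conc_range = c(0.6, 1.2),
                       hema_conc_range = c(0.5, 0.9), bg_conc = 0.12,
                       hole_stain_factor = 0.15, noise_sd = 0.01,
                       overlap_frac = 0.05, max_tries = 400L, seed = 1L) {
  stopifnot(height > 0, width > 0, pixel_size > 0, all(n_cells >= 0),
            n_nests >= 0, nucleus_fraction >= 0, nucleus_fraction < 1,
            all(unlist(cell_radius_um) > 0), all(nest_radius_um > 0),
            noise_sd >= 0, overlap_frac >= 0, overlap_frac <= 1)
  structure(as.list(environment()), class = "synth_spec")
}

# irregular (optionally wobbled, elliptical, rotated) shape mask; returns
# linear pixel indices into an H x W matrix, or integer(0) if out of bounds
.shape_indices <- function(H, W, cx, cy, r, axis_ratio = 1, angle = 0,
                           wobble = 0) {
  ext <- ceiling(r / min(axis_ratio, 1) * (1 + wobble)) + 1L
  rs <- max(1L, floor(cy - ext)):min(H, ceiling(cy + ext))
  cs <- max(1L, floor(cx - ext)):min(W, ceiling(cx + ext))
  dy <- rep(rs - cy, times = length(cs))
  dx <- rep(cs - cx, each = length(rs))
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  rad2 <- u^2 + (v / axis_ratio)^2
  rr <- r
  if (wobble > 0) {
    th <- atan2(v, u)
    k1 <- 3; k2 <- 5
    ph <- stats::runif(2, 0, 2 * pi)
    rr <- r * (1 + wobble * sin(k1 * th + ph[1]) +
                 0.5 * wobble * sin(k2 * th + ph[2]))
  }
  keep <- rad2 <= rr^2
  ridx <- rep(rs, times = length(cs))[keep]
  cidx <- rep(cs, each = length(rs))[keep]
  ridx + (cidx - 1L) * H
}

.dilate_indices <- function(idx, H, W) {
  r <- (idx - 1L) %% H + 1L
  c <- (idx - 1L) %/% H + 1L
  out <- integer(0)
  for (dr in -1:1) {
    for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
      out <- c(out, rr[ok] + (cc[ok] - 1L) * H)
    }
  }
  unique(out)
}

.is_connected <- function(idx, H, W) {
  if (length(idx) <= 1L) return(TRUE)
  m <- matrix(FALSE, H, W)
  m[idx] <- TRUE
  max(.label_mask_cpp(m, 8L)) == 1L
}

#' Generate one synthetic patch with full ground truth
#'
#' @param spec a [synth_spec()].
#' @param palette a [stain_palette()] with the 8 standard channels
#'   (default [generate_palette()] on the spec's seed).
#' @return a list with elements `image` (H x W x 3 RGB array) and `truth`, a
#'   list with `label_map` (integer matrix, 0 = background, 1..6 = classes),
#'   `masks` (named list of per-class logical matrices), `seeds` (data.frame
#'   `x`, `y`, `class`; 0-based pixel coordinates of one centroid per cell),
#'   and `conc` (H x W x 8 true concentration array in palette order).
#' @export
generate_patch <- function(spec, palette = generate_palette(spec$seed)) {
  stopifnot(inherits(spec, "synth_spec"))
  validate_palette(palette)
  set.seed(spec$seed)
  H <- spec$height; W <- spec$width; ps <- spec$pixel_size
  classes <- mihc_class_names()
  owner <- matrix(0L, H, W)       # cell id owning each pixel (visible label)
  class_occ <- matrix(0L, H, W)   # class of owner, for same-class adjacency
  cells <- list()                 # id -> list(class, shape_idx, vis_idx, ...)
  nid <- 0L

  try_place <- function(class_id, r_px, axis_ratio, angle, wobble,
                        center_pool = NULL, ally_ids = integer(0)) {
    for (attempt in seq_len(spec$max_tries)) {
      # objects may clip the patch border (as cells do in real tissue); the
      # margin only keeps most of the shape in view
      margin <- max(2, 0.25 * r_px * (1 + wobble) / min(axis_ratio, 1))
      if (2 * margin + 2 >= min(H, W)) {
        stop("placement error: object radius exceeds patch size",
             call. = FALSE)
      }
      if (is.null(center_pool)) {
        cx <- stats::runif(1, margin + 1, W - margin)
        cy <- stats::runif(1, margin + 1, H - margin)
      } else {
        cx <- min(max(center_pool[1] + stats::rnorm(1, 0, r_px * 0.9),
                      margin + 1), W - margin)
        cy <- min(max(center_pool[2] + stats::rnorm(1, 0, r_px * 0.9),
                      margin + 1), H - margin)
      }
      idx <- .shape_indices(H, W, cx, cy, r_px, axis_ratio, angle, wobble)
      if (length(idx) < 4L) next
      # same-class components must stay separated (8-connectivity), except
      # among allied blobs of one nest, which are meant to merge
      dil <- .dilate_indices(idx, H, W)
      if (any(class_occ[dil] == class_id & !(owner[dil] %in% ally_ids))) next
      ov <- owner[idx] != 0L & !(owner[idx] %in% ally_ids)
      ov_ally <- owner[idx] %in% setdiff(ally_ids, 0L)
      affected <- integer(0)
      if (any(ov)) {
        if (stats::runif(1) > spec$overlap_frac || mean(ov) > 0.25) next
        affected <- unique(owner[idx][ov])
        ok <- TRUE
        for (j in affected) {
          vis <- setdiff(cells[[j]]$vis_idx, idx)
          if (length(vis) < 0.5 * length(cells[[j]]$shape_idx) ||
              !.is_connected(vis, H, W)) { ok <- FALSE; break }
        }
        if (!ok) next
      }
      nid <<- nid + 1L
      for (j in c(affected, unique(owner[idx][ov_ally]))) {
        cells[[j]]$vis_idx <<- setdiff(cells[[j]]$vis_idx, idx)
      }
      owner[idx] <<- nid
      class_occ[idx] <<- class_id
      cells[[nid]] <<- list(class = class_id, shape_idx = idx, vis_idx = idx,
                            cx = cx, cy = cy, r = r_px)
      return(nid)
    }
    stop("placement error: could not place object after ", spec$max_tries,
         " attempts", call. = FALSE)
  }

  # tumor nests first (largest structures), as merged K17 blobs
  nest_ids <- integer(0)
  for (i in seq_len(spec$n_nests)) {
    nb <- sample(spec$nest_blobs[1]:spec$nest_blobs[2], 1)
    anchor <- NULL
    this_nest <- integer(0)
    for (b in seq_len(nb)) {
      r_px <- stats::runif(1, spec$nest_radius_um[1],
                           spec$nest_radius_um[2]) / ps
      id <- try_place(6L, r_px, stats::runif(1, 0.6, 0.95),
                      stats::runif(1, 0, pi), 0.2, center_pool = anchor,
                      ally_ids = this_nest)
      if (is.null(anchor)) anchor <- c(cells[[id]]$cx, cells[[id]]$cy)
      this_nest <- c(this_nest, id)
    }
    nest_ids <- c(nest_ids, this_nest)
  }

  # immune cells
  for (k in seq_along(classes[1:5])) {
    cls <- classes[k]
    n_k <- if (cls %in% names(spec$n_cells)) spec$n_cells[[cls]] else 0L
    rng <- spec$cell_radius_um[[cls]]
    for (i in seq_len(n_k)) {
      r_px <- stats::runif(1, rng[1], rng[2]) / ps
      if (k <= 4L) {
        try_place(k, r_px, stats::runif(1, 0.88, 1), stats::runif(1, 0, pi),
                  0)
      } else {
        try_place(5L, r_px, stats::runif(1, 0.55, 0.9),
                  stats::runif(1, 0, pi), 0.18)
      }
    }
  }

  # concentration truth
  conc <- array(0, dim = c(H, W, 8))
  conc[, , 8] <- spec$bg_conc
  hema <- matrix(0, H, W)
  stain <- array(0, dim = c(H, W, 6))
  for (cell in cells) {
    cc <- stats::runif(1, spec$conc_range[1], spec$conc_range[2])
    sl <- matrix(stain[, , cell$class], H, W)
    sl[cell$shape_idx] <- sl[cell$shape_idx] + cc
    stain[, , cell$class] <- sl
    if (cell$class != 6L && spec$nucleus_fraction > 0) {
      nuc <- .shape_indices(H, W, cell$cx, cell$cy,
                            cell$r * sqrt(spec$nucleus_fraction))
      hema[nuc] <- hema[nuc] + stats::runif(1, spec$hema_conc_range[1],
                                            spec$hema_conc_range[2])
    }
  }
  # nuclear holes inside tumor nests: hematoxylin replaces most of the K17
  for (id in nest_ids) {
    cell <- cells[[id]]
    n_holes <- max(1L, round(spec$nucleus_fraction * length(cell$shape_idx) /
                               max(1, pi * (1.8 / ps)^2) / 2))
    for (hh in seq_len(n_holes)) {
      pick <- cell$shape_idx[sample.int(length(cell$shape_idx), 1)]
      hx <- (pick - 1L) %/% H + 1L
      hy <- (pick - 1L) %% H + 1L
      hole <- .shape_indices(H, W, hx, hy, stats::runif(1, 1.4, 2.2) / ps)
      hole <- intersect(hole, cell$shape_idx)
      sl <- matrix(stain[, , 6], H, W)
      sl[hole] <- sl[hole] * spec$hole_stain_factor
      stain[, , 6] <- sl
      hema[hole] <- hema[hole] + stats::runif(1, spec$hema_conc_range[1],
                                              spec$hema_conc_range[2])
    }
  }
  # stromal nuclei on background
  for (i in seq_len(spec$n_stroma_nuclei)) {
    for (attempt in seq_len(spec$max_tries)) {
      r_px <- stats::runif(1, 1.4, 2.2) / ps
      cx <- stats::runif(1, r_px + 2, W - r_px - 1)
      cy <- stats::runif(1, r_px + 2, H - r_px - 1)
      idx <- .shape_indices(H, W, cx, cy, r_px)
      if (all(owner[idx] == 0L)) {
        hema[idx] <- hema[idx] + stats::runif(1, spec$hema_conc_range[1],
                                              spec$hema_conc_range[2])
        break
      }
    }
  }
  conc[, , 1:6] <- stain
  conc[, , 7] <- hema

  img <- render_beer_lambert(conc, palette, noise_sd = spec$noise_sd)

  # label map and masks from visible ownership
  label_map <- matrix(0L, H, W)
  seeds <- list()
  for (id in seq_along(cells)) {
    cell <- cells[[id]]
    vis <- cell$vis_idx
    if (length(vis) == 0L) next
    label_map[vis] <- cell$class
    r <- (vis - 1L) %% H + 1L
    c <- (vis - 1L) %/% H + 1L
    cr <- mean(r); ccol <- mean(c)
    sel <- which.min((r - cr)^2 + (c - ccol)^2)  # centroid, snapped inside
    seeds[[length(seeds) + 1L]] <-
      data.frame(x = c[sel] - 1L, y = r[sel] - 1L, class = cell$class,
                 cell_id = id)
  }
  seeds <- if (length(seeds)) do.call(rbind, seeds) else
    data.frame(x = integer(0), y = integer(0), class = integer(0),
               cell_id = integer(0))
  # one seed per connected component of a nest (blobs may merge): collapse
  # seeds of merged same-class components to the component centroid
  seeds <- .dedupe_seeds(seeds, label_map)
  masks <- lapply(1:6, function(k) label_map == k)
  names(masks) <- classes
  list(image = img,
       truth = list(label_map = label_map, masks = masks,
                    seeds = seeds[, c("x", "y", "class")], conc = conc))
}

# merged same-class components (e.g. nest blobs) must carry exactly one seed
.dedupe_seeds <- function(seeds, label_map) {
  if (nrow(seeds) == 0L) return(seeds)
  H <- nrow(label_map)
  out <- list()
  for (k in sort(unique(seeds$class))) {
    lab <- .label_mask_cpp(label_map == k, 8L)
    sk <- seeds[seeds$class == k, , drop = FALSE]
    comp <- lab[cbind(sk$y + 1L, sk$x + 1L)]
    for (cp in unique(comp)) {
      grp <- sk[comp == cp, , drop = FALSE]
      if (nrow(grp) == 1L) { out[[length(out) + 1L]] <- grp; next }
      idx <- which(lab == cp)
      r <- (idx - 1L) %% H + 1L
      c <- (idx - 1L) %/% H + 1L
      sel <- which.min((r - mean(r))^2 + (c - mean(c))^2)
      out[[length(out) + 1L]] <-
        data.frame(x = c[sel] - 1L, y = r[sel] - 1L, class = k,
                   cell_id = grp$cell_id[1])
    }
  }
  do.call(rbind, out)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `images/patch_###.png`, `seeds/patch_###.csv`, `labels/patch_###.png`
#' (with JSON legends), `palette.yaml` and a `manifest.json` listing every
#' file. Deterministic given `spec$seed` (patch i uses seed
#' `spec$seed + i - 1`).
#'
#' @param n_patches number of patches.
#' @param spec a [synth_spec()]; its seed anchors the whole dataset.
#' @param out_dir output directory (created).
#' @param palette palette used for rendering (default seeded from the spec).
#' @return the manifest, invisibly.
#' @export
generate_dataset <- function(n_patches, spec, out_dir,
                             palette = generate_palette(spec$seed)) {
  if (!dir.create(out_dir, showWarnings = FALSE, recursive = TRUE) &&
      !dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  for (d in c("images", "seeds", "labels")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  write_palette(palette, file.path(out_dir, "palette.yaml"))
  entries <- vector("list", n_patches)
  for (i in seq_len(n_patches)) {
    sp <- spec
    sp$seed <- spec$seed + i - 1L
    patch <- generate_patch(sp, palette)
    tag <- sprintf("patch_%03d", i)
    img_path <- file.path(out_dir, "images", paste0(tag, ".png"))
    seed_path <- file.path(out_dir, "seeds", paste0(tag, ".csv"))
    lab_path <- file.path(out_dir, "labels", paste0(tag, ".png"))
    write_image_rgb(patch$image, img_path)
    write_seeds(patch$truth$seeds, seed_path)
    write_label_png(patch$truth$label_map, lab_path)
    entries[[i]] <- list(id = tag, image = file.path("images",
                                                     paste0(tag, ".png")),
                         seeds = file.path("seeds", paste0(tag, ".csv")),
                         labels = file.path("labels", paste0(tag, ".png")),
                         seed = sp$seed)
  }
  manifest <- list(n_patches = n_patches, pixel_size = spec$pixel_size,
                   palette = "palette.yaml", patches = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
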