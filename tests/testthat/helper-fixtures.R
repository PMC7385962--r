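# Shared fixtures and independent brute-force oracles. The oracles use only
# base R and deliberately different algorithms from the package internals.

# desk-scale synthetic patch spec: 64 px at 0.7 um/px (44.8 um field) so whole
# cells (radius 2.8-4.5 um) fit with room for a tumor nest
fixture_spec <- function(seed, noise_sd = 0.01, overlap_frac = 0.05) {
  synth_spec(height = 64L, width = 64L, pixel_size = 0.7,
             n_cells = c(CD3 = 2L, CD4 = 2L, CD8 = 2L, CD20 = 1L,
                         CD16 = 3L),
             cell_radius_um = list(CD3 = c(2.8, 4.2), CD4 = c(2.8, 4.2),
                                   CD8 = c(2.8, 4.2), CD20 = c(2.8, 4.2),
                                   CD16 = c(3, 4.5)),
             nest_radius_um = c(3, 6), n_stroma_nuclei = 2L,
             noise_sd = noise_sd, overlap_frac = overlap_frac, seed = seed)
}

fixture_palette <- function() generate_palette(1)

random_mask <- function(h = 64, w = 64, p = 0.2, blur = TRUE) {
  m <- matrix(stats::runif(h * w) < p, h, w)
  if (blur) {
    # grow a few blobs so components are nontrivial
    nb <- matrix(FALSE, h, w)
    nb[-1, ] <- nb[-1, ] | m[-h, ]
    nb[-h, ] <- nb[-h, ] | m[-1, ]
    m <- m | (nb & matrix(stats::runif(h * w) < 0.5, h, w))
  }
  m
}

# --- independent connected-component labelling (8-connectivity) by iterative
# label propagation over shifted copies, nothing shared with the C++ BFS
oracle_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(seq_len(h * w), h, w)
  lab[!mask] <- 0L
  repeat {
    nxt <- lab
    shift <- function(m, dr, dc) {
      out <- matrix(0L, h, w)
      rs <- max(1, 1 + dr):min(h, h + dr)
      cs <- max(1, 1 + dc):min(w, w + dc)
      out[rs, cs] <- m[rs - dr, cs - dc]
      out
    }
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      s <- shift(lab, dr, dc)
      upd <- mask & s > 0 & (nxt == 0 | s < nxt)
      nxt[upd] <- s[upd]
    }
    nxt[!mask] <- 0L
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  ids <- sort(unique(lab[lab > 0]))
  out <- matrix(0L, h, w)
  for (i in seq_along(ids)) out[lab == ids[i]] <- i
  out
}

# disk pixel set (matches the documented definition: centres within radius)
oracle_disk_pixels <- function(y0, x0, r, h, w) {
  which(outer(seq_len(h) - (y0 + 1), seq_len(w) - (x0 + 1),
              function(dy, dx) dx^2 + dy^2 <= r^2))
}

# brute-force dilated-seed detection counting by explicit pair enumeration
oracle_match <- function(mask, disks_df, h = nrow(mask), w = ncol(mask)) {
  lab <- oracle_label(mask)
  n_comp <- max(lab)
  comp_hit <- rep(FALSE, n_comp)
  fn <- 0L
  for (i in seq_len(nrow(disks_df))) {
    px <- oracle_disk_pixels(disks_df$y[i], disks_df$x[i],
                             disks_df$radius_px[i], h, w)
    touched <- setdiff(unique(lab[px]), 0L)
    if (length(touched) == 0L) fn <- fn + 1L
    comp_hit[touched] <- TRUE
  }
  list(tp = sum(comp_hit), fp = n_comp - sum(comp_hit), fn = fn)
}

# brute-force nearest-neighbour: min over all pixel-pairs between each source
# component and the union of target pixels
oracle_nn_px <- function(src_mask, tgt_mask) {
  lab <- oracle_label(src_mask)
  tgt <- which(tgt_mask)
  if (length(tgt) == 0L) return(rep(NA_real_, max(lab)))
  h <- nrow(src_mask)
  ty <- (tgt - 1) %% h; tx <- (tgt - 1) %/% h
  vapply(seq_len(max(lab)), function(i) {
    sp <- which(lab == i)
    sy <- (sp - 1) %% h; sx <- (sp - 1) %/% h
    sqrt(min(outer(sy, ty, "-")^2 + outer(sx, tx, "-")^2))
  }, numeric(1))
}

# textbook SSIM: explicit loop over every fully-contained window
oracle_ssim <- function(a, b, win = 11L, sigma = 1.5, k1 = 0.01, k2 = 0.03) {
  half <- (win - 1) / 2
  g1 <- exp(-((-half:half)^2) / (2 * sigma^2))
  G <- outer(g1, g1); G <- G / sum(G)
  c1 <- k1^2; c2 <- k2^2
  vals <- c()
  for (r in (half + 1):(nrow(a) - half)) {
    for (cc in (half + 1):(ncol(a) - half)) {
      wa <- a[(r - half):(r + half), (cc - half):(cc + half)]
      wb <- b[(r - half):(r + half), (cc - half):(cc + half)]
      mua <- sum(G * wa); mub <- sum(G * wb)
      saa <- sum(G * wa^2) - mua^2
      sbb <- sum(G * wb^2) - mub^2
      sab <- sum(G * wa * wb) - mua * mub
      vals <- c(vals, ((2 * mua * mub + c1) * (2 * sab + c2)) /
                        ((mua^2 + mub^2 + c1) * (saa + sbb + c2)))
    }
  }
  mean(vals)
}
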