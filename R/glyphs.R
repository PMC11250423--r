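# Procedural glyph silhouettes.
#
# Each class is drawn as a binary silhouette on a normalized [0,1]^2 patch
# (x rightwards, y downwards), then filled with a near-uniform intensity
# chosen to hit a target mean luminance.  All silhouettes are drawn in the
# "up" orientation and are rotation-asymmetric by construction (distinctive
# features at the top and/or one side), so every 90-degree rotation is
# decodable from pixels alone.

glyph_classes <- function() {
  c("t-shirt", "pant", "shoe", "bag", "pullover", "coat", "shirt")
}

# Normalized pixel-center coordinate grids for an s x s patch.
px_grid <- function(s) {
  cc <- (seq_len(s) - 0.5) / s
  list(
    x = matrix(rep(cc, each = s), s, s), # column coordinate
    y = matrix(rep(cc, times = s), s, s) # row coordinate (top = 0)
  )
}

in_rect <- function(g, x0, x1, y0, y1) {
  g$x >= x0 & g$x < x1 & g$y >= y0 & g$y < y1
}

# j: numeric vector of jitter draws in [-1, 1], recycled per feature.
glyph_mask <- function(class_name, s, j = rep(0, 8)) {
  g <- px_grid(s)
  j <- rep_len(j, 8)
  m <- switch(class_name,
    "t-shirt" = {
      torso <- in_rect(g, 0.28 + 0.03 * j[1], 0.72 + 0.03 * j[2],
                       0.18, 0.92 + 0.04 * j[3])
      sleeves <- in_rect(g, 0.04, 0.96, 0.18, 0.46 + 0.04 * j[4])
      neck <- in_rect(g, 0.44, 0.56, 0, 0.26 + 0.02 * j[5])
      (torso | sleeves) & !neck
    },
    "pant" = {
      waist <- in_rect(g, 0.26 + 0.03 * j[1], 0.74 + 0.03 * j[2], 0.06, 0.30)
      gap_w <- 0.06 + 0.02 * (1 + j[3]) / 2
      left <- in_rect(g, 0.26 + 0.03 * j[1], 0.50 - gap_w,
                      0.30, 0.94 + 0.03 * j[4])
      right <- in_rect(g, 0.50 + gap_w, 0.74 + 0.03 * j[2],
                       0.30, 0.94 + 0.03 * j[4])
      waist | left | right
    },
    "shoe" = {
      sole <- in_rect(g, 0.06, 0.94, 0.66 + 0.03 * j[1], 0.92)
      shaft <- in_rect(g, 0.52 + 0.04 * j[2], 0.88, 0.28 + 0.04 * j[3],
                       0.66 + 0.03 * j[1])
      toe <- in_rect(g, 0.06, 0.30 + 0.04 * j[4], 0.56, 0.66 + 0.03 * j[1])
      sole | shaft | toe
    },
    "bag" = {
      body <- in_rect(g, 0.12 + 0.03 * j[1], 0.88 + 0.03 * j[2],
                      0.36, 0.95 + 0.03 * j[3])
      r <- sqrt((g$x - 0.5)^2 + (g$y - 0.36)^2)
      rh <- 0.22 + 0.03 * j[4]
      handle <- r < rh & r > rh - 0.09 & g$y < 0.36
      body | handle
    },
    "pullover" = {
      torso <- in_rect(g, 0.28 + 0.03 * j[1], 0.72 + 0.03 * j[2],
                       0.20, 0.90 + 0.03 * j[3])
      sl <- in_rect(g, 0.06, 0.28 + 0.03 * j[1], 0.20, 0.82 + 0.04 * j[4]) |
        in_rect(g, 0.72 + 0.03 * j[2], 0.94, 0.20, 0.82 + 0.04 * j[4])
      collar <- in_rect(g, 0.38, 0.62, 0.12, 0.20)
      torso | sl | collar
    },
    "coat" = {
      torso <- in_rect(g, 0.26 + 0.03 * j[1], 0.74 + 0.03 * j[2],
                       0.16, 0.96)
      sl <- in_rect(g, 0.05, 0.26 + 0.03 * j[1], 0.16, 0.88 + 0.03 * j[3]) |
        in_rect(g, 0.74 + 0.03 * j[2], 0.95, 0.16, 0.88 + 0.03 * j[3])
      front <- in_rect(g, 0.465, 0.535, 0.35 + 0.04 * j[4], 1)
      lapel <- in_rect(g, 0.40, 0.60, 0, 0.24)
      (torso | sl) & !front & !lapel
    },
    "shirt" = {
      torso <- in_rect(g, 0.28 + 0.03 * j[1], 0.72 + 0.03 * j[2],
                       0.18, 0.92 + 0.03 * j[3])
      sl <- in_rect(g, 0.06, 0.28 + 0.03 * j[1], 0.18, 0.56 + 0.04 * j[4]) |
        in_rect(g, 0.72 + 0.03 * j[2], 0.94, 0.18, 0.56 + 0.04 * j[4])
      collar <- abs(g$x - 0.5) < (0.30 - g$y) * 0.55 & g$y < 0.30
      placket <- in_rect(g, 0.48, 0.52, 0.30, 0.92)
      (torso | sl) & !collar & !placket
    },
    stop(sprintf("unknown glyph class '%s'", class_name), call. = FALSE)
  )
  m
}

# Pixels of `mask` whose 4-neighbourhood is entirely inside the mask.
mask_interior <- function(mask) {
  s <- nrow(mask)
  pad <- matrix(FALSE, s + 2, s + 2)
  pad[2:(s + 1), 2:(s + 1)] <- mask
  mask &
    pad[1:s, 2:(s + 1)] & pad[3:(s + 2), 2:(s + 1)] &
    pad[2:(s + 1), 1:s] & pad[2:(s + 1), 3:(s + 2)]
}

# Render one glyph exemplar aiming at `target_lum` mean patch luminance.
# Like photographic clothing items, a glyph keeps a brighter outline and a
# few near-white highlight pixels even when its overall luminance is low, so
# dark objects remain visible against the black background.  The interior
# fill absorbs the luminance target; the achievable mean is bounded by the
# silhouette area and targets are truncated into the representable range.
# Consumes the current RNG stream.
render_glyph <- function(class_name, s, target_lum) {
  jit <- runif(8, -1, 1)
  mask <- glyph_mask(class_name, s, jit)
  interior <- mask_interior(mask)
  outline <- mask & !interior
  n_px <- length(mask)
  hi <- sample(which(mask), min(4, sum(mask)))
  hi_val <- runif(length(hi), 200, 255)
  target <- clamp(target_lum, 4, 0.93 * 255 * mean(mask))
  # solve interior/outline fill for the target mean with outline ~2.5x
  # brighter than the interior (floor 40, cap 255)
  v <- (target * n_px - sum(hi_val)) /
    max(1, sum(interior) + 2.5 * sum(outline))
  o <- clamp(2.5 * v, 40, 255)
  v <- (target * n_px - sum(hi_val) - o * sum(outline)) / max(1, sum(interior))
  v <- clamp(v, 2, 255)
  img <- matrix(0, s, s)
  img[interior] <- clamp(v * runif(sum(interior), 0.9, 1.1), 1, 255)
  img[outline] <- clamp(o * runif(sum(outline), 0.9, 1.1), 1, 255)
  img[hi] <- hi_val
  round(img) # 8-bit intensities, as in photographic source imagery
}
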