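# Brute-force oracles and small fixture builders shared across tests.

# O(n^2) all-pairs nearest pre-existing distance (independent of the
# package's chunked pmin implementation)
brute_nearest <- function(new_xy, pre_xy) {
  apply(as.matrix(new_xy), 1, function(p) {
    min(sqrt((pre_xy[, 1] - p[1])^2 + (pre_xy[, 2] - p[2])^2))
  })
}

# recursive flood-fill connected components (8-connectivity) on a logical
# matrix; slow but obviously correct on small masks
flood_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (mask[r, c] && lab[r, c] == 0L) {
      nxt <- nxt + 1L
      stack <- list(c(r, c))
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        if (p[1] < 1 || p[2] < 1 || p[1] > nrow(mask) || p[2] > ncol(mask))
          next
        if (!mask[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
        lab[p[1], p[2]] <- nxt
        for (dr in -1:1) for (dc in -1:1)
          if (dr != 0 || dc != 0)
            stack[[length(stack) + 1L]] <- c(p[1] + dr, p[2] + dc)
      }
    }
  }
  lab
}

# a plaque_regions object built directly from a label matrix, bypassing
# thresholding (for classification tests on constructed masks)
regions_from_labels <- function(lab, pixel_size_um = 1) {
  fake_channel <- matrix(1, nrow(lab), ncol(lab))
  bg <- structure(list(mean = 0, sd = 1,
                       region = list(x = 0, y = 0, w = 10, h = 10)),
                  class = "background_model")
  det <- detect_plaques(matrix(0, nrow(lab), ncol(lab)) + (lab > 0) * 100,
                        bg, pixel_size_um, min_area_px = 1L)
  det
}

# disc mask helper: TRUE inside a disc of radius r px centred at (row, col)
disc_mask <- function(nr, nc, row, col, r) {
  outer(seq_len(nr), seq_len(nc),
        function(y, x) (y - row)^2 + (x - col)^2 <= r^2)
}

# resolvable scenes: separated plaques so per-blob properties (counts,
# monotonicity, recovery) are not confounded by physical halo merging
small_scene_config <- function(...) {
  scene_config(n_pre = 6, n_new = 5, p_cluster = 0.3, multicore_p = 0.3,
               min_separation_um = 35, seed = 99, ...)
}
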