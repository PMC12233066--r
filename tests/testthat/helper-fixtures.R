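# Shared fixtures: cell tables drawn straight from shape distributions
# (no imaging), category pools with experiment provenance, and small
# utilities used across test files.

# cell table with plausible descriptor covariance, drawn from a stated
# length/width world; `sd_scale` inflates population heterogeneity
make_cells <- function(n, length_mean = 100, length_sd = 20, width_mean = 15,
                       width_sd = 3, sd_scale = 1, well = "w1", cond = "A",
                       group = NULL) {
  len <- pmax(rnorm(n, length_mean, length_sd * sd_scale), 4)
  wid <- pmax(rnorm(n, width_mean, width_sd * sd_scale), 2)
  l <- pmax(len, wid); w <- pmin(len, wid)
  area <- l * w * runif(n, 0.75, 0.85)          # capsules fill ~80% of box
  per <- 2 * (l + w) * runif(n, 0.88, 0.95)
  df <- data.frame(cell_id = seq_len(n), well_id = well, condition = cond,
                   area_um2 = area, perimeter_um = per, length_um = l,
                   width_um = w, lw_ratio = l / w,
                   compactness = pmin(4 * pi * area / per^2, 1))
  if (!is.null(group)) df$group <- group
  morphocell:::as_cell_table(df, 1)
}

# six-category design with graded length separation, 5 experiments per
# category (group column), for classifier tests
make_category_pools <- function(n_per_exp = 600, n_exp = 5, sep = 15,
                                base = 60, seed = 1) {
  set.seed(seed)
  cats <- paste0("cat", 1:6)
  pools <- lapply(seq_along(cats), function(i) {
    parts <- lapply(seq_len(n_exp), function(e)
      as.data.frame(make_cells(n_per_exp, length_mean = base + i * sep,
                               well = paste0("e", e), cond = cats[i],
                               group = paste0("exp", e))))
    morphocell:::as_cell_table(do.call(rbind, parts), 1)
  })
  names(pools) <- cats
  pools
}

# adjusted Rand index (closed form over the pair-count contingency table)
ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n2 <- ch2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# rasterized shapes for morphometry oracles
disk_pixels <- function(r, at = c(0, 0)) {
  g <- morphocell:::disk_offsets(r)
  data.frame(rows = g$dr + at[1], cols = g$dc + at[2])
}

rect_pixels <- function(h, w, at = c(1, 1)) {
  g <- expand.grid(rows = seq_len(h) + at[1] - 1, cols = seq_len(w) + at[2] - 1)
  g
}

# rotated rectangle rasterized by center-inclusion (the clean way)
rot_rect_pixels <- function(len, wid, theta, offset = c(40, 40)) {
  bb <- expand.grid(r = -ceiling(len):ceiling(len), c = -ceiling(len):ceiling(len))
  u <- bb$c * cos(theta) + bb$r * sin(theta)
  v <- -bb$c * sin(theta) + bb$r * cos(theta)
  inside <- u >= 0 & u < len & v >= -wid & v < 0
  data.frame(rows = bb$r[inside] + offset[1], cols = bb$c[inside] + offset[2])
}
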