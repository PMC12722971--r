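# Shared fixture builders; everything is generated in code at test time.

rand_rigid <- function() {
  v <- rnorm(4)
  rigid(quaternion(v[1], v[2], v[3], v[4]), runif(3, -100, 100))
}

rand_points <- function(n, range = 50) {
  matrix(runif(3 * n, -range, range), ncol = 3)
}

# raw EMT file from a samples data frame (columns channel step x y z
# [pose...] [quality])
write_raw_fixture <- function(df, path = tempfile(fileext = ".tsv"),
                              extra_lines = character()) {
  con <- file(path, "w")
  writeLines(c("# fixture", paste(names(df), collapse = "\t")), con)
  utils::write.table(format(df, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  if (length(extra_lines)) writeLines(extra_lines, con)
  close(con)
  path
}

# samples for a clean multi-needle session: k samples per (channel, step)
# at given truth points (list by channel of n x 3), plus per-axis noise
make_samples <- function(truth, k = 5, sigma = 0) {
  rows <- list()
  for (ch in names(truth)) {
    pts <- truth[[ch]]
    for (s in seq_len(nrow(pts))) {
      for (j in seq_len(k)) {
        rows[[length(rows) + 1]] <- data.frame(
          channel = as.integer(ch), step = s - 1L,
          x = pts[s, 1] + rnorm(1, 0, sigma),
          y = pts[s, 2] + rnorm(1, 0, sigma),
          z = pts[s, 3] + rnorm(1, 0, sigma))
      }
    }
  }
  do.call(rbind, rows)
}

# straight-needle truth: 11 points, 5 mm apart, along +z, distal first
straight_series_points <- function(x = 0, y = 0, n = 11, step = 5,
                                   z_tip = 55) {
  cbind(x = rep(x, n), y = rep(y, n), z = z_tip - step * (seq_len(n) - 1))
}

# constant radial dose function g == 1 over the tabulated range
unit_g_source <- function(sk = 40820, Lambda = 1, phi_an = 1) {
  source_model(data.frame(r_cm = c(0.05, 1, 20), g = c(1, 1, 1)),
               Lambda = Lambda, phi_an = phi_an, sk = sk)
}

# brute-force two-sided exact signed-rank p over all 2^n sign patterns
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-12)
  p_ge <- mean(w_all >= w_obs - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}
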