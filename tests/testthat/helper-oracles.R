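# Independent oracles used to check the implementation by a second route.

# Exhaustive pixel enumeration of protrusion/retraction lune centroids and
# their distance (dynamic polarity), looping pixel by pixel.
oracle_polarity <- function(mask_t, mask_t1, pixel_size_um = 1) {
  nr <- nrow(mask_t); nc <- ncol(mask_t)
  psx <- psy <- pn <- rsx <- rsy <- rn <- 0
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (mask_t1[r, c] && !mask_t[r, c]) {
      psx <- psx + (c - 1); psy <- psy + (r - 1); pn <- pn + 1
    }
    if (mask_t[r, c] && !mask_t1[r, c]) {
      rsx <- rsx + (c - 1); rsy <- rsy + (r - 1); rn <- rn + 1
    }
  }
  if (pn == 0 || rn == 0) return(NA_real_)
  sqrt((psx / pn - rsx / rn)^2 + (psy / pn - rsy / rn)^2) * pixel_size_um
}

# Brute-force optimal (minimum total distance) assignment of 2 previous
# objects to 2 next objects under the mass gate; returns the permutation.
oracle_assign2 <- function(prev_xy, prev_m, next_xy, next_m,
                           d_max = Inf, mass_tol = 0.35) {
  perms <- list(c(1, 2), c(2, 1))
  best <- NULL; best_cost <- Inf
  for (p in perms) {
    cost <- 0; ok <- TRUE
    for (i in 1:2) {
      j <- p[i]
      d <- sqrt(sum((prev_xy[i, ] - next_xy[j, ])^2))
      md <- abs(prev_m[i] - next_m[j]) / max(prev_m[i], next_m[j])
      if (d > d_max || md > mass_tol) { ok <- FALSE; break }
      cost <- cost + d
    }
    if (ok && cost < best_cost) { best_cost <- cost; best <- p }
  }
  best
}

# Textbook nested-ANOVA decomposition by explicit sums (balanced case):
# SS_pop over movie means, SS_movie(pop) over cell values.
oracle_nested_F <- function(y, pop, movie) {
  pop <- as.character(pop); movie <- paste(pop, movie)
  grand <- mean(y)
  ss_pop <- 0; ss_movie <- 0
  for (p in unique(pop)) {
    yp <- y[pop == p]
    ss_pop <- ss_pop + length(yp) * (mean(yp) - grand)^2
    for (m in unique(movie[pop == p])) {
      ym <- y[movie == m]
      ss_movie <- ss_movie + length(ym) * (mean(ym) - mean(yp))^2
    }
  }
  a <- length(unique(pop))
  b <- length(unique(movie))
  df1 <- a - 1; df2 <- b - a
  F <- (ss_pop / df1) / (ss_movie / df2)
  list(F = F, df1 = df1, df2 = df2,
       p = pf(F, df1, df2, lower.tail = FALSE))
}

# Upper-tail chi-square(1) probability by numeric integration of the
# density (independent of pchisq's internals beyond the density formula).
oracle_chisq1_p <- function(x) {
  stats::integrate(function(t) exp(-t / 2) / sqrt(2 * pi * t),
                   lower = x, upper = Inf,
                   rel.tol = 1e-10)$value
}
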