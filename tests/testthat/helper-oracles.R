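# Shared oracles and micro-fixtures.  The brute-force dominance scan is
# deliberately independent of the package's sweep implementation.

# O(n^2) non-dominated scan; returns row indices of the front (exact
# (x, y) duplicates collapsed to the first-pushed row, matching the
# documented tie rule).
brute_force_front <- function(points, maxX = FALSE, maxY = FALSE) {
  x <- points$x
  y <- points$y
  sx <- if (maxX) -x else x
  sy <- if (maxY) -y else y
  dup <- duplicated(cbind(x, y))
  keep <- logical(length(x))
  for (i in seq_along(x)) {
    if (dup[i]) next
    dominated <- any(sx <= sx[i] & sy <= sy[i] & (sx < sx[i] | sy < sy[i]))
    keep[i] <- !dominated
  }
  which(keep)
}

# deterministic micro-complex: 6-atom receptor plate, 4-atom ligand with
# k jittered conformers; no RNG involved
tiny_pose <- function(k_conformers = 3, center = c(0, 0, 4)) {
  receptor <- atom_records(
    x = c(-2, 0, 2, -1, 1, 0), y = c(0, 0, 0, 1.5, 1.5, -1.5),
    z = c(0, 0, 0, 0, 0, 0),
    element = c("N", "C", "O", "C", "O", "C"),
    name = c("N", "CA", "O", "CB", "OG", "C"),
    role = c("receptor-backbone", "receptor-backbone", "receptor-backbone",
             "receptor-sidechain", "receptor-sidechain", "receptor-backbone"))
  base <- rbind(c(0.5, 0, 0), c(-0.5, 0, 0), c(0, 0.5, 0), c(0, -0.3, 0.4))
  base <- sweep(base, 2, colMeans(base))
  conformers <- lapply(seq_len(k_conformers), function(j) {
    cf <- base + (j - 1) * 0.05
    sweep(cf, 2, colMeans(cf))
  })
  new_pose(receptor, conformers, elements = c("C", "O", "C", "O"),
           center = center)
}

# random objective clouds for Pareto property tests
random_points <- function(n, style = c("continuous", "gridded")) {
  style <- match.arg(style)
  if (style == "gridded") {
    data.frame(x = sample(1:20, n, replace = TRUE),
               y = sample(1:20, n, replace = TRUE))
  } else {
    data.frame(x = runif(n, 0, 100), y = rnorm(n))
  }
}

flag_grid <- expand.grid(maxX = c(FALSE, TRUE), maxY = c(FALSE, TRUE))
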