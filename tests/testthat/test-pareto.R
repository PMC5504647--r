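# Pareto dominance, the sweep front, and the three replica selectors.

test_that("dominance is oriented by the scenario flags", {
  expect_true(dominates(c(1, 1), c(2, 2)))
  expect_false(dominates(c(1, 3), c(3, 1)))
  expect_false(dominates(c(3, 1), c(1, 3)))
  expect_false(dominates(c(1, 1), c(1, 1)))
  expect_true(dominates(c(2, 2), c(1, 1), maxX = TRUE, maxY = TRUE))
  expect_true(dominates(c(2, 1), c(1, 1), maxX = TRUE))
  expect_false(dominates(c(2, 1), c(1, 1)))
})

test_that("pareto front matches hand examples", {
  pts <- data.frame(x = c(1, 2, 3, 4), y = c(5, 3, 4, 1))
  mm <- pareto_front(pts)
  expect_equal(mm$x, c(1, 2, 4))
  expect_equal(mm$y, c(5, 3, 1))
  xm <- pareto_front(pts, maxX = TRUE)
  expect_equal(nrow(xm), 1)
  expect_equal(c(xm$x, xm$y), c(4, 1))
  single <- pareto_front(data.frame(x = 3, y = 7))
  expect_equal(single$index, 1)
  expect_error(pareto_front(data.frame(x = numeric(), y = numeric())),
               "at least one")
})

test_that("pareto front equals the brute-force scan on random clouds", {
  set.seed(101)
  for (rep in 1:200) {
    n <- sample(1:60, 1)
    pts <- random_points(n, style = sample(c("continuous", "gridded"), 1))
    for (f in seq_len(nrow(flag_grid))) {
      got <- pareto_front(pts, flag_grid$maxX[f], flag_grid$maxY[f])
      expect_equal(sort(got$index),
                   sort(brute_force_front(pts, flag_grid$maxX[f],
                                          flag_grid$maxY[f])))
    }
  }
})

test_that("front membership is permutation-invariant and stable under
           dominated additions", {
  set.seed(55)
  pts <- random_points(40, "gridded")
  base <- pareto_front(pts)
  perm <- sample(nrow(pts))
  shuffled <- pareto_front(pts[perm, , drop = FALSE])
  expect_setequal(paste(base$x, base$y),
                  paste(shuffled$x, shuffled$y))
  # append a point dominated by an existing member: front unchanged
  worse <- data.frame(x = base$x[1] + 1, y = base$y[1] + 1)
  again <- pareto_front(rbind(pts, worse))
  expect_setequal(paste(base$x, base$y), paste(again$x, again$y))
})

test_that("duplicates collapse to the first-pushed entry", {
  arch <- make_decoy_archive(30, seed = 4, front_size = 5,
                             duplicate_points = 6)
  pts <- data.frame(x = arch$step, y = arch$tscore)
  got <- pareto_front(pts)
  expect_equal(sort(got$index), sort(brute_force_front(pts)))
  expect_true(all(got$index <= 30))  # duplicates live in rows 31..36
})

test_that("last-numR selection is the queue tail", {
  arch <- make_decoy_archive(20, seed = 1)
  sel <- select_remc_replicas(arch, 16)
  expect_equal(sel$step, 5:20)
  all20 <- select_remc_replicas(arch, 20)
  expect_equal(all20$step, 1:20)
  expect_error(select_remc_replicas(arch, 21), "at least")
})

test_that("min-min selection is front-then-fill and keeps the minimiser", {
  # front exactly numR: the front itself comes back
  arch <- make_decoy_archive(50, seed = 2, front_size = 6)
  sel <- select_mo_remc_replicas(arch, 6)
  expect_setequal(sel$index, attr(arch, "front_index"))

  # front larger than numR: lowest-TScore front members
  sel4 <- select_mo_remc_replicas(arch, 4)
  front_ts <- sort(arch$tscore[attr(arch, "front_index")])
  expect_equal(sort(sel4$tscore), front_ts[1:4])

  # all points share one minimum at the earliest step: front of size 1
  # plus the numR-1 most recent entries
  flat <- data.frame(step = 1:10, tscore = rep(1, 10))
  self <- select_mo_remc_replicas(flat, 4)
  expect_setequal(self$step, c(1, 10, 9, 8))
})

test_that("selector contracts hold on random archives", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(8:80, 1)
    arch <- data.frame(step = 1:n, tscore = rnorm(n))
    numR <- sample(1:min(8, n), 1)
    for (f in list(select_remc_replicas, select_mo_remc_replicas,
                   select_hmo_remc_replicas)) {
      sel <- f(arch, numR)
      expect_equal(nrow(sel), numR)
      expect_true(all(sel$index %in% seq_len(n)))
      expect_equal(anyDuplicated(sel$index), 0)
    }
    # MO and HMO always carry the global TScore minimiser
    expect_true(min(arch$tscore) %in% select_mo_remc_replicas(arch, numR)$tscore)
    expect_true(min(arch$tscore) %in% select_hmo_remc_replicas(arch, numR)$tscore)
  }
})

test_that("hybrid selection keeps the lowest-TScore members of both fronts", {
  ts <- c(5, 4, 3, 9, 1, 7, 6, 2.5, 2.6, 2.7)
  arch <- data.frame(step = 1:10, tscore = ts)
  # brute-force the two fronts from first principles
  pts <- data.frame(x = arch$step, y = arch$tscore)
  mm <- brute_force_front(pts)
  xm <- brute_force_front(pts, maxX = TRUE)
  expect_equal(mm, c(1, 2, 3, 5))
  expect_equal(xm, c(5, 8, 9, 10))
  u <- union(mm, xm)
  sel <- select_hmo_remc_replicas(arch, 4)
  expect_equal(sort(sel$tscore), sort(ts[u])[1:4])
  expect_true(5 %in% sel$index)   # global minimiser
  # union smaller than numR: most recent entries fill the remainder
  sel9 <- select_hmo_remc_replicas(arch, 9)
  expect_true(all(u %in% sel9$index))
  expect_equal(nrow(sel9), 9)

  # degenerate case: selection windows where both strategies coincide
  dec <- data.frame(step = 1:5, tscore = c(5, 4, 3, 2, 1))
  expect_setequal(select_hmo_remc_replicas(dec, 3)$index,
                  select_mo_remc_replicas(dec, 3)$index)
})

test_that("selectors reject non-archive-like input", {
  expect_error(select_mo_remc_replicas(
    data.frame(step = c(1, 1, 2), tscore = 1:3), 2), "strictly increasing")
})
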