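# Coarse-grained score, full-atom score engine, surrogate terms,
# interface delta.

test_that("coarse-grained counts respect the distance bands", {
  rec1 <- atom_records(0, 0, 0, element = "C", name = "CA",
                       role = "receptor-backbone")
  lig_at <- function(d) atom_records(d, 0, 0, element = "C")

  far <- coarse_grained_counts(rec1, lig_at(10))
  expect_equal(list(far$R, far$A, far$N), list(0L, 0L, 1L))

  contact <- coarse_grained_counts(rec1, lig_at(3.0))
  expect_equal(list(contact$R, contact$A, contact$N), list(0L, 1L, 1L))

  clash <- coarse_grained_counts(rec1, lig_at(1.0))
  expect_equal(list(clash$R, clash$A, clash$N), list(1L, 0L, 1L))

  # boundaries are exclusive: exactly 2.25 is neither clash nor contact
  edge <- coarse_grained_counts(rec1, lig_at(2.25))
  expect_equal(list(edge$R, edge$A), list(0L, 0L))

  # clash against a side-chain CB counts via the atom name
  rec_cb <- atom_records(0, 0, 0, element = "C", name = "CB",
                         role = "receptor-sidechain")
  expect_equal(coarse_grained_counts(rec_cb, lig_at(1.0))$R, 1L)
  # ...but a generic side-chain atom cannot clash, only contact
  rec_sc <- atom_records(0, 0, 0, element = "C", name = "OG",
                         role = "receptor-sidechain")
  cnt <- coarse_grained_counts(rec_sc, lig_at(1.0))
  expect_equal(list(cnt$R, cnt$A), list(0L, 0L))

  # hydrogens are excluded from the ligand counts
  lig_h <- atom_records(c(3, 3.1), 0, 0, element = c("C", "H"))
  expect_equal(coarse_grained_counts(rec1, lig_h)$N, 1L)
  expect_error(
    coarse_grained_counts(rec1, atom_records(1, 0, 0, element = "H")),
    "non-hydrogen")
})

test_that("coarse-grained score matches hand values and its bounds", {
  expect_equal(coarse_grained_score(0, 10, 10), -0.85)
  expect_equal(coarse_grained_score(2, 5, 10), 1.5)
  expect_equal(coarse_grained_score(0, 0, 5), 0)
  cnt <- structure(list(R = 0, A = 5, N = 5), class = "cg_counts")
  expect_equal(coarse_grained_score(cnt), -0.85)

  set.seed(1)
  for (i in 1:200) {
    N <- sample(1:30, 1)
    R <- sample(0:N, 1)
    A <- sample(0:N, 1)
    s <- coarse_grained_score(R, A, N)
    expect_gte(s, -0.85)
    if (s == -0.85) expect_true(R == 0 && A / N >= 0.85)
    # monotone: worse with one more clash, no worse with one more contact
    if (R < N) expect_gt(coarse_grained_score(R + 1, A, N), s)
    if (A < N) expect_lte(coarse_grained_score(R, A + 1, N), s)
  }
})

test_that("weight presets reproduce the published table bit-exactly", {
  hard_ref <- c(pro_close = 1.00, fa_atr = 0.80, fa_rep = 0.40,
                fa_sol = 0.60, fa_pair = 0.80, ref = 1.00,
                hbond_lr_bb = 2.00, hbond_sr_bb = 2.00, hbond_bb_sc = 2.00,
                hbond_sc = 2.00, rama = 0.50, omega = 0.50)
  soft_ref <- c(pro_close = 1.00, fa_atr = 0.80, fa_rep = 0.60,
                fa_sol = 0.50, fa_pair = 0.50, ref = 1.00,
                hbond_lr_bb = 1.20, hbond_sr_bb = 1.20, hbond_bb_sc = 1.20,
                hbond_sc = 1.20, rama = 0.32, omega = 0.50)
  expect_identical(unclass(score_weights("hard"))[names(hard_ref)], hard_ref)
  expect_identical(unclass(score_weights("soft"))[names(soft_ref)], soft_ref)

  # round trip through the key-value config file
  f <- withr::local_tempfile(fileext = ".yaml")
  write_score_weights(score_weights("soft"), f)
  expect_equal(unclass(read_score_weights(f))[names(soft_ref)], soft_ref)
})

test_that("full-atom score is the exact weighted linear combination", {
  w <- score_weights("hard")
  zero <- setNames(numeric(12), score_term_names())
  expect_equal(full_atom_score(zero, w), 0)
  one <- zero; one["fa_atr"] <- 2.0
  expect_equal(full_atom_score(one, w), 1.6)

  set.seed(7)
  for (i in 1:50) {
    s <- setNames(rnorm(12), score_term_names())
    expect_equal(full_atom_score(s, w), sum(unclass(w)[names(s)] * s))
    expect_equal(full_atom_score(2 * s, w), 2 * full_atom_score(s, w))
  }
  bad <- zero; bad["omega"] <- NaN
  expect_error(full_atom_score(bad, w), "omega")
  expect_warning(full_atom_score(c(unclass(zero), mystery = 1), w), "mystery")
})

test_that("surrogate terms: limits, determinism, well depth, overlap cap", {
  pose <- tiny_pose()
  p <- surrogate_params()

  far <- translate_pose(pose, c(1e4, 0, 0))
  terms_far <- surrogate_terms(far, p)
  expect_true(all(terms_far == 0))

  expect_identical(surrogate_terms(pose, p), surrogate_terms(pose, p))
  expect_true(all(is.finite(surrogate_terms(pose, p))))
  expect_setequal(names(surrogate_terms(pose, p)), score_term_names())

  # single receptor atom, single apolar ligand atom at the pair minimum:
  # attractive term equals the documented well depth, repulsive is zero
  rec1 <- atom_records(0, 0, 0, element = "C", name = "CA",
                       role = "receptor-backbone")
  probe <- new_pose(rec1, list(matrix(0, 1, 3)), elements = "C",
                    center = c(p$lj_rmin, 0, 0))
  tm <- surrogate_terms(probe, p)
  expect_equal(tm[["fa_atr"]], -p$lj_depth)
  expect_equal(tm[["fa_rep"]], 0)

  # full overlap stays finite at the documented cap
  overlap <- new_pose(rec1, list(matrix(0, 1, 3)), elements = "C",
                      center = c(0, 0, 0))
  expect_equal(surrogate_terms(overlap, p)[["fa_rep"]], p$rep_cap)
})

test_that("model fast path agrees with breakdown x weights", {
  pose <- tiny_pose()
  model <- surrogate_energy_model(score_weights("hard"))
  set.seed(11)
  for (i in 1:25) {
    q <- rotamer_trial_move(pose, move_config(trial_translation_sd = 2,
                                              trial_rotation_sd = 60))
    expect_equal(model$score(q),
                 full_atom_score(surrogate_terms(q), score_weights("hard")))
  }
})

test_that("interface delta: zero model, pocket fixture, separation limit", {
  pose <- tiny_pose()
  flat <- energy_model(function(p) 0, name = "flat")
  expect_equal(interface_delta(pose, flat), 0)

  toy <- make_toy_complex(toy_complex_spec(seed = 5))
  ifd_nat <- interface_delta(toy$native_pose, toy$model)
  expect_lt(ifd_nat, 0)
  expect_lt(ifd_nat, interface_delta(toy$start_pose, toy$model))
  expect_lt(abs(interface_delta(toy$native_pose, toy$model, 500) -
                interface_delta(toy$native_pose, toy$model, 1000)), 1e-6)
})
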