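two_state_line <- function(xs_start, xs_target) {
  n <- length(xs_start)
  list(start = calpha_model(cbind(xs_start, 0, 0), rep("A", n), 1:n),
       target = calpha_model(cbind(xs_target, 0, 0), rep("A", n), 1:n))
}

test_that("the progress variable is the summed squared distance mismatch", {
  s <- two_state_line(c(0, 1, 2), c(0, 2, 4))
  tg <- target_distances(s$start, s$target)
  # pairs (1,2): (1-2)^2, (1,3): (2-4)^2, (2,3): (1-2)^2
  expect_equal(progress_variable(s$start$xyz, tg), 6)
  expect_equal(progress_variable(s$target$xyz, tg), 0)

  p <- two_state_line(c(0, 3.8), c(0, 4.8))
  tgp <- target_distances(p$start, p$target)
  expect_equal(progress_variable(p$start$xyz, tgp), 1)
})

test_that("the progress variable is invariant under rigid-body transforms", {
  fx <- make_two_state(20, 1, "hinge", amplitude = 25)
  tg <- target_distances(fx$start, fx$target)
  g0 <- progress_variable(fx$start$xyz, tg)
  set.seed(9)
  for (rep in 1:5) {
    moved <- rotate_random(fx$start$xyz)
    expect_equal(progress_variable(moved, tg), g0, tolerance = 1e-9)
  }
  # positions equal to a rigid transform of the target give exactly 0
  expect_equal(progress_variable(rotate_random(fx$target$xyz), tg),
               0, tolerance = 1e-9)
})

test_that("the overdamped step is quiescent at zero temperature and equilibrium", {
  m <- random_model(10, seed = 1)
  topo <- build_topology(m, enm_params(cutoff = 20))
  bp <- bd_params(temperature = 0)
  st <- sampler_state(m$xyz)
  st2 <- bd_step(st, topo, bp)
  expect_equal(st2$positions, m$xyz)
  expect_equal(st2$step, 1L)
})

test_that("at zero temperature a stretched spring relaxes by mobility * force", {
  m <- calpha_model(cbind(c(0, 4.8), 0, 0), rep("A", 2), 1:2)
  topo <- build_topology(m, enm_params(sequence_constant = 1,
                                       sequence_span = 1))
  topo$pairs$d0 <- 3.8
  bp <- bd_params(temperature = 0, friction = 20, timestep = 0.015)
  st <- bd_step(sampler_state(m$xyz), topo, bp)
  mu <- bp$timestep / bp$friction
  expect_equal(st$positions[1L, ], c(mu * 1, 0, 0))
  expect_equal(st$positions[2L, ], c(4.8 - mu * 1, 0, 0))
})

test_that("free-diffusion displacement variance matches 2 kB T dt / gamma", {
  # two beads far beyond any interaction, no springs
  m <- calpha_model(rbind(c(0, 0, 0), c(500, 0, 0)), c("A", "B"), c(1L, 1L))
  topo <- build_topology(m, enm_params(cutoff = 1, sequence_span = 0))
  expect_equal(nrow(topo$pairs), 0L)
  bp <- bd_params()
  expected <- 2 * 0.0019872041 * bp$temperature * bp$timestep / bp$friction
  set.seed(11)
  n_steps <- 10000L
  st <- sampler_state(m$xyz)
  prev <- st$positions
  disp2 <- numeric(n_steps)
  for (s in seq_len(n_steps)) {
    st <- bd_step(st, topo, bp)
    disp2[s] <- (st$positions[1L, 1L] - prev[1L, 1L])^2
    prev <- st$positions
  }
  expect_equal(mean(disp2), expected, tolerance = 0.05)
})

test_that("checkpoints accept on strict decrease only and roll back otherwise", {
  s <- two_state_line(c(0, 3.8), c(0, 4.8))
  tg <- target_distances(s$start, s$target)
  st <- sampler_state(s$start$xyz, gamma = 0.6)

  # move that lands at gamma 0.25 (< 0.6): accepted
  st$positions <- cbind(c(0, 4.3), 0, 0)
  out <- dims_checkpoint(st, tg)
  expect_true(out$accepted)
  expect_equal(out$state$last_accepted_gamma, 0.25)

  # worse move: rejected, coordinates rolled back
  st2 <- out$state
  st2$positions <- cbind(c(0, 3.5), 0, 0)
  out2 <- dims_checkpoint(st2, tg)
  expect_false(out2$accepted)
  expect_equal(out2$state$positions, out$state$last_accepted_positions)

  # exact tie is a rejection (strict inequality)
  st3 <- out2$state
  st3$positions <- cbind(c(0, 4.3), 0, 0)   # gamma = 0.25 again
  out3 <- dims_checkpoint(st3, tg)
  expect_false(out3$accepted)
})

test_that("a run starting at the target converges immediately with one frame", {
  fx <- make_two_state(12, 1, "uniform_translation", 0)
  p <- run_transition(fx$start, fx$start, seed = 1)
  expect_true(p$converged)
  expect_equal(p$checkpoints, 0L)
  expect_length(p$frames, 1L)
})

test_that("an exhausted checkpoint budget reports an unconverged path", {
  fx <- make_two_state(12, 1, "hinge", 40)
  p <- run_transition(fx$start, fx$target,
                      bd = bd_params(max_checkpoints = 1), seed = 1)
  expect_false(p$converged)
  expect_equal(p$termination_reason, "budget")
  expect_error(run_transition(fx$start,
                              calpha_model(matrix(1:9 + 0.0, 3, 3),
                                           rep("Z", 3), 1:3)),
               "match|matched")
})

test_that("identical seeds give identical paths; seeds differ otherwise", {
  fx <- make_two_state(15, 1, "hinge", amplitude = 60)
  bp <- bd_params(max_checkpoints = 400, convergence_rmsd = 1.5)
  p1 <- run_transition(fx$start, fx$target, bd = bp, seed = 7)
  p2 <- run_transition(fx$start, fx$target, bd = bp, seed = 7)
  expect_identical(lapply(p1$frames, `[[`, "xyz"),
                   lapply(p2$frames, `[[`, "xyz"))
  expect_identical(p1$log, p2$log)
  p3 <- run_transition(fx$start, fx$target, bd = bp, seed = 8)
  expect_false(identical(p1$final_gamma, p3$final_gamma))
})

test_that("gamma at accepted checkpoints decreases strictly; frames follow", {
  fx <- make_two_state(15, 1, "hinge", amplitude = 60)
  p <- run_transition(fx$start, fx$target,
                      bd = bd_params(max_checkpoints = 2000,
                                     convergence_rmsd = 1.5), seed = 3)
  acc <- p$log$gamma_accepted[p$log$accepted]
  expect_true(all(diff(acc) < 0))
  expect_true(all(diff(p$gamma) < 0))
  if (p$converged && p$termination_reason == "rmsd")
    expect_lte(p$final_rmsd, 1.5)
})

test_that("rigid-transforming the target changes nothing (internal-distance bias)", {
  fx <- make_two_state(12, 1, "hinge", amplitude = 60)
  set.seed(5)
  target2 <- set_coords(fx$target, rotate_random(fx$target$xyz))
  bp <- bd_params(max_checkpoints = 600, convergence_rmsd = 1.2)
  p1 <- run_transition(fx$start, fx$target, bd = bp, seed = 4)
  p2 <- run_transition(fx$start, target2, bd = bp, seed = 4)
  expect_equal(lapply(p1$frames, `[[`, "xyz"),
               lapply(p2$frames, `[[`, "xyz"), tolerance = 1e-8)
  expect_equal(p1$gamma, p2$gamma, tolerance = 1e-8)
})

test_that("the compiled and pure-R engines consume the same noise stream", {
  m <- random_model(8, seed = 2)
  topo <- build_topology(m, enm_params(cutoff = 25))
  bp <- bd_params()
  xyz0 <- m$xyz + matrix(rnorm(24, sd = 0.2), 8, 3)

  set.seed(21)
  cpp <- cpp_bd_segment(xyz0, topo$pairs$i, topo$pairs$j, topo$pairs$k,
                        topo$pairs$d0, bp$timestep / bp$friction,
                        sqrt(2 * 0.0019872041 * bp$temperature *
                             bp$timestep / bp$friction), 5L)
  set.seed(21)
  st <- sampler_state(xyz0)
  for (s in 1:5) st <- bd_step(st, topo, bp)
  expect_equal(unname(cpp), unname(st$positions), tolerance = 1e-12)

  # and whole runs agree across engines at a fixed seed
  fx <- make_two_state(12, 1, "hinge", amplitude = 60)
  bp2 <- bd_params(max_checkpoints = 60, convergence_rmsd = 1.2)
  pr <- run_transition(fx$start, fx$target, bd = bp2, engine = "r",
                       seed = 2)
  pc <- run_transition(fx$start, fx$target, bd = bp2, engine = "cpp",
                       seed = 2)
  expect_equal(pr$log$accepted, pc$log$accepted)
  expect_equal(pr$final_gamma, pc$final_gamma, tolerance = 1e-9)
})

test_that("a rigid block preserves its internal distances along a biased run", {
  fx <- make_two_state(14, 2, "rotor", amplitude = 30)
  block <- which(fx$start$chain == "B")
  p <- run_transition(fx$start, fx$target, rigid_blocks = list(block),
                      bd = bd_params(max_checkpoints = 3000,
                                     convergence_rmsd = 1), seed = 6)
  d0 <- dist(fx$start$xyz[block, ])
  worst <- max(vapply(p$frames, function(f)
    max(abs(dist(f$xyz[block, ]) - d0)), numeric(1)))
  expect_lt(worst, 0.1)
})

test_that("unmatched residues fluctuate freely but do not block convergence", {
  fx <- make_two_state(16, 2, "rotor", amplitude = 20)
  target_partial <- degrade_model(fx$target, drop_keys = "A")
  p <- run_transition(fx$start, target_partial,
                      bd = bd_params(max_checkpoints = 4000), seed = 3)
  expect_equal(n_beads(p$frames[[1L]]), 32L)  # frames keep all residues
  expect_true(p$final_rmsd < 2 || p$converged)
})

test_that("cutoff-restricted and all-pair progress variables agree when the cutoff spans the system", {
  fx <- make_two_state(12, 1, "hinge", amplitude = 40)
  tg_all <- target_distances(fx$start, fx$target, scope = "all")
  tg_cut <- target_distances(fx$start, fx$target, scope = "cutoff",
                             cutoff = 1000)
  expect_equal(progress_variable(fx$start$xyz, tg_cut),
               progress_variable(fx$start$xyz, tg_all))
  p1 <- run_transition(fx$start, fx$target, gamma_scope = "all",
                       enm = enm_params(cutoff = 1000),
                       bd = bd_params(max_checkpoints = 100), seed = 9)
  p2 <- run_transition(fx$start, fx$target, gamma_scope = "cutoff",
                       enm = enm_params(cutoff = 1000),
                       bd = bd_params(max_checkpoints = 100), seed = 9)
  expect_equal(p1$final_gamma, p2$final_gamma, tolerance = 1e-9)
})
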