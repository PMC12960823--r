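#' @useDynLib bdpath, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm median quantile coef lm sd
#' @importFrom utils combn write.csv read.csv
NULL

KB_KCAL <- 0.0019872041  # Boltzmann constant, kcal/mol/K

#' Brownian-dynamics parameters
#'
#' Physical and sampling parameters of the overdamped (Brownian) integrator
#' and of the importance-sampling schedule. The position update is
#' `dr = (dt/friction) * F + sqrt(2 kB T dt / friction) * eta` with standard
#' normal `eta` per coordinate; there is no inertial term, so bead masses are
#' not parameters. Defaults give a per-step free-diffusion RMS displacement
#' of ~0.03 Angstrom per coordinate.
#'
#' @param temperature K (default 300).
#' @param friction uniform per-bead friction coefficient, 1/ps (default 20).
#' @param timestep ps (default 0.015).
#' @param bias_frequency steps between accept/reject checkpoints
#'   (default 10).
#' @param convergence_rmsd stop when the matched-residue RMSD to the target
#'   (after superposition) falls to this value, Angstrom (default 1).
#' @param gamma_epsilon stop when the progress variable falls to this floor,
#'   Angstrom^2 (default 0.01).
#' @param max_checkpoints checkpoint budget (default 300000).
#' @param frame_stride accepted checkpoints per saved frame (default 10).
#' @param rebuild_every rebuild the pair list every this many accepted
#'   checkpoints (default 25); a rebuild is also forced whenever any bead has
#'   moved more than a quarter of the cutoff since the last build.
#' @param adapt_after shrink the integration step after this many
#'   consecutive rejected checkpoints (default 50). A rejection streak of
#'   this length signals that the per-segment diffusion is too coarse for
#'   the remaining distance mismatch, so strict-decrease acceptance would
#'   otherwise starve; the step is multiplied by `adapt_factor` (noise by
#'   its square root, i.e. proper Brownian dynamics at a finer timestep) and
#'   gently restored by `recover_factor` on each acceptance, never above the
#'   nominal `timestep` nor below `timestep * min_step_scale`.
#' @param adapt_factor multiplicative step shrink (default 0.6).
#' @param recover_factor multiplicative step recovery per acceptance
#'   (default 1.05).
#' @param min_step_scale floor of the step controller, as a fraction of the
#'   nominal timestep (default 1/1024).
#' @param seed RNG seed used by [run_transition()] (default 1).
#' @return a list of class `bd_params`.
#' @export
bd_params <- function(temperature = 300, friction = 20, timestep = 0.015,
                      bias_frequency = 10, convergence_rmsd = 1,
                      gamma_epsilon = 0.01, max_checkpoints = 300000,
                      frame_stride = 10, rebuild_every = 25,
                      adapt_after = 50, adapt_factor = 0.6,
                      recover_factor = 1.05, min_step_scale = 1 / 1024,
                      seed = 1) {
  p <- list(temperature = temperature, friction = friction,
            timestep = timestep,
            bias_frequency = as.integer(bias_frequency),
            convergence_rmsd = convergence_rmsd,
            gamma_epsilon = gamma_epsilon,
            max_checkpoints = as.integer(max_checkpoints),
            frame_stride = as.integer(frame_stride),
            rebuild_every = as.integer(rebuild_every),
            adapt_after = as.integer(adapt_after),
            adapt_factor = adapt_factor,
            recover_factor = recover_factor,
            min_step_scale = min_step_scale,
            seed = as.integer(seed))
  if (p$adapt_after < 1L || p$adapt_factor <= 0 || p$adapt_factor >= 1 ||
      p$recover_factor < 1 || p$min_step_scale <= 0 || p$min_step_scale > 1)
    stop("invalid step-controller parameters", call. = FALSE)
  for (nm in c("temperature", "friction", "timestep", "convergence_rmsd",
               "gamma_epsilon"))
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0 ||
        (p[[nm]] <= 0 && !nm %in% c("temperature")))
      stop("bd parameter `", nm, "` must be positive", call. = FALSE)
  if (p$bias_frequency < 1L)
    stop("bias_frequency must be >= 1", call. = FALSE)
  if (p$max_checkpoints < 1L || p$frame_stride < 1L || p$rebuild_every < 1L)
    stop("max_checkpoints, frame_stride and rebuild_every must be >= 1",
         call. = FALSE)
  structure(p, class = "bd_params")
}

bd_mobility <- function(params) params$timestep / params$friction

bd_noise_sd <- function(params)
  sqrt(2 * KB_KCAL * params$temperature * params$timestep / params$friction)

#' Target pairwise distances for the biasing progress variable
#'
#' Builds the pair set over which the progress variable is evaluated, with
#' the distances those pairs have in the target conformation. Pairs are drawn
#' only from residues matched between the two end states. The default scope
#' is every matched pair (the full double sum); a cutoff-restricted scope
#' (pairs proximal in either end state) is available for very large systems.
#'
#' @param start,target [calpha_model()]s.
#' @param map optional [match_residues()] result (computed if missing).
#' @param scope `"all"` or `"cutoff"`.
#' @param cutoff Angstrom, used when `scope = "cutoff"` (default 8).
#' @return a list of class `target_distances`: `i`, `j` (bead indices in the
#'   start model), `d_t` (target distances), `matched` (bead indices of the
#'   start model that have a partner), `scope`.
#' @export
target_distances <- function(start, target, map = NULL,
                             scope = c("all", "cutoff"), cutoff = 8) {
  scope <- match.arg(scope)
  if (is.null(map)) map <- match_residues(start, target)
  mp <- map$matched_pairs
  m <- nrow(mp)
  if (m < 2L)
    stop("need at least 2 matched residues to define a progress variable",
         call. = FALSE)
  if (scope == "all") {
    cmb <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    ai <- cmb[, "row"]; aj <- cmb[, "col"]
  } else {
    ps <- cpp_pairs_within_cutoff(start$xyz[mp[, 1L], , drop = FALSE],
                                  cutoff)
    pt <- cpp_pairs_within_cutoff(target$xyz[mp[, 2L], , drop = FALSE],
                                  cutoff)
    key <- sort(unique(c((ps$i - 1) * m + ps$j, (pt$i - 1) * m + pt$j)))
    aj <- as.integer((key - 1L) %% m + 1L)
    ai <- as.integer((key - aj) %/% m + 1L)
  }
  d_t <- pair_distances(target$xyz, mp[ai, 2L], mp[aj, 2L])
  structure(
    list(i = mp[ai, 1L], j = mp[aj, 1L], d_t = d_t,
         matched = mp[, 1L], matched_target = mp[, 2L], scope = scope),
    class = "target_distances")
}

#' Progress variable toward the target
#'
#' The sum over biased pairs of squared differences between current and
#' target distances, in Angstrom^2. It depends only on internal distances,
#' so it is invariant under any rigid-body transformation of either
#' conformation.
#'
#' @param positions N x 3 matrix or [calpha_model()] (start-model indexing).
#' @param target a [target_distances()] object.
#' @return scalar Gamma in Angstrom^2.
#' @export
progress_variable <- function(positions, target) {
  xyz <- if (inherits(positions, "calpha_model")) positions$xyz
         else as.matrix(positions)
  d_s <- pair_distances(xyz, target$i, target$j)
  sum((d_s - target$d_t)^2)
}

#' Initial sampler state
#'
#' @param positions N x 3 start coordinates.
#' @param gamma initial progress-variable value.
#' @return a list of class `sampler_state`.
#' @export
sampler_state <- function(positions, gamma = Inf) {
  structure(
    list(positions = as.matrix(positions), step = 0L,
         last_accepted_positions = as.matrix(positions),
         last_accepted_gamma = gamma, checkpoint_count = 0L),
    class = "sampler_state")
}

#' One overdamped Brownian-dynamics step (reference implementation)
#'
#' Pure-R position update `dr = (dt/friction) * F + noise`. Noise is drawn from
#' R's global RNG as a single `rnorm(3N)` block laid out column-wise
#' (x, then y, then z), the same stream the compiled segment integrator
#' consumes, so the two engines follow the same noise realization at a fixed
#' seed (positions agree to floating-point round-off).
#'
#' @param state a [sampler_state()].
#' @param topology a `spring_topology`.
#' @param params a [bd_params()].
#' @return the updated state.
#' @export
bd_step <- function(state, topology, params) {
  xyz <- state$positions
  f <- compute_forces(topology, xyz)
  if (!all(is.finite(f)))
    stop("non-finite force at bead ",
         which(!is.finite(rowSums(f)))[1L], call. = FALSE)
  n <- nrow(xyz)
  eta <- matrix(rnorm(3L * n), n, 3L)
  xyz <- xyz + bd_mobility(params) * f + bd_noise_sd(params) * eta
  if (!all(is.finite(xyz)))
    stop("non-finite position at bead ",
         which(!is.finite(rowSums(xyz)))[1L], call. = FALSE)
  state$positions <- xyz
  state$step <- state$step + 1L
  state
}

#' Importance-sampling checkpoint: accept or reject the last segment
#'
#' Compares the current progress variable to the last accepted one. Strictly
#' smaller: the conformation is accepted and stored. Otherwise (including
#' exact ties) the coordinates are rolled back to the last accepted ones; the
#' RNG is left untouched, so the next segment uses fresh noise.
#'
#' @param state a [sampler_state()].
#' @param target a [target_distances()] object.
#' @return list with `state` and `accepted` (logical), plus the evaluated
#'   `gamma`.
#' @export
dims_checkpoint <- function(state, target) {
  gamma_s <- progress_variable(state$positions, target)
  accepted <- gamma_s < state$last_accepted_gamma
  if (accepted) {
    state$last_accepted_positions <- state$positions
    state$last_accepted_gamma <- gamma_s
  } else {
    state$positions <- state$last_accepted_positions
  }
  state$checkpoint_count <- state$checkpoint_count + 1L
  list(state = state, accepted = accepted, gamma = gamma_s)
}

# RMSD to target over matched residues, after optimal superposition when
# at least 3 non-collinear matched beads exist (translation-only otherwise).
matched_rmsd_to_target <- function(xyz, target_xyz, target) {
  a <- xyz[target$matched, , drop = FALSE]
  b <- target_xyz[target$matched_target, , drop = FALSE]
  if (nrow(a) >= 3L) {
    fit <- try(kabsch_superpose(a, b), silent = TRUE)
    if (!inherits(fit, "try-error")) return(fit$rmsd)
  }
  ac <- sweep(a, 2L, colMeans(a)); bc <- sweep(b, 2L, colMeans(b))
  sqrt(mean(rowSums((ac - bc)^2)))
}

#' Sample a conformational transition between two end states
#'
#' Drives the start conformation toward the target with elastic-network
#' Brownian dynamics and importance sampling: segments of `bias_frequency`
#' BD steps are accepted only when they strictly decrease the pairwise
#' distance progress variable. The pair list is rebuilt on its schedule as
#' the structure deforms. Residues present in only one end state carry no
#' bias terms and fluctuate freely under the network and thermal noise.
#' The run stops when the matched-residue RMSD to the target falls to
#' `convergence_rmsd`, when the progress variable falls to `gamma_epsilon`,
#' or when the checkpoint budget is exhausted. Runs are exactly reproducible
#' from the seed.
#'
#' @param start,target [calpha_model()]s (matched by residue key).
#' @param enm an [enm_params()].
#' @param bd a [bd_params()].
#' @param rigid_blocks list of bead-index vectors (indices into `start`), or
#'   character selectors resolved via [rigid_block_indices()].
#' @param gamma_scope `"all"` (every matched pair, the default) or
#'   `"cutoff"`.
#' @param engine `"cpp"` (compiled inner loop, the default) or `"r"` (pure-R
#'   reference). Both consume the RNG identically and each is exactly
#'   reproducible from the seed; across engines, trajectories agree to
#'   floating-point round-off (force summation order differs).
#' @param seed overrides `bd$seed` when given.
#' @return an object of class `transition_path`: `frames` (accepted
#'   checkpoints at `frame_stride`, always including the start and the final
#'   state), `gamma` and `rmsd_to_target` per frame, `converged`,
#'   `termination_reason` (`"rmsd"`, `"gamma"` or `"budget"`), and `log`
#'   (one row per checkpoint: step, gamma, accepted, rmsd).
#' @export
run_transition <- function(start, target, enm = enm_params(),
                           bd = bd_params(), rigid_blocks = NULL,
                           gamma_scope = c("all", "cutoff"),
                           engine = c("cpp", "r"), seed = NULL) {
  gamma_scope <- match.arg(gamma_scope)
  engine <- match.arg(engine)
  if (!is.null(seed)) bd$seed <- as.integer(seed)
  if (is.character(rigid_blocks))
    rigid_blocks <- lapply(rigid_blocks, rigid_block_indices, model = start)

  map <- match_residues(start, target)
  if (nrow(map$matched_pairs) == 0L)
    stop("no residues match between start and target", call. = FALSE)
  tg <- target_distances(start, target, map, scope = gamma_scope,
                         cutoff = enm$cutoff)

  set.seed(bd$seed)
  topo <- build_topology(start, enm, rigid_blocks)
  mu <- bd_mobility(bd)
  nsd <- bd_noise_sd(bd)
  k <- bd$bias_frequency

  pos <- start$xyz
  gamma0 <- progress_variable(pos, tg)
  rmsd0 <- matched_rmsd_to_target(pos, target$xyz, tg)

  frames <- list(pos)
  frame_gamma <- gamma0
  frame_rmsd <- rmsd0
  accepted_count <- 0L
  gamma_prev <- gamma0
  rmsd_cur <- rmsd0
  last_build_pos <- pos
  move_limit <- enm$cutoff * 0.25

  converged <- FALSE
  reason <- "budget"
  if (rmsd0 <= bd$convergence_rmsd) { converged <- TRUE; reason <- "rmsd" }
  if (!converged && gamma0 <= bd$gamma_epsilon) {
    converged <- TRUE; reason <- "gamma"
  }

  cp <- 0L
  block_gammas <- list()
  block_accept <- list()
  block_gacc <- list()
  block_rmsd <- list()
  block_scale <- list()
  nb <- 0L
  scale <- 1
  while (!converged && cp < bd$max_checkpoints) {
    budget <- min(bd$adapt_after, bd$max_checkpoints - cp)
    mu_s <- mu * scale
    nsd_s <- nsd * sqrt(scale)
    if (engine == "cpp") {
      res <- cpp_run_until_accept(pos, topo$pairs$i, topo$pairs$j,
                                  topo$pairs$k, topo$pairs$d0,
                                  tg$i, tg$j, tg$d_t, mu_s, nsd_s, k,
                                  gamma_prev, budget)
    } else {
      bd_s <- bd
      bd_s$timestep <- bd$timestep * scale
      gam <- numeric(0)
      acc <- FALSE
      trials <- 0L
      while (!acc && trials < budget) {
        trials <- trials + 1L
        st <- sampler_state(pos)
        for (s in seq_len(k)) st <- bd_step(st, topo, bd_s)
        g <- progress_variable(st$positions, tg)
        gam <- c(gam, g)
        if (g < gamma_prev) acc <- TRUE
      }
      res <- list(positions = if (acc) st$positions else pos,
                  accepted = acc, trials = trials, gammas = gam,
                  gamma_new = if (acc) gam[trials] else gamma_prev)
    }
    if (res$trials == 0L) break
    if (res$accepted) {
      scale <- min(scale * bd$recover_factor, 1)
    } else if (res$trials == bd$adapt_after) {
      scale <- max(scale * bd$adapt_factor, bd$min_step_scale)
    }
    if (any(!is.finite(res$gammas)))
      stop("progress variable diverged (non-finite) near checkpoint ",
           cp + res$trials, call. = FALSE)
    cp <- cp + res$trials
    accepted_flags <- c(rep(FALSE, res$trials - 1L), res$accepted)
    if (res$accepted) {
      pos <- res$positions
      gamma_prev <- res$gamma_new
      accepted_count <- accepted_count + 1L
      rmsd_cur <- matched_rmsd_to_target(pos, target$xyz, tg)
      if (accepted_count %% bd$frame_stride == 0L) {
        frames[[length(frames) + 1L]] <- pos
        frame_gamma <- c(frame_gamma, gamma_prev)
        frame_rmsd <- c(frame_rmsd, rmsd_cur)
      }
      rebuild <- accepted_count %% bd$rebuild_every == 0L ||
        max(abs(pos - last_build_pos)) > move_limit
      if (rebuild) {
        topo <- rebuild_pair_list(topo, pos)
        last_build_pos <- pos
      }
      if (rmsd_cur <= bd$convergence_rmsd) {
        converged <- TRUE; reason <- "rmsd"
      } else if (gamma_prev <= bd$gamma_epsilon) {
        converged <- TRUE; reason <- "gamma"
      }
    }
    nb <- nb + 1L
    block_gammas[[nb]] <- res$gammas
    block_accept[[nb]] <- accepted_flags
    block_gacc[[nb]] <- gamma_prev
    block_rmsd[[nb]] <- rmsd_cur
    block_scale[[nb]] <- scale
  }
  # flatten per-block checkpoint records; rejected checkpoints carry the
  # last accepted Gamma and RMSD forward
  gp_all <- unlist(block_gammas)
  acc_all <- unlist(block_accept)
  log_df <- if (length(gp_all)) {
    lens <- vapply(block_gammas, length, integer(1L))
    acc_g <- unlist(block_gacc)
    acc_r <- unlist(block_rmsd)
    gacc <- rep(NA_real_, length(gp_all))
    rlog <- rep(NA_real_, length(gp_all))
    ends <- cumsum(lens)
    gacc[ends[acc_all[ends]]] <- acc_g[acc_all[ends]]
    rlog[ends[acc_all[ends]]] <- acc_r[acc_all[ends]]
    carry <- function(v, v0) {
      for (t in seq_along(v)) {
        if (is.na(v[t])) v[t] <- v0 else v0 <- v[t]
      }
      v
    }
    data.frame(checkpoint = seq_along(gp_all),
               step = seq_along(gp_all) * k,
               gamma_proposed = gp_all, accepted = acc_all,
               gamma_accepted = carry(gacc, gamma0),
               rmsd_to_target = carry(rlog, rmsd0),
               step_scale = rep(unlist(block_scale), lens))
  } else {
    data.frame(checkpoint = integer(0), step = integer(0),
               gamma_proposed = numeric(0), accepted = logical(0),
               gamma_accepted = numeric(0), rmsd_to_target = numeric(0),
               step_scale = numeric(0))
  }

  # final accepted state is always the last frame
  if (length(frames) == 0L ||
      !isTRUE(all.equal(frames[[length(frames)]], pos)) ) {
    if (frame_gamma[length(frame_gamma)] > gamma_prev) {
      frames[[length(frames) + 1L]] <- pos
      frame_gamma <- c(frame_gamma, gamma_prev)
      frame_rmsd <- c(frame_rmsd, rmsd_cur)
    }
  }

  structure(
    list(frames = lapply(frames, function(x) set_coords(start, x)),
         gamma = frame_gamma, rmsd_to_target = frame_rmsd,
         converged = converged, termination_reason = reason,
         checkpoints = cp, accepted = accepted_count,
         final_rmsd = rmsd_cur, final_gamma = gamma_prev,
         log = log_df, map = map, enm = enm, bd = bd),
    class = "transition_path")
}

#' @export
print.transition_path <- function(x, ...) {
  cat("transition_path:", length(x$frames), "frames,",
      x$checkpoints, "checkpoints (", x$accepted, "accepted )\n",
      " converged:", x$converged, "(", x$termination_reason, ")",
      sprintf(" final RMSD %.3f A, final Gamma %.4g A^2\n",
              x$final_rmsd, x$final_gamma))
  invisible(x)
}

#' Plot the progress of a sampled transition
#'
#' Two stacked panels: the progress variable at accepted checkpoints, and the
#' RMSD to the target, both against checkpoint index.
#'
#' @param x a `transition_path`.
#' @param ... ignored.
#' @export
plot.transition_path <- function(x, ...) {
  lg <- x$log[x$log$accepted, ]
  op <- graphics::par(mfrow = c(2L, 1L), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(lg$checkpoint, lg$gamma_accepted, type = "l", log = "y",
                 xlab = "checkpoint", ylab = "Gamma (A^2)")
  graphics::plot(lg$checkpoint, lg$rmsd_to_target, type = "l",
                 xlab = "checkpoint", ylab = "RMSD to target (A)")
  invisible(x)
}
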