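# Tick-based contagion engine: gender-specific spread along links,
# gender-specific failure to persevere, stopping rules and run summaries.

#' Diffusion parameters
#'
#' @param spread_chance named vector `c(mm=, ff=, mf=)` of per-tick,
#'   per-link transmission probabilities by link gender composition.
#' @param resistance_chance named vector `c(male=, female=)` of
#'   failure-to-persevere probabilities.
#' @param reversion_mode `"per_tick"`: every influenced non-seed agent
#'   independently reverts each tick with its gender's resistance chance.
#'   `"on_influence"`: a newly influenced agent draws persistence once - with
#'   its resistance chance it reverts at the next tick and re-enters
#'   diffusion, otherwise it is permanently persisted.
#' @param seeds_immune seeds never revert (the trained influential agents
#'   are treated as committed).
#' @param max_ticks hard stop.
#' @param equilibrium_window number of trailing ticks over which the
#'   influenced fraction must be quiet to declare equilibrium.
#' @param equilibrium_tol absolute change in influenced fraction (of the
#'   whole population) below which a tick counts as quiet; the default 0.005
#'   is half a percentage point.
#' @return an object of class `diffusion_params`.
#' @export
diffusion_params <- function(spread_chance = c(mm = 0.20, ff = 0.25, mf = 0.10),
                             resistance_chance = c(male = 0.10, female = 0.20),
                             reversion_mode = c("per_tick", "on_influence"),
                             seeds_immune = TRUE,
                             max_ticks = 500,
                             equilibrium_window = 10,
                             equilibrium_tol = 0.005) {
  reversion_mode <- match.arg(reversion_mode)
  for (nm in names(spread_chance)) check_prob(spread_chance[[nm]], paste0("spread_chance$", nm))
  for (nm in names(resistance_chance)) check_prob(resistance_chance[[nm]], paste0("resistance_chance$", nm))
  if (!all(c("mm", "ff", "mf") %in% names(spread_chance)))
    stop_config("spread_chance needs entries mm, ff, mf")
  if (!all(c("male", "female") %in% names(resistance_chance)))
    stop_config("resistance_chance needs entries male, female")
  if (max_ticks < equilibrium_window || equilibrium_window < 1)
    stop_config("need max_ticks >= equilibrium_window >= 1")
  structure(list(spread_chance = spread_chance,
                 resistance_chance = resistance_chance,
                 reversion_mode = reversion_mode, seeds_immune = seeds_immune,
                 max_ticks = max_ticks,
                 equilibrium_window = equilibrium_window,
                 equilibrium_tol = equilibrium_tol),
            class = "diffusion_params")
}

# precompute the flat arrays the tick loop needs
.diffusion_net <- function(net, params) {
  el <- igraph::as_edgelist(net, names = FALSE)
  gender <- igraph::V(net)$gender
  g1 <- gender[el[, 1]]; g2 <- gender[el[, 2]]
  sp <- params$spread_chance
  spread <- ifelse(g1 == "F" & g2 == "F", sp[["ff"]],
                   ifelse(g1 == "M" & g2 == "M", sp[["mm"]], sp[["mf"]]))
  list(n = igraph::vcount(net), el = el, gender = gender,
       log_keep = log1p(-spread),
       resist = ifelse(gender == "F", params$resistance_chance[["female"]],
                       params$resistance_chance[["male"]]))
}

#' Run a diffusion simulation
#'
#' Synchronous tick updates from the tick-start state: each uninfluenced
#' agent is influenced with probability
#' `1 - prod over influenced neighbours (1 - spread_chance[link type])`,
#' then reversion is applied according to the reversion mode. The run stops
#' when the influenced fraction's largest per-tick change over the trailing
#' `equilibrium_window` ticks is below `equilibrium_tol` ("equilibrium"),
#' when every agent is influenced and none can revert ("absorbed"), or at
#' `max_ticks`.
#'
#' @param net igraph network with genders assigned.
#' @param seeds a `seed_set` or integer vector of node ids; seeds start
#'   influenced.
#' @param params a [diffusion_params()].
#' @param seed RNG seed (`NULL`: current stream).
#' @return an object of class `diffusion_trajectory`: a data.frame with
#'   columns `tick`, `n_influenced`, `n_influenced_female`,
#'   `n_influenced_male`, plus attributes `stop_reason`, `n`,
#'   `n_female`, `n_male`, and `final_state` (logical influenced vector).
#' @export
run_diffusion <- function(net, seeds, params = diffusion_params(), seed = NULL) {
  ids <- if (inherits(seeds, "seed_set")) seeds$ids else as.integer(seeds)
  dn <- .diffusion_net(net, params)
  if (length(ids) == 0)
    warning("empty seed set: trajectory stays all-uninfluenced")
  if (any(ids < 1 | ids > dn$n)) stop_config("seed ids out of range")

  with_seed(seed, {
    n <- dn$n
    female <- dn$gender == "F"
    influenced <- rep(FALSE, n); influenced[ids] <- TRUE
    is_seed <- influenced
    persisted <- is_seed & params$seeds_immune
    will_revert <- rep(FALSE, n)
    on_influence <- params$reversion_mode == "on_influence"

    frac <- numeric(params$max_ticks + 1)
    n_inf <- integer(params$max_ticks + 1)
    n_inf_f <- integer(params$max_ticks + 1)
    n_inf[1] <- sum(influenced); n_inf_f[1] <- sum(influenced & female)
    frac[1] <- n_inf[1] / n
    stop_reason <- "max_ticks"; t_stop <- params$max_ticks

    e1 <- dn$el[, 1]; e2 <- dn$el[, 2]; lk <- dn$log_keep
    for (t in seq_len(params$max_ticks)) {
      # infection pressure on uninfluenced endpoints of active edges
      i1 <- influenced[e1]; i2 <- influenced[e2]
      acc <- numeric(n)
      tgt <- c(e1[i2 & !i1], e2[i1 & !i2])
      wts <- c(lk[i2 & !i1], lk[i1 & !i2])
      if (length(tgt)) {
        sums <- rowsum(wts, tgt)
        acc[as.integer(rownames(sums))] <- sums[, 1]
      }
      p_inf <- 1 - exp(acc)
      newly <- !influenced & runif(n) < p_inf

      if (on_influence) {
        revert_now <- will_revert
        draws <- runif(n) < dn$resist
        eligible <- newly & !(is_seed & params$seeds_immune)
        will_revert <- eligible & draws
        persisted <- persisted | (newly & !will_revert)
        influenced <- (influenced & !revert_now) | newly
      } else {
        at_risk <- influenced & !persisted &
          !(is_seed & params$seeds_immune)
        revert_now <- at_risk & runif(n) < dn$resist
        influenced <- (influenced & !revert_now) | newly
      }

      n_inf[t + 1] <- sum(influenced)
      n_inf_f[t + 1] <- sum(influenced & female)
      frac[t + 1] <- n_inf[t + 1] / n

      cannot_revert <- if (on_influence) all(persisted | !influenced)
        else all(dn$resist[influenced & !(is_seed & params$seeds_immune)] == 0)
      if (all(influenced) && cannot_revert) {
        stop_reason <- "absorbed"; t_stop <- t; break
      }
      if (t >= params$equilibrium_window) {
        w <- params$equilibrium_window
        changes <- abs(diff(frac[(t + 1 - w):(t + 1)]))
        if (max(changes) < params$equilibrium_tol) {
          stop_reason <- "equilibrium"; t_stop <- t; break
        }
      }
    }

    traj <- data.frame(tick = 0:t_stop,
                       n_influenced = n_inf[1:(t_stop + 1)],
                       n_influenced_female = n_inf_f[1:(t_stop + 1)],
                       n_influenced_male = n_inf[1:(t_stop + 1)] - n_inf_f[1:(t_stop + 1)])
    attr(traj, "stop_reason") <- stop_reason
    attr(traj, "n") <- n
    attr(traj, "n_female") <- sum(female)
    attr(traj, "n_male") <- n - sum(female)
    attr(traj, "final_state") <- influenced
    class(traj) <- c("diffusion_trajectory", "data.frame")
    traj
  })
}

#' Summarise a diffusion run
#'
#' Diffusion speed is the gain in influenced percentage per tick:
#' `100 * (final fraction - initial fraction) / ticks_elapsed`, with the
#' whole population as denominator for the population speed and each gender
#' subgroup as denominator for the per-gender speeds (both per-gender speeds
#' use the same global `ticks_elapsed`, so the subgroup-share-weighted
#' per-gender speeds recombine exactly to the population speed). Success is
#' either the final influenced percentage (`"final_fraction"`) or a 0/100
#' indicator that the final fraction reached `success_threshold`
#' (`"replicate_threshold"`, to be averaged across replicates).
#'
#' @param traj a `diffusion_trajectory`.
#' @param success_mode `"final_fraction"` or `"replicate_threshold"`.
#' @param success_threshold threshold on the final influenced fraction.
#' @return list with `ticks`, `stop_reason`, `speed` (population, points per
#'   tick), `speed_female`, `speed_male`, `final_fraction`, `success`.
#' @export
summarize_run <- function(traj, success_mode = c("final_fraction",
                                                 "replicate_threshold"),
                          success_threshold = 0.95) {
  success_mode <- match.arg(success_mode)
  ticks <- max(traj$tick)
  if (ticks == 0) stop_config("undefined speed: zero ticks elapsed")
  n <- attr(traj, "n"); nf <- attr(traj, "n_female"); nm <- attr(traj, "n_male")
  first <- traj[1, ]; last <- traj[nrow(traj), ]
  final_fraction <- last$n_influenced / n
  speed <- 100 * (last$n_influenced - first$n_influenced) / n / ticks
  speed_f <- if (nf > 0)
    100 * (last$n_influenced_female - first$n_influenced_female) / nf / ticks
  else 0
  speed_m <- if (nm > 0)
    100 * (last$n_influenced_male - first$n_influenced_male) / nm / ticks
  else 0
  success <- if (success_mode == "final_fraction") 100 * final_fraction
  else 100 * as.numeric(final_fraction >= success_threshold)
  list(ticks = ticks, stop_reason = attr(traj, "stop_reason"),
       speed = speed, speed_female = speed_f, speed_male = speed_m,
       final_fraction = final_fraction, success = success)
}

#' Write a trajectory as CSV
#'
#' Columns `tick`, `n_influenced`, `n_influenced_female`,
#' `n_influenced_male`, `stop_reason` (populated on the last row).
#'
#' @param traj a `diffusion_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)
  df$stop_reason <- c(rep("", nrow(df) - 1), attr(traj, "stop_reason"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
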