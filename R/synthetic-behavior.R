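#' Design of the dynamic temporal prediction (DTP) task schedule
#'
#' A warned reaction-time task in which a warning stimulus is followed,
#' after a short (500 ms), medium (1000 ms) or long (1500 ms)
#' stimulus-onset asynchrony (SOA), by an imperative stimulus. The SOA
#' probability distribution is biased per block type: fast blocks are
#' short-biased (50%, 33.33%, 16.67%), uniform blocks are flat, slow
#' blocks are long-biased (16.67%, 33.33%, 50%). Each block holds 60
#' trials and each block type is delivered three times, for 540 trials
#' in total.
#'
#' @param soa_levels named numeric vector of SOAs in ms
#'   (`short`, `medium`, `long`).
#' @param soa_probabilities named list per block type, each a triple of
#'   probabilities over (short, medium, long) summing to 1; the rounded
#'   per-block trial counts `round(p * per_block_trials)` must sum to
#'   `per_block_trials`.
#' @param per_block_trials trials per block (default 60).
#' @param blocks_per_type repetitions of each block type (default 3).
#' @param iti_range inter-trial-interval range in ms.
#' @param seed integer seed used for schedule randomization.
#' @return Object of class `dtp_design`.
#' @export
dtp_design <- function(soa_levels = c(short = 500, medium = 1000, long = 1500),
                       soa_probabilities = list(
                         fast    = c(0.50, 1 / 3, 1 / 6),
                         uniform = c(1 / 3, 1 / 3, 1 / 3),
                         slow    = c(1 / 6, 1 / 3, 0.50)),
                       per_block_trials = 60L,
                       blocks_per_type = 3L,
                       iti_range = c(600, 1500),
                       seed = 1L) {
  stopifnot(length(soa_levels) == 3, all(soa_levels > 0),
            per_block_trials >= 1, blocks_per_type >= 1,
            length(iti_range) == 2, iti_range[1] <= iti_range[2])
  stopifnot(setequal(names(soa_probabilities), c("fast", "uniform", "slow")))
  for (bt in names(soa_probabilities)) {
    p <- soa_probabilities[[bt]]
    stopifnot(length(p) == 3, all(p >= 0))
    if (abs(sum(p) - 1) > 1e-9)
      stop("SOA probabilities for block type '", bt, "' do not sum to 1")
    counts <- round(p * per_block_trials)
    if (sum(counts) != per_block_trials)
      stop("rounded SOA counts for block type '", bt, "' sum to ",
           sum(counts), ", not ", per_block_trials)
  }
  structure(list(soa_levels = soa_levels,
                 soa_probabilities = soa_probabilities,
                 per_block_trials = as.integer(per_block_trials),
                 blocks_per_type = as.integer(blocks_per_type),
                 iti_range = iti_range,
                 seed = as.integer(seed)),
            class = "dtp_design")
}

#' Parametric reaction-time model for the DTP task
#'
#' Linear-in-SOA-rank RT with a block-type adaptation shift and
#' Gaussian noise, plus Bernoulli premature responses. The shift is
#' `+adaptation_gain / 2` in fast blocks and `-adaptation_gain / 2` in
#' slow blocks, so with `hazard_slope = 0` the downstream fast-minus-slow
#' delta-global RT recovers `adaptation_gain` exactly.
#'
#' @param base_rt mean RT in ms at the medium SOA, no adaptation.
#' @param hazard_slope ms decrease in RT per SOA step (RT falls with
#'   longer foreperiods as conditional expectancy rises).
#' @param adaptation_gain fast-minus-slow block RT shift in ms.
#' @param premature_rate probability of a premature response; scalar or
#'   named triple over block types (`fast`, `uniform`, `slow`).
#' @param rt_noise_sd sd of trial-level RT noise in ms.
#' @return Object of class `behavior_model`.
#' @export
behavior_model <- function(base_rt = 350,
                           hazard_slope = 15,
                           adaptation_gain = -40,
                           premature_rate = 0.03,
                           rt_noise_sd = 60) {
  stopifnot(base_rt > 0, rt_noise_sd >= 0)
  if (length(premature_rate) == 1L)
    premature_rate <- c(fast = premature_rate, uniform = premature_rate,
                        slow = premature_rate)
  stopifnot(setequal(names(premature_rate), c("fast", "uniform", "slow")),
            all(premature_rate >= 0), all(premature_rate < 1))
  structure(list(base_rt = base_rt, hazard_slope = hazard_slope,
                 adaptation_gain = adaptation_gain,
                 premature_rate = premature_rate,
                 rt_noise_sd = rt_noise_sd),
            class = "behavior_model")
}

#' Simulate DTP trial tables for a cohort
#'
#' Builds, per subject, the full 9-block schedule (three fast, three
#' uniform, three slow blocks in subject-random order; per-block SOA
#' counts equal `round(p * 60)`, shuffled within block) and draws RTs
#' and premature responses from the behavior model. Premature trials are
#' assigned an RT below 150 ms.
#'
#' @param design a [dtp_design()].
#' @param model a [behavior_model()].
#' @param n_subjects number of subjects (>= 1).
#' @return data frame with columns `subject`, `block_index`,
#'   `block_type`, `soa_ms`, `rt_ms`, `premature`.
#' @export
simulate_dtp_behavior <- function(design, model, n_subjects = 46L) {
  stopifnot(inherits(design, "dtp_design"),
            inherits(model, "behavior_model"), n_subjects >= 1)
  set.seed(design$seed)
  out <- vector("list", n_subjects)
  types <- rep(names(design$soa_probabilities), design$blocks_per_type)
  for (s in seq_len(n_subjects)) {
    order_s <- sample(types)
    rows <- vector("list", length(order_s))
    for (b in seq_along(order_s)) {
      bt <- order_s[b]
      counts <- round(design$soa_probabilities[[bt]] * design$per_block_trials)
      soa_rank <- sample(rep(1:3, times = counts))
      soa <- design$soa_levels[soa_rank]
      shift <- switch(bt, fast = model$adaptation_gain / 2,
                      slow = -model$adaptation_gain / 2, 0)
      rt <- model$base_rt - model$hazard_slope * (soa_rank - 2) + shift +
        stats::rnorm(length(soa), 0, model$rt_noise_sd)
      prem <- stats::runif(length(soa)) < model$premature_rate[[bt]]
      rt[prem] <- stats::runif(sum(prem), 0, 149)
      rows[[b]] <- data.frame(subject = sprintf("S%03d", s),
                              block_index = b,
                              block_type = bt,
                              soa_ms = as.numeric(soa),
                              rt_ms = rt,
                              premature = prem)
    }
    out[[s]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
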