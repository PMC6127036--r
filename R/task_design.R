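#' Sample block lengths from the task's truncated geometric rule
#'
#' Block lengths follow a geometric distribution (success probability `p`)
#' conditioned on the interval `[min_trials, max_trials]`.
#'
#' @param n number of draws.
#' @param p geometric parameter; the task uses 1/15.
#' @param min_trials,max_trials truncation limits (15 and 42 in the task).
#' @return integer vector of block lengths.
#' @export
sample_block_length <- function(n = 1, p = 1 / 15, min_trials = 15L,
                                max_trials = 42L) {
  stopifnot(n >= 1, p > 0, p <= 1, min_trials <= max_trials)
  support <- min_trials:max_trials
  w <- p * (1 - p)^(support - min_trials)
  if (sum(w) == 0) w[1] <- 1 # p = 1 collapses to the lower truncation
  support[sample.int(length(support), n, replace = TRUE, prob = w)]
}

#' Sample stimulus durations from a truncated exponential
#'
#' Durations have density proportional to `exp(-t / tau)` on `[lo, hi]`.
#' `tau = Inf` gives the uniform limit (used as a degenerate test hook).
#'
#' @param n number of draws.
#' @param tau time constant in seconds (0.6 in the task).
#' @param lo,hi truncation limits in seconds (0.1 and 0.9 in the task).
#' @return numeric vector of durations in seconds.
#' @export
sample_duration <- function(n = 1, tau = 0.6, lo = 0.1, hi = 0.9) {
  stopifnot(n >= 1, tau > 0, lo < hi)
  u <- runif(n)
  if (!is.finite(tau)) return(lo + u * (hi - lo))
  lo - tau * log(1 - u * (1 - exp(-(hi - lo) / tau)))
}

# round half away from zero; the task's base rates and block lengths never
# produce exact .5 fractions, but the convention is fixed for safety
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Assign motion directions within a block
#'
#' Exactly `round(base_rate * n_trials)` trials are rightward; the order is a
#' uniform random permutation. Zero-coherence trials carry a nominal
#' direction too, since the base rate counts all trials.
#'
#' @param n_trials number of trials in the block.
#' @param base_rate one of 0, 0.2, 0.4, 0.6, 0.8, 1.
#' @return character vector of "L"/"R".
#' @export
assign_directions <- function(n_trials, base_rate) {
  if (!base_rate %in% BASE_RATES) {
    stop("invalid design: base_rate must be one of ",
         paste(BASE_RATES, collapse = ", "))
  }
  stopifnot(n_trials >= 1)
  n_r <- round_half_away(base_rate * n_trials)
  sample(c(rep("R", n_r), rep("L", n_trials - n_r)))
}

#' Build the near-balanced coherence list for a block
#'
#' The six magnitudes are repeated up to the first multiple of six strictly
#' larger than `n_trials`, shuffled, and the first `n_trials` values taken.
#'
#' @param n_trials number of trials in the block.
#' @return numeric vector of coherence magnitudes (fractions).
#' @export
build_coherence_list <- function(n_trials) {
  stopifnot(n_trials >= 1)
  m <- floor(n_trials / 6) + 1 # first multiple of six strictly > n_trials
  pool <- rep(COHERENCES, times = m)
  sample(pool)[seq_len(n_trials)]
}

#' Generate one block of the task
#'
#' @param block_id integer block label.
#' @param base_rate block base rate; sampled uniformly from the six values
#'   when `NULL`.
#' @param subject_id subject label.
#' @return a stimulus trial table (one row per trial) with columns
#'   `subject_id`, `block_id`, `trial_index`, `base_rate`,
#'   `coherence_signed`, `duration_s`, `direction`.
#' @export
generate_block <- function(block_id = 1L, base_rate = NULL,
                           subject_id = "s1") {
  if (is.null(base_rate)) base_rate <- sample(BASE_RATES, 1)
  ntr <- sample_block_length(1)
  dir <- assign_directions(ntr, base_rate)
  coh <- build_coherence_list(ntr)
  data.frame(
    subject_id = subject_id,
    block_id = as.integer(block_id),
    trial_index = seq_len(ntr),
    base_rate = base_rate,
    coherence_signed = ifelse(dir == "R", coh, -coh),
    duration_s = sample_duration(ntr),
    direction = dir,
    stringsAsFactors = FALSE
  )
}

#' Generate a full experiment design
#'
#' Blocks are generated from independent per-block random substreams derived
#' from `seed`, so any block can be regenerated on its own and the whole
#' design is reproducible bit-exactly.
#'
#' @param n_blocks number of blocks.
#' @param seed integer seed.
#' @param subject_id subject label.
#' @return a stimulus trial table (class `trial_table`), rows ordered by
#'   block and trial.
#' @export
generate_experiment <- function(n_blocks, seed, subject_id = "s1") {
  stopifnot(n_blocks >= 1)
  set.seed(seed)
  block_seeds <- sample.int(.Machine$integer.max - 1L, n_blocks)
  out <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    set.seed(block_seeds[b])
    out[[b]] <- generate_block(b, subject_id = subject_id)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("trial_table", "data.frame")
  attr(res, "seed") <- seed
  res
}
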