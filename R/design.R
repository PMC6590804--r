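#' Build a session design
#'
#' Lays out one experimental session: a sequence of 20 s holds, each with a
#' single median-nerve stimulus 8-12 s after the hold starts. In the `main`
#' scenario the conditions are hand-to-face positions `p0` (ultrafar, hand on
#' thigh), `p1` (far) and `p2` (near, ~4 cm from the face); in the `control`
#' scenario the arm is held at three angles in a horizontal plane (`a0`,
#' `a45`, `a90`), all equidistant from the face. The sequence is random with
#' exact balance (each label `repetitions` times) and no immediate repetition
#' of a position.
#'
#' @param scenario `"main"` or `"control"`.
#' @param repetitions holds per position (default 50, i.e. 150 holds).
#' @param hold_duration hold length in seconds.
#' @param stimulus_delay_range stimulus latency range (s) after hold onset.
#' @param seed integer RNG seed; the design is deterministic given the seed.
#' @return A `session_design`: data frame with columns `hold`, `position`,
#'   `onset_s`, `stimulus_s`, plus attributes `scenario`, `hold_duration`,
#'   `seed`.
#' @export
build_design <- function(scenario = c("main", "control"), repetitions = 50,
                         hold_duration = 20, stimulus_delay_range = c(8, 12),
                         seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(repetitions >= 1, hold_duration > 0,
            length(stimulus_delay_range) == 2,
            stimulus_delay_range[1] <= stimulus_delay_range[2],
            stimulus_delay_range[2] < hold_duration)
  labels <- scenario_labels(scenario)
  if (length(labels) < 2)
    stop("cannot avoid position repetition with fewer than 2 labels")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  position <- no_repeat_sequence(labels, repetitions)
  n <- length(position)
  onset <- (seq_len(n) - 1) * hold_duration
  delay <- stats::runif(n, stimulus_delay_range[1], stimulus_delay_range[2])
  out <- data.frame(
    hold = seq_len(n),
    position = factor(position, levels = labels),
    onset_s = onset,
    stimulus_s = onset + delay
  )
  structure(out,
            scenario = scenario, hold_duration = hold_duration,
            repetitions = repetitions, seed = as.integer(seed),
            class = c("session_design", "data.frame"))
}

scenario_labels <- function(scenario) {
  switch(scenario,
         main = c("p0", "p1", "p2"),
         control = c("a0", "a45", "a90"),
         stop("unknown scenario: ", scenario))
}

# Random balanced sequence with no adjacent duplicates. Greedy: at each step
# sample (weighted by remaining count) among the labels that differ from the
# previous pick AND leave a completable remainder. A remainder with counts
# `rem` over `m` slots and forbidden first label `p` is completable iff
# max over other labels <= ceil(m/2) and rem[p] <= floor(m/2).
no_repeat_sequence <- function(labels, repetitions) {
  rem <- stats::setNames(rep(repetitions, length(labels)), labels)
  n <- sum(rem)
  feasible <- function(rem, m, prev) {
    if (m == 0) return(TRUE)
    other <- rem[names(rem) != prev]
    (if (length(other)) max(other) else 0) <= ceiling(m / 2) &&
      (!prev %in% names(rem) || rem[[prev]] <= floor(m / 2))
  }
  out <- character(n)
  prev <- ""
  for (i in seq_len(n)) {
    cand <- names(rem)[rem > 0 & names(rem) != prev]
    cand <- cand[vapply(cand, function(c) {
      r2 <- rem; r2[c] <- r2[c] - 1
      feasible(r2, n - i, c)
    }, logical(1))]
    if (!length(cand)) stop("no admissible label sequence exists")
    pick <- if (length(cand) == 1) cand else sample(cand, 1, prob = rem[cand])
    out[i] <- pick
    rem[pick] <- rem[pick] - 1
    prev <- pick
  }
  out
}

# save/restore the global RNG state so seeded helpers do not disturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.session_design <- function(x, ...) {
  cat(sprintf("<session_design> scenario=%s, %d holds (%d per position), hold=%gs\n",
              attr(x, "scenario"), nrow(x), attr(x, "repetitions"),
              attr(x, "hold_duration")))
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}
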