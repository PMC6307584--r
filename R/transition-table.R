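# Shared low-level event-structure builder. Works on bare vectors so the
# bootstrap can avoid data-frame overhead in its resampling loop.
#
# Tie conventions, applied at every event time u:
#   * 0->1 entries are processed before 1->2 exits, and all transitions
#     before censorings;
#   * a patient with t_intervention == t_end spends an infinitesimal sojourn
#     in state 1 before leaving it.
# Consequently y1(u) counts patients at risk in state 1 immediately after
# the 0->1 entries at u (it gains exactly d01(u) relative to the risk set
# just before u), and d12(u) <= y1(u) always holds.
transition_counts <- function(t_int, t_end, discharged) {
  has_int <- !is.na(t_int)
  # exit time from state 0: intervention if any, otherwise end of follow-up
  t_exit0 <- ifelse(has_int, t_int, t_end)
  times <- sort(unique(c(t_int[has_int], t_end)))
  K <- length(times)

  count_at <- function(x) {
    if (length(x) == 0) return(integer(K))
    tabulate(match(x, times), nbins = K)
  }
  d01 <- count_at(t_int[has_int])
  d02 <- count_at(t_end[discharged & !has_int])
  d12 <- count_at(t_end[discharged & has_int])
  c0 <- count_at(t_end[!discharged & !has_int])
  c1 <- count_at(t_end[!discharged & has_int])

  n <- length(t_end)
  # risk sets: y0 just before u; y1 after the 0->1 entries at u
  y0 <- n - findInterval(times, sort(t_exit0), left.open = TRUE)
  y1 <- findInterval(times, sort(t_int[has_int])) -
    findInterval(times, sort(t_end[has_int]), left.open = TRUE)

  list(times = times, d01 = d01, d02 = d02, d12 = d12,
       c0 = c0, c1 = c1, y0 = y0, y1 = y1, n = n)
}

#' Build the transition table of the three-state model
#'
#' Tabulates, at every distinct event time, the observed transition counts
#' (`d01` entries into the intermediate state, `d02` discharges from the
#' initial state, `d12` discharges from the intermediate state), censoring
#' counts per state (`c0`, `c1`), and the risk sets `y0` and `y1`. These are
#' the sufficient statistics for the Aalen-Johansen estimator.
#'
#' Ties are resolved with the convention that 0 to 1 entries precede 1 to 2
#' exits, which precede censorings; `y1` therefore already includes patients
#' entering the intermediate state at that same time, so a same-day
#' intervention-and-discharge patient contributes a momentary state-1
#' sojourn rather than an undefined hazard.
#'
#' @param records A patient tibble (see [validate_patients()], which is
#'   applied first).
#' @return A tibble of class `transition_table` with one row per distinct
#'   event time and columns `time, d01, d02, d12, c0, c1, y0, y1`; the
#'   number of patients is attached as attribute `n_patients`.
#' @export
build_transition_table <- function(records) {
  records <- validate_patients(records)
  tc <- transition_counts(records$t_intervention, records$t_end, records$discharged)
  out <- tibble::tibble(
    time = tc$times, d01 = tc$d01, d02 = tc$d02, d12 = tc$d12,
    c0 = tc$c0, c1 = tc$c1, y0 = tc$y0, y1 = tc$y1
  )
  attr(out, "n_patients") <- tc$n
  class(out) <- c("transition_table", class(out))
  out
}
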