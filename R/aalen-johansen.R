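# Per-event-time increment matrices of the product-integral estimator.
# Under the tie convention the increment at u factorises into a state-0
# stage (0->1, 0->2 at hazards d01/y0, d02/y0) followed by a state-1 stage
# (1->2 at hazard d12/y1, with y1 already including same-time entrants);
# multiplying the stages gives row 0 = [1-h01-h02, h01(1-h12), h02+h01*h12]
# and row 1 = [0, 1-h12, h12]. With distinct continuous event times this
# reduces exactly to the classical Aalen-Johansen increment. An empty risk
# set contributes the identity.
increment_entries <- function(tab) {
  h01 <- ifelse(tab$y0 > 0, tab$d01 / tab$y0, 0)
  h02 <- ifelse(tab$y0 > 0, tab$d02 / tab$y0, 0)
  h12 <- ifelse(tab$y1 > 0, tab$d12 / tab$y1, 0)
  list(
    h01 = h01, h02 = h02, h12 = h12,
    m00 = 1 - h01 - h02,
    m01 = h01 * (1 - h12),
    m02 = h02 + h01 * h12,
    m11 = 1 - h12,
    m12 = h12
  )
}

#' Aalen-Johansen transition probabilities of the three-state model
#'
#' Estimates the matrix of transition probabilities `P(s, t)` of the
#' admission / intermediate-event / discharge model as the finite product
#' over observed event times `u` in `(s, t]` of the increment matrices
#' `I + dA(u)`, where the off-diagonal increments are the empirical hazards
#' `d01/y0`, `d02/y0`, `d12/y1` and the diagonal makes each row sum to one.
#' Event times with an empty risk set contribute the identity.
#'
#' @param table A [build_transition_table()] result.
#' @param s Origin time (days from admission), `s >= 0`. If `s` is at or
#'   beyond the last event time the grid degenerates to the identity and a
#'   message flags it.
#' @return A tibble of class `transition_probabilities` with one row per
#'   grid time `t` (the origin `s` first) and columns
#'   `time, p00, p01, p02, p11, p12`. Rows of the underlying matrix not
#'   shown are structural: `p10 = p20 = p21 = 0`, `p22 = 1`. The origin is
#'   attached as attribute `s`.
#' @export
aalen_johansen <- function(table, s = 0) {
  if (!inherits(table, "transition_table")) {
    abort_bad_param("`table` must be created by build_transition_table().")
  }
  check_number(s, "s", lower = 0)
  keep <- table$time > s
  if (!any(keep)) {
    inform(sprintf(
      "Origin s = %s is at or beyond the last event time; returning an identity grid.", s))
    out <- tibble::tibble(time = s, p00 = 1, p01 = 0, p02 = 0, p11 = 1, p12 = 0)
    attr(out, "s") <- s
    class(out) <- c("transition_probabilities", class(out))
    return(out)
  }
  tab <- table[keep, ]
  en <- increment_entries(tab)
  K <- nrow(tab)
  p00 <- p01 <- p02 <- p11 <- p12 <- numeric(K)
  cur <- c(1, 0, 0, 1, 0) # p00, p01, p02, p11, p12
  for (k in seq_len(K)) {
    cur <- c(
      cur[1] * en$m00[k],
      cur[1] * en$m01[k] + cur[2] * en$m11[k],
      cur[1] * en$m02[k] + cur[2] * en$m12[k] + cur[3],
      cur[4] * en$m11[k],
      cur[4] * en$m12[k] + cur[5]
    )
    p00[k] <- cur[1]; p01[k] <- cur[2]; p02[k] <- cur[3]
    p11[k] <- cur[4]; p12[k] <- cur[5]
  }
  out <- tibble::tibble(
    time = c(s, tab$time),
    p00 = c(1, p00), p01 = c(0, p01), p02 = c(0, p02),
    p11 = c(1, p11), p12 = c(0, p12)
  )
  attr(out, "s") <- s
  class(out) <- c("transition_probabilities", class(out))
  out
}

#' Expected length of stay given the state occupied at time s
#'
#' Integrates the estimated probability of still being in hospital,
#' `P_j0(s, u) + P_j1(s, u)`, over the grid as a right-continuous step
#' function from `s` to the horizon `tau`, and adds the `s` days already
#' spent: `e_j(s) = s + sum_k (u_{k+1} - u_k) [P_j0(s, u_k) + P_j1(s, u_k)]`
#' over grid points in `[s, tau)`.
#'
#' @param P A [aalen_johansen()] result.
#' @param s Origin time; defaults to the origin stored in `P`.
#' @param j State occupied at `s`: 0 (in hospital, pre-event) or 1 (in
#'   hospital, post-event). State 2 is rejected: expected LOS conditional on
#'   already being discharged is not part of the estimand.
#' @param tau Integration horizon in days, `tau >= s`.
#' @return Expected length of stay in days.
#' @export
expected_los_given_state <- function(P, s = attr(P, "s"), j, tau) {
  if (!inherits(P, "transition_probabilities")) {
    abort_bad_param("`P` must be created by aalen_johansen().")
  }
  if (!j %in% c(0, 1)) {
    abort("`j` must be state 0 or 1; expected LOS is undefined for the discharged state.",
          class = "bedrelease_error_state")
  }
  check_number(s, "s", lower = 0)
  check_number(tau, "tau", lower = s)
  if (tau == s) return(s)
  keep <- P$time >= s & P$time < tau
  if (!any(keep)) {
    # the whole grid lies at or beyond tau: occupancy is 1 up to the horizon
    return(s + (tau - s))
  }
  u <- P$time[keep]
  in_hospital <- if (j == 0) P$p00[keep] + P$p01[keep] else P$p11[keep]
  s + sum(diff(c(u, tau)) * in_hospital)
}
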