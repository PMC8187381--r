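#' Reputation as perceived by an observer
#'
#' An unfused observer (`f_observer = 0`) sees only the target's personal
#' reputation. A fused observer sees the target's integrated reputation:
#' the convex combination of the target's personal reputation and the
#' shared group reputation, weighted by the target's own fusion level,
#' `(1 - f_target) * r_target + f_target * r_group`.
#'
#' @param f_observer Observer's fusion level in `[0, 1]`.
#' @param f_target Target's fusion level in `[0, 1]`.
#' @param r_target Target's personal reputation (integer in `[-5, 5]`).
#' @param r_group Shared group reputation (integer in `[-5, 5]`).
#' @return The perceived (real-valued) reputation, always within
#'   `[min(r_target, r_group), max(r_target, r_group)]` for a fused
#'   observer. Vectorised over all arguments.
#' @examples
#' perceived_reputation(0.3, 0.5, 4, -2) # 1
#' perceived_reputation(0,   0.9, 3, -5) # 3: unfused observers ignore the group
#' @export
perceived_reputation <- function(f_observer, f_target, r_target, r_group) {
  n <- max(length(f_observer), length(f_target), length(r_target),
           length(r_group))
  out <- rep_len((1 - f_target) * r_target + f_target * r_group, n)
  unfused <- rep_len(f_observer, n) == 0
  out[unfused] <- rep_len(as.numeric(r_target), n)[unfused]
  out
}

#' Classify a social comparison of reputations
#'
#' Compares the donor's view of the potential recipient's reputation with
#' its view of its own. Similarity holds when the two views differ by at
#' most `delta`; otherwise the comparison is upward (recipient viewed as
#' more reputable) or downward. The model fixes `delta = 0`, so similarity
#' means exact equality of the two real-valued views.
#'
#' @param r_self Donor's view of its own reputation.
#' @param r_other Donor's view of the potential recipient's reputation.
#' @param delta Similarity half-width (default 0).
#' @return Character vector with values `"upward"`, `"similar"` or
#'   `"downward"`; exactly one class per comparison.
#' @examples
#' classify_comparison(2, 2)      # "similar"
#' classify_comparison(2, 3)      # "upward"
#' classify_comparison(2.0, 1.5)  # "downward"
#' @export
classify_comparison <- function(r_self, r_other, delta = 0) {
  ifelse(r_other > r_self + delta, "upward",
         ifelse(r_other < r_self - delta, "downward", "similar"))
}

#' Donation decision from action rules
#'
#' An agent's heritable strategy is the binary triple `(s, u, d)`: donate
#' on similarity, on upward comparison, on downward comparison. The
#' decision is the rule bit matching the comparison class; `(1, 1, 0)` is
#' the strategy known to dominate and sustain cooperation when identity is
#' purely personal.
#'
#' @param rule_s,rule_u,rule_d Rule bits in `{0, 1}` (or logical).
#' @param comparison `"similar"`, `"upward"` or `"downward"`.
#' @return Logical: donate?
#' @examples
#' donation_decision(1, 1, 0, "upward")   # TRUE
#' donation_decision(1, 1, 0, "downward") # FALSE
#' @export
donation_decision <- function(rule_s, rule_u, rule_d, comparison) {
  out <- ifelse(comparison == "similar", rule_s,
                ifelse(comparison == "upward", rule_u, rule_d))
  out > 0
}

#' Group contribution ratio
#'
#' The fraction of a fused agent's group-relevant actions this generation
#' that supported the group reputation (donations, counted by `n_pos`) or
#' legitimately spared it (defections on the less reputable and
#' interaction-stage ostracisms, counted by `n_neu`), out of all actions
#' touching the group reputation. Undefined (`NA`) before the agent has
#' acted as a donor: with a zero denominator no contribution evidence
#' exists.
#'
#' @param n_pos,n_neu,n_neg Non-negative action counters.
#' @return Numeric in `[0, 1]`, or `NA_real_` when all counters are zero.
#'   Vectorised.
#' @examples
#' contribution_ratio(3, 1, 1) # 0.8
#' contribution_ratio(0, 0, 0) # NA
#' @export
contribution_ratio <- function(n_pos, n_neu, n_neg) {
  den <- n_pos + n_neu + n_neg
  ifelse(den == 0, NA_real_, (n_pos + n_neu) / den)
}

#' Vicarious hypocrisy judgement
#'
#' A fused observer perceives a fused target as a hypocrite when the
#' target is at least as fused as the observer yet is perceived to
#' contribute less to the group reputation: `f_target >= f_observer` and
#' `ctr_target < ctr_observer`. If either contribution ratio is undefined
#' (`NA`) no judgement is possible and the result is `FALSE`.
#'
#' The judgement is monotone in the target's perceived contribution:
#' raising `ctr_target` with other arguments fixed can only flip a
#' hypocrite to a non-hypocrite, never the reverse.
#'
#' @param f_observer,f_target Fusion levels; callers should ensure both
#'   are positive (only fused agents judge or are judged).
#' @param ctr_observer Observer's own contribution ratio (or `NA`).
#' @param ctr_target Perceived contribution ratio of the target (or `NA`),
#'   possibly already distorted by perception error.
#' @return Logical, vectorised.
#' @examples
#' is_hypocrite(0.4, 0.6, 0.9, 0.5) # TRUE
#' is_hypocrite(0.6, 0.4, 0.9, 0.1) # FALSE: target less fused
#' is_hypocrite(0.4, 0.6, NA, 0.5)  # FALSE: no evidence to compare
#' @export
is_hypocrite <- function(f_observer, f_target, ctr_observer, ctr_target) {
  out <- f_target >= f_observer & ctr_target < ctr_observer
  out & !is.na(out)
}

#' Perception of a contribution ratio under error
#'
#' With probability `e_p` the perceived ratio is replaced by a
#' Uniform(0, 1) draw (mis-information); otherwise the true value passes
#' through unchanged. Replacement applies even when the true ratio is
#' undefined: noise fabricates a value where none exists.
#'
#' Consumes one uniform draw for the error gate, and a second draw only
#' when the gate fires, from the current R RNG stream.
#'
#' @param ctr True contribution ratio, or `NA_real_`.
#' @param e_p Perception error rate in `[0, 1]`.
#' @return Perceived ratio (or `NA_real_` if undefined and not replaced).
#' @export
apply_perception_error <- function(ctr, e_p) {
  if (stats::runif(1) < e_p) stats::runif(1) else ctr
}

#' Hypocrisy check with ostracism gates
#'
#' The full decision of whether an observer ostracises a target, applied
#' per encounter (interaction stage, types 1 and 3) or per candidate
#' (reproduction stage, types 2 and 3). All gates must pass:
#' the observer's fusion reaches the threshold `T`; both parties are
#' fused; a Bernoulli draw with the observer's fusion level as success
#' probability fires (more fused agents check more often); the target,
#' seen through perception error, satisfies the hypocrisy condition; and
#' no execution error intervenes.
#'
#' RNG draw order (one stream, shared with both engines): check gate,
#' perception-error gate (plus replacement value if it fires), execution
#' gate (only reached for a perceived hypocrite).
#'
#' @param f_observer,f_target Fusion levels.
#' @param ctr_observer Observer's true contribution ratio (or `NA`).
#' @param ctr_target Target's true contribution ratio (or `NA`).
#' @param threshold Ostracism threshold `T`.
#' @param e_p,e_x Perception and execution error rates.
#' @return Logical: ostracise the target?
#' @export
check_ostracism <- function(f_observer, f_target, ctr_observer, ctr_target,
                            threshold = 0, e_p = 0, e_x = 0) {
  if (f_observer < threshold || f_observer <= 0 || f_target <= 0) {
    return(FALSE)
  }
  if (stats::runif(1) >= f_observer) {
    return(FALSE)
  }
  perceived <- apply_perception_error(ctr_target, e_p)
  if (!is_hypocrite(f_observer, f_target, ctr_observer, perceived)) {
    return(FALSE)
  }
  stats::runif(1) >= e_x
}

#' Partner selection with in-group mixing
#'
#' With probability `S_i` (the fixed mixing parameter, or the donor's own
#' fusion level under the `"fusion"` policy) the partner is drawn
#' uniformly from the donor's in-group: the other agents whose fusion is
#' at least the donor's. Otherwise -- and as a fallback when the in-group
#' contains no other agent -- the partner is drawn uniformly from the
#' whole population excluding the donor, so a game is always played.
#'
#' Draw order: one uniform for the in-group gate (always consumed, even
#' when `S_i = 0`), then one uniform for the partner index.
#'
#' @param donor Index of the donor (1-based).
#' @param fusion Numeric vector of all agents' fusion levels.
#' @param params A [sim_params()] object (uses `s_policy`).
#' @return Integer index of the selected recipient, never equal to
#'   `donor`.
#' @export
select_partner <- function(donor, fusion, params) {
  n <- length(fusion)
  if (n < 2L) stop("population must contain at least two agents")
  s_i <- s_prob(params, fusion[donor])
  in_group <- stats::runif(1) < s_i
  if (in_group) {
    eligible <- which(fusion >= fusion[donor])
    eligible <- eligible[eligible != donor]
    if (length(eligible) > 0L) {
      return(eligible[1L + floor(stats::runif(1) * length(eligible))])
    }
    # empty in-group: fall through to a global draw
  }
  t <- 1L + floor(stats::runif(1) * (n - 1L))
  if (t >= donor) t + 1L else t
}

#' Assess one donation-game encounter
#'
#' Applies the standing norm to the donor's reputations and transfers
#' payoff, given the donor's decision and its pre-update reputation views.
#' A donation increments the donor's personal reputation and, if the donor
#' is fused, the group reputation. A defection against a recipient viewed
#' as at least as reputable decrements both (personal only, if unfused); a
#' defection against a less reputable recipient is legitimate and changes
#' nothing. A defection forced by interaction-stage ostracism still incurs
#' the personal-reputation penalty when the target is viewed as at least
#' as reputable, but never penalises the group reputation: from the
#' group's perspective that defection is legitimate.
#'
#' Reputation increments saturate at the caps of `[-5, 5]`: an increment
#' at the cap is lost, not banked. Contribution counters accumulate only
#' for fused donors: a donation counts toward `n_pos`, a legitimate or
#' ostracism-forced defection toward `n_neu`, an illegitimate defection
#' toward `n_neg`.
#'
#' @param donated Logical: did the donor donate?
#' @param ostracised Logical: was the defection forced by
#'   interaction-stage ostracism? (`donated` must then be `FALSE`.)
#' @param f_donor Donor's fusion level.
#' @param view_self,view_other Donor's reputation views computed before
#'   any update.
#' @param params A [sim_params()] object (uses `benefit`, `cost`,
#'   `extra_cost`, `threshold`).
#' @return A list with the encounter's consequences: `delta_personal` and
#'   `delta_group`, raw reputation steps in `{-1, 0, 1}` to be applied by
#'   the caller with [clamp_rep()]; `counter`, one of `"pos"`, `"neu"`,
#'   `"neg"`, `"none"`; `payoff_donor` and `payoff_recipient`.
#' @export
assess_interaction <- function(donated, ostracised, f_donor,
                               view_self, view_other, params) {
  stopifnot(!(donated && ostracised))
  fused <- f_donor > 0
  if (donated) {
    d_pers <- 1L
    d_group <- if (fused) 1L else 0L
    counter <- if (fused) "pos" else "none"
    cost <- params$cost +
      if (f_donor >= params$threshold) params$extra_cost else 0
    return(list(delta_personal = d_pers, delta_group = d_group,
                counter = counter,
                payoff_donor = -cost, payoff_recipient = params$benefit))
  }
  penal <- view_other >= view_self
  d_pers <- if (penal) -1L else 0L
  if (ostracised) {
    # legitimate from the group's perspective: no group penalty
    d_group <- 0L
    counter <- if (fused) "neu" else "none"
  } else if (penal) {
    d_group <- if (fused) -1L else 0L
    counter <- if (fused) "neg" else "none"
  } else {
    d_group <- 0L
    counter <- if (fused) "neu" else "none"
  }
  list(delta_personal = d_pers, delta_group = d_group, counter = counter,
       payoff_donor = 0, payoff_recipient = 0)
}

#' Saturating reputation clamp
#'
#' Reputations are integers kept in `[-5, 5]`; steps beyond a cap are
#' lost.
#'
#' @param x Integer reputation value(s) after an unclamped step.
#' @param lo,hi Caps.
#' @return Clamped value(s).
#' @export
clamp_rep <- function(x, lo = -5L, hi = 5L) {
  pmin(hi, pmax(lo, x))
}
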