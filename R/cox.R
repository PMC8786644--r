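#' Cox negative partial log-likelihood
#'
#' Computes the Breslow-style negative partial log-likelihood
#' `-sum_{i: event_i = 1} [ s_i - log sum_{j: T_j >= T_i} exp(s_j) ]`
#' of per-patient linear predictors (risk scores) for right-censored
#' survival data. The risk set at an event time includes ties
#' (`T_j >= T_i`); the log-sum-exp is computed overflow-safely. This is the
#' loss the boosting stage minimizes.
#'
#' @param scores Numeric vector of per-patient linear predictors.
#' @param time Positive survival/censoring times, aligned with `scores`.
#' @param event Event flags (1 = death observed, 0 = censored).
#' @return The scalar loss. Invariant under a constant shift of `scores`.
#' @export
cox_nll <- function(scores, time, event) {
  check_survival_args(scores, time, event)
  ord <- order(time, decreasing = TRUE)
  s <- scores[ord]; tt <- time[ord]; ev <- event[ord]
  m <- max(s)
  prefix <- cumsum(exp(s - m))          # risk-set sums in descending time order
  group_end <- cummax_tail_positions(tt)
  lse <- log(prefix[group_end]) + m
  -sum((s - lse)[ev == 1])
}

#' Gradient and curvature of the Cox loss
#'
#' First and second partial derivatives of [cox_nll()] with respect to each
#' patient's score. Gradients sum to zero (the partial likelihood is
#' invariant under score shifts) and curvatures are nonnegative.
#'
#' @inheritParams cox_nll
#' @return List with numeric vectors `gradient` and `curvature`, aligned with
#'   the input order.
#' @export
cox_gradient_curvature <- function(scores, time, event) {
  check_survival_args(scores, time, event)
  n <- length(scores)
  ord <- order(time, decreasing = TRUE)
  s <- scores[ord]; tt <- time[ord]; ev <- event[ord]
  m <- max(s)
  es <- exp(s - m)
  prefix <- cumsum(es)
  group_end <- cummax_tail_positions(tt)
  rs <- prefix[group_end]               # scaled risk-set sum for each position
  # accumulate sum over events i with T_i <= T_k of 1/R_i (and 1/R_i^2);
  # in descending-time order these are the events at positions >= k's group start
  inv1 <- ifelse(ev == 1, 1 / rs, 0)
  inv2 <- ifelse(ev == 1, 1 / rs^2, 0)
  suf1 <- rev(cumsum(rev(inv1)))
  suf2 <- rev(cumsum(rev(inv2)))
  group_start <- group_start_positions(tt)
  c1 <- suf1[group_start]
  c2 <- suf2[group_start]
  grad <- -ev + es * c1
  curv <- es * c1 - es^2 * c2
  out_g <- numeric(n); out_h <- numeric(n)
  out_g[ord] <- grad
  out_h[ord] <- pmax(curv, 0)
  list(gradient = out_g, curvature = out_h)
}

#' Concordance index for censored survival predictions
#'
#' Fraction of comparable patient pairs whose predicted risk ordering matches
#' the observed survival ordering. An ordered pair (i, j) is comparable when
#' patient i is uncensored and has a strictly shorter survival time than
#' patient j (who may be censored or uncensored); each informative pair is
#' thus counted once, from the side of the earlier event. The numerator
#' counts comparable pairs with `(T_i - T_j) * (risk_j - risk_i) > 0`; ties
#' in predicted risk or equal times contribute 0 (strict inequality). 0.5 is
#' chance level, 1 perfect.
#'
#' @param risks Numeric risk scores (higher = shorter predicted survival).
#' @param time Observed times, aligned with `risks`.
#' @param event Event flags (1 = uncensored).
#' @return The C-index in `[0, 1]`.
#' @export
concordance_index <- function(risks, time, event) {
  stopifnot(length(risks) == length(time), length(time) == length(event),
            all(is.finite(risks)))
  ev <- event == 1
  dT <- outer(time, time, `-`)          # dT[i,j] = T_i - T_j
  comparable <- matrix(ev, length(ev), length(ev)) & dT < 0
  diag(comparable) <- FALSE
  n_comp <- sum(comparable)
  if (n_comp == 0L) stop("no comparable pairs: C-index undefined")
  dR <- outer(risks, risks, `-`)        # dR[i,j] = risk_i - risk_j
  concordant <- (dT * -dR) > 0
  sum(concordant & comparable) / n_comp
}

check_survival_args <- function(scores, time, event) {
  stopifnot(length(scores) == length(time), length(time) == length(event),
            all(is.finite(scores)), all(time > 0), all(event %in% c(0, 1)))
  if (!any(event == 1)) stop("loss undefined: empty event sum (no uncensored patient)")
  invisible(TRUE)
}

# positions of the last member of each tie group, for times sorted descending
cummax_tail_positions <- function(sorted_desc_time) {
  n <- length(sorted_desc_time)
  idx <- seq_len(n)
  last <- ave(idx, sorted_desc_time, FUN = max)
  as.integer(last)
}

# positions of the first member of each tie group, same ordering
group_start_positions <- function(sorted_desc_time) {
  idx <- seq_along(sorted_desc_time)
  as.integer(ave(idx, sorted_desc_time, FUN = min))
}
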