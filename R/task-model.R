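#' Configuration of the norm-compliance punishment game
#'
#' Fixes the economic parameters of the two-player game: both players start
#' with an endowment of 30 points, the proposer additionally receives a 100
#' point pie and transfers 0--50 points (steps of 10) to the responder, who
#' may then spend up to 30 points on punishment. Each point spent removes
#' `punishment_leverage` (default 5) points from the proposer.
#'
#' @param responder_endowment Initial endowment of the responder, in points.
#' @param proposer_endowment Initial endowment of the proposer, in points.
#' @param pie Additional points the proposer can share, in points.
#' @param transfer_levels Admissible transfer amounts, in points.
#' @param punishment_leverage Points removed from the proposer per point the
#'   responder spends on punishment.
#' @param max_punishment Maximum punishment expenditure, in points.
#' @param response_window Response deadline in seconds.
#' @param points_per_chf Conversion rate from points to Swiss francs
#'   (reporting only; no computation depends on it).
#'
#' @return An object of class `task_config`.
#' @export
#' @examples
#' cfg <- task_config()
#' compute_payoffs(20, 0, cfg)
task_config <- function(responder_endowment = 30,
                        proposer_endowment = 30,
                        pie = 100,
                        transfer_levels = seq(0L, 50L, by = 10L),
                        punishment_leverage = 5,
                        max_punishment = 30,
                        response_window = 7,
                        points_per_chf = 100) {
  money <- c(responder_endowment = responder_endowment,
             proposer_endowment = proposer_endowment,
             pie = pie, max_punishment = max_punishment)
  if (any(money < 0) || any(money != round(money))) {
    stop("endowments, pie and max_punishment must be non-negative integers",
         call. = FALSE)
  }
  if (any(transfer_levels < 0) || any(transfer_levels > pie)) {
    stop("transfer_levels must lie within [0, pie]", call. = FALSE)
  }
  if (punishment_leverage < 1) {
    stop("punishment_leverage must be >= 1", call. = FALSE)
  }
  if (response_window <= 0) stop("response_window must be positive", call. = FALSE)
  structure(
    list(responder_endowment = as.integer(responder_endowment),
         proposer_endowment = as.integer(proposer_endowment),
         pie = as.integer(pie),
         transfer_levels = as.integer(sort(unique(transfer_levels))),
         punishment_leverage = punishment_leverage,
         max_punishment = as.integer(max_punishment),
         response_window = response_window,
         points_per_chf = points_per_chf),
    class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("Norm-compliance task configuration\n")
  cat("  endowments (responder / proposer):", x$responder_endowment, "/",
      x$proposer_endowment, "points; pie:", x$pie, "points\n")
  cat("  transfers:", paste(x$transfer_levels, collapse = ", "),
      "| punishment: 0 -", x$max_punishment,
      sprintf("(leverage %g:1)\n", x$punishment_leverage))
  invisible(x)
}

check_transfer <- function(transfer, cfg) {
  if (!all(transfer %in% cfg$transfer_levels)) {
    stop("transfer must be one of {", paste(cfg$transfer_levels, collapse = ", "),
         "}", call. = FALSE)
  }
}

check_punishment <- function(punishment, cfg) {
  ok <- punishment >= 0 & punishment <= cfg$max_punishment &
    punishment == round(punishment)
  if (!all(ok)) {
    stop("punishment must be an integer in [0, ", cfg$max_punishment, "]",
         call. = FALSE)
  }
}

#' Post-punishment payoffs of both players
#'
#' The responder keeps their endowment plus the transfer minus the points spent
#' on punishment. The proposer keeps their endowment plus the unshared part of
#' the pie minus the leveraged punishment, floored at zero.
#'
#' @param transfer Transfer(s) from the proposer, in points.
#' @param punishment Punishment expenditure(s) of the responder, in points.
#' @param cfg A [task_config()].
#'
#' @return A data.frame with columns `payoff_proposer` and `payoff_responder`.
#' @export
#' @examples
#' compute_payoffs(20, 20, task_config())  # proposer 10, responder 30
compute_payoffs <- function(transfer, punishment, cfg = task_config()) {
  check_transfer(transfer, cfg)
  check_punishment(punishment, cfg)
  payoff_responder <- cfg$responder_endowment + transfer - punishment
  payoff_proposer <- pmax(0, cfg$proposer_endowment + (cfg$pie - transfer) -
                            cfg$punishment_leverage * punishment)
  data.frame(payoff_proposer = payoff_proposer,
             payoff_responder = payoff_responder)
}

#' Smallest punishment that drives the proposer's payoff to zero
#'
#' Scans integer punishments 0..`max_punishment` and returns the first at
#' which the proposer's payoff reaches 0, or `NA_integer_` if no admissible
#' punishment reaches it.
#'
#' @inheritParams compute_payoffs
#' @return Integer punishment in points, or `NA_integer_` if unreachable.
#' @export
#' @examples
#' min_punishment_to_zero(20)  # 22
min_punishment_to_zero <- function(transfer, cfg = task_config()) {
  check_transfer(transfer, cfg)
  vapply(transfer, function(t) {
    for (p in 0:cfg$max_punishment) {
      if (compute_payoffs(t, p, cfg)$payoff_proposer == 0) return(p)
    }
    NA_integer_
  }, integer(1))
}

#' Classify the final payoff distribution
#'
#' Advantageous inequality (AI) when the responder ends up with more than the
#' proposer, disadvantageous inequality (DI) when with less, equality (E)
#' otherwise.
#'
#' @param payoff_responder,payoff_proposer Non-negative final payoffs, points.
#' @return A factor with levels `AI`, `E`, `DI`.
#' @export
#' @examples
#' classify_inequality(30, 10)   # AI
#' classify_inequality(50, 110)  # DI
classify_inequality <- function(payoff_responder, payoff_proposer) {
  if (any(payoff_responder < 0) || any(payoff_proposer < 0)) {
    stop("payoffs must be non-negative", call. = FALSE)
  }
  cls <- ifelse(payoff_responder > payoff_proposer, "AI",
                ifelse(payoff_responder < payoff_proposer, "DI", "E"))
  factor(cls, levels = c("AI", "E", "DI"))
}

#' Assemble a trial table from raw responder decisions
#'
#' Computes payoffs and inequality classes for a sequence of
#' (transfer, punishment, RT) decisions of one participant.
#'
#' @param participant_id Scalar participant identifier.
#' @param transfer,punishment Vectors of equal length, in points.
#' @param rt_s Response times in seconds, in (0, response_window].
#' @param cfg A [task_config()].
#' @return A `trial_table` data.frame with one row per trial.
#' @export
make_trial_table <- function(participant_id, transfer, punishment, rt_s,
                             cfg = task_config()) {
  stopifnot(length(transfer) == length(punishment),
            length(transfer) == length(rt_s))
  if (any(rt_s <= 0 | rt_s > cfg$response_window)) {
    stop("rt_s must lie in (0, response_window]", call. = FALSE)
  }
  pay <- compute_payoffs(transfer, punishment, cfg)
  out <- data.frame(
    participant_id = participant_id,
    trial_index = seq_along(transfer),
    transfer = as.integer(transfer),
    punishment = as.integer(punishment),
    rt_s = rt_s,
    payoff_responder = pay$payoff_responder,
    payoff_proposer = pay$payoff_proposer,
    inequality_class = classify_inequality(pay$payoff_responder,
                                           pay$payoff_proposer))
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Read / write trial tables as CSV
#'
#' @param x A `trial_table`.
#' @param path File path.
#' @return `read_trial_table` returns a `trial_table`; `write_trial_table`
#'   returns `path` invisibly.
#' @export
write_trial_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "trial_index", "transfer", "punishment",
              "rt_s", "payoff_responder", "payoff_proposer", "inequality_class")
  missing <- setdiff(needed, names(out))
  if (length(missing)) {
    stop("trial table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out$inequality_class <- factor(out$inequality_class, levels = c("AI", "E", "DI"))
  class(out) <- c("trial_table", "data.frame")
  out
}
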