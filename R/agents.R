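#' Specify a simulated foraging strategy
#'
#' Agents operationalise the candidate decision strategies for the six-disc
#' relative-size task:
#' \describe{
#'   \item{random}{uniform choice among the discs other than the one just
#'     visited (a bee never re-lands immediately on the same disc).}
#'   \item{rule}{follows the relational size rule with bout-dependent
#'     accuracy `p(bout) = p_min + (p_max - p_min)(1 - exp(-rate * bout))`,
#'     a smooth learning ramp; with probability `p(bout)` the agent targets a
#'     disc of the rewarded size class, otherwise the unrewarded class,
#'     uniformly within the class.}
#'   \item{wsls}{win-stay/lose-switch keyed on the outcome of the previous
#'     landing: after a rewarded landing it stays with the same size class,
#'     after an unrewarded one it switches class. The heuristic is followed
#'     with probability `wsls_fidelity`, otherwise the agent explores
#'     uniformly; its first choice of a bout is uninformed (uniform).}
#'   \item{proximity}{always lands on the nearest disc other than the
#'     previous one (ties broken uniformly); first choice uniform.}
#'   \item{hybrid}{rule strategy before `switch_bout`, WSLS from
#'     `switch_bout` onwards.}
#' }
#'
#' In unrewarded test bouts every landing goes unrewarded, so a WSLS agent
#' keeps switching; hybrid agents start a test with WSLS and fall back on
#' their learned rule after `test_revert_after` unrewarded choices.
#'
#' The default `wsls_fidelity = 0.4666` calibrates the agent's expected
#' second-choice accuracy, `(1 + f)/2` on a 6-disc/3-rewarded arena, to the
#' ~73% level typical of late training in this paradigm, implying win-stay
#' and lose-switch conditionals of about 0.68 and 0.79.
#'
#' @param strategy One of `"random"`, `"rule"`, `"wsls"`, `"proximity"`,
#'   `"hybrid"`.
#' @param contingency Which relative size class is rewarded for this agent:
#'   `"larger"` or `"smaller"`.
#' @param rule_accuracy_min,rule_accuracy_max Floor and ceiling of the rule
#'   accuracy ramp (defaults 0.5 and 0.75).
#' @param rule_learning_rate Per-bout rate of the ramp (default 0.15).
#' @param wsls_fidelity Probability a WSLS choice follows the heuristic
#'   (default 0.4666).
#' @param switch_bout First bout at which a hybrid agent uses WSLS
#'   (required for `"hybrid"`, ignored otherwise).
#' @param wsls_memory What the WSLS memory keys on; only `"reward_outcome"`
#'   is implemented (a drained but correct disc counts as a loss).
#' @param test_revert_after Number of unrewarded test choices after which a
#'   hybrid agent reverts to its learned rule (default 5).
#' @return An object of class `agent_spec`.
#' @export
agent_spec <- function(strategy = c("random", "rule", "wsls", "proximity",
                                    "hybrid"),
                       contingency = c("larger", "smaller"),
                       rule_accuracy_min = 0.5, rule_accuracy_max = 0.75,
                       rule_learning_rate = 0.15, wsls_fidelity = 0.4666,
                       switch_bout = NULL,
                       wsls_memory = "reward_outcome",
                       test_revert_after = 5L) {
  strategy <- match.arg(strategy)
  contingency <- match.arg(contingency)
  wsls_memory <- match.arg(wsls_memory)
  for (p in c(rule_accuracy_min, rule_accuracy_max, wsls_fidelity))
    if (!is.finite(p) || p < 0 || p > 1)
      stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (rule_accuracy_max < rule_accuracy_min)
    stop("`rule_accuracy_max` must be >= `rule_accuracy_min`", call. = FALSE)
  if (rule_learning_rate < 0)
    stop("`rule_learning_rate` must be non-negative", call. = FALSE)
  if (strategy == "hybrid") {
    if (is.null(switch_bout) || switch_bout < 1)
      stop("hybrid agents require `switch_bout` >= 1", call. = FALSE)
    switch_bout <- as.integer(switch_bout)
  } else {
    switch_bout <- NULL
  }
  structure(
    list(strategy = strategy, contingency = contingency,
         rule_accuracy_min = rule_accuracy_min,
         rule_accuracy_max = rule_accuracy_max,
         rule_learning_rate = rule_learning_rate,
         wsls_fidelity = wsls_fidelity,
         switch_bout = switch_bout, wsls_memory = wsls_memory,
         test_revert_after = as.integer(test_revert_after)),
    class = "agent_spec")
}

#' Rule accuracy at a given bout
#'
#' The logistic-style learning ramp
#' `p(bout) = p_min + (p_max - p_min)(1 - exp(-rate * bout))`.
#'
#' @param agent An [agent_spec()].
#' @param bout_index Bout number (1-based); vectorised.
#' @return Accuracy in `[p_min, p_max]`.
#' @export
rule_accuracy <- function(agent, bout_index) {
  agent$rule_accuracy_min +
    (agent$rule_accuracy_max - agent$rule_accuracy_min) *
      (1 - exp(-agent$rule_learning_rate * bout_index))
}

# Strategy actually in force for one choice. `phase` distinguishes rewarded
# bouts (training/refresh) from unrewarded tests.
effective_strategy <- function(agent, bout_index, phase, choice_index) {
  testing <- phase %in% c("learning_test", "novel_shape_test",
                          "novel_color_test")
  strat <- agent$strategy
  if (strat == "hybrid") {
    if (testing) {
      if (choice_index <= agent$test_revert_after) "wsls" else "rule"
    } else if (bout_index >= agent$switch_bout) "wsls" else "rule"
  } else {
    strat
  }
}
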