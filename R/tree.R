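#' Branch probability expressions
#'
#' Branch probabilities in the decision tree are either numeric
#' constants or expressions over parameter names restricted to the two
#' forms a diagnostic chance node needs: a parameter itself
#' (`prob_of("p_severe_intervention")`) or its complement
#' (`prob_not("p_severe_intervention")`).  Restricting the expression
#' language keeps validation exact: for any parameter value in
#' \[0, 1\] a complementary branch pair sums to one identically.
#'
#' @param name parameter name.
#' @return a `cea_prob` expression object.
#' @export
prob_of <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  structure(list(param = name, complement = FALSE), class = "cea_prob")
}

#' @rdname prob_of
#' @export
prob_not <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  structure(list(param = name, complement = TRUE), class = "cea_prob")
}

#' Decision-tree node constructors
#'
#' A tree is built from two node kinds: chance nodes, whose branches
#' carry probability expressions and child nodes, and terminal nodes,
#' which carry a cost payoff (USD, either a constant or a parameter
#' name) and an effect payoff (1 for a leaf that counts as a diagnosed
#' severe case under the chosen effect definition, 0 otherwise).
#'
#' @param label node label.
#' @param branches for `chance_node`, a list of [branch()] objects.
#' @param cost for `terminal_node`, numeric constant or parameter name.
#' @param effect for `terminal_node`, 0 or 1.
#' @param prob for `branch`, a numeric constant in \[0, 1\] or a
#'   `cea_prob` expression.
#' @param node for `branch`, the child `cea_node`.
#' @return a `cea_node` (or branch component).
#' @export
chance_node <- function(label, branches) {
  stopifnot(is.list(branches), length(branches) >= 2)
  structure(list(kind = "chance", label = label, branches = branches),
            class = "cea_node")
}

#' @rdname chance_node
#' @export
terminal_node <- function(label, cost, effect) {
  stopifnot(effect %in% c(0, 1))
  structure(list(kind = "terminal", label = label, cost = cost,
                 effect = effect),
            class = "cea_node")
}

#' @rdname chance_node
#' @export
branch <- function(prob, node) {
  stopifnot(inherits(node, "cea_node"))
  if (!inherits(prob, "cea_prob")) {
    stopifnot(is.numeric(prob), length(prob) == 1)
  }
  list(prob = prob, node = node)
}

# evaluate a probability expression or constant against an assignment
eval_prob <- function(prob, assignment) {
  if (inherits(prob, "cea_prob")) {
    val <- assignment[[prob$param]]
    if (is.null(val)) {
      stop("missing parameter '", prob$param, "' in assignment",
           call. = FALSE)
    }
    if (prob$complement) 1 - val else val
  } else {
    prob
  }
}

# evaluate a payoff: numeric constant or parameter name
eval_payoff <- function(x, assignment) {
  if (is.character(x)) {
    val <- assignment[[x]]
    if (is.null(val)) {
      stop("missing parameter '", x, "' in assignment", call. = FALSE)
    }
    val
  } else {
    x
  }
}

# vectorized expected-value recursion; assignment values may be vectors
roll_node <- function(node, assignment, prob_tol = 1e-9) {
  if (node$kind == "terminal") {
    return(list(cost = eval_payoff(node$cost, assignment),
                effect = node$effect))
  }
  probs <- lapply(node$branches, function(b) eval_prob(b$prob, assignment))
  for (p in probs) {
    if (any(p < -prob_tol | p > 1 + prob_tol)) {
      stop("branch probability outside [0, 1] at node '", node$label, "'",
           call. = FALSE)
    }
  }
  total <- Reduce(`+`, probs)
  if (any(abs(total - 1) > prob_tol)) {
    stop("branch probabilities at node '", node$label,
         "' do not sum to 1", call. = FALSE)
  }
  cost <- 0
  effect <- 0
  for (i in seq_along(node$branches)) {
    child <- roll_node(node$branches[[i]]$node, assignment, prob_tol)
    cost <- cost + probs[[i]] * child$cost
    effect <- effect + probs[[i]] * child$effect
  }
  list(cost = cost, effect = effect)
}

#' Build the two-strategy diagnostic decision tree
#'
#' Constructs the canonical model comparing pulse oximetry combined
#' with IMCI (intervention) against IMCI alone (control).  For each
#' strategy a chance node splits children into diagnosed severe (with
#' the arm's proportion) versus diagnosed non-severe; the severe branch
#' then splits into true positives (arm sensitivity) versus false
#' positives, and the non-severe branch into true negatives (arm
#' specificity) versus false negatives.  Severe-diagnosis leaves carry
#' the arm's average severe-case cost, the others its non-severe cost.
#'
#' The effect payoff is 1 on true-positive leaves under the default
#' `"true_positive"` definition, or on every severe-diagnosis leaf
#' under `"any_severe_diagnosis"`; with perfect sensitivity the two
#' definitions coincide.
#'
#' @param params a `cea_parameters` tibble containing, for each arm,
#'   `p_severe_<arm>`, `sens_<arm>`, `spec_<arm>`,
#'   `cost_severe_<arm>` and `cost_nonsevere_<arm>`.
#' @param effect_definition `"true_positive"` (default) or
#'   `"any_severe_diagnosis"`.
#' @return a `cea_model` with one sub-tree per strategy.
#' @examples
#' model <- build_model(default_parameters())
#' rollback(model, base_assignment(default_parameters()))
#' @export
build_model <- function(params,
                        effect_definition = c("true_positive",
                                              "any_severe_diagnosis")) {
  effect_definition <- match.arg(effect_definition)
  needed <- as.vector(outer(
    c("p_severe", "sens", "spec", "cost_severe", "cost_nonsevere"),
    c("intervention", "control"), paste, sep = "_"
  ))
  missing_params <- setdiff(needed, params$name)
  if (length(missing_params) > 0) {
    stop("parameter table is missing: ",
         paste(missing_params, collapse = ", "), call. = FALSE)
  }
  strategy_tree <- function(arm) {
    p_sev <- paste0("p_severe_", arm)
    sens <- paste0("sens_", arm)
    spec <- paste0("spec_", arm)
    c_sev <- paste0("cost_severe_", arm)
    c_non <- paste0("cost_nonsevere_", arm)
    fp_effect <- if (effect_definition == "any_severe_diagnosis") 1 else 0
    chance_node(arm, list(
      branch(prob_of(p_sev), chance_node(
        paste0(arm, ": diagnosed severe"), list(
          branch(prob_of(sens),
                 terminal_node("true_positive", cost = c_sev, effect = 1)),
          branch(prob_not(sens),
                 terminal_node("false_positive", cost = c_sev,
                               effect = fp_effect))
        ))),
      branch(prob_not(p_sev), chance_node(
        paste0(arm, ": diagnosed non-severe"), list(
          branch(prob_of(spec),
                 terminal_node("true_negative", cost = c_non, effect = 0)),
          branch(prob_not(spec),
                 terminal_node("false_negative", cost = c_non, effect = 0))
        )))
    ))
  }
  structure(
    list(
      strategies = list(intervention = strategy_tree("intervention"),
                        control = strategy_tree("control")),
      effect_definition = effect_definition
    ),
    class = "cea_model"
  )
}

#' Roll back expected cost and effect
#'
#' Computes, for each strategy (or for a single node), the expectation
#' of the cost and effect payoffs over the mutually exclusive root-to-
#' leaf paths: `sum over paths of P(path) * payoff`.  Branch
#' probabilities are validated against the assignment (each in
#' \[0, 1\], each chance node summing to 1).
#'
#' @param x a `cea_model` or a `cea_node`.
#' @param assignment named list of parameter values (scalars).
#' @param ... unused.
#' @return tibble with columns `strategy`, `cost`, `effect`.
#' @export
rollback <- function(x, assignment, ...) UseMethod("rollback")

#' @rdname rollback
#' @export
rollback.cea_model <- function(x, assignment, ...) {
  rows <- lapply(names(x$strategies), function(s) {
    res <- roll_node(x$strategies[[s]], assignment)
    tibble::tibble(strategy = s, cost = res$cost, effect = res$effect)
  })
  do.call(rbind, rows)
}

#' @rdname rollback
#' @export
rollback.cea_node <- function(x, assignment, ...) {
  res <- roll_node(x, assignment)
  tibble::tibble(strategy = x$label, cost = res$cost, effect = res$effect)
}

#' Incremental cost-effectiveness of one strategy over another
#'
#' Computes the cost and effect differences and, when the effect
#' difference is non-zero, the incremental cost-effectiveness ratio
#' (ICER, USD per extra diagnosed severe case).  The qualitative status
#' distinguishes the sign cases: `"icer"` (a meaningful ratio),
#' `"dominant"` (comparator cheaper and more effective), `"dominated"`
#' (comparator costlier and less effective), and `"equal_effect"`
#' (no effect difference, so no ratio).
#'
#' @param outcomes rollback result (tibble with `strategy`, `cost`,
#'   `effect`) containing both strategies.
#' @param comparator strategy evaluated against the reference.
#' @param reference baseline strategy.
#' @return a `cea_incremental` list: `delta_cost`, `delta_effect`,
#'   `icer` (NA when undefined), `status`.
#' @export
incremental <- function(outcomes, comparator = "intervention",
                        reference = "control") {
  stopifnot(all(c(comparator, reference) %in% outcomes$strategy))
  comp <- outcomes[outcomes$strategy == comparator, ]
  ref <- outcomes[outcomes$strategy == reference, ]
  dc <- comp$cost - ref$cost
  de <- comp$effect - ref$effect
  if (de == 0) {
    status <- "equal_effect"
    icer <- NA_real_
  } else {
    icer <- dc / de
    status <- if (dc < 0 && de > 0) {
      "dominant"
    } else if (dc > 0 && de < 0) {
      "dominated"
    } else {
      "icer"
    }
  }
  structure(
    list(comparator = comparator, reference = reference,
         delta_cost = dc, delta_effect = de, icer = icer, status = status),
    class = "cea_incremental"
  )
}

#' @export
print.cea_incremental <- function(x, ...) {
  cat(sprintf("Incremental result (%s vs %s):\n", x$comparator, x$reference))
  cat(sprintf("  delta cost   %8.4f USD per child\n", x$delta_cost))
  cat(sprintf("  delta effect %8.4f diagnosed severe cases per child\n",
              x$delta_effect))
  if (x$status %in% c("icer", "dominant", "dominated")) {
    if (!is.na(x$icer)) {
      cat(sprintf("  ICER         %8.2f USD per extra diagnosed severe case\n",
                  x$icer))
    }
    if (x$status != "icer") cat("  status      ", x$status, "\n")
  } else {
    cat("  status       equal_effect (no ratio defined)\n")
  }
  invisible(x)
}

#' Serialize a model to JSON
#'
#' Writes the tree document (strategies, nested nodes, branch
#' expressions, payoffs) so a model can be archived next to its
#' results.
#'
#' @param model a `cea_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "cea_model"))
  strip <- function(node) {
    if (node$kind == "terminal") {
      list(kind = "terminal", label = node$label, cost = node$cost,
           effect = node$effect)
    } else {
      list(kind = "chance", label = node$label,
           branches = lapply(node$branches, function(b) {
             prob <- if (inherits(b$prob, "cea_prob")) {
               list(param = b$prob$param, complement = b$prob$complement)
             } else {
               list(constant = b$prob)
             }
             list(prob = prob, node = strip(b$node))
           }))
    }
  }
  doc <- list(effect_definition = model$effect_definition,
              strategies = lapply(model$strategies, strip))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
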