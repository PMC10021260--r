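# Independent oracles used across the suite.

# Brute-force path enumeration: collects every root-to-leaf path with its
# probability and payoffs, then sums probability-weighted payoffs.  Kept
# structurally separate from the package's expected-value recursion.
enumerate_paths <- function(node, assignment) {
  paths <- list()
  walk <- function(n, prob_so_far) {
    if (n$kind == "terminal") {
      cost <- if (is.character(n$cost)) assignment[[n$cost]] else n$cost
      paths[[length(paths) + 1]] <<- c(prob = prob_so_far, cost = cost,
                                       effect = n$effect)
      return(invisible(NULL))
    }
    for (b in n$branches) {
      p <- if (inherits(b$prob, "cea_prob")) {
        v <- assignment[[b$prob$param]]
        if (b$prob$complement) 1 - v else v
      } else {
        b$prob
      }
      walk(b$node, prob_so_far * p)
    }
  }
  walk(node, 1)
  do.call(rbind, paths)
}

oracle_expectation <- function(node, assignment = list()) {
  tab <- enumerate_paths(node, assignment)
  list(cost = sum(tab[, "prob"] * tab[, "cost"]),
       effect = sum(tab[, "prob"] * tab[, "effect"]),
       leaf_costs = tab[, "cost"])
}

# Random tree with numeric branch probabilities and payoffs, depth <= max_depth.
random_tree <- function(max_depth) {
  build <- function(depth) {
    if (depth >= max_depth || stats::runif(1) < 0.35) {
      return(terminal_node("leaf", cost = stats::runif(1, 0, 100),
                           effect = stats::rbinom(1, 1, 0.5)))
    }
    k <- sample(2:3, 1)
    w <- stats::runif(k)
    probs <- w / sum(w)
    chance_node("node", lapply(seq_len(k), function(i) {
      branch(probs[i], build(depth + 1))
    }))
  }
  # force at least one chance level
  k <- sample(2:3, 1)
  w <- stats::runif(k)
  probs <- w / sum(w)
  chance_node("root", lapply(seq_len(k), function(i) {
    branch(probs[i], build(1))
  }))
}

# Annual-equivalent cost via the discounted-payment definition: the annual
# amount whose discounted sum over the lifetime repays the purchase price.
oracle_annual_equivalent <- function(price, n, r) {
  discount_sum <- sum((1 + r)^-(seq_len(n)))
  price / discount_sum
}

# Hand-expanded expectations of the canonical two-strategy tree.
oracle_strategy_expectation <- function(p, sens, spec, c_sev, c_non,
                                        effect = c("true_positive",
                                                   "any_severe_diagnosis")) {
  effect <- match.arg(effect)
  e <- if (effect == "true_positive") p * sens else p
  list(cost = p * c_sev + (1 - p) * c_non, effect = e)
}
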