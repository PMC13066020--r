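# Small fixture networks built in code.

# single node with constant-TRUE rule and given activation probability
const_net <- function(p = 1) {
  boolean_network(list(A = rule_const(TRUE)), c(A = p))
}

# negation oscillator
oscillator_net <- function() {
  boolean_network(list(A = rule_not(rule_var("A"))))
}

# A = TRUE (poly p), B = A
relay_net <- function(p = 0.5) {
  boolean_network(list(A = rule_const(TRUE), B = rule_var("A")), c(A = p))
}

# three-node chain A -> B -> C with stochastic source
chain_net <- function(p = 0.6) {
  boolean_network(list(A = rule_const(TRUE), B = rule_var("A"), C = rule_var("B")),
                  c(A = p))
}

akt_rule <- function() {
  rule_and(rule_var("PDK1"), rule_not(rule_or(rule_var("CASP3"), rule_var("PP2A"))))
}

# binomial 3-standard-error band with continuity correction
mc_tol <- function(p, reps) 3 * sqrt(p * (1 - p) / reps) + 1.5 / reps
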