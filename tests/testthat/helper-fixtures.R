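# Small deterministic fixtures shared across test files.

# a hand-built truth table with known Kis fractions
makeTinyTruth <- function() {
  GeneTruth(gene_id = c("gA", "gB", "gC"),
            tr_wt = c(10, 5, 2),
            kd_cls = c(0.4, 0.1, 0.25),   # f = 0.6, 0.5, 0
            kd_kis = c(0.6, 0.1, 0),
            kd_exo = c(0.2, 0.05, 0.1))
}

# noiseless kinetics tables for a WT/mutant pair from a truth table
noiselessKinetics <- function(truth, cond) {
  prof <- applyCondition(truth, cond)
  KineticsTable(prof$gene_id, cond$name,
                TR = prof$tr, RA = prof$tr / prof$kd)
}

# independent log-linear regression oracle: slope and intercept from the
# textbook covariance formulas, no lm()
slopeOracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sum((x - mx)^2)
}

# exhaustive hypergeometric oracle: distribution of |A  intersect  B| over all
# C(N, b) equally likely draws of B from a universe of size N
enumOverlapP <- function(a, b, N, k) {
  universe <- seq_len(N)
  setsB <- utils::combn(N, b, simplify = FALSE)
  hits <- vapply(setsB, function(B) length(intersect(seq_len(a), B)) >= k,
                 TRUE)
  mean(hits)
}
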