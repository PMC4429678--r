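# Random instance generators shared across tests. All property loops set
# their own seed so runs are reproducible.

table1_models <- function() {
  list(JC = model_preset("act1-jc"), K2P = model_preset("act1-k2p"),
       HKY = model_preset("act1-hky"), GTR = model_preset("act1-gtr"))
}

random_gtr_model <- function() {
  ex <- stats::runif(6, 0.2, 10)
  ex[3] <- 1 # rTG reference
  pi <- stats::runif(4, 0.5, 2)
  substitution_model("GTR", exchangeabilities = ex, frequencies = pi / sum(pi))
}

random_study_model <- function() {
  pool <- table1_models()
  pool[[sample.int(length(pool), 1)]]
}

# Random quartet with per-branch expected lengths bounded by max_len.
random_quartet <- function(model = random_study_model(), max_len = 5) {
  rates <- stats::runif(5, 0.1, 2)
  durs <- stats::runif(5, 0, max_len) / rates
  quartet_tree(durs[1], durs[2], durs[3], durs[4], durs[5],
               lam0 = rates[1], lam1 = rates[2], lam2 = rates[3],
               lam3 = rates[4], lam4 = rates[5], model = model)
}

swap_branches <- function(tree, i, j) {
  # i, j in 1:4 (subtending branch numbers)
  d <- tree$durations; r <- tree$rates
  d[c(i, j) + 1L] <- d[c(j, i) + 1L]
  r[c(i, j) + 1L] <- r[c(j, i) + 1L]
  quartet_tree(d[[1]], d[[2]], d[[3]], d[[4]], d[[5]],
               lam0 = r[[1]], lam1 = r[[2]], lam2 = r[[3]],
               lam3 = r[[4]], lam4 = r[[5]], model = tree$model)
}
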