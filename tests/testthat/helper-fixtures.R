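# shared fixtures and independent oracles

dori_table <- function() door_fixture("dori05_door")
dori_components <- function() door_fixture("dori05_components")

# random 2 x K table with nonempty arms
random_table <- function(K = sample(2:8, 1), n_max = 50) {
  repeat {
    n1 <- sample(2:n_max, 1)
    n2 <- sample(2:n_max, 1)
    a <- as.vector(stats::rmultinom(1, n1, prob = rexp(K)))
    b <- as.vector(stats::rmultinom(1, n2, prob = rexp(K)))
    if (sum(a) >= 1 && sum(b) >= 1)
      return(door_table(rbind(a, b)))
  }
}

# brute-force O(n1*n2) pair counting over expanded participants;
# independent of the closed-form implementation
brute_force_pairs <- function(table) {
  K <- ncol(table)
  x <- rep(seq_len(K), times = as.numeric(table[1, ]))
  y <- rep(seq_len(K), times = as.numeric(table[2, ]))
  wins <- 0
  ties <- 0
  for (xi in x) {
    wins <- wins + sum(xi < y)
    ties <- ties + sum(xi == y)
  }
  list(wins = wins, ties = ties, losses = length(x) * length(y) - wins - ties,
       total = length(x) * length(y))
}

# write a small patient-level CSV and return its path
write_patient_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# strip class/scheme/dimnames, keep the 2 x K numbers
bare <- function(tb) matrix(as.numeric(unclass(tb)), nrow = nrow(tb))

arm_sizes <- function(data) as.integer(table(data$records$arm))
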