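# shared fixtures: everything is generated in code at test time

pop_sigma <- function() population_sigma()

# build a 2-item ordinal_data with exactly the given m x m count table
dataset_from_table <- function(tab) {
  m <- nrow(tab)
  codes <- NULL
  for (a in seq_len(m))
    for (b in seq_len(m))
      if (tab[a, b] > 0)
        codes <- rbind(codes, matrix(rep(c(a, b), tab[a, b]),
                                     ncol = 2, byrow = TRUE))
  ordinal_data(codes, m = m)
}

# small reproducible study dataset
tiny_data <- function(n = 300, m = 3, seed = 42)
  simulate_ordinal(generation_config(n, m, seed = seed))

quiet_fit <- function(...) suppressWarnings(fit_pml(...))
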