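# Small shared fixtures for diffusion tests.

# a path graph with given genders and uniform spread parameters
path_net <- function(n, genders = rep("M", n)) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  graph_from_adj(A, genders)
}

uniform_params <- function(s, r_male = 0, r_female = 0, ...) {
  diffusion_params(spread_chance = c(mm = s, ff = s, mf = s),
                   resistance_chance = c(male = r_male, female = r_female), ...)
}
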