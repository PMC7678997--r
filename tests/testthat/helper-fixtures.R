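# Shared fixtures: one default acquisition scheme and small builders used
# across test files. Everything is generated in code; no stored data.

the_scheme <- make_gradient_scheme(21, 1000, 2)
the_scheme1 <- make_gradient_scheme(21, 1000, 1)

# noise-free signals for a planted axially symmetric voxel
planted_signal <- function(fa, md, f, axis = c(0, 1, 0), scheme = the_scheme,
                           snr = NULL, seed = 1L) {
  ev <- tensor_from_scalars(fa, md)
  vm <- voxel_model(tensor_from_eigen(ev, axis), fw_fraction = f)
  simulate_bitensor_signal(vm, scheme, snr = snr, seed = seed)
}

# random symmetric positive-definite diffusivity tensor in a realistic range
random_spd_tensor <- function(seed) {
  set.seed(seed)
  L <- matrix(rnorm(9, sd = 0.5), 3, 3)
  D <- L %*% t(L)
  D / sum(diag(D)) * 3 * runif(1, 0.4e-3, 1.2e-3)  # trace -> 3 * MD
}

# exhaustive permutations of 1..n (small n only), for enumeration oracles
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- vector("list", factorial(n))
  k <- 0L
  rec <- function(prefix, rest) {
    if (!length(rest)) { k <<- k + 1L; out[[k]] <<- prefix; return(invisible()) }
    for (i in seq_along(rest)) rec(c(prefix, rest[i]), rest[-i])
  }
  rec(integer(0), seq_len(n))
  out
}

# independent closed-form scalar oracle (kept separate from tensor_scalars)
oracle_scalars <- function(l) {
  md <- (l[1] + l[2] + l[3]) / 3
  fa <- sqrt(1.5 * ((l[1] - md)^2 + (l[2] - md)^2 + (l[3] - md)^2) /
               (l[1]^2 + l[2]^2 + l[3]^2))
  c(fa = fa, md = md, rd = (l[2] + l[3]) / 2, ad = l[1])
}
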