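# Shared fixtures, built in code.

# the four-object toy instance: d12=1 d13=2 d14=3 d23=4 d24=5 d34=6
d4 <- local({
  D <- matrix(0, 4, 4)
  D[1, 2] <- 1; D[1, 3] <- 2; D[1, 4] <- 3
  D[2, 3] <- 4; D[2, 4] <- 5; D[3, 4] <- 6
  D + t(D)
})

# random squared-Euclidean instance with equal group sizes
random_instance <- function(n, K, P = 3, sd = 1) {
  X <- matrix(rnorm(n * P, sd = sd), n, P)
  list(X = X, D = distance_matrix(X), K = K, sizes = rep(n %/% K, K))
}

# draw n divisible by K from a candidate set
draw_divisible <- function(cands, K) {
  ok <- cands[cands %% K == 0]
  ok[sample.int(length(ok), 1)]
}
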