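# shared fixtures: small demographic models and hand-built genealogies

const_model <- function(ne = 1e4, rho = 1e-8, mu = 2.5e-8)
  demographic_model(ne = ne, rho = rho, mu = mu)

two_epoch_model <- function(ne = c(1000, 2000), split = 100, rho = 1e-8, mu = 2.5e-8)
  demographic_model(ne = ne, epoch_start = c(0, split), rho = rho, mu = mu)

# n = 2 genealogy with given TMRCA
g2 <- function(t) genealogy(parent = c(3L, 3L, NA), time = c(0, 0, t))

# n = 3 caterpillar: (1,2) merge at t1, root at t2
g3 <- function(t1, t2) genealogy(parent = c(4L, 4L, 5L, 5L, NA),
                                 time = c(0, 0, 0, t1, t2))

# n = 4 with cherries (1,2) at t1 and (3,4) at t2, root at t3
g4 <- function(t1 = 1000, t2 = 2000, t3 = 5000)
  genealogy(parent = c(5L, 5L, 6L, 6L, 7L, 7L, NA),
            time = c(0, 0, 0, 0, t1, t2, t3))

# all fully-observed non-wildtype patterns over n haplotypes
all_patterns <- function(n) {
  m <- as.matrix(expand.grid(rep(list(0:1), n)))
  m[rowSums(m) > 0, , drop = FALSE]
}
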