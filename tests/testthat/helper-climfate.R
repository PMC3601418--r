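# shared fixtures built in code

small_grid <- function() {
  chemspace_grid(logKOA_min = 6, logKOA_max = 10, logKAW_min = -4,
                 logKAW_max = 0, step = 2)
}

# a hand-assembled fate system with one compartment (closed form f = E/D)
one_box_system <- function(D_deg = 2, D_removal = 0, E = 10,
                           Z = 4e-4, V = 1e6) {
  structure(
    list(
      index = tibble::tibble(region = "R1", medium = "air", i = 1L),
      A = matrix(D_deg + D_removal), transfers = matrix(0),
      D_deg = D_deg, D_removal = D_removal,
      Z_bulk = Z, Z_water = Z, volumes = V, emissions = E
    ),
    class = "fate_system"
  )
}

# random n-compartment exchange system (gains/losses consistent by construction)
random_system <- function(n, seed) {
  set.seed(seed)
  Tm <- matrix(0, n, n)
  Tm[upper.tri(Tm) | lower.tri(Tm)] <- runif(n * (n - 1), 0.1, 5)
  D_deg <- runif(n, 0.5, 3)
  D_removal <- runif(n, 0, 1)
  A <- -t(Tm)
  diag(A) <- D_deg + rowSums(Tm) + D_removal
  structure(
    list(
      index = tibble::tibble(region = paste0("R", seq_len(n)),
                             medium = rep("air", n), i = seq_len(n)),
      A = A, transfers = Tm, D_deg = D_deg, D_removal = D_removal,
      Z_bulk = rep(4e-4, n), Z_water = rep(4e-4, n),
      volumes = runif(n, 1e5, 1e7), emissions = runif(n, 0, 20)
    ),
    class = "fate_system"
  )
}
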