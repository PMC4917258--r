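# shared fixtures for the test suite

default_params <- cell_params()

# a state vector with all gates partly open and realistic Ca, used to probe
# current formulas away from trivial corners
probe_state <- function(V = -20, gate = 0.5, params = default_params) {
  st <- initial_state(params)
  st[["V"]] <- V
  st[2:18] <- gate
  st
}

# random admissible states for property-style loops
random_states <- function(n, seed = 42, params = default_params) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    st <- initial_state(params)
    st[["V"]] <- runif(1, -100, 60)
    st[2:18] <- runif(17)
    st[["Ca_tot_i"]] <- runif(1, 1e-3, 2e-2)
    st[["Ca_NSR"]] <- runif(1, 0.2, 1.2)
    st[["Ca_tot_JSR"]] <- runif(1, 2, 20)
    ry <- runif(3); ry <- ry / sum(ry) * runif(1, 0.5, 1)
    st[c("RyR_R", "RyR_O", "RyR_I")] <- ry
    st
  })
}

# small 1D strip grid for fast tissue checks
strip_grid <- function(nx = 128, ny = 3) {
  build_monolayer(nx = nx, ny = ny, shape = "square")
}

E_K <- nernst_potential(1, default_params$K_o, default_params$K_i,
                        default_params$T)
E_Na <- nernst_potential(1, default_params$Na_o, default_params$Na_i,
                         default_params$T)
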