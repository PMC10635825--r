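# Shared fixtures built in code.

# Parameter set with effectively inert T-cell kinetics (rates at a tiny
# epsilon; cart_params requires strict positivity) for dosing-subsystem
# closed forms.
kinetics_free_params <- function(f_loss = 9, routing = c(1, 1, 2, 1),
                                 eps = 1e-12) {
  p <- unclass(archetype_params("CR"))
  p[c("mu_m", "mu_e", "r_m", "k_ex",
      "d_m", "d_e1", "d_e2", "d_x")] <- eps
  p["f_loss"] <- f_loss
  p[c("f_tm", "f_te1", "f_te2", "f_tx")] <- routing
  cart_params(p)
}

# Tumor-only parameter set: negligible killing, chosen logistic growth.
tumor_only_params <- function(mu_b = 0.05, b_max = 1e11) {
  p <- unclass(archetype_params("CR"))
  p["k_kill"] <- 1e-15
  p["mu_b"] <- mu_b
  p["b_max"] <- b_max
  cart_params(p)
}

# Hand-built trajectory object for exposure-metric checks.
fake_trajectory <- function(time_days, cart_per_ul,
                            tumor_per_ul = rep(0, length(time_days))) {
  df <- data.frame(time_days = time_days,
                   cart_cells_per_ul = cart_per_ul,
                   tumor_cells_per_ul = tumor_per_ul)
  structure(df, class = c("cart_trajectory", "data.frame"))
}

# Gaussian feature table: first `n_informative` features shifted by `delta`
# (in within-group sd units) in the responder class.
gaussian_feature_table <- function(n_per_class = 20, n_features = 6,
                                   n_informative = 2, delta = 2,
                                   seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  lab <- rep(c(TRUE, FALSE), each = n_per_class)
  X <- matrix(rnorm(n * n_features), n, n_features,
              dimnames = list(NULL, paste0("f", seq_len(n_features))))
  if (n_informative > 0)
    X[lab, seq_len(n_informative)] <-
      X[lab, seq_len(n_informative)] + delta
  feature_table(X, lab)
}
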