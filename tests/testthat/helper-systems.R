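# shared fixtures built in code

probe_grid <- function(n = 200, lo = 0.1, hi = 200) {
  exp(seq(log(lo), log(hi), length.out = n))
}

# a random stable proper SISO transfer function with conjugate pole pairs
random_stable_tf <- function(n_pairs = 2, seed = 1) {
  set.seed(seed)
  poles <- complex(real = -stats::runif(n_pairs, 5, 50),
                   imaginary = stats::runif(n_pairs, 10, 300))
  poles <- c(poles, Conj(poles))
  zeros <- complex(real = -stats::runif(n_pairs - 1, 5, 80),
                   imaginary = stats::runif(n_pairs - 1, 5, 100))
  zeros <- c(zeros, Conj(zeros))
  den <- Re(neuroloop:::poly_from_roots(poles))
  num <- Re(neuroloop:::poly_from_roots(zeros))
  transfer_function(num, den, domain = "s")
}

brain_plant_fixture <- function(condition = "pathological", dt = 1e-3) {
  pars <- linear_brain_params(condition)
  model <- build_linear_model(pars)
  list(pars = pars, model = model, plant = discretize(model, dt),
       G = analytic_transfer(model), dt = dt)
}

# one estimation trial on the linear brain model
estimation_trial <- function(seed, input_sd = 0.005, duration = 30,
                             fit = fit_config()) {
  pars <- linear_brain_params()
  u <- white_noise_input(duration, sd = input_sd, seed = seed * 1000 + 1)
  y0 <- simulate_linear_brain(pars, duration, seed = seed * 1000 + 100)
  y <- simulate_linear_brain(pars, duration, input = u, seed = seed * 1000 + 200)
  Py0 <- welch_psd(y0); Py <- welch_psd(y); Pu <- welch_psd(u)
  gs <- extract_gain(Py, Py0, Pu)
  list(gain = gs, fit = magnitude_vector_fit(gs, fit),
       ar = amplitude_ratio(Py, Py0), psd = list(y = Py, y0 = Py0, u = Pu))
}
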