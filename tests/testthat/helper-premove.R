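# Shared fixtures: cached synthetic sessions, compact montages, and
# independent numerical oracles used across test files.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, maker) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, maker(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 17-channel sensorimotor montage (plus CPz reference and the anterior
# AFp pair) used for fast end-to-end tests.
test_montage <- function() {
  c("F3", "Fz", "F4", "FC1", "FC2", "FCC1h", "FCC2h", "C3", "C1", "Cz",
    "C2", "C4", "CP1", "CP2", "CPz", "AFp1", "AFp2")
}

# 12-channel montage in which exactly C1 and C2 are informative (all other
# channels sit far from the planted effect topographies).
sparse_montage <- function() {
  c("C1", "C2", "F7", "F8", "AF7", "AF8", "P7", "P8", "PO7", "PO8",
    "Fz", "Pz")
}

std_session <- function(snr, n_trials = 140, seed = 101,
                        channels = test_montage(), ...) {
  key <- paste("ses", snr, n_trials, seed, length(channels),
               paste(c(...), collapse = "_"), sep = "_")
  cache_get(key, function() {
    generate_session(synth_config(channel_names = channels,
                                  n_trials = n_trials, effect_snr = snr,
                                  seed = seed, ...))
  })
}

# Standard preprocessing used in tests: epoch, CPz reference, baseline.
prep_epochs <- function(ses, pre = 1.0, post = 0.4, ref = "CPz") {
  ep <- extract_epochs(ses$recording, pre, post)
  if (!is.null(ref)) ep <- rereference(ep, ref)
  baseline_correct(ep)
}

# One balanced 80/20 split -> held-out accuracy with the ICA backend.
quick_accuracy <- function(ep, window = window_spec(-150, 150),
                           split_seed = 2, fit_seed = 1, M = 30) {
  split <- prepare_datasets(ep$labels, 0.2, seed = split_seed)
  train <- select_trials(ep, split$train_idx)
  test <- select_trials(ep, split$test_idx)
  fm <- suppressWarnings(fit_feature_ica(train, window, M = M,
                                         seed = fit_seed))
  clf <- fit_logistic_cv(ica_features(train, fm), ep$labels[split$train_idx],
                         seed = fit_seed)
  evaluate_classifier(clf, ica_features(test, fm),
                      ep$labels[split$test_idx])$accuracy
}

# Epochs of pure channel noise with given labels (bookkeeping tests).
noise_epochs <- function(n_trials, channels, n_times = 61, fs = 1000,
                         labels = NULL, seed = 1, t0_frac = 0.5) {
  set.seed(seed)
  pre_n <- round(n_times * t0_frac)
  times <- ((1:n_times) - pre_n) / fs * 1000
  data <- array(rnorm(n_trials * length(channels) * n_times),
                c(n_trials, length(channels), n_times))
  eeg_epochs(data, times, fs, channels, labels)
}

# --- independent oracles -------------------------------------------------

# Moore-Penrose pseudoinverse via SVD.
pinv <- function(A, tol = 1e-12) {
  s <- svd(A)
  keep <- s$d > max(s$d) * tol
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Full-batch proximal-gradient minimizer of
#   mean logistic loss + lambda * (alpha*|w|_1 + (1-alpha)/2*|w|_2^2),
# intercept unpenalized. Independent of the coordinate-descent path used
# by the package.
prox_logistic <- function(x, y01, lambda, alpha, max_iter = 2e5,
                          tol = 1e-11) {
  n <- nrow(x); p <- ncol(x)
  xb <- cbind(1, x)
  L <- max(eigen(crossprod(xb) / (4 * n), symmetric = TRUE,
                 only.values = TRUE)$values) + lambda * (1 - alpha)
  step <- 1 / L
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  w <- rep(0, p); b <- 0
  for (i in seq_len(max_iter)) {
    eta <- drop(b + x %*% w)
    mu <- 1 / (1 + exp(-eta))
    gw <- drop(crossprod(x, mu - y01)) / n + lambda * (1 - alpha) * w
    gb <- mean(mu - y01)
    w_new <- soft(w - step * gw, step * lambda * alpha)
    b_new <- b - step * gb
    if (max(abs(c(w_new - w, b_new - b))) < tol) {
      return(list(weights = w_new, intercept = b_new, iterations = i))
    }
    w <- w_new; b <- b_new
  }
  list(weights = w, intercept = b, iterations = max_iter)
}

# 95% binomial confidence band around chance for n Bernoulli trials.
chance_band <- function(n) 0.5 + c(-1, 1) * 1.96 * sqrt(0.25 / n)

# Evaluated-set-size ladder of the greedy schedule (+1 to 5, +3 to 30,
# +5 after), stated independently of the implementation.
premove_schedule_sizes <- function(n_channels) {
  sizes <- integer(0); n <- 0
  while (n < n_channels) {
    b <- if (n < 5) 1 else if (n < 30) 3 else 5
    n <- n + min(b, n_channels - n)
    sizes <- c(sizes, n)
  }
  sizes
}

# Seeded label permutation (for permutation-null checks).
with_seed_labels <- function(labels, seed) {
  set.seed(seed)
  sample(labels)
}
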