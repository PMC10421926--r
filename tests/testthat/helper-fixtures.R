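# Shared tiny fixtures; built in code, cached per test run.

.fixture_env <- new.env(parent = emptyenv())

tiny_cohort <- function(n = 40, t_max = 5, seed = 5, ...) {
  key <- paste("cohort", n, t_max, seed, sep = "-")
  if (is.null(.fixture_env[[key]])) {
    g <- generate_cohort(toy_config(n_patients = n, t_max = t_max,
                                    seed = seed, ...))
    .fixture_env[[key]] <- g
  }
  .fixture_env[[key]]
}

# Worked-example normalizer: unique values (1, 2, 3) at ratios (.1, .7, .2)
worked_example_params <- function() {
  fit_normalizer(c(1, rep(2, 7), 3, 3))
}

# A small fully trained model, shared across test files (trained once).
tiny_model <- function() {
  if (is.null(.fixture_env$model)) {
    g <- tiny_cohort(n = 80, t_max = 5, seed = 7)
    cfg <- training_config(d_e = 12, hidden = 16, epochs = 10,
                           batch_size = 40, lr = 5e-3, gan_hidden = 32,
                           gan_epochs = 30, gan_batch = 64, gan_lr = 3e-4,
                           cat_epochs = 250, seed = 7)
    .fixture_env$model <- suppressWarnings(
      train_ehr_generator(g$data, g$masks, cfg))
    .fixture_env$model_train <- g
  }
  list(model = .fixture_env$model, train = .fixture_env$model_train)
}

# Finite-difference gradient check over randomly sampled coordinates of a
# nested parameter list. Returns the worst relative error.
fd_worst_err <- function(f_loss, params, grads, n_checks = 15, h = 1e-6) {
  paths <- list()
  walk <- function(p, path) {
    if (is.list(p)) for (nm in seq_along(p)) walk(p[[nm]], c(path, nm))
    else for (j in seq_along(p)) paths[[length(paths) + 1]] <<- c(path, j)
  }
  walk(params, integer(0))
  pick <- sample(length(paths), min(n_checks, length(paths)))
  getp <- function(p, path) {
    for (k in path[-length(path)]) p <- p[[k]]
    p[path[length(path)]]
  }
  setp <- function(p, path, val) {
    if (length(path) == 1L) { p[path] <- val; return(p) }
    p[[path[1]]] <- setp(p[[path[1]]], path[-1], val)
    p
  }
  worst <- 0
  for (i in pick) {
    pa <- paths[[i]]
    v0 <- getp(params, pa)
    num <- (f_loss(setp(params, pa, v0 + h)) -
              f_loss(setp(params, pa, v0 - h))) / (2 * h)
    ana <- getp(grads, pa)
    worst <- max(worst, abs(num - ana) / max(1e-6, abs(num) + abs(ana)))
  }
  worst
}
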