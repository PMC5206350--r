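## Shared fixtures, built once per test run.

## Small noisy experiment: full 2x2 design, 2 tillers in 1 chamber per cell.
tiny_config <- function(...) {
  args <- utils::modifyList(list(n_tillers = 2, n_chambers = 1, seed = 11),
                            list(...))
  do.call(generator_config, args)
}

fixture_noisy <- generate_experiment(tiny_config())

## Deterministic (zero-noise) experiment on the exact ruler grid.
fixture_clean <- generate_experiment(
  tiny_config(n_tillers = 1, length_cv = 0, timing_sd = 0))

## Zero-noise with a continuous (unrounded) ruler.
fixture_exact <- generate_experiment(
  tiny_config(n_tillers = 1, length_cv = 0, timing_sd = 0,
              measurement_resolution = 0))

quiet_recon <- function(obs, dis, ...) {
  suppressWarnings(suppressMessages(reconstruct_experiment(obs, dis, ...)))
}

timecourse_curve <- function() sigmoid_curve(1, 1.82, 1.81)
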